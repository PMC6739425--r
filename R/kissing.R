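#' Hairpin loops of a nested structure
#'
#' A hairpin loop is the maximal unpaired run `i+1 .. j-1` under a closing
#' pair `(i, j)` that encloses no other pair.
#'
#' @param structure A [secondary_structure()] (nested layer only is used).
#' @return Data frame with columns `start`, `end`, `closing_i`, `closing_j`.
#' @export
#' @examples
#' hairpin_loops(parse_dotbracket("(((...)))"))
hairpin_loops <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  pr <- structure$pairs
  pr <- pr[pr$layer == "nested", , drop = FALSE]
  out <- list()
  for (p in seq_len(nrow(pr))) {
    i <- pr$i[p]; j <- pr$j[p]
    if (j - i < 2L) next
    inner <- (i + 1L):(j - 1L)
    if (all(structure$pt[inner] == 0L))
      out[[length(out) + 1L]] <- c(i + 1L, j - 1L, i, j)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      closing_i = integer(), closing_j = integer()))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start = m[, 1L], end = m[, 2L],
             closing_i = m[, 3L], closing_j = m[, 4L])
}

#' Scan parameters for kissing-loop discovery
#'
#' @param k Motif length scanned in each hairpin loop (default 5, the GUGAG
#'   scale).
#' @param min_distance Minimum sequence separation (nt) between the loop
#'   window and a candidate repeat (default 100; kissing partners are
#'   long-range).
#' @param allow_wobble Accept G-U wobble pairs (default `TRUE`; forced by
#'   natural kissing interactions such as the G370-U869 wobble).
#' @param max_unpaired_violations How many candidate-repeat positions may be
#'   paired in the input structure (default 0: the repeat must be fully
#'   single-stranded).
#' @param max_mismatches Allowed non-pairing positions in a register
#'   (default 0).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(k = 5L, min_distance = 100L, allow_wobble = TRUE,
                        max_unpaired_violations = 0L, max_mismatches = 0L) {
  stopifnot(k >= 3L, min_distance >= 0L, max_unpaired_violations >= 0L,
            max_mismatches >= 0L)
  structure(list(k = as.integer(k), min_distance = as.integer(min_distance),
                 allow_wobble = allow_wobble,
                 max_unpaired_violations = as.integer(max_unpaired_violations),
                 max_mismatches = as.integer(max_mismatches)),
            class = "scan_params")
}

# pair type of loop base x facing repeat base y: "WC", "wobble" or NA
pair_type_of <- function(x, y, allow_wobble = TRUE) {
  ifelse(wc_partner[x] == y, "WC",
         ifelse(allow_wobble & !is.na(wobble_partner[x]) &
                  wobble_partner[x] == y, "wobble", NA))
}

#' Scan for kissing-loop registers
#'
#' Slides a `k`-window over every hairpin loop of the input structure and
#' searches all distal single-stranded `k`-windows for antiparallel
#' complements (Watson-Crick, optionally wobble). Each hit is one pairing
#' register; registers are labeled `TR1..TRn` 5' to 3' along the transcript
#' and registers sharing any loop position are collected into one
#' mutual-exclusivity group (a loop can engage only one partner at a time).
#'
#' @param sequence RNA string.
#' @param structure The matching nested [secondary_structure()].
#' @param params A [scan_params()].
#' @return Data frame of class `kissing_registers` with one row per
#'   register: `label`, `loop_start`, `loop_end`, `repeat_start`,
#'   `repeat_end`, `n_wc`, `n_wobble`, `group`, plus a `pairs` attribute —
#'   a list of per-register data frames `(loop_pos, repeat_pos, type)`.
#' @export
scan_kissing <- function(sequence, structure, params = scan_params()) {
  stopifnot(inherits(structure, "secondary_structure"),
            inherits(params, "scan_params"))
  bases <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]]
  if (length(bases) != structure$length)
    stop("sequence length does not match structure")
  k <- params$k
  n <- length(bases)
  loops <- hairpin_loops(structure)
  unpaired <- structure$pt == 0L
  hits <- list()
  for (li in seq_len(nrow(loops))) {
    ls <- loops$start[li]; le <- loops$end[li]
    if (le - ls + 1L < k) {
      message(sprintf("scan_kissing: loop %d-%d shorter than k=%d, skipped",
                      ls, le, k))
      next
    }
    for (w in ls:(le - k + 1L)) {
      wseq <- bases[w:(w + k - 1L)]
      for (p in seq_len(n - k + 1L)) {
        pe <- p + k - 1L
        # disjoint from the loop window and far enough away
        gap <- if (p > w + k - 1L) p - (w + k - 1L) - 1L
               else if (pe < w) w - pe - 1L else -1L
        if (gap < params$min_distance) next
        viol <- sum(!unpaired[p:pe])
        if (viol > params$max_unpaired_violations) next
        ty <- pair_type_of(wseq, rev(bases[p:pe]), params$allow_wobble)
        mism <- sum(is.na(ty))
        if (mism > params$max_mismatches) next
        hits[[length(hits) + 1L]] <-
          list(loop_start = w, repeat_start = p, types = ty)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(label = character(), loop_start = integer(),
                      loop_end = integer(), repeat_start = integer(),
                      repeat_end = integer(), n_wc = integer(),
                      n_wobble = integer(), group = integer())
    attr(out, "pairs") <- list()
    class(out) <- c("kissing_registers", "data.frame")
    return(out)
  }
  tab <- data.frame(
    loop_start = vapply(hits, function(h) as.integer(h$loop_start), integer(1)),
    repeat_start = vapply(hits, function(h) as.integer(h$repeat_start),
                          integer(1)))
  ord <- order(tab$repeat_start, tab$loop_start)
  tab <- tab[ord, , drop = FALSE]
  hits <- hits[ord]
  tab$loop_end <- tab$loop_start + k - 1L
  tab$repeat_end <- tab$repeat_start + k - 1L
  pair_list <- lapply(hits, function(h) {
    data.frame(loop_pos = h$loop_start + 0:(k - 1L),
               repeat_pos = h$repeat_start + (k - 1L):0,
               type = h$types, row.names = NULL)
  })
  tab$n_wc <- vapply(pair_list, function(p) sum(p$type == "WC", na.rm = TRUE),
                     integer(1))
  tab$n_wobble <- vapply(pair_list,
                         function(p) sum(p$type == "wobble", na.rm = TRUE),
                         integer(1))
  # exclusivity groups: connected components of shared loop positions
  m <- nrow(tab)
  grp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      share <- tab$loop_start[a] <= tab$loop_end[b] &&
        tab$loop_start[b] <= tab$loop_end[a]
      if (share && grp[b] != grp[a]) {
        grp[grp == grp[b]] <- grp[a]; changed <- TRUE
      }
    }
    if (!changed || m < 2L) break
  }
  tab$group <- match(grp, unique(grp))
  tab$label <- paste0("TR", seq_len(m))
  out <- tab[, c("label", "loop_start", "loop_end", "repeat_start",
                 "repeat_end", "n_wc", "n_wobble", "group")]
  rownames(out) <- NULL
  attr(out, "pairs") <- pair_list
  class(out) <- c("kissing_registers", "data.frame")
  out
}

#' Annotate kissing registers on a structure as a pseudoknot layer
#'
#' @param structure A nested [secondary_structure()].
#' @param registers A `kissing_registers` frame from [scan_kissing()].
#' @param which Row index of the register to annotate (kissing registers of
#'   one group are mutually exclusive, so exactly one is drawn).
#' @return A [secondary_structure()] with the register's pairs on the
#'   pseudoknot layer.
#' @export
annotate_pseudoknot <- function(structure, registers, which = 1L) {
  prs <- attr(registers, "pairs")[[which]]
  prs <- prs[!is.na(prs$type), , drop = FALSE]
  all_pairs <- rbind(
    cbind(structure$pairs$i, structure$pairs$j),
    cbind(pmin(prs$loop_pos, prs$repeat_pos),
          pmax(prs$loop_pos, prs$repeat_pos)))
  layer <- c(structure$pairs$layer, rep("pseudoknot", nrow(prs)))
  secondary_structure(structure$length, all_pairs, layer = layer)
}

#' Design the compensatory (rescue) substitution for a loop mutation
#'
#' Given a pairing register and a point mutation in the loop, returns the
#' unique repeat-side substitution that restores a Watson-Crick pair with
#' the mutated base — the double-mutant design that validates a kissing
#' interaction in vivo (e.g. loop G-to-C rescued by repeat U-to-G).
#'
#' @param register One row of a `kissing_registers` frame (with its pair
#'   list attached via the `pairs` attribute of the parent frame, or pass
#'   the parent frame plus `which`).
#' @param registers A `kissing_registers` frame.
#' @param which Row index of the register.
#' @param position Loop position of the mutation (transcript coordinates).
#' @param from,to Original and mutated loop base.
#' @return A one-row data frame `(position, from, to)` with the repeat-side
#'   substitution, or `NULL` when the loop position is unpaired in this
#'   register.
#' @export
#' @examples
#' # enumerate over a group's registers to obtain one double mutant each
design_compensatory <- function(registers, which, position, from, to) {
  prs <- attr(registers, "pairs")[[which]]
  row <- prs[prs$loop_pos == position, , drop = FALSE]
  if (!nrow(row)) stop("position is not inside this register's loop window")
  if (is.na(row$type)) return(NULL)
  to <- toupper(to)
  partner <- unname(wc_partner[to])
  if (is.na(partner)) stop("mutated base must be one of ACGU")
  data.frame(position = row$repeat_pos,
             from = NA_character_, to = partner,
             stringsAsFactors = FALSE)
}

#' Design all compensatory double mutants for one loop mutation
#'
#' Applies [design_compensatory()] across every register of the frame,
#' yielding one double mutant per register (six registers give six double
#' mutants, the full rescue panel).
#'
#' @param registers A `kissing_registers` frame.
#' @param position,from,to The loop point mutation.
#' @param sequence Optional sequence used to fill the repeat `from` base.
#' @return Data frame with one row per register: `register`, `loop_position`,
#'   `loop_from`, `loop_to`, `repeat_position`, `repeat_from`, `repeat_to`,
#'   `construct`.
#' @export
design_rescue_panel <- function(registers, position, from, to,
                                sequence = NULL) {
  bases <- if (!is.null(sequence))
    strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]] else NULL
  rows <- list()
  for (w in seq_len(nrow(registers))) {
    d <- design_compensatory(registers, w, position, from, to)
    if (is.null(d)) next
    rfrom <- if (!is.null(bases)) bases[d$position] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      register = registers$label[w], loop_position = position,
      loop_from = toupper(from), loop_to = toupper(to),
      repeat_position = d$position, repeat_from = rfrom, repeat_to = d$to,
      construct = sprintf("%s%d%s/%s%d%s", toupper(from), position,
                          toupper(to), rfrom %||% "N", d$position, d$to),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Tandem-repeat conservation across an alignment
#'
#' Counts, per species, how many degapped windows complement the motif
#' (antiparallel, wobble-aware), and flags species meeting a minimum count
#' — the test that homologs retain enough tandem repeats to form the
#' kissing interaction (at least three in all mammalian MEG3 homologs).
#'
#' @param alignment A list with `sequences` (gapped rows), as returned by
#'   [read_stockholm()] or [simulate_alignment()].
#' @param motif Ungapped motif string (default `"GUGAG"`).
#' @param min_count Minimum repeats required to pass (default 3).
#' @param allow_wobble Accept wobble complements (default `TRUE`).
#' @return Data frame: `species`, `count`, `pass`.
#' @export
repeat_conservation <- function(alignment, motif = "GUGAG", min_count = 3L,
                                allow_wobble = TRUE) {
  sq <- alignment$sequences
  if (!length(sq)) stop("empty alignment")
  mb <- strsplit(toupper(motif), "")[[1L]]
  k <- length(mb)
  counts <- vapply(sq, function(row) {
    b <- strsplit(gsub("-", "", chartr("T", "U", toupper(row))), "")[[1L]]
    if (length(b) < k) return(0L)
    hits <- 0L
    for (p in seq_len(length(b) - k + 1L)) {
      ty <- pair_type_of(mb, rev(b[p:(p + k - 1L)]), allow_wobble)
      if (!anyNA(ty)) hits <- hits + 1L
    }
    hits
  }, integer(1))
  data.frame(species = names(sq), count = unname(counts),
             pass = unname(counts >= min_count), row.names = NULL)
}

#' Covariation support for base pairs in an alignment
#'
#' For each tested column pair, reports the fraction of rows forming a
#' canonical (Watson-Crick or wobble) pair, the number of compensatory
#' double substitutions (rows canonical but differing from the modal pair
#' at both columns), a combined score
#' `fraction_canonical + weight * compensatory_fraction`, and a permutation
#' E-value: columns are shuffled independently (preserving per-column
#' composition), the score recomputed `n_perm` times, and the E-value is
#' the expected number of tested pairs with a null score at least as large
#' — a simplified permutation-null stand-in for dedicated covariation
#' statistics.
#'
#' @param alignment A list with `sequences` and optionally `ss_cons`.
#' @param pairs Two-column matrix/data frame of column pairs to test;
#'   defaults to the pairs annotated in `ss_cons`.
#' @param weight Weight of the compensatory fraction in the score
#'   (default 2).
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer seed for the permutation null.
#' @return Data frame of class `pair_covariation`: `i`, `j`,
#'   `fraction_canonical`, `n_compensatory`, `score`, `evalue`.
#' @export
covariation <- function(alignment, pairs = NULL, weight = 2, n_perm = 200L,
                        seed = 1L) {
  sq <- alignment$sequences
  if (!length(sq)) stop("empty alignment")
  rows <- do.call(rbind, strsplit(chartr("T", "U", toupper(sq)), ""))
  ncol_aln <- ncol(rows)
  if (is.null(pairs)) {
    if (is.null(alignment$ss_cons))
      stop("no pairs given and no consensus structure in the alignment")
    st <- parse_dotbracket(alignment$ss_cons)
    pairs <- as.matrix(st$pairs[, c("i", "j")])
  }
  pairs <- as.matrix(pairs)
  if (any(pairs < 1L | pairs > ncol_aln))
    stop("tested pair column outside the alignment")
  score_pair <- function(a, b) {
    ok <- a != "-" & b != "-"
    if (!any(ok)) return(c(frac = 0, comp = 0, score = 0))
    a <- a[ok]; b <- b[ok]
    canon <- !is.na(pair_type_of(a, b, allow_wobble = TRUE))
    duo <- paste0(a, b)
    modal <- names(sort(table(duo), decreasing = TRUE))[1L]
    comp <- sum(canon & a != substr(modal, 1L, 1L) &
                  b != substr(modal, 2L, 2L))
    frac <- mean(canon)
    c(frac = frac, comp = comp, score = frac + weight * comp / length(a))
  }
  obs <- t(apply(pairs, 1L, function(p)
    score_pair(rows[, p[1L]], rows[, p[2L]])))
  null_ge <- numeric(nrow(pairs))
  with_seed(seed, {
    nr <- nrow(rows)
    for (b in seq_len(n_perm)) {
      for (p in seq_len(nrow(pairs))) {
        a1 <- rows[sample(nr), pairs[p, 1L]]
        a2 <- rows[sample(nr), pairs[p, 2L]]
        s <- score_pair(a1, a2)["score"]
        if (s >= obs[p, "score"]) null_ge[p] <- null_ge[p] + 1L
      }
    }
  })
  evalue <- null_ge / n_perm * nrow(pairs)
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                    fraction_canonical = obs[, "frac"],
                    n_compensatory = as.integer(obs[, "comp"]),
                    score = obs[, "score"], evalue = evalue)
  class(out) <- c("pair_covariation", "data.frame")
  out
}
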