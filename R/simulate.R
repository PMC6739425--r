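# Seeded generators for every input class the pipeline consumes: synthetic
# transcript cores with planted kissing-loop architecture, structure-
# conditioned reactivity profiles, mutational-profiling counts, star-phylogeny
# alignments with planted covariation, AFM-like particle topographies, and
# Hill-shaped Mg2+ titration curves.

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

BASES <- c("A", "C", "G", "U")

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")
wobble_partner <- c(G = "U", U = "G")

# TRUE when loop base x (5'->3') can pair antiparallel repeat base y
can_pair_bases <- function(x, y, wobble = TRUE) {
  wc <- wc_partner[x] == y
  if (!wobble) return(wc & !is.na(wc))
  wob <- !is.na(wobble_partner[x]) & wobble_partner[x] == y
  (wc & !is.na(wc)) | wob
}

#' Layout of a synthetic transcript core with planted kissing-loop repeats
#'
#' Describes the architecture the generator plants: a helix plan (list of
#' stems), one hairpin loop carrying a conserved motif (default `GUGAG`,
#' echoing the H11 terminal loop of MEG3), and a distal single-stranded
#' region carrying `n_repeats` tandem repeats, each the antiparallel
#' (wobble-aware) complement of the motif — the architecture of the
#' H11-H27 tandem-repeat kissing loops.
#'
#' @param total_length Core length in nt.
#' @param stems Data frame with columns `start5`, `end5`, `start3`, `end3`:
#'   each stem pairs `start5+t` with `end3-t`. Stems must be non-crossing.
#' @param loop_motif Motif string planted in a hairpin loop (default
#'   `"GUGAG"`).
#' @param motif_loop_position 1-based position of the motif's first base.
#' @param n_repeats Number of planted tandem repeats (default 6).
#' @param repeat_region_start First position of the repeat array.
#' @param repeat_spacing Unpaired spacer length between consecutive repeats.
#' @param wobble_at Integer offsets (1-based within the motif) that pair by
#'   G-U wobble instead of Watson-Crick (default 3: the central G of GUGAG
#'   faces a U, as in the G370-U869 wobble).
#' @return An object of class `core_layout`.
#' @export
core_layout <- function(total_length = 360L,
                        stems = data.frame(
                          start5 = c(20L, 60L, 120L, 180L, 230L),
                          end5   = c(31L, 75L, 135L, 192L, 242L),
                          start3 = c(44L, 86L, 150L, 205L, 255L),
                          end3   = c(55L, 101L, 165L, 217L, 267L)),
                        loop_motif = "GUGAG",
                        motif_loop_position = 78L,
                        n_repeats = 6L,
                        repeat_region_start = 290L,
                        repeat_spacing = 0L,
                        wobble_at = 3L) {
  total_length <- as.integer(total_length)
  stems <- data.frame(start5 = as.integer(stems$start5),
                      end5 = as.integer(stems$end5),
                      start3 = as.integer(stems$start3),
                      end3 = as.integer(stems$end3))
  loop_motif <- toupper(loop_motif)
  k <- nchar(loop_motif)
  n_repeats <- as.integer(n_repeats)
  stopifnot(k >= 3L, n_repeats >= 0L, repeat_spacing >= 0L,
            all(wobble_at >= 1L & wobble_at <= k) || length(wobble_at) == 0L)
  if (any(stems$start5 > stems$end5 | stems$end5 >= stems$start3 |
          stems$start3 > stems$end3))
    stop("malformed stem intervals")
  if (any(stems$end5 - stems$start5 != stems$end3 - stems$start3))
    stop("stem strand lengths differ")
  if (any(stems$start5 < 1L | stems$end3 > total_length))
    stop("stem outside the transcript")
  # build pair list; secondary_structure() validates non-crossing/overlap
  prs <- do.call(rbind, lapply(seq_len(nrow(stems)), function(s) {
    t <- 0:(stems$end5[s] - stems$start5[s])
    cbind(stems$start5[s] + t, stems$end3[s] - t)
  }))
  st <- secondary_structure(total_length, prs)
  motif_iv <- c(motif_loop_position, motif_loop_position + k - 1L)
  loops <- hairpin_loops(st)
  inloop <- which(loops$start <= motif_iv[1L] & loops$end >= motif_iv[2L])
  if (length(inloop) != 1L)
    stop("motif does not lie inside a hairpin loop of the plan")
  rep_len_total <- if (n_repeats > 0L)
    n_repeats * k + (n_repeats - 1L) * repeat_spacing else 0L
  rep_iv <- c(repeat_region_start, repeat_region_start + rep_len_total - 1L)
  if (n_repeats > 0L) {
    if (rep_iv[2L] > total_length) stop("repeat region outside the transcript")
    if (any(st$pt[rep_iv[1L]:rep_iv[2L]] != 0L))
      stop("repeat region is not single-stranded in the plan")
  }
  structure(list(total_length = total_length, stems = stems,
                 loop_motif = loop_motif, k = k,
                 motif_loop_position = as.integer(motif_loop_position),
                 motif_loop = as.integer(loops[inloop, c("start", "end")]),
                 n_repeats = n_repeats,
                 repeat_region_start = as.integer(repeat_region_start),
                 repeat_spacing = as.integer(repeat_spacing),
                 wobble_at = as.integer(wobble_at),
                 structure = st),
            class = "core_layout")
}

# repeat unit complementary (antiparallel, wobble-aware) to the motif
repeat_unit <- function(motif, wobble_at) {
  mb <- strsplit(motif, "")[[1L]]
  k <- length(mb)
  unit <- character(k)
  for (t in seq_len(k)) {
    unit[k + 1L - t] <- if (t %in% wobble_at) {
      if (is.na(wobble_partner[mb[t]]))
        stop("wobble offset on a base without a wobble partner")
      wobble_partner[mb[t]]
    } else wc_partner[mb[t]]
  }
  paste(unit, collapse = "")
}

# naive complement matcher used only by the generator's cleanliness repair:
# returns data.frame(loop_start, ss_start) of all full-length wobble-aware
# antiparallel complements between any k-window of any hairpin loop and any
# disjoint single-stranded k-window
naive_complement_hits <- function(bases, st, k, wobble = TRUE) {
  loops <- hairpin_loops(st)
  ss <- which(st$pt == 0L)
  n <- length(bases)
  ss_starts <- ss[vapply(ss, function(p)
    p + k - 1L <= n && all((p:(p + k - 1L)) %in% ss), logical(1))]
  hits <- list()
  for (li in seq_len(nrow(loops))) {
    ls <- loops$start[li]; le <- loops$end[li]
    if (le - ls + 1L < k) next
    for (w in ls:(le - k + 1L)) {
      wseq <- bases[w:(w + k - 1L)]
      for (p in ss_starts) {
        if (p + k - 1L >= w && p <= w + k - 1L) next       # overlapping
        cand <- bases[p:(p + k - 1L)]
        # antiparallel: loop t faces candidate k+1-t
        if (all(can_pair_bases(wseq, rev(cand), wobble = wobble)))
          hits[[length(hits) + 1L]] <- c(w, p)
      }
    }
  }
  if (!length(hits))
    return(data.frame(loop_start = integer(), ss_start = integer()))
  h <- do.call(rbind, hits)
  data.frame(loop_start = h[, 1L], ss_start = h[, 2L])
}

#' Generate a synthetic transcript core with planted kissing-loop registers
#'
#' Emits a random sequence realizing a [core_layout()]: stem 3' strands are
#' reverse complements of their 5' strands, the motif sits in its hairpin
#' loop, and each tandem repeat is the wobble-aware antiparallel complement
#' of the motif. A repair pass then mutates stray bases so that no
#' *accidental* full complement exists between any hairpin-loop window and
#' any disjoint single-stranded window — the planted registers are exactly
#' the ground truth a scanner should recover at zero noise.
#'
#' @param layout A [core_layout()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list with `sequence`, `structure` (nested
#'   [secondary_structure()]), and `registers` (ground-truth data frame:
#'   `label`, `loop_start`, `loop_end`, `repeat_start`, `repeat_end`).
#' @export
#' @examples
#' core <- gen_core(core_layout(), seed = 1)
#' core$registers$label   # TR1 ... TR6
gen_core <- function(layout = core_layout(), seed) {
  stopifnot(inherits(layout, "core_layout"))
  with_seed(seed, {
    n <- layout$total_length
    k <- layout$k
    st <- layout$structure
    bases <- sample(BASES, n, replace = TRUE)
    # stems: 3' strand mirrors the 5' strand (Watson-Crick)
    pr <- st$pairs
    bases[pr$j] <- wc_partner[bases[pr$i]]
    # motif
    mpos <- layout$motif_loop_position
    bases[mpos:(mpos + k - 1L)] <- strsplit(layout$loop_motif, "")[[1L]]
    # repeats
    unit <- strsplit(repeat_unit(layout$loop_motif, layout$wobble_at), "")[[1L]]
    rep_starts <- integer(0)
    if (layout$n_repeats > 0L) {
      rep_starts <- layout$repeat_region_start +
        (0:(layout$n_repeats - 1L)) * (k + layout$repeat_spacing)
      for (s in rep_starts) bases[s:(s + k - 1L)] <- unit
    }
    planted <- data.frame(loop_start = rep(mpos, length(rep_starts)),
                          ss_start = rep_starts)
    protected <- c(outer(rep_starts, 0:(k - 1L), `+`),
                   mpos:(mpos + k - 1L))
    loops <- hairpin_loops(st)
    loop_pos <- unlist(lapply(seq_len(nrow(loops)), function(i)
      loops$start[i]:loops$end[i]))
    # cleanliness repair: break accidental complements by mutating one base
    # to something that cannot pair the base it faces
    non_pairing_base <- function(facing) {
      ok <- BASES[!can_pair_bases(rep(facing, 4L), BASES)]
      if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    converged <- FALSE
    for (round in 1:200) {
      hits <- naive_complement_hits(bases, st, k)
      extra <- hits[!(paste(hits$loop_start, hits$ss_start) %in%
                        paste(planted$loop_start, planted$ss_start)), ,
                    drop = FALSE]
      if (!nrow(extra)) { converged <- TRUE; break }
      h <- extra[1L, ]
      win <- h$ss_start:(h$ss_start + k - 1L)
      lwin <- h$loop_start:(h$loop_start + k - 1L)
      # a hit dies if either side gains a base that cannot pair its partner
      mutable <- c(setdiff(win, protected),
                   setdiff(intersect(lwin, loop_pos), protected))
      if (!length(mutable))
        stop("cannot repair accidental complement without touching ",
             "planted material")
      p <- if (length(mutable) == 1L) mutable else sample(mutable, 1L)
      facing <- if (p %in% win) {
        bases[h$loop_start + (k - (p - h$ss_start + 1L))]
      } else {
        bases[h$ss_start + (k - (p - h$loop_start + 1L))]
      }
      bases[p] <- non_pairing_base(facing)
    }
    if (!converged) stop("cleanliness repair did not converge")
    registers <- if (length(rep_starts)) {
      data.frame(label = paste0("TR", seq_along(rep_starts)),
                 loop_start = mpos, loop_end = mpos + k - 1L,
                 repeat_start = rep_starts, repeat_end = rep_starts + k - 1L)
    } else {
      data.frame(label = character(), loop_start = integer(),
                 loop_end = integer(), repeat_start = integer(),
                 repeat_end = integer())
    }
    list(sequence = paste(bases, collapse = ""), structure = st,
         registers = registers, layout = layout)
  })
}

#' Random core layouts for property testing
#'
#' Draws a valid [core_layout()] with randomized stem positions, repeat
#' count, spacing and wobble pattern — used to fuzz the closure property
#' that a scanner recovers exactly the planted registers at zero noise.
#'
#' @param seed Integer seed.
#' @return A [core_layout()].
#' @export
random_core_layout <- function(seed) {
  with_seed(seed, {
    k <- 5L
    stem_len <- sample(8:14, 1L)
    loop_len <- sample(k:(k + 4L), 1L)
    s5 <- sample(15:40, 1L)
    e5 <- s5 + stem_len - 1L
    s3 <- e5 + loop_len + 1L
    e3 <- s3 + stem_len - 1L
    # a second, plain hairpin downstream
    g <- sample(10:25, 1L)
    s5b <- e3 + g; e5b <- s5b + 9L; s3b <- e5b + 6L; e3b <- s3b + 9L
    n_rep <- sample(1:6, 1L)
    spacing <- sample(0:3, 1L)
    rep_start <- e3b + sample(110:140, 1L)
    total <- rep_start + n_rep * k + (n_rep - 1L) * spacing +
      sample(10:30, 1L)
    motif_pos <- e5 + 1L + sample(0:(loop_len - k), 1L)
    wob <- sort(sample(c(1L, 3L, 5L), sample(0:2, 1L)))  # G offsets of GUGAG
    core_layout(total_length = total,
                stems = data.frame(start5 = c(s5, s5b), end5 = c(e5, e5b),
                                   start3 = c(s3, s3b), end3 = c(e3, e3b)),
                loop_motif = "GUGAG", motif_loop_position = motif_pos,
                n_repeats = n_rep, repeat_region_start = rep_start,
                repeat_spacing = spacing, wobble_at = wob)
  })
}

#' Noise model for structure-conditioned reactivity simulation
#'
#' Paired positions draw low reactivities, unpaired positions high ones:
#' by default paired ~ Exponential(mean 0.15) and unpaired ~ Gamma(shape 2,
#' scale 0.5), both clipped at 4.0 — reproducing the three-class occupancy
#' pattern of SHAPE data (paired positions mostly below 0.40) without
#' claiming any experiment's actual noise. A fraction of positions is
#' masked as no-data.
#'
#' @param paired_mean Mean of the exponential paired-position distribution.
#' @param unpaired_shape,unpaired_scale Gamma parameters for unpaired
#'   positions.
#' @param nodata_fraction Fraction of positions masked as no-data.
#' @param clip Upper clip for all values.
#' @param constant When `TRUE`, draw no noise at all: paired positions get
#'   exactly `paired_mean` and unpaired ones exactly
#'   `unpaired_shape * unpaired_scale` (a zero-variance, exactly bimodal
#'   profile useful for limiting cases).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(paired_mean = 0.15, unpaired_shape = 2,
                        unpaired_scale = 0.5, nodata_fraction = 0.05,
                        clip = 4.0, constant = FALSE) {
  stopifnot(paired_mean > 0, unpaired_shape > 0, unpaired_scale > 0,
            nodata_fraction >= 0, nodata_fraction < 1)
  if (unpaired_shape * unpaired_scale <= paired_mean)
    stop("expected unpaired value must exceed expected paired value")
  structure(list(paired_mean = paired_mean, unpaired_shape = unpaired_shape,
                 unpaired_scale = unpaired_scale,
                 nodata_fraction = nodata_fraction, clip = clip,
                 constant = constant),
            class = "noise_model")
}

#' Simulate a reactivity profile conditioned on a structure
#'
#' @param structure A [secondary_structure()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A raw [reactivity_profile()].
#' @export
simulate_reactivity <- function(structure, noise = noise_model(), seed) {
  stopifnot(inherits(structure, "secondary_structure"),
            inherits(noise, "noise_model"))
  with_seed(seed, {
    n <- structure$length
    paired <- structure$pt != 0L
    v <- numeric(n)
    if (isTRUE(noise$constant)) {
      v[paired] <- noise$paired_mean
      v[!paired] <- noise$unpaired_shape * noise$unpaired_scale
    } else {
      v[paired] <- stats::rexp(sum(paired), rate = 1 / noise$paired_mean)
      v[!paired] <- stats::rgamma(sum(!paired), shape = noise$unpaired_shape,
                                  scale = noise$unpaired_scale)
    }
    v <- pmin(v, noise$clip)
    if (noise$nodata_fraction > 0) {
      nd <- stats::runif(n) < noise$nodata_fraction
      v[nd] <- NA_real_
    }
    reactivity_profile(v, reagent = "1M7", state = "raw")
  })
}

#' Simulate mutational-profiling counts from a reactivity profile
#'
#' Emulates the MaP readout in which reagent adducts become
#' reverse-transcription mutations: per-position mutation counts are
#' binomial with rate `background + slope * reactivity` in the modified
#' channel and `background` in the untreated channel.
#'
#' @param profile A [reactivity_profile()] (its values set the rates;
#'   no-data positions fall back to background).
#' @param depth Read depth per position and channel.
#' @param slope Reactivity-to-rate slope (default 0.02).
#' @param background Background mutation rate (default 0.002).
#' @param seed Integer seed.
#' @return A [map_counts()].
#' @export
simulate_map_counts <- function(profile, depth, slope = 0.02,
                                background = 0.002, seed) {
  stopifnot(depth >= 0, background >= 0, slope >= 0)
  with_seed(seed, {
    v <- as.numeric(profile)
    v[!is.finite(v)] <- 0
    rate <- background + slope * v
    if (any(rate > 0.5)) stop("mutation rate above 0.5: rescale the slope")
    n <- length(v)
    dm <- rep(depth, n); du <- rep(depth, n)
    mod <- stats::rbinom(n, dm, rate)
    unt <- stats::rbinom(n, du, background)
    map_counts(mod, unt, dm, du)
  })
}

#' Simulate a star-phylogeny alignment with planted covariation
#'
#' Each species descends independently from the core sequence (star
#' phylogeny). Paired columns substitute together: with probability
#' `covary_prob` a substituted pair is replaced by a random canonical pair
#' (a compensatory double substitution), otherwise one side mutates alone.
#' Every species keeps the loop motif and a species-specific number of
#' intact tandem repeats drawn from `repeat_count_range` (mirroring the
#' observation that all mammalian MEG3 homologs retain at least three);
#' repeats beyond that count are scrambled.
#'
#' @param core Output of [gen_core()].
#' @param n_species Number of rows (>= 2).
#' @param sub_prob Per-column substitution probability (default 0.15).
#' @param covary_prob Probability that a paired-column substitution is
#'   compensatory (default 0.9).
#' @param repeat_count_range Integer `c(min, max)` of intact repeats per
#'   species (default `c(3, 6)`).
#' @param seed Integer seed.
#' @return A list with `sequences` (named, ungapped rows), `ss_cons`
#'   (dot-bracket consensus) and attributes `repeat_counts` and
#'   `planted_pairs`; writable with [write_stockholm()].
#' @export
simulate_alignment <- function(core, n_species = 41L, sub_prob = 0.15,
                               covary_prob = 0.9,
                               repeat_count_range = c(3L, 6L), seed) {
  if (n_species < 2L) stop("n_species must be >= 2")
  if (repeat_count_range[1L] < 1L) stop("repeat_count_range min must be >= 1")
  layout <- core$layout
  k <- layout$k
  with_seed(seed, {
    anc <- strsplit(core$sequence, "")[[1L]]
    n <- length(anc)
    prs <- core$structure$pairs
    paired_cols <- c(prs$i, prs$j)
    motif_cols <- layout$motif_loop_position:(layout$motif_loop_position + k - 1L)
    reg <- core$registers
    rep_cols_list <- lapply(seq_len(nrow(reg)), function(t)
      reg$repeat_start[t]:reg$repeat_end[t])
    free_cols <- setdiff(seq_len(n),
                         c(paired_cols, motif_cols, unlist(rep_cols_list)))
    canon <- rbind(c("A", "U"), c("U", "A"), c("G", "C"),
                   c("C", "G"), c("G", "U"), c("U", "G"))
    rc_max <- min(repeat_count_range[2L], nrow(reg))
    rc_min <- min(repeat_count_range[1L], rc_max)
    seqs <- character(n_species)
    rcounts <- integer(n_species)
    for (s in seq_len(n_species)) {
      row <- anc
      # unpaired, unconstrained columns
      mut <- free_cols[stats::runif(length(free_cols)) < sub_prob]
      row[mut] <- vapply(row[mut], function(b)
        sample(setdiff(BASES, b), 1L), character(1))
      # paired columns: compensatory or one-sided
      for (p in seq_len(nrow(prs))) {
        if (stats::runif(1) >= sub_prob) next
        i <- prs$i[p]; j <- prs$j[p]
        if (stats::runif(1) < covary_prob) {
          cur <- paste0(row[i], row[j])
          alt <- canon[paste0(canon[, 1L], canon[, 2L]) != cur, , drop = FALSE]
          pick <- alt[sample(nrow(alt), 1L), ]
          row[i] <- pick[1L]; row[j] <- pick[2L]
        } else {
          side <- sample(c(i, j), 1L)
          row[side] <- sample(setdiff(BASES, row[side]), 1L)
        }
      }
      # repeats: keep the first r intact, scramble the rest
      r <- if (rc_max >= rc_min) sample(rc_min:rc_max, 1L) else 0L
      rcounts[s] <- min(r, length(rep_cols_list))
      if (length(rep_cols_list) > rcounts[s]) {
        for (t in (rcounts[s] + 1L):length(rep_cols_list)) {
          cols <- rep_cols_list[[t]]
          row[cols] <- vapply(row[cols], function(b)
            sample(setdiff(BASES, b), 1L), character(1))
        }
      }
      seqs[s] <- paste(row, collapse = "")
    }
    names(seqs) <- sprintf("species%02d", seq_len(n_species))
    out <- list(sequences = seqs,
                ss_cons = write_dotbracket(core$structure))
    attr(out, "repeat_counts") <- rcounts
    attr(out, "planted_pairs") <- prs[, c("i", "j")]
    out
  })
}

#' Height-map raster with physical pixel size
#'
#' @param heights Numeric matrix of heights in nm (rows = scan lines).
#' @param pixel_size_nm Lateral pixel size in nm/pixel.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm) {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), all(is.finite(heights)), pixel_size_nm > 0)
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px at %.3g nm/px (%.0f nm side)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              ncol(x$heights) * x$pixel_size_nm))
  invisible(x)
}

# flat-topped dome (smoothed disc) centred at (cx, cy) nm with footprint
# diameter d; the tanh edge width approximates tip-broadened particle edges
add_dome <- function(z, xs, ys, cx, cy, d, amp, edge = 2) {
  r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  z + amp * 0.5 * (1 - tanh((r - d / 2) / edge))
}

#' Simulate a single-particle AFM topography
#'
#' Generates a square crop (default 250 nm at 0.98 nm/pixel, the standard
#' single-particle crop) around one synthetic particle in one of three
#' folding states: `compact` — a single flat-topped dome (smoothed disc);
#' `intermediate` — a chain of smaller domes (globular domains connected by
#' linkers) inside an envelope; `denatured` — a thin meandering filament.
#' Particle "diameter" means the full footprint of a dome (the width of its
#' smoothed-disc profile). Additive pixel noise is Gaussian.
#'
#' @param kind `"compact"`, `"intermediate"` or `"denatured"`.
#' @param pixel_size_nm Pixel size (default 0.98 nm).
#' @param crop_nm Crop side (default 250 nm).
#' @param diameter_nm Dome footprint diameter for `compact` (default 65 nm,
#'   the compacted-particle scale).
#' @param n_domes,dome_diameter_nm,envelope_nm `intermediate` parameters:
#'   number of domains (default 3), their footprint (default 30 nm), and
#'   the envelope they span (default 85 nm).
#' @param amplitude_nm Dome height (default 1.5 nm).
#' @param noise_sd_nm Pixel noise standard deviation (default 0.05 nm).
#' @param seed Integer seed.
#' @return A [height_map()].
#' @export
simulate_heightmap <- function(kind = c("compact", "intermediate", "denatured"),
                               pixel_size_nm = 0.98, crop_nm = 250,
                               diameter_nm = 65, n_domes = 3L,
                               dome_diameter_nm = 30, envelope_nm = 85,
                               amplitude_nm = 1.5, noise_sd_nm = 0.05,
                               seed) {
  kind <- match.arg(kind)
  npx <- floor(crop_nm / pixel_size_nm)
  if (npx < 64L) stop("crop must span at least 64 pixels")
  with_seed(seed, {
    xs <- (seq_len(npx) - (npx + 1) / 2) * pixel_size_nm
    ys <- xs
    z <- matrix(0, npx, npx)
    c0 <- stats::runif(2, -0.05, 0.05) * crop_nm  # centre jitter
    if (kind == "compact") {
      z <- add_dome(z, xs, ys, c0[1L], c0[2L], diameter_nm, amplitude_nm)
    } else if (kind == "intermediate") {
      theta <- stats::runif(1, 0, pi)
      span <- envelope_nm - dome_diameter_nm
      offs <- if (n_domes > 1L)
        seq(-span / 2, span / 2, length.out = n_domes) else 0
      for (o in offs) {
        jit <- stats::rnorm(2, 0, 1.5)
        z <- add_dome(z, xs, ys,
                      c0[1L] + o * cos(theta) + jit[1L],
                      c0[2L] + o * sin(theta) + jit[2L],
                      dome_diameter_nm, amplitude_nm)
      }
    } else {
      # meandering filament: smooth random-walk path, thin cross-section
      steps <- 200L
      ang <- cumsum(stats::rnorm(steps, 0, 0.25))
      px <- c0[1L] + cumsum(cos(ang)) * 0.9
      py <- c0[2L] + cumsum(sin(ang)) * 0.9
      px <- px - mean(px); py <- py - mean(py)
      for (t in seq_len(steps))
        z <- add_dome(z, xs, ys, px[t], py[t], 6, amplitude_nm * 0.25)
      z <- pmin(z, amplitude_nm * 0.4)
    }
    if (noise_sd_nm > 0)
      z <- z + matrix(stats::rnorm(npx * npx, 0, noise_sd_nm), npx, npx)
    height_map(z, pixel_size_nm)
  })
}

#' Write / read a height map as whitespace-matrix text
#'
#' Plain-text raster with a `# pixel_size_nm:` sidecar header line.
#'
#' @param map A [height_map()].
#' @param path File path.
#' @return `read_heightmap_txt`: a [height_map()].
#' @export
write_heightmap_txt <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm: %.6g", map$pixel_size_nm), con)
  utils::write.table(map$heights, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_heightmap_txt
#' @export
read_heightmap_txt <- function(path) {
  first <- readLines(path, n = 1L)
  ps <- as.numeric(sub("^#\\s*pixel_size_nm:\\s*", "", first))
  if (!is.finite(ps)) stop("missing '# pixel_size_nm:' header in ", path)
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  height_map(m, ps)
}

#' Simulate a Hill-shaped Mg2+ titration of hydration radius
#'
#' Noiseless values follow
#' `Rh(c) = Rh_inf + (Rh_0 - Rh_inf) / (1 + (c / C_half)^n)` — the standard
#' RNA-folding isotherm with midpoint `C_half` — on a log-spaced grid over
#' 0.01-100 mM by default, the usual Mg2+ titration range.
#'
#' @param R0 Hydration radius at zero Mg2+ (nm).
#' @param Rinf Hydration radius at saturation (nm); must satisfy
#'   `R0 > Rinf > 0` for a compacting RNA.
#' @param C_half Transition midpoint (mM).
#' @param n_hill Hill coefficient.
#' @param concentrations Mg2+ grid in mM (default 12 log-spaced points,
#'   0.01-100).
#' @param noise_sd Gaussian noise on Rh (nm).
#' @param seed Integer seed.
#' @return A data frame of class `titration_curve` with columns `conc_mM`
#'   and `Rh_nm`.
#' @export
simulate_titration <- function(R0 = 12, Rinf = 9.6, C_half = 1.0,
                               n_hill = 2,
                               concentrations = 10^seq(-2, 2,
                                                       length.out = 12L),
                               noise_sd = 0, seed = 1L) {
  if (!length(concentrations)) stop("empty concentration list")
  stopifnot(R0 > Rinf, Rinf > 0, C_half > 0)
  with_seed(seed, {
    y <- hill_curve(concentrations, R0, Rinf, C_half, n_hill)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    structure(data.frame(conc_mM = concentrations, Rh_nm = y),
              class = c("titration_curve", "data.frame"))
  })
}

# the Hill isotherm shared by the simulator and the fitter
hill_curve <- function(c, R0, Rinf, C_half, n) {
  Rinf + (R0 - Rinf) / (1 + (c / C_half)^n)
}
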