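#' RNA secondary structure with an optional pseudoknot layer
#'
#' Holds a pair table for a structure of given length. Pairs live on one of
#' two layers: `nested` pairs must be mutually non-crossing (ordinary
#' secondary structure), while `pseudoknot` pairs may cross nested pairs —
#' the representation used for kissing-loop interactions, which are annotated
#' on top of an otherwise nested fold.
#'
#' @param length Number of nucleotides.
#' @param pairs Two-column matrix or data frame of pairs `(i, j)`, `i < j`;
#'   may be empty.
#' @param layer Character vector, one of `"nested"`/`"pseudoknot"` per pair
#'   (recycled).
#' @return An object of class `secondary_structure` with elements `length`,
#'   `pairs` (data frame `i`, `j`, `layer`) and `pt` (pair table: partner of
#'   each position, 0 if unpaired).
#' @export
secondary_structure <- function(length, pairs = NULL, layer = "nested") {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pr <- data.frame(i = integer(), j = integer(), layer = character())
  } else {
    pairs <- as.data.frame(pairs)
    pr <- data.frame(i = as.integer(pairs[[1L]]), j = as.integer(pairs[[2L]]),
                     layer = rep_len(as.character(layer), nrow(pairs)))
  }
  if (nrow(pr)) {
    if (any(pr$i >= pr$j)) stop("pairs must have i < j")
    if (any(pr$i < 1L | pr$j > length)) stop("pair position out of range")
    pos <- c(pr$i, pr$j)
    if (anyDuplicated(pos)) stop("a position participates in more than one pair")
    if (!all(pr$layer %in% c("nested", "pseudoknot")))
      stop("layer must be 'nested' or 'pseudoknot'")
    nest <- pr[pr$layer == "nested", , drop = FALSE]
    if (pairs_cross(nest$i, nest$j))
      stop("nested-layer pairs must be non-crossing")
    pr <- pr[order(pr$i), , drop = FALSE]
    rownames(pr) <- NULL
  }
  pt <- integer(length)
  if (nrow(pr)) { pt[pr$i] <- pr$j; pt[pr$j] <- pr$i }
  structure(list(length = length, pairs = pr, pt = pt),
            class = "secondary_structure")
}

# TRUE if any two pairs (i,k),(j,l) interleave: i < j < k < l
pairs_cross <- function(i, j) {
  n <- length(i)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if ((i[a] < i[b] && i[b] < j[a] && j[a] < j[b]) ||
        (i[b] < i[a] && i[a] < j[b] && j[b] < j[a])) return(TRUE)
  }
  FALSE
}

#' @export
print.secondary_structure <- function(x, ...) {
  npk <- sum(x$pairs$layer == "pseudoknot")
  cat(sprintf("<secondary_structure> %d nt, %d pair(s) (%d pseudoknot)\n",
              x$length, nrow(x$pairs), npk))
  if (x$length <= 120L) cat(" ", write_dotbracket(x), "\n")
  invisible(x)
}

#' Parse Vienna dot-bracket notation
#'
#' Round brackets `()` hold the nested layer; square brackets `[]` hold one
#' pseudoknot layer (used for kissing-loop pairs). Dots are unpaired.
#'
#' @param text A dot-bracket string over the alphabet `.()[]`.
#' @return A [secondary_structure()].
#' @export
#' @examples
#' parse_dotbracket("((..[[..))..]]")
parse_dotbracket <- function(text) {
  chars <- strsplit(gsub("\\s", "", text), "")[[1L]]
  bad <- setdiff(unique(chars), c(".", "(", ")", "[", "]"))
  if (length(bad))
    stop("invalid dot-bracket character(s): ", paste(bad, collapse = " "))
  st1 <- integer(0); st2 <- integer(0)
  i_out <- integer(0); j_out <- integer(0); lay <- character(0)
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "(") st1 <- c(st1, k)
    else if (ch == "[") st2 <- c(st2, k)
    else if (ch == ")") {
      if (!length(st1)) stop("unbalanced ')' at position ", k)
      i_out <- c(i_out, st1[length(st1)]); j_out <- c(j_out, k)
      lay <- c(lay, "nested"); st1 <- st1[-length(st1)]
    } else if (ch == "]") {
      if (!length(st2)) stop("unbalanced ']' at position ", k)
      i_out <- c(i_out, st2[length(st2)]); j_out <- c(j_out, k)
      lay <- c(lay, "pseudoknot"); st2 <- st2[-length(st2)]
    }
  }
  if (length(st1) || length(st2)) stop("unbalanced open bracket(s)")
  secondary_structure(length(chars),
                      if (length(i_out)) cbind(i_out, j_out) else NULL,
                      layer = lay)
}

#' Write Vienna dot-bracket notation
#'
#' @param structure A [secondary_structure()].
#' @return A dot-bracket string; `write_dotbracket` is the inverse of
#'   [parse_dotbracket()].
#' @export
write_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  out <- rep(".", structure$length)
  pr <- structure$pairs
  nest <- pr[pr$layer == "nested", , drop = FALSE]
  pk <- pr[pr$layer == "pseudoknot", , drop = FALSE]
  out[nest$i] <- "("; out[nest$j] <- ")"
  out[pk$i] <- "["; out[pk$j] <- "]"
  paste(out, collapse = "")
}

#' Read / write connect-table (CT) structure files
#'
#' Standard 6-column CT format: index, base, previous, next, partner, index.
#' Lines beginning with `#` are ignored. Only the nested layer is
#' representable in CT; pseudoknot pairs are written like any other pair and
#' read back onto the nested layer when non-crossing, else pseudoknot.
#'
#' @param path File path.
#' @param structure A [secondary_structure()].
#' @param sequence Nucleotide string (required for writing).
#' @return `read_ct`: a list with `sequence` and `structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(hdr[1L])
  body <- lines[-1L]
  if (length(body) < n) stop("CT file truncated")
  f <- do.call(rbind, lapply(body[seq_len(n)], function(l)
    strsplit(trimws(l), "\\s+")[[1L]][1:5]))
  idx <- as.integer(f[, 1L]); partner <- as.integer(f[, 5L])
  seq <- paste(f[, 2L], collapse = "")
  sel <- which(partner > idx)
  prs <- if (length(sel)) cbind(idx[sel], partner[sel]) else NULL
  st <- tryCatch(secondary_structure(n, prs),
                 error = function(e) {
                   # fall back: peel crossing pairs onto the pseudoknot layer
                   split_layers(n, prs)
                 })
  list(sequence = seq, structure = st)
}

# assign a maximal non-crossing subset to nested, remainder to pseudoknot
split_layers <- function(n, prs) {
  ord <- order(prs[, 1L])
  prs <- prs[ord, , drop = FALSE]
  lay <- rep("nested", nrow(prs))
  for (a in seq_len(nrow(prs))) {
    if (a == 1L) next
    sel <- which(lay[seq_len(a - 1L)] == "nested")
    for (b in sel) {
      i1 <- prs[b, 1L]; j1 <- prs[b, 2L]; i2 <- prs[a, 1L]; j2 <- prs[a, 2L]
      if (i1 < i2 && i2 < j1 && j1 < j2) { lay[a] <- "pseudoknot"; break }
    }
  }
  secondary_structure(n, prs, layer = lay)
}

#' @rdname read_ct
#' @export
write_ct <- function(structure, sequence, path) {
  stopifnot(inherits(structure, "secondary_structure"))
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (length(bases) != structure$length)
    stop("sequence length does not match structure length")
  n <- structure$length
  pt <- structure$pt
  lines <- c(sprintf("%d structure", n),
             sprintf("%5d %s %7d %5d %5d %5d",
                     1:n, bases, 0:(n - 1L), c(2:n, 0L), pt, 1:n))
  writeLines(lines, path)
  invisible(path)
}
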