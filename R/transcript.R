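#' Transcript coordinate model
#'
#' A `transcript_model` describes a spliced transcript in its own 1-based,
#' inclusive coordinate system: a total length plus optional exon and
#' structural-domain intervals. It is the frame of reference for building
#' splice variants and point mutants by interval arithmetic, so that mutations
#' can always be reported in the reference numbering (e.g. G370C on MEG3 v1).
#'
#' @param name Transcript name.
#' @param length Transcript length in nucleotides.
#' @param exons,domains Data frames with columns `label`, `start`, `end`
#'   (1-based inclusive), or `NULL`. Intervals must lie within the transcript,
#'   be non-overlapping and sorted 5' to 3'.
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' transcript_model("toy", 100,
#'                  domains = data.frame(label = "D1", start = 10, end = 40))
transcript_model <- function(name, length, exons = NULL, domains = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  check_intervals <- function(x, what) {
    if (is.null(x)) return(data.frame(label = character(), start = integer(),
                                      end = integer()))
    stopifnot(is.data.frame(x), all(c("label", "start", "end") %in% names(x)))
    x <- data.frame(label = as.character(x$label), start = as.integer(x$start),
                    end = as.integer(x$end))
    if (any(x$start < 1L | x$end > length | x$start > x$end))
      stop(sprintf("%s intervals must satisfy 1 <= start <= end <= length", what))
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start[-1L] <= x$end[-nrow(x)]))
      stop(sprintf("%s intervals overlap", what))
    rownames(x) <- NULL
    x
  }
  structure(list(name = name, length = length,
                 exons = check_intervals(exons, "exon"),
                 domains = check_intervals(domains, "domain")),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt, %d exon(s), %d domain(s)\n",
              x$name, x$length, nrow(x$exons), nrow(x$domains)))
  invisible(x)
}

#' Reference model of human MEG3 splice variant v1
#'
#' The most abundant MEG3 splice variant (v1) spans 1,595 nt and folds into
#' five structural domains whose boundaries track the exon junctions:
#' D1 (2-196), D2 (230-410), D3 (471-902), D4 (951-1113) and D5 (1116-1486).
#' The variable exon E5 occupies nt 936-1049; deleting it yields variant v9.
#' Exon boundaries other than E5 are not part of the model.
#'
#' @return A `transcript_model` for MEG3 v1.
#' @export
meg3_v1_model <- function() {
  transcript_model(
    name = "MEG3_v1", length = 1595L,
    exons = data.frame(label = "E5", start = 936L, end = 1049L),
    domains = data.frame(
      label = c("D1", "D2", "D3", "D4", "D5"),
      start = c(2L, 230L, 471L, 951L, 1116L),
      end   = c(196L, 410L, 902L, 1113L, 1486L)))
}

#' Specify a splice/mutant variant of a transcript
#'
#' A `variant_spec` lists edits relative to a base [transcript_model]:
#' deletions (1-based inclusive intervals), point substitutions, and opaque
#' insertions of given length (used for variable exons whose sequence is not
#' modeled, e.g. MEG3 E6 in variant v3).
#'
#' @param deletions Data frame with columns `start`, `end`, or `NULL`.
#' @param substitutions Data frame with columns `position`, `base`, or `NULL`.
#' @param insertions Data frame with columns `after` (base position after
#'   which the insert goes; 0 = before the first base), `length`, and
#'   optionally `label`, or `NULL`.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(deletions = NULL, substitutions = NULL,
                         insertions = NULL) {
  del <- if (is.null(deletions)) {
    data.frame(start = integer(), end = integer())
  } else {
    data.frame(start = as.integer(deletions$start),
               end = as.integer(deletions$end))
  }
  if (any(del$start > del$end)) stop("deletion start > end")
  del <- del[order(del$start), , drop = FALSE]
  if (nrow(del) > 1L && any(del$start[-1L] <= del$end[-nrow(del)]))
    stop("deletion intervals overlap")
  sub <- if (is.null(substitutions)) {
    data.frame(position = integer(), base = character())
  } else {
    data.frame(position = as.integer(substitutions$position),
               base = toupper(as.character(substitutions$base)))
  }
  if (nrow(sub) && nrow(del)) {
    inside <- vapply(sub$position, function(p)
      any(p >= del$start & p <= del$end), logical(1))
    if (any(inside)) stop("substitution position falls inside a deletion")
  }
  ins <- if (is.null(insertions)) {
    data.frame(after = integer(), length = integer(), label = character())
  } else {
    data.frame(after = as.integer(insertions$after),
               length = as.integer(insertions$length),
               label = if (is.null(insertions$label))
                 rep("ins", nrow(insertions)) else as.character(insertions$label))
  }
  if (any(ins$length < 1L)) stop("insertion length must be >= 1")
  structure(list(deletions = del, substitutions = sub, insertions = ins),
            class = "variant_spec")
}

#' Build a variant sequence and its coordinate map
#'
#' Applies a [variant_spec] to a base transcript: deletions are removed,
#' substitutions applied, opaque insertions filled with `N`. The returned
#' variant retains a per-position map back to base coordinates so any variant
#' position can be reported in reference numbering.
#'
#' @param model A [transcript_model].
#' @param spec A [variant_spec].
#' @param sequence Nucleotide string of length `model$length`.
#' @param name Name for the variant.
#' @return A list with `sequence` (character scalar) and `variant`
#'   (a `variant_transcript` holding the coordinate map).
#' @export
#' @examples
#' m <- meg3_v1_model()
#' seq <- paste(rep("A", 1595), collapse = "")
#' v9 <- build_variant(m, variant_spec(deletions = data.frame(start = 936, end = 1049)),
#'                     seq, name = "v9")
#' nchar(v9$sequence)  # 1481
build_variant <- function(model, spec, sequence, name = "variant") {
  stopifnot(inherits(model, "transcript_model"), inherits(spec, "variant_spec"))
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) != model$length)
    stop(sprintf("sequence length (%d) does not match model length (%d)",
                 nchar(sequence), model$length))
  if (nrow(spec$deletions) &&
      (any(spec$deletions$start < 1L) || any(spec$deletions$end > model$length)))
    stop("deletion interval out of bounds")
  if (nrow(spec$substitutions) &&
      (any(spec$substitutions$position < 1L) ||
       any(spec$substitutions$position > model$length)))
    stop("substitution position out of bounds")
  if (nrow(spec$insertions) &&
      (any(spec$insertions$after < 0L) || any(spec$insertions$after > model$length)))
    stop("insertion anchor out of bounds")

  bases <- strsplit(sequence, "")[[1]]
  if (nrow(spec$substitutions))
    bases[spec$substitutions$position] <- spec$substitutions$base

  keep <- rep(TRUE, model$length)
  for (k in seq_len(nrow(spec$deletions)))
    keep[spec$deletions$start[k]:spec$deletions$end[k]] <- FALSE

  # assemble: base positions (kept) interleaved with opaque insertions
  base_map <- which(keep)                      # variant idx -> base idx (pre-insert)
  out_bases <- bases[keep]
  out_map <- base_map
  if (nrow(spec$insertions)) {
    ins <- spec$insertions[order(spec$insertions$after), , drop = FALSE]
    pieces_b <- list(); pieces_m <- list(); prev <- 0L
    for (k in seq_len(nrow(ins))) {
      upto <- sum(base_map <= ins$after[k])
      pieces_b[[length(pieces_b) + 1L]] <- out_bases[seq_len(upto)][seqed(prev, upto)]
      pieces_m[[length(pieces_m) + 1L]] <- out_map[seq_len(upto)][seqed(prev, upto)]
      pieces_b[[length(pieces_b) + 1L]] <- rep("N", ins$length[k])
      pieces_m[[length(pieces_m) + 1L]] <- rep(NA_integer_, ins$length[k])
      prev <- upto
    }
    pieces_b[[length(pieces_b) + 1L]] <- out_bases[seqed(prev, length(out_bases))]
    pieces_m[[length(pieces_m) + 1L]] <- out_map[seqed(prev, length(out_map))]
    out_bases <- unlist(pieces_b)
    out_map <- unlist(pieces_m)
  }
  variant <- structure(
    list(name = name, base = model, length = length(out_bases), map = out_map),
    class = "variant_transcript")
  list(sequence = paste(out_bases, collapse = ""), variant = variant)
}

# positions (prev, upto] as an integer sequence, empty-safe
seqed <- function(prev, upto) if (upto > prev) (prev + 1L):upto else integer(0)

#' @export
print.variant_transcript <- function(x, ...) {
  cat(sprintf("<variant_transcript> %s: %d nt on base %s (%d nt)\n",
              x$name, x$length, x$base$name, x$base$length))
  invisible(x)
}

#' Map a variant position to base (reference) coordinates
#'
#' @param variant A `variant_transcript` from [build_variant()].
#' @param pos 1-based position(s) on the variant.
#' @return Integer base coordinate(s); `NA` for positions inside an opaque
#'   insertion (which have no base equivalent).
#' @export
map_position <- function(variant, pos) {
  stopifnot(inherits(variant, "variant_transcript"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > variant$length))
    stop(sprintf("position out of range 1..%d", variant$length))
  variant$map[pos]
}

#' Map a base (reference) position to variant coordinates
#'
#' Inverse of [map_position()]; defined only for base positions that survive
#' the variant's deletions.
#'
#' @param variant A `variant_transcript`.
#' @param pos 1-based base position(s).
#' @return Integer variant coordinate(s); `NA` where the base position was
#'   deleted.
#' @export
unmap_position <- function(variant, pos) {
  stopifnot(inherits(variant, "variant_transcript"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > variant$base$length))
    stop(sprintf("base position out of range 1..%d", variant$base$length))
  idx <- match(pos, variant$map)
  as.integer(idx)
}
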