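#' Classification schemes for normalized probing reactivities
#'
#' Two reference schemes are built in. `shape3` is the three-class SHAPE
#' convention: 0-0.40 not reactive (most likely base-paired), 0.40-0.85
#' moderately reactive, > 0.85 very reactive (most likely single-stranded).
#' `hrf4` is the four-class hydroxyl-radical-footprinting convention:
#' 0-0.29 not reactive (most solvent-protected), 0.29-0.58 poorly reactive,
#' 0.58-0.86 moderately reactive, > 0.86 very reactive (most
#' solvent-exposed). Interval membership is left-closed with the top class
#' strictly above the last boundary, so 0.40 and 0.85 both classify as
#' moderately reactive.
#'
#' @param name `"shape3"`, `"hrf4"`, or `"custom"`.
#' @param boundaries Strictly increasing numeric boundaries (custom scheme).
#' @param labels Class labels, one more than there are boundaries.
#' @return An object of class `classification_scheme`.
#' @export
classification_scheme <- function(name = c("shape3", "hrf4", "custom"),
                                  boundaries = NULL, labels = NULL) {
  name <- match.arg(name)
  if (name == "shape3") {
    boundaries <- c(0.40, 0.85)
    labels <- c("not reactive", "moderately reactive", "very reactive")
  } else if (name == "hrf4") {
    boundaries <- c(0.29, 0.58, 0.86)
    labels <- c("not reactive", "poorly reactive", "moderately reactive",
                "very reactive")
  }
  stopifnot(is.numeric(boundaries), length(boundaries) >= 1L,
            all(diff(boundaries) > 0),
            length(labels) == length(boundaries) + 1L)
  structure(list(name = name, boundaries = boundaries, labels = labels),
            class = "classification_scheme")
}

#' Box-plot normalization of a reactivity profile
#'
#' The standard SHAPE box-plot rule: values above `Q3 + 1.5 IQR` are treated
#' as outliers (at most 10% of the finite values are excluded); the
#' normalization factor is the mean of the top decile of the surviving
#' values; every finite value is divided by it. The alternative 2%/8% rule
#' (exclude the top 2%, normalize by the mean of the next 8%) is available
#' via `method = "percentile2_8"`. No-data positions pass through untouched.
#'
#' @param profile A [reactivity_profile()] with at least 10 finite values.
#' @param method `"boxplot"` (default) or `"percentile2_8"`.
#' @return A list with `profile` (state `"normalized"`) and `factor`.
#' @export
normalize_boxplot <- function(profile, method = c("boxplot", "percentile2_8")) {
  method <- match.arg(method)
  v <- as.numeric(profile)
  fin <- which(is.finite(v))
  if (length(fin) < 10L)
    stop("normalization needs at least 10 finite values")
  x <- v[fin]
  if (method == "boxplot") {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    thr <- q[2L] + 1.5 * (q[2L] - q[1L])
    out_idx <- order(x, decreasing = TRUE)
    n_out <- min(sum(x > thr), floor(0.10 * length(x)))
    survivors <- if (n_out > 0L) x[-out_idx[seq_len(n_out)]] else x
    n_top <- max(1L, round(0.10 * length(survivors)))
    top <- sort(survivors, decreasing = TRUE)[seq_len(n_top)]
    factor <- mean(top)
  } else {
    s <- sort(x, decreasing = TRUE)
    n <- length(s)
    i2 <- max(1L, floor(0.02 * n))
    i10 <- max(i2 + 1L, floor(0.10 * n))
    factor <- mean(s[(i2 + 1L):i10])
  }
  if (!is.finite(factor) || factor <= 0)
    stop("normalization factor is not positive")
  v[fin] <- v[fin] / factor
  message(sprintf("normalize_boxplot: factor %.6g (%s, %d finite values)",
                  factor, method, length(fin)))
  list(profile = reactivity_profile(v, reagent = attr(profile, "reagent"),
                                    state = "normalized"),
       factor = factor)
}

#' Classify normalized reactivities into reactivity classes
#'
#' @param profile A normalized (or scaled) [reactivity_profile()].
#' @param scheme A [classification_scheme()]; default `shape3`.
#' @return Character vector of class labels; `NA` at no-data positions.
#' @export
#' @examples
#' p <- reactivity_profile(c(0.3, 0.6, 0.9), state = "normalized")
#' classify(p)
classify <- function(profile, scheme = classification_scheme("shape3")) {
  stopifnot(inherits(scheme, "classification_scheme"))
  if (profile_state(profile) == "raw")
    stop("classify expects a normalized (or scaled) profile")
  v <- as.numeric(profile)
  b <- scheme$boundaries
  m <- length(b)
  idx <- rep(NA_integer_, length(v))
  fin <- is.finite(v)
  # [low, high) intervals, top class strictly above the last boundary
  cnt <- rowSums(outer(v[fin], b[-m], ">=")) + (v[fin] > b[m])
  idx[fin] <- cnt + 1L
  scheme$labels[idx]
}

#' Merge overlapping primer reads into one profile
#'
#' Probing reads from consecutive primers overlap by a few tens of
#' nucleotides; in the overlaps the contributing values are averaged, and
#' positions covered by a single read pass through. Each input profile is
#' placed on the common coordinate system at its `offset` (position of its
#' first value, 1-based).
#'
#' @param profiles List of [reactivity_profile()]s.
#' @param offsets Integer vector of start positions (default all 1).
#' @param length Total length of the merged profile (default: rightmost end).
#' @return A merged [reactivity_profile()].
#' @export
merge_primer_reads <- function(profiles, offsets = rep(1L, length(profiles)),
                               length = NULL) {
  stopifnot(length(profiles) >= 1L, length(offsets) == length(profiles),
            all(offsets >= 1L))
  ends <- offsets + vapply(profiles, base::length, integer(1)) - 1L
  n <- if (is.null(length)) max(ends) else as.integer(length)
  sums <- numeric(n); cnts <- numeric(n)
  for (k in seq_along(profiles)) {
    v <- as.numeric(profiles[[k]])
    idx <- offsets[k]:(offsets[k] + base::length(v) - 1L)
    ok <- is.finite(v)
    sums[idx[ok]] <- sums[idx[ok]] + v[ok]
    cnts[idx[ok]] <- cnts[idx[ok]] + 1L
  }
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  reactivity_profile(out, reagent = attr(profiles[[1L]], "reagent"),
                     state = profile_state(profiles[[1L]]))
}

#' Scale a profile onto a reference by least squares through the origin
#'
#' Multiplies the target by the factor `sum(t*r) / sum(t^2)` computed over
#' positions finite in both profiles — the scaling used to put a mutant's
#' footprinting profile on the reactivity scale of the wild type.
#'
#' @param target,reference Equal-length [reactivity_profile()]s with at
#'   least 10 common finite positions.
#' @return A list with `profile` (state `"scaled"`) and `factor`.
#' @export
scale_to_reference <- function(target, reference) {
  t <- as.numeric(target); r <- as.numeric(reference)
  stopifnot(length(t) == length(r))
  ok <- is.finite(t) & is.finite(r)
  if (sum(ok) < 10L) stop("need at least 10 common finite positions")
  denom <- sum(t[ok]^2)
  if (denom <= 0) stop("degenerate target: zero sum of squares")
  factor <- sum(t[ok] * r[ok]) / denom
  out <- t * factor
  message(sprintf("scale_to_reference: factor %.6g (%d common positions)",
                  factor, sum(ok)))
  list(profile = reactivity_profile(out, reagent = attr(target, "reagent"),
                                    state = "scaled"),
       factor = factor)
}

#' Windowed difference of two reactivity profiles
#'
#' Computes `a - b` per position and smooths the difference with a centered
#' mean over finite values — the operation used to contrast reagents with
#' different chemistries (e.g. NMIA minus 1M6) and localize enhanced or
#' suppressed stretches.
#'
#' @param a,b Equal-length [reactivity_profile()]s.
#' @param window Odd window size (default 3).
#' @return Numeric difference profile (`NA` where no finite value in window).
#' @export
diff_by_window <- function(a, b, window = 3L) {
  va <- as.numeric(a); vb <- as.numeric(b)
  stopifnot(length(va) == length(vb))
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1")
  d <- va - vb
  centered_mean(d, window)
}

# centered running mean over finite values; NA when window holds none
centered_mean <- function(x, window) {
  n <- length(x); h <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    w <- w[is.finite(w)]
    if (length(w)) out[i] <- mean(w)
  }
  out
}

#' Mutational-profiling counts
#'
#' Per-position mutation counts and read depths for a reagent-modified and an
#' untreated channel, as produced by mutational-profiling (MaP) sequencing
#' where reagent adducts are read out as reverse-transcription mutations.
#'
#' @param modified,untreated Integer vectors of mutation counts.
#' @param depth_modified,depth_untreated Integer vectors of read depths.
#' @return An object of class `map_counts`.
#' @export
map_counts <- function(modified, untreated, depth_modified, depth_untreated) {
  n <- length(modified)
  stopifnot(length(untreated) == n, length(depth_modified) == n,
            length(depth_untreated) == n,
            all(depth_modified >= 0), all(depth_untreated >= 0),
            all(modified <= depth_modified), all(untreated <= depth_untreated))
  structure(list(modified = as.numeric(modified),
                 untreated = as.numeric(untreated),
                 depth_modified = as.numeric(depth_modified),
                 depth_untreated = as.numeric(depth_untreated)),
            class = "map_counts")
}

#' Raw reactivity from mutational-profiling counts
#'
#' Per-channel mutation rate is `mutations / depth`; the raw reactivity is
#' the modified-minus-untreated rate difference. Positions where either
#' channel is below `min_depth` reads become no-data. Negative raw values
#' (background above signal) are retained — normalization handles them —
#' and flagged in the `n_negative` attribute.
#'
#' @param counts A [map_counts()].
#' @param min_depth Minimum read depth per channel (default 1000).
#' @return A raw [reactivity_profile()].
#' @export
map_reactivity <- function(counts, min_depth = 1000L) {
  stopifnot(inherits(counts, "map_counts"))
  if (min_depth <= 0L) stop("min_depth must be positive")
  ok <- counts$depth_modified >= min_depth & counts$depth_untreated >= min_depth
  r <- rep(NA_real_, length(counts$modified))
  r[ok] <- counts$modified[ok] / counts$depth_modified[ok] -
    counts$untreated[ok] / counts$depth_untreated[ok]
  out <- reactivity_profile(r, reagent = "1M7", state = "raw")
  attr(out, "n_negative") <- sum(r < 0, na.rm = TRUE)
  out
}

#' Write / read mutational-profiling count tables
#'
#' Five-column TSV: position, modified mutations, untreated mutations,
#' modified depth, untreated depth; `#` comments tolerated.
#'
#' @param counts A [map_counts()].
#' @param path File path.
#' @return `read_map_counts`: a [map_counts()].
#' @export
write_map_counts <- function(counts, path) {
  utils::write.table(
    data.frame(position = seq_along(counts$modified),
               modified = counts$modified, untreated = counts$untreated,
               depth_modified = counts$depth_modified,
               depth_untreated = counts$depth_untreated),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_counts
#' @export
read_map_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  map_counts(tab$modified, tab$untreated,
             tab$depth_modified, tab$depth_untreated)
}
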