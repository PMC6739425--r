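#' Parameters for differential-probing calls
#'
#' Constants of the in-cell vs protein-free differential analysis: profiles
#' are smoothed, their difference is screened by a Z-factor (separation of
#' the difference from its combined measurement error) and by a standard
#' score (magnitude relative to the transcript-wide spread), and a call
#' requires a minimum number of passing positions inside a short site
#' window.
#'
#' @param smooth_window Odd smoothing window (default 3).
#' @param site_window Odd site window for the hit-count rule (default 5).
#' @param min_hits Minimum passing positions within the site window
#'   (default 3).
#' @param z_multiplier Error multiplier in the Z-factor (default 1.96,
#'   i.e. 95% confidence).
#' @param score_cutoff Standard-score magnitude cutoff (default 1.0).
#' @return An object of class `delta_params`.
#' @export
delta_params <- function(smooth_window = 3L, site_window = 5L, min_hits = 3L,
                         z_multiplier = 1.96, score_cutoff = 1.0) {
  stopifnot(smooth_window %% 2L == 1L, smooth_window >= 1L,
            site_window %% 2L == 1L, site_window >= 1L,
            min_hits >= 1L, min_hits <= site_window, z_multiplier > 0)
  structure(list(smooth_window = as.integer(smooth_window),
                 site_window = as.integer(site_window),
                 min_hits = as.integer(min_hits),
                 z_multiplier = z_multiplier, score_cutoff = score_cutoff),
            class = "delta_params")
}

#' Centered-mean smoothing of a reactivity profile
#'
#' @param profile A [reactivity_profile()] (or plain numeric vector).
#' @param window Odd window size.
#' @return Numeric vector; `NA` where the window holds no finite value.
#' @export
smooth_profile <- function(profile, window = 3L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  centered_mean(as.numeric(profile), window)
}

#' Call differential protections between ex vivo and in vivo profiles
#'
#' Computes the smoothed difference `delta = smooth(ex) - smooth(in)`, the
#' Z-factor `1 - z_multiplier * (err_ex + err_in) / |delta|`, and the
#' standard score `(delta - mean(delta)) / sd(delta)`. A position is called
#' when its Z-factor is positive, its standard-score magnitude is at or
#' above the cutoff, and at least `min_hits` positions within the centered
#' site window satisfy both. Positive `delta` (more reactive protein-free)
#' is reported as `protected_in_vivo`; negative as `enhanced_in_vivo`.
#'
#' @param ex_vivo,in_vivo Equal-length [reactivity_profile()]s on a common
#'   normalized scale.
#' @param errs_ex,errs_in Per-position standard errors (numeric vectors or
#'   single constants, recycled).
#' @param params A [delta_params()].
#' @return Data frame of class `delta_calls`: `position`, `delta`,
#'   `z_factor`, `std_score`, `direction` — one row per called position.
#' @export
delta_call <- function(ex_vivo, in_vivo, errs_ex = 0.1, errs_in = 0.1,
                       params = delta_params()) {
  ex <- as.numeric(ex_vivo); iv <- as.numeric(in_vivo)
  if (length(ex) != length(iv)) stop("profiles differ in length")
  n <- length(ex)
  errs_ex <- rep_len(errs_ex, n); errs_in <- rep_len(errs_in, n)
  d <- smooth_profile(ex, params$smooth_window) -
    smooth_profile(iv, params$smooth_window)
  fin <- is.finite(d)
  if (sum(fin) < 2L || stats::sd(d[fin]) == 0) {
    warning("zero variance of the difference: no calls")
    return(empty_delta_calls())
  }
  z <- 1 - params$z_multiplier * (errs_ex + errs_in) / abs(d)
  score <- (d - mean(d[fin])) / stats::sd(d[fin])
  hit <- fin & z > 0 & abs(score) >= params$score_cutoff
  h <- (params$site_window - 1L) %/% 2L
  called <- logical(n)
  for (i in which(hit)) {
    w <- max(1L, i - h):min(n, i + h)
    if (sum(hit[w]) >= params$min_hits) called[i] <- TRUE
  }
  idx <- which(called)
  out <- data.frame(position = idx, delta = d[idx], z_factor = z[idx],
                    std_score = score[idx],
                    direction = ifelse(d[idx] > 0, "protected_in_vivo",
                                       "enhanced_in_vivo"))
  class(out) <- c("delta_calls", "data.frame")
  out
}

empty_delta_calls <- function() {
  out <- data.frame(position = integer(), delta = numeric(),
                    z_factor = numeric(), std_score = numeric(),
                    direction = character())
  class(out) <- c("delta_calls", "data.frame")
  out
}

#' Merge called positions into BED-like regions
#'
#' Adjacent called positions (within `gap` nt) are merged into 1-based
#' inclusive intervals, one strand-less region per run, with the dominant
#' direction annotated.
#'
#' @param calls A `delta_calls` frame from [delta_call()].
#' @param gap Maximum gap bridged when merging (default 1).
#' @return Data frame: `start`, `end`, `n_positions`, `direction`.
#' @export
merge_delta_regions <- function(calls, gap = 1L) {
  if (!nrow(calls))
    return(data.frame(start = integer(), end = integer(),
                      n_positions = integer(), direction = character()))
  pos <- sort(calls$position)
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  out <- lapply(seq_len(length(brk) - 1L), function(r) {
    run <- pos[(brk[r] + 1L):brk[r + 1L]]
    dirs <- calls$direction[calls$position %in% run]
    data.frame(start = run[1L], end = run[length(run)],
               n_positions = length(run),
               direction = names(sort(table(dirs), decreasing = TRUE))[1L])
  })
  do.call(rbind, out)
}
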