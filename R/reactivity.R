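#' Per-nucleotide chemical-probing reactivity profile
#'
#' A numeric vector of per-position probing values with `NA` as the internal
#' no-data marker (written as `-999` on disk, the common probing-file
#' convention). The object carries its reagent and processing state so that,
#' e.g., classification refuses to run on unnormalized values.
#'
#' @param values Numeric vector; `NA` marks positions without data.
#' @param reagent Probing reagent label (`"1M7"`, `"1M6"`, `"NMIA"`, `"DMS"`,
#'   `"HRF"`, ...).
#' @param state Processing state: `"raw"`, `"normalized"` or `"scaled"`.
#' @return An object of class `reactivity_profile` (a numeric vector with
#'   attributes).
#' @export
reactivity_profile <- function(values, reagent = "1M7", state = "raw") {
  stopifnot(is.numeric(values))
  state <- match.arg(state, c("raw", "normalized", "scaled"))
  structure(as.numeric(values), reagent = reagent, state = state,
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  fin <- sum(is.finite(x))
  cat(sprintf("<reactivity_profile> %d nt (%s, %s), %d with data; mean %.3f\n",
              length(x), attr(x, "reagent"), attr(x, "state"), fin,
              mean(x[is.finite(x)])))
  invisible(x)
}

# keep attributes through subsetting
#' @export
`[.reactivity_profile` <- function(x, i, ...) {
  r <- NextMethod()
  attributes(r) <- c(attributes(r),
                     attributes(x)[c("reagent", "state", "class")])
  r
}

profile_state <- function(p) attr(p, "state") %||% "raw"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write two-column reactivity tables
#'
#' Plain-text format: one `position<TAB>value` row per nucleotide, `-999`
#' encoding no-data, `#` comments allowed. Positions may be any explicit
#' 1-based index set; gaps in the index are filled with no-data so the
#' profile always covers `1..max(position)`.
#'
#' @param path File path.
#' @param profile A [reactivity_profile()] (for writing).
#' @param reagent,state Metadata attached on reading.
#' @return `read_reactivity_table`: a [reactivity_profile()].
#' @export
read_reactivity_table <- function(path, reagent = "1M7", state = "raw") {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("position", "value"),
                           colClasses = c("integer", "character"))
  val <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(val)) stop("non-numeric reactivity value in ", path)
  if (anyDuplicated(tab$position)) stop("duplicate positions in ", path)
  if (any(tab$position < 1L)) stop("positions must be >= 1")
  out <- rep(NA_real_, max(tab$position))
  out[tab$position] <- val
  out[out <= -998] <- NA_real_   # -999 sentinel
  reactivity_profile(out, reagent = reagent, state = state)
}

#' @rdname read_reactivity_table
#' @export
write_reactivity_table <- function(profile, path) {
  v <- as.numeric(profile)
  v[!is.finite(v)] <- -999
  utils::write.table(data.frame(position = seq_along(v), value = v),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine replicate profiles by position-wise mean
#'
#' Replicates are averaged on the raw scale before normalization, matching
#' the convention of averaging individual reactivity values from repeated
#' probing experiments. Positions lacking data in every replicate stay
#' no-data.
#'
#' @param profiles List of equal-length [reactivity_profile()]s.
#' @return A [reactivity_profile()] (state `"raw"`).
#' @export
combine_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  n <- unique(vapply(profiles, length, integer(1)))
  if (length(n) != 1L) stop("replicate profiles must share one length")
  m <- do.call(cbind, lapply(profiles, as.numeric))
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  reactivity_profile(out, reagent = attr(profiles[[1L]], "reagent"),
                     state = "raw")
}
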