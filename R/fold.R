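#' Folding model parameters
#'
#' A simplified nearest-neighbor energy model: a 6x6 stacking-energy table
#' over the canonical pair types (AU, UA, GC, CG, GU, UG) plus affine
#' hairpin, bulge, internal-loop and multiloop penalties, with the
#' reactivity pseudo-energy `m * ln(S + 1) + b` charged once per paired
#' nucleotide. The default stack table is built from per-pair strengths
#' (GC 2.4, AU 1.1, GU 0.8 kcal/mol) averaged over the two stacked pairs;
#' all terms are replaceable, so the model is a configuration, not a
#' constant. `RT` sets the temperature-equivalent scale used by the
#' partition function (0.616 kcal/mol, i.e. 37 C).
#'
#' @param m,b Pseudo-energy slope and intercept in kcal/mol (defaults 2.6
#'   and -0.8).
#' @param stack 6x6 stacking table (kcal/mol, negative = stabilizing), rows =
#'   outer pair, cols = inner pair, order AU, UA, GC, CG, GU, UG.
#' @param hairpin_a,hairpin_b,bulge_a,bulge_b,internal_a,internal_b Affine
#'   loop penalties `a + b * size` (kcal/mol).
#' @param ml_a,ml_b,ml_c Multiloop closing / per-branch / per-unpaired terms.
#' @param min_hairpin Minimum hairpin loop size (>= 3).
#' @param max_interior Maximum interior loop size (s1 + s2).
#' @param RT Boltzmann scale in kcal/mol.
#' @return An object of class `folding_params`.
#' @export
folding_params <- function(m = 2.6, b = -0.8, stack = NULL,
                           hairpin_a = 5.0, hairpin_b = 0.05,
                           bulge_a = 3.5, bulge_b = 0.3,
                           internal_a = 3.0, internal_b = 0.3,
                           ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
                           min_hairpin = 3L, max_interior = 30L,
                           RT = 0.616) {
  if (is.null(stack)) {
    w <- c(AU = 1.1, UA = 1.1, GC = 2.4, CG = 2.4, GU = 0.8, UG = 0.8)
    stack <- -outer(w, w, function(a, b) (a + b) / 2)
  }
  stack <- as.matrix(stack)
  stopifnot(nrow(stack) == 6L, ncol(stack) == 6L,
            min_hairpin >= 3L, m >= 0, RT > 0)
  if (any(diag(stack) > 0))
    stop("canonical stacking energies must be <= 0")
  structure(list(m = m, b = b, stack = stack,
                 hairpin_a = hairpin_a, hairpin_b = hairpin_b,
                 bulge_a = bulge_a, bulge_b = bulge_b,
                 internal_a = internal_a, internal_b = internal_b,
                 ml_a = ml_a, ml_b = ml_b, ml_c = ml_c,
                 min_hairpin = as.integer(min_hairpin),
                 max_interior = as.integer(max_interior), RT = RT),
            class = "folding_params")
}

#' Reactivity pseudo-energy
#'
#' The probing-directed folding bonus/penalty `m * ln(S + 1) + b` applied
#' once per paired nucleotide. No-data positions contribute 0. Slightly
#' negative reactivities (down to -0.3, plausible noise) are clamped to 0;
#' values below -0.3 are rejected as data errors.
#'
#' @param S Reactivity value(s); `NA` = no data.
#' @param params A [folding_params()].
#' @return Pseudo-energy in kcal/mol, vectorized over `S`.
#' @export
#' @examples
#' pseudo_energy(0)           # intercept b = -0.8
#' pseudo_energy(exp(1) - 1)  # m + b = 1.8
pseudo_energy <- function(S, params = folding_params()) {
  out <- numeric(length(S))
  fin <- is.finite(S)
  if (any(S[fin] < -0.3))
    stop("reactivity below -0.3: beyond plausible noise")
  Sc <- pmax(S[fin], 0)
  out[fin] <- params$m * log(Sc + 1) + params$b
  out
}

encode_sequence <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  sequence <- chartr("T", "U", sequence)
  codes <- match(strsplit(sequence, "")[[1L]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) stop("sequence contains characters outside ACGU/T")
  codes
}

prepare_pseudo <- function(n, profile, params) {
  if (is.null(profile)) return(numeric(n))
  v <- as.numeric(profile)
  if (length(v) != n) stop("reactivity profile length does not match sequence")
  pe <- numeric(n)
  fin <- is.finite(v)
  pe[fin] <- pseudo_energy(v[fin], params)
  pe
}

#' Minimum-free-energy secondary structure
#'
#' Probing-directed MFE folding by dynamic programming over the simplified
#' nearest-neighbor model of [folding_params()]. The returned structure is
#' nested-only (pseudoknots are annotated downstream by the kissing-loop
#' scanner); its energy is the exact minimum of the model over all nested
#' structures (interior loops capped at `max_interior`).
#'
#' @param sequence RNA string over ACGU (T accepted and read as U).
#' @param profile Optional [reactivity_profile()] for pseudo-energies.
#' @param params A [folding_params()].
#' @return A list with `structure` (a [secondary_structure()]) and `energy`
#'   (kcal/mol).
#' @export
#' @examples
#' fold_mfe("GGGGAAAACCCC")
fold_mfe <- function(sequence, profile = NULL, params = folding_params()) {
  codes <- encode_sequence(sequence)
  n <- length(codes)
  pe <- prepare_pseudo(n, profile, params)
  res <- .fold_mfe_cpp(codes, pe, unclass(params))
  prs <- res$pairs
  st <- secondary_structure(n, if (nrow(prs)) prs else NULL)
  list(structure = st, energy = res$energy)
}

#' Base-pair probabilities and per-nucleotide Shannon entropy
#'
#' Boltzmann-weighted pair probabilities over the same energy model as
#' [fold_mfe()] (McCaskill-style inside-outside computation), plus the
#' unpaired probability and the positional Shannon entropy
#' `S(i) = -sum p log10 p` over the outcomes \{each pair partner,
#' unpaired\}, in the log-base-10 convention of probing-directed structure
#' pipelines. Low entropy marks positions with a well-defined structural
#' fate; high entropy marks structurally ambiguous regions.
#'
#' @inheritParams fold_mfe
#' @param max_length Guard on sequence length (default 2000).
#' @return A list with `p` (upper-triangular matrix of pair probabilities),
#'   `p_unpaired` (vector) and `entropy` (vector).
#' @export
pair_probabilities <- function(sequence, profile = NULL,
                               params = folding_params(),
                               max_length = 2000L) {
  codes <- encode_sequence(sequence)
  n <- length(codes)
  if (n > max_length) stop("sequence longer than max_length")
  pe <- prepare_pseudo(n, profile, params)
  mfe <- .fold_mfe_cpp(codes, pe, unclass(params))$energy
  P <- .pairprob_cpp(codes, pe, unclass(params), mfe)
  Pfull <- P + t(P)
  pu <- pmax(0, 1 - rowSums(Pfull))
  ent <- vapply(seq_len(n), function(i) {
    probs <- c(Pfull[i, ], pu[i])
    probs <- probs[probs > 0]
    -sum(probs * log10(probs))
  }, numeric(1))
  list(p = P, p_unpaired = pu, entropy = ent)
}

#' Write sparse pair probabilities as TSV
#'
#' Emits rows `(i, j, p)` for all pairs with probability at or above a
#' cutoff.
#'
#' @param pp Result of [pair_probabilities()].
#' @param path File path.
#' @param min_p Smallest probability written (default 1e-4).
#' @export
write_pair_probabilities <- function(pp, path, min_p = 1e-4) {
  idx <- which(pp$p >= min_p, arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    p = pp$p[idx])
  tab <- tab[order(tab$i, tab$j), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a `.shape`-style reactivity file
#'
#' Two columns (position, value), `-999` = no data; a convenience alias of
#' [read_reactivity_table()] for folding input.
#'
#' @param path File path.
#' @return A normalized-state [reactivity_profile()].
#' @export
read_shape <- function(path) {
  read_reactivity_table(path, reagent = "1M7", state = "normalized")
}
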