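# Independent oracles used by the folding tests: exhaustive enumeration of
# nested structures and a loop-decomposition energy scorer. Both are written
# against the model definition only and share no code with the package's
# dynamic program.

oracle_ptype <- function(a, b) {
  key <- paste0(a, b)
  idx <- c(AU = 1L, UA = 2L, GC = 3L, CG = 4L, GU = 5L, UG = 6L)
  unname(idx[key])
}

# all nested structures (lists of 2-col pair matrices) over bases[i..j]
enumerate_structures <- function(bases, min_hairpin = 3L) {
  n <- length(bases)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i >= j) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity)            # i unpaired
    for (k in (i + 1L):j) {
      if (k - i - 1L < min_hairpin) next
      if (is.na(oracle_ptype(bases[i], bases[k]))) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (s1 in inner) for (s2 in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# energy of one structure under the simplified nearest-neighbor model
oracle_energy <- function(bases, pairs, params, reactivity = NULL) {
  p <- params
  pe <- numeric(length(bases))
  if (!is.null(reactivity)) {
    v <- as.numeric(reactivity)
    fin <- is.finite(v)
    pe[fin] <- p$m * log(pmax(v[fin], 0) + 1) + p$b
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  pt <- integer(length(bases))
  pt[pairs[, 1L]] <- pairs[, 2L]
  pt[pairs[, 2L]] <- pairs[, 1L]
  children <- function(i, j) {
    kids <- NULL
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) { kids <- rbind(kids, c(k, pt[k])); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    kids
  }
  loop_e <- function(i, j) {
    kids <- children(i, j)
    if (is.null(kids)) return(p$hairpin_a + p$hairpin_b * (j - i - 1L))
    if (nrow(kids) == 1L) {
      k <- kids[1L, 1L]; l <- kids[1L, 2L]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 + s2 > p$max_interior) return(Inf)
      pij <- oracle_ptype(bases[i], bases[j])
      pkl <- oracle_ptype(bases[k], bases[l])
      if (s1 == 0L && s2 == 0L) return(p$stack[pij, pkl])
      if (s1 == 0L || s2 == 0L) return(p$bulge_a + p$bulge_b * (s1 + s2))
      return(p$internal_a + p$internal_b * (s1 + s2))
    }
    unp <- (j - i - 1L) - sum(kids[, 2L] - kids[, 1L] + 1L)
    p$ml_a + p$ml_b * nrow(kids) + p$ml_c * unp
  }
  e <- sum(pe[c(pairs[, 1L], pairs[, 2L])])
  for (r in seq_len(nrow(pairs)))
    e <- e + loop_e(pairs[r, 1L], pairs[r, 2L])
  unname(e)
}

# brute-force MFE and Boltzmann pair probabilities over the enumeration
oracle_fold <- function(sequence, params, reactivity = NULL) {
  bases <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]]
  structs <- enumerate_structures(bases, params$min_hairpin)
  energies <- vapply(structs, function(s)
    oracle_energy(bases, s, params, reactivity), numeric(1))
  list(structures = structs, energies = energies,
       mfe = min(energies))
}

oracle_pair_probs <- function(sequence, params, reactivity = NULL) {
  of <- oracle_fold(sequence, params, reactivity)
  w <- exp(-(of$energies - min(of$energies)) / params$RT)
  w[!is.finite(of$energies)] <- 0
  Z <- sum(w)
  n <- nchar(sequence)
  P <- matrix(0, n, n)
  for (s in seq_along(of$structures)) {
    prs <- of$structures[[s]]
    if (is.null(prs)) next
    for (r in seq_len(nrow(prs)))
      P[prs[r, 1L], prs[r, 2L]] <- P[prs[r, 1L], prs[r, 2L]] + w[s]
  }
  P / Z
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
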