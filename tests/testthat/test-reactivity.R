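test_that("box-plot normalization matches a direct-sort oracle", {
  # 20 identical values: factor is the value itself
  r <- suppressMessages(normalize_boxplot(reactivity_profile(rep(2, 20))))
  expect_equal(r$factor, 2)
  expect_true(all(as.numeric(r$profile) == 1))

  # oracle on random fixtures: exclude > Q3 + 1.5 IQR (capped at 10%),
  # then average the top decile of survivors
  set.seed(2)
  for (rep in 1:10) {
    x <- c(rgamma(90, 2, 4), runif(10, 2, 8))
    r <- suppressMessages(normalize_boxplot(reactivity_profile(x)))
    q <- quantile(x, c(.25, .75), names = FALSE)
    thr <- q[2] + 1.5 * (q[2] - q[1])
    n_out <- min(sum(x > thr), floor(0.1 * length(x)))
    surv <- sort(x, decreasing = TRUE)
    if (n_out > 0) surv <- surv[-seq_len(n_out)]
    fac <- mean(surv[seq_len(max(1, round(0.1 * length(surv))))])
    expect_equal(r$factor, fac)
  }
})

test_that("normalization is scale-invariant and idempotent", {
  set.seed(4)
  x <- rgamma(150, 2, 3)
  x[sample(150, 10)] <- NA
  r1 <- suppressMessages(normalize_boxplot(reactivity_profile(x)))
  r2 <- suppressMessages(normalize_boxplot(reactivity_profile(7.3 * x)))
  expect_equal(as.numeric(r1$profile), as.numeric(r2$profile))
  # renormalizing a normalized profile is a no-op (factor exactly 1)
  r3 <- suppressMessages(normalize_boxplot(r1$profile))
  expect_equal(r3$factor, 1)
  # state tracking and guards
  expect_identical(attr(r1$profile, "state"), "normalized")
  expect_error(suppressMessages(normalize_boxplot(
    reactivity_profile(c(1, 2, NA, NA)))), "at least 10")
})

test_that("the percentile alternative uses the 2%/8% rule", {
  set.seed(5)
  x <- rgamma(200, 2, 3)
  r <- suppressMessages(normalize_boxplot(reactivity_profile(x),
                                          method = "percentile2_8"))
  s <- sort(x, decreasing = TRUE)
  expect_equal(r$factor, mean(s[(floor(0.02 * 200) + 1):floor(0.10 * 200)]))
})

test_that("classification follows the probing thresholds exactly", {
  p <- reactivity_profile(c(0.30, 0.60, 0.90, 0.40, 0.85, NA),
                          state = "normalized")
  expect_identical(classify(p),
                   c("not reactive", "moderately reactive", "very reactive",
                     "moderately reactive", "moderately reactive", NA))
  h <- reactivity_profile(c(0.50, 0.20, 0.70, 0.90), state = "normalized")
  expect_identical(classify(h, classification_scheme("hrf4")),
                   c("poorly reactive", "not reactive",
                     "moderately reactive", "very reactive"))
  # boundaries are sharp at machine scale
  eps <- 1e-9
  for (b in c(0.40, 0.85)) {
    pm <- reactivity_profile(c(b - eps, b + eps), state = "normalized")
    cl <- classify(pm)
    expect_false(cl[1] == cl[2])
  }
  for (b in c(0.29, 0.58, 0.86)) {
    pm <- reactivity_profile(c(b - eps, b + eps), state = "normalized")
    cl <- classify(pm, classification_scheme("hrf4"))
    expect_false(cl[1] == cl[2])
  }
  expect_error(classify(reactivity_profile(0.5)), "normalized")
})

test_that("primer reads merge by averaging overlaps", {
  a <- reactivity_profile(rep(0.4, 50))
  b <- reactivity_profile(rep(0.6, 50))
  merged <- merge_primer_reads(list(a, b), offsets = c(1L, 31L))
  v <- as.numeric(merged)
  expect_true(all(v[1:30] == 0.4))
  expect_true(all(v[31:50] == 0.5))   # ~20-nt overlap averaged
  expect_true(all(v[51:80] == 0.6))

  single <- merge_primer_reads(list(a))
  expect_equal(as.numeric(single), as.numeric(a))

  # a no-data position defers to the read that has data
  c1 <- reactivity_profile(c(0.2, NA, 0.2, 0.2, NA))
  c2 <- reactivity_profile(c(0.8, 0.8, NA, 0.8, NA))
  m <- merge_primer_reads(list(c1, c2))
  expect_equal(as.numeric(m), c(0.5, 0.8, 0.2, 0.5, NA))

  # permutation invariance
  set.seed(6)
  ps <- lapply(1:3, function(i) reactivity_profile(runif(40)))
  offs <- c(1L, 21L, 41L)
  m1 <- merge_primer_reads(ps, offs)
  m2 <- merge_primer_reads(rev(ps), rev(offs))
  expect_equal(as.numeric(m1), as.numeric(m2))
})

test_that("scaling to a reference is least squares through the origin", {
  set.seed(7)
  ref <- reactivity_profile(rgamma(50, 2, 2), state = "normalized")
  s1 <- suppressMessages(scale_to_reference(ref, ref))
  expect_equal(s1$factor, 1)
  dbl <- reactivity_profile(2 * as.numeric(ref), state = "normalized")
  expect_equal(suppressMessages(scale_to_reference(dbl, ref))$factor, 0.5)

  # closed-form oracle on 50 positions with 10 no-data
  t <- as.numeric(ref); t[sample(50, 10)] <- NA
  t <- reactivity_profile(0.7 * t + rnorm(50, 0, 0.05), state = "normalized")
  out <- suppressMessages(scale_to_reference(t, ref))
  ok <- is.finite(as.numeric(t)) & is.finite(as.numeric(ref))
  expect_equal(out$factor,
               sum(as.numeric(t)[ok] * as.numeric(ref)[ok]) /
                 sum(as.numeric(t)[ok]^2))
  short <- reactivity_profile(c(1, rep(NA, 49)), state = "normalized")
  expect_error(suppressMessages(scale_to_reference(short, ref)),
               "common finite")
})

test_that("windowed differencing localizes reagent contrasts", {
  a <- reactivity_profile(rep(0.5, 20), reagent = "NMIA")
  b <- reactivity_profile(rep(0.5, 20), reagent = "1M6")
  expect_true(all(diff_by_window(a, b) == 0))
  a2 <- reactivity_profile(rep(0.7, 20))
  expect_true(all(abs(diff_by_window(a2, b) - 0.2) < 1e-12))
  # impulse spreads to 1/3 over a 3-nt window
  ai <- reactivity_profile(c(rep(0, 9), 1, rep(0, 10)))
  bi <- reactivity_profile(rep(0, 20))
  d <- diff_by_window(ai, bi, window = 3)
  expect_equal(d[9:11], rep(1 / 3, 3))
  expect_equal(d[8], 0)
  expect_error(diff_by_window(a, b, window = 4), "odd")
})

test_that("MaP reactivities are background-corrected rates", {
  cnt <- map_counts(modified = c(50, 0, 100), untreated = c(10, 0, 5),
                    depth_modified = c(1e4, 0, 1e4),
                    depth_untreated = c(1e4, 0, 1e4))
  r <- map_reactivity(cnt, min_depth = 1000)
  expect_equal(as.numeric(r)[1], 0.004)
  expect_true(is.na(as.numeric(r)[2]))      # zero depth
  # background above signal: negative value retained and flagged
  cnt2 <- map_counts(rep(5, 20), rep(50, 20), rep(1e4, 20), rep(1e4, 20))
  r2 <- map_reactivity(cnt2)
  expect_true(all(as.numeric(r2) < 0))
  expect_identical(attr(r2, "n_negative"), 20L)
  expect_error(map_reactivity(cnt, min_depth = 0), "positive")
  expect_error(map_counts(2, 1, 1, 1), NULL)  # count above depth
})

test_that("map count tables round-trip", {
  cnt <- map_counts(c(3, 7), c(1, 2), c(100, 200), c(100, 150))
  path <- tempfile(fileext = ".tsv")
  write_map_counts(cnt, path)
  back <- read_map_counts(path)
  expect_equal(back$modified, cnt$modified)
  expect_equal(back$depth_untreated, cnt$depth_untreated)
})

test_that("replicates combine by position-wise mean before normalization", {
  p1 <- reactivity_profile(c(1, 2, NA))
  p2 <- reactivity_profile(c(3, NA, NA))
  m <- combine_replicates(list(p1, p2))
  expect_equal(as.numeric(m), c(2, 2, NA))
})
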