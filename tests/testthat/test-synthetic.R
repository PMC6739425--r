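test_that("the default core plants six tandem-repeat registers", {
  core <- gen_core(core_layout(), seed = 1)
  expect_identical(nchar(core$sequence), 360L)
  expect_identical(nrow(core$registers), 6L)
  expect_identical(core$registers$label, paste0("TR", 1:6))
  # every repeat is the wobble-aware antiparallel complement of the motif
  bases <- strsplit(core$sequence, "")[[1]]
  expect_identical(paste(bases[78:82], collapse = ""), "GUGAG")
  for (r in seq_len(6))
    expect_identical(paste(bases[core$registers$repeat_start[r]:
                                   core$registers$repeat_end[r]],
                           collapse = ""), "CUUAC")
})

test_that("core generation handles edge counts and is seed-deterministic", {
  empty <- gen_core(core_layout(n_repeats = 0), seed = 2)
  expect_identical(nrow(empty$registers), 0L)
  a <- gen_core(core_layout(), seed = 5)
  b <- gen_core(core_layout(), seed = 5)
  d <- gen_core(core_layout(), seed = 6)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, d$sequence))
})

test_that("scanning recovers exactly the planted registers on random layouts", {
  for (s in 1:60) {
    lay <- random_core_layout(s)
    core <- gen_core(lay, seed = s + 5000)
    got <- suppressMessages(
      scan_kissing(core$sequence, core$structure, scan_params()))
    expect_same_registers(got, core$registers)
  }
})

test_that("simulated reactivities separate paired from unpaired positions", {
  st <- big_paired_structure()
  # zero-variance limit: exactly bimodal
  cp <- simulate_reactivity(st, noise_model(paired_mean = 0.1,
                                            unpaired_shape = 2,
                                            unpaired_scale = 0.5,
                                            nodata_fraction = 0,
                                            constant = TRUE), seed = 1)
  expect_setequal(unique(as.numeric(cp)), c(0.1, 1.0))

  p <- simulate_reactivity(st, noise_model(nodata_fraction = 0.05), seed = 2)
  paired <- st$pt != 0
  v <- as.numeric(p)
  expect_gt(mean(v[!paired], na.rm = TRUE), mean(v[paired], na.rm = TRUE))
  # paired positions sit mostly below the not-reactive threshold
  expect_gt(mean(v[paired] < 0.40, na.rm = TRUE), 0.7)
  # no-data fraction close to the configured rate
  expect_lt(abs(mean(is.na(v)) - 0.05), 0.01)
  expect_true(all(v >= 0, na.rm = TRUE))
  # marginal means near the configured distributions (3 sd of the mean)
  expect_lt(abs(mean(v[paired], na.rm = TRUE) - 0.15),
            3 * 0.15 / sqrt(sum(paired)))
  expect_lt(abs(mean(v[!paired], na.rm = TRUE) - 1.0),
            3 * sqrt(2 * 0.25) / sqrt(sum(!paired)))
})

test_that("mutational-profiling counts follow the configured rates", {
  prof <- reactivity_profile(rep(0, 2000))
  cnt <- simulate_map_counts(prof, depth = 1e6, background = 0.001, seed = 3)
  rate <- mean(cnt$untreated / cnt$depth_untreated)
  se <- sqrt(0.001 * 0.999 / 1e6 / 2000)
  expect_lt(abs(rate - 0.001), 3 * se)

  # zero depth propagates to all-no-data downstream
  z <- simulate_map_counts(prof, depth = 0, seed = 4)
  expect_true(all(is.na(as.numeric(map_reactivity(z)))))
})

test_that("a planted profile survives the MaP round trip", {
  core <- gen_core(core_layout(), seed = 11)
  prof <- simulate_reactivity(core$structure,
                              noise_model(nodata_fraction = 0), seed = 12)
  cnt <- simulate_map_counts(prof, depth = 1e5, seed = 13)
  rec <- suppressMessages(normalize_boxplot(map_reactivity(cnt)))$profile
  expect_gt(cor(as.numeric(rec), as.numeric(prof), use = "complete.obs"),
            0.9)
})

test_that("star-phylogeny alignments carry the planted signals", {
  core <- gen_core(core_layout(), seed = 3)
  expect_error(simulate_alignment(core, n_species = 1, seed = 1),
               "n_species")
  aln <- simulate_alignment(core, n_species = 41, seed = 4)
  expect_identical(length(aln$sequences), 41L)
  expect_identical(unique(nchar(aln$sequences)), nchar(core$sequence))

  # every species keeps at least the configured minimum of repeats
  rc <- repeat_conservation(aln, min_count = 3)
  expect_true(all(rc$pass))
  expect_true(all(rc$count >= attr(aln, "repeat_counts")))

  # full covariation keeps every substituted pair canonical
  aln2 <- simulate_alignment(core, n_species = 12, covary_prob = 1,
                             sub_prob = 0.3, seed = 7)
  cv <- covariation(aln2, pairs = attr(aln2, "planted_pairs"),
                    n_perm = 5, seed = 8)
  expect_true(all(cv$fraction_canonical == 1))

  # planted pairs outrank unpaired column pairs by covariation score
  ss <- which(core$structure$pt == 0)
  set.seed(9)
  fake <- cbind(sample(ss, 15), sample(ss, 15))
  fake <- fake[fake[, 1] < fake[, 2], , drop = FALSE]
  prs <- attr(aln, "planted_pairs")
  cv_p <- covariation(aln, pairs = prs[seq_len(15), ], n_perm = 5, seed = 10)
  cv_f <- covariation(aln, pairs = fake, n_perm = 5, seed = 10)
  expect_gt(min(cv_p$score), max(cv_f$score))
})

test_that("height maps realize the three folding states", {
  hm <- simulate_heightmap("compact", seed = 1)
  expect_identical(dim(hm$heights), c(255L, 255L))

  # compact, noise-free: a single strict regional maximum above half-height
  quiet <- simulate_heightmap("compact", noise_sd_nm = 0, diameter_nm = 40,
                              seed = 2)
  z <- quiet$heights
  half <- max(z) / 2
  n_max <- 0L
  for (i in 2:(nrow(z) - 1)) for (j in 2:(ncol(z) - 1)) {
    if (z[i, j] <= half) next
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (z[i, j] > max(nb[-5])) n_max <- n_max + 1L
  }
  expect_identical(n_max, 1L)

  # intermediate, 3 domes: at least two maxima separated by >= 20 nm
  im <- simulate_heightmap("intermediate", noise_sd_nm = 0, seed = 3)
  zi <- im$heights
  peaks <- which(zi > 0.9 * max(zi), arr.ind = TRUE)
  km <- stats::kmeans(peaks, centers = 3, nstart = 5)
  dists <- as.matrix(dist(km$centers)) * im$pixel_size_nm
  expect_gte(sum(dists[upper.tri(dists)] >= 20), 1)

  expect_error(simulate_heightmap("compact", crop_nm = 30, seed = 1),
               "64 pixels")
  a <- simulate_heightmap("denatured", seed = 4)
  b <- simulate_heightmap("denatured", seed = 4)
  expect_identical(a$heights, b$heights)
})

test_that("height maps round-trip through matrix text", {
  hm <- simulate_heightmap("compact", crop_nm = 80, pixel_size_nm = 1.2,
                           seed = 5)
  path <- tempfile(fileext = ".txt")
  write_heightmap_txt(hm, path)
  back <- read_heightmap_txt(path)
  expect_equal(back$pixel_size_nm, 1.2)
  expect_equal(back$heights, hm$heights, tolerance = 1e-6)
})

test_that("titration curves follow the Hill isotherm", {
  # midpoint and low-concentration limit, noiseless
  tc <- simulate_titration(R0 = 12, Rinf = 9.6, C_half = 1, n_hill = 2,
                           concentrations = c(1e-6, 1, 1e6), noise_sd = 0,
                           seed = 1)
  expect_equal(tc$Rh_nm[2], (12 + 9.6) / 2)
  expect_equal(tc$Rh_nm[1], 12, tolerance = 1e-6)
  expect_equal(tc$Rh_nm[3], 9.6, tolerance = 1e-6)
  # the planted pair of radii implies 20% compaction
  expect_equal(100 * (12 - 9.6) / 12, 20)
  expect_error(simulate_titration(concentrations = numeric(0)), "empty")
  expect_error(simulate_titration(R0 = 9, Rinf = 12), "R0 > Rinf")
})
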