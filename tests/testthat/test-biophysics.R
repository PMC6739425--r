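test_that("PSD obeys Fourier identities", {
  N <- 256; px <- 0.98
  # constant map: no power anywhere
  flat <- height_map(matrix(1.5, N, N), px)
  expect_true(all(compute_psd(flat)$power == 0))

  # single cosine of period 16 px: unique peak at 1/(16 * 0.98)
  row <- cos(2 * pi * (0:(N - 1)) / 16)
  hm <- height_map(matrix(rep(row, N), N, N, byrow = TRUE), px)
  sp <- compute_psd(hm)
  expect_equal(sp$freq[which.max(sp$power)], 1 / (16 * px))
  expect_lt(max(sp$power[-which.max(sp$power)]), 1e-20)

  # white noise: sum of power equals row variance (Parseval)
  set.seed(31)
  z <- matrix(rnorm(N * N), N, N)
  spw <- compute_psd(height_map(z, px))
  zd <- z - rowMeans(z)
  expect_lt(abs(sum(spw$power) / mean(rowMeans(zd^2)) - 1), 0.01)

  # height offset invariance; c^2 scaling under height scaling
  sp0 <- compute_psd(height_map(z + 4.2, px))
  expect_equal(sp0$power, spw$power, tolerance = 1e-10)
  sp2 <- compute_psd(height_map(2 * z, px))
  expect_equal(sp2$power, 4 * spw$power, tolerance = 1e-10)

  expect_error(compute_psd(list(height_map(z, 1), height_map(z, 2))),
               "mixed pixel")
})

test_that("the y axis option transposes the raster", {
  set.seed(32)
  z <- outer(sin((1:128) / 5), rep(1, 128))   # structure along columns
  spx <- compute_psd(height_map(z, 1), axis = "x")
  spy <- compute_psd(height_map(z, 1), axis = "y")
  expect_gt(max(spy$power), max(spx$power) * 10)
})

test_that("auto-affine fits recover exact power laws and intersections", {
  f <- 10^seq(-2.5, -0.5, length.out = 40)
  sp <- structure(data.frame(freq = f, power = 1e-4 * f^-2),
                  class = c("psd_spectrum", "data.frame"))
  fit <- lncstruct:::fit_loglog(sp, range(f))
  expect_equal(fit$gamma, 2, tolerance = 1e-6)
  expect_equal(fit$a0, 1e-4, tolerance = 1e-6)

  # two analytic lines: steep g=2 through (1e-2, 1e-4) and a flat line at
  # 1e-4; they intersect at f = 1e-2, i.e. L = 100 nm
  f2 <- 10^seq(-3, 0, length.out = 60)
  pw <- ifelse(f2 < 1e-2, 1e-4, NA)
  pw[f2 >= 1e-2] <- 1e-8 * f2[f2 >= 1e-2]^-2
  spi <- structure(data.frame(freq = f2, power = pw),
                   class = c("psd_spectrum", "data.frame"))
  out <- suppressMessages(
    fit_autoaffine(spi, range_low = c(1e-3, 9e-3), range_high = c(1.1e-2, 1)))
  expect_equal(out$crossover_freq, 1e-2, tolerance = 1e-6)
  expect_equal(out$length_nm, 100, tolerance = 1e-4)
  # angular convention differs by 2*pi
  out2 <- suppressMessages(
    fit_autoaffine(spi, c(1e-3, 9e-3), c(1.1e-2, 1), convention = "angular"))
  expect_equal(out2$length_nm, 2 * pi * 100, tolerance = 1e-3)

  # parallel lines cannot intersect
  expect_error(suppressMessages(
    fit_autoaffine(sp, range(f)[1] * c(1, 3), range(f)[2] * c(0.3, 1))),
    "parallel")
})

test_that("characteristic length tracks planted particle diameter", {
  ds <- c(15, 25, 35, 45, 55, 65, 75, 85)
  Ls <- vapply(ds, function(d) {
    maps <- lapply(1:8, function(s)
      simulate_heightmap("compact", diameter_nm = d, crop_nm = 500,
                         seed = 100 + s))
    suppressMessages(characteristic_length(maps))$length_nm
  }, numeric(1))
  expect_gte(cor(ds, Ls, method = "spearman"), 0.95)
})

test_that("percent compaction is plain arithmetic with guards", {
  expect_equal(percent_compaction(85, 65), 100 * 20 / 85)
  expect_equal(round(percent_compaction(85, 65), 1), 23.5)
  expect_equal(percent_compaction(50, 50), 0)
  expect_equal(percent_compaction(70, 56), 20)
  expect_error(percent_compaction(0, 10), "positive")
})

test_that("Hill fits are exact at zero noise and unbiased across truths", {
  tc <- simulate_titration(R0 = 12, Rinf = 9.6, C_half = 1, n_hill = 2,
                           noise_sd = 0, seed = 1)
  f <- fit_hill(tc)
  expect_equal(f$R0, 12, tolerance = 1e-6)
  expect_equal(f$Rinf, 9.6, tolerance = 1e-6)
  expect_equal(f$C_half, 1, tolerance = 1e-6)
  expect_equal(f$n, 2, tolerance = 1e-6)
  expect_equal(f$percent_compaction, 20, tolerance = 1e-6)
  expect_true(f$C_half_in_range)
  # fitted curve obeys the midpoint identity
  mid <- f$Rinf + (f$R0 - f$Rinf) / (1 + (f$C_half / f$C_half)^f$n)
  expect_equal(mid, (f$R0 + f$Rinf) / 2)

  set.seed(33)
  for (r in 1:20) {
    R0 <- runif(1, 10, 15); Rinf <- R0 * runif(1, 0.7, 0.9)
    Ch <- 10^runif(1, -1, 1); nh <- runif(1, 0.8, 3)
    tcr <- simulate_titration(R0, Rinf, Ch, nh, noise_sd = 0, seed = r)
    fr <- fit_hill(tcr)
    expect_lt(abs(fr$R0 - R0) / R0, 0.02)
    expect_lt(abs(fr$Rinf - Rinf) / Rinf, 0.02)
    expect_lt(abs(fr$C_half - Ch) / Ch, 0.02)
    expect_lt(abs(fr$n - nh) / nh, 0.02)
  }
})

test_that("expansion trends are flagged and degenerate curves rejected", {
  tc <- simulate_titration(R0 = 12, Rinf = 9.6, noise_sd = 0, seed = 1)
  up <- tc; up$Rh_nm <- rev(up$Rh_nm)
  expect_warning(f <- fit_hill(up), "expansion")
  expect_identical(f$direction, "expansion")
  flat <- tc; flat$Rh_nm <- rep(10, nrow(flat))
  expect_error(fit_hill(flat), "degenerate")
  expect_error(fit_hill(tc[1:3, ]), "at least 5")
})

test_that("construct comparison is antisymmetric and zero on identity", {
  a <- fit_hill(simulate_titration(noise_sd = 0, seed = 1))
  expect_equal(compare_constructs(a, a), 0)
  b <- fit_hill(simulate_titration(R0 = 12, Rinf = 9.6 * 1.08,
                                   noise_sd = 0, seed = 2))
  ab <- compare_constructs(a, b)
  ba <- compare_constructs(b, a)
  expect_equal(ab, 8, tolerance = 1e-6)
  expect_lt(abs(ab + ba * (1 + ab / 100)), 1e-6)  # sign flip up to scale
  expect_true(ba < 0)

  # below the midpoint the two fitted curves coincide; the difference
  # emerges only above it
  grid_lo <- 10^seq(-2, -1, length.out = 5)
  lo_a <- a$Rinf + (a$R0 - a$Rinf) / (1 + (grid_lo / a$C_half)^a$n)
  lo_b <- b$Rinf + (b$R0 - b$Rinf) / (1 + (grid_lo / b$C_half)^b$n)
  expect_lt(max(abs(lo_a - lo_b) / lo_a), 0.01)
  hi <- 100
  hi_a <- a$Rinf + (a$R0 - a$Rinf) / (1 + (hi / a$C_half)^a$n)
  hi_b <- b$Rinf + (b$R0 - b$Rinf) / (1 + (hi / b$C_half)^b$n)
  expect_gt((hi_b - hi_a) / hi_a, 0.05)
})
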