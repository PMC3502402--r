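bank5 <- wavelet_bank(5)

level_energies <- function(dec) {
  vapply(dec$wavelet, function(c) sum(Mod(c)^2) / 2, numeric(1))
}

test_that("zero input gives zero coefficients everywhere", {
  dec <- dtcwt_decompose(rep(0, 256), bank5)
  expect_true(all(vapply(dec$wavelet, function(c) all(Mod(c) == 0),
                         logical(1))))
  expect_true(all(Mod(dec$scaling) == 0))
})

test_that("the filter bank conserves energy within the near-orthogonal bound", {
  withr::local_seed(7)
  for (x in list(replace(rep(0, 256), 100, 1), rnorm(512))) {
    dec <- dtcwt_decompose(x, bank5)
    total <- sum(level_energies(dec)) + sum(Mod(dec$scaling)^2) / 2
    expect_lt(abs(total - sum(x^2)) / sum(x^2), 0.02)
  }
})

test_that("a pure tone lands in its dyadic band", {
  # fs = 250, level 3 band ~ 15.6-31.25 Hz
  dec <- dtcwt_decompose(sine_seg(22), bank5)
  e <- level_energies(dec)
  expect_gt(e[3] / sum(e), 0.60)
})

test_that("quantized entropy matches hand-computed values and bounds", {
  expect_equal(quantized_entropy(rep(3.3, 50)), 0)
  # counts [2, 2, 4] over 3 bins: -(0.25 ln 0.25 * 2 + 0.5 ln 0.5)
  expect_equal(quantized_entropy(c(1, 1, 2, 2, 3, 3, 3, 3), bins = 3),
               1.039720770839918, tolerance = 1e-12)
  # uniform occupancy attains the log(bins) maximum
  vals <- rep(seq_len(8), each = 5) + 0.001
  expect_equal(quantized_entropy(vals, bins = 8), log(8), tolerance = 1e-9)
  withr::local_seed(2)
  for (i in 1:10) {
    e <- quantized_entropy(rnorm(200), bins = 25)
    expect_gte(e, 0); expect_lte(e, log(25))
  }
  expect_error(quantized_entropy(numeric(0)), "non-empty")
})

test_that("level statistics scale homogeneously with amplitude", {
  x <- rnorm(300)
  withr::local_seed(5)
  x <- rnorm(300)
  a <- 3.7
  s1 <- level_stats(dtcwt_decompose(x, bank5), 2)
  s2 <- level_stats(dtcwt_decompose(a * x, bank5), 2)
  expect_equal(s2$energy, a^2 * s1$energy, tolerance = 1e-9)
  expect_equal(s2$mean, a * s1$mean, tolerance = 1e-9)
  expect_equal(s2$median, a * s1$median, tolerance = 1e-9)
  expect_equal(s2$std, a * s1$std, tolerance = 1e-9)
  expect_equal(s2$entropy, s1$entropy, tolerance = 1e-9)
  z <- level_stats(dtcwt_decompose(rep(0, 256), bank5), 1)
  expect_equal(unlist(z), c(mean = 0, median = 0, std = 0, energy = 0,
                            entropy = 0))
})

test_that("the feature map has 5 statistics for J bands plus scaling", {
  ft <- dtcwt_features(sine_seg(6), bank5)
  expect_equal(ncol(ft), 30)
  expect_true(all(grepl("^cw\\.(L[1-5]|scaling)\\.", names(ft))))
  co2 <- dtcwt_features(sine_seg(0.2, fs = 25, duration_s = 8),
                        wavelet_bank(4), prefix = "cw_co2.")
  expect_true(all(grepl("^cw_co2\\.", names(co2))))
})

test_that("dual-tree energies are nearly shift invariant, unlike the real DWT", {
  spec <- tiny_spec(baseline_jump_prob = 0)
  seg <- extract_preshock_window(gen_vf_signal(1, spec, seed = 77), 7.8)
  x <- seg$samples
  e0 <- level_energies(dtcwt_decompose(x, bank5))
  r0 <- vapply(dwt_decompose(x, bank5)$wavelet, function(c) sum(c^2),
               numeric(1))
  carrier <- e0 / sum(e0) >= 0.01    # bands holding >= 1% of wavelet energy
  worst_c <- 0; worst_carrier <- 0; worst_r <- 0
  for (s in 1:16) {
    xs <- c(x[(s + 1):length(x)], x[1:s])
    e <- level_energies(dtcwt_decompose(xs, bank5))
    worst_c <- max(worst_c, abs(e - e0) / e0)
    worst_carrier <- max(worst_carrier, (abs(e - e0) / e0)[carrier])
    r <- vapply(dwt_decompose(xs, bank5)$wavelet, function(c) sum(c^2),
                numeric(1))
    worst_r <- max(worst_r, abs(r - r0) / r0)
  }
  # energy-carrying bands are tightly stable; near-empty bands are looser
  # (their variation is leakage-dominated) but always beat the real DWT
  expect_gt(sum(carrier), 1)
  expect_lt(worst_carrier, 0.05)
  expect_gt(worst_r, worst_c)
})

test_that("decomposition depth is validated against input length", {
  expect_error(dtcwt_decompose(rnorm(16), wavelet_bank(5)), "too short")
  expect_error(wavelet_bank(0), "levels")
})
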