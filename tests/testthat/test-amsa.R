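test_that("amplitude spectrum is calibrated for pure tones", {
  # 8 Hz tone, integer cycles in 7.8 s
  sp <- amplitude_spectrum(sine_seg(8, duration_s = 8))
  peak <- which.max(sp$amps)
  expect_equal(sp$freqs[peak], 8, tolerance = 0.1)
  expect_equal(sp$amps[peak], 1, tolerance = 0.05)
  z <- amplitude_spectrum(signal_segment(rep(0, 512), 250))
  expect_true(all(z$amps == 0))
  expect_error(amplitude_spectrum(signal_segment(rnorm(32), 250)), "short")
})

test_that("Parseval's identity holds for the single-sided spectrum", {
  withr::local_seed(21)
  x <- rnorm(1000); x <- x - mean(x)
  sp <- amplitude_spectrum(signal_segment(x, 250))
  expect_equal(sum(sp$amps^2) / 2, mean(x^2), tolerance = 0.01 * mean(x^2))
})

test_that("AMSA reproduces single-tone and additivity oracles", {
  expect_equal(amsa(signal_segment(rep(0, 1000), 250)), 0)
  one <- amsa(sine_seg(10, duration_s = 8))
  expect_equal(one, 10, tolerance = 0.3)
  t <- (0:1999) / 250
  two <- signal_segment(sin(2 * pi * 5 * t) + 2 * sin(2 * pi * 20 * t), 250)
  expect_equal(amsa(two), 45, tolerance = 1)
  # homogeneity of degree one
  a <- 2.9
  seg <- sine_seg(7, duration_s = 4)
  expect_equal(amsa(signal_segment(a * seg$samples, 250)), a * amsa(seg),
               tolerance = 1e-9)
  expect_error(amsa(seg, band = c(48, 2)), "f_lo < f_hi")
  expect_error(amsa(seg, band = c(2, 200)), "Nyquist")
})

test_that("the decision stump matches hand and oracle computations", {
  st <- stump_threshold(c(1, 2, 9, 10), c(0, 0, 1, 1))
  expect_equal(st$threshold, 5.5)
  expect_equal(st$polarity, ">")
  expect_equal(st$accuracy, 1)
  # replication leaves the split unchanged
  st2 <- stump_threshold(rep(c(1, 2, 9, 10), 3), rep(c(0, 0, 1, 1), 3))
  expect_equal(st2$threshold, 5.5)
  expect_error(stump_threshold(c(1, 2), c(1, 1)), "both classes")
})

test_that("stump equals an independent exhaustive entropy scan", {
  scan_oracle <- function(v, y, w_pos = 2) {
    w <- ifelse(y == 1, w_pos, 1)
    ent <- function(a, b) {
      p <- c(a, b) / (a + b); p <- p[p > 0]; -sum(p * log(p))
    }
    uv <- sort(unique(v))
    mids <- (uv[-1] + uv[-length(uv)]) / 2
    es <- vapply(mids, function(thr) {
      hi <- v > thr
      (sum(w[hi]) * ent(sum(w[hi & y == 1]), sum(w[hi & y == 0])) +
         sum(w[!hi]) * ent(sum(w[!hi & y == 1]), sum(w[!hi & y == 0]))) /
        sum(w)
    }, numeric(1))
    mids[which.min(es)]
  }
  withr::local_seed(31)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    v <- rnorm(n) + 1.2 * y
    expect_equal(stump_threshold(v, y)$threshold, scan_oracle(v, y))
  }
})

test_that("label-independent values give near-zero information gain", {
  withr::local_seed(41)
  v <- rnorm(200)
  y <- rbinom(200, 1, 0.5)
  st <- stump_threshold(v, y)
  expect_lt(st$gain, 0.05)
  expect_lt(abs(st$accuracy - max(mean(y), 1 - mean(y))), 0.12)
})

test_that("AMSA evaluation runs end to end on a synthetic dataset", {
  dd <- gen_dataset(tiny_spec(seed = 17, n_success = 10, n_fail = 14))
  ev <- amsa_evaluate(dd$records)
  expect_s3_class(ev, "vf_amsa_eval")
  expect_equal(nrow(ev$values), 24)
  expect_true(ev$metrics$auc >= 0 && ev$metrics$auc <= 1)
  expect_true(is.finite(ev$stump$threshold))
})
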