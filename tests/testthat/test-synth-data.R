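test_that("generation is bit-reproducible and seed-sensitive", {
  spec <- tiny_spec(seed = 5)
  a <- gen_vf_signal(1, spec, seed = 101)
  b <- gen_vf_signal(1, spec, seed = 101)
  expect_identical(a$samples, b$samples)
  c_ <- gen_vf_signal(1, spec, seed = 102)
  expect_false(identical(a$samples, c_$samples))
  d1 <- gen_dataset(tiny_spec(seed = 1))
  d2 <- gen_dataset(tiny_spec(seed = 1))
  expect_identical(d1$records[[3]]$ecg$samples, d2$records[[3]]$ecg$samples)
  d3 <- gen_dataset(tiny_spec(seed = 2))
  expect_false(identical(d1$records[[3]]$ecg$samples,
                         d3$records[[3]]$ecg$samples))
  expect_length(d3$records, length(d1$records))
})

test_that("the default dataset mirrors the study shape", {
  dd <- gen_dataset(synth_spec(seed = 3, duration_s = 2))
  expect_length(dd$records, 90)
  labs <- vapply(dd$records, function(r) r$outcome, integer(1))
  expect_equal(sum(labs == 1L), 34)
  expect_equal(sum(labs == 0L), 56)
  has_co2 <- vapply(dd$records, function(r) !is.null(r$petco2), logical(1))
  expect_equal(sum(has_co2 & labs == 1L), 20)
  expect_equal(sum(has_co2 & labs == 0L), 28)
  expect_length(dd$prototypes$signals, 8)
  expect_equal(sum(dd$prototypes$classes == 1L), 4)
  # degenerate shapes remain constructible for error-path testing
  empty <- gen_dataset(synth_spec(n_success = 0, n_fail = 3,
                                  n_petco2_success = 0, n_petco2_fail = 0,
                                  duration_s = 2, seed = 1))
  expect_length(empty$records, 3)
  expect_true(all(vapply(empty$records, function(r) r$outcome,
                         integer(1)) == 0L))
})

test_that("coarse and smooth classes differ in amplitude and spectrum", {
  spec <- tiny_spec()
  n <- 30
  stats_of <- function(cls) {
    t(vapply(seq_len(n), function(s) {
      seg <- extract_preshock_window(gen_vf_signal(cls, spec,
                                                   seed = 5000 + 10 * s + cls),
                                     7.8)
      sp <- amplitude_spectrum(seg)
      sel <- sp$freqs >= 1 & sp$freqs <= 30
      centroid <- sum(sp$freqs[sel] * sp$amps[sel]) / sum(sp$amps[sel])
      c(range = diff(range(seg$samples)), centroid = centroid)
    }, numeric(2)))
  }
  coarse <- stats_of(1); smooth <- stats_of(0)
  expect_lt(stats::wilcox.test(coarse[, "range"], smooth[, "range"],
                               alternative = "greater")$p.value, 0.01)
  expect_lt(stats::wilcox.test(coarse[, "centroid"],
                               smooth[, "centroid"])$p.value, 0.01)
})

test_that("PetCO2 traces encode the class-dependent plateau", {
  spec <- tiny_spec()
  lev <- function(cls) {
    mean(vapply(1:15, function(s) {
      mean(gen_petco2(cls, spec, seed = 300 + 7 * s + cls)$samples)
    }, numeric(1)))
  }
  expect_gt(lev(1), lev(0))
  a <- gen_petco2(1, spec, seed = 4)
  expect_identical(a$samples, gen_petco2(1, spec, seed = 4)$samples)
  expect_identical(a$channel, "PETCO2")
  expect_equal(a$fs, spec$fs_co2)
})

test_that("prototypes are extreme-parameter signals near their class", {
  spec <- tiny_spec(seed = 11)
  pr <- gen_prototypes(spec)
  expect_length(pr$signals, 8)
  expect_equal(pr$classes, rep(c(1L, 0L), each = 4))
  # KD closeness: coarse instances sit nearer coarse prototypes
  grid1 <- list(m = 2, tau = 6, r = 0.25, t_max = 300)
  dens <- function(seg) rpd_density(preprocess_segment(seg), grid1$m,
                                    grid1$tau, grid1$r, grid1$t_max)
  proto_d <- lapply(pr$signals, function(s) {
    dens(extract_preshock_window(s, 7.8))
  })
  wins <- 0; n_trials <- 20
  for (s in seq_len(n_trials)) {
    d <- dens(extract_preshock_window(
      gen_vf_signal(1, spec, seed = 9000 + s), 7.8))
    kd <- vapply(proto_d, function(p) kd_distance(as.numeric(p),
                                                  as.numeric(d)), numeric(1))
    wins <- wins + (mean(kd[pr$classes == 1]) < mean(kd[pr$classes == 0]))
  }
  expect_gte(wins, 0.9 * n_trials)
})
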