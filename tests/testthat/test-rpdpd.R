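test_that("delay embedding matches its definition", {
  expect_equal(drop(embed_trajectory(c(1, 2, 3, 4), m = 1, tau = 3)),
               c(1, 2, 3, 4))
  tr <- embed_trajectory(c(1, 2, 3), m = 2, tau = 1)
  expect_equal(tr, matrix(c(2, 3, 1, 2), nrow = 2))
  withr::local_seed(1)
  for (i in 1:10) {
    n <- sample(20:100, 1); m <- sample(1:4, 1); tau <- sample(1:5, 1)
    if (n <= (m - 1) * tau) next
    expect_equal(nrow(embed_trajectory(rnorm(n), m, tau)), n - (m - 1) * tau)
  }
  expect_error(embed_trajectory(rnorm(5), m = 3, tau = 4), "too short")
})

test_that("recurrence scan agrees exactly with the brute-force oracle", {
  withr::local_seed(3)
  for (i in 1:8) {
    n <- sample(80:200, 1)
    x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
    m <- sample(2:4, 1); tau <- sample(1:8, 1); r <- runif(1, 0.1, 0.6)
    traj <- embed_trajectory(x, m, tau)
    radius <- r * sqrt(mean(rowSums(sweep(traj, 2, colMeans(traj))^2)))
    expect_identical(recurrence_periods(traj, r),
                     as.integer(rpd_oracle(traj, radius)))
  }
})

test_that("periodic, monotone and degenerate signals behave as stated", {
  # exact 20-sample period, quarter-period delay: all periods equal 20
  x <- sin(2 * pi * seq_len(400) / 20)
  traj <- embed_trajectory(x, m = 2, tau = 5)
  p <- recurrence_periods(traj, r = 0.05)
  expect_gt(length(p), 0)
  expect_true(all(p == 20L))
  # monotone ramp: no state is ever revisited
  expect_length(recurrence_periods(embed_trajectory(1:200, 2, 2), 0.1), 0)
  # huge radius covers the attractor: nothing ever exits
  withr::local_seed(8)
  expect_length(recurrence_periods(embed_trajectory(rnorm(200), 2, 2), 50), 0)
  expect_error(recurrence_periods(traj, r = 0), "positive")
})

test_that("period densities normalize, bin and flag degeneracy", {
  d <- period_density(c(7L, 7L, 7L), t_max = 10)
  expect_equal(as.numeric(d), replace(rep(0, 10), 7, 1))
  d2 <- period_density(c(rep(3L, 6), rep(9L, 2)), t_max = 10)
  expect_equal(sum(d2), 1)
  expect_equal(d2[3], 0.75); expect_equal(d2[9], 0.25)
  d3 <- period_density(integer(0), t_max = 5)
  expect_true(attr(d3, "degenerate"))
  expect_equal(sum(d3), 0)
  expect_equal(sum(period_density(c(3L, 600L), t_max = 10)), 1)  # overflow cut
})

test_that("KD distance reproduces hand-evaluated asymmetry", {
  dc <- c(0.7, 0.2, 0.1); ds <- c(0.1, 0.4, 0.5)
  expect_equal(kd_distance(dc, ds), 0.836, tolerance = 1e-12)
  expect_equal(kd_distance(ds, dc), 0.692, tolerance = 1e-12)
  expect_equal(kd_distance(dc, dc), 0)
  expect_error(kd_distance(dc, c(0.5, 0.5)), "period axis")
  expect_error(kd_distance(dc, ds, window = c(2, 1)), "lo < hi")
  withr::local_seed(4)
  for (i in 1:10) {
    a <- runif(6); a <- a / sum(a); b <- runif(6); b <- b / sum(b)
    expect_gte(kd_distance(a, b), 0)
  }
})

test_that("signed KD keeps per-period signs and is bounded by KD", {
  dp <- c(0.7, 0.3); ds <- c(0.3, 0.7)
  expect_equal(signed_kd(dp, ds), 0.064, tolerance = 1e-12)
  expect_equal(signed_kd(dp, dp), 0)
  withr::local_seed(9)
  for (i in 1:20) {
    a <- runif(8); a <- a / sum(a); b <- runif(8); b <- b / sum(b)
    expect_lte(abs(signed_kd(a, b)), kd_distance(a, b) + 1e-12)
  }
  # equality when every period difference shares one sign
  a <- c(0.4, 0.35, 0.25); b <- c(0.2, 0.3, 0.2)    # a > b everywhere
  expect_equal(signed_kd(a, b), kd_distance(a, b))
  # aggregate signing variant collapses to a single sign
  expect_equal(signed_kd(dp, ds, sign_mode = "aggregate"), 0)
})

test_that("prototype features are label-blind and order invariant", {
  withr::local_seed(5)
  dens <- lapply(1:4, function(i) { d <- runif(10); d / sum(d) })
  ps <- prototype_set(dens, c(1, 1, 0, 0))
  target <- dens[[1]]
  ft <- skd_features(structure(target, degenerate = FALSE), ps)
  expect_named(ft, c("rpd.skd_success", "rpd.skd_fail"))
  ps_perm <- prototype_set(dens[c(2, 1, 4, 3)], c(1, 1, 0, 0))
  ft_perm <- skd_features(structure(target, degenerate = FALSE), ps_perm)
  expect_equal(ft, ft_perm)
  # a signal equal to the sole prototype of a class scores 0 for that class
  ps_single <- prototype_set(dens[c(1, 3)], c(1, 0))
  ft1 <- skd_features(structure(target, degenerate = FALSE), ps_single)
  expect_equal(ft1$rpd.skd_success, 0)
  # degenerate densities yield the sentinel, flagged
  degen <- period_density(integer(0), 10)
  ftd <- skd_features(degen, ps)
  expect_equal(unlist(ftd), c(rpd.skd_success = 0, rpd.skd_fail = 0))
  expect_true(attr(ftd, "degenerate"))
})

test_that("sep matches an independent straight-line recomputation", {
  withr::local_seed(6)
  mkd <- function() { d <- runif(12); d / sum(d) }
  ts_d <- lapply(1:6, function(i) mkd())
  labels <- c(1, 1, 1, 0, 0, 0)
  pd <- lapply(1:6, function(i) mkd())
  pcls <- c(1, 1, 1, 0, 0, 0)
  ps <- prototype_set(pd, pcls)
  win <- c(1, 12)
  got <- sep_score(ts_d, labels, ps, window = win)
  # independent recomputation, written directly from the formula
  manual <- 0
  for (i in 1:6) {
    kd <- sapply(1:6, function(j) {
      sum((1 + pd[[j]]) * (pd[[j]] - ts_d[[i]])^2)
    })
    w <- kd[pcls == labels[i]]; b <- kd[pcls != labels[i]]
    psd <- function(v) sqrt(mean((v - mean(v))^2))
    manual <- manual + (mean(b) - mean(w)) / max(psd(b), psd(w), 1e-12)
  }
  expect_equal(got, manual, tolerance = 1e-9)
  # equidistant densities give zero separation
  same <- lapply(1:4, function(i) rep(1 / 12, 12))
  ps0 <- prototype_set(same, c(1, 1, 0, 0))
  expect_equal(sep_score(ts_d[1:2], c(1, 0), ps0, win), 0)
})

test_that("label shuffling degrades mean separation", {
  withr::local_seed(12)
  # well-separated point-mass-ish classes matching their prototypes
  mkd <- function(center) {
    d <- dnorm(1:20, center, 1); d / sum(d)
  }
  ts_d <- c(lapply(1:5, function(i) mkd(5 + rnorm(1, 0, 0.3))),
            lapply(1:5, function(i) mkd(15 + rnorm(1, 0, 0.3))))
  labels <- rep(c(1, 0), each = 5)
  ps <- prototype_set(c(lapply(1:3, function(i) mkd(5)),
                        lapply(1:3, function(i) mkd(15))),
                      rep(c(1, 0), each = 3))
  true_sep <- sep_score(ts_d, labels, ps, c(1, 20))
  expect_gt(true_sep, 0)
  shuffled <- replicate(50, sep_score(ts_d, sample(labels), ps, c(1, 20)))
  expect_gt(true_sep, mean(shuffled))
})

test_that("parameter optimization is exhaustive with deterministic ties", {
  withr::local_seed(13)
  sigs <- lapply(1:6, function(i) {
    sine_seg(sample(c(5, 9), 1), duration_s = 2)
  })
  labels <- c(1, 1, 1, 0, 0, 0)
  protos <- c(lapply(1:2, function(i) sine_seg(5, 2)),
              lapply(1:2, function(i) sine_seg(9, 2)))
  g1 <- rpd_grid(m = 2, tau = 4, r = 0.2, t_max = 80,
                 windows = list(c(1, 80)))
  p1 <- optimize_rpd_params(sigs, labels, protos, c(1, 1, 0, 0), grid = g1)
  expect_equal(c(p1$m, p1$tau, p1$r), c(2, 4, 0.2))
  expect_equal(p1$window, c(1, 80))
  # a superset grid can only improve the maximum
  g2 <- rpd_grid(m = c(2, 3), tau = c(4, 8), r = c(0.2, 0.4), t_max = 80,
                 windows = list(c(1, 40), c(41, 80), c(1, 80)))
  p2 <- optimize_rpd_params(sigs, labels, protos, c(1, 1, 0, 0), grid = g2)
  expect_gte(p2$sep, p1$sep - 1e-12)
  expect_equal(nrow(p2$search), 8 * 3)
})

test_that("the point-mass limit of periodicity emerges as r shrinks", {
  x <- sin(2 * pi * seq_len(500) / 25)
  mass_at_p <- sapply(c(0.5, 0.2, 0.08), function(r) {
    rpd_density(x, m = 2, tau = 6, r = r, t_max = 50)[25]
  })
  expect_true(all(diff(mass_at_p) >= -1e-12))
  expect_gt(mass_at_p[3], 0.99)
})
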