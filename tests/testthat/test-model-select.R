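test_that("ROC metrics match hand enumeration and the pROC cross-check", {
  expect_equal(roc_and_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  # 3 concordant pairs, 1 discordant out of 4
  expect_equal(roc_and_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc,
               0.75)
  withr::local_seed(51)
  for (i in 1:5) {
    s <- round(runif(60), 2)          # ties included
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_and_metrics(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  big <- roc_and_metrics(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  expect_error(roc_and_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("threshold metrics report sensitivity and specificity", {
  r <- roc_and_metrics(c(0.1, 0.3, 0.6, 0.9), c(0, 1, 0, 1),
                       threshold = 0.5)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$accuracy, 0.5)
})

test_that("RFE keeps a planted informative feature to the end", {
  hits <- 0
  for (s in 1:20) {
    withr::local_seed(600 + s)
    n <- 60
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 10), n, 10)
    X[, 4] <- X[, 4] + 2 * y
    colnames(X) <- paste0("f", 1:10)
    rk <- rfe_rank(vfshock:::standardize_by(X, seq_len(n)), y)
    hits <- hits + (rk$feature[rk$rank == 1] == "f4")
  }
  expect_gte(hits, 18)
})

test_that("a duplicated informative feature occupies the top two ranks", {
  withr::local_seed(3)
  n <- 60; y <- rep(c(0L, 1L), each = 30)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 2] <- X[, 2] + 2 * y
  X[, 5] <- X[, 2]
  colnames(X) <- paste0("f", 1:8)
  rk <- rfe_rank(vfshock:::standardize_by(X, seq_len(n)), y)
  expect_setequal(rk$rank[rk$feature %in% c("f2", "f5")], c(1L, 2L))
  # single feature is trivially rank 1; constant features still rankable
  one <- rfe_rank(matrix(rnorm(20), ncol = 1,
                         dimnames = list(NULL, "only")), rep(c(0L, 1L), 10))
  expect_equal(one$rank, 1L)
  Xc <- cbind(X[, 1:3], const = 0)
  rkc <- rfe_rank(Xc, y)
  expect_equal(rkc$feature[rkc$elim_step == 1], "const")
})

test_that("subset selection breaks ties toward fewer features", {
  path <- tibble::tibble(
    size = 10:1,
    features = lapply(10:1, function(k) paste0("f", seq_len(k))),
    accuracy = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  expect_length(select_subset(path), 6)    # plateau from 6 features up
  path$accuracy <- seq(0.5, 0.95, length.out = 10)  # decreasing with size
  expect_length(select_subset(path), 1)
  path$accuracy <- seq(0.95, 0.5, length.out = 10)  # increasing with size
  expect_length(select_subset(path), 10)
})

test_that("selection frequencies are exact rationals with the run-count denominator", {
  feats <- paste0("f", 1:5)
  runs <- c(replicate(70, c("f1", "f2"), simplify = FALSE),
            replicate(20, c("f2", "f3"), simplify = FALSE),
            replicate(10, "f2", simplify = FALSE))
  fr <- selection_frequencies(runs, feats, k_l1 = 10, k_l2 = 10)
  expect_identical(fr$s_l2, c(70L, 100L, 20L, 0L, 0L))
  expect_identical(fr$f_s, fr$s_l2 / 100)
  expect_true(all(fr$f_s * 100 == round(fr$f_s * 100)))
  # the 70% boundary is inclusive; 20% is spurious and excluded
  expect_identical(fr$selected, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(selection_frequencies(runs[1:99], feats, 10, 10), "expected")
})

test_that("stratified folds preserve the class ratio within one instance", {
  y <- rep(c(0L, 1L), c(56, 34))
  f <- make_folds(y, 10, seed = 4)
  tab <- table(f, y)
  expect_true(all(abs(tab[, "0"] - 5.6) <= 1))
  expect_true(all(abs(tab[, "1"] - 3.4) <= 1))
  expect_identical(make_folds(y, 10, seed = 4), f)   # seeded determinism
  # grouped mode keeps subjects intact
  g <- rep(paste0("p", 1:30), each = 3)
  fg <- make_folds(rep(c(0L, 1L), 45), 5, seed = 2, groups = g)
  for (gr in unique(g)) expect_length(unique(fg[g == gr]), 1L)
})

test_that("raising the misclassification cost never hurts training sensitivity", {
  viol <- 0
  for (s in 1:10) {
    withr::local_seed(700 + s)
    n <- 60
    y <- rep(c(0L, 1L), c(40, 20))
    X <- matrix(rnorm(n * 5), n, 5)
    X[, 1] <- X[, 1] + 1.2 * y
    sens <- vapply(c(1, 2), function(cr) {
      m <- vfshock:::fit_cost_svm(X, y, cost_ratio = cr)
      mean(stats::predict(m, X)[y == 1] == "1")
    }, numeric(1))
    viol <- viol + (sens[2] < sens[1])
  }
  expect_lte(viol, 1)
})
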