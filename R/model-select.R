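## Cost-sensitive RFE-SVM feature selection and evaluation metrics.

#' ROC curve, AUC and threshold metrics
#'
#' Trapezoidal area under the ROC curve of `scores` against binary `labels`
#' (1 = success, the positive class), plus sensitivity/specificity/accuracy
#' at a fixed decision threshold.
#'
#' @param scores Numeric classifier scores, larger = more likely positive.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Decision threshold applied as `score > threshold`.
#' @param score_scale `"prob"` for calibrated `[0, 1]` scores (default) or
#'   `"raw"` for uncalibrated decision values; informational only.
#' @return A list of class `vf_roc`: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`, and `roc` (a tibble of FPR/TPR points).
#' @export
roc_and_metrics <- function(scores, labels, threshold = 0.22,
                            score_scale = c("prob", "raw")) {
  score_scale <- match.arg(score_scale)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties so the curve steps diagonally through tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred <- as.integer(scores > threshold)
  structure(list(
    auc = auc,
    accuracy = mean(pred == labels),
    sensitivity = mean(pred[labels == 1L] == 1L),
    specificity = mean(pred[labels == 0L] == 0L),
    threshold = threshold, score_scale = score_scale,
    roc = tibble::tibble(fpr = fpr, tpr = tpr)),
    class = "vf_roc")
}

## ---- SVM helpers ------------------------------------------------------------

# cost-sensitive SVM; y integer 0/1, X numeric matrix (already standardized)
fit_cost_svm <- function(X, y, kernel = "linear", cost = 1, gamma = NULL,
                         cost_ratio = 2) {
  yf <- factor(y, levels = c(0L, 1L))
  args <- list(x = X, y = yf, kernel = kernel, cost = cost, scale = FALSE,
               class.weights = c("0" = 1, "1" = cost_ratio))
  if (kernel == "radial" && !is.null(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

# decision values oriented so larger = class 1
svm_decision <- function(model, X) {
  pr <- stats::predict(model, X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  first <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
  if (first == "1") dv else -dv
}

svm_linear_weights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

#' SVM hyperparameter grid
#'
#' @param kernels Kernels to try (`"linear"`, `"radial"`).
#' @param C Soft-margin costs.
#' @param gamma_mult Multipliers on the scale heuristic `1 / n_features`
#'   (features are standardized, so this matches `1 / (p * var)`); radial
#'   kernel only.
#' @return A tibble with one row per parameter combination, in search order.
#' @export
svm_param_grid <- function(kernels = c("linear", "radial"),
                           C = c(0.1, 1, 10, 100),
                           gamma_mult = c(0.5, 1, 2)) {
  rows <- list()
  for (k in kernels) {
    for (cc in C) {
      if (k == "linear") {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(kernel = k, cost = cc, gamma_mult = NA_real_)
      } else {
        for (g in gamma_mult) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(kernel = k, cost = cc, gamma_mult = g)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

## ---- RFE --------------------------------------------------------------------

#' Recursive feature elimination ranking with a cost-sensitive linear SVM
#'
#' Fits a linear SVM (false negatives weighted `cost_ratio`:1), removes the
#' feature with the smallest absolute weight (ties: the later column), refits
#' and repeats. The last surviving feature has rank 1.
#'
#' @param X Numeric feature matrix or data frame (standardized).
#' @param y 0/1 labels; both classes must be present.
#' @param cost_ratio Positive-class weight.
#' @param C Linear SVM cost parameter.
#' @return A tibble with `feature`, `rank` (1 = retained longest) and
#'   `elim_step` (step at which the feature was eliminated; the survivor gets
#'   the final step).
#' @export
rfe_rank <- function(X, y, cost_ratio = 2, C = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(X)))
  remaining <- seq_len(ncol(X))
  order_out <- integer(0)
  while (length(remaining) > 1L) {
    m <- fit_cost_svm(X[, remaining, drop = FALSE], y, cost = C,
                      cost_ratio = cost_ratio)
    w <- abs(svm_linear_weights(m))
    worst <- max(which(w == min(w)))          # ties: drop the later column
    order_out <- c(order_out, remaining[worst])
    remaining <- remaining[-worst]
  }
  order_out <- c(order_out, remaining)
  tibble::tibble(feature = feats[order_out],
                 elim_step = seq_along(order_out),
                 rank = rev(seq_along(order_out)))
}

# RFE with per-step validation accuracy: fits on (X_tr, y_tr), measures
# accuracy of each nested subset on (X_val, y_val). Returns the path tibble
# used by select_subset(); the elimination order doubles as the feature
# ranking (rank 1 = last survivor), attached as attribute "ranks".
rfe_validation_path <- function(X_tr, y_tr, X_val, y_val, cost_ratio = 2,
                                C = 1) {
  X_tr <- as.matrix(X_tr); X_val <- as.matrix(X_val)
  feats <- colnames(X_tr)
  remaining <- seq_len(ncol(X_tr))
  elim <- integer(0)
  rows <- list()
  repeat {
    m <- fit_cost_svm(X_tr[, remaining, drop = FALSE], y_tr, cost = C,
                      cost_ratio = cost_ratio)
    pred <- as.integer(as.character(
      stats::predict(m, X_val[, remaining, drop = FALSE])))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      size = length(remaining),
      features = list(feats[remaining]),
      accuracy = mean(pred == y_val))
    if (length(remaining) == 1L) break
    w <- abs(svm_linear_weights(m))
    worst <- max(which(w == min(w)))
    elim <- c(elim, remaining[worst])
    remaining <- remaining[-worst]
  }
  elim <- c(elim, remaining)
  out <- dplyr::bind_rows(rows)
  attr(out, "ranks") <- tibble::tibble(feature = feats[elim],
                                       rank = rev(seq_along(elim)))
  out
}

#' Best-performing feature subset along an elimination path
#'
#' The smallest subset attaining the maximum (cross-validated) accuracy; ties
#' on accuracy break toward fewer features.
#'
#' @param path A tibble with columns `size`, `features` (list column) and
#'   `accuracy`, as produced during RFE.
#' @return The selected character vector of feature names.
#' @export
select_subset <- function(path) {
  best_acc <- max(path$accuracy)
  cand <- path[path$accuracy >= best_acc - 1e-12, ]
  cand$features[[which.min(cand$size)]]
}

#' Selection frequencies over inner cross-validation runs
#'
#' `f_s = S_L2 / (k_L1 * k_L2)` where `S_L2` counts the inner level-2 runs in
#' which a feature was a member of the best-performing subset. Features at or
#' above `cutoff` (default 70%) form the reduced matrix used for parameter
#' tuning; rarely selected features are treated as spurious.
#'
#' @param runs List of character vectors: the selected subset of each inner
#'   run (`k_L1 * k_L2` of them).
#' @param features All candidate feature names.
#' @param k_l1,k_l2 Fold counts of the two inner levels.
#' @param cutoff Selection-frequency cutoff (inclusive).
#' @param ranks Optional list of per-run rank tibbles (from [rfe_rank()]) to
#'   add rank-median and rank-range columns.
#' @return A tibble with `feature`, `s_l2`, `f_s`, `selected`, and (when
#'   `ranks` is given) `rank_median`, `rank_min`, `rank_max`.
#' @export
selection_frequencies <- function(runs, features, k_l1, k_l2, cutoff = 0.7,
                                  ranks = NULL) {
  if (length(runs) != k_l1 * k_l2) {
    stop(sprintf("expected %d runs, got %d", k_l1 * k_l2, length(runs)),
         call. = FALSE)
  }
  s_l2 <- vapply(features, function(f) {
    sum(vapply(runs, function(r) f %in% r, logical(1)))
  }, integer(1))
  out <- tibble::tibble(feature = features, s_l2 = as.integer(s_l2),
                        f_s = s_l2 / (k_l1 * k_l2),
                        selected = s_l2 / (k_l1 * k_l2) >= cutoff)
  if (!is.null(ranks)) {
    rk <- dplyr::bind_rows(ranks)
    stats_tb <- rk |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(rank_median = stats::median(.data$rank),
                       rank_min = min(.data$rank), rank_max = max(.data$rank),
                       .groups = "drop")
    out <- dplyr::left_join(out, stats_tb, by = "feature")
  }
  out
}

## ---- folds ------------------------------------------------------------------

#' Stratified cross-validation fold assignment
#'
#' Instances are shuffled within class and dealt round-robin, so each fold
#' preserves the class ratio to within one instance. With `groups`, whole
#' groups (e.g. subjects) are kept in one fold.
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @param groups Optional grouping vector (same length as `labels`).
#' @return Integer fold assignment in `1..k` per instance.
#' @export
make_folds <- function(labels, k, seed = 1, groups = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  fold <- integer(n)
  rs <- local_rng(seed)
  if (is.null(groups)) {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[order(rs$unif(length(idx)))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gs <- unique(groups)
    g_lab <- vapply(gs, function(g) round(mean(labels[groups == g])), numeric(1))
    for (cls in unique(g_lab)) {
      gsel <- gs[g_lab == cls]
      gsel <- gsel[order(rs$unif(length(gsel)))]
      gf <- rep_len(seq_len(k), length(gsel))
      for (i in seq_along(gsel)) fold[groups == gsel[i]] <- gf[i]
    }
  }
  fold
}

# small deterministic RNG stream independent of the global .Random.seed,
# so nested components can draw reproducibly without interfering
local_rng <- function(seed) {
  state <- as.numeric(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
  list(unif = function(n) vapply(seq_len(n), function(i) nxt(), numeric(1)),
       int = function(max) floor(nxt() * max) + 1L)
}

# standardize columns by training statistics; constant columns get sd 1
standardize_by <- function(X, train_idx) {
  X <- as.matrix(X)
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale(X, center = mu, scale = sdv)
}
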