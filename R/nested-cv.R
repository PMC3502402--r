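#' Configuration for twice-nested cross-validation
#'
#' @param k_outer Outer evaluation folds.
#' @param k_l1 Level-1 folds (hyperparameter tuning).
#' @param k_l2 Level-2 folds (feature selection), nested inside each level-1
#'   training set.
#' @param cost_ratio Misclassification cost on the positive class (false
#'   negatives penalized `cost_ratio`:1).
#' @param fs_cutoff Selection-frequency cutoff defining the reduced feature
#'   matrix.
#' @param threshold Classifier-output decision threshold on the calibrated
#'   score.
#' @param svm_grid Hyperparameter grid from [svm_param_grid()].
#' @param rfe_C Linear-SVM cost used during RFE ranking.
#' @param seed Integer seed controlling all fold draws.
#' @return A named list.
#' @export
nested_cv_config <- function(k_outer = 10, k_l1 = 10, k_l2 = 10,
                             cost_ratio = 2, fs_cutoff = 0.7,
                             threshold = 0.22, svm_grid = svm_param_grid(),
                             rfe_C = 1, seed = 1) {
  list(k_outer = k_outer, k_l1 = k_l1, k_l2 = k_l2, cost_ratio = cost_ratio,
       fs_cutoff = fs_cutoff, threshold = threshold, svm_grid = svm_grid,
       rfe_C = rfe_C, seed = seed)
}

# Platt-style monotone calibration of decision values, fit on training only
platt_calibrate <- function(dv_train, y_train) {
  df <- data.frame(dv = dv_train, y = y_train)
  fit <- suppressWarnings(stats::glm(y ~ dv, family = stats::binomial(),
                                     data = df))
  function(dv) {
    as.numeric(suppressWarnings(
      stats::predict(fit, newdata = data.frame(dv = dv), type = "response")))
  }
}

#' Twice-nested cross-validated evaluation
#'
#' Outer folds estimate generalization; inside each outer training set,
#' level-2 cross-validation (nested within each level-1 training set) selects
#' features by cost-sensitive RFE-SVM, selection frequencies over the
#' `k_l1 * k_l2` inner runs define a reduced feature matrix (`f_s >=`
#' `fs_cutoff`), level-1 cross-validation tunes SVM hyperparameters on that
#' reduced matrix, and the modal parameter combination is used to train the
#' final fold model. Feature subsets and parameters are therefore blind to
#' the outer test fold.
#'
#' @param X Feature tibble/matrix (numeric columns only).
#' @param y 0/1 outcome per row (1 = successful defibrillation).
#' @param config A [nested_cv_config()].
#' @param fold_feature_fn Optional `function(train_idx)` returning a tibble
#'   of additional feature columns for all rows, fitted using training rows
#'   only (used for the RPD-PD features, whose embedding parameters are
#'   re-selected per fold).
#' @param outer_folds Optional precomputed outer fold assignment (1..k per
#'   row); by default stratified folds are drawn from `config$seed`.
#' @param groups Optional subject identifiers for grouped outer folds.
#' @return An object of class `vf_nested_cv`: `predictions` (tibble of
#'   per-instance out-of-fold scores), `folds` (per-fold selections,
#'   parameters and selection-frequency tables), `metrics` (mean per-fold
#'   accuracy, pooled accuracy, AUC, sensitivity, specificity), `roc`.
#' @export
nested_cv <- function(X, y, config = nested_cv_config(),
                      fold_feature_fn = NULL, outer_folds = NULL,
                      groups = NULL) {
  X <- tibble::as_tibble(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  if (is.null(outer_folds)) {
    outer_folds <- make_folds(y, config$k_outer, seed = config$seed,
                              groups = groups)
  }
  grid <- config$svm_grid
  fold_info <- list()
  preds <- list()

  for (f in sort(unique(outer_folds))) {
    test_idx <- which(outer_folds == f)
    train_idx <- which(outer_folds != f)
    Xf <- X
    if (!is.null(fold_feature_fn)) {
      extra <- fold_feature_fn(train_idx)
      Xf <- dplyr::bind_cols(X, extra)
    }
    Xs <- standardize_by(Xf, train_idx)
    feats <- colnames(Xs)
    y_tr <- y[train_idx]

    ## Level 1 folds (hyperparameter tuning); level 2 nested inside each
    l1_folds <- make_folds(y_tr, config$k_l1,
                           seed = config$seed + 1000L * f + 1L)
    sel_runs <- list(); sel_ranks <- list()
    for (l1 in seq_len(config$k_l1)) {
      l1_tr <- train_idx[l1_folds != l1]
      l2_folds <- make_folds(y[l1_tr], config$k_l2,
                             seed = config$seed + 1000L * f + 10L * l1 + 2L)
      for (l2 in seq_len(config$k_l2)) {
        tr <- l1_tr[l2_folds != l2]
        va <- l1_tr[l2_folds == l2]
        if (length(unique(y[tr])) < 2L || length(va) == 0L) next
        path <- rfe_validation_path(Xs[tr, , drop = FALSE], y[tr],
                                    Xs[va, , drop = FALSE], y[va],
                                    cost_ratio = config$cost_ratio,
                                    C = config$rfe_C)
        sel_runs[[length(sel_runs) + 1L]] <- select_subset(path)
        sel_ranks[[length(sel_ranks) + 1L]] <- attr(path, "ranks")
      }
    }
    n_runs <- length(sel_runs)
    if (n_runs == 0L) {
      stop("no inner selection run had both classes; use fewer folds for ",
           "this sample size", call. = FALSE)
    }
    freq <- selection_frequencies(sel_runs, feats,
                                  k_l1 = 1L, k_l2 = n_runs,
                                  cutoff = config$fs_cutoff,
                                  ranks = sel_ranks)
    reduced <- freq$feature[freq$selected]
    if (length(reduced) == 0L) {
      reduced <- freq$feature[freq$f_s == max(freq$f_s)]
    }

    ## Level 1: tune hyperparameters on the reduced matrix
    choice <- integer(0)
    for (l1 in seq_len(config$k_l1)) {
      tr <- train_idx[l1_folds != l1]
      va <- train_idx[l1_folds == l1]
      if (length(unique(y[tr])) < 2L || length(va) == 0L) next
      accs <- vapply(seq_len(nrow(grid)), function(g) {
        gamma <- if (!is.na(grid$gamma_mult[g])) {
          grid$gamma_mult[g] / length(reduced)
        } else NULL
        m <- fit_cost_svm(Xs[tr, reduced, drop = FALSE], y[tr],
                          kernel = grid$kernel[g], cost = grid$cost[g],
                          gamma = gamma, cost_ratio = config$cost_ratio)
        pred <- as.integer(as.character(
          stats::predict(m, Xs[va, reduced, drop = FALSE])))
        mean(pred == y[va])
      }, numeric(1))
      choice <- c(choice, which.max(accs))   # ties: first in grid order
    }
    tabc <- tabulate(choice, nbins = nrow(grid))
    modal <- which.max(tabc)                  # ties: earliest grid row

    ## final fold model
    gamma <- if (!is.na(grid$gamma_mult[modal])) {
      grid$gamma_mult[modal] / length(reduced)
    } else NULL
    m_final <- fit_cost_svm(Xs[train_idx, reduced, drop = FALSE], y_tr,
                            kernel = grid$kernel[modal],
                            cost = grid$cost[modal], gamma = gamma,
                            cost_ratio = config$cost_ratio)
    cal <- platt_calibrate(svm_decision(m_final,
                                        Xs[train_idx, reduced, drop = FALSE]),
                           y_tr)
    score <- cal(svm_decision(m_final, Xs[test_idx, reduced, drop = FALSE]))
    preds[[length(preds) + 1L]] <- tibble::tibble(
      row = test_idx, fold = f, score = score, label = y[test_idx])
    fold_info[[length(fold_info) + 1L]] <- list(
      fold = f, selected = reduced, params = grid[modal, ],
      frequencies = freq, n_inner_runs = n_runs,
      l1_choices = choice)
  }

  predictions <- dplyr::bind_rows(preds)
  pooled <- roc_and_metrics(predictions$score, predictions$label,
                            threshold = config$threshold)
  fold_acc <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(acc = mean((.data$score > config$threshold) ==
                                  (.data$label == 1L)), .groups = "drop")
  structure(list(
    predictions = predictions, folds = fold_info,
    outer_folds = outer_folds, config = config,
    metrics = list(accuracy = mean(fold_acc$acc),
                   accuracy_pooled = pooled$accuracy,
                   auc = pooled$auc,
                   sensitivity = pooled$sensitivity,
                   specificity = pooled$specificity),
    fold_accuracies = fold_acc, roc = pooled$roc),
    class = "vf_nested_cv")
}

#' @export
print.vf_nested_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<vf_nested_cv> %d instances, %d outer folds\n",
                     "  accuracy (mean over folds) %.3f | pooled %.3f\n",
                     "  ROC AUC %.3f | sens %.3f / spec %.3f @ %.2f\n"),
              nrow(x$predictions), length(x$folds), m$accuracy,
              m$accuracy_pooled, m$auc, m$sensitivity, m$specificity,
              x$config$threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold summary of a nested cross-validation result
#'
#' @param x A `vf_nested_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per outer fold: fold id, number of selected
#'   features, the selected feature names, the modal kernel and cost, and the
#'   fold's test accuracy.
#' @export
tidy.vf_nested_cv <- function(x, ...) {
  purrr::map_dfr(x$folds, function(fi) {
    tibble::tibble(fold = fi$fold,
                   n_selected = length(fi$selected),
                   features = paste(fi$selected, collapse = ";"),
                   kernel = fi$params$kernel,
                   cost = fi$params$cost)
  }) |>
    dplyr::left_join(x$fold_accuracies, by = "fold")
}

#' One-row performance summary of a nested cross-validation result
#'
#' @param x A `vf_nested_cv` object.
#' @param ... Unused.
#' @export
glance.vf_nested_cv <- function(x, ...) {
  tibble::as_tibble(x$metrics)
}

#' ROC curve plot for a nested cross-validation result
#'
#' @param object A `vf_nested_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vf_nested_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  title = sprintf("Pooled ROC (AUC = %.3f)",
                                  object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
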