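## End-to-end feature extraction and evaluation over a shock dataset.

#' Static (label-free) feature table of a shock dataset
#'
#' Preprocesses each record's pre-shock window and extracts time-series and
#' dual-tree complex wavelet features from the ECG and, when present, from
#' the PetCO2 trace (prefixes `tf_co2.` / `cw_co2.`). RPD-PD features are
#' NOT included here: their embedding parameters must be fitted on training
#' data, so [evaluate_shock_dataset()] adds them per cross-validation fold
#' (and [extract_features()] adds them only when given already-fitted
#' parameters).
#'
#' @param records List of [shock_record()]s.
#' @param duration_s Analysis window (s).
#' @param bank A [wavelet_bank()].
#' @param use_petco2 Include PetCO2 features (every record must then carry a
#'   PetCO2 trace).
#' @param config Preprocessing configuration for the ECG channel.
#' @param co2_config Preprocessing configuration for the PetCO2 channel: the
#'   same two-stage methodology, with windows rescaled to the slow channel
#'   (mild smoothing; 5 s linear baseline window at the 25 Hz capnography
#'   rate). A capnogram's information lives in the 0.1-0.3 Hz respiratory
#'   oscillation, which the 1 s ECG baseline window would treat as drift and
#'   subtract.
#' @return A tibble: `shock_id`, `subject_id`, `label`, plus feature
#'   columns.
#' @export
static_features <- function(records, duration_s = 7.8, bank = wavelet_bank(),
                            use_petco2 = FALSE,
                            config = preprocess_config(),
                            co2_config = preprocess_config(savgol_k = 9,
                                                           savgol_p = 3,
                                                           baseline_k = 125,
                                                           baseline_p = 1)) {
  purrr::map_dfr(records, function(rec) {
    seg <- preprocess_segment(extract_preshock_window(rec$ecg, duration_s),
                              config)
    row <- dplyr::bind_cols(
      tibble::tibble(shock_id = rec$shock_id, subject_id = rec$subject_id,
                     label = rec$outcome),
      timeseries_features(seg),
      dtcwt_features(seg, bank))
    if (use_petco2) {
      if (is.null(rec$petco2)) {
        stop("record ", rec$shock_id, " has no PetCO2 trace", call. = FALSE)
      }
      co2 <- preprocess_segment(
        extract_preshock_window(rec$petco2, duration_s), co2_config)
      row <- dplyr::bind_cols(
        row,
        timeseries_features(co2, prefix = "tf_co2."),
        dtcwt_features(co2, bank, prefix = "cw_co2."))
    }
    row
  })
}

#' Full feature table including RPD-PD features at fixed parameters
#'
#' Convenience wrapper for use OUTSIDE cross-validation: when `rpd_params`
#' is supplied (or fitted here on the full input, which is only legitimate
#' for exploratory use), the two signed prototype-distance features are
#' appended to the static features.
#'
#' @inheritParams static_features
#' @param prototypes A `vf_prototype_signals` set (required for RPD
#'   features).
#' @param rpd_params A `vf_rpd_params` object, or `NULL` to fit on the full
#'   input.
#' @param grid An [rpd_grid()] used when fitting.
#' @return A feature tibble.
#' @export
extract_features <- function(records, prototypes = NULL, rpd_params = NULL,
                             duration_s = 7.8, bank = wavelet_bank(),
                             use_petco2 = FALSE, grid = rpd_grid(),
                             config = preprocess_config()) {
  ft <- static_features(records, duration_s, bank, use_petco2, config)
  if (is.null(prototypes)) return(ft)
  segs <- lapply(records, function(r) {
    preprocess_segment(extract_preshock_window(r$ecg, duration_s), config)
  })
  proto_segs <- lapply(prototypes$signals, function(s) {
    preprocess_segment(extract_preshock_window(s, duration_s), config)
  })
  if (is.null(rpd_params)) {
    rpd_params <- optimize_rpd_params(segs, ft$label, proto_segs,
                                      prototypes$classes, grid = grid)
  }
  proto_dens <- lapply(proto_segs, function(s) {
    rpd_density(s, rpd_params$m, rpd_params$tau, rpd_params$r,
                t_max = rpd_params$t_max)
  })
  ps <- prototype_set(proto_dens, prototypes$classes)
  rpd <- purrr::map_dfr(segs, function(s) {
    skd_features(rpd_density(s, rpd_params$m, rpd_params$tau, rpd_params$r,
                             t_max = rpd_params$t_max),
                 ps, window = rpd_params$window)
  })
  dplyr::bind_cols(ft, rpd)
}

#' Per-fold RPD-PD feature hook for nested cross-validation
#'
#' Builds the label-free density caches once and returns a
#' `function(train_idx)` suitable as `fold_feature_fn` in [nested_cv()]: for
#' each outer training set it selects embedding parameters by [sep_score()]
#' maximization on training instances only, then emits the two signed
#' prototype-distance features for all instances. Results are memoised per
#' training set, so evaluations sharing folds (e.g. an ECG-only and an
#' ECG + PetCO2 run) reuse the fitted parameters.
#'
#' @param records List of [shock_record()]s.
#' @param prototypes A `vf_prototype_signals` set.
#' @param labels 0/1 outcome per record.
#' @param grid An [rpd_grid()].
#' @param duration_s Analysis window (s).
#' @param config Preprocessing configuration.
#' @return A function `function(train_idx)` returning a tibble of RPD-PD
#'   features for all records; fitted parameters are accumulated in the
#'   `"params"` attribute environment.
#' @export
rpd_fold_hook <- function(records, prototypes, labels, grid = rpd_grid(),
                          duration_s = 7.8, config = preprocess_config()) {
  segs <- lapply(records, function(r) {
    preprocess_segment(extract_preshock_window(r$ecg, duration_s), config)
  })
  proto_segs <- lapply(prototypes$signals, function(s) {
    preprocess_segment(extract_preshock_window(s, duration_s), config)
  })
  cache <- rpd_density_cache(segs, grid)
  proto_cache <- rpd_density_cache(proto_segs, grid)
  labels <- as.integer(labels)
  memo <- new.env(parent = emptyenv())
  log_env <- new.env(parent = emptyenv()); log_env$params <- list()
  hook <- function(train_idx) {
    key <- paste(train_idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    par <- optimize_rpd_params(cache, labels, proto_cache,
                               prototypes$classes, subset = train_idx)
    log_env$params[[length(log_env$params) + 1L]] <- par
    ps <- prototype_set(proto_cache$densities[[par$combo]],
                        prototypes$classes)
    out <- purrr::map_dfr(cache$densities[[par$combo]], skd_features,
                          ps = ps, window = par$window)
    memo[[key]] <- out
    out
  }
  attr(hook, "params") <- log_env
  hook
}

#' Evaluate a shock dataset by the full twice-nested protocol
#'
#' Runs the complete pipeline: preprocessing, static feature extraction,
#' per-outer-fold RPD-PD parameter selection (training instances only, via a
#' shared label-free density cache), cost-sensitive RFE-SVM feature
#' selection, hyperparameter tuning, and pooled out-of-fold evaluation.
#'
#' @param records List of [shock_record()]s.
#' @param prototypes A `vf_prototype_signals` set, or `NULL` to skip RPD-PD
#'   features.
#' @param cv_config A [nested_cv_config()].
#' @param rpd_grid_spec An [rpd_grid()] for per-fold parameter selection.
#' @param duration_s Analysis window (s).
#' @param use_petco2 Include PetCO2 features (records must carry traces).
#' @param config Preprocessing configuration.
#' @return A `vf_nested_cv` object; the per-fold RPD parameters are recorded
#'   in `$rpd_params`.
#' @export
evaluate_shock_dataset <- function(records, prototypes = NULL,
                                   cv_config = nested_cv_config(),
                                   rpd_grid_spec = rpd_grid(),
                                   duration_s = 7.8, use_petco2 = FALSE,
                                   config = preprocess_config()) {
  ft <- static_features(records, duration_s, use_petco2 = use_petco2,
                        config = config)
  y <- ft$label
  X <- ft[, setdiff(names(ft), c("shock_id", "subject_id", "label"))]
  fold_fn <- NULL
  if (!is.null(prototypes)) {
    fold_fn <- rpd_fold_hook(records, prototypes, y, grid = rpd_grid_spec,
                             duration_s = duration_s, config = config)
  }
  res <- nested_cv(X, y, config = cv_config, fold_feature_fn = fold_fn)
  res$rpd_params <- if (!is.null(fold_fn)) attr(fold_fn, "params")$params
  res$feature_table <- ft
  res
}
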