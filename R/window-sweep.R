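## Window-duration sweep: how much class-separating information a pre-shock
## analysis window carries as a function of its duration.

# Eq.-8-style separation of one feature dimension, with |difference| to the
# prototypes' feature values as the distance
sep_one_dimension <- function(x, labels, x_proto, proto_classes) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  total <- 0
  for (i in seq_along(x)) {
    d <- abs(x[i] - x_proto)
    w <- proto_classes == labels[i]
    denom <- max(pop_sd(d[!w]), pop_sd(d[w]), 1e-12)
    total <- total + (mean(d[!w]) - mean(d[w])) / denom
  }
  total
}

#' Separation of every feature dimension against class prototypes
#'
#' @param ft Feature tibble (numeric columns) for the instances.
#' @param labels 0/1 outcome per instance.
#' @param ft_proto Feature tibble for the prototypes.
#' @param proto_classes 0/1 class per prototype.
#' @return A tibble with `feature` and `sep`, sorted by decreasing `sep`.
#' @export
feature_separation <- function(ft, labels, ft_proto, proto_classes) {
  feats <- names(ft)[vapply(ft, is.numeric, logical(1))]
  sep <- vapply(feats, function(f) {
    sep_one_dimension(ft[[f]], as.integer(labels), ft_proto[[f]],
                      as.integer(proto_classes))
  }, numeric(1))
  tibble::tibble(feature = feats, sep = sep) |>
    dplyr::arrange(dplyr::desc(.data$sep))
}

#' Window-duration sweep of class-separating information
#'
#' The pre-shock window is grown from `durations[1]` to the final duration
#' (default 2 s to 11 s in 0.1 s steps); at each duration, features are
#' extracted from the window of every instance and prototype, the separation
#' of each feature dimension is computed against the prototypes, and the mean
#' of the top `top_k` dimensions is recorded. Durations whose mean separation
#' falls below `sep_floor` (default 0.8) are flagged non-discriminative.
#'
#' @param records List of [shock_record()]s (ECG used).
#' @param prototypes A prototype signal set: list with `signals` (list of
#'   [signal_segment()]) and `classes` (0/1 per signal).
#' @param durations Window durations in seconds; durations longer than the
#'   shortest signal are dropped with a warning.
#' @param feature_fn `function(segment)` returning a one-row feature tibble;
#'   default: time-series plus dual-tree complex wavelet features.
#' @param top_k Number of top dimensions averaged (fewer available => mean
#'   over all, with a warning).
#' @param sep_floor Non-discriminative flag threshold.
#' @param config Preprocessing configuration.
#' @return A tibble of class `vf_window_sweep`: `duration_s`,
#'   `sep_mean_top`, `n_features`, `non_discriminative`.
#' @export
window_sweep <- function(records, prototypes,
                         durations = seq(2, 11, by = 0.1),
                         feature_fn = NULL, top_k = 5, sep_floor = 0.8,
                         config = preprocess_config()) {
  if (is.null(feature_fn)) {
    bank <- wavelet_bank()
    feature_fn <- function(seg) {
      dplyr::bind_cols(timeseries_features(seg), dtcwt_features(seg, bank))
    }
  }
  min_dur <- min(vapply(records, function(r) signal_duration(r$ecg), numeric(1)),
                 vapply(prototypes$signals, signal_duration, numeric(1)))
  keep <- durations <= min_dur + 1e-9
  if (!all(keep)) {
    warning(sprintf("truncating sweep at %.1f s (shortest signal)", min_dur))
    durations <- durations[keep]
  }
  labels <- vapply(records, function(r) r$outcome, integer(1))
  rows <- purrr::map_dfr(durations, function(d) {
    ft <- purrr::map_dfr(records, function(r) {
      feature_fn(preprocess_segment(extract_preshock_window(r$ecg, d), config))
    })
    ftp <- purrr::map_dfr(prototypes$signals, function(s) {
      feature_fn(preprocess_segment(extract_preshock_window(s, d), config))
    })
    sep <- feature_separation(ft, labels, ftp, prototypes$classes)
    k <- min(top_k, nrow(sep))
    if (k < top_k) warning("fewer feature dimensions than `top_k`")
    tibble::tibble(duration_s = d,
                   sep_mean_top = mean(sep$sep[seq_len(k)]),
                   n_features = nrow(sep))
  })
  rows$non_discriminative <- rows$sep_mean_top < sep_floor
  class(rows) <- c("vf_window_sweep", class(rows))
  rows
}

#' Bar plot of a window-duration sweep
#'
#' @param object A `vf_window_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vf_window_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$duration_s, y = .data$sep_mean_top)) +
    ggplot2::geom_col(width = 0.08, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Window duration (s)",
                  y = "Mean separation of top dimensions") +
    ggplot2::theme_minimal()
}
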