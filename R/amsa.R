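#' Single-sided amplitude spectrum of a segment
#'
#' Normalized so that a unit-amplitude pure tone at a bin frequency yields a
#' spectral amplitude of about 1 mV at that bin (rectangular window, integer
#' number of cycles).
#'
#' @param seg A [signal_segment()]; at least 64 samples.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A list of class `vf_spectrum` with `freqs` (Hz) and `amps` (mV).
#' @export
amplitude_spectrum <- function(seg, window = c("rectangular", "hann")) {
  stopifnot(inherits(seg, "vf_signal"))
  window <- match.arg(window)
  x <- seg$samples
  n <- length(x)
  if (n < 64) stop("segment too short for spectral analysis (need >= 64 samples)",
                   call. = FALSE)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w / mean(w)   # preserve tone amplitude calibration
  }
  sp <- stats::fft(x)
  half <- floor(n / 2) + 1L
  amps <- Mod(sp[seq_len(half)]) / n
  amps[-1L] <- 2 * amps[-1L]
  if (n %% 2 == 0) amps[half] <- amps[half] / 2   # Nyquist bin not doubled
  structure(list(freqs = (seq_len(half) - 1L) * seg$fs / n, amps = amps),
            class = "vf_spectrum")
}

#' Amplitude spectrum area (AMSA)
#'
#' The classical Fourier-domain shock-outcome predictor: the sum of spectral
#' amplitudes weighted by their frequencies, `sum(amp_i * f_i)` over bins in
#' `band` (default 2-48 Hz). Homogeneous of degree one in signal amplitude.
#'
#' @param seg A [signal_segment()] (ECG; PetCO2 is not used for AMSA).
#' @param band `c(f_lo, f_hi)` in Hz; must lie within the Nyquist range.
#' @param window Spectral window passed to [amplitude_spectrum()].
#' @return AMSA in mV*Hz.
#' @export
amsa <- function(seg, band = c(2, 48), window = "rectangular") {
  if (band[2] <= band[1]) stop("`band` must satisfy f_lo < f_hi", call. = FALSE)
  if (band[2] > seg$fs / 2) stop("`band` exceeds the Nyquist frequency", call. = FALSE)
  sp <- amplitude_spectrum(seg, window = window)
  sel <- sp$freqs >= band[1] & sp$freqs <= band[2]
  if (!any(sel)) stop("no spectral bins inside `band`", call. = FALSE)
  sum(sp$amps[sel] * sp$freqs[sel])
}

weighted_entropy <- function(w1, w0) {
  tot <- w1 + w0
  if (tot == 0) return(0)
  p <- c(w1, w0) / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Decision-stump threshold by entropy minimization
#'
#' A C4.5-style 1-rule: every midpoint between consecutive sorted unique
#' values is scanned and the split minimizing the weighted class-membership
#' entropy of the two resulting subsets (equivalently, maximizing
#' information gain) is returned. Class counts are cost-weighted: positives
#' (label 1) weigh `cost_ratio`, so missed successes are penalized more.
#'
#' @param values Scalar feature value per shock (e.g. AMSA).
#' @param labels 0/1 outcome per shock; both classes must be present.
#' @param cost_ratio Weight on the positive class.
#' @return A list of class `vf_stump`: `threshold`, `polarity` (`">"` if
#'   values above threshold are classified positive, else `"<"`), `gain`
#'   (information gain, nats), training `accuracy` (unweighted),
#'   `sensitivity`, `specificity`.
#' @export
stump_threshold <- function(values, labels, cost_ratio = 2) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels))
  if (length(values) < 2L || length(unique(labels)) < 2L) {
    stop("need at least two instances and both classes", call. = FALSE)
  }
  w <- ifelse(labels == 1L, cost_ratio, 1)
  uv <- sort(unique(values))
  cand <- if (length(uv) > 1L) (uv[-1] + uv[-length(uv)]) / 2 else uv
  parent <- weighted_entropy(sum(w[labels == 1L]), sum(w[labels == 0L]))
  best <- NULL
  for (thr in cand) {
    hi <- values > thr
    n_hi <- sum(w[hi]); n_lo <- sum(w[!hi])
    e <- (n_hi * weighted_entropy(sum(w[hi & labels == 1L]),
                                  sum(w[hi & labels == 0L])) +
          n_lo * weighted_entropy(sum(w[!hi & labels == 1L]),
                                  sum(w[!hi & labels == 0L]))) / (n_hi + n_lo)
    if (is.null(best) || e < best$e - 1e-15) best <- list(thr = thr, e = e)
  }
  hi <- values > best$thr
  # side with the larger weighted positive share is the positive side
  share_hi <- if (any(hi)) sum(w[hi & labels == 1L]) / sum(w[hi]) else 0
  share_lo <- if (any(!hi)) sum(w[!hi & labels == 1L]) / sum(w[!hi]) else 0
  polarity <- if (share_hi >= share_lo) ">" else "<"
  pred <- if (polarity == ">") as.integer(hi) else as.integer(!hi)
  structure(list(
    threshold = best$thr, polarity = polarity, gain = parent - best$e,
    accuracy = mean(pred == labels),
    sensitivity = mean(pred[labels == 1L] == 1L),
    specificity = mean(pred[labels == 0L] == 0L)),
    class = "vf_stump")
}

#' @export
print.vf_stump <- function(x, ...) {
  cat(sprintf(
    "<vf_stump> predict success when value %s %.4g (gain %.3f nats, acc %.3f)\n",
    x$polarity, x$threshold, x$gain, x$accuracy))
  invisible(x)
}

#' Predictions of a decision stump
#' @param object A `vf_stump`.
#' @param newdata Numeric vector of feature values.
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @export
predict.vf_stump <- function(object, newdata, ...) {
  hi <- newdata > object$threshold
  if (object$polarity == ">") as.integer(hi) else as.integer(!hi)
}

#' AMSA baseline evaluation of a shock dataset
#'
#' Computes per-shock AMSA on the preprocessed pre-shock ECG window, fits the
#' entropy-minimizing decision stump, and reports threshold metrics and ROC
#' AUC (AMSA values oriented by the stump polarity serve as the ranking
#' score).
#'
#' @param records List of [shock_record()]s.
#' @param band AMSA frequency band in Hz.
#' @param duration_s Analysis window length in seconds.
#' @param cost_ratio Stump cost weighting for the positive class.
#' @param config Preprocessing configuration.
#' @return A list of class `vf_amsa_eval`: tibble `values` (shock_id, amsa,
#'   label), `stump`, and `metrics` (accuracy, auc, sensitivity,
#'   specificity).
#' @export
amsa_evaluate <- function(records, band = c(2, 48), duration_s = 7.8,
                          cost_ratio = 2, config = preprocess_config()) {
  vals <- purrr::map_dfr(records, function(rec) {
    seg <- preprocess_segment(extract_preshock_window(rec$ecg, duration_s),
                              config)
    tibble::tibble(shock_id = rec$shock_id, amsa = amsa(seg, band = band),
                   label = rec$outcome)
  })
  st <- stump_threshold(vals$amsa, vals$label, cost_ratio = cost_ratio)
  score <- if (st$polarity == ">") vals$amsa else -vals$amsa
  roc <- roc_and_metrics(score, vals$label,
                         threshold = if (st$polarity == ">") st$threshold else
                           -st$threshold, score_scale = "raw")
  structure(list(values = vals, stump = st,
                 metrics = list(accuracy = st$accuracy, auc = roc$auc,
                                sensitivity = st$sensitivity,
                                specificity = st$specificity)),
            class = "vf_amsa_eval")
}
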