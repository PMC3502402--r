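#' Savitzky-Golay smoothing of a signal segment
#'
#' Least-squares local-polynomial smoothing: a moving window of `k` samples is
#' fitted with a degree-`p` polynomial. Small `k` with a small `k - p` gap
#' gives the "slight" smoothing used for high-frequency noise attenuation;
#' wide windows with low degree estimate baseline drift. Edges are handled by
#' the boundary polynomial fits (the filter is exact on polynomials of degree
#' at most `p`, including at the edges).
#'
#' @param seg A [signal_segment()].
#' @param k Window width in samples; odd, `k >= 3`.
#' @param p Polynomial degree, `0 <= p <= k - 1`.
#' @return A smoothed [signal_segment()] of the same length.
#' @export
savgol_smooth <- function(seg, k = 15, p = 5) {
  stopifnot(inherits(seg, "vf_signal"))
  check_savgol(k, p)
  if (length(seg$samples) < k) {
    stop("segment shorter than the smoothing window", call. = FALSE)
  }
  out <- signal::sgolayfilt(seg$samples, sg_filter(k, p))
  signal_segment(out, seg$fs, seg$channel)
}

# memoised Savitzky-Golay projection matrices; building one is O(k^2) and
# dominates runtime for wide baseline windows, so reuse across calls
.sg_cache <- new.env(parent = emptyenv())

sg_filter <- function(k, p) {
  key <- paste0(k, "_", p)
  f <- .sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = p, n = k)
    .sg_cache[[key]] <- f
  }
  f
}

check_savgol <- function(k, p) {
  if (k %% 2 == 0 || k < 3) stop("`k` must be odd and >= 3", call. = FALSE)
  if (p < 0 || p > k - 1) stop("`p` must satisfy 0 <= p <= k - 1", call. = FALSE)
  invisible(TRUE)
}

#' Remove sudden baseline jumps by iterated wide smoothing
#'
#' The baseline (jumps and slow drifts) is estimated by repeatedly applying a
#' wide Savitzky-Golay filter to the signal until successive iterates change
#' by less than `tol` in relative L2 norm (or `max_iter` is reached); the
#' estimate is then subtracted. No frequency-domain filtering is involved, so
#' the broadband content of a step does not leak into the passband the way it
#' would with a Butterworth-style filter.
#'
#' @param seg A [signal_segment()], normally already lightly smoothed by
#'   [savgol_smooth()].
#' @param k,p Wide-window Savitzky-Golay parameters for the baseline pass
#'   (default about one second at 250 Hz, cubic).
#' @param tol Relative L2 convergence tolerance between iterates; must be
#'   positive.
#' @param max_iter Iteration cap.
#' @return A baseline-corrected [signal_segment()]; the estimated baseline is
#'   attached as attribute `"baseline"`.
#' @export
remove_baseline_jumps <- function(seg, k = 251, p = 3, tol = 1e-3,
                                  max_iter = 10) {
  stopifnot(inherits(seg, "vf_signal"))
  check_savgol(k, p)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  x <- seg$samples
  n <- length(x)
  keff <- min(k, if (n %% 2 == 0) n - 1 else n)
  if (keff %% 2 == 0) keff <- keff - 1
  if (keff <= p) stop("segment too short for the baseline window", call. = FALSE)
  # reflect the segment at both ends so the boundary polynomial fits see
  # continuous data; otherwise edge fits inject spurious baseline energy
  npad <- min(keff, n - 1L)
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  b <- signal::sgolayfilt(xp, sg_filter(keff, p))
  for (i in seq_len(max_iter - 1L)) {
    b_new <- signal::sgolayfilt(b, sg_filter(keff, p))
    denom <- sqrt(sum(b^2))
    rel <- if (denom > 0) sqrt(sum((b_new - b)^2)) / denom else 0
    b <- b_new
    if (rel < tol) break
  }
  b <- b[(npad + 1L):(npad + n)]
  out <- signal_segment(x - b, seg$fs, seg$channel)
  attr(out, "baseline") <- b
  out
}

#' Default preprocessing configuration
#'
#' @param savgol_k,savgol_p Narrow smoothing pass (noise attenuation).
#' @param baseline_k,baseline_p Wide pass used for baseline estimation.
#' @param baseline_tol,baseline_max_iter Convergence control for the baseline
#'   iteration.
#' @return A named list of preprocessing parameters.
#' @export
preprocess_config <- function(savgol_k = 15, savgol_p = 5,
                              baseline_k = 251, baseline_p = 3,
                              baseline_tol = 1e-3, baseline_max_iter = 10) {
  list(savgol_k = savgol_k, savgol_p = savgol_p,
       baseline_k = baseline_k, baseline_p = baseline_p,
       baseline_tol = baseline_tol, baseline_max_iter = baseline_max_iter)
}

#' Clean a raw segment: smoothing then baseline-jump removal
#'
#' @param seg A [signal_segment()].
#' @param config A [preprocess_config()].
#' @return The preprocessed [signal_segment()]; deterministic.
#' @export
preprocess_segment <- function(seg, config = preprocess_config()) {
  sm <- savgol_smooth(seg, k = config$savgol_k, p = config$savgol_p)
  out <- remove_baseline_jumps(sm, k = config$baseline_k, p = config$baseline_p,
                               tol = config$baseline_tol,
                               max_iter = config$baseline_max_iter)
  attr(out, "baseline") <- NULL
  out
}
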