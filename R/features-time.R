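#' Find local maxima with a dynamically relaxing prominence threshold
#'
#' Local maxima are detected and filtered by topographic prominence. The
#' prominence threshold starts at `c_start` times the standard deviation of
#' the samples and is halved until at least `n_min` maxima survive (or the
#' threshold falls below a negligible floor), so a minimum number of maxima is
#' always found on any non-constant signal.
#'
#' @param seg A [signal_segment()].
#' @param n_min Minimum number of maxima sought; `>= 2`.
#' @param c_start Initial threshold as a multiple of `sd(samples)`.
#' @param eps_frac Floor for the threshold, as a fraction of `sd(samples)`.
#' @return A list of class `vf_maxima` with `values` (amplitudes), `indices`
#'   (sample positions, strictly increasing) and `n`. A constant signal gives
#'   `n = 0`.
#' @export
find_maxima_adaptive <- function(seg, n_min = 5, c_start = 0.5,
                                 eps_frac = 1e-6) {
  stopifnot(inherits(seg, "vf_signal"))
  if (n_min < 2) stop("`n_min` must be >= 2", call. = FALSE)
  x <- seg$samples
  s <- stats::sd(x)
  empty <- structure(list(values = numeric(0), indices = integer(0), n = 0L),
                     class = "vf_maxima")
  if (!is.finite(s) || s == 0) return(empty)
  peaks <- local_maxima(x)
  if (length(peaks) == 0L) return(empty)
  prom <- peak_prominence(x, peaks)
  thr <- c_start * s
  repeat {
    keep <- prom >= thr
    if (sum(keep) >= min(n_min, length(peaks)) || thr < eps_frac * s) break
    thr <- thr / 2
  }
  idx <- peaks[keep]
  structure(list(values = x[idx], indices = idx, n = length(idx)),
            class = "vf_maxima")
}

# strict local maxima; plateaus contribute their first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- sign(diff(x))
  d_nz <- d
  # propagate the last non-zero slope through plateaus (right-to-left)
  for (i in seq(length(d_nz) - 1L, 1L)) {
    if (d_nz[i] == 0) d_nz[i] <- d_nz[i + 1L]
  }
  which(diff(d_nz) < 0 & d[seq_len(n - 2L)] != 0) + 1L
}

# topographic prominence: height minus the higher of the two saddle minima
# reached before a strictly taller sample on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    taller_l <- which(left > h)
    base_l <- if (length(taller_l)) {
      min(left[(max(taller_l)):(p - 1L)])
    } else min(left)
    right <- x[(p + 1L):length(x)]
    taller_r <- which(right > h)
    base_r <- if (length(taller_r)) {
      min(right[seq_len(min(taller_r))])
    } else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Pole count of a maxima sequence
#'
#' Counts maxima that jump above their predecessor by more than 1.2 times the
#' population standard deviation of all detected maxima:
#' \deqn{V_{mx,i} > V_{mx,i-1} + 1.2 \sqrt{\tfrac1N \sum_j (V_{mx,j} -
#'   \bar V_{mx})^2}.}
#' High counts indicate strong beat-to-beat amplitude variation, a property of
#' coarse (type-1) VF; the count is invariant to positive amplitude scaling
#' and to constant offsets.
#'
#' @param mx A `vf_maxima` object from [find_maxima_adaptive()].
#' @return Integer pole count; `0` when fewer than two maxima exist.
#' @export
pole_count <- function(mx) {
  stopifnot(inherits(mx, "vf_maxima"))
  v <- mx$values
  n <- length(v)
  if (n <= 1L) return(0L)
  sigma <- sqrt(mean((v - mean(v))^2))
  sum(v[-1L] > v[-n] + 1.2 * sigma)
}

#' Time-series features of a preprocessed segment
#'
#' Emits the pole count plus two documented extensions: the amplitude range
#' and the mean absolute sample-to-sample slope (mV per sample). Extensions
#' carry the `tf.ext.` prefix.
#'
#' @param seg A preprocessed [signal_segment()].
#' @param prefix Feature-name prefix (default `"tf."`; PetCO2 features use
#'   `"tf_co2."`).
#' @inheritParams find_maxima_adaptive
#' @return A one-row tibble of named features.
#' @export
timeseries_features <- function(seg, prefix = "tf.", n_min = 5) {
  mx <- find_maxima_adaptive(seg, n_min = n_min)
  x <- seg$samples
  out <- tibble::tibble(
    pole_count = as.numeric(pole_count(mx)),
    ext.amp_range = max(x) - min(x),
    ext.mean_abs_slope = mean(abs(diff(x)))
  )
  names(out) <- paste0(prefix, names(out))
  out
}
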