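## Recurrence Period Density Prototype Distance (RPD-PD).
##
## A pre-shock signal is delay-embedded into an m-dimensional state space;
## the distribution of its recurrence periods (times for the trajectory to
## re-enter a small ball around a reference state after having left it) is
## compared, through an asymmetric Kullback-Leibler-inspired distance, with
## the distributions of a small set of prototype signals from each outcome
## class. Embedding parameters are chosen to maximize a normalized
## between-minus-within class separation on training data only.

#' Time-delay embedding of a signal
#'
#' Builds states `p(n) = (x(n), x(n - tau), ..., x(n - (m-1) tau))` for
#' `n = (m-1) tau + 1, ..., length(x)`.
#'
#' @param seg A [signal_segment()] or numeric vector.
#' @param m Embedding dimension, `>= 1`.
#' @param tau Delay in samples, `>= 1`.
#' @return A `count x m` matrix with `count = length(x) - (m - 1) * tau`
#'   rows, each a state in time order.
#' @export
embed_trajectory <- function(seg, m, tau) {
  x <- if (inherits(seg, "vf_signal")) seg$samples else as.numeric(seg)
  if (m < 1 || tau < 1) stop("`m` and `tau` must be >= 1", call. = FALSE)
  n <- length(x)
  count <- n - (m - 1L) * tau
  if (count < 1L) {
    stop("signal too short for this embedding (need length > (m-1)*tau)",
         call. = FALSE)
  }
  start <- (m - 1L) * tau + 1L
  cols <- vapply(0:(m - 1L), function(k) x[(start:n) - k * tau],
                 numeric(count))
  matrix(cols, nrow = count, ncol = m)
}

# absolute ball radius: r is a fraction of the trajectory's RMS distance to
# its centroid, making the method invariant to amplitude scale
trajectory_radius <- function(traj, r) {
  centred <- sweep(traj, 2, colMeans(traj))
  rms <- sqrt(mean(rowSums(centred^2)))
  r * rms
}

#' Recurrence periods of an embedded trajectory
#'
#' For every reference state the trajectory is followed forward; each time it
#' exits the ball of radius `r` around the reference and later re-enters, the
#' elapsed time (in samples) since the previous in-ball event is recorded as
#' a recurrence period. Periodicity is the special case where `r -> 0` and
#' every state yields the same period.
#'
#' @param traj Embedded trajectory matrix from [embed_trajectory()].
#' @param r Ball radius as a fraction of the trajectory's RMS distance to its
#'   centroid; `> 0`.
#' @return Integer vector (multiset) of recurrence periods; empty when no
#'   state is ever re-entered.
#' @export
recurrence_periods <- function(traj, r) {
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  .recurrence_periods_cpp(traj, trajectory_radius(traj, r))
}

#' Recurrence period density
#'
#' Histogram of recurrence periods over `1..t_max`, normalized to sum to one;
#' periods beyond `t_max` are discarded. An empty multiset yields an all-zero
#' density flagged with attribute `"degenerate"`.
#'
#' @param periods Integer vector from [recurrence_periods()].
#' @param t_max Longest period retained, in samples.
#' @return Numeric density vector `D` of length `t_max` (class
#'   `vf_rpd`).
#' @export
period_density <- function(periods, t_max = 500) {
  if (t_max < 1) stop("`t_max` must be >= 1", call. = FALSE)
  periods <- periods[periods >= 1L & periods <= t_max]
  d <- tabulate(periods, nbins = t_max)
  tot <- sum(d)
  out <- if (tot > 0) d / tot else rep(0, t_max)
  structure(as.numeric(out), class = "vf_rpd", degenerate = tot == 0)
}

#' Recurrence period density of a signal
#'
#' Convenience composition: embed, scan recurrences, normalize.
#'
#' @inheritParams embed_trajectory
#' @inheritParams recurrence_periods
#' @inheritParams period_density
#' @export
rpd_density <- function(seg, m, tau, r, t_max = 500) {
  period_density(recurrence_periods(embed_trajectory(seg, m, tau), r), t_max)
}

window_idx <- function(window, len) {
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) stop("window must satisfy lo < hi", call. = FALSE)
  if (lo < 1 || hi > len) stop("window outside the period axis", call. = FALSE)
  lo:hi
}

#' Asymmetric KD distance between two period densities
#'
#' `KD = sum_i (1 + D^c_i) (D^c_i - D^s_i)^2` over the period window, where
#' `c` is the comparator (prototype) density and `s` the signal density. The
#' `(1 + D^c)` weight biases the distance toward the comparator's
#' characteristics, so `KD(c, s) != KD(s, c)` in general.
#'
#' @param dc Comparator (prototype) density.
#' @param ds Signal density; must share `dc`'s period axis.
#' @param window `c(lo, hi)` period range in samples; default full axis.
#' @return Non-negative scalar; zero iff the densities agree on the window.
#' @export
kd_distance <- function(dc, ds, window = c(1, length(dc))) {
  if (length(dc) != length(ds)) {
    stop("densities must share the same period axis", call. = FALSE)
  }
  i <- window_idx(window, length(dc))
  sum((1 + dc[i]) * (dc[i] - ds[i])^2)
}

#' Signed KD distance
#'
#' Like [kd_distance()] but each period's squared difference carries the sign
#' of `D^p_i - D^s_i` (per-period signing; set `sign_mode = "aggregate"` to
#' apply a single sign to the unsigned total instead).
#'
#' @param dp Prototype density.
#' @param ds Signal density.
#' @inheritParams kd_distance
#' @param sign_mode `"per_period"` (default) or `"aggregate"`.
#' @return Scalar; `abs(signed_kd) <= kd_distance` with equality when all
#'   period differences share one sign.
#' @export
signed_kd <- function(dp, ds, window = c(1, length(dp)),
                      sign_mode = c("per_period", "aggregate")) {
  sign_mode <- match.arg(sign_mode)
  if (length(dp) != length(ds)) {
    stop("densities must share the same period axis", call. = FALSE)
  }
  i <- window_idx(window, length(dp))
  diff <- dp[i] - ds[i]
  if (sign_mode == "per_period") {
    sum((1 + dp[i]) * diff^2 * sign(diff))
  } else {
    sign(sum(diff)) * sum((1 + dp[i]) * diff^2)
  }
}

#' Prototype set of period densities
#'
#' @param densities List of `vf_rpd` densities (or numeric vectors on a
#'   shared period axis).
#' @param classes Integer vector of outcome classes (1 = success,
#'   0 = fail), one per density; both classes must be present.
#' @return A list of class `vf_prototypes`.
#' @export
prototype_set <- function(densities, classes) {
  classes <- as.integer(classes)
  if (length(densities) != length(classes)) {
    stop("one class per density required", call. = FALSE)
  }
  if (!all(classes %in% c(0L, 1L)) || length(unique(classes)) < 2L) {
    stop("both prototype classes must be present", call. = FALSE)
  }
  structure(list(densities = densities, classes = classes),
            class = "vf_prototypes")
}

#' Signed prototype-distance features of a signal density
#'
#' The signal is compared with every prototype in each class; the mean signed
#' KD over the `Q` prototypes of a class is emitted as that class's feature.
#' Both classes are always computed, so no outcome-label knowledge enters the
#' features. A degenerate (all-zero) signal density yields the documented
#' sentinel value `0` for both features, flagged via attribute
#' `"degenerate"`.
#'
#' @param ds Signal density (`vf_rpd`).
#' @param ps A [prototype_set()] of densities.
#' @param window Period window `c(lo, hi)`.
#' @inheritParams signed_kd
#' @return A one-row tibble with `rpd.skd_success` and `rpd.skd_fail`.
#' @export
skd_features <- function(ds, ps, window = c(1, length(ds)),
                         sign_mode = "per_period") {
  stopifnot(inherits(ps, "vf_prototypes"))
  if (isTRUE(attr(ds, "degenerate"))) {
    out <- tibble::tibble(rpd.skd_success = 0, rpd.skd_fail = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mean_skd <- function(cls) {
    vals <- vapply(which(ps$classes == cls), function(q) {
      signed_kd(as.numeric(ps$densities[[q]]), as.numeric(ds),
                window = window, sign_mode = sign_mode)
    }, numeric(1))
    mean(vals)
  }
  tibble::tibble(rpd.skd_success = mean_skd(1L), rpd.skd_fail = mean_skd(0L))
}

#' Class-separation score of labeled training densities
#'
#' For each training instance `i`, the KD distances from its density to all
#' prototype densities are split into between-class and within-class sets
#' (relative to `i`'s own label); the separation is
#' \deqn{sep = \sum_i \frac{\overline{KD^B_i} - \overline{KD^W_i}}
#'   {\max(\mathrm{sd}(KD^B_i), \mathrm{sd}(KD^W_i))},}
#' with population standard deviations over the prototype distances of
#' instance `i` and the denominator floored at `1e-12`. Larger is better; the
#' normalization accounts for one class being more homogeneous than the
#' other.
#'
#' @param densities List of training densities.
#' @param labels 0/1 outcome label per training density.
#' @param ps A [prototype_set()].
#' @param window Period window `c(lo, hi)`.
#' @return Scalar separation score.
#' @export
sep_score <- function(densities, labels, ps, window) {
  stopifnot(inherits(ps, "vf_prototypes"))
  labels <- as.integer(labels)
  if (length(densities) < 1L) stop("need at least one training density", call. = FALSE)
  if (length(densities) != length(labels)) {
    stop("one label per density required", call. = FALSE)
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  total <- 0
  for (i in seq_along(densities)) {
    kd <- vapply(ps$densities, function(dp) {
      kd_distance(as.numeric(dp), as.numeric(densities[[i]]), window = window)
    }, numeric(1))
    w <- ps$classes == labels[i]
    kd_w <- kd[w]; kd_b <- kd[!w]
    denom <- max(pop_sd(kd_b), pop_sd(kd_w), 1e-12)
    total <- total + (mean(kd_b) - mean(kd_w)) / denom
  }
  total
}

#' Default RPD-PD parameter grid
#'
#' @param m Candidate embedding dimensions.
#' @param tau Candidate delays (samples).
#' @param r Candidate radii (fraction of trajectory RMS scale).
#' @param t_max Period axis length (samples); 500 samples = 2 s at 250 Hz.
#' @param windows List of `c(lo, hi)` period windows; default the four equal
#'   non-overlapping quarters of `1..t_max` plus the full range.
#' @return A list with components `mtr` (tibble of m/tau/r combinations in
#'   lexicographic order) and `windows`.
#' @export
rpd_grid <- function(m = c(2, 3, 4, 5), tau = c(2, 4, 6, 8, 10, 12),
                     r = c(0.1, 0.2, 0.3, 0.5), t_max = 500,
                     windows = NULL) {
  if (is.null(windows)) {
    q <- floor(t_max / 4)
    windows <- list(c(1, q), c(q + 1, 2 * q), c(2 * q + 1, 3 * q),
                    c(3 * q + 1, t_max), c(1, t_max))
  }
  mtr <- tidyr::expand_grid(m = m, tau = tau, r = r)
  list(mtr = mtr, windows = windows, t_max = t_max)
}

#' Cache recurrence period densities over a parameter grid
#'
#' Densities depend only on each signal and on `(m, tau, r)` - not on labels
#' or data splits - so they are computed once per dataset and reused by
#' [optimize_rpd_params()] and by every cross-validation fold.
#'
#' @param signals List of [signal_segment()]s (or numeric vectors).
#' @param grid An [rpd_grid()].
#' @return A list of class `vf_rpd_cache`: for each m/tau/r combination, a
#'   list of densities (one per signal).
#' @export
rpd_density_cache <- function(signals, grid = rpd_grid()) {
  combos <- grid$mtr
  dens <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    dens[[ci]] <- lapply(signals, function(s) {
      rpd_density(s, m = combos$m[ci], tau = combos$tau[ci], r = combos$r[ci],
                  t_max = grid$t_max)
    })
  }
  structure(list(grid = grid, densities = dens, n_signals = length(signals)),
            class = "vf_rpd_cache")
}

#' Select RPD-PD embedding parameters by maximizing class separation
#'
#' Exhaustive search over the m/tau/r/window grid for the combination
#' maximizing [sep_score()] of the training densities against the prototype
#' densities. Ties break to the first combination in lexicographic grid
#' order. Prototype densities are recomputed per m/tau/r combination from
#' `prototype_signals`.
#'
#' @param signals List of training signals, or a `vf_rpd_cache` built on
#'   them.
#' @param labels 0/1 outcome per training signal.
#' @param prototype_signals List of prototype signals.
#' @param prototype_classes 0/1 class per prototype.
#' @param grid An [rpd_grid()]; ignored when `signals` is a cache.
#' @param subset Optional integer indices of the training signals to use
#'   (with a cache, the indices into the cached signal list).
#' @return A list of class `vf_rpd_params`: `m`, `tau`, `r`, `window`,
#'   `sep`, plus `search` (a tibble with the sep of every combination).
#' @export
optimize_rpd_params <- function(signals, labels, prototype_signals,
                                prototype_classes, grid = rpd_grid(),
                                subset = NULL) {
  if (inherits(signals, "vf_rpd_cache")) {
    cache <- signals
    grid <- cache$grid
  } else {
    cache <- rpd_density_cache(signals, grid)
  }
  proto_cache <- if (inherits(prototype_signals, "vf_rpd_cache")) {
    prototype_signals
  } else {
    rpd_density_cache(prototype_signals, grid)
  }
  labels <- as.integer(labels)
  combos <- grid$mtr
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    ts_dens <- cache$densities[[ci]]
    if (!is.null(subset)) ts_dens <- ts_dens[subset]
    lab <- if (!is.null(subset)) labels[subset] else labels
    ok <- !vapply(ts_dens, function(d) isTRUE(attr(d, "degenerate")), logical(1))
    ps <- prototype_set(proto_cache$densities[[ci]], prototype_classes)
    for (wi in seq_along(grid$windows)) {
      w <- grid$windows[[wi]]
      s <- if (any(ok)) sep_score(ts_dens[ok], lab[ok], ps, window = w) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        combo = ci, m = combos$m[ci], tau = combos$tau[ci], r = combos$r[ci],
        window_lo = w[1], window_hi = w[2], sep = s)
    }
  }
  search <- dplyr::bind_rows(rows)
  if (all(is.na(search$sep))) {
    stop("all parameter combinations produced degenerate densities", call. = FALSE)
  }
  best <- which.max(replace(search$sep, is.na(search$sep), -Inf))
  structure(list(m = search$m[best], tau = search$tau[best], r = search$r[best],
                 window = c(search$window_lo[best], search$window_hi[best]),
                 sep = search$sep[best], combo = search$combo[best],
                 t_max = grid$t_max, search = search),
            class = "vf_rpd_params")
}

#' Serialize fitted RPD-PD parameters to a JSON config artifact
#'
#' One small JSON file per training fold makes the per-fold parameter
#' choices auditable and replayable.
#'
#' @param params A `vf_rpd_params` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rpd_params <- function(params, path) {
  stopifnot(inherits(params, "vf_rpd_params"))
  jsonlite::write_json(
    list(m = params$m, tau = params$tau, r = params$r,
         window = as.integer(params$window), t_max = params$t_max,
         sep = params$sep),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read RPD-PD parameters written by [write_rpd_params()]
#' @param path JSON path.
#' @return A `vf_rpd_params` object (without the search table).
#' @export
read_rpd_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(m = as.integer(p$m), tau = as.integer(p$tau), r = p$r,
                 window = as.integer(p$window), sep = p$sep, combo = NA,
                 t_max = as.integer(p$t_max), search = NULL),
            class = "vf_rpd_params")
}

#' @export
print.vf_rpd_params <- function(x, ...) {
  cat(sprintf("<vf_rpd_params> m=%d tau=%d r=%.3g window=[%d,%d] sep=%.4g\n",
              x$m, x$tau, x$r, x$window[1], x$window[2], x$sep))
  invisible(x)
}
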