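# shared fixtures built in code

sine_seg <- function(freq, duration_s = 7.8, fs = 250, amp = 1, phase = 0,
                     channel = "ECG") {
  t <- (seq_len(floor(duration_s * fs)) - 1) / fs
  signal_segment(amp * sin(2 * pi * freq * t + phase), fs, channel)
}

# independent plain-R brute-force recurrence-period oracle: full distance
# matrix + explicit per-reference state machine
rpd_oracle <- function(traj, radius) {
  n <- nrow(traj)
  d2 <- as.matrix(stats::dist(traj))^2
  r2 <- radius^2
  periods <- integer(0)
  for (i in seq_len(n)) {
    inside <- TRUE
    last_event <- i
    j <- i
    while (j < n) {
      j <- j + 1
      in_ball <- d2[i, j] <= r2
      if (inside && !in_ball) {
        inside <- FALSE
      } else if (!inside && in_ball) {
        periods <- c(periods, j - last_event)
        last_event <- j
        inside <- TRUE
      }
    }
  }
  periods
}

fast_cv_config <- function(seed = 1, ...) {
  nested_cv_config(k_outer = 4, k_l1 = 3, k_l2 = 2,
                   svm_grid = svm_param_grid(C = c(0.1, 1, 10),
                                             gamma_mult = 1),
                   seed = seed, ...)
}

tiny_spec <- function(seed = 1, n_success = 8, n_fail = 10, duration_s = 8,
                      ...) {
  synth_spec(n_success = n_success, n_fail = n_fail,
             n_petco2_success = min(4, n_success),
             n_petco2_fail = min(4, n_fail),
             duration_s = duration_s, seed = seed, ...)
}
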