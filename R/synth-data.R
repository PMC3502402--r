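## Seeded generator of two-class VF-like datasets.
##
## The generator does not aim at physiological realism; it reproduces the
## statistical contrasts the features are designed to detect. "Coarse"
## (type-1) VF - the phenotype associated with successful defibrillation -
## has larger amplitude, deeper slow amplitude modulation and wider
## wandering of the dominant frequency than "smooth" (type-2) VF. PetCO2
## traces are slow quasi-periodic capnogram-like waves whose plateau level is
## higher for the successful class.

#' Specification of a synthetic shock dataset
#'
#' Class-contrast defaults define the study conditions used throughout the
#' package's evaluation: dataset shape 34 successful / 56 unsuccessful
#' shocks with a 20/28 PetCO2 subset and 4 + 4 extreme-parameter prototype
#' signals.
#'
#' @param n_success,n_fail Shock counts per outcome class.
#' @param fs Sampling rate (Hz).
#' @param duration_s Segment duration (s); 12 s leaves room for the full
#'   2-11 s window sweep.
#' @param n_petco2_success,n_petco2_fail Shocks (per class) that also carry a
#'   PetCO2 trace.
#' @param fs_co2 PetCO2 sampling rate (Hz); capnography is a slow channel and
#'   is sampled far below the ECG rate.
#' @param amp Per-class signal amplitude scale (mV), `c(success, fail)`.
#' @param mod_depth Per-class depth of the slow amplitude modulation (0-1).
#' @param f0_range Dominant-frequency ranges (Hz): list of `c(lo, hi)` for
#'   success and fail.
#' @param f_wander Per-class standard deviation of the instantaneous
#'   frequency random walk (Hz per step).
#' @param spectral_spread Per-class frequency offset scale of the secondary
#'   components (Hz).
#' @param noise_sd Additive Gaussian noise (mV).
#' @param baseline_jump_prob Probability of one baseline step artifact.
#' @param baseline_jump_mv Step amplitude (mV).
#' @param petco2_level Per-class PetCO2 plateau (mmHg).
#' @param petco2_noise PetCO2 additive noise (mmHg).
#' @param seed Integer master seed; every signal derives its own substream.
#' @return A list of class `vf_synth_spec`.
#' @export
synth_spec <- function(n_success = 34, n_fail = 56, fs = 250,
                       duration_s = 12,
                       n_petco2_success = 20, n_petco2_fail = 28,
                       fs_co2 = 25,
                       amp = c(success = 0.9, fail = 0.4),
                       mod_depth = c(success = 0.65, fail = 0.25),
                       f0_range = list(success = c(4.0, 5.5),
                                       fail = c(5.8, 7.2)),
                       f_wander = c(success = 0.06, fail = 0.02),
                       spectral_spread = c(success = 1.6, fail = 0.7),
                       noise_sd = 0.05,
                       baseline_jump_prob = 0.3, baseline_jump_mv = 1.5,
                       petco2_level = c(success = 38, fail = 18),
                       petco2_noise = 2,
                       seed = 1) {
  stopifnot(n_success >= 0, n_fail >= 0, fs > 0, duration_s > 0)
  structure(as.list(environment()), class = "vf_synth_spec")
}

#' Moderate-discriminability study conditions
#'
#' A [synth_spec()] preset with strongly overlapping ECG class parameters
#' (near-equal amplitudes, overlapping dominant-frequency ranges, higher
#' noise) but an intact PetCO2 level contrast. This emulates the clinical
#' regime where ECG-only discrimination is good but imperfect, leaving
#' headroom for the capnography channel to add information; the well
#' separated defaults of [synth_spec()] are instead the positive-control
#' conditions.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [synth_spec()].
#' @return A `vf_synth_spec`.
#' @export
synth_spec_moderate <- function(seed = 1, ...) {
  synth_spec(amp = c(success = 0.6, fail = 0.5),
             mod_depth = c(success = 0.45, fail = 0.35),
             f0_range = list(success = c(4.5, 6.8), fail = c(5.0, 7.2)),
             f_wander = c(success = 0.035, fail = 0.03),
             spectral_spread = c(success = 1.1, fail = 0.9),
             noise_sd = 0.2, petco2_noise = 3, seed = seed, ...)
}

# deterministic 32-bit child seed from the master seed and a stream tag
child_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# core VF-like waveform; `extreme` pushes the class parameters to their edge
# of the range (used for prototypes)
vf_waveform <- function(class_label, spec, extreme = FALSE) {
  cls <- if (class_label == 1L) "success" else "fail"
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  f0r <- spec$f0_range[[cls]]
  f0 <- if (extreme) {
    if (cls == "success") f0r[1] else f0r[2]
  } else stats::runif(1, f0r[1], f0r[2])
  depth <- spec$mod_depth[[cls]]
  wander <- spec$f_wander[[cls]]
  spread <- spec$spectral_spread[[cls]]
  if (extreme) {
    depth <- min(1, depth * 1.3)
    spread <- spread * 1.2
  }
  k <- sample(3:5, 1)
  x <- numeric(n)
  for (comp in seq_len(k)) {
    f_off <- if (comp == 1) 0 else stats::rnorm(1, 0, spread / 2)
    f_inst <- f0 + f_off + cumsum(stats::rnorm(n, 0, wander))
    f_inst <- pmin(pmax(f_inst, 1), 12)
    phase <- 2 * pi * cumsum(f_inst) / spec$fs + stats::runif(1, 0, 2 * pi)
    w <- if (comp == 1) 1 else stats::runif(1, 0.15, 0.45)
    x <- x + w * sin(phase)
  }
  # random amplitude envelope (smoothed noise); the coarse class's defining
  # irregularity makes its envelope vary faster as well as deeper
  env_rate <- 1.5 + 5 * depth        # control points per second
  env_raw <- stats::rnorm(ceiling(n / spec$fs * env_rate) + 4)
  env <- stats::approx(seq_along(env_raw), env_raw,
                       xout = seq(1, length(env_raw), length.out = n))$y
  env <- 1 + depth * env / max(abs(env), 1e-9)
  env <- pmax(env, 0.05)
  amp <- spec$amp[[cls]]
  x <- amp * env * x / stats::sd(x)
  x + stats::rnorm(n, 0, spec$noise_sd)
}

#' Generate one synthetic VF-like ECG segment
#'
#' @param class_label 1 (successful / coarse) or 0 (unsuccessful / smooth).
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the same seed reproduces the signal bit for bit.
#' @return A [signal_segment()] (ECG).
#' @export
gen_vf_signal <- function(class_label, spec = synth_spec(), seed = 1) {
  with_seed(seed, {
    x <- vf_waveform(as.integer(class_label), spec)
    if (stats::runif(1) < spec$baseline_jump_prob) {
      pos <- sample(seq(length(x) %/% 4, 3 * (length(x) %/% 4)), 1)
      x[pos:length(x)] <- x[pos:length(x)] +
        sample(c(-1, 1), 1) * spec$baseline_jump_mv
    }
    signal_segment(x, spec$fs, "ECG")
  })
}

#' Generate one synthetic PetCO2 trace
#'
#' Quasi-periodic capnogram-like waveform (respiratory rate 0.1-0.3 Hz):
#' exhalation plateaus near the class-dependent level, inspiratory troughs
#' near zero, plus noise.
#'
#' @inheritParams gen_vf_signal
#' @return A [signal_segment()] (PETCO2).
#' @export
gen_petco2 <- function(class_label, spec = synth_spec(), seed = 1) {
  cls <- if (as.integer(class_label) == 1L) "success" else "fail"
  with_seed(seed, {
    n <- round(spec$duration_s * spec$fs_co2)
    t <- (seq_len(n) - 1) / spec$fs_co2
    f_resp <- stats::runif(1, 0.1, 0.3)
    level <- spec$petco2_level[[cls]] * stats::runif(1, 0.85, 1.15)
    sharp <- stats::runif(1, 4, 8)
    x <- level / (1 + exp(-sharp * sin(2 * pi * f_resp * t +
                                         stats::runif(1, 0, 2 * pi))))
    x + stats::rnorm(n, 0, spec$petco2_noise)
  }) |>
    signal_segment(spec$fs_co2, "PETCO2")
}

#' Generate the prototype signal set
#'
#' Four extreme-parameter signals per class, emulating post-shock-selected
#' prototypes: coarse extremes for the successful class, smooth extremes for
#' the unsuccessful class. Prototype seeds are disjoint from instance seeds,
#' so prototypes never coincide with train/test instances.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `vf_prototype_signals` with `signals` (8
#'   [signal_segment()]s) and `classes` (0/1 per signal).
#' @export
gen_prototypes <- function(spec = synth_spec()) {
  signals <- list(); classes <- integer(0)
  for (cls in c(1L, 0L)) {
    for (q in 1:4) {
      s <- child_seed(spec$seed, sprintf("proto-%d-%d", cls, q))
      signals[[length(signals) + 1L]] <- with_seed(s, {
        signal_segment(vf_waveform(cls, spec, extreme = TRUE), spec$fs, "ECG")
      })
      classes <- c(classes, cls)
    }
  }
  structure(list(signals = signals, classes = classes),
            class = "vf_prototype_signals")
}

#' Generate a complete synthetic shock dataset
#'
#' @param spec A [synth_spec()].
#' @return A list of class `vf_synth_dataset` with `records` (list of
#'   [shock_record()]s; the first `n_petco2_*` of each class carry PetCO2
#'   traces) and `prototypes` ([gen_prototypes()] output).
#' @export
gen_dataset <- function(spec = synth_spec()) {
  records <- list()
  counts <- c(success = spec$n_success, fail = spec$n_fail)
  co2_counts <- c(success = spec$n_petco2_success, fail = spec$n_petco2_fail)
  for (cls in c(1L, 0L)) {
    nm <- if (cls == 1L) "success" else "fail"
    for (i in seq_len(counts[[nm]])) {
      sid <- sprintf("S%d%03d", cls, i)
      ecg <- gen_vf_signal(cls, spec, seed = child_seed(spec$seed,
                                                        paste0("ecg-", sid)))
      co2 <- if (i <= co2_counts[[nm]]) {
        gen_petco2(cls, spec, seed = child_seed(spec$seed, paste0("co2-", sid)))
      } else NULL
      records[[length(records) + 1L]] <- shock_record(
        subject_id = sprintf("P%d%03d", cls, i), shock_id = sid,
        ecg = ecg, outcome = cls, petco2 = co2)
    }
  }
  structure(list(records = records, prototypes = gen_prototypes(spec),
                 spec = spec),
            class = "vf_synth_dataset")
}
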