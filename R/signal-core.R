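#' Construct a uniformly sampled physiological signal segment
#'
#' A `vf_signal` is the package's basic container: an ordered vector of
#' amplitudes sampled at a fixed rate, tagged with the channel it came from
#' (`"ECG"`, in millivolts, or `"PETCO2"`, in mmHg).
#'
#' @param samples Numeric vector of amplitudes (mV for ECG, mmHg for PetCO2).
#' @param fs Sampling rate in Hz; must be positive.
#' @param channel `"ECG"` or `"PETCO2"`.
#' @return An object of class `vf_signal` with fields `samples`, `fs`,
#'   `channel`.
#' @examples
#' s <- signal_segment(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250)
#' signal_duration(s)
#' @export
signal_segment <- function(samples, fs, channel = c("ECG", "PETCO2")) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, channel = channel),
            class = "vf_signal")
}

#' @export
print.vf_signal <- function(x, ...) {
  cat(sprintf("<vf_signal> %s, %d samples @ %g Hz (%.3f s)\n",
              x$channel, length(x$samples), x$fs, signal_duration(x)))
  invisible(x)
}

#' Duration of a signal segment in seconds
#' @param seg A [signal_segment()].
#' @return Duration in seconds, `length(samples) / fs`.
#' @export
signal_duration <- function(seg) {
  stopifnot(inherits(seg, "vf_signal"))
  length(seg$samples) / seg$fs
}

#' Construct one defibrillation shock record
#'
#' Bundles the pre-shock ECG segment, an optional PetCO2 segment, and the
#' binary shock outcome. Outcome coding: `1` = successful defibrillation
#' (return of spontaneous circulation; the positive class), `0` = unsuccessful.
#'
#' @param subject_id Opaque subject identifier.
#' @param shock_id Opaque shock identifier, unique within a dataset.
#' @param ecg A [signal_segment()] with channel `"ECG"`.
#' @param outcome 0/1 outcome label (1 = success).
#' @param petco2 Optional [signal_segment()] with channel `"PETCO2"`.
#' @return An object of class `vf_shock`.
#' @export
shock_record <- function(subject_id, shock_id, ecg, outcome, petco2 = NULL) {
  stopifnot(inherits(ecg, "vf_signal"))
  if (ecg$channel != "ECG") stop("`ecg` must have channel ECG", call. = FALSE)
  if (!is.null(petco2)) {
    stopifnot(inherits(petco2, "vf_signal"))
    if (petco2$channel != "PETCO2") {
      stop("`petco2` must have channel PETCO2", call. = FALSE)
    }
  }
  outcome <- as.integer(outcome)
  if (!outcome %in% c(0L, 1L)) stop("`outcome` must be 0 or 1", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 shock_id = as.character(shock_id),
                 ecg = ecg, petco2 = petco2, outcome = outcome),
            class = "vf_shock")
}

#' @export
print.vf_shock <- function(x, ...) {
  cat(sprintf("<vf_shock> %s/%s outcome=%d ecg=%.2fs%s\n",
              x$subject_id, x$shock_id, x$outcome, signal_duration(x$ecg),
              if (is.null(x$petco2)) "" else
                sprintf(" petco2=%.2fs", signal_duration(x$petco2))))
  invisible(x)
}

#' Extract the immediately pre-shock analysis window
#'
#' Returns the final `duration_s` seconds of a segment, i.e. the window that
#' ends at shock delivery. The default 7.8 s window is the short-term analysis
#' duration used throughout the package.
#'
#' @param seg A [signal_segment()].
#' @param duration_s Window length in seconds; the segment must be at least
#'   this long (no padding is performed).
#' @return A [signal_segment()] containing the last
#'   `floor(duration_s * fs)` samples.
#' @export
extract_preshock_window <- function(seg, duration_s = 7.8) {
  stopifnot(inherits(seg, "vf_signal"))
  n_keep <- floor(duration_s * seg$fs)
  n <- length(seg$samples)
  if (n_keep < 1L) stop("`duration_s` too small for this sampling rate", call. = FALSE)
  if (n_keep > n) {
    stop(sprintf("segment is %.3f s, shorter than requested %.3f s window",
                 n / seg$fs, duration_s), call. = FALSE)
  }
  signal_segment(seg$samples[(n - n_keep + 1L):n], seg$fs, seg$channel)
}

## ---- dataset I/O: manifest CSV + one sidecar CSV per signal -----------------

sidecar_name <- function(shock_id, channel) {
  sprintf("%s_%s.csv", shock_id, tolower(channel))
}

#' Write shock records to a manifest directory
#'
#' On-disk layout: `manifest.csv` with columns `subject_id`, `shock_id`,
#' `channel`, `fs`, `outcome`, `file`; one sidecar CSV per signal with columns
#' `t_s`, `value`. Amplitudes are written in full double precision so a
#' write/read round trip is exact.
#'
#' @param records List of [shock_record()] objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_records <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (rec in records) {
    stopifnot(inherits(rec, "vf_shock"))
    sigs <- list(rec$ecg)
    if (!is.null(rec$petco2)) sigs <- c(sigs, list(rec$petco2))
    for (sig in sigs) {
      f <- sidecar_name(rec$shock_id, sig$channel)
      tb <- tibble::tibble(
        t_s = sprintf("%.17g", (seq_along(sig$samples) - 1) / sig$fs),
        value = sprintf("%.17g", sig$samples)
      )
      readr::write_csv(tb, file.path(dir, f), progress = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = rec$subject_id, shock_id = rec$shock_id,
        channel = sig$channel, fs = sig$fs, outcome = rec$outcome, file = f)
    }
  }
  readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "manifest.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read shock records from a manifest directory
#'
#' @param path Directory containing `manifest.csv` (or the path to the
#'   manifest itself).
#' @param format Only `"csv"` (the manifest layout written by
#'   [write_records()]) is supported.
#' @return A list of [shock_record()] objects, one per shock.
#' @export
read_records <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") {
    stop("WFDB reading is not supported by this build; use the manifest CSV format",
         call. = FALSE)
  }
  manifest <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  dir <- dirname(manifest)
  mf <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "shock_id", "channel", "fs", "outcome", "file")
  if (!all(needed %in% names(mf))) {
    stop("manifest is missing columns: ",
         paste(setdiff(needed, names(mf)), collapse = ", "), call. = FALSE)
  }
  bad <- !mf$channel %in% c("ECG", "PETCO2")
  if (any(bad)) {
    stop("unknown channel in manifest line ", which(bad)[1] + 1L, ": ",
         mf$channel[which(bad)[1]], call. = FALSE)
  }
  read_sig <- function(row) {
    f <- file.path(dir, row$file)
    if (!file.exists(f)) stop("missing sidecar file: ", f, call. = FALSE)
    # base parser: correctly-rounded doubles, so write/read is bit-exact
    tb <- utils::read.csv(f, colClasses = "numeric")
    if (!all(c("t_s", "value") %in% names(tb)) || nrow(tb) == 0) {
      stop("malformed sidecar file: ", f, call. = FALSE)
    }
    signal_segment(tb$value, fs = row$fs, channel = row$channel)
  }
  out <- list()
  for (sid in unique(mf$shock_id)) {
    sub <- mf[mf$shock_id == sid, ]
    ecg_row <- sub[sub$channel == "ECG", ]
    if (nrow(ecg_row) != 1L) {
      stop("shock ", sid, " must have exactly one ECG signal", call. = FALSE)
    }
    co2_row <- sub[sub$channel == "PETCO2", ]
    out[[length(out) + 1L]] <- shock_record(
      subject_id = ecg_row$subject_id[1], shock_id = sid,
      ecg = read_sig(ecg_row[1, ]),
      outcome = ecg_row$outcome[1],
      petco2 = if (nrow(co2_row) == 1L) read_sig(co2_row[1, ]) else NULL)
  }
  out
}

#' Write a feature table to CSV
#'
#' Feature columns first, then `label` and `subject_id` (grouping) last.
#'
#' @param table A tibble with one row per shock; must contain `label` and
#'   `subject_id` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (!all(c("label", "subject_id") %in% names(table))) {
    stop("feature table must have `label` and `subject_id` columns", call. = FALSE)
  }
  tail_cols <- c("label", "subject_id")
  ord <- c(setdiff(names(table), tail_cols), tail_cols)
  tb <- table[, ord, drop = FALSE]
  num <- vapply(tb, is.numeric, logical(1)) & !(names(tb) %in% "label")
  tb[num] <- lapply(tb[num], function(x) format(x, digits = 17))
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
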