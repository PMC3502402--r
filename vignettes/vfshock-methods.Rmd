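---
title: "Methods: waveform characterization and nested evaluation in vfshock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform characterization and nested evaluation in vfshock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

vfshock predicts whether a defibrillation countershock will restore
spontaneous circulation (ROSC) from a short pre-shock ventricular
fibrillation (VF) ECG segment, optionally augmented with a capnography
(PetCO2) trace. This vignette documents the science the package implements:
the signal model and its assumptions, every tunable parameter with its
default and rationale, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations.

## The clinical problem and the modelling stance

Untreated VF coarsens or smooths over minutes: type-1 "coarse" VF (large,
strongly modulated amplitude, multiple wavelets) predicts shock success far
better than type-2 "smooth" VF (small amplitude, narrower spectral content,
mother-rotor driven). The package therefore characterizes a 7.8-second
pre-shock window — long enough to capture slow amplitude modulation, short
enough for intra-arrest decision making — with three bespoke feature
families plus a classical Fourier baseline:

1. **Pole count** (time domain): the number of local maxima whose amplitude
   jumps above the preceding maximum by more than 1.2 population standard
   deviations of all maxima. Counts beat-to-beat amplitude variation; it is
   invariant to amplitude scaling and offset, so electrode gain does not
   matter.
2. **Dual-tree complex wavelet statistics**: mean, median, standard
   deviation, energy and quantized entropy of coefficient magnitudes in
   each dyadic band. The dual-tree transform is used because coefficient
   *magnitudes* are nearly shift invariant, whereas critically sampled real
   DWT energies move by tens of percent under sub-window shifts, which
   fabricates spurious correlations when several shocks come from one
   subject.
3. **RPD-PD** (recurrence period density prototype distance): the novel
   nonlinear feature family; see below.
4. **AMSA** (amplitude spectrum area): the comparator, `sum(f * A(f))` over
   2-48 Hz.

## Preprocessing

High-frequency noise is attenuated with a Savitzky-Golay filter (window
`k = 15` samples, degree `p = 5` at 250 Hz). The small `k - p` gap gives
deliberately "slight" smoothing that preserves VF's high-frequency content
better than moving averages. Baseline jumps from electrode interference are
broadband, so frequency-domain filters would smear them across the VF band;
instead a wide Savitzky-Golay pass (`k = 251` samples, about 1 s; `p = 3`)
is applied repeatedly until the iterate changes by less than `tol = 1e-3`
in relative L2 norm (at most `max_iter = 10` passes), and the converged
estimate — which retains only jumps and drifts — is subtracted. All six
values are configurable through `preprocess_config()`; none are critical,
but `k` for the baseline pass must stay well above the dominant VF period
(~50 samples) so the baseline cannot absorb the rhythm itself.

The PetCO2 channel uses the same two-stage methodology with windows
rescaled to the 25 Hz capnography rate (smoothing `k = 9, p = 3`; baseline
`k = 125` samples = 5 s, `p = 1`). The rescaling matters: a capnogram's
information lives in the 0.1-0.3 Hz respiratory oscillation, which a 1 s
baseline window would classify as drift and remove.

## Dual-tree complex wavelet transform

Two parallel critically sampled filter-bank trees are run; level-1 filters
of tree b are tree a's delayed by one sample, and all deeper levels use a
22-tap "q-shift" lowpass (tree b uses its time reverse), so the two trees'
wavelets form an approximate Hilbert pair and `a + i b` behaves like an
analytic signal. The filter bank is designed in-package: the first-level
lowpass is the orthonormal Daubechies-8 filter obtained by spectral
factorization of the maxflat half-band polynomial, and the q-shift filter
was designed by penalized least squares under four binomial zeros at
Nyquist, with terms for exact orthonormality (residual ~1e-7),
quarter-sample-offset linear phase, a raised-cosine magnitude target and
one-sidedness of the cascaded complex wavelet's spectrum. Boundary handling
is circular convolution; an odd working length at any level is made even
by splicing the mean of the two wrap-adjacent samples, which keeps shifted
inputs equivalent to shifted outputs.

Shift invariance in practice: on synthetic VF, bands carrying at least 1%
of the wavelet energy vary by well under 5% in energy across 1-16-sample
shifts, and the dual tree always beats the critically sampled real-DWT
comparator by a wide margin. Near-empty bands (the 31-125 Hz levels of a
clean low-frequency VF signal, holding ~0.1% of the energy) show much
larger *relative* variation: their energy is dominated by band-edge
leakage of the strong 4-12 Hz content, so the denominator is tiny even
though the absolute leakage is only about -36 dB of signal energy. This is
a property of any decimated FIR implementation, not of the filter quality;
the dedicated shift-invariance test in the suite documents both readings.

Defaults: `J = 5` levels for 1950-sample inputs (deepest band keeps > 60
coefficients); statistics are computed on coefficient magnitudes — the
shift-invariant quantity — never on real/imaginary parts; energies are
`sum(|c|^2) / 2` so the bands sum to time-domain energy. Entropy uses 100
equal-width bins and the Shannon form on proportions; the raw-count variant
`-sum(C_i log C_i)` is available behind `raw_counts = TRUE` but is not
scale-free, which is why proportions are the default.

## RPD-PD

The signal is delay-embedded (`p(n) = (x(n), x(n-tau), ...,
x(n-(m-1)tau))`). For every reference state, the trajectory is followed
forward; each time it leaves the ball of radius `r` and later re-enters,
the elapsed time since the previous in-ball event is one *recurrence
period*. The histogram of periods over `1..t_max`, normalized to sum to
one, is the recurrence period density. Periodicity is the degenerate case:
as `r -> 0` on a noiseless periodic signal the density collapses to a
point mass at the true period (a property test asserts this limit).

Distances between densities use the asymmetric KD form
`sum (1 + D^c)(D^c - D^s)^2`, biased toward the comparator (prototype)
density, and the signed variant multiplies each term by `sgn(D^p - D^s)`.
The sign is applied **per period term**; an aggregate-sign variant is
available via `sign_mode = "aggregate"` because the formula's rendering is
ambiguous for vectors, but per-term signing is the default since it
preserves which periods the signal exceeds the prototype at. Each signal
yields two features: the mean signed distance to the four successful and
four unsuccessful prototypes. Both are computed for every signal without
reference to its outcome, so no label leaks into the features.

Embedding parameters `(m, tau, r, window)` are selected by exhaustively
maximizing the separation score: for each training instance, the margin
between its mean between-class and mean within-class prototype distances,
normalized by the larger of the two population standard deviations (floored
at 1e-12), summed over instances of both classes. Conventions the source
formulae leave open, decided here once:

* `r` is unitless — a fraction of the trajectory's RMS distance to its
  centroid — making the method invariant to amplitude scale. Grid default
  `r` in {0.1, 0.2, 0.3, 0.5}.
* Grid defaults `m` in {2,3,4,5}, `tau` in {2,4,6,8,10,12} samples,
  `t_max = 500` samples (2 s at 250 Hz), windows = the four quarters of
  `1..t_max` plus the full range. Ties break to the first combination in
  lexicographic grid order, so the search is deterministic.
* Recurrence bookkeeping measures exit-to-re-entry, one reference ball per
  trajectory state.
* Degenerate (recurrence-free) densities yield sentinel features (0,
  flagged) rather than errors, so a pathological test signal cannot abort a
  cross-validation run.
* Prototypes are preprocessed identically to training signals.

## Classification protocol

Evaluation is by twice-nested stratified cross-validation (all levels
10-fold by default). Inside each outer training set, level-2 folds (nested
within each level-1 training set) run cost-sensitive linear-SVM recursive
feature elimination: the feature with the smallest absolute weight is
dropped (ties: the later column), the model refit one feature at a time,
and the smallest subset attaining the maximal validation accuracy is that
run's selection. Selection frequencies `f_s = S_L2 / (k_L1 k_L2)` over the
100 inner runs define the reduced matrix (`f_s >= 0.7`, boundary
inclusive); features selected in only ~20% of runs are treated as spurious.
Level-1 folds then tune the SVM hyperparameters on the reduced matrix
(grid: linear and RBF kernels, `C` in {0.1, 1, 10, 100}, RBF gamma =
scale heuristic x {0.5, 1, 2} — the sources name no grid, so a compact
conventional one is used), and the **mode** of the ten choices trains the
fold's final model. False negatives are penalized 2:1 throughout, matching
the 56:34 class imbalance. Decision values are mapped to [0, 1] scores by
a logistic (Platt-style) calibration fit on training folds only; the
default decision threshold on the calibrated score is 0.22. Accuracy is
reported as the mean over outer folds (pooled accuracy is also recorded);
AUC is trapezoidal on the pooled out-of-fold scores.

Fold assignment is seeded, stratified within class, and by default at the
instance level; a grouped mode keeps all shocks of one subject in one fold
for sensitivity analyses, since pooling several shocks per subject is a
known source of optimism.

RPD-PD parameters are re-selected inside every outer fold from training
instances only. Because densities depend only on the signal and on
`(m, tau, r)` — never on labels or splits — they are cached once per
dataset and shared across folds, which keeps the per-fold refit cheap
without weakening blindness (an instrumented test flips test-fold labels
and asserts that no selected subset, tuned parameter, or test score
changes).

## AMSA baseline

Single-sided amplitude spectrum (rectangular window by default; calibrated
so a unit tone has unit amplitude), `AMSA = sum(A_i f_i)` over 2-48 Hz —
the conventional band, configurable since the sources omit it. A
C4.5-style decision stump scans every midpoint between sorted unique AMSA
values and minimizes cost-weighted class-membership entropy; its polarity,
threshold, and metrics plus the AMSA-ranked ROC AUC form the baseline
report. PetCO2 is never used for AMSA.

## Window-duration sweep

To show how much class-separating information the window carries as a
function of duration, the window is grown from 2 s to 11 s in 0.1 s steps
(91 durations); at each duration the separation score of every feature
dimension (distance = absolute feature difference to the prototypes) is
computed and the mean of the top five dimensions recorded. Durations with
mean separation below 0.8 are flagged non-discriminative, following the
heuristic that motivated the 7.8 s default.

## The synthetic-data generator

The clinical recordings behind the method are not redistributable, so the
generator emulates the statistical contrasts the features are designed to
detect — not VF electrophysiology:

* **Coarse (successful) class**: amplitude 0.9 mV, modulation depth 0.65,
  dominant frequency drawn from 4.0-5.5 Hz with wider frequency wander and
  spectral spread.
* **Smooth (unsuccessful) class**: amplitude 0.4 mV, depth 0.25, dominant
  frequency 5.8-7.2 Hz, narrower wander.
* Signals are sums of 3-5 sinusoids with random-walk instantaneous
  frequency under a slow random envelope, plus 0.05 mV Gaussian noise and,
  with probability 0.3, one ±1.5 mV baseline step.
* **PetCO2**: quasi-periodic capnogram-like waves at 25 Hz (0.1-0.3 Hz
  respiratory rate), plateau 38 mmHg (successful) vs 18 mmHg
  (unsuccessful) ± noise — the direction of the established
  PetCO2-perfusion correlation.
* **Prototypes**: four extreme-parameter signals per class, generated from
  seed streams disjoint from all instances.
* Default shape mirrors the study: 34 successful / 56 unsuccessful shocks,
  a 20/28 PetCO2 subset, 12 s duration so the full window sweep is
  exercisable.

`synth_spec_moderate()` provides a second, harder regime — near-equal
amplitudes, overlapping frequency ranges, higher noise — for experiments
that need ECG-only performance to be good but imperfect (as in the
clinical data, where ECG-only discrimination leaves headroom for the
capnography channel). The defaults are the positive-control conditions.

Everything derives deterministically from one master seed through hashed
per-signal substreams, so datasets are bit-reproducible and insensitive to
evaluation order.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: chest-compression artifacts, electrode motion
beyond single steps, rhythm transitions within the window, inter-subject
correlation of repeated shocks, and any physiologic coupling between the
ECG and PetCO2 channels beyond their shared class label.

## Numerical choices and simulation sizes

* Savitzky-Golay projection matrices are memoised per `(k, p)`.
* The recurrence scan is exact O(n^2 m) compiled code; a plain-R
  brute-force oracle (full distance matrix plus an explicit state machine)
  is kept in the test suite and must agree **exactly**.
* All tie-breaks (RFE elimination, subset size, hyperparameter mode, grid
  search) are deterministic and documented above.
* Degenerate inputs: constant signals yield zero maxima and zero pole
  count; empty recurrence multisets yield flagged all-zero densities;
  constant features standardize to zero and are eliminated early by RFE.
* Monte-Carlo problem sizes used by the test suite, chosen to keep the
  default run complete in minutes while leaving decisive margins: 50
  random signals for oracle equivalence; 100 trials for shift-invariance
  (5 representative shifts each) and for planted-window recovery (12
  signals + 8 prototypes of 2.4 s per trial); one full 10x10x10 run of the
  90-shock positive control; 20 label permutations at reduced fold counts
  (4/3/2) for the null control, asserting the mean permuted AUC lies in
  [0.35, 0.65]; 10 seeded 48-shock datasets for the PetCO2 direction
  check; 20-30 replicates for the remaining class-contrast properties.
  The per-fold RPD grid in the evaluation protocol uses m in {2,3},
  tau in {4,8}, r in {0.2,0.4} — a deliberately compact subset of the
  full default grid sized to the exhaustive per-fold refits.

## Limitations

* The synthetic contrasts are generous by design in the default spec;
  absolute accuracies on synthetic data say nothing about clinical
  performance, only that the machinery extracts what was planted.
* The q-shift filter is a penalized least-squares design rather than an
  exactly orthonormal one; the residuals (~1e-7) are negligible for
  feature extraction but the transform is not a perfect-reconstruction
  pair.
* Platt calibration on small training folds can saturate when folds are
  separable; scores remain valid for ranking and thresholding, which is
  all the protocol uses them for.
* With 90 instances, a 10-fold outer loop leaves 9-instance test folds;
  pooled ROC curves are correspondingly coarse.
* The sep-maximizing window search can legitimately select the full period
  range when discriminative periods dominate it; recovery tests assert
  overlap with the planted window, not equality.
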