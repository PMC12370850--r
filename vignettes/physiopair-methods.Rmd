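---
title: "Methods: paired EEG/ECG analysis with physiopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired EEG/ECG analysis with physiopair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiopair)
```

## The analysis problem

Within-subject experiments that contrast two task conditions (here labelled
*altruistic* and *selfish*) commonly combine three physiological readouts:

* **Frontal alpha asymmetry (FAA)** — the difference in relative alpha-band
  (8–13 Hz) power between the right (F4) and left (F3) frontal electrodes.
  Because alpha power is inversely related to cortical activation, a higher
  FAA score indexes relatively greater left-frontal activity, the classic
  electrophysiological marker of approach motivation.
* **Lorenz-plot (Poincaré) heart-rate-variability indices** — each RR
  interval plotted against the next; the spread of that cloud perpendicular
  to the identity line (SD1) reflects beat-to-beat, vagally mediated
  variability, and the spread along the identity line (SD2) longer-term
  variability. The cardiac sympathetic index (CSI) and cardiac vagal index
  (CVI) are derived from the cloud axes.
* **Lagged phase synchronization (LPS)** — a functional-connectivity
  measure between cortical ROI time series that discards the instantaneous
  component of phase coupling, making it robust to volume conduction and
  other zero-lag mixing artifacts.

`physiopair` implements this pipeline end to end as tested, reusable code,
together with a synthetic-data module that generates paired cohorts with
known ground truth, so every analysis stage can be validated by parameter
recovery rather than by eyeballing.

## The synthetic cohort: what it emulates, and what it does not

`gen_paired_cohort()` produces, per subject, one bundle per condition: a
19-channel 10–20-montage EEG recording, a 19-ROI source series set, an RR
interval series, and a task completion time. Defaults in `sim_config()`
encode the study conditions the package targets: 31 subjects, roughly
four-minute tasks of which 30 s at each edge are discarded, RR intervals
around 790 ms with SD1/SD2 near 20/45 ms (total CSI ≈ 2.25), and
condition contrasts of roughly half a (paired) standard deviation.

Design choices, in the order they matter:

* **Band components are filtered noise, not sinusoids.** Each channel is a
  sum of five band-limited stochastic processes (white noise band-limited
  in the FFT domain, one per frequency band, each normalized to unit SD and
  scaled by its amplitude) plus 1/f-shaped background noise. This matches
  the broadband character of EEG and makes expected relative band powers a
  pure function of the generating amplitudes (Parseval), which is exactly
  what the recovery tests exploit.
* **FAA injection is symmetric.** `faa_shift` multiplies the F4 alpha
  amplitude by `1 + shift` and the F3 alpha amplitude by `1 - shift`, so
  the injected asymmetry has a closed-form expected value.
* **ROI coupling.** A coupling entry `(roi_a, roi_b, band, lag, strength)`
  replaces roi_b's band component with a `strength`-weighted, `lag`-sample
  circularly delayed copy of roi_a's component plus
  `sqrt(1 - strength^2)` of roi_b's own independent component. The circular
  shift preserves the component's spectrum exactly. `lag = 0` yields purely
  instantaneous mixing — the case LPS must suppress.
* **RRI geometry by construction.** For a stationary series, the Poincaré
  axes satisfy `sd1^2 = gamma0 - gamma1` and `sd2^2 = gamma0 + gamma1`,
  where `gamma0`/`gamma1` are the lag-0/lag-1 autocovariances. `gen_rri()`
  therefore sums an AR(1) "slow" component (coefficient 0.9, variance
  solved from `gamma1`) and a white "fast" component (variance from the
  remainder), plus optional linear trends on the mean and on the fast
  spread. Finite-series SD1/SD2 estimators are biased, so recovery
  tolerances (15% at 400 beats) were fixed by pilot simulation rather than
  asymptotics.
* **Random-effects structure.** Condition effects are additive on generator
  parameters; subjects carry Gaussian random intercepts (asymmetry, RRI
  mean, SD1/SD2 scale, task time). Gaussian subject effects are an
  assumption of the generator, documented rather than inferred; they are
  the simplest structure under which paired tests are exactly the right
  analysis.
* **Reproducibility.** Every generator takes an explicit seed and derives
  per-subject/per-condition child streams deterministically
  (`child_seed()`); identical configuration implies bit-identical output,
  which the suite asserts.

What the generator does **not** emulate: volume-conducted scalp mixing from
dipolar sources, ECG waveform morphology (only R-peak timing), eye/muscle
artifacts, respiration coupling, and non-stationarities beyond linear
trends. Passing recovery tests therefore demonstrates that the analysis
code measures what it claims on data with known structure — not that the
pipeline is robust to every pathology of human recordings.

## Preprocessing

`bandpass()` applies a cascade of 4th-order Butterworth high-pass and
low-pass filters (defaults 1.5 and 60 Hz), each run forward and backward
(`filtfilt`), so the net filter has zero phase — connectivity downstream
depends on phase structure, which forward-only filtering would distort. A
cascade is used instead of a single recursive band-pass because a narrow
relative band at high sampling rates puts a one-shot band-pass design's
poles dangerously close to the unit circle.

`trim_edges()` removes the first and last 30 s of each task (movement
artifacts cluster at task boundaries); trimming is compositional
(`trim(a)` then `trim(b)` equals `trim(a + b)`).

`reject_artifacts()` replaces multi-stage artifact-removal chains (subspace
reconstruction, independent-component rejection) with windowed amplitude
rejection: 1-s windows are dropped when any channel deviates from its
median by more than 10 robust standard deviations (median absolute
deviation × 1.4826 — a spike must not inflate its own threshold). Those
chains target human artifacts that the synthetic data does not contain;
the stand-in keeps the "reject beyond 10 SD" spirit while keeping the
pipeline honest about the gap.

## Spectral analysis

`psd()` is a Welch estimator: 2-s Hann-tapered windows with 50% overlap,
one-sided density scaling, so total power integrates to the signal variance
(asserted to 5%). The 2-s window fixes the frequency resolution at 0.5 Hz.
A vendor-style "spectral step" display parameter has no meaning at this
resolution and is deliberately not a parameter of the implementation.

Band membership is half-open, `low < f <= high`, so adjacent bands tile a
range without double counting; for a flat spectrum the relative power of
8–13 Hz within 1–60 Hz is exactly `5/59`.

Two band dialects coexist and are selected explicitly by every caller:
the *sensor* scheme (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–60 Hz) for electrode-level work and the *source* scheme (delta 1–3.5,
theta 4–8, alpha 8.5–13, beta 13.5–30, gamma 30.5–60 Hz) for ROI-level
work, mirroring the distinct conventions of scalp and source toolchains.

`faa()` uses relative (not absolute) alpha power — relative power has the
better test–retest reliability — and raw fractions rather than
log-transformed ones; the resulting score is scale-free and antisymmetric
under an F3/F4 swap, both asserted exactly.

## Lorenz-plot indices

From points `(RRI_n, RRI_{n+1})`, `sd1` is the sample SD of
`(RRI_{n+1} - RRI_n)/sqrt(2)` and `sd2` of `(RRI_{n+1} + RRI_n)/sqrt(2)`;
`T = 4*sd1`, `L = 4*sd2`, `CSI = L/T`, `CVI = log10(L*T)`.

Two conventions deserve comment because the field's verbal descriptions
are frequently inconsistent with its numbers:

* **Axis pairing.** `physiopair` fixes SD1 as the perpendicular
  (transverse, vagal) axis and SD2 as the along-identity (longitudinal)
  axis, so CSI = SD2/SD1 — the Toichi formulation. For normal RR series the
  along-identity spread exceeds the perpendicular spread, so CSI > 1;
  published totals near 2.2 are only possible under this pairing.
* **CVI logarithm.** CVI defaults to `log10(L*T)`: with RRI near 790 ms
  and typical spreads, `log10` yields CVI ≈ 4.2 whereas a natural log
  would yield ≈ 9.7; published values match the former. A `log_base`
  argument switches to the natural log for toolchains that use it.

Sample (n−1) standard deviations are used throughout, matching common HRV
software. CSI is undefined when SD1 = 0 and CVI when either SD is zero;
both are reported as explicit `NA` with a `defined` flag, never as silent
infinities. A range sanity filter (`sanitize_rri()`, 300–2000 ms) is
available and applied by the pipeline; ectopic-beat interpolation is out
of scope. `segment_indices()` assigns beats to the first/last task minute
by R-peak time and reports change scores (last minute minus first minute)
for CSI, CVI, and mean RRI; it requires at least 120 s of data, so
short-task cohorts report totals only.

## Lagged phase synchronization

Per 2-s Hann window and per in-band frequency bin, each ROI's Fourier
coefficient is normalized to unit modulus (pure phase). The coherency of a
pair at a bin is the window-average of one ROI's normalized coefficient
times the conjugate of the other's; LPS is

    LPS = Im(rho)^2 / (1 - Re(rho)^2)

which removes the zero-phase (instantaneous) component. The
unit-modulus (phase-synchronization) variant is used rather than
amplitude-weighted coherency, so multiplying any ROI by a positive
constant cannot change any LPS value (asserted exactly).

Band-level values convert each bin's coherency to LPS **before** averaging
bins. Averaging the complex coherency across bins first would rotate
bin-wise phase ramps into partial cancellation and dilute a pure delay;
with per-bin conversion a noise-free delayed copy scores 1 at every bin
whose phase is nonzero. If `1 - Re(rho)^2` falls below `1e-12` the pair is
flagged as perfect zero-lag synchronization and scored 0 — a purely real
coherency has no lagged component by definition.

Finite data gives independent series a positive bias of order `1/K` in
`|rho|^2`, with `K` the number of window–bin samples; the suite checks the
`K^(-1/2)` scaling against a Monte-Carlo oracle, and null-cohort
connectivity sits at this bias level.

## The statistics layer

Scalar endpoints (task time, FAA, CSI/CVI/RRI totals and change scores)
are compared with `paired_compare()`: the paired differences are routed by
a Shapiro–Wilk test at alpha 0.05 to either a paired t-test (effect size
Cohen's `d = mean(diff)/sd(diff)`) or a Wilcoxon signed-rank test (effect
size matched-pairs rank-biserial `r = 2W/S - 1`). The Wilcoxon p-value
defaults to the continuity-corrected normal approximation — the convention
of the statistics GUIs this mirrors, and the only convention compatible
with half-integer W from mid-ranked ties; an exact mode (signed-rank
distribution, n ≤ 25, no ties) is selected automatically where valid and
is verified against full `2^n` sign enumeration.

Reporting is two-tier: p < 0.05 is *significant*, 0.05 ≤ p < 0.10 a
*trend* (half-open at both boundaries: exactly 0.05 is a trend, exactly
0.10 is ns), and effect sizes are labelled small/medium/large at
d = 0.2/0.5/0.8 and r = 0.1/0.3/0.5.

Multi-site maps are corrected in two ways, matching the two-tier practice
of sensor- versus source-level toolchains:

* **Sensor topographies** — per-electrode paired t-tests with
  Benjamini–Hochberg FDR across the 19 electrodes within each band.
* **ROI power, connectivity, and index–map correlations** — permutation
  max-statistic familywise correction: the null is built by per-subject
  sign flips of difference maps (or index shuffles for correlations), and
  each site's corrected p is the proportion of permutations (plus the
  observed arrangement) whose maximum |statistic| over sites reaches that
  site's observed value, with 5000 permutations by default and a floor of
  `1/(n_perm + 1)`. The permutation seed is a required, logged parameter.
  An exhaustive mode enumerates all `2^n` sign patterns for small n and is
  the oracle for the Monte-Carlo path.

The a-priori sample-size calculation uses the normal-approximation closed
form `n = ceiling(((z_{1-alpha/2} + z_{power}) / d)^2)`, which gives
n = 32 at d = 0.5, alpha = 0.05, power = 0.80 (and 34 after a 5% attrition
margin); an exact noncentral-t mode is provided as an alternative and
gives 34 directly. Both are exposed because reported power analyses rarely
state which form was used.

## Numerical and degenerate-input conventions

* Filtering: channel means are removed before filtering; the passband is
  idempotent to < 1% RMS (asserted).
* Welch scaling: periodic Hann window, one-sided density, DC and Nyquist
  bins not doubled.
* Artifact windows: trailing partial windows are treated as windows; a
  flat (zero-MAD) channel can never trigger rejection; rejecting every
  window is an error, not an empty recording.
* Zero-variance sites in permutation maps are flagged and excluded
  (p = NA) rather than silently dropped.
* All-zero paired differences are an error (no test is defined);
  constant nonzero differences route to the signed-rank branch.
* `lps()` rejects |rho| > 1 and clamps output to [0, 1].

## Problem sizes used by the test suite and acceptance script

Recovery and calibration checks run at sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while keeping the suite
quick: SD1/SD2 recovery at 400 beats (15% tolerance, pilot-calibrated),
FAA sign recovery over 100 seeded 180-s two-channel recordings, LPS checks
on 20-s three-ROI sets at 1000 Hz, type-I calibration over 400 null
cohorts of n = 31, power recovery over 500 cohorts of n = 34 at d = 0.5,
familywise calibration over 200 null maps with 199 permutations, and
end-to-end determinism on five-subject, 125-Hz, ~2-minute cohorts. The
full-scale defaults (31 subjects, 240-s tasks, 5000 permutations) are the
package defaults and run the same code paths.

## Known limitations

* ROI series are simulated or supplied directly; source reconstruction
  (inverse solutions, head models, voxel space) is explicitly out of
  scope, so ROI-level results stand in for voxel-level source analyses.
* The artifact-rejection stage is a transparent amplitude rule, not a
  reconstruction method; on real recordings it will reject more data than
  a subspace method would repair.
* Six of the nineteen default ROI labels complete the atlas by convention
  and are configurable; they are not verified against any specific
  published atlas.
* Frequency-domain HRV, respiration correction, and directed-connectivity
  measures are out of scope.
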