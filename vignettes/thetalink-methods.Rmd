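---
title: "Methods: oscillatory power, theta-phase connectivity and mediation in cued instruction tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory power, theta-phase connectivity and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`thetalink` implements the oscillatory-analysis chain used to contrast two
ways of holding novel stimulus–response instructions in working memory:
*implementing* them (preparing the instructed action) versus merely
*memorizing* them. The chain operates on epoched, source-level EEG — a
`trials x sources x time` tensor per subject, time-locked to a retro-cue,
with a per-trial metadata table — and produces:

1. band-limited power time courses per region of interest (ROI), with
   contralateral/ipsilateral laterality contrasts;
2. cluster-based sign-flip permutation statistics on those time courses;
3. within-trial multivariate phase synchronization (PLV, wPLI) between a
   medial-prefrontal (mPFC) seed and posterior ROIs;
4. trial-level linear mixed models and a bootstrap causal mediation
   analysis of task demands on reaction times via frontal theta power;
5. a synthetic-data generator that reproduces the statistical structure
   all of the above assumes, so the chain can be validated end to end
   against known ground truth.

Sensor-space preprocessing, forward/inverse modelling and atlas-based ROI
geometry are out of scope: ROIs here are abstract labelled source sets
with per-source orientation signs.

# Spectral analysis

**Bands and wavelets.** Three bands are fixed: theta 3–7 Hz, alpha
8–14 Hz, beta 15–30 Hz. Power is computed by convolution with complex
Morlet wavelets at integer frequencies in 1 Hz steps, with cycle counts
adapted per band (3/4/5 for theta/alpha/beta) to balance temporal and
spectral precision. Per-frequency power (squared magnitude) is averaged
across the band's frequencies and then decimated to the 128 samples/s
power grid; a moving-average guard of the decimation width precedes
subsampling, and because averaging, guarding and subsampling are all
linear, decimating after band-averaging is equivalent to averaging
decimated per-frequency power.

**ROI time courses.** A single time course per ROI and trial is obtained
by the sign-adjusted first right-singular vector of the sources-by-time
matrix: orientation signs are applied, the first right-singular vector is
taken, rescaled so its RMS matches the mean RMS of the member sources, and
the global sign is aligned with the sign-adjusted ROI mean. This maximizes
the variance captured by one trace while respecting dipole orientation.

**Phase for connectivity.** Phases come from a Hamming-window FIR
band-pass (3–7 Hz, 2 Hz transition bands, ~0.0194 passband ripple, ~53 dB
stopband attenuation) followed by the FFT Hilbert transform — not from
wavelet coefficients — applied at the data's native sampling rate. The
filter is linear-phase and applied with exact group-delay compensation, so
filtering is zero-phase.

**Edge handling.** The epoch (−1.0 to 2.5 s by default) is deliberately
longer than the statistical window (0–1.8 s): the pipeline *asserts* that
at least one wavelet half-length of the slowest analysis frequency
separates the window from both epoch edges and refuses to run otherwise,
so filter and wavelet edge effects can never silently contaminate the
analysis window.

**Windows and conventions.** All time windows are closed intervals with
inclusive endpoints; time is in seconds relative to cue onset. On the
128 Hz grid with the default epoch, the 355–985 ms trial-scalar window
contains 81 samples. Power is analyzed raw (induced contrasts between
within-subject conditions); no baseline normalization is applied, since
every statistic is a within-subject condition contrast and a common
multiplicative baseline cancels.

# Cluster-based permutation statistics

Subject-level condition-mean time courses are compared pointwise with a
paired *t* (or, for the 2×2 task-by-laterality designs, single-df
repeated-measures *F* statistics computed from within-subject cell-mean
contrasts; for a 2×2 design each effect's F is exactly the squared paired
*t* of its contrast, which a textbook `aov` oracle confirms in the test
suite). Contiguous samples exceeding the pointwise critical value at
α = 0.05 and sharing a sign form clusters whose mass is the sum of the
statistic. The null distribution of the *largest* cluster mass is built by
randomly flipping the sign of each subject's contrast (10,000 permutations
by default); because sign flips leave each subject's squared contribution
unchanged, the permuted *t* traces are computed fully vectorized from the
permuted means alone. A cluster's p-value is the proportion of
permutations whose maximum mass reaches the observed mass; ties count
against the observed cluster, the denominator is the permutation count
(so the smallest reportable p is `1/n_permutations`), and one-sided tests
use the one-sided critical value and compare signed mass.

Three deliberate conventions, chosen where the procedure is genuinely
open:

* the 2×2 *interaction* is permuted by sign-flipping the per-subject
  double difference, which is exchangeable under the no-interaction null
  (standard restricted-permutation practice);
* the directional beta interaction (implementation more contra-suppressed
  than memorization) is a one-sided test via the `tail` argument;
* every report of a significant cluster carries the caveat that cluster
  boundaries are a property of the cluster-level inference, not of the
  individual boundary timepoints.

Per-cluster effect size is Cohen's *d* of the subject window means of the
condition difference over the cluster extent (mean over SD, n−1
denominator — the convention used everywhere in the package).

# Connectivity

Within each trial, the phase-locking value between two phase series is the
resultant length of the phase-difference phasors over the 355–985 ms
window. Two ROIs are compared multivariately: the RMS of the M×N matrix of
all pairwise source PLVs. The weighted phase-lag index,
`|Σ Im X| / Σ |Im X|` with `X = s1 conj(s2)`, discards zero-lag coupling
(the volume-conduction signature); a pure zero-lag pair has a vanishing
denominator and is defined as 0 with a degeneracy flag. wPLI is aggregated
across source pairs with the same RMS rule as PLV (the aggregation rule
for wPLI is a package convention, stated here because no canonical choice
exists); the standard, non-debiased wPLI estimator is used. PLV is
computed within-trial (one value per trial, subject and ROI pair), at the
native sampling rate of the data, not on the decimated power grid.
Connectivity uses only correct, non-catch trials; hand-area laterality is
assigned per trial from the response side, occipital laterality from the
cued side, and the mPFC seed is bilateral. A parahippocampal pair serves
as a spatial-specificity control.

Within-trial PLV of two independent narrowband oscillators is well above
zero by construction (over a short window two independent 5 Hz rhythms
keep a near-constant phase difference), so absolute PLV values are not
interpretable as coupling strength; all inference is on *condition
contrasts* of PLV, which is also how the estimator is validated here.

# Trial-level models and mediation

The trial theta scalar is the mean mPFC theta power in the 355–985 ms
window (configurable; a flag allows re-centering on an observed cluster
instead). Before modelling, trials are trimmed with a single-pass ±3 SD
rule (n−1 SD, computed once on the full sample, never iterated): theta per
subject across tasks, reaction times per subject and task. Missing
reaction times (no response) are kept in the tables as missing and
excluded from RT models.

The fixed model structures are exactly:

```
RT         ~ Task               + (1 + Task | Subject)
Mean_theta ~ Task               + (1 + Task | Subject)
RT         ~ Mean_theta + Task  + (1 + Task | Subject)
PLV        ~ Task * Laterality  + (1 + Task | Subject)
```

fit by REML with Satterthwaite-approximate df p-values (a normal
approximation is available for large simulation loops). No random-effect
selection is performed; a singular fit falls back to a random-intercept
structure and is flagged.

Mediation follows the criterion chain (task must influence RT and theta;
theta must predict RT given task) and then estimates ACME = a·b (task
effect on the mediator times the mediator effect on the outcome),
ADE = c′, and the total effect. Uncertainty comes from a nonparametric
bootstrap resampling *subjects* with replacement and refitting both models
per draw. The default bootstrap engine refits with a two-stage estimator —
per-subject OLS coefficients averaged over the resampled subjects — whose
fixed effects coincide with the mixed-model solution in balanced
within-subject designs; since resampling a subject does not change that
subject's coefficients, the bootstrap reduces to resampling rows of a
subjects-by-coefficients matrix and is effectively instant, which is what
makes coverage validation over a hundred simulated datasets practical.
`boot_fit = "full"` performs literal mixed-model refits per draw and is
checked against the two-stage engine in the test suite. Intervals are
percentile CI95; `p = 2·min(frac ≤ 0, frac ≥ 0)`, floored at the
bootstrap resolution `2/B`. For these linear models total ≈ ACME + ADE,
which is asserted within bootstrap tolerance.

# Behavioral tests

Per-subject means come first (correct trials; regular and catch trials
separately); tasks are compared on subject means. RTs use paired *t*
tests. Error rates are gated by a Shapiro–Wilk test on the paired
differences: below p = 0.05 a Wilcoxon signed-rank test is reported (exact
distribution whenever defined, always below five subjects), otherwise a
paired *t*. Effect sizes are Cohen's *d* for *t* tests and the
matched-pairs rank-biserial correlation for Wilcoxon.

# Subject exclusion

A subject is excluded when overall accuracy falls more than 2.5 SD *below*
the group mean, or when catch-trial accuracy drops under 60% in either
task. The deviation rule is deliberately one-sided low: the exclusion
targets poor task performance, and the chosen reading (mean − 2.5·SD) is
recorded machine-readably in every exclusion decision.

# The synthetic-data generator

Each source signal is 1/f background noise (spectrally shaped white
noise, exponent 1, unit SD) plus band-limited oscillations:

* **alpha (11 Hz carrier)** in lateral-occipital ROIs, amplitude reduced
  by a fraction (default 0.4) contralateral to the cued side, identically
  in both tasks;
* **beta (22 Hz carrier)** in hand-motor ROIs, reduced (default 0.3)
  contralateral to the response side, with extra suppression (default
  ×1.3) under implementation;
* **theta (5 Hz carrier)** everywhere relevant: a large-amplitude mPFC
  rhythm whose amplitude gains a fraction (default 0.3) under
  implementation and varies lognormally from trial to trial — that trial
  amplitude is the mediator's ground truth — plus posterior theta in
  hand/occipital ROIs and an uncoupled control rhythm in the
  parahippocampal ROI.

**Coupling without power confounds.** Task-dependent phase coupling is
generated by *correlated Gaussian jitter streams*. A common jitter stream
`u` (one node per theta cycle, linearly interpolated, marginal SD
`sigma = 1/sqrt(min kappa)`) rides on the mPFC phase. Each coupled ROI
carries `v = rho(task)·u + sqrt(1 − rho(task)²)·eps` with an independent
stream `eps` of the same SD, shared by that ROI's sources; `rho(task)` is
chosen so the mPFC–ROI phase-difference variance equals `1/kappa(task)`.
Three properties follow by construction, not tuning:

* every signal's *marginal* statistics — hence spectrum and band power —
  are exactly task-invariant (a naive scheme that widens the posterior
  jitter itself under one task broadens that signal's spectrum, and the
  4-cycle alpha wavelet, spectral SD ≈ 2 Hz at 8 Hz, reads the difference
  as a spurious alpha "task effect");
* the *within-ROI joint* statistics are also task-invariant, because the
  ROI's sources share one `eps` stream — this matters because the
  SVD-based ROI extraction is data-dependent, so even a pure cross-source
  correlation difference would otherwise leak into extracted power;
* equal kappas give identical joint distributions across tasks, so the
  coupling contrast is then *exactly* null, and larger `kappa_impl` means
  tighter implementation-trial phase locking (expected PLV is monotone in
  kappa).

The mean lag defaults to π/4 so the lag-sensitive wPLI can see the
coupling; a zero-lag mode demonstrates the PLV/wPLI divergence.
Oscillation components are additionally confined to 2.5–7.5 Hz with a
soft spectral mask, honouring the band-limited premise. (The
von Mises machinery remains in `coupling_calibration()`, which maps
concentrations to expected window PLV by Monte Carlo; Gaussian node SD
`1/sqrt(kappa)` matches the von Mises dispersion for moderate kappa.)

The mPFC theta amplitude is deliberately large relative to the in-band
share of the background noise. Phase-estimation noise shrinks with
oscillation SNR, so a condition that raises oscillation amplitude also
sharpens measured phases and would otherwise inflate PLV for *every* pair
— including the control pair — mimicking connectivity. At the default
amplitude this estimation artifact is negligible; it is a real concern for
empirical EEG power/connectivity dissociations and the generator is built
so the control pair stays clean.

**Behavior.** Correctness is Bernoulli with per-task rates (defaults
0.940/0.911 regular, 0.965/0.964 catch, mirroring the error-rate structure
the analyses expect). Reaction times for correct regular trials follow
`beta0 + beta_task·[memorization] + beta_theta·(true trial theta
amplitude) + subject offset + residual`; the defaults (871, 471, −30 ms
per unit, subject SD 80 ms, residual SD 120 ms) are chosen so the
generated group means land near 708 ms (implementation) and 1217 ms
(memorization) with a genuine indirect path, giving the mediation stage a
known a·b to recover. Catch-trial RTs have their own baseline and task
effect. Subject random effects (theta gain, log-kappa, RT task slope,
suppression fractions, accuracy) are drawn once per subject, so the
`(1 + Task | Subject)` structures the models assume are actually present.
Trials are balanced across the task × cued-side × response-side cells to
within one trial; 10% are catch trials.

**What the generator does not emulate.** Volume conduction and source
leakage (ROIs are statistically independent except through the modelled
coupling), eye and muscle artifacts, non-stationary drift across blocks,
learning effects, and realistic head geometry. Passing the validation
suite therefore shows the *estimators and inference machinery* behave as
designed under the assumed statistical structure — it does not certify
robustness to leakage or artifacts in empirical recordings.

# Numerical choices and degenerate inputs

* SD always uses the n−1 denominator; time windows are closed intervals.
* The trimming rule is single-pass by contract; a zero-SD input keeps all
  values with a warning.
* Zero-variance timepoints get statistic 0 (they can never cross the
  cluster threshold) with a warning; an all-zero ROI yields a zero time
  course with a warning; a pure zero-lag pair yields wPLI 0 with a flag.
* Permutation p-values are floored at `1/n_permutations`, bootstrap
  p-values at `2/B`.
* Epochs are stored on disk as a raw little-endian float64 array plus an
  authoritative JSON sidecar (shape, sampling rate, epoch start, labels);
  trial metadata is tab-separated with `n/a` for missing RTs; ROI
  definitions are JSON with 0-based indices on disk and 1-based in R.
* Per-subject seeds and per-stage permutation seeds are derived
  deterministically from the master seeds, so a group simulation and a
  full pipeline run are bit-reproducible.

# Validation problem sizes

The generator's defaults mirror the target study design (30 subjects, 240
trials per task, 512 samples/s, epochs −1.0 to 2.5 s). The package's
standing choices for its repeated validation runs are smaller, chosen once
as the point where every effect in the generator is comfortably detectable
while a full validation pass stays fast: 128 samples/s sampling (all
analysis bands lie well below the 64 Hz Nyquist), 12–20 subjects, 80–120
trials per task, 1,000–2,000 permutations, and 200–500 bootstrap draws.
Type-I calibration uses 500 null simulations of 20 subjects; detection
power uses 200 simulations of a 300 ms pointwise-standardized difference;
mediation coverage uses 100 simulated datasets of 30 subjects × 200 trials
with B = 500. `scripts/acceptance.R` re-runs the headline pipeline at
20 subjects × 120 trials and writes every quantity it computes to JSON.

# Known limitations

* The two-stage bootstrap engine relies on within-subject balance; for
  severely unbalanced designs use `boot_fit = "full"`.
* Cluster inference is temporal only (no spatial adjacency, no TFCE), and
  p-values inherit Monte-Carlo resolution.
* wPLI on short windows is noisy and, near zero lag, conservative by
  design; the generator's nonzero default lag is what makes the wPLI
  cross-check informative.
* The congruency contrasts are separate tests; the report explicitly warns
  that their separate significance is not evidence for an interaction.
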