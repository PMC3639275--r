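---
title: "RT-equated congruency analysis: model, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-equated congruency analysis: model, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rtbold` packages one analysis idea: a congruency effect in an
interference task can be re-expressed at *equated reaction time*, using
the within-condition trial-by-trial relationship between RT and the BOLD
signal, and the way the effect responds to that correction discriminates
a conflict-monitoring account from a time-on-task account. This vignette
documents the statistical model, the synthetic-data generator, and every
place where a design decision had to be made, with the reasoning.

## 1. First-level model

Each run is modeled as a linear time-invariant system. Neural events are
zero-duration impulses at trial onsets; the impulse response is a
canonical double-gamma HRF. Per condition present in a run the design
holds:

* a **condition-mean regressor** — unit impulses at the onsets of
  included (correct, responded, non-outlier) trials, convolved;
* an **RT modulator** — the same onsets weighted by RT in seconds,
  mean-centered within the condition *before* convolution. Centering
  makes the pre-convolution weight vectors exactly orthogonal, so the
  modulator estimates the trial-by-trial RT-BOLD slope `β_RT` without
  stealing variance from the condition mean. The modulation is applied at
  microtime resolution and then convolved (the convention in SPM-style
  parametric modulation, and the construction under which the
  orthogonality claim is exact).

Excluded trials — commission errors, misses (no response; in the simple
RT task an error *is* a miss), and RTs more than 3 SD from their
conditional mean (computed once, non-iteratively, over correct responded
trials) — are pooled into one nuisance regressor per run, so their
evoked signal does not contaminate the condition estimates. The nuisance
tail is the 24-column motion expansion (linear, squared, lag-1 shifted,
squared-of-shifted of 6 rigid-body parameters), a discrete-cosine
high-pass basis (cutoff 128 s; `floor(2·N·TR/128)` columns, 5 for a
292-volume run at TR 1.25 s), and a run intercept. Runs are concatenated
with run-separate columns (session convention).

Estimation is two-pass: OLS residuals pooled across units and runs give a
single global lag-1 autocorrelation (Yule–Walker, computed within runs so
run boundaries contribute no spurious lag products); data and design are
then AR(1)-whitened identically and refit. A single global ρ mirrors the
classic SPM approximation and is much more stable than per-unit ρ when
only a handful of ROI time courses are analyzed. Contrasts are
`t = w'β / sqrt(w'(X'X)⁻¹w·σ²)` on the whitened system.

Only *linear* RT terms are modeled. Higher-order (quadratic, cubic)
RT-BOLD relationships are deliberately out of scope: they multiply the
regressor count for little expected gain, and the equating algebra below
is defined for the linear term.

## 2. RT equating

Let `Congruent`, `Incongruent` be condition-mean estimates (signal
units), `β_RT-Congruent`, `β_RT-Simple` the RT-BOLD slopes (signal units
per second), and `ΔRT = IncongruentRT − CongruentRT` the subject's mean
RT difference (ms, converted to seconds exactly once, at the multiply).
Then

```
CongruentEQ_Congruent = Congruent + β_RT-Congruent · ΔRT
CongruentEQ_Simple    = Congruent + β_RT-Simple    · ΔRT
```

and the corrected congruency effects are `Incongruent − CongruentEQ_*`.
Decisions made here:

* **Subject-level point estimates.** Equating uses each subject's own
  `β_RT` and own condition mean RTs; the estimation variance of `β_RT` is
  not propagated into the group test. This mirrors the
  subject-then-group (summary-statistics) procedure standard in fMRI;
  the cost is a slightly conservative group variance. A config switch
  allows group-mean `ΔRT` instead.
* **Slope aggregation across runs.** `β_RT` per condition is the
  unweighted mean of run-wise modulator betas — runs have equal length,
  so weighting is moot.
* **Centering scope.** RT modulators are centered within run by default
  (regressors are built per run); session-wise centering is available
  (`glm_options(rt_centering = "session")`). The difference is a small
  redistribution between the condition mean and the modulator when run
  mean RTs differ.
* The "MSIT-average" slope reported in slope comparisons is the
  unweighted mean of the congruent and incongruent slopes.

## 3. Group inference

One-sample t-tests across subjects (df = n − 1, two-tailed), FDR control
by Benjamini–Hochberg step-up at q ≤ 0.05 over all units in the analyzed
map, optional cluster-extent filtering (k ≥ 20) with face connectivity by
default (18/26 available), conjunction as the intersection of two
independently thresholded masks (no pooled minimum-statistic p — the
stricter and simpler reading), and 6-mm-sphere ROI averages with
voxel-center membership (the simplest reproducible rule). The extent
threshold is applied to each map before intersection.

## 4. The synthetic-data generator

The generator emulates the study design the analysis targets: 24
subjects; 4 MSIT runs and 2 simple-RT runs per subject; 96 trials per
run; 500 ms stimuli; SOAs drawn from {2500, 3750, 5000, 6250} ms
(multiples of the TR) with halving weights 8:4:2:1 — a discrete
pseudo-exponential that favors short SOAs, the standard
rapid-event-related jitter scheme; TR 1.25 s; 297 volumes per run, first
5 discarded, no trials during them, onsets referenced to the run start
and analyzed relative to the first retained volume.

**Behavior.** RTs are ex-Gaussian per condition — the standard
descriptive family for RT distributions — with defaults calibrated so the
generative condition means are 661 ms (congruent), 858 ms (incongruent)
and 376 ms (simple): mu/sigma/tau = 486/60/175, 633/75/225, 291/40/85 ms.
The 3-SD trimming rule removes the deep exponential tail, so *included*
means sit ~1–1.5 % below the generative means; this is inherent to
trimming a right-skewed distribution, affects all conditions alike, and
is well within every tolerance used. Subject-level mean shifts are
normal with SDs 70/90/60 ms — chosen so that 24-subject group t-values
for behavioral contrasts land in the low-to-mid teens, the range typical
for this design. Accuracies are 99.8/98.1/98.9 %; an incorrect simple-RT
trial is a miss (no RT), an incorrect MSIT trial keeps its RT.

**Neural amplitudes.** Under `time_on_task`, every trial of both tasks
has amplitude `a + b·RT` with one slope `b` (default 1 signal unit/s)
shared across conditions and tasks; the congruency effect is then purely
RT-borne, and the corrected effect is zero *by algebra*, not by tuning.
Under `conflict_monitoring`, MSIT trials have amplitude
`a_cond + c·(RT − condition mean RT)` and simple-RT trials a constant
`a_simple`: conflict tracks RT within the interference task only. The
default condition baselines are themselves conflict-generated
(`a_cond = a0 + c·(calibrated condition mean RT)`), which is exactly the
decomposition of "amplitude ∝ conflict ∝ RT" into the within/between
form — and is what makes the congruent-slope correction eliminate the
effect under this account while the simple-slope correction does not.
Miss trials get amplitude 0 (no response process; configurable).

**Noise.** AR(1) Gaussian noise (marginal SD 0.8 signal units, ρ = 0.3)
plus low-frequency cosine drift (3 components with period ≥ ⅔ of the run,
coefficient SD 1.0 — inside the high-pass stopband by construction).
Between-subject SDs of baseline/slope/gain are 0.25/0.4/0.4. These
levels were chosen once so that group-level slope and congruency
t-statistics fall in the single-digit-to-low-teens range reported for
ROI analyses of this design — i.e., a realistic effect-to-noise regime,
not a best case. Motion traces are smooth bounded random walks carrying
no signal; they exist to exercise the nuisance path.

**What the generator does not emulate:** physiological noise and its
correction, motion-corrupted images, slice timing, spatial structure and
smoothing, nonlinear BOLD saturation at short SOAs. Passing tests
therefore demonstrate the *statistical logic* of the pipeline — unbiased
slope recovery, correct elimination/survival of the corrected effect —
not robustness to scanner artifacts. All units within a subject share
the event-locked signal and differ only in noise; spatial heterogeneity
across ROIs is not modeled.

**Determinism.** One master seed; per-subject, per-run and per-stream
child seeds derived by a fixed integer hash (`derive_seed`), all below
2³¹. The same configuration and seed reproduce a dataset bit for bit.

## 5. Numerical choices

* HRF: difference of two gamma densities parameterised by their *mode*
  (peak 6 s, undershoot 16 s, dispersion 1 s, ratio 6, support truncated
  at 32 s), scaled to unit peak. Parameterising by the mode keeps the
  kernel's argmax at the nominal peak delay. Microtime oversampling 16
  bins per TR; onsets bin to the nearest microtime sample. Because both
  the simulator and the analysis use this forward model, noise-free
  recovery is exact to machine precision (a tested contract).
* Convolution by direct superposition of shifted kernels (events are
  sparse), not FFT.
* All-zero design columns (constant-RT modulators, idle motion channels)
  are dropped with a warning to keep designs full rank; genuinely
  collinear designs abort with the offending column names.
* Zero-variance group effects: t = ±Inf with p = 0 and a warning (t = 0,
  p = 1 when the mean is also zero).
* A condition with < 2 usable trials cannot support the outlier rule:
  nothing is flagged, with a warning.

## 6. Scale of the shipped checks

The test suite runs the full pipeline at the study scale (24 subjects,
4+2 runs of 96 trials, 292 retained volumes, 5 ROIs) for the behavioral
calibration, slope-recovery and discrimination checks; the discrimination
check uses 20 replicate experiments per generative account and requires
≥ 90 % correct classification, with the significance pattern
(uncorrected effect present; both corrections eliminate it under time on
task; the simple-slope correction fails to eliminate it under conflict
monitoring) asserted on across-replicate aggregates. Aggregates are used
deliberately: each "non-significant at α = .05" reading is a 5 % coin
under the null, so demanding the triple conjunction in ≥ 90 % of
individual replicates would fail a material fraction of the time even
when the method is exactly calibrated — a property of test multiplicity,
not of the method. Structural and oracle tests use a `tiny` fixture
(4 subjects, 1 run per task, 24 trials, 96 volumes) generated in code.

## 7. Known limitations

* `β_RT` estimation error is ignored in the equating step (see §2);
  with many units and weak slopes this inflates the variance of the
  corrected effect rather than biasing it.
* The conflict operationalization is linear in within-condition RT
  deviation; saturating or threshold conflict signals would weaken the
  congruent-slope correction but leave the simple-slope logic intact.
* ROI mode is primary. Volumetric utilities (NIfTI I/O, cluster extent,
  sphere averages) operate on arrays + affines and are exercised on
  synthetic grids, not on simulated 4-D images.
* The trial-sequence generator imposes no condition-order constraints
  and does not optimize jitter sequences per run; analyses here do not
  condition on trial history, so none is needed.
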