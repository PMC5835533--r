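---
title: "Classifying depth electrodes by evoked task modulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying depth electrodes by evoked task modulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stereo-EEG depth electrodes implanted through the temporal lobe record
intracranial evoked potentials (iEPs) simultaneously from the lateral
temporal cortex (LTC) and the hippocampus while a patient performs a
cognitive task — here, self-projection tasks with two collapsed
conditions per task ("now" vs "then" in time, "here" vs "there" in
space). With a handful of patients and electrodes, conventional group
statistics are unavailable, and electrode-wise waveform comparison is
hampered by polarity reversal: the same local generator can produce
sign-inverted deflections at electrodes on opposite sides of it.

`ieptask` implements the alternative inferential route: summarize each
electrode by two sign-invariant scalars — early and late *task
modulation* — classify electrodes by region in that two-dimensional
space with a linear max-margin classifier, and attach significance by
exhaustively permuting the region labels. Because no such patient data
set is public, the package also contains a first-class simulator that
reproduces the statistical structure of the recordings, so every stage
is testable end to end.

## The task-modulation statistic

For electrode $i$ with mean evoked waveforms $S^i_{\mathrm{now}}(t)$ and
$S^i_{\mathrm{then}}(t)$, the early modulation is

$$
M^i_{\mathrm{early}} \;=\;
\frac{\bigl|\int_{100}^{400} S^i_{\mathrm{then}}(t) - S^i_{\mathrm{now}}(t)\,dt\bigr|}
     {\bigl|\int_{100}^{400} S^i_{\mathrm{now}}(t)\,dt\bigr|},
$$

with the late modulation defined identically over 400–800 ms. The
numerator is the absolute signed area between conditions; the
denominator normalizes by the reference ("now"/"here") condition's
signed area in the same window, making the statistic dimensionless,
invariant under common rescaling, and — because both integrals flip sign
together — invariant under polarity reversal.

Numerical choices:

* Integrals are trapezoidal over the continuous interval $[w_0, w_1]$,
  with linear interpolation at window edges. This reproduces closed-form
  areas exactly for piecewise-linear signals and makes abutting windows
  additive: the shared 400 ms boundary contributes zero double-counted
  measure, so no sample is ever counted in both periods.
* The epoch ends at 800 ms nominally but the sampling grid at 512 or
  1024 Hz ends just short of it (900 ms is not an integer number of
  samples); a window edge may overshoot the grid by at most one sample
  interval and is clipped.
* The denominator follows the equation as typeset: the *signed* area
  $|\int S\,dt|$, not the rectified area $\int |S|\,dt$. The phrase
  "area under the curve" admits the rectified reading, so
  `abs_auc = TRUE` provides it. A signed-area denominator can be
  degenerate (a biphasic waveform can integrate to nearly zero); such
  electrodes are flagged `degenerate` with a classed warning and
  excluded from classification rather than silently zeroed. The
  degeneracy threshold is relative: $10^{-9} \times$ window length
  $\times \max|S_a|$.
* Features are computed in physical units (µV·ms) so patients sampled at
  512 and 1024 Hz are commensurable.

## Classification and permutation inference

Electrodes of one hemisphere and task form observations
$x_i = (M^i_{\mathrm{early}}, M^i_{\mathrm{late}})$ with labels LTC /
hippocampus. The chain is:

1. **Z-scoring** per feature over the full electrode set, using the
   population standard deviation (divisor $n$). Scaling on the full set
   mildly leaks across cross-validation folds; this is how the statistic
   is defined here, and `fold_safe_scaling = TRUE` offers the
   leakage-free variant (both are tested).
2. **Penalty selection**: leave-one-out (n-fold) accuracy of a
   soft-margin linear SVM at ten values of $C$ log-spaced over
   $[10^{-3}, 10^3]$; the arg-max is selected, ties going to the
   smallest $C$ (strongest regularization, deterministic).
3. **Leave-one-out accuracy** at the selected $C$. A training fold
   containing a single class predicts that class.
4. **Exhaustive label permutation**: every distinct labeling preserving
   the class sizes — $\binom{12}{6} = 924$ for six electrodes per class —
   is scored by its LOO accuracy with $C$ held fixed at the
   observed-data selection; permuting identical labels is a no-op, so
   full $n!$ enumeration would be redundant. The p-value is the
   proportion of labelings, observed included, whose accuracy is at
   least the observed one; it is therefore never zero and is bounded
   below by $1/\binom{n}{n_1}$. Beyond a configurable cap (default
   20,000 labelings) a seeded Monte-Carlo sample with the add-one
   convention is used instead. `reselect_C_per_perm = TRUE` re-runs the
   grid search inside every permutation as a sensitivity analysis.

The SVM quadratic programs are solved to a stopping tolerance that
scales with the penalty, $\min(10^{-3}, \max(10^{-8}, 10^{-6} C))$:
KKT violations scale with $C$, so a fixed absolute epsilon would be
needlessly tight (and extremely slow to reach) for large-$C$ fits on
inseparable labelings, while small and typically-selected $C$ values are
solved essentially exactly, so near-boundary predictions reflect the
converged decision rule rather than solver slack. On tight,
well-separated class
clusters exactly two labelings (the true one and its complement) achieve
perfect accuracy, giving $p = 2/924 \approx 0.0022$.

## Cluster-based permutation statistics

Single-trial amplitude comparisons between conditions use a pointwise
independent two-sample t-test at every time sample (pooled variance,
$df = n_a + n_b - 2$; Welch by flag), with the uncorrected two-tailed
$p < 0.05$ mask reported. Because adjacent samples are strongly
dependent, family-wise control uses the randomization cluster test:
clusters are maximal runs of contiguous samples whose $t$ exceeds the
two-tailed critical value, found separately for positive and negative
excursions; the cluster mass is the sum of $t$ within the run; and each
observed cluster's absolute mass is referred to the permutation null of
the *maximum* absolute cluster mass under random reassignment of trial
labels (class sizes preserved, default 1,000 permutations, seeded).
Cluster p-values use the add-one convention. Two-sidedness is handled by
building the null from the maximum over both excursion signs; the
sidedness convention at cluster level is a design choice here, made
explicit because it is frequently left unstated.

## The synthetic-data generator

The generator emulates the recording setup the analyses target: 6 LTC +
6 hippocampal electrodes on the left, 3 + 5 on the right; ~120 trials
per block split across two conditions (60 per condition after the
past/future factor is collapsed — that factor is carried as metadata
with no injected effect); epochs −100 to +800 ms at 512 Hz (1024
supported); and region-specific condition effects — the non-reference
condition template equals the reference template scaled by
$1 + \mathrm{effect}$ inside 100–300 ms at LTC electrodes and inside
400–600 ms at hippocampal electrodes, with 20 ms raised-cosine tapers at
the window edges so the injected difference has no sharp spectral edges.

Values the source setting does not fix were chosen once as plausible for
intracranial evoked responses and are not tuned: an evoked kernel of
three Gaussian deflections (+10 µV at 180 ms, σ 40 ms; −4 µV at 300 ms,
σ 50 ms; +6 µV at 550 ms, σ 60 ms), chosen biphasic but with signed area
well away from zero in both analysis windows so clean-data denominators
are never degenerate; additive i.i.d. Gaussian noise of 2 µV sd
(single-trial peak SNR ≈ 5); effect sizes 0.5; polarity reversal
probability 0.25 per electrode (applied identically to all its trials);
and an artifact rate of 0.02 — each artifact trial receives one local
Gaussian transient (peak 10 × noise sd, σ 15 ms) on one random
electrode, deliberately *not* pre-flagged so rejection has to find it.
Every electrode draws from a deterministic substream of the top seed, so
datasets are bit-reproducible and adding electrodes never perturbs
existing ones.

What the simulator does not emulate: continuous raw recordings with
event triggers, epileptic background rhythms, 50/60 Hz line noise,
cross-electrode correlated noise, and trial-to-trial latency jitter.
Passing tests therefore demonstrate that the *procedures* are correct
and calibrated on data with the declared structure — not that real
recordings would yield any particular result.

## Preprocessing choices

* **Filter**: 4th-order Butterworth band-pass 1–120 Hz applied
  forward-backward (`signal::filtfilt`, zero phase), after removing each
  trace's mean. The demeaning matters: on a 0.9 s epoch the impulse
  response of a 1 Hz high-pass is comparable to the epoch itself, and
  filtering alone leaves a double-digit percentage of a DC offset in the
  mid-epoch. With demeaning, DC is removed exactly; in-band tones (50 Hz)
  pass within 5% and out-of-band tones (200 Hz at 1024 Hz sampling) are
  attenuated by over 90%. The first and last 50 ms remain
  edge-contaminated and are flagged untrusted. A consequence worth
  stating plainly: a 1 Hz high-pass on sub-second epochs redistributes
  the near-DC signed area of slow deflections, so window-integral
  features after filtering differ from the injected construction even at
  zero noise (classes remain cleanly separated); generator-level
  structural checks are therefore run on raw trial averages.
* **Baseline correction** (default on) subtracts the mean over −100–0 ms
  per trial. Whether to baseline is the single most consequential
  unstated choice for a signed-area denominator, so it is a flag
  (`baseline = FALSE` preserves the literal band-pass-only reading) and
  is recorded in the report.
* **Artifact rejection** replaces visual inspection: for each electrode
  and time sample, amplitudes are standardized across trials by
  median/MAD (scaled by 1.4826); a trial is flagged if any sample
  exceeds 6 robust z. Standardizing per time sample removes the evoked
  template from the statistic, so detection power targets
  trial-specific transients. On clean Gaussian data the false-flag rate
  is far below 5% of trials; rejection refuses to leave fewer than two
  trials in any condition.

## The subset power analysis

To ask whether a null result in the smaller right-hemisphere complement
(3 LTC + 5 hippocampal) could be mere power loss, the full
classification chain — z-scoring, penalty selection and the exhaustive
permutation test, all redone within the subset, since the subset *is*
the dataset for that analysis — is run on every left-hemisphere subset
matching that composition: $\binom{6}{5}\binom{6}{3} = 120$ subsets,
each with $\binom{8}{5} = 56$ labelings. The report aggregates the
fraction of subsets with accuracy strictly above 75% and the fraction
significant at $p < 0.05$. On strongly separable synthetic data all 120
subsets stay separable while many lose significance — the floor p-value
of a 5v3 design is $1/56 \approx 0.018$, so power, not effect size, is
what the reduction removes.

## Orchestration and reproducibility

`run_config()` + `run_all()` assemble the full scenario: a time task
with left-hemisphere effects, a right hemisphere with none, and a space
task with none (configurable), yielding the 2 × 2
hemisphere-by-task grid of classification results, per-electrode cluster
tests and the subset report. Every stage's randomness derives
deterministically from the single top seed; re-running a config
reproduces the report bit-identically; stage errors propagate with the
stage name attached. Epoch sets serialize to a TSV (one row per
trial × electrode) plus a JSON sidecar; reading validates region and
hemisphere labels, the trial × electrode grid, and sample completeness,
with errors naming the offending field or row.

## Problem sizes used in the test suite

The simulations behind the statistical guarantees use reduced sizes
chosen to make the checks sharp but routine to re-run: type-I behavior
of the classifier permutation p-value over 200 seeds with 4 + 4
electrodes (70 labelings each, 10 trials/condition at 256 Hz);
family-wise error of the cluster test over 200 seeds (300 permutations
each); effect recovery and localization over 100 seeds; the naive-oracle
equivalence on 4 + 4 electrodes against a from-scratch re-implementation
(scipy dual-QP SVM, explicit loops). The acceptance-scale scenario —
6 + 6 electrodes, 60 trials/condition, 512 Hz — is run in full for the
headline accuracy and the 924-labeling permutation test.

## Known limitations

* The exhaustive permutation test enumerates class-size-preserving
  labelings; with $C$ fixed at the observed selection, selection
  optimism is not re-permuted (the per-permutation re-selection flag
  exists for sensitivity analysis).
* The cluster test controls family-wise error per electrode and
  condition pair; no correction across electrodes is applied, matching
  the per-electrode reporting convention.
* Window-integral features after a 1 Hz high-pass are not identical to
  the same features on unfiltered data (see above); comparisons across
  preprocessing settings should hold the filter fixed.
* The simulator's i.i.d. noise makes the pointwise t-test exactly
  calibrated per sample; real iEP noise is autocorrelated in time, which
  is precisely why the cluster statistic, not the pointwise mask, is the
  inferential quantity.
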