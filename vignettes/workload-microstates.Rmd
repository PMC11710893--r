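---
title: "EEG band power and microstates under mental workload: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG band power and microstates under mental workload: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

## Scope

This package implements a complete analysis chain for multichannel scalp
EEG recorded under contrasting mental-workload conditions: offline
preprocessing, periodogram band power in the classical delta / theta /
alpha / beta bands, four-class microstate segmentation with temporal and
syntax parameters, and the statistical battery used to contrast conditions
and relate spectral to microstate features. Because the kind of study it
targets rarely deposits raw EEG, the package also ships a synthetic
generator that plants known microstate dynamics and band-power contrasts,
so that every stage of the chain can be verified by recovery tests rather
than by eye.

## Preprocessing

The default chain mirrors standard offline practice for workload EEG:
downsample to 250 Hz, zero-phase band-pass 1–40 Hz with a 50 Hz notch, cut
into 2 s epochs, reject any epoch whose peak absolute amplitude exceeds
100 µV on any channel, and re-reference to the common average.

Choices the underlying data do not dictate:

* **Filter family.** No filter family is mandated by the analysis
  conventions this implements, so we use forward–backward (zero-phase)
  IIR filtering: Butterworth high-pass and low-pass of 4 poles each plus
  a second-order notch (quality 25). Zero phase matters because microstate
  analysis is about the *timing* of topographic changes; a causal filter
  would smear segment boundaries. The forward–backward pass squares the
  magnitude response, so effective attenuation is twice the single-pass
  value in dB. Edge transients are controlled by padding with a tapered
  even reflection of the signal — unlike the common odd reflection, this
  extension carries no DC step, which a narrow notch would otherwise ring
  on.
* **Rejection granularity.** The >100 µV artifact rule is applied per 2 s
  epoch, which makes the survivor mask well defined and matches the
  epoching that follows.
* **Chain order.** Epoching before rejection is equivalent to rejecting
  on continuous data split at the same boundaries; common-average
  re-referencing commutes with epoching (asserted in the tests), so its
  position in the chain is immaterial.
* **Omitted steps.** Visual inspection and ICA-based artifact removal are
  human-in-the-loop or off-the-shelf steps, and the synthetic data contain
  no ocular/cardiac components; both are deliberately out of scope.
* **Resampling** is rational-ratio polyphase (upsample, windowed-sinc FIR,
  downsample) with linear-phase delay compensation.

One definitional tension is preserved as-is: the delta band is defined as
0.5–3 Hz while the analysis band-pass starts at 1 Hz, so effective delta
content is 1–3 Hz. The band edges are kept at their conventional values
rather than silently redefined.

## Spectral analysis

Per epoch and channel the unwindowed periodogram is
\(P(k) = |X(k)|^2 / N\), with \(X\) the raw DFT of the \(N\)-sample
epoch. Band power is the arithmetic mean of \(P(k)\) over the
non-negative-frequency bins with \(f_{lo} \le f \le f_{hi}\) (both edges
inclusive), then the mean across epochs; averaging across bins and across
epochs commute, so the order is immaterial. Powers stay linear (µV²); no
dB or relative normalization is applied. Parseval's identity
(\(\mathrm{mean}(x^2) = \sum_k P(k)/N\)) is asserted in the tests, which
pins the DFT normalization. "Total average power" of a band is the
unweighted mean over all 31 channels and task blocks.

The rectangular window means spectral leakage is that of the raw
periodogram. One consequence worth knowing: even a signal with no true
4–7 Hz content shows a small theta reading (of order 1% of the
neighboring band) when its spectrum has a sharp edge nearby. The test
suite therefore uses bin-aligned tones where exact zero leakage is
required.

## Microstate analysis

*Global field power* (GFP) is the per-sample population SD across
channels — for average-referenced data, the RMS across channels.
Topographies at strict local maxima of the GFP series (the high-SNR maps)
are extracted and clustered with the polarity-invariant **modified
k-means** (k = 4): maps are normalized; the assignment step labels each
map by maximal squared spatial correlation to the templates; the update
step replaces each template with the dominant eigenvector of the scatter
matrix of its assigned maps. Because all maps are average-referenced,
spatial correlation reduces to the normalized dot product, and squaring
it makes polarity irrelevant — the appropriate convention for oscillatory
generators whose topography reverses sign every half-cycle.

Numerical conventions:

* The clustering objective is the mean squared spatial correlation of
  the normalized maps to their assigned templates; convergence is a
  change below 1e-6, iteration cap 100, best of 50 random restarts
  (seeded, deterministic). GFP-weighted global explained variance (GEV)
  is reported as fit quality alongside; the assignment step is optimal
  for both, the eigenvector update is the exact maximizer of the
  unweighted objective given an assignment, which keeps the iterate an
  ascent method for a single well-defined criterion (and lets a
  brute-force enumeration oracle verify global optima on small
  instances).
* An emptied cluster is re-seeded from the currently worst-fit map.
* Ties in any argmax break toward the lowest class index.

Subject-level template sets are combined by **grand-mean clustering**:
each subject's four maps are aligned to the evolving mean maps by
exhaustive search over the 4! label permutations (polarity fixed by the
sign of the correlation), the aligned maps are averaged and re-normalized,
and the procedure iterates until the alignment stabilizes. The grand
templates are then given canonical A–D labels by the permutation
maximizing total absolute correlation to analytic reference maps: A
right-frontal-to-left-posterior, B its left-right mirror, C a symmetric
anterior-posterior pattern, D a frontocentral maximum. These references
are dipolar patterns constructed on an idealized spherical 10-20 montage
(cosine of the angle between electrode position and a class axis); they
are geometric stand-ins, not maps fitted to any dataset.

**Back-fitting** converts the recording into a label series by maximal
absolute Pearson spatial correlation to the templates. Two fitting
domains are provided. `fit_at = "all"` labels every sample
independently; `fit_at = "peaks"` labels only the GFP peaks and extends
each peak's label to the midpoints between neighboring peaks, which is
how the peak-domain back-fitting of standard microstate toolboxes
converts peak labels into a continuous series. The *pipeline* defaults
to the peak domain, and this choice is substantive: at realistic noise
(10 dB SNR) per-sample labeling makes roughly three quarters of observed
segments single-flicker misclassifications, which both shortens apparent
durations several-fold and — more insidiously — flattens the transition
matrix toward the spatial-confusion structure of the templates, to the
point of erasing a planted 0.15 reduction in one A↔B cell. Peak-domain
fitting restores observed durations to the planted dwell means and
observed transition contrasts to within ~30% of the planted ones (both
verified in the recovery tests). Per-sample fitting remains available
and is the appropriate choice at high SNR or for method comparisons. No
temporal smoothing or minimum-duration rejection is applied in either
mode (both are deliberately absent rather than defaulted on); in
all-sample mode zero-variance samples inherit the previous sample's
label.

Parameters per class: *duration* = mean length of maximal constant-label
runs (ms), *occurrence* = runs per second, *coverage* = fraction of
samples. Runs never span epoch joins (epochs are concatenated per subject
and condition before segmentation; boundaries cut runs and no transition
is counted across them, so 2 s epochs do not bias the syntax).
*GEV* \(= \sum_t (\mathrm{GFP}(t)\, r_t)^2 / \sum_t \mathrm{GFP}(t)^2\)
with \(r_t\) the absolute correlation of the sample map to its assigned
template — the standard GFP-weighted definition. *Transition
probabilities* are counted at segment resolution (self-transitions are
impossible by construction); rows with no departures are flagged rather
than zero-filled.

## Synthetic data: the stated world

The generator emulates 31-channel average-referenced EEG at 250 Hz with:

* a semi-Markov microstate sequence over the four canonical maps —
  dwell times geometric (memoryless, the simplest law with a controllable
  mean, so recovery tolerances have a closed form) with mean 80 ms per
  class (70 ms for D), minimum one sample; successors drawn from a
  row-stochastic zero-diagonal transition matrix; the initial class drawn
  from the stationary occupancy;
* a band-limited Gaussian carrier (alpha band, 8–13 Hz, unit RMS scaled
  to 25 µV total) multiplying the active template — band-limited noise
  rather than a pure sinusoid so that spectral structure and microstate
  dynamics coexist;
* independent per-channel band-limited background activity in each
  classical band (RMS 3 / 2.5 / 2 / 1.5 µV for delta / theta / alpha /
  beta, a decreasing 1/f-like profile) carrying the spectral contrasts as
  multiplicative power gains;
* spatially white sensor noise scaled to a stated SNR (default 10 dB),
  defined as RMS(microstate signal) / RMS(noise) after average reference.

Band-limited components are synthesized by spectral masking of white
Gaussian noise (exact band limits, no filter roll-off). The workload
scenario plants, in the high condition relative to low: theta and beta
power gains of 1.5 and 1.4; B dwell shortened from 80 to 60 ms; more
frequent transitions into D; A↔B transition probabilities reduced
(0.40 → 0.25) and C↔D increased (0.30 → 0.45); between-subject lognormal
jitter (σ = 0.1) on dwell means and gains. Directions mirror the workload
phenomenology the package targets; magnitudes are package choices, fixed
once.

What a green recovery test does establish: the analysis chain recovers
planted templates, dwell structure, syntax and spectral contrasts from
data *generated under this model*. What it does not establish: robustness
to real artifacts (ocular, muscle, electrode drift), non-geometric dwell
laws, non-stationarity across a session, or volume-conduction effects
beyond the dipolar map construction — none of which are simulated.

## Statistics

Paired t tests (two-sided) contrast conditions; Cohen's d uses the
pooled-condition-SD convention
\(|m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}\), chosen because it is the one
convention that reproduces printed effect sizes from condition-level
summary statistics alone (verified in the acceptance tests for both
reference rows). One-way repeated-measures ANOVA uses the standard
within-subject decomposition with partial
\(\eta^2 = SS_{effect}/(SS_{effect}+SS_{error})\); no sphericity
correction by default (Greenhouse–Geisser available as an option). Fisher
protected LSD compares level pairs with the ANOVA error term, only when
the omnibus test is significant. Pearson correlations carry the
conventional strength categories (|R| > 0.70 strong, 0.50–0.70 moderate,
0.30–0.50 weak). Electrode-wise band-power contrasts are corrected with
Benjamini–Hochberg FDR across the 31 channels within each band; no
across-band correction is applied, matching per-band reporting.
Correlation observations pool subject × condition × block by default.

## Worked example

A small run (3 subjects, 10 s blocks — far below the defaults, for speed):

```{r example, eval = FALSE}
cfg <- run_config(n_subjects = 3, seed = 9, block_s = 10, n_restarts = 5)
report <- run_pipeline(cfg)
report$band_contrast
report$microstate_contrast
```

At the default scale (36 subjects, two 3-minute blocks per condition,
SNR 10 dB) the planted directions — theta and beta power up, B duration
and coverage down, D occurrence and coverage up, A↔B transitions down,
C↔D up in the high-workload condition — are reported with the correct
sign in effectively every seed; the acceptance suite verifies this on 10
seeds at a reduced block length (30 s) and restart count (10), a
documented budget scaling that tests directions, not magnitudes.

## Known limitations

* No EDF I/O: recordings interchange through a plain-text container
  (CSV matrix + JSON sidecar).
* No ICA, channel interpolation, or re-referencing schemes other than
  common average; no Welch/multitaper spectra; no relative power.
* k is fixed at 4; no alternative clusterings (AAHC, PCA/ICA-based) or
  optimal-k criteria.
* Observed microstate durations are noise-dependent: faithful at the
  pipeline's peak-domain fitting, several-fold shortened under
  per-sample fitting at low SNR. Treat absolute durations with care and
  prefer within-subject contrasts.
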