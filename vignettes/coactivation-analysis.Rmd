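---
title: "Event-based co-activation analysis of task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based co-activation analysis of task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactr)
library(dplyr)
```

## The method

Classical task fMRI analysis regresses every voxel's BOLD signal on a
predicted response. The approach implemented here inverts the direction
of comparison: the *stimulus timeline itself* is turned into a synthetic
"source" signal, reduced to a point process of discrete high-amplitude
events, and each event is correlated with the simultaneous BOLD segment
of every region of interest. Amplitude thresholding acts as a simple
non-linear filter — only the moments where the expected response is
large contribute — which raises the signal-to-noise ratio of the
correlation estimate and gives it a natural directionality (stimulus
leads, BOLD follows) and time stamps.

The pipeline has five stages.

**1. Source series.** Stimulus onsets of one task phase (memory sets for
encoding, probes for retrieval) are encoded as a 1 kHz indicator — by
default a boxcar equal to 1 for the full stimulus duration; a
single-impulse variant is available via `shape = "impulse"`. The
indicator is convolved with the canonical double-gamma haemodynamic
response function

$$ h(t) \;=\; g(t;\,6,1) \;-\; \tfrac{1}{6}\, g(t;\,16,1), $$

where $g(t;a,b)$ is the gamma density with shape $a$ and scale $b$
(peak near 5 s, undershoot near 15 s, 32 s of support). The convolution
is sampled at the volume acquisition times $t = k\,\mathrm{TR}$
($k = 0, \dots, n-1$; point evaluation, no within-TR averaging) and
z-scored over the run with the population ($n$-denominator) standard
deviation.

**2. Events.** A source event starts at every upward crossing of the
threshold (1 z by default): a volume above the threshold whose
predecessor is not. Requiring an *upward* crossing prevents a sustained
plateau from being counted repeatedly. Each event spans 5 consecutive
TRs including the crossing — enough to cover the whole positive lobe of
the response at TR = 1.8 s. The time-matched 5-sample BOLD segment of
each region is the target event, and each source/target pair contributes
one Pearson correlation. Degenerate (zero-variance) segments yield a
missing correlation, which is excluded from averaging and logged.

**3. Cells.** Per-event correlations are averaged within each
combination of subject, session (diurnal condition), task, phase, probe
type, response and region, and the average is Fisher-transformed,
$z = \operatorname{atanh}(\bar r)$. Because a 5-point correlation can be
exactly $\pm 1$, $|\bar r|$ is clamped at $1 - 10^{-7}$ first. Events are
attributed to the most recent same-phase trial at or before the
crossing; a gap above 12 s flags an implausible attribution. Encoding
events additionally inherit the probe type and behavioural response of
the probe that concludes the same memory-set trial, so encoding cells
can be keyed by probe and response exactly like retrieval cells — the
factorial response model below needs both phases on both sides of every
factor.

**4. Delays.** For each event the reference point is the parabolically
refined maximum of the source series inside the event window.
Candidate BOLD peaks are strict local maxima (plateau midpoints for
ties, endpoints never); each is refined by fitting a parabola through
the three samples around it,

$$ \delta \;=\; \frac{y_{-1} - y_{+1}}{2\,(y_{-1} - 2 y_0 + y_{+1})}, $$

and a candidate is admitted when its integer index lies within
$[0, 9]$ TRs of the rounded reference. The admitted peak closest in
time to the reference (ties to the earlier peak) defines the delay.
Refinement at the window edges can move a peak slightly outside the
search range, which is exactly why refined delays are kept on the wider
interval $[-1, 10]$ and discarded (with a reason code) outside it.
`round()` is used for the admission window because it is the one
convention under which the keep range is precisely the search window
plus the maximal refinement overshoot of half a TR per side.

**5. Response model.** Each cell is one observation of a logistic
regression predicting the behavioural response, coded `response_no = 1`
for "no" — so a positive trend means the correlation predicts more "no"
answers. Negative-probe cells are excluded (too few errors to carry
information). The term set contains `probe`, `condition`,
`probe:condition`, and every correlation-bearing term up to the
four-way `correlation:ROI:(pair of phase/probe/condition)`
interactions; `phase` and `ROI` main effects and their correlation-free
interactions are excluded a priori, since responses cannot depend on
those labels by design. All factors use a fixed alphabetical level
order and sum-to-zero contrasts, without which type-III tests are not
meaningful. Type-III tables are likelihood-ratio tests computed by
refitting without each term's model-matrix columns. Backward reduction
deletes, at each step, the term whose removal most lowers the AIC, and
stops when that term is itself significant at $p < 0.05$ — or when no
deletion lowers the AIC at all, an edge the stopping rule must also
cover. Marginal correlation trends are estimated per factor
combination with equal weights over omitted factor levels
(estimated-marginal-means semantics, via emmeans), back-transformed to
the probability scale by the delta method at the mean correlation, and
contrasted with a Sidak family correction
$p_{\mathrm{adj}} = 1 - (1-p)^m$ over all contrasts of one call.
Cells enter unweighted by default; `weight_by_events = TRUE` weights
them by their event counts (neither convention is clearly preferable a
priori, so both are provided).

## The synthetic-data generator

The generator reproduces the task design the package models as its
test bed: 60 memory sets of 1,800 ms, each
followed after a 1,000 ms gap by a mask and, 2,000–16,000 ms later, by
a 2,000 ms probe — 25 positive, 25 lure, 10 negative — inside a run of
709 volumes at TR = 1,800 ms with 90 regions. Choices the design left
open, fixed once here:

* **Mask-to-probe delays** are drawn from an exponential distribution
  truncated to 2,000–16,000 ms whose rate is solved numerically so the
  mean equals the design's 6,097 ms. A right-skewed family is the
  natural choice because that mean sits far below the 9,000 ms midpoint
  of the range.
* **Mask duration** is not printed in the design; 500 ms.
* **Inter-trial intervals** after each probe are solved to fill the run
  exactly (uniform jitter in $[0.5, 1.5]\times$ the mean, rescaled),
  with 10 s lead-in and 20 s tail. A draw that does not fit is redrawn.
* **Responses** are sampled from per-probe accuracy and reaction-time
  profiles matching the behavioural pattern of the task (hit rate 0.82,
  lure correct rejections 0.74, negative correct rejections 0.98).
* **BOLD forward model**: region $r$'s signal is
  $\sum_i A_{r,c(i)}\, u_{c(i)}(t - \mathrm{shift}_{r,c(i)}\cdot
  \mathrm{TR})$ over trials $i$ of class $c$ (phase × probe), where
  $u_c$ is the boxcar–HRF convolution normalised so one isolated event
  peaks at 1 — so amplitude is single-event peak height in BOLD units.
  Noise is AR(1) with coefficient 0.3 and stationary SD 0.5 (peak SNR 2
  at unit amplitude), plus a slow sinusoidal drift; the nuisance table
  carries six scripted motion series, the global mean, white-matter and
  CSF proxies, and the drift.

What the generator does *not* emulate: spatial structure (voxels,
smoothing, registration), physiological noise spectra, habituation or
attentional drift of the response amplitude, and between-subject
variability of the HRF. Green tests therefore certify the estimators
and their calibration on data that match the model's assumptions; they
cannot certify robustness to the ways real BOLD violates them.

### A degeneracy worth knowing about

Global (mean) signal regression is standard for this kind of
preprocessing, and `condition_series()` applies it by default. In the simulation, however,
every region shares the *same* response kernel, so the global mean *is*
the stimulus-locked signal and regressing it removes the effect being
recovered by construction. The recovery test harnesses therefore
condition without the global-mean column (simply by omitting it from
the nuisance table); with real data, where regional responses differ,
the default stands.

## Numerical choices

* Convolutions run at the 1 ms indicator resolution via FFT,
  zero-padded to a 2-3-5-smooth length.
* The band-pass (0.01–0.1 Hz) is an ideal rectangular mask on the
  discrete frequency grid, including removal of the DC bin, applied
  after linear detrending and OLS nuisance regression (the conventional
  order: detrend, regress, filter); collinear
  nuisance columns are dropped with a warning via pivoted QR.
* Ties in the closest-peak rule go to the earlier peak; collinear
  triples refine to $\delta = 0$.
* The factorial fit uses `stats::glm`; type-III refits drop
  model-matrix columns and call `glm.fit` directly, which keeps the
  634-parameter full model (17 terms with 90 regions) tractable.

## What the tests established about the delay estimator

Noise-free recovery of a known regional response shift is exact for
shifts of 0–5 TRs (unit tests). Under the generator's default noise
(SNR 2) and the pipeline band-pass, the acceptance-level recovery
experiment — one phase silenced per run so each stimulus series is
compared only with responses of its own phase — recovers every shift
$d \ge 1$ TR within 0.5 TR per region, but shows a positive bias of
roughly two-thirds of a TR at $d = 0$, which that test reports and
currently fails on. Two mechanisms, separable by construction: the
rectangular low-pass smooths the asymmetric response and moves its peak
right by about a quarter TR; and the forward-only candidate window
censors noise-jittered BOLD peaks that land just before the reference,
clipping the left half of the error distribution exactly at zero lag.
Both are properties of the estimator's definition — delay
distributions obtained with it should be read with that zero-lag bias
in mind — and with both phases active the overlap of set and probe
responses under the band-pass adds a further upward distortion at small
shifts. The package reproduces the estimator faithfully rather than
correcting it; `anchor = "onset"` is available for sensitivity
analyses.

## Problem sizes

The test suite runs the full 60-trial, 709-volume, 90-region design
wherever the quantity under test depends on it (event counts, type-III
degrees of freedom, delay recovery), and a 12-trial, 120-volume,
4-region variant of the same generator for unit-level properties.
Coefficient recovery uses 50,400 simulated cells; interval coverage and
null calibration use 200 replicates at reduced size, with binomial
3-sigma acceptance bands fixed in advance.

## A short worked example

```{r example, eval = FALSE}
sch <- generate_schedule(design_spec(), seed = 1, session = "morning")
truth <- sim_truth(n_rois = 90, amplitude = rep(c(1.2, 0.6, 0), 30))
sim <- generate_bold(sch, truth, seed = 2)

cond <- condition_series(sim$bold, nuisance = sim$nuisance)
cells <- coactivation_cells(sch, cond)

series <- build_stimulus_series(sch, "retrieval")
events <- detect_source_events(series, sch)
delays <- compute_delays(series, cond, events)
autoplot(delay_histogram(delays, group_keys = "roi"))
```

Model fitting needs cells from at least two sessions (conditions); see
`run_pipeline()` for the orchestrated multi-run flow whose artifacts
are plain TSV files with a config echo and structured log.

## Known limitations

* One observation per cell discards within-cell event-count
  information unless `weight_by_events` is set.
* No subject-level random effects: like the emulated analysis, the
  model treats cells from the same subject as independent.
* The zero-lag delay bias described above.
* ROI extraction supports integer-label atlases only (no probabilistic
  parcellations).
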