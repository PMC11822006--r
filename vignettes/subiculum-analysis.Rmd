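---
title: "Methods: deep-subiculum neuron analysis with subitools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-subiculum neuron analysis with subitools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`subitools` implements the quantitative machinery used to characterize a
functionally specialized excitatory neuron class in the deep subiculum
(small "ovoid" somata elongated along the alveus, Ly6g6e expression,
selective projections to the anterior thalamic nuclei, and selective
responses to novel objects) against the background population of subiculum
pyramidal neurons. This vignette documents the models, the parameters that
matter, the synthetic-data generators used for validation, and the
numerical choices made where a published description leaves the design
open.

## 1. Calcium-imaging session statistics

### Trace normalization

Input traces are the denoised output `C` of a CNMF-style source-extraction
pipeline, at a miniscope-like sampling rate (20 samples/s by default).
`zscore_traces()` normalizes each cell over the full session using the
population standard deviation (denominator `n`), so a trace `0,2,0,2` maps
exactly to `-1,1,-1,1`. `global_dff()` computes `(C - F)/F` with `F`
either a user-supplied per-cell baseline (the manual route used with real
recordings) or a low percentile of the trace (default: 10th), and
`local_dff_response()` measures bout-locked responses with `F` taken as
the mean trace over the 10 s before bout onset and the response as the
average fractional change over the following 20 s.

### Peri-event responses and responder classification

`peri_event_deltaz()` aligns z-scored traces to interaction-bout onsets,
subtracts each cell-event's 10-s pre-onset mean, and averages in 2-s bins;
the pre-window subtraction runs at sample resolution, so the pre-window
bins average exactly to zero.

`classify_responders()` flags a cell as a responder for an object class if
its baseline-subtracted activity stays at or above a minimum delta-Z of
0.25 *contiguously* for at least 10 s somewhere in the post-onset
evaluation window. Both boundaries are inclusive: exactly 0.25 held for
exactly 10 s qualifies. Published descriptions of this criterion do not
state whether the duration must be contiguous, nor the evaluation-window
length; we require contiguity (the natural reading of "for a minimum of
10 s") and default the window to 30 s, both exposed as parameters. The
duration test runs on sample-resolution traces, never on the 2-s bins.

### The duration-free peak-percentile statistic

For each cell, the peak delta-Z in the 20 s after each novel-object
encounter is converted to a percentile relative to a per-cell null of peak
delta-Z values over sliding windows spanning the whole session (stride
1 s). Trial windows are *not* excluded from the null; this is conservative
(observed peaks compete against themselves) and is configurable. Pooled
trial percentiles of two populations are compared with a Mann-Whitney
rank-sum test (`compare_peak_percentiles()`). Under stationary noise the
pooled percentiles are uniform on [0, 100]; the test suite checks this
with a KS test on 1000 simulated trials, and checks the rank-sum level
using populations of 30 cells with one trial each — one trial per cell
keeps the pooled samples independent, so the nominal 5% level is exact.

## 2. Tuning statistics with circular-shift nulls

Spatial information uses the plug-in estimator on the joint histogram of
binned position X and the binarized deconvolved spike signal K:

I_pos = sum_i sum_k P(x_i,k) log2( P(x_i,k) / (P(x_i) P(k)) ),

with the 0 log 0 = 0 convention, unvisited bins excluded, and base-2 logs
(bits; the log base is unstated in published descriptions, so we document
bits). The arena is binned on a default 10 x 10 grid over its bounding
square — bin size is likewise a documented default, not a published value.
`mutual_information_from_joint()` exposes the estimator so it can be
checked against an independent double-loop implementation; the suite does
so on random joint tables at 1e-12 tolerance.

Significance uses a circular-shift null: the signal is rotated relative to
behavior by 500 offsets drawn uniformly with a minimum lag of 10 s, the
statistic is recomputed per shuffle, and a place cell must exceed 95% of
its shuffled scores (strict inequality; ties fail). Speed tuning (Pearson
correlation of trace with instantaneous speed) and mobility tuning
((mean_mobile - mean_immobile)/mean_immobile, with mobility defined as
speed strictly above 1 cm/s) use the same machinery with a two-sided
criterion: significant when outside the central 95% of the null. Published
text reads "shifting calcium activity by 10 s" but also refers to a
distribution of shuffled scores; we interpret the null as many circular
shifts of at least 10 s, matching the spatial-information null, and treat
the single-fixed-shift reading as a rejected alternative.

Calibration is tested, not assumed: 1000 untuned synthetic cells yield a
flagged fraction inside the 99% binomial interval around the nominal 5%,
and 100 planted place cells are recovered at 95% or better.

## 3. Behavior

Interaction bouts are inputs (scored annotations); `parse_interactions()`
validates them (positive durations, known classes, no overlap within an
object). The discrimination index is DI = (T_novel - T_familiar) /
(T_novel + T_familiar) over summed bout durations; in object-location
sessions the moved-location bouts take the novel role. Speed is the norm
of central-difference displacement over time (one-sided at the ends),
optionally smoothed with a 0.5-s boxcar — smoothing is a documented
default, unstated in published methods.

## 4. FISH morphometrics

Probe channels are binarized at the intensity-histogram tail: the
threshold is the smallest intensity for which the fraction of pixels
strictly above is at most the tail fraction. Published practice uses
0.2-1%; we default to the midpoint 0.5% with per-channel override. Nuclei
are segmented from DAPI (Gaussian blur, Otsu threshold, connected
components) and dilated by 3 um into cell ROIs, with contested pixels
assigned to the nearest nucleus. PAC (percent area covered) is 100 x the
covered fraction of ROI pixels. Excitatory neurons require Slc17a7 PAC of
at least 0.3 (inclusive) and Gad1 PAC of exactly 0. The phenotype index
(Ly6g6e - Cck)/(Ly6g6e + Cck) partitions cells at 0; an index of exactly 0
is left unassigned rather than forced into a class, and cells with zero
PAC in both channels are excluded.

Shape features are measured with the alveus rotated to horizontal: width
is the extent along the alveus, height perpendicular to it, and the alveus
aspect ratio is height/width (so a soma elongated *along* the alveus has
ratio < 1). Area uses the shoelace formula, circularity is
4 pi area / perimeter^2, and Feret diameters come from rotating calipers
on the convex hull while the perimeter uses the original polygon. PCA is
performed on centred, unit-variance features with a deterministic sign
convention.

## 5. Axon-projection profiles

Region-by-neuron axon-length tables (mm; atlas parcellation itself is out
of scope — the tables are inputs) are normalized to unit length. "Unit
length" is read as sum-normalization (length fractions summing to 1); an
L2 option is provided because the published phrase is ambiguous.
Clustering is agglomerative with Ward linkage on Euclidean distances
between the *normalized profiles*, cut at two clusters; the seeded 2-D
UMAP embedding (20 neighbours) is for visualization only and never feeds
the clustering, reflecting the separation of "dimensionality reduction and
clustering analysis". Regions shown in summaries keep an across-neuron
mean of at least 1 mm.

## 6. Compartmental biophysics

Morphologies are SWC trees; structure type 5 marks radial-oblique
dendrites (a documented extension; a sidecar id list is also accepted).
Cables are split into compartments of at most 5 um, and densities are
evaluated at the compartment-midpoint path distance from the soma
(`xdist`): leak 0.003125 mS/cm2 within 100 um and 0.00625 mS/cm2 beyond
(path distance, consistent with the xdist convention); A-type potassium
0.00495 S/cm2 within 50 um (strict boundary) and 0.00495 (1 + 0.01 xdist)
S/cm2 beyond, with obliques overridden to 0.0198 S/cm2; sodium 0.09 S/cm2
at the soma, 0.027 S/cm2 elsewhere; delayed-rectifier potassium 0.04 S/cm2
and T-type calcium 0.03125 mS/cm2 uniform. Specific capacitance
(1 uF/cm2) and axial resistivity (150 Ohm cm) are standard values exposed
in the configuration, as they are not part of the printed density set. The
leak reversal is adjustable per cell within [-46, -35] mV to match a
target resting potential (bisection, 0.5 mV tolerance, clipped with a
warning outside the interval).

Passive input resistance is a sparse steady-state solve on the compartment
tree (5-pA somatic step); current steps integrate with backward Euler, and
gating kinetics are plug-ins (`hh_channel()`): exact published gating
equations are cited to prior hippocampal models rather than printed, so
quantitative claims are restricted to passive properties and structural
directions, and `default_channels()` ships illustrative kinetics only.
Verification is against closed forms: an isopotential sphere matches
1/(gA) to 0.1%, a sealed-end cylinder matches R_inf coth(L/lambda) to 1%
at 5-um compartments, the transient steady state matches the linear solve
to 1%, steady-state current is conserved to 0.1%, and pruning obliques
strictly increases input resistance — the direction observed when
comparing ovoid-like (oblique-free) with pyramidal morphologies.
`trace_metrics()` mirrors slice electrophysiology: input resistance from
the steady-state response to a -40 to -50 pA step, sag ratio
(V_ss - V_peak)/(V_peak - V_baseline) from a -100 pA step, rheobase as the
smallest spiking step, and the spike-count input-output curve (0-mV upward
crossings, 2-ms refractory).

## 7. What the synthetic data emulate — and what they do not

The generators produce 5-minute sessions at 20 samples/s in a 60-cm
circular arena with two objects, matching the novel-object-recognition
design. The behavior track is an Ornstein-Uhlenbeck velocity walk with
wall reflection and a two-state move/rest process (mean bouts 20 s / 5 s),
so both mobility states occur; scripted-dwell mode plants exact per-object
interaction times for testing bout scoring. Bout emission uses a 3-cm
interaction radius, 0.5-s minimum dwell and 1-s closing gap — published
studies scored interactions manually, so this rule is a stand-in for
synthesis, not a claim about manual scoring.

Traces are built from planted effects plus calcium-kernel-filtered
Gaussian noise (single-exponential kernel, tau = 1.5 s, unit stationary
SD). The filtering matters: denoised traces carry smooth residuals, and a
contiguous-duration criterion like the responder rule is degenerate
against white sample noise (any 10-s run would be broken with probability
approaching 1 regardless of amplitude). Object responders default to a
sustained 15-s plateau of 3 noise-SD amplitude at novel-bout onsets —
a strong response, as observed for ovoid cells — place cells emit Poisson
events from a Gaussian rate field (peak 8 Hz, SD 5 cm) convolved with the
calcium kernel, speed cells scale with instantaneous speed, and untuned
cells are constant-rate events plus noise. Per-entity random substreams
make every output bit-reproducible and insensitive to adding cells.

The generators do not model optics or photon noise, motion artefacts,
source-extraction crosstalk, spike-inference errors (the binarized `S` is
exact by construction), or non-exponential indicator dynamics. Passing the
suite therefore validates the *statistics* under their stated assumptions;
it does not certify performance on raw imaging data.

Problem sizes used in the validation suite are chosen to make Monte-Carlo
error small relative to the tested bands: 1000 cells for false-positive
calibration, 100 planted cells for recovery, 1000 replicates for the
rank-sum level, 500-offset nulls throughout (the published shuffle count).

## 8. Known limitations

* Active-channel kinetics are illustrative; firing patterns (Fig.-style
  spike trains) are not quantitatively reproduced, by design.
* The histogram-tail binarization assumes every probe channel contains
  genuine signal; a channel that is pure background puts the tail
  threshold inside the noise (the synthetic image therefore plants enough
  Gad1-positive interneurons that the Gad1 tail sits in real signal).
* `filter_excitatory()` reads "0 PAC of Gad1" literally as exactly zero;
  sub-pixel bleed-through tolerance, if needed, must be set explicitly.
* Spatial-information bin size, speed smoothing, the responder evaluation
  window, and percentile-null exclusion are defaults exposed as
  parameters, since no published value fixes them.
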