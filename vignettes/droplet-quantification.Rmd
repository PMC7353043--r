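---
title: "Quantifying droplet-forming PKA biosensor responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying droplet-forming PKA biosensor responses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparkdrop)
```

## The measurement problem

Phase-separating PKA activity biosensors report kinase activation as bright
fluorescent droplets: the evenly distributed sensor condenses into puncta
when phosphorylated, and the droplets disassemble slowly once phosphatases
win out. In a heterogeneous cell population only part of the cells can
activate the cAMP/PKA axis at all, and different Gs-coupled hormones
activate overlapping subsets of those cells with different dynamics —
strong transient bursts or long, weak sustained activation. The quantity of
interest is the *responder share*: the fraction of analysable cells that
form droplets after a stimulus, summarised as mean ± SE across replicate
fields, together with the overlap structure of responder sets under
sequential stimulation and the per-clone shares in single-cell-derived
clones.

`sparkdrop` implements this measurement as a tested pipeline and, because
raw microscopy movies of such experiments are generally not deposited,
pairs it with a synthetic-data generator that emulates the study design
closely enough for the whole pipeline to be validated end to end against
known ground truth.

## The population model

A simulated field is a roster of `n_cells` non-overlapping discs (radius 15
px by default) with log-normal biosensor expression `E_i`
(`meanlog = log(100)`, `sdlog = 0.5`, arbitrary fluorescence units).
Subset structure is deterministic: exactly `round(n * frac)` cells
(round-half-up) belong to each subset, drawn as prefixes of one seeded
permutation. This makes the ground-truth share exact at roster level, so
any deviation measured downstream is attributable to imaging and detection,
not to sampling of the roster itself. The subsets are:

* the *capable* set (default fraction 0.482) — cells possessing adenylyl
  cyclase, able to respond to receptor agonists and to forskolin;
* the *PKA-responsive* set (default 0.95, a superset of the capable set
  whenever its fraction is larger) — cells responding to a direct,
  cyclase-independent PKA activator;
* per-hormone responder sets. In the default *nested* mode these are
  prefixes of the capable ordering, largest hormone first, so every
  hormone set is contained in the capable set and smaller sets are
  contained in larger ones — the structure in which a second hormone
  activates (almost) only cells the first already activated. An
  `nested_epsilon` parameter can divert a small fraction of a later
  hormone's set to fresh capable cells; it defaults to 0 because the
  reported "small addition" of new responders was not quantified.
  The *independent* mode draws each set independently from the capable
  pool instead.

The default hormone panel carries the five reported agonists with their
responder fractions (adenosine 0.370, noradrenaline 0.347, dopamine 0.252,
serotonin 0.166, histamine 0.042), transient archetypes for the first
three and sustained for serotonin and histamine.

## Latent kinetics

Per cell and stimulus, PKA activity follows the archetype law: transient
`A(e^{-t/τ_d} - e^{-t/τ_r})` (τ_r = 0.5 min, τ_d = 5 min), sustained
`A(1 - e^{-t/τ_s})` (τ_s = 3 min). Droplet mass integrates

$$\frac{dD}{dt} = k_{on}\max(a - \theta, 0) - k_{off} D$$

by forward Euler (dt = 0.1 min), clipped at zero; a wash zeroes activity
but leaves D to decay, and a dissolving response (the signature of
Gi-coupled signalling) contributes no activity and adds a fast `k_diss` =
0.5/min disassembly from its stimulus on.

Three defaults deserve justification, because they interact:

* `k_off = log(2)/10` (10-min droplet half-life). Two published
  observations pull in opposite directions: transitory responses visibly
  decay within roughly a quarter of an hour, while droplets partially
  remain half an hour after washing out the hormone. A half-life of 30+
  minutes satisfies the second but makes the first impossible — the trace
  of a transient burst would still sit at ~80% of peak 15 minutes later.
  At a 10-minute half-life about 12% of droplet mass remains 30 minutes
  after a wash ("partially remains") and transient decay is clearly
  observable. The half-life is a free parameter; the persistence property
  itself is tested with an explicit slow `k_off` where it holds in closed
  form.
* `k_on = 2.5` mass units per activity-minute. A typical transient burst
  then peaks around 4–5 puncta per cell. Much larger values crowd the
  finite cell footprint: puncta merge, the detected area saturates and no
  longer tracks latent mass, and very crowded blobs grow wider than the
  rolling ball and are swallowed into the background estimate.
* `sustained_amp_factor = 0.2`. Because droplet mass *integrates*
  activity, a sustained drive accumulates steady-state mass
  `k_on(fA-θ)/k_off`, which at f = 0.25 equals or exceeds a transient
  peak — the observed amplitudes would tie, contradicting the
  long-but-weak phenomenology. At f = 0.2 the observed amplitude ratio is
  ~0.6 while ~90% of sustained responders stay above the nucleation
  threshold θ = 0.1 and remain detectable.

## Rendering

Cells render as uniform discs of `background + E_i × photon_scale` counts;
droplets as `N ~ Poisson(D/μ)` puncta (μ = 1 mass unit per punctum) at
fixed seeded positions inside the disc, appearing and disappearing in
seniority order so patterns are temporally coherent. Each punctum is a
flat disc of `droplet_unit_area` = 6 px² convolved with a Gaussian PSF
(σ = 1.5 px), with peak brightness `E_i × droplet_intensity_gain` — droplet
visibility scales with expression, which is what makes an expression gate
necessary. Gaussian read noise (SD 3 counts) is added per pixel and frames
are clipped to 16 bits. A 512×512 field holds the default 60 cells;
250-cell fields (the scale used for share-recovery studies) use 1024×1024,
standing in for tiled large-image acquisition.

The Poisson redraw has one statistical consequence worth stating plainly:
near a smooth mass peak, adjacent frames differ by a couple of percent
while the per-frame area CV is `1/sqrt(N)` ≈ 20–50%, so the *argmax* of a
rendered trace is a broad random variable. Tests therefore assert that the
latent mass at the trace's smoothed argmax is ≥ 90% of the latent peak,
not frame-exact argmax agreement, and archetype classification is designed
around level comparisons rather than peak positions.

## Quantification

*Background subtraction.* The rolling-ball estimate is the grayscale
morphological opening with a flat disc; the subtraction keeps structures
narrower than the disc (puncta) and removes wider ones (cell bodies,
shading). The default radius of 8 px sits between the punctum footprint
(~3 px) and the cell radius (15 px); a ball *larger* than the cell would
fail to reconstruct the cell body and leave it in the foreground. The
implementation is verified pixel-exactly against a brute-force min/max
sliding window.

*Segmentation and gating.* Cells are segmented on the mean pre-stimulus
frame with a robust global threshold (`median + 5 × MAD`), hole filling
and a minimum area of 200 px². The per-cell baseline brightness `B_c`
(mean raw intensity in the mask) is the expression proxy; only cells with
`B_c` above the expression gate (default 140 counts = background + the
expression level at which droplets sink into the noise under default
optics) are analysed. Gating is monotone in the threshold.

*Droplet detection.* Within each gated cell, droplet pixels on the
subtracted frame are those above `median + 6 × MAD`; the median is
per-frame (making the cutoff invariant to constant offsets) while the MAD
is estimated once per cell on the droplet-free first frame — a per-frame
MAD would inflate up to eight-fold once droplets cover part of the cell
and make detected area anti-correlate with droplet mass. Detection is
restricted to the cell core (mask eroded by 2 px) because the opening
cannot perfectly reconstruct the jagged digital rim of a cell, which would
otherwise shed false droplets; 8-connected components of at least 4 px²
become droplets. On pure noise this yields fewer than one false droplet
per 100 cells.

*The three statistics.* (1) droplet/cell intensity ratio on the raw frame
— when used in traces, droplet pixels are defined by the simple
`mean + 2 SD` raw threshold of the original biosensor literature, which
gives the statistic its nonzero resting baseline; (2) within-cell
intensity SD of the raw frame; (3) total droplet area on the subtracted
frame. Strategy 3 has an exactly zero resting baseline and hence the
highest contrast (fold-change over t0 is computed with a +1 px² floor to
make it finite); the package reproduces this ordering over simulated
responding cells, which is why area is the default calling statistic.

## Response calling

The baseline window (5 min) is re-anchored immediately before *each*
stimulus — droplets persist, so after a first stimulus only a further rise
counts. A responder must exceed baseline + `max(8 px², 5 × baseline SD)`
for 3 consecutive frames. A dissolving call requires pre-existing signal
and a *rapid* fractional loss (below 0.35 × baseline within 8 min): with a
10-minute half-life every persisting cell passively decays past any
noise-scaled margin eventually, so a pure level criterion would call every
second-stimulus window "dissolving".

Archetype classification compares levels, not peak positions: the peak
time is the end of the 90%-of-maximum plateau of the 3-frame-smoothed
trace, the peak level is the plateau mean, and the response is transient
when the smoothed trace has fallen below half-amplitude by `t_trans` = 18
min after the peak (probed as a 3-min average, clipped to the observation
window). Measured accuracy on single simulated cells is ~80% for
transient and ~100% for sustained calls; misclassification reflects
genuine trace ambiguity under punctum-count noise, and the population
share — the primary quantity — does not depend on the archetype split.

Shares are computed per replicate field as `100 × responders / gated`
(dissolving calls are responders but not droplet-*forming*, so they are
excluded from the numerator), then summarised across fields as mean ± SE.
Sequential overlap reports, per stimulus, the responders, the *new*
responders and the cumulative union share; clone summaries treat each
clone as a replicate.

## The transcriptomic census

`zero_expression_census` counts cells with zero counts across an entire
gene set — presence/absence, not a low-count threshold, matching how such
filters are applied in count-matrix browsers. Default gene sets are the
ten adenylyl cyclase isoform genes in human (`ADCY1`–`ADCY10`) or mouse
(`Adcy1`–`Adcy10`) symbol dialect, with an optional case-insensitive mode
bridging the two. Percentages are rounded half-up to one decimal, the
format in which such shares are reported. The census is verified against
a dense brute-force loop, is invariant under row/column permutation and
round-trips through the MatrixMarket triplet layout. The paired simulator
plants an exact round-half-up number of all-zero cells, so published
counts (e.g. 5756 of 9429 → 61.0%) are reproduced exactly by
construction plus arithmetic.

## Problem sizes and what the tests show

Share-recovery studies use 4 replicate fields of 250 cells (1024×1024 px,
41 frames at 1-min intervals), the clone study 7 clones of 36–44 cells;
at these sizes a full study runs in a few minutes on one CPU. Across
them the pipeline recovers ground-truth shares within ~1 percentage
point: the residual biases are dim cells near the expression gate,
weak-amplitude sustained responders near the nucleation threshold, and
(sub-1%) false positives.

What passing tests do *not* show: the generator renders stationary discs
with isotropic Gaussian puncta, no photobleaching, focus drift, cell
migration, division, or shape change, and no receptor pharmacology
(hormone concentrations are metadata). Real movies violate all of these;
the pipeline's segmentation-from-baseline design (masks are reused across
frames) in particular assumes negligible cell movement over ~40 minutes.
The synthetic validation demonstrates the correctness of the computation,
not the adequacy of these assumptions for any particular microscope.

## Numerical choices and degenerate inputs

Round-half-up is used wherever a fraction of cells becomes a count, for
determinism across platforms. The Euler step (0.1 min) changes end-of-movie
mass by <1% when halved; steps above `tau_rise/2` are rejected. A uniform
cell produces zero droplets (strictly-greater cutoff); an all-zero trace
cannot be normalised to its maximum or to t0 without an explicit floor;
replicates or clones without gated cells are excluded with a warning
rather than contributing NaN shares. All simulation entry points take
explicit integer seeds and restore the caller's RNG state.
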