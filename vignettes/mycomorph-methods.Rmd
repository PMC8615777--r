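---
title: "Methods: pellet morphometrics in mono- and coculture bioreactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pellet morphometrics in mono- and coculture bioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Filamentous microorganisms in submerged stirred-tank culture occur in two
morphological fractions: compact, roughly spherical *fully evolved
pellets* with a fringed rim of protruding hyphae, and a dispersed fraction
of *hyphal fragments and loose clumps*.  The package quantifies both with
three per-object descriptors computed from 2-D silhouettes in calibrated
phase-contrast images:

* projected area $A$ (µm²) — pixel count × scale²;
* elongation $E = d_{max}/d_{min}$ — ratio of maximum to minimum Feret
  (caliper) diameter, computed by rotating calipers on the convex hull of
  boundary pixel centres, with a one-pixel extent correction so a
  rasterised disk of diameter $d$ reports $d$;
* morphology number $Mo = 2\sqrt{\pi A}/(P\,E) = \sqrt{C}/E$, with
  circularity $C = 4\pi A/P^2$; $Mo$ is 1 for a smooth disk and tends to 0
  for elongated hyphae, so it compresses "compactness per unit
  elongation" into one number.

The identity $Mo = \sqrt{C}/E$ holds for every emitted row to machine
precision and is asserted in the tests.

**Perimeter.** $P$ uses a 4-direction Crofton estimate,
$P \approx \tfrac{\pi}{8}\left(N_0 + N_{90} + (N_{45}+N_{135})/\sqrt2\right)$,
where $N_\theta$ counts foreground/background transitions along each line
family.  Naive pixel-edge counting overestimates the perimeter of a disk
by up to ~27 %, which would push $C$ down by ~40 % and expel compact
pellets from their expected $Mo$ band; the Crofton estimator is accurate
to ~0.3 % on disks of radius 100 px.

**Elongation definition.** Commercial image-analysis suites differ in
whether elongation is a Feret-diameter ratio or an ellipse-fit axis ratio;
the Feret ratio was chosen because it reproduces the known anchors
(disk → 1, square → $\sqrt2$, thin rod → length/width) without a model
fit, and because the generator's axis-ratio parameter then equals the
expected measured elongation of a smooth elliptical pellet exactly.

## Segmentation

The front end mirrors semiautomatic phase-contrast practice: a square
median filter (default radius 2 px) smooths object edges; the Sobel
gradient magnitude is computed for boundary QC and is available as an
alternative threshold channel; binarisation is Otsu's threshold on the
median-filtered intensity (objects darker than background) by default.
Hole filling, a *physical* minimum-object-area filter (default 500 µm²,
converted to pixels via the scale, so the same speck is removed at any
calibration), optional exclusion of border-touching objects (their area is
censored), and 8-connected component labelling in raster order complete
the stage.

Two numerical choices deserve a note:

* **Otsu contrast guard.** Otsu's criterion always splits a histogram,
  even of pure noise; a blank frame would otherwise flood with spurious
  foreground.  Automatic thresholding therefore only accepts the split if
  the class means differ by at least `otsu_guard_sd` (default 4)
  background-class standard deviations; otherwise the image yields zero
  objects with a warning.  The guard is disabled for fixed thresholds,
  which express an explicit operator decision.
* **Connectivity.** Components are 8-connected (a diagonal pixel chain is
  one object) and labelled by first-pixel position in a column-major scan,
  making label numbers reproducible run to run.

The human-in-the-loop part of the workflow is declarative:
`apply_overrides()` replays an edit table (delete / merge / split /
species-tag) in file order and emits an audit log, so "the operator" is a
reviewable artefact rather than an interactive session.

## Fractionation and species attribution

An object is a fully evolved pellet iff $Mo \ge 0.35$ **and** $E \le 1.9$
**and** $A \ge 10^4$ µm² (all inclusive); everything else is
hyphae/clumps.  These limits are operator-settable per experiment
(`filter_config()`); the defaults are reconstructions from the typical
descriptor bands of the two fractions (pellets $Mo$ 0.36–0.77 and $E$ up
to ~1.9; dispersed objects $Mo$ 0.1–0.35, $E$ 1.75–3.25), not recovered
instrument settings — the published workflows this emulates do not report
their numeric filter limits.

In monocultures every object carries the vessel's organism.  In
cocultures, pellets are attributed by size: at or above
`species_area_threshold_um2` (default 10⁶ µm²) the pellet is assigned to
the large-pellet-forming fungal partner (species A), below it to the
actinomycete partner (species B), reflecting the order-of-magnitude size
separation between the two species' pellets.  Because the species size
ranges can overlap late in a culture, calls within ±20 % of the threshold
are flagged `review` while still receiving the rule-based call — the
pipeline never silently resolves the overlap.  Coculture hyphae/clumps
remain `undetermined` unless an operator override names the species;
operator calls always win and are marked in the provenance column.  The
pellet area floor is a single scalar rather than per-species because the
fraction call precedes species attribution; per-experiment configuration
covers the cases where the two species would warrant different floors.

## Population statistics

Statistics are computed on per-object values pooled per (experiment,
culture, time, species, fraction) stratum — not on per-image means.  Each
stratum reports the mean of $A$, $E$, $Mo$ with the Student-t confidence
half-width $t_{1-\alpha/2,\,n-1}\, s/\sqrt n$ (sample SD, default
$\alpha = 0.05$).  Strata with fewer than `min_n` = 30 objects are still
emitted but flagged `below_min_n` and excluded from outcome evidence,
implementing the "at least 30 objects per mean" reliability rule.

Coculture-vs-monoculture comparisons use a hand-computed two-sided
unequal-variance t-test with Welch–Satterthwaite degrees of freedom;
`stats::t.test()` serves as an independent cross-check in the test suite
(agreement to 10⁻¹⁰), never as the implementation.  Welch is the default
because mono- and coculture strata routinely differ in variance; a
pooled-variance mode is available by flag.  P-values are reported raw,
tiered at 0.05 / 0.01 / 0.001, with no multiple-testing correction —
per-timepoint raw p-values are the convention this output reproduces.  A
log-scale option for area comparisons exists conceptually in the design
space but was deliberately not added: the reference workflow compares raw
means, and switching scales would change what the confidence bands
describe.

Degenerate comparisons are explicit records, not errors: an empty stratum
on either side yields an `"absent"` record (pellet-disappearance
evidence), a small stratum a `"below_min_n"` record, and two zero-variance
samples fall back to exact comparison (p = 1 if the means agree, p = 0
otherwise) with a warning.

## The outcome rule

Over a mono-/coculture time course the package distinguishes:

* **morphological domination** — the loser's pellet stratum is absent from
  the coculture at *every* evaluated timepoint while present in the
  loser's own monoculture (in more than half of those timepoints);
* **morphological advantage** — the loser's coculture pellets persist but
  their projected area is significantly smaller than in its monoculture
  (p < α with coculture mean below monoculture mean) in a *strict
  majority* of the usable window timepoints;
* **none** otherwise, or with a conflict flag if both species qualify at
  the same level.

Three quantifiers here are package decisions where the underlying notion
is qualitative: (1) the *strict majority* count makes "significantly
smaller at most timepoints" testable; (2) the evaluation window drops a
24 h settling period after the second organism's introduction, because
preculture-formed pellets of the later species can persist briefly before
being destroyed; (3) domination globally outranks advantage — a species
can dominate (destroy the competitor's pellets) even though its own
pellets are smaller than in its monoculture, so advantage is only
evaluated when no species is dominated.  A pellet stratum present with
fewer than `min_n` objects counts as *present but unquantified*: presence
for the domination logic (conservative — a few surviving pellets block a
domination call), unusable for the advantage test.

As an independent corroboration, `profile_similarity()` compares the
bioreactor's dissolved-oxygen controller logs (air flowrate, 1.5–5.5
L min⁻¹; stirring speed, 220–300 min⁻¹): both profiles are linearly
interpolated onto a common grid over the overlapping time range and the
per-channel Pearson correlations are averaged.  Pearson is scale-free
(invariant to affine rescaling of a channel), matching the visual
"the coculture's aeration course looks like monoculture X" argument this
indicator formalises; constant channels are skipped with a warning, and
`dominant_from_profiles()` declares a tie when the two scores are within
0.05.

## The synthetic-data generator

The generator is the test substrate for the whole pipeline, emulating the
statistical structure the analysis assumes rather than optical physics:

* **pellet** — filled disk of core radius $\sqrt{A/\pi}$, made elliptical
  (area-preserving) at the generative axis ratio, with a radial
  sinusoidal hair fringe: depth = `fringe_depth_frac` × core radius
  (default 0.10), lobe count = `fringe_density` × 64 (default 0.4 → 26
  lobes).  These defaults put measured pellet $Mo$ near 0.6–0.77 at the
  default elongation band, inside the compact-pellet band and safely
  above the 0.35 classification floor;
* **clump** — a chained union of 3–8 jittered, fringed sub-ellipses
  spread along a major axis (axis ratio ~2–3), guaranteed connected;
  measured $Mo$ ≈ 0.2–0.4, $E$ ≈ 2–3;
* **hypha** — constant-thickness tube (thickness 8–15 µm, length 150–400
  µm by default) stamped along a smooth two-harmonic curve whose heading
  swings by ±`tortuosity` radians (default 1.6); the skeleton is trimmed
  by one cap radius at both ends so the rendered extent equals the
  nominal length, and disks are stamped around fractional centres so the
  mean tube width converges to the nominal thickness.

Scenes are rendered as dark bodies (default grey 0.25) on a bright
background (0.80) with a one-pixel bright halo rim (phase-contrast
signature) and additive Gaussian noise (SD 0.04); rendering is
bit-identical given the scene seed.  Placement rejects overlapping
bounding circles, so ground truth is unambiguous; deliberate overlaps are
flagged in the truth table.  The default calibration is 2 µm/px on
2048×2048 frames; scenes holding millimetre-scale pellets use a coarser
per-scene calibration (the time-course generator picks the finest scale
from {2, 4, …, 64} µm/px that packs the population), and the scale is
per-scene metadata, never a global constant.  Per-scene and per-record
seeds derive from the master seed by fixed multipliers on the scene and
record indices, kept below 2³¹.

Scenario templates (`coculture_scenario()`) encode the three coculture
initiation strategies of the emulated experiment design — simultaneous
preculture inoculation, delayed introduction of the actinomycete, and
spore-vs-spore start — with stratum mean areas taken from the published
time-course values where printed (e.g. fungal monoculture pellets rising
from 1.2×10⁶ to 1.3×10⁷ µm² by 24 h; coculture pellets an order of
magnitude smaller; actinomycete pellets ~10⁵ µm² and equal across
vessels; dispersed fraction fluctuating at 10⁵ µm²) and set to
field-plausible values where not (e.g. the fungal monoculture pellet
trajectory in the spores template, for which no areas are printed).
Areas are log-normal with CV 0.3 per stratum; in the simultaneous
template the actinomycete's mono- and coculture means are set identical
from 48 h on, reflecting "practically the same" published behaviour while
keeping the advantage logic's false-positive rate at its nominal α.
`sample_scenario_truth()` draws classified-equivalent object tables
directly (bypassing rasterisation) for statistics/outcome testing;
`generate_timecourse()` renders full scenes with manifest and truth
tables.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: optical point-spread and defocus, uneven
illumination, 3-D pellet structure projected to 2-D, touching/overlapping
objects that need declumping, biomass growth kinetics (scenario means are
prescribed, not simulated), and real within-image correlation of object
shapes.  Results on real micrographs will depend on illumination
correction and declumping that are explicit non-goals here.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: single scenes of 35 objects
on 2048² frames for the band checks; 30 single-pellet 1024² frames at
8 µm/px for the millimetre-pellet area recovery; 36 objects per stratum
and 8–9 timepoints for scenario-level outcome calls; 2 000 null and 500
alternative simulations (n = 30 per group) for the Welch calibration
checks.  These sizes were chosen as the smallest that keep the sampling
error of each checked quantity well below its assertion band (e.g. a CV
0.3 population of 30 pellets has a 5.5 % standard error on the mean area,
against a 10 % recovery band).  Rasterisation accuracy floors used in
assertions: 1 % on disk area and Crofton perimeter (r ≥ 50 px), 3 % on
rod area, 2–7 % on cross-calibration consistency of A/E/Mo; the
$C, Mo \le 1$ bound is asserted with an ε = 0.05 allowance rather than
clamped, so any estimator bias stays visible.

## Known limitations

* Species attribution in cocultures is a size rule plus operator
  overrides; no learned classifier, no tracking of pellets across
  timepoints.
* No watershed declumping: touching pellets merge unless an operator
  split is provided.
* The hyphae/clumps fraction in cocultures is species-undetermined by
  design, so its statistics pool both organisms.
* Elongation of strongly curled hyphae reflects the chord geometry of the
  curve, not contour length over width; very tortuous filaments can
  report moderate $E$ despite great length.
* The outcome rule needs at least two usable window timepoints and one
  coculture with both monoculture controls; partial designs raise
  explicit errors rather than guessing.
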