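---
title: "Methods: magnitude cues, the nine-neuron model, and the simulated test battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnitude cues, the nine-neuron model, and the simulated test battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(magbee)
```

This vignette is the package's account of its science: what the stimulus
generator emulates, how the continuous cues are measured, how the
magnitude network learns and is tested, and which choices were genuinely
open when the package was designed. Nothing here states an empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. What the package models

Numerosity discrimination experiments present two displays differing in
element count and reward one side. Because physical displays cannot vary
count while clamping *every* continuous magnitude — total area, total
edge length, convex hull, spatial-frequency content — a subject can solve
the task from a single continuous cue. `magbee` builds the whole loop in
software: generate displays with the confound structure of real stimulus
sets, measure the cues, feed one cue (spatial frequency) into a minimal
neural circuit, train it like an animal, and run the standard test
battery on a population of such model subjects.

The point of the exercise is a *sufficiency* argument: if this circuit,
which never receives a count, reproduces the behavioural signatures
(learning, transfer to novel shapes and counts, ordering the empty
display below all others, following cues against numerosity), then those
signatures cannot by themselves establish numerical processing.

## 2. The stimulus generator

A display is a 120 × 120 binary raster (20 px/cm for a 6 × 6 cm card)
holding 0–6 black elements of one shape: axis-aligned squares, diamonds
(squares rotated 45°), or discs. The core constraint is **constant total
ink**: the default 1024 px² (~7% cover) is partitioned among the
elements, so count carries no information through area. Each display's
black-pixel total stays within ±2% of the target; element placement is
rejection sampling with a 2-px display margin and a 2-px inter-element
gap, so the number of connected components always equals the element
count.

**Element-size heterogeneity.** Element areas within a display are a
floored Dirichlet partition of the total (`size_lambda = 1`,
`size_alpha = 0.4`, each element at least 25% of the equal share).
Printed stimulus sets in this literature use visibly variable element
sizes, and that variability is what keeps cue–count correlations high
but imperfect. With equal-sized elements, total edge length would be a
deterministic, strictly increasing function of count (Spearman rho
exactly 1.0), which no measured stimulus set shows. The concentration
was fixed once, during generator design, so that the edge-length–count
rank correlation of a generated set matches the published covariation of
the reference stimulus set (rho ≈ 0.93); it is not adjusted per
experiment.

**Cue-biased displays.** Two constructions manipulate cues at fixed
count and fixed area: `cue_bias = "high"` uses elongated (3:1) elements
forced far apart — more boundary, larger hull, more fine structure;
`cue_bias = "low"` uses compact elements, a strongly skewed size
partition (one dominant element minimises total boundary at fixed area)
and tight clustering. Pairs are *verified by measurement*: the generator
redraws until the high member strictly exceeds the low member on edge
length, hull and spatial-frequency power (for single-element pairs the
hull comparison is relaxed to a tolerance tie, since any lone convex
element's hull equals its own area). The same machinery opposes cues to
numerosity: a high-cue 2-element display that measurably beats a
low-cue 3-element display on all three cues.

What the generator does **not** emulate: grey levels, printing and
lighting artifacts, the physical apparatus, or the exact bitmaps of any
published stimulus set. Tests that pass on these synthetic sets show
that the *analysis pipeline* behaves correctly under the stated
statistical structure; they do not certify performance on photographs of
real cards.

## 3. Cue measurement

* **Area** — black-pixel count.
* **Edge length** — length of the marching-squares contour, with
  straight steps counting 1 px and diagonal corner cuts 0.65 px. The
  naive √2/2 chord weight overestimates digitized discs and oblique
  edges by ~8%; 0.65 is the usual estimator correction that keeps
  squares, 45° edges and discs within a few percent of their true
  perimeters. Disjoint elements are exactly additive.
* **Convex hull** — the number of pixel centers inside the convex hull
  of the black pixels. Counting pixels (rather than polygon area) keeps
  the hull on the same units as area, makes `hull >= area` exact, and
  recovers a convex element's own area.
* **Spatial-frequency power** — 2-D FFT, squared amplitudes, averaged
  over orientation in 1-cycle/image annuli up to Nyquist; the scalar cue
  is the trapezoidal area under this curve over the *alternation band*.
  Two low-frequency exclusions are deliberate. The DC bin carries only
  total area. Less obviously, the first few non-DC bins carry the
  display-wide layout envelope, and — because total spectral power is
  conserved at fixed ink (Parseval) — a curve integrated from bin 1
  *falls* with element count: few-element displays concentrate their
  conserved power at low frequency where annuli are small. The measured
  quantity everyone means by "spatial frequency" — the amount of
  dark/light alternation, which rises with count — lives above the
  fundamental of the coarsest possible element, `width / sqrt(ink)`
  cycles/image (bin 4 at the default geometry). The band bound is
  derived from geometry, not fitted.

The Parseval identity (total power = image energy) is asserted in the
tests as the correctness oracle for the spectrum code.

## 4. From images to the model's input axis

The network reads a single scalar `s`. A training set is measured once,
and the mean spatial-frequency power per element count is mapped to the
count value by least squares, constrained through the origin so that the
empty display — zero power in every non-DC bin — maps to exactly
`s = 0`. The constrained fit is therefore proportional,
`s = beta * sf_power`.

Because sf power grows sub-linearly with count at constant area, this
one-parameter map is mildly concave in count: on generator output the
1-element mean lands near `s ≈ 1.9` and the 6-element mean near
`s ≈ 5`, rather than exactly on the integers. We keep the constrained
form (the zero anchor is scientifically non-negotiable — the empty
display must score zero on a magnitude axis) and note two consequences:
top-of-range pairs (5 vs 6) are genuinely hard for the model, and the
zero-to-one gap is wider than an identity mapping would give, making
zero-versus-one discriminations comparatively easy. Both show up in the
battery statistics.

## 5. The nine-neuron model

Seven sensory neurons with Gaussian tuning (preferred values 0–6, width
σ = 2.5, baseline 50 and peak amplitude 200 spikes/s, additive Gaussian
rate noise), one logistic decision neuron (A₀ = 100 spikes/s, a = 0.05,
b = 50), one reinforcement signal gating the online gradient rule on the
seven weights. Parameters the source architecture leaves open, fixed
here as package defaults:

| parameter | default | units | why |
|---|---|---|---|
| `sigma_N` | 10 | spikes/s | single-trial discrimination of adjacent counts imperfect but learnable |
| `eta` | 1e-3 | — | monotone ascent at small steps; criterion reached well inside 500 trials |
| `W⁰` | U[0, 0.01] per weight | — | near-zero start keeps the readout off the logistic's saturated tails |
| `max_trials` | 500 | choices | guard for non-converging bees (flagged, kept) |

Training mirrors the behavioural protocol: each trial draws a fresh
exemplar pair, the choice is correct when the noisy decision response to
the rewarded display exceeds the other, the update reuses the same noisy
tuning draws as the forward pass (online, biologically consistent;
noise-free gradients remain available for the oracle tests), and
training stops at ≥80% correct over the last 10 choices after at least
20 (or at `max_trials`). With the defaults the criterion floor usually
binds: model bees reach criterion at the 20-choice minimum, i.e. the
circuit learns faster than real bees — population heterogeneity at test
time then comes from initial weights, residual rate noise, and each
bee's particular test exemplars.

Numerical notes: the logistic and its derivative are computed via
`plogis` (no overflow); in the saturated tails the decision response
reaches `A0` to machine precision, so strict-bound checks and
finite-difference oracles are run in the responsive regime; the
analytic-vs-numeric gradient identity is enforced at 1e-5 relative over
100 random states.

## 6. The simulated test battery

One experiment = one stimulus library (seeded), one frozen s-calibration
(training shapes, counts ≥ 1), and `n_bees` (default 50) independently
seeded model bees per rule (`more_than`, `less_than`). Training uses two
shapes (squares, diamonds); tests use the held-out shape (circles).
Every test presents one exemplar pair per bee for 100 noisy repeats; the
per-bee score is the fraction of repeats choosing the display the
trained rule designates as correct (for cue-biased tests, the display
the learned cue preference predicts). The mean decision difference is
recorded alongside.

The element counts of the published batteries are not restated in the
source, so the package fixes them a priori, ordered by the difficulty
pattern of the reported statistics:

* **novel_shape** (train 1–4): learning 1 v 4, conflict 0 v 3, transfer
  2 v 5;
* **outside_range** (train 1–4): learning 4 v 5, conflict 0 v 1
  (the hardest zero pairing — zero against anything farther is easier),
  transfer 5 v 6;
* **novel_pairs_zero** (train on pairs from 0–6 with 1 v 4 held out):
  learning 1 v 4, conflict 0 v 3;
* **zero_continuum** (train 1–4): 0 v n for n = 1…6, plus a
  Kruskal–Wallis test across the six distances;
* **incongruent** (train 1–4): equal-count cue-biased pair, cues opposed
  to numerosity (2-high v 3-low), and an unbiased equal-count control.

Statistics: Wilcoxon signed-rank of per-bee choice fractions minus 0.5,
normal approximation with zero-dropping, tie-corrected variance,
continuity correction on, z signed by direction, two-sided p. Heavy ties
(many bees at fraction 1.0) legitimately push |z| above the no-ties
n = 50 maximum of ≈ 6.15 — the tie correction shrinks the null variance —
which is why pooled two-rule tests can report z near 10. Summaries are
emitted per rule and pooled. A run in which fewer than 80% of bees reach
criterion is flagged invalid; populations of fewer than 10 bees report
their statistics as not computable rather than pretending the normal
approximation holds.

Two sampling-design notes. First, each bee's test uses its own exemplar
pair: this mirrors animals being tested on particular printed cards and
is the main source of between-bee score variance. Second, a Wilcoxon z
computed from 50 such bees has a sampling standard deviation near 1 when
the underlying effect is moderate; repeated runs with different master
seeds scatter the moderate z values by about that much, while the
saturated tests (all bees correct) are stable.

## 7. Problem sizes and determinism

Default experiment scale: 30 exemplars per count × shape cell, 50 bees
per rule, ≤ 500 training trials per bee, 100 test repeats per pair —
about one to two minutes per battery on one CPU. The covariation
analyses use 30 displays per count (counts 1–6, mixed shapes). Every
stimulus, weight initialization, training stream and test repeat derives
from one master seed through `withr::local_seed`, so a configuration
reproduces bit-for-bit.

## 8. Known limitations

* The model is single-axis by design: it cannot weigh multiple cues, and
  nothing here addresses which cue a real animal uses.
* The s-calibration inherits the concavity of the spatial-frequency cue
  (section 4); consequences at both ends of the axis are visible in the
  battery.
* The convex-hull covariation of generated sets is placement-dependent
  and typically stronger than in printed stimulus sets, whose hulls were
  constrained by card layout conventions; it is reported but not used as
  a model input.
* Real-bee choice data are not bundled and their mixed-effects analyses
  are out of scope; the package's claims are about the synthetic
  pipeline and the model, not about any individual animal dataset.
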