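---
title: "Quantifying stereotypical checking and two-epoch IEG ensemble overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stereotypical checking and two-epoch IEG ensemble overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkfish)
```

## The system and the two readouts

Repeated dosing of rats with the D2/D3 agonist quinpirole (QNP), combined
with daily exposure to an object-enriched open field, induces two robust
phenotypes: **locomotor sensitization** (path length grows with each
injection day) and **stereotypical checking** — an idiosyncratic, stable
pattern of repeated visits to a small set of arena locations, the leading
animal model of compulsive checking in OCD. The molecular readout is
**catFISH**: because intronic *Arc* probes and 3'UTR *Homer1a* probes detect
nascent transcription with different delays, a single brain collected after
two 5-min arena sessions separated by ~20 min reports, in one tissue
section, which neurons were active in each session — *Homer1a* foci (green)
mark the first session A1, *Arc* foci (orange/red) the second session A2.
This package implements the analysis chain for both readouts plus seeded
generators that emulate the study design (two arms, 10 daily 50-min
exposures, day-11 A1/A2 sessions, a 2×2 treatment × environment design with
home-cage controls).

## Behavior: zones, visits, ranking

The arena model is a 95 × 95 cm square; the six checking zones are two
10 cm discs at the object positions and four 15 cm quarter-discs anchored
at the corner vertices (radii from the empirical calibration of the assay
against human scoring). Zones are validated pairwise disjoint at
construction, so zone membership of a head sample is unique.

**Visit rule.** The calibrated radii are published but the confirmation
criterion — what distinguishes engaging with an object or corner from a
brief transit through its zone — is not. We operationalize it
deterministically: an episode opens at an
outside→inside transition of the head point, closes when the head exceeds
`radius + hysteresis` (default 2 cm — boundary dithering does not split a
visit), and counts as a visit when its duration reaches `min_dwell`
(default 0.5 s). All three parameters are explicit arguments. Timing is
sample-based; at the assay's 25 Hz that quantization is ≤ 40 ms per edge.
An episode still open when the recording ends counts if it already lasted
`min_dwell`. The implementation is vectorized; a per-frame state-machine
oracle re-implements the same rule as a plain loop, and equality of the two
over hundreds of seeded trajectories is part of the test suite.

**A–F ranking.** Visits are summed over days 1–10 per animal and zone, and
zones are relabeled A (most visited) to F (least). Ties — possible in
short sessions — break by the fixed enumeration order corner_NW, corner_NE,
corner_SW, corner_SE, object_1, object_2; the source assay is silent here,
so the rule is simply documented and deterministic. Ranking lets animals
with different idiosyncratic preferences be pooled ("zone A" always means
*this animal's* top location). Day-10 vs day-11 comparisons standardize
counts to visits per 5 min (day-10 counts divided by the 10:1 duration
ratio).

## The behavior generator

No kinematic description of checking (bout rates, dwell times, speeds) is
published, so the generator's movement model is the simplest one that can
express both phenotypes: a **bout-based correlated walk** — each bout is a
goal-directed segment (straight line plus lateral Brownian-bridge noise
whose amplitude scales with step length) followed by an exponential dwell at
the goal.

* **Idiosyncrasy**: each QNP animal gets one preferred corner and one
  preferred object, a deterministic function of (seed, animal index), so
  per-animal stability across days holds by construction.
* **Checking loop**: a fraction `home_zone_attraction` (default 0.7) of QNP
  bouts target the preferred pair. Within the pair the loop is anchored at
  the corner: from the object the animal always returns to the corner; from
  the corner it re-checks the corner (a brief wall-hugging excursion out of
  the zone and back) with probability `corner_recheck` (default 0.4),
  otherwise proceeds to the object. The stationary split is 62.5% corner /
  37.5% object, reproducing the observed structure in which the top-ranked
  zone is a corner and the second is the object. A symmetric alternation
  would make the two zones equally visited and could not show rank-A
  dominance.
* **Sensitization**: on day *d* the QNP arm's speed is multiplied and its
  dwells divided by `sensitization_factor^(d−1)` (default 1.15) — the whole
  checking cycle accelerates — which makes the expected session path length
  exactly geometric in *d*, giving a closed-form oracle
  (day-10/day-1 ≈ 1.15⁹ ≈ 3.52). Controls move at constant speed with a
  mild wall bias and no persistent preference.
* **Bounds**: per-frame steps are clamped to `max_speed` (default
  150 cm/s) and positions projected into the arena; both operations are
  1-Lipschitz, so neither re-breaks the other.

Defaults (25 Hz, 3000 s sessions, 15 + 14 animals, 10 days + A1/A2) match
the study design. Where the tests replicate across many simulated cohorts
they lower the frame rate to 5 Hz — time resolution does not affect bout or
zone structure — and the planted-effect module tests use shorter sessions;
the acceptance-level dominance check runs one QNP cohort at full scale.

What the generator does *not* emulate: real rats' thigmotaxis gradients,
grooming pauses, body-size-dependent zone occupancy, tracking noise and
dropped frames. Passing tests therefore show the *analysis chain* is
correct and recovers planted structure, not that the generator is a
substitute for real video.

## The catFISH chain

Per nucleus the chain consumes: z-centroid (fraction of stack depth), size,
elongation, counterstain brightness, and one focus intensity per channel
(from labeled stacks: the mean of the top 1% brightest in-mask voxels,
capturing bright intranuclear foci). Segmentation itself is out of scope —
masks or feature tables are inputs.

* **Mid-Z selection** keeps nuclei with z-centroid in
  `[0.5 − b/2, 0.5 + b/2)`, default `b = 0.2`, avoiding truncated nuclei at
  section edges that read falsely negative. The interval is half-open so
  boundary behavior is deterministic; for a 21-slice stack the retained
  0-based slices are 8–12 (centre fractions 8.5/21 … 12.5/21).
* **Thresholds** per slide × region × channel equal the *minimum* intensity
  over the flagged weakest-positive exemplars of arena-exploring animals
  (home-cage animals are excluded: their expression is too low to provide
  reliable weak positives). Since the exemplars are by definition the
  weakest accepted positives, the minimum is the natural statistic; with
  it, every true positive in the group sits
  at or above threshold by construction, and specificity then rests on the
  positive/negative intensity separation. Thresholds are never imputed
  across regions; a missing group is an error naming it.
* **Glia exclusion** is the explicit conjunction: size below the slide's
  `size_quantile_cut` (default 0.25) *and* (elongation > 1.6 *or*
  counterstain brightness > 125) *and* both channels sub-threshold. The
  source description is qualitative ("smaller, prolonged, bright, no IEG
  signal"); the conjunctive/disjunctive structure and all cut values are
  explicit arguments with these logged defaults. A supra-threshold nucleus
  is never discarded as glia.
* **Classification**: intensity ≥ threshold is positive (boundary counts
  positive, documented); the two booleans give
  negative / homer_pos / arc_pos / double_pos, with Homer1a ↦ A1 and
  Arc ↦ A2 fixed by the probes' detection kinetics.

The nuclei generator plants latent (A1, A2) activity per nucleus from the
joint law implied by the two marginals and a target similarity (inverted in
closed form; infeasible combinations fail loudly), draws intensities from
clipped normals (defaults 30 ± 3 positive vs 8 ± 3 negative, times a small
per-slide × channel log-normal staining gain), gives a `glia_fraction` of
records glia-like features, and flags the k = 3 weakest true actives per
slide × region × channel of exploring animals as exemplars (the number of
manual picks per slide is not published; 3 is our default). Exploring-arm
CA1 marginals default to the published group percentages (29.4/30.6%
control, 11.2/20.7% QNP); cortical regions get plausible defaults (strong
exploration effect in OFC, weak in ACC/mPFC, 3% home-cage baseline). With
the default ≥ 7-SD separation the chain recovers latent classes at > 99%
agreement; note that the min-over-exemplars threshold needs this kind of
separation — at ~4 SD the minimum of hundreds of positives dips far enough
into the negative distribution to cost specificity, which is why the
threshold statistic is also configurable in principle (a low quantile) for
noisier material.

## Similarity score and statistics

With marginals `p1 = p_homer_only + p_double`, `p2 = p_arc_only + p_double`:

\[ s = \frac{p_{double} - p_1 p_2}{\min(p_1, p_2) - p_1 p_2} \]

This is the standard normalization of the founding catFISH methodology —
independence → 0, maximal overlap given marginals → 1, negative values mean
fewer doubles than chance. When a marginal is 0 or 1 the denominator
vanishes and the score is returned as flagged-undefined, never 0; undefined
scores are excluded listwise from the score ANOVAs with counts reported
(how such animals are best handled is not standardized in the field;
listwise exclusion is our choice).

Group statistics use factorial ANOVA with the design's factor structure in
base R, in place of proprietary general-mixed-model software: `aov()` with an `Error(animal)`
stratum — between-subject factors treatment × environment, repeated
measures on session, each brain region analyzed separately. Sequential sums
of squares give exact F tests under the null; the suite verifies type-I
error 0.05 ± 0.02 over 1,000 null replicates of the 9/9/6/5 design and
agreement with a permutation oracle on a small balanced design. Exact
replication of proprietary covariance-structure options is out of scope.
Degenerate inputs (zero within-cell variance) yield flagged infinite F with
a warning; constant responses yield F = 0, p = 1.

## Numerical and design choices, in brief

| Choice | Value | Why |
|---|---|---|
| visit `min_dwell` | 0.5 s | separates interaction from passing at assay speeds; configurable |
| exit hysteresis | 2 cm | boundary dithering does not split visits |
| rank tie-break | fixed zone order | determinism; source silent |
| mid-Z band | half-open `[0.4, 0.6)` | deterministic boundaries |
| threshold statistic | min over exemplars | exemplars are the weakest accepted positives |
| positivity | intensity ≥ threshold | boundary counts positive |
| joint activity law | `p11 = p1 p2 + s (min(p1,p2) − p1 p2)` | closed-form inversion of the score |
| RNG | one master seed, per-animal sub-streams | reproducibility, logged in the manifest |

Problem sizes in the tests are the package's own choices: full-scale single
cohorts where a study-scale claim is checked (15 QNP animals, 50-min
sessions, 25 Hz; 1,000 nuclei per region over the 9/9/6/5 design), reduced
frame rates or session lengths where a property is replicated across many
seeds, and ~10,000 scored nuclei (50,000 simulated, mid-Z keeps ~20%) for
overlap recovery to ±0.05.

## Known limitations

* The generators' parameter defaults for kinematics and intensity
  distributions are invented — no quantitative description of checking
  kinematics or staining distributions is available; only the design
  structure and the CA1 marginals are anchored to published values.
* Visit detection assumes cleaned, in-arena head coordinates; no tracking
  artifact handling.
* Real-data use of the catFISH chain requires upstream segmentation; the
  stack feature extractor consumes masks it is given.
* The similarity ANOVA pools nuclei per animal before scoring (per-slide
  averaging is not implemented); whether the source pooled per slide or per
  animal is unstated.
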