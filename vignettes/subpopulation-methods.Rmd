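---
title: "Motile sperm subpopulations from CASA kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motile sperm subpopulations from CASA kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

casaclust classifies motile spermatozoa into kinematic subpopulations from
computer-assisted sperm analysis (CASA) descriptors, follows how those
subpopulations redistribute during in vitro capacitation, and relates their
proportions to imaging-cytometry endpoints (mitochondrial activity,
viability, regional protein tyrosine phosphorylation). Because the
experimental datasets this kind of study rests on are rarely redistributable,
the package ships a fully parameterized synthetic-data generator with known
ground truth; every statistical component is validated by parameter recovery
against that generator and by brute-force oracles. This vignette documents
the models, the defaults and why they are what they are, the numerical
conventions, and the limits of what the validation shows.

## The kinematic data model

A record is one motile spermatozoon's eight CASA descriptors: the velocities
VCL, VSL, VAP (µm/s), the ratio descriptors LIN = 100·VSL/VCL,
STR = 100·VSL/VAP, WOB = 100·VAP/VCL (%), the lateral head displacement ALH
(µm) and the beat-cross frequency BCF (Hz), plus its provenance (sample type
fresh / frozen-thawed, medium CAP / NC, incubation time, replicate). Loading
enforces hard invariants — non-negative velocities, ratios in [0, 100],
VSL ≤ VAP ≤ VCL, and the three ratio identities within a 2% relative
tolerance that absorbs CASA export rounding. Violating rows are dropped and
counted, never repaired: repairing would invent data. The incubation grid is
fixed (CAP: 1, 5, 15, 30, 60, 120, 180, 240 min; NC: 0, 15, 240 min) unless
explicitly overridden.

CASA vendors do not document their internal motility cutoff, so "motile" is
a package convention: VCL ≥ 10 µm/s (configurable, with an optional VAP
floor). At 10 µm/s a cell traverses roughly its own head length per frame
interval at 25 frames/s — below that, track-derived descriptors are mostly
segmentation noise.

## The two-step classification

The classification runs on four driver variables — VCL, LIN, ALH, BCF — one
representative per correlated block of the eight descriptors (velocities;
linearity ratios; head displacement; beat frequency). `variable_group_select()`
reproduces that choice data-dependently: variables are clustered on the
dissimilarity 1 − |r| (average linkage) and each group is represented by its
most centrally correlated member.

Driver variables are standardized to mean 0, sd 1 (sample sd, n − 1
denominator — so the column (1, 2, 3) maps exactly to (−1, 0, 1)), because
k-means on raw scales would be dominated by VCL's numeric range.

**Step 1 (compression).** k-means (Lloyd iterations, k-means++ seeding, best
of 20 restarts by within-cluster sum of squares, ties to the earliest
restart) partitions the standardized records into k₁ clusters, k₁ chosen by
the silhouette average width over a configurable range. Silhouette cost is
O(n²), so it is evaluated on a fixed seeded subsample of at most 2000
records; the same distance matrix is reused across the whole scan. Ties go
to the smallest k.

The scanned range defaults to 10..25. The floor matters: step 1 exists to
*over-partition* — to compress tens of thousands of records into a tractable
set of centroids for the hierarchical step. If the floor is placed at or
below the true subpopulation count, the silhouette criterion happily selects
that count (on mixture data its argmax sits at the true k), the dendrogram
then has almost nothing to agglomerate, and the second-step selection is
crippled. The floor is therefore max(final_k_range) + 2.

**Step 2 (agglomeration).** The k₁ centroids are merged hierarchically
(Ward's criterion on Euclidean distances in standardized space, via
`ward.D2`; average and complete linkage are available). The final count is
selected over 2..8 by two criteria:

* the **Hubert Γ coefficient** of each cut — the Pearson correlation, over
  unordered record pairs, between distance and the 0/1 "different cluster"
  indicator. Γ is evaluated at record level (on the seeded subsample, with
  partitions induced by the cut through each record's step-1 cluster) rather
  than on the bare centroid set: that weights each centroid by its cluster
  size and lets the final count equal k₁ when nothing should merge.
* the **L-method knee** of the merge-height-versus-count curve: two straight
  lines are fitted to the left (x ≤ c) and right (x > c) parts at every
  admissible breakpoint (each segment ≥ 2 points) and c minimizes the
  length-weighted total RMSE. Numeric ties — an exactly straight curve — go
  to the smallest c. A knee landing on the boundary of the admissible range
  is treated as *not identified* (the steep segment may extend past the
  range), a situation that arises when the true count is 2.

When the two candidates agree, done. When they disagree, the knee wins by
default and both are recorded. This reverses a plausible alternative
(Γ argmax wins) for an empirical reason visible in the package's own
validation: with mildly overlapping adjacent components, Γ's argmax sits
persistently one below the true count (it prefers to merge the two adjacent
"progressive" components, whose between-pair distances straddle the
within-cluster range), while the merge-height knee identifies the true count
robustly. The choice is configurable (`reconcile = "gamma"`).

Final clusters are relabeled canonically — SP1..SPk by ascending mean VCL of
their member records, ALH breaking ties — so labels are comparable across
independent runs; SP1 is always the slowest subpopulation and SPk the
fastest. On the reference profile this produces the familiar ordering: SP1
slow-progressive, SP2 medium-progressive, SP3 fast-progressive, SP4 fastest
and least linear with the highest ALH (hyperactivated-like phenotype).

**Stability ensemble.** The records are split uniformly at random into 10
subsamples and the full two-step fit is repeated 10 times, each excluding
one subsample; standardization is refitted within each run, so each run is a
self-contained analysis of its 9/10 of the data. Per-condition subpopulation
proportions are summarized as mean and sd across runs; the kinematic summary
reports per-SP means with the across-run standard error. Every run uses the
same base seed, so the ensemble is reproducible and two runs over identical
records yield identical fits. Conditions absent from a run are averaged over
the runs that contain them, with the run count reported.

## Cytometry gating

The gating module consumes per-event feature tables (mask-derived
morphometrics plus channel intensities); pixel-level segmentation is
upstream of the package. Gates use the printed bounds of the imaging
protocol verbatim, with their printed open/closed senses:

* sperm-compatible events: aspect ratio ≤ 0.40, area 50–400 µm² (both ends
  inclusive);
* mitochondrial activity: quadrants of MitoTracker (ch11) × YO-PRO-1 (ch2);
* viability: YO-PRO-1 × propidium iodide (ch4), three classes. The printed
  class definitions leave YO-PRO-1+/PI+ events unassigned; the package
  classes *any* PI-positive event as dead, so the classification partitions
  its input. This superset rule is a deliberate choice, flagged here.
* regional pY: exclude PI+ (live cells only), focus gate gradient RMS 65–78,
  single-cell gate area 25–300 µm² and aspect ratio < 0.4, then mask-quality
  gates — true head (head aspect ratio > 0.4, head length < 20 µm), true
  principal piece from true head (< 0.6, < 30 µm), true tail from true head
  (< 0.58, < 45 µm; the tail mask covers midpiece + principal piece), true
  midpiece from true head ∩ true principal piece (< 0.8, < 15 µm). Each
  region's mean fluorescence over its surviving set is divided by the same
  region's mean in the 0 min NC baseline sample. A sample normalized against
  itself returns exactly 1 in every region.

Stain positivity cutoffs are never printed in imaging-cytometry reports; the
default estimate splits each channel's bimodal log-intensity distribution by
1-D 2-means and takes the midpoint of the two centers. The gating *logic* is
the content here, not the cutoffs, which are always overridable. PI
exclusion is applied before the focus gate, following the order in which the
protocol lists them; channel compensation is out of scope (the generator
produces spectrally clean intensities).

## Time-course and correlation statistics

Endpoint dynamics are compared with a saturated one-way model per
(sample type, medium) — `value ~ 0 + factor(time)` — whose fitted values are
exactly the per-time means, with all-pairs Wald contrasts on the residual
variance and a compact-letter display (insert-and-absorb; two times share a
letter iff not significantly different at α = 0.05, verified in tests
against an exhaustive check of that relation). Pairwise p values are
unadjusted by default because all-pairs letter displays in this literature
are conventionally shown uncorrected; a Holm correction sits behind the
`adjust` argument. When the residual variance is numerically zero the
contrast degenerates to p = 1 for identical means and p = 0 otherwise.

Associations between subpopulation proportions and capacitation endpoints
use the Pearson coefficient over all (time × replicate) points pooled within
a sample type and medium — per-time correlations are deliberately out of
scope — with two-sided p from t = r√((n−2)/(1−r²)) and significance flagged
at α = 0.01. Zero-variance series yield a missing cell rather than a number.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not knobs.

**Kinematic mixture.** Four components with the canonical subpopulation mean
profile (`ram_subpopulation_means()`). Per record, VCL, LIN, ALH, BCF and
WOB are drawn from independent truncated normals (sd = cv · mean, velocities
truncated at 0, ratio descriptors within (0, 100)); VSL, VAP and STR are then
*derived* from the identities, so every generated record is exactly
self-consistent. LIN < WOB is enforced by redrawing the pair (STR must stay
below 100%). Published subpopulation tables report SEMs of run summaries,
not within-cluster spreads, so the within-component coefficient of variation
is unknowable from them; the default cv = 0.12 makes components overlap
mildly yet remain separable, and the recovery tests sweep 0.08–0.20. The
mean matrix itself is reproduced as printed even where its internal ratio
consistency is imperfect (the medium-velocity component's LIN is well below
100·VSL/VCL); the scenario constructor surfaces this as a warning rather
than an error precisely because derivation, not sampling, guarantees record
consistency.

**Mixture weights.** `default_weight_trajectories()` encodes the qualitative
capacitation dynamics as configuration data: fresh CAP — SP1 declining
monotonically, SP4 rising late with its maximum at 240 min; frozen-thawed
CAP — SP4 surging to a 15 min maximum and declining, SP1 dipping to 15 min
and recovering, SP3 flat to 60 min then declining; NC — SP1 dominant, SP4
scarce. The exact numbers are the package's invention shaped by those verbal
constraints and are validated only against them.

**Linked time-courses.** Observed proportions are multinomial counts of 200
spermatozoa (a realistic per-evaluation count) over the latent weights.
Each endpoint is a + b·w + ε where w is the latent weight of the *driver*
subpopulation — the one with the largest |ρ| in the endpoint's target row —
b carries the sign of ρ, and sd(ε) = |b|·σ_w·√(1/ρ²−1)
(`calibrate_noise()`, verified against a Monte-Carlo oracle). A single
endpoint series can be linked to only one driver; the correlations of the
other subpopulations emerge through the geometry of the weight trajectories.
For the frozen-thawed mitochondrial endpoint the driver is SP1 (ρ = −0.99);
because the SP1 and SP4 trajectories are nearly mirror images
(r ≈ −0.98 across the CAP design), the SP4–mitochondria correlation emerges
at ≈ 0.93–0.95, close to its 0.91 target. Under NC, endpoints are unlinked
noise, matching the absence of significant NC correlations. Endpoint levels
(mitochondrial activity around 0.45 ± 0.12, normalized pY around 1.6 ± 0.45)
are plausible magnitudes, not estimates.

**Cytometry events.** Tables of 10,000 events: single in-gate sperm plus
20% debris (off the aspect/area gate), 5% out-of-focus (gradient RMS outside
65–78) and 5% doublets (area above the single-cell window), with log-normal
stain intensities around well-separated negative/positive modes (50 and
1000 a.u., sdlog 0.35) at configured class fractions, mask morphometrics
with a 10% failed-segmentation fraction, and regional pY fluorescence scaled
relative to the 0 min NC baseline by condition-specific factors that follow
the observed dynamics (early flagellar peak in frozen-thawed CAP, late in
fresh CAP, flat in NC and in the head). Ground truth — event class, stain
class, segmentation status — travels with every event.

## Numerical conventions and degenerate inputs

* Sample-sd standardization; zero-variance driver columns are an error
  naming the column.
* k-means ties on inertia keep the earliest restart; empty clusters trigger
  re-seeding and, if persistent, a k reduction with a warning.
* Silhouette: singleton clusters contribute width 0; a single cluster is an
  error.
* Hubert Γ: undefined (error) when all pairs share a cluster or all
  distances are equal; in the final-k scan an undefined value at one
  candidate is skipped rather than fatal.
* L-method: requires ≥ 4 points; exact ties go to the smallest breakpoint;
  boundary knees are treated as unidentified.
* Merge heights from Ward agglomeration are non-decreasing; two coincident
  centroids merge at height 0, which is valid.
* Proportions sum to 1 within 1e-9 in every run and condition; assignments
  cover every motile record exactly once.
* All randomness flows from explicit integer seeds; every pipeline stage is
  bit-reproducible given (data, config, seed).

## Problem sizes used in validation

The full-scale recovery runs use the complete frozen-thawed design (8 CAP +
3 NC conditions × 2000 spermatozoa = 22,000 records) per seed, ten seeds,
with the default configuration — about a minute per seed on one core. Unit
and property tests use 120–300 records per condition with narrowed scan
ranges, which the recovery results show is already comfortably inside the
method's operating regime; correlation recovery uses the exact study design
(3 replicates × 8 times, 20 seeds).

## What passing tests do and do not show

The generator draws independent truncated normals within components: real
CASA clouds are skewed, within-cell correlated (fast cells tend to be
high-ALH), and contaminated by tracking artifacts; real cytometry channels
spill into each other and drift. Passing recovery tests therefore shows the
*pipeline* is correct and well-calibrated under the stated mixture model —
it does not certify that four subpopulations exist in any particular
ejaculate, nor that the default cutoffs suit a particular instrument.
Fuzzy/probabilistic clustering, morphometric subpopulations, mixed-effects
models of ram/ejaculate structure, pixel-level mask computation and
fluorescence compensation are explicitly out of scope.
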