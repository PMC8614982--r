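# casaclust

Motile sperm subpopulation analysis from CASA kinematics and imaging
cytometry, for reproductive biologists studying in vitro capacitation in
fresh and frozen-thawed semen.

Computer-assisted sperm analysis (CASA) measures, per motile spermatozoon,
the velocities VCL, VSL, VAP (µm/s), the ratio descriptors
LIN = 100·VSL/VCL, STR = 100·VSL/VAP, WOB = 100·VAP/VCL (%), the lateral
head displacement ALH (µm) and the beat-cross frequency BCF (Hz). A sample
is not one motility phenotype but a mixture: slow-progressive cells,
medium-progressive cells, fast-progressive cells, and fast, non-linear,
high-ALH cells with hyperactivated-like movement. casaclust implements the
two-step classification that identifies these subpopulations and the
statistics that track them through capacitation:

1. **Two-step clustering.** Driver variables (VCL, LIN, ALH, BCF — one
   representative per correlated block, selectable by a variable-group
   analysis) are standardized to mean 0, sd 1; k-means (Lloyd, k-means++
   seeding, best of 20 restarts) over-partitions the records into k₁
   clusters with k₁ chosen by the silhouette average width
   s̄ = mean((b−a)/max(a,b)); the k₁ centroids are merged by Ward's
   criterion, and the final subpopulation count is selected by the Hubert Γ
   coefficient (correlation between pairwise distance and cluster
   separation) together with the L-method knee of the merge-height curve.
   Final clusters are labeled SP1..SPk by ascending VCL.
2. **Subsample stability.** The whole analysis is repeated 10 times, each
   run excluding one random tenth of the data; per-condition subpopulation
   proportions and per-SP kinematics are reported as mean ± across-run
   variation.
3. **Imaging-cytometry gating.** Sperm/debris gating on aspect ratio and
   area, quadrant classification of mitochondrial activity
   (MitoTracker × YO-PRO-1) and viability (YO-PRO-1 × PI), and a masked
   region pipeline that quantifies tyrosine phosphorylation (pY) in the
   head, midpiece, principal piece and tail of live, in-focus, correctly
   segmented single spermatozoa, normalized to a 0 min non-capacitating
   baseline.
4. **Time-course statistics.** Saturated per-time models with all-pairs
   contrasts and compact-letter displays, and pooled Pearson correlations
   (all times × replicates within sample type and medium) between
   subpopulation proportions and capacitation endpoints, flagged at
   p < 0.01.
5. **Synthetic-data generator.** Every input above can be generated with
   known ground truth — a four-component kinematic mixture with the
   canonical subpopulation profile, condition-dependent mixture weights
   encoding the capacitation dynamics, latently linked time-courses with
   calibrated correlation targets, and 10,000-event cytometry tables — so
   the entire pipeline is validated by parameter recovery.

See `vignettes/subpopulation-methods.Rmd` for the models, defaults and
numerical conventions.

## Worked example

```r
library(casaclust)

scn <- synthetic_scenario()                     # study-condition defaults
g   <- generate_kinematics(scn, sample_types = "frozen_thawed", seed = 1)
ds  <- filter_motile(g$dataset)                 # VCL >= 10 um/s
m   <- fit_subpopulations(ds, clustering_config(), seed = 1)
m
```

```
<subpopulation_model> n = 22000 | step-1 k = 10 | final k = 4
       VCL   VSL    VAP   LIN   STR   WOB  ALH  BCF
SP1  26.39 14.74  19.48 55.85 76.46 73.80 1.23 2.56
SP2  76.08 33.47  56.63 44.00 59.97 74.42 2.03 5.72
SP3 162.20 85.43 137.95 52.68 62.63 85.04 2.91 7.27
SP4 183.53 54.19 159.45 29.53 34.35 86.88 5.39 7.84
```

Four subpopulations are recovered from the 22,000 generated spermatozoa
(8 capacitating + 3 non-capacitating conditions × 2000 cells). SP1 is the
slow-progressive class (VCL ≈ 26 µm/s, LIN ≈ 56%), SP4 the fastest and
least linear with the highest head displacement (VCL ≈ 184 µm/s,
LIN ≈ 30%, ALH ≈ 5.4 µm) — the hyperactivated-like phenotype. The driver
variables VCL, LIN, ALH and BCF sit within a fraction of a percent of the
generator's component means; VSL/VAP/STR are derived quantities and track
the component identities.

The linked time-course reproduces the capacitation correlation structure:

```r
tc <- generate_linked_timecourse(scn, sample_types = "frozen_thawed", seed = 1)
correlation_table(tc, "frozen_thawed",
                  sp_endpoints = c("sp1_prop", "sp4_prop"),
                  marker_endpoints = "mito_activity")[, c("SP", "r", "p", "significant")]
```

```
        SP          r            p significant
1 sp1_prop -0.9810181 3.638561e-17        TRUE
2 sp4_prop  0.9689010 7.852586e-15        TRUE
```

The proportion of spermatozoa with active mitochondria falls as the
slow subpopulation re-expands (r ≈ −0.98) and rises with the
hyperactivated-like subpopulation (r ≈ +0.97) across the frozen-thawed
capacitating time-course.

## The analysis workflow

The `analysis/` scripts run the full study pipeline over generated data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # kinematics, cytometry, time-courses + truth
Rscript analysis/02_cluster.R    # ten-fold two-step classification per sample type
Rscript analysis/03_gate.R       # gating, stain classification, normalized pY
Rscript analysis/04_stats.R      # time models, letters, correlation tables
```

Each script is seeded (`--seed`, default 1) and rerunning it reproduces its
outputs byte for byte.

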