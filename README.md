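# redtime

Replication timing and nuclear localization of single telomeres.

## What this solves

Bulk measurements show human telomeres replicating throughout S phase, but
they say nothing about whether the telomere of a *particular* chromosome
arm has its own preferred replication window. Replicative-detargeting FISH
(ReDFISH, a CO-FISH variant) answers that question one telomere at a time:
synchronized cells receive one-hour BrdU/BrdC pulses tiling the S phase;
telomeres that replicate during a pulse lose one (substituted) strand per
sister chromatid during the CO-FISH procedure, so the two sisters are
subsequently *detargeted* — recognized exclusively by either the C-rich or
the G-rich strand-specific probe (reciprocal single-colour signals) —
while non-replicating telomeres keep mixed two-colour signals. Counting
detargeted telomeres per arm and per pulse over scored metaphases yields
each arm's replication-time distribution.

`redtime` is the quantification pipeline for this experiment (and the
associated 3D-localization and Q-FISH measurements), for cytogeneticists
and genome-organization labs: signal classification, per-pulse
normalization, mean replication timing with exact confidence intervals,
exact inferential statistics, radial nuclear-position metrics, and a fully
seeded synthetic-data generator so the entire chain is testable without
image data.

## The statistics at its core

With pulse midpoints `Y_i = (i - 0.5) * pulse_length` (0.5 h, 1.5 h, … for
one-hour pulses) and raw per-pulse detargeting proportions
`p_i = n_detargeted_i / n_scored_i` pooled over 30–50 metaphases per
pulse, the normalized fractions and mean replication timing of an arm are

    f_i = p_i / Σ_j p_j          (sum adjusted to 100%)
    mrt = Σ_i f_i · Y_i          (hours after S-phase entry)

Fractions are grouped into early S (pulses 1+2), mid S (3+4) and late S
(5+6) with exact Clopper–Pearson confidence intervals (α = 0.05); arms are
compared by exact Fisher tests (2×3 early/mid/late by full Freeman–Halton
enumeration, or collapsed 2×2) under Bonferroni thresholds `α/k`. Radial
nuclear position of a 3D FISH spot is its **volume ratio** — the fraction
of nuclear volume enclosed by the boundary surface shrunk concentrically
through the spot (0 = centre, 1 = lamin B periphery; `s³` for ellipsoids,
distance-transform quantile for anisotropic voxel masks) — with three
equal-volume zones that are equal-probability under uniform placement.
Q-FISH intensities divided by their metaphase mean give relative telomere
lengths per allele.

## Worked example

```r
library(redtime)

design <- sphase_design(s_length = 6, n_pulses = 6)   # six 1 h pulses
counts <- data.frame(pulse_index = 1:6, n_scored = 60,
                     n_detargeted = c(3, 6, 12, 18, 15, 9))

round(normalize_fractions(counts), 3)
#> [1] 0.048 0.095 0.190 0.286 0.238 0.143
compute_mrt(normalize_fractions(counts), design)
#> [1] 3.5
```

This arm replicates on average 3.5 h into S phase — a mid/late telomere:
29% of its replication events fall in the first half of S, 71% in the
second. The binned profile with exact 95% CIs:

```r
bin_phases(counts, design)[, c("bin", "fraction", "lo", "hi")]
#>     bin  fraction         lo        hi
#> 1 early 0.1428571 0.06641408 0.2620973
#> 2   mid 0.4761905 0.33421832 0.6424176
#> 3  late 0.3809524 0.25247156 0.5386855
```

Comparing an early-replicating against a late-replicating arm within a
family of 20 comparisons (threshold 0.05/20 = 0.0025):

```r
early <- data.frame(pulse_index = 1:6, n_scored = 60,
                    n_detargeted = c(20, 18, 8, 6, 4, 2))
late  <- data.frame(pulse_index = 1:6, n_scored = 60,
                    n_detargeted = c(2, 4, 8, 10, 18, 20))
compare_arm_timing(early, late, design, alpha_family = 0.05, k = 20)
#> fisher_2x3: p = 5.85e-12; threshold 0.0025 (alpha 0.05 / k = 20) -> significant
```

Nuclear position: in a sphere, a spot at half the radius encloses 1/8 of
the volume:

```r
volume_ratio(c(2, 0, 0), nucleus_ellipsoid(c(4, 4, 4)))
#> [1] 0.125
```

End-to-end synthetic run (simulate → score → timing → compare → localize →
Q-FISH), deterministic under the seed:

```r
cfg <- default_config()
cfg$arms$n_arms <- 5
res <- run_pipeline(cfg, seed = 1)
res$timing[, c("arm_id", "mrt", "early", "mid", "late")]
#>   arm_id  mrt  early   mid   late
#> 1  arm01 1.16 0.8811 0.104 0.0145
#> 2  arm02 1.74 0.6431 0.330 0.0273
#> 3  arm03 1.78 0.6373 0.334 0.0287
#> 4  arm04 1.97 0.5227 0.430 0.0469
#> 5  arm05 3.60 0.0487 0.606 0.3450
res$timing_localization$rho
#> [1] 1
```

The per-arm `mrt` values recover the simulated replication-window order,
and because the generator couples later windows to more peripheral radial
laws, the timing–localization rank correlation is 1 here.

A thin CLI wrapper around the pipeline ships in
`inst/scripts/redtime.R`; the methods vignette
(`vignettes/telomere-replication-timing.Rmd`) documents the model,
parameter choices and limitations.

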