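# hsspme

Computational toolkit for developing and validating cooled headspace
solid-phase microextraction (HS-SPME) GC–MS methods, built around the
quantification of urinary 2-phenyl-2-propanol — the biomarker of
occupational cumene exposure — via its acetylated derivative BMDA. It
is aimed at analytical chemists and method developers who want the
modelling, design and statistics side of SPME method development as
reproducible code rather than spreadsheets.

## What it computes

**Three-phase equilibrium uptake.** A sealed vial is coating (V1) +
liquid (V2) + headspace (V3); the mass absorbed by the fiber at
equilibrium is

```
n = C0 V1 V2 K1 K2 / (K1 K2 V1 + K2 V3 + V2)
```

with K1 the coating/headspace and K2 the headspace/liquid partition
coefficients. K2 comes from the Henry constant as `K_H / (R T)`;
K1 from the octanol–water coefficient (`10^logKow / K2`), from the
retention-index correlation `log10 K1 = 0.0042 LTPRI − 0.188`, or from
a van't Hoff temperature correction `log10 K1 = a/T + b`. First-order
uptake kinetics use the convention that the equilibration time is when
the fiber holds 95% of the equilibrium mass.

**Retention indexing.** Linear temperature-programmed retention
indices from an n-alkane ladder, with minimal peak detection and
trapezoidal integration for synthetic chromatograms.

**D-optimal design.** Exact (exhaustive) D-optimal subset selection on
small coded candidate grids, saturated response-surface fitting on
replicated runs with replicate-pooled error, 90%-confidence test-point
validation, and multi-response optimum/Pareto selection.

**Validation statistics.** Calibration by unweighted OLS of
internal-standard-corrected responses, LOD = 3.3 · SD(Y-intercept) /
slope and LOQ = 3 · LOD, RSD, accuracy, recovery against a
liquid-injection curve, and daily / inter-day / intra-day aggregation.

**Synthetic data.** Seeded generators for chromatograms, alkane
ladders, calibration campaigns, design-of-experiments response tables
and uptake kinetics, so the whole pipeline is testable offline.

## Worked example

```r
library(hsspme)

# Partition coefficients for BMDA at the heated (60 C) condition
k2 <- k2_from_henry(5.25e-4, celsius_to_kelvin(60))
k1 <- k1_from_kow_k2(2.88, k2)
c(k2 = k2, k1 = k1)
#>           k2           k1
#> 1.920524e-02 3.949847e+04

# ... and from the retention index at the cooled condition
k1_from_ltpri(1384)
#> [1] 421502.3

# Equilibrium uptake with a 30-um PDMS fiber, 0.3 mg/L spike
prot <- default_prep_protocol()
c0 <- effective_c0(prot, 0.3, formula_weight("C9H12O"),
                   formula_weight("C11H14O2"))
sys <- phase_system(pdms_coating_volume(30), liquid_volume(prot),
                    headspace_volume(prot), 60, unit = "C")
equilibrium_uptake(sys, c0, partition_set(k1, k2, "from_kow"))
#> [1] 23.6209

# D-optimal 5-run design on the 3x2 fiber x temperature grid
grid <- build_candidates(list(
  factor_spec("x1", c(-1, 0, 1), c("7 um", "30 um", "100 um")),
  factor_spec("x2", c(-1, 1), c("60 C", "10 C"))))
des <- d_optimal_subset(grid, saturated_model(), k = 5)
des$det; des$excluded
#> [1] 256
#>   x1 x2
#> 5  0  1
```

The 0.0192 and 3.95e4 are the dimensionless headspace/liquid and
coating/headspace partition coefficients at 60 °C; 4.215e5 is the
cooled-condition K1 implied by the derivative's retention index of
1384; 23.6 ng is the predicted equilibrium mass on the fiber under the
nominal 30-µm coating volume; and the design search confirms that the
optimal 5-run screening design drops a center (30 µm) run, leaving it
as the model-validation test point.

A full seeded run of the pipeline — generation, partition modelling,
retention indexing, design optimization, performance report — is one
call:

```r
run_pipeline(default_pipeline_config(seed = 1), "out/")
```

See the vignette (`vignettes/cooled-hs-spme-workflow.Rmd`) for the
models, assumptions and design choices.

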