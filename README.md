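# t1retain

Quantitative T1-mapping pipeline for assessing gadolinium retention in
brain, with the synthetic-cohort machinery needed to validate every stage
without patient data.

## The problem

Gadolinium-based contrast agents shorten the longitudinal relaxation time
T1 of tissue in proportion to their local concentration
(1/T1 increases by r1·C). A prospective design — quantitative T1 mapping
before and four weeks after an administration — can therefore detect
retention directly: regions that retain gadolinium show shortened T1 at
follow-up. Because the T1-mapping methodology itself varies by a few
percent between sessions, changes within a pre-defined ±3% safety margin
are attributed to the method, not to retention.

The package implements the full computational chain for a 3D
inversion-recovery Look-Locker acquisition (first TI 19.6 ms, 12 phases
spaced 400.3 ms per inversion cycle):

* **Signal model** — signed recovery S(TI) = A − B·exp(−TI/T1\*), sampled
  as magnitude; apparent relaxation 1/T1\* = 1/T1 − ln(cos α)/τ under the
  readout train (flip angle α, phase interval τ).
* **Voxelwise fitting** — polarity recovery (every restoration index tried,
  best residual wins), three-parameter Levenberg-Marquardt fit, Look-Locker
  correction back to T1, and a validity clamp excluding artifact values
  outside (0, 10000) ms from all statistics.
* **Alignment** — 6-DOF rigid registration of synthetic T1-weighted images
  (multi-resolution, halfway-space mean-squared-difference metric), with
  nearest-neighbour label resampling and region volumes as an alignment
  diagnostic.
* **Longitudinal inference** — per-subject percent change, paired and
  one-sample t-tests, the ±3% margin classification, age correlations and
  forest-plot tables.
* **Pharmacokinetics** — biexponential plasma decay driving tissue uptake
  through a leakage coefficient K_i (default 10⁻³ min⁻¹), to compare the
  brain load of intravenous versus intrathecal dosing on one scale.
* **Synthetic cohorts** — digital brain phantoms whose region means and
  between-subject spreads match a 76-participant 3T cohort (white matter
  1082.1 ± 46.7 ms, cortex 1479.3 ± 61.2 ms, ...), gadolinium fields,
  rigid session misalignment, and a fast region-level cohort simulator.

## Worked example

A null cohort (88 imaged, 12 excluded for registration/segmentation
errors, no gadolinium exposure), analyzed region-wise:

```r
library(t1retain)
m   <- filterCohort(makeCohort(88, 12, seed = 7))   # 76 analyzable
ch  <- simulateCohortMeans(m, defaultRegionTable("all"))
inf <- regionInference(ch, margin = 3)
forestTable(inf, defaultRegionTable("all"))[1:4, c("region_name", "n",
    "mean_pct", "ci95_lo", "ci95_hi", "margin_class")]
#>                region_name  n mean_pct ci95_lo ci95_hi  margin_class
#> 1          cerebral_cortex 76   0.0161  -0.975   1.007 within_margin
#> 2 subcortical_white_matter 76  -0.0219  -0.780   0.737 within_margin
#> 3            basal_ganglia 76  -0.1234  -0.929   0.682 within_margin
#> 4      frontal_gray_matter 76  -0.0730  -1.398   1.252 within_margin
```

Every region's mean percent T1 change sits inside the ±3% band, as it
should under the null. Injecting 0.05 mM gadolinium into the cortex
(`gadolinium = list(regions = "cerebral_cortex", concentrationMM = 0.05,
relaxivityR1 = 4)`) flips its classification to
`exceeds_margin_shortening`.

The pharmacokinetic side:

```r
doseRatio(doseScenario("intravenous", doseMmolPerKg = 0.1, bodyMassKg = 80),
          doseScenario("intrathecal", doseMmol = 0.5))
#> [1] 16
up <- tissueUptake(plasmaModel(), transferModel(1e-3))
sprintf("IV brain peak: %.4f mM at t = %.0f min", up$peak, up$peakTime)
#> "IV brain peak: 0.0361 mM at t = 233 min"
```

A standard intravenous dose carries 16× the total gadolinium of a
0.5 mmol intrathecal one, and the modelled IV brain-tissue peak
(≈ 0.04 mM) is the same order of magnitude as the ≈ 0.1 mM literature
estimate for the intrathecal route — the two routes load brain tissue
comparably. `table5Report()` assembles the full route-comparison ledger,
marking literature cells as inputs and the modelled cell as computed.

End-to-end runs (simulate → fit → align → aggregate → infer) go through
`runNullStudy(runConfig(...))`; `mode = "regional"` is the scalable
statistical path, `mode = "voxel"` exercises the full image chain. A thin
command-line wrapper with `simulate` / `fit` / `align` / `stats` / `pk` /
`run` subcommands lives in `inst/cli/t1retain.R`.

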