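# calciscan

Micro-CT densitometry and individual-level stable-isotope statistics for
calcareous microfossil shells.

## What problem this solves

Planktic foraminifers build calcite shells a few micrometers thick whose
density, wall thickness, and δ¹³C/δ¹⁸O composition carry ecological and
paleoceanographic signal. Non-destructive micro-focus X-ray CT (MXCT) can
image these shells at 0.8 µm/voxel — but the raw 16-bit grayscale of any
given scan drifts with the X-ray spectrum and detector gain, so grayscale
is not comparable between scans. The fix is to scan a block of homogeneous
standard calcite in every field of view and normalize each volume to the
**calcite CT number (CCN)** scale:

    CCN = 1000 × (μ_sample − μ_air) / (μ_calcite − μ_air)

so air = 0 and pure calcite (density 2.71 g/cm³) = 1000, analogous to the
clinical Hounsfield scale `CT = k(μ_m − μ_w)/μ_w` (water = 0, air =
−1000 HU). Because the mapping is affine in grayscale, per-scan gain and
offset cancel exactly.

`calciscan` is for micropaleontologists and biomineralization researchers
who want to (a) measure shell density and local wall thickness from CT
volumes with per-scan standard-calcite calibration, (b) test whether a
treatment (e.g. hot guanidinium DNA-extraction buffer) changed shells,
using paired pre/post designs, and (c) compare δ¹³C/δ¹⁸O across treatment
groups and genetic types with a normality-gated parametric/nonparametric
branch and per-genotype δ¹³C–weight regressions.

It also ships a first-class synthetic module: trochospiral shell phantoms
with exact density/thickness ground truth, polychromatic scan simulation
(Kramers spectrum, aluminum pre-filter, beam hardening, per-scan gain
drift, optional Poisson noise), and parallel-beam filtered back
projection — so every step of the measurement chain is testable against a
known world.

## Worked example

The package ships the reference per-specimen tables as fixtures: a CT
table (20 specimens; CCN and wall thickness for a pre-treatment scan, a
post-treatment scan with three specimens mounted together, and a
post-treatment scan mounted individually) and an isotope table (49
specimens in treatment groups A/B/C with genetic types Ia/Ib/IIa where
sequenced).

```r
library(calciscan)

rep <- run_physical_comparison(load_ct_table())
rep$summary$mean_ccn_diff_post1_post2   # -20.805
rep$summary$mean_ccn_diff_pre_post2     #   8.36
rep$tests$ccn_post1_vs_post2            # paired t: t = -3.584, df = 19, p = 0.00198
rep$tests$ccn_pre_vs_post2              # paired t: t =  1.508, df = 19, p = 0.148
```

Reading: scanning three specimens together depresses CCN by ~20.8 units on
average (p < 0.05) — beam hardening, the front shells preferentially
absorbing the soft part of the polychromatic beam. Re-scanning the same
specimen individually before and after DNA extraction differs by only
~8.4 CCN (1.04% of the mean pre-treatment CCN of ~806; p > 0.05), and mean
wall thickness changes by 0.07 µm on average (min −0.41 µm): the
extraction left density and thickness unchanged.

```r
g <- run_group_isotope_analysis(load_isotope_table())
g$tests$d13c$selected          # "one-way ANOVA"   (all groups pass the gate)
g$tests$d13c$anova$p_value     # 0.199  -> no treatment effect on d13C
g$tests$d18o$selected          # "Kruskal-Wallis"  (one group fails the gate)
g$tests$d18o$kruskal$p_value   # 0.0662 -> no treatment effect on d18O

ge <- run_genotype_analysis(load_isotope_table())
ge$tests$d13c$anova$p_value    # 0.000823 -> d13C differs among genotypes
ge$tests$d13c_posthoc          # only IIa-involving pairs flagged
ge$regressions$Ia              # slope 0.0839 permil/ug, R^2 0.364 (n = 15)
ge$regressions$IIa             # slope 0.1251 permil/ug, R^2 0.549 (n = 11)
```

Reading: treatment groups don't differ isotopically, but genetic type IIa
carries heavier δ¹³C than types Ia/Ib, and its δ¹³C rises more steeply
with shell weight — a genotype-level vital effect. (The shipped table
yields regression values that differ from the original figure captions;
the report carries this caveat — see the methods vignette.)

Simulated end-to-end scan study:

```r
rep <- run_scan_pipeline(specimens = 3, seed = 1)
rep$summary$hardening_shift      # < 0: stacked mounting depresses CCN
rep$summary$ccn_drift_rel_diff   # < 0.01: gain drift cancels in CCN
```

## Command line

```sh
Rscript <libpath>/calciscan/exec/calciscan physical --out report.json
Rscript <libpath>/calciscan/exec/calciscan isotopes-genotypes --out report.json
Rscript <libpath>/calciscan/exec/calciscan simulate --specimens 3 --seed 1 --out outdir
Rscript <libpath>/calciscan/exec/calciscan reproduce --out outdir
```

Verbs: `simulate`, `ccn`, `thickness`, `physical`, `isotopes-groups`,
`isotopes-genotypes`, `fixtures`, `reproduce`. Volumes are NRRD; reports
are JSON; color slices are PPM with a JSON palette sidecar.

## Layout

- `R/`, `src/` — implementation (Rcpp for projection/backprojection, exact
  3-D EDT, inscribed-sphere thickness, 26-connected labelling)
- `inst/extdata/` — reference tables (CSV)
- `tests/testthat/` — unit, property, and acceptance suites with
  independent oracles
- `vignettes/calciscan-methods.Rmd` — model assumptions, synthetic-world
  defaults, numerical choices, limitations
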