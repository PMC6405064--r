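---
title: "Methods: CCN densitometry, wall thickness, and isotope statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCN densitometry, wall thickness, and isotope statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciscan)
```

# The problem

Micro-focus X-ray computed tomography (MXCT) resolves the calcite shells of
planktic foraminifers — walls only ~4 µm thick — at sub-micron voxel sizes.
The reconstructed 16-bit grayscale of such a scan is *not* a stable density
scale: the tube's energy spectrum and the detector gain drift from scan to
scan, so the same shell re-scanned an hour later lands on a different
grayscale. `calciscan` implements the normalization that fixes this: a block
of homogeneous standard calcite (NBS-19 grade) is scanned *inside every
field of view*, and each volume is mapped onto the calcite CT number scale

$$\mathrm{CCN} = 1000 \times
  \frac{\mu_\mathrm{sample} - \mu_\mathrm{air}}
       {\mu_\mathrm{calcite} - \mu_\mathrm{air}},$$

so that air reads 0 and pure calcite (density 2.71 g/cm³) reads 1000.
Because the mapping is affine in the recorded grayscale, *any* per-scan
gain/offset applied to sample and references alike cancels exactly; this is
the package's central invariant and is tested to 1e−9 relative tolerance
under randomized gain/offset. The clinical Hounsfield mapping
$k(\mu_m-\mu_w)/\mu_w$ is provided for reference (`ct_number()`), with its
fixed points water = 0 HU and air = −1000 HU.

On this scale the package supports the three analyses of a paired
DNA-extraction experiment: (1) per-specimen pre/post comparison of mean
shell CCN and mean wall thickness with paired t-tests; (2) comparison of
δ¹³C and δ¹⁸O (‰ VPDB) across treatment groups; (3) genotype-stratified
isotope comparison and δ¹³C–weight regression.

# Per-scan calibration

`calibrate_scan()` averages the air and standard-calcite reference regions
after a one-voxel 6-neighborhood erosion: the rim of a region mixes
materials across the voxel boundary (partial-volume effect) and biases the
reference mean, which the erosion removes. Both eroded regions must retain
at least 100 voxels. When no labels are present the standard is
auto-detected as the brightest large connected component above the Otsu
threshold, with a guard that the bright/dark separation exceed three times
the pooled within-region spread — a volume of pure noise must fail
calibration rather than return a meaningless reference.

CCN values are deliberately **not clipped** to [0, 1000]: noise pushes
individual voxels outside the physical range symmetrically, and clipping
would bias the paired pre/post differences the pipeline exists to measure.
Per-specimen summaries default to the *mean* CCN over the shell mask; the
choice of mean (vs. median or mode) is a documented assumption, since
closed-source scanner software does not disclose its reduction.

# Segmentation

`segment_shell()` applies an Otsu threshold to the CCN histogram restricted
to [0, 1200] (the overshoot band above the calcite ceiling is kept so noise
is not truncated asymmetrically), retains 26-connected components of at
least 1000 voxels, and excludes the labeled standard-calcite region. Pores
are left open — no hole filling — because pore structure carries signal.
An automatically chosen threshold below 100 CCN means the volume contains
no calcite-bright class (an all-air scan) and raises an error. Histograms
use 50 bins over [0, 1200].

# Local wall thickness

Thickness follows the Hildebrand largest-inscribed-sphere definition: the
thickness at a voxel is the diameter of the largest sphere that fits
entirely inside the mask and covers that voxel. It is computed by an exact
3-D Euclidean distance transform (distance to the nearest background voxel
center, array zero-padded) followed by inscribed-sphere propagation in
exact integer squared-distance arithmetic. This definition was chosen over
surface-normal ray casting because it is well defined at chamber junctions
and admits a brute-force oracle (direct pairwise sphere search) that the
test suite runs on masks up to 32³.

The discrete diameter is reported as 2·EDT voxels — the standard
Hildebrand/BoneJ convention. Its known bias is up to one voxel upward on
structures whose half-width falls between voxel centers (a 5-voxel slab at
0.8 µm/voxel reads 4.8 µm rather than 4.0 µm); the hollow-sphere phantom
with a 4 µm wall is recovered within ±1 voxel (±0.8 µm), which is the
resolution-limited accuracy the acceptance suite asserts. Walls thinner
than 2 voxels are rejected as unmeasurable at the stated resolution.

# The synthetic world

The simulator states the world the tests run in; none of its defaults were
chosen by looking at test outcomes.

**Shell phantoms** (`make_shell_phantom()`): a trochospiral sequence of
hollow calcite spheres (three chambers per whorl, geometric radius growth,
default factor 1.2), later chambers carving their cavities through earlier
walls, with optional radial pores. Defaults: 128³ voxels at 0.8 µm/voxel
and a 4 µm wall, matching the scanner metadata the package emulates
(0.8 µm/pixel, ~4 µm walls). Density is binary calcite (2.71 g/cm³) sampled
at voxel centers; the generating geometry provides the exact thickness
truth. Not emulated: spine morphology, sub-voxel partial-volume density,
chamber-wall ontogenetic layering. A green phantom test therefore
establishes correctness of the measurement chain, not realism of
foraminiferal morphology.

**Physics** (`attenuation_coefficient()`, `beam_spectrum()`): a two-term
attenuation model µ = ρ(aE⁻³ + b), a = 120, b = 0.003 (per-µm per-unit
density), strictly decreasing in energy and linear in density — the two
properties beam hardening requires. The absolute µ scale is arbitrary
(CCN is scale-free) and is set so that calcite attenuates appreciably over
the ~100 µm desk-scale field of view, which makes hardening visible at
phantom scale; consequently only the *direction* of hardening effects is a
testable claim, never their printed magnitude. The spectrum is Kramers-law
bremsstrahlung on ≤ 16 bins below the 80 kV tube voltage, optionally
hardened by a 0.2 mm aluminum pre-filter applied as Beer–Lambert
transmission.

**Scanning and reconstruction**: 2-D parallel-beam geometry per slice
replaces the instrument's cone beam — the claims under test concern
relative density, not geometric fidelity. Projections are ray-marched at
half-voxel steps with bilinear sampling; reconstruction is filtered back
projection with a Ram–Lak kernel. The monochromatic round trip recovers µ
within 3% in object interiors at 128²/360 angles, and the error shrinks
with angle count. Poisson counting noise is off by default and seedable
when on.

**Scan-to-scan drift** enters the chain the way it does physically: the
per-scan gain multiplies detected intensities and the 16-bit digitization
of the reconstructed map. The sinogram itself is flat-field-corrected
within the scan (−log(I/I₀) with I₀ taken from the same scan's air rays),
so gain shifts raw grayscale affinely and the CCN mapping cancels it; a
drift of ×1.1 moves the raw grayscale by 10% and the CCN by < 1%.

**Isotope datasets** (`make_isotope_dataset()`): treatment groups at the
study's sizes (A = 14, B = 20, C = 15), genotype composition of typed
specimens Ia/Ib/IIa = 15/8/11 with one untyped B/C record, log-normal shell
weights (meanlog log 2.8, sdlog 0.5; ~1–8 µg), genotype-specific linear
δ¹³C–weight structure with slopes 0.085/0.05/0.128 ‰/µg, residual noise
0.2 ‰ (instrument precision ±0.10 ‰ plus within-type vital-effect spread),
δ¹⁸O at −1.85 ± 0.32 ‰, and null treatment effects (the study detected
none). Genotype intercepts (−0.75, −0.71, −0.54 ‰) are set so that
intercept + slope × E[weight] reproduces each genotype's observed mean
δ¹³C under the common weight distribution. Group-A records are untyped but
keep a latent genotype for the mean structure.

# Statistical kernels and the normality gate

All tests are two-sided at α = 0.05. The kernels wrap R's reference
implementations (Student t, Royston's Shapiro–Wilk, classical F,
Kruskal–Wallis with tie correction, Tukey HSD, OLS with t-based 95%
mean-response bands) behind uniform result records; the test suite checks
each against an independent closed-form, sums-of-squares, or
rank-arithmetic oracle, and calibrates type-I error to 5% ± 1.5% over 2000
null replicates. The Lilliefors-corrected Kolmogorov–Smirnov test estimates
the normal's moments from the sample and draws its p-value from a seeded
Monte-Carlo null distribution of D (20 000 replicates, cached per sample
size) — self-contained and deterministic, with no dependence on published
approximation tables.

Degenerate inputs are defined rather than fatal: identical pairs give
t = 0, p = 1; zero-variance nonzero-mean differences give p → 0 with a
warning; all-tied Kruskal–Wallis data give H = 0, p = 1.

The **normality gate** mirrors the analysis protocol: a variable is
"normal" only if *both* Shapiro–Wilk and Lilliefors KS give p > 0.05 in
*every* compared group; the parametric branch (ANOVA) requires all groups
to pass, otherwise the nonparametric branch (Kruskal–Wallis) is used.
Whether the original protocol gated per group or on the pooled variable is
unstated; per-group gating is implemented and logged, and on the shipped
tables it selects exactly the reported branches — δ¹³C parametric
everywhere, δ¹⁸O nonparametric (driven by one group and one genotype
failing Shapiro–Wilk). Both branches' statistics are always present in the
report alongside the gate decision, so the branch choice is auditable.
Tukey HSD is the post-hoc procedure; the reference analysis left its
post-hoc method unnamed, so this is an implementation choice.

# Regression scope

Per-genotype OLS of δ¹³C on shell weight is restricted to genotypes whose
weight range spans at least 3 µg: correlation over a narrow weight range is
not meaningful, and this threshold admits the two wide-ranging genotypes
(Ia, IIa) while excluding the narrow one (Ib). The threshold is
configurable.

Two printed reference values are knowingly *not* reproduced and are
excluded from acceptance: the regression R² values 0.643/0.755 (and slopes
0.0853/0.1281) are not obtainable from the shipped per-specimen table —
its typed counts (Ia = 15, IIa = 11) disagree with the figure captions'
(16, 10), so the published fit used a sample composition the table does not
encode; the table yields R² = 0.364/0.549 and slopes 0.0839/0.1251, which
the pipeline reports with an explicit caveat. Likewise the "1.05%"
relative-variation figure has an unstated denominator; the ratio of the
mean signed pre/post CCN difference to the grand-mean pre-treatment CCN
gives 1.04%, which is reported with the operationalization caveat logged.

# Numerical choices

* Ray-marching step 0.5 voxels (0.25 in symmetry-sensitive tests); ramp
  filtering via the exact discrete Ram–Lak kernel, FFT-convolved at
  2×-padded power-of-two length.
* EDT pad handling: the implicit background outside the array enters each
  separable pass as sentinel parabola sites at virtual positions −1 and n,
  keeping diagonal pad distances exact.
* Sphere-coverage decisions in the thickness propagation use integer
  squared distances, so voxels exactly on a sphere surface are covered.
* Otsu histograms use 256 bins; CCN histograms 50 bins over [0, 1200].
* The color slice palette is a monotone 256-step black–purple–red–yellow–
  white ramp with all entries distinct, so slices decode back to CCN
  within one bin.

# Known limitations

Cone-beam geometry, detector blur and scatter are not modeled; hardening
magnitudes are therefore illustrative. Thickness truth at chamber junctions
retains the generating wall value even where chambers merge. The phantom
places specimens side by side along one axis; real stacked mounts have
arbitrary geometry. Treatment chemistry is representable only as an
optional density offset, not modeled mechanistically.
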