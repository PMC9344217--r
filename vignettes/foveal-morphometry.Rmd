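---
title: "Foveal pit morphometry from OCT volumes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal pit morphometry from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(foveapit)
```

# What this package computes

`foveapit` quantifies the shape of the foveal pit from macular spectral-domain
OCT volume scans (128 B-scans x 512 A-scans over a 6 x 6 mm field, the Topcon
3D OCT-1000 protocol) and relates the resulting measure to participant
covariates with sex-stratified linear mixed models. Three quantities are
produced per eye:

* **FC, foveal curvature** — the leading coefficient of an ordinary
  least-squares quadratic fitted to the internal limiting membrane (ILM)
  boundary over the 25 columns spanning 12 pixels left and right of the fovea
  center, in pixel coordinates. Reported on a x100 scale; healthy adults
  average about 7.25 with SD about 2.
* **MC, macular curvature** — per-B-scan quadratic leading coefficients of the
  retinal pigment epithelium (RPE) boundary over the 32 central B-scans,
  summarized by their median (x100 scale, about 0.21 on average).
* **CPRT, center point retinal thickness** — the ILM-to-RPE distance at the
  thinnest-retina point of the volume, in pixels and micrometers (about
  226 um on average).

Row indices increase downward (toward the choroid), so a pit makes the ILM row
*maximal* at its center and the raw quadratic coefficient negative; both FC
and MC are sign-adjusted so that a normal pit / bowl is positive and "steeper"
means larger. All indices in this package are 1-based, the R convention.

# Boundary segmentation

Each B-scan is segmented by a shortest-path search: the ILM is the
minimum-cost left-to-right path on a cost image built from the dark-to-bright
vertical gradient (one minus the normalized signed gradient), the RPE on the
bright-to-dark counterpart. A path visits one row per column, may jump at most
`max_jump = 15` rows per column step (this blocks shortcuts across shadow
artifacts), and pays a smoothness penalty `lambda * |row jump|` with
`lambda = 0.1`. The search is A* with the admissible suffix-sum-of-column-
minima heuristic, so the returned path attains the global cost minimum — the
test suite checks this against an exhaustive dynamic-programming oracle.
Images are pre-smoothed with a 1-pixel Gaussian before gradients are taken.

Integer paths are then refined to sub-pixel precision. The renderer (and, to
first order, any intensity edge) produces a two-level partial-volume profile
per column: `I(r) = above + (below - above) * clip(r + 0.5 - pos, 0, 1)`.
The refinement estimates `pos` per column by minimizing the negative gamma
log-likelihood of the log-intensity residuals over a 17-row window centered
on the path row, with the two plateau levels estimated from medians just
outside the window. Under the package's multiplicative gamma speckle model
this is the exact likelihood (and closely matches any multiplicative noise
after log transform); on a noiseless render the loss vanishes at the true
boundary, so the refinement is exact there. Finally, isolated columns that
deviate more than 1.5 rows from a 9-column running median are replaced by the
median: extreme speckle can capture single columns, while a genuine smooth
boundary never strays that far from its own running median (the worst case,
the pit vertex, deviates by about `a * 4` = 0.5 row), so the step is again a
no-op on clean data.

If the two refined boundaries cross, the ILM is clamped one row above the RPE
and the scan is flagged low-confidence. Featureless inputs (gradient dynamic
range below `grad_tol` of the image maximum) raise a boundary-not-found error
rather than returning a spurious path.

# Morphometry

The fovea center is the centroid of the minimal connected region of the
thickness map (RPE minus ILM row, 128 x 512) after a 3-slice x 11-column
moving average — anisotropic because the slice pitch (46.9 um) is four times
the column pitch (11.7 um); ties break to the lowest slice then column. A
minimum on the volume border, or a center closer than 12 columns to a lateral
edge, is a QC failure (the pit was not captured), and `quantify_volume()`
then emits a record with missing measures and the reason, never a silent
number.

The FC window of "12 pixels left and right" is read as 25 columns inclusive
of the center, and the "two-dimensional polynomial of degree two" as a
univariate quadratic in the column coordinate; fitting is plain OLS on pixel
coordinates, no lateral/axial aspect correction (axial length is not
available in the emulated protocol, and the source pipeline also fit raw
pixels). The central 32 of 128 B-scans (slices 49–80) are used for MC; the
median over slices makes MC robust to up to 15 one-sided slice failures.
CPRT converts to micrometers with the configured axial scale only.

# The synthetic scene generator

Real volumes from the emulated study are access-controlled, so the package
ships a generator whose outputs stand in for them with known ground truth.
A scene is two surfaces: an RPE bowl, quadratic in both lateral directions
with column-coefficient `a_macula` (default 0.0021, the published MC mean),
and an ILM equal to the RPE minus a thickness field. The thickness field is a
flat rim (default 118 rows) minus a pit bump that is *exactly* quadratic
within 16 columns of the pit center — so the 25-column fit window sees a pure
quadratic and FC is exactly recoverable — then blends to the rim with a
cosine taper by 40 columns; across slices the pit falls off with a cosine
over 6 B-scans. The ILM's leading coefficient at the pit equals `a_fovea` by
construction (the pit carries `a_fovea - a_macula` on top of the bowl).

Rendering uses three intensity bands (vitreous 30, retina 160, choroid 60)
with exact partial-volume blending at the boundaries, multiplied by
gamma-distributed speckle with unit mean and standard deviation
`noise_sigma`. Default frame height is 650 rows and the axial scale 2.6
um/row — the instrument's export geometry is not published, and these values
put a 87-pixel center thickness at the published 226 um scale; both are
configuration parameters, and FC/MC are unaffected by the axial scale.

**Default speckle level.** The scanner's processed B-scans are not raw
interferograms; registration, averaging and display processing leave a
speckle contrast well below the fully-developed-speckle limit of 1. The
package's segmentation contract for default noise (boundary traces within
2 rows of truth everywhere) was used to calibrate the default: 0.2 is the
largest level in {0.2, 0.25, 0.3, 0.4, 0.5} at which the measured maximum
boundary deviation honors that contract. At this default the pipeline
measures mean IoU ≈ 0.997 against truth masks and an FC noise SD of ≈ 0.08
on the x100 scale.

Per-scan truth for validation sets couples the draws realistically: rim
thickness (118 ± 5 rows) and the pit's beyond-quadratic depth (12 ± 4 rows)
are sampled, and CPRT is *derived* as rim minus total pit depth, so steeper
pits have thinner centers — the inverse FC–CPRT association seen in the real
cohort — and every draw satisfies the scene invariants by construction.
Foveal curvature draws are N(0.0725, 0.02) truncated to the renderable range
[0.01, 0.115].

What a green test does *not* establish: the generator has no vascular
shadows, motion artifacts, pathology, or spatially correlated speckle grain,
and its layer model is two-boundary only; segmentation accuracy on real
Topcon exports is expected to be lower than on these renders, as the source
study's own 0.97 IoU (against A*-derived masks) suggests.

# The synthetic cohort and the multilevel models

`generate_cohort()` draws participants with marginals matching the published
cohort (45.1% male; 92.1% white; age 56 ± 8; sex-specific height; the
published income, education, deprivation and birth-order proportions; VA
85 ± 5 letters; SE −0.69 ± 2.5 D; CPRT 223/230 ± 20 um by sex; IOP 16 ± 3.5
mm Hg, an assumption — the source reports no IOP summary). Each person
contributes a right eye and, with probability 0.707, a left eye, reproducing
the published ~1.71 eyes per participant. Disease and surgery flags use
small assumed prevalences (0.2–2%); the exclusion *mechanics*, not the
counts, are the modeled object.

The outcome is built on a latent standardized scale:
`z = effects x covariates + person intercept + eye noise`, then
`fc_raw = 0.0725 + 0.02 z`. Effects are specified in SD units per
conventional increment (per decade, per 5 cm, per category, vs-white,
vs-female), optionally sex-specific. Defaults reproduce the three headline
associations: male-female difference 0.36 SD, black-vs-white −0.70 SD
(females) / −0.80 SD (males), and +0.06 SD per income category. The default
variance components (between-person SD 0.86, residual SD 0.457; intraclass
correlation 0.78, appropriate for a bilateral anatomical trait) were chosen
analytically so the latent variance under the default effects is ≈ 1.0003 —
this keeps "effects in SD units" consistent with the analysis step, which
z-scores by the sample SD as the source analysis did. If you change the
effects substantially, the estimand shifts by the ratio of latent SDs
(about 1–2% per 0.05 of added effect variance).

The analysis applies the published exclusion list eye-wise (disease flags,
eye surgeries; sensitivity mode additionally drops SE outside ±6 D and VA
below 80 letters), z-scores FC on the pooled included sample (the source
reports sex differences in SD units on a common scale, which requires pooled
standardization; computed after exclusions), and fits nested REML mixed
models with a person-level random intercept: model 1 (age, ethnicity,
height, assessment centre), model 2 (+ VA, SE, corneal astigmatism, IOP, MC,
CPRT), model 3 (+ deprivation, education, fluid intelligence, income, birth
order), each in both sex strata, plus pooled crude and model-1-adjusted sex
contrasts. Missing categorical values form their own level; rows missing the
one continuous optional covariate (fluid intelligence) drop from model 3,
mirroring the published per-model attrition. The income trend test rescores
the informative bands 1–5 as a single integer term while keeping
"prefer not to say"/"missing" as adjustment dummies. No multiple-testing
correction is applied, matching the source presentation of per-term p-values.

**Satterthwaite degrees of freedom.** The environment provides lme4 but not
lmerTest, so the package implements the Satterthwaite approximation itself:
for each coefficient, `df = 2 v^2 / (g' A g)` with `v` the coefficient
variance, `g` its numeric gradient in the variance parameters
(theta, sigma), and `A = 2 H^{-1}` from the numeric Hessian of the REML
deviance rebuilt at arbitrary (theta, sigma) from lme4's penalized
least-squares components. The implementation is validated structurally: in a
balanced two-eyes-per-person design with high ICC, a person-level covariate
gets ≈ (persons − p) df, far below the eye-level residual df, and the null
simulation in the acceptance suite checks type-I calibration at alpha=0.05.
Singular or boundary fits fall back to residual df and are flagged.

# Numerical choices and degenerate inputs

* Tie-breaks: fovea-center plateaus resolve to the centroid of the minimal
  connected region, then lowest slice, lowest column; A* ties resolve by
  node id, deterministically.
* A zero-curvature scene (`a_fovea = 0`, `a_macula = 0`) renders a flat ILM
  and the fitted FC is 0; `a_fovea > 0` requires enough pit depth to carry
  the quadratic over the exact zone, otherwise scene construction errors.
* Constant images raise boundary-not-found; volumes that are not 128 x 512
  raise shape errors; ILM = RPE thickness raises a QC error.
* The refinement grid (0.25-row coarse, 0.01-row fine) bounds the noiseless
  FC error near 5e-4 relative, inside the 1e-3 end-to-end contract.
* Seeds: every stochastic entry point takes a `seed`; child seeds are drawn
  below 2^31 and the caller's RNG state is restored afterwards.

# Interfaces

Tabular results are tibbles throughout (`quantify_volume()` rows,
`generate_cohort()`, `tidy()`/`glance()` on fits) and chain with the pipe;
`autoplot()` draws B-scan overlays and coefficient forest plots, and
`plot_thickness_map()` the thickness field. Because no TIFF codec is
available in this R environment, volumes serialize as a raw float32 stack
plus a JSON sidecar carrying scales, identifiers and truth surfaces
(`write_volume()`/`read_volume()`), traces and tables as CSV, and pipeline
configuration as YAML. A thin command-line driver (`inst/cli/foveapit`)
exposes simulate / segment / quantify / analyze / validate-tertiles /
run-all over these functions; `run_pipeline()` is the same driver as a
function and writes a machine-readable run log with seeds and QC tallies.

# Known limitations

* The deep-learning distillation stage of the source pipeline (PSPNet /
  ResNet-18 trained on A*-derived masks) is out of scope; the A* teacher is
  the production segmenter here.
* Published cohort tables cannot be reproduced numerically without the
  access-controlled data; the statistical layer is validated by
  parameter-recovery and calibration simulations instead.
* Single-layer (ILM/RPE) segmentation only; no pathology handling; no axial
  length distortion correction (unavailable in the emulated protocol).
* The tertile-ordering exercise is a pipeline-vs-truth analog of the source
  study's human-grader validation, not a reproduction of grader behavior.
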