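---
title: "Models and methods behind lungqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lungqct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqct)
```

`lungqct` implements a multiscale quantitative-CT analysis of paired
inspiratory (total lung capacity, TLC) and expiratory scans for
three-group comparisons of healthy, asthmatic and COPD subjects. This
vignette is the package's own account of the models, the tunable
parameters, the synthetic data that the tests rely on, and the design
choices that were genuinely open.

## Densitometry: the air-fraction model

A lung voxel is modelled as a two-component mixture of air and soft
tissue, so its attenuation interpolates linearly between the air
reference and the tissue reference:

$$\beta_{air} = \frac{HU_{tissue} - HU}{HU_{tissue} - HU_{air}},
  \qquad \beta_{tissue} = 1 - \beta_{air}.$$

`densitometry_refs()` holds the references and thresholds:

| parameter | default | units | rationale |
|---|---|---|---|
| `hu_air` | −1000 | HU | CT definition of air |
| `hu_tissue` | +55 | HU | conventional soft-tissue/blood attenuation |
| `emph_threshold` | 0.985 | β_air | emphysema call on the inspiratory scan |
| `fsad_threshold` | 0.90 | β_air | air-trapping call on the expiratory scan |

Thresholding the *fraction* rather than raw HU makes the call invariant
to an affine recalibration applied consistently to the scan and the
references (tested as a property). With the defaults, the thresholds are
algebraically equivalent to HU cutoffs of −984.175 and −894.5, which the
test suite re-derives by inversion. Percentages are voxel counts over the
lobe mask; with constant voxel volume within an image this equals a
volume percentage, and voxels outside the mask never enter numerator or
denominator.

fSAD% uses the parametric-response-map idea: a voxel counts as
functional small-airways disease only if it is air-trapped at expiration
*and not* emphysematous on the inspiratory scan resampled to the
expiration grid through the displacement field. Voxels whose warped
sample leaves the inspiration domain are excluded from both numerator
and denominator. The expiration lung volume state (FRC vs RV) is
recorded in the configuration for reporting but deliberately not
corrected for; the two states yield systematically different fSAD% and
Jacobian levels, so mixed-protocol comparisons must be interpreted with
that in mind.

## Airway morphometry and tracheal normalisation

Per branch, from lumen area $A$ and perimeter $P$:
$Cr = 4\pi A / P^2$ (1 for a circle, smaller for heterogeneous lumen
shapes) and $D_h = 4A/P$. The $Cr$ formula was an open choice — we fixed
the isoperimetric ratio because it is dimensionless, scale-invariant and
equals 1 exactly in the circular limit, matching the intended reading of
"decreasing circularity = shape heterogeneity". Inputs violating the
isoperimetric inequality $P^2 \ge 4\pi A$ are rejected as measurement
inconsistencies rather than silently clamped.

WT\* and Dh\* divide a subject's regional WT and $D_h$ by that subject's
*predicted healthy tracheal* value. The reference model is ordinary
least squares of the tracheal value on sex, age and height over healthy
subjects only. Sex is the dominant determinant of airway calibre; OLS on
these three covariates is the simplest model consistent with that, and
the fit refuses rank-deficient designs (naming the collinear column) and
fewer than 4 complete healthy subjects. Because normalisation is a plain
ratio, a consistent multiplicative body-size factor cancels exactly
(tested as a property). Regional aggregation is the unweighted mean over
a subject's branches in each of the ten named regions — the aggregation
rule was unstated in the source design, and the unweighted mean keeps
single-branch regions as pass-throughs; absent regions are reported as
missing, never as zero.

## Deformation metrics

The displacement field u(x), in mm on the expiration grid, maps an
expiration-grid point x to its inspiration-space position x + u(x). We
fixed the convention fixed-image = expiration, moving = inspiration so
that metrics live on the same grid as the fSAD subtraction and J > 1
means expansion toward inspiration. The deformation gradient
F = I + ∂u/∂x uses central differences interiorly and one-sided stencils
on the boundary faces, scaled by voxel spacing; lobar summaries exclude
the one-voxel boundary shell where one-sided stencils bias the estimate.
Principal stretches are square roots of the eigenvalues of FᵀF (right
stretch — immune to rotations), computed with the closed-form
trigonometric solution for symmetric 3×3 matrices, vectorised over
voxels with the Cardano argument clamped to [−1, 1] against rounding.

$$ADI = \sqrt{\left(\frac{\lambda_1-\lambda_2}{\lambda_2}\right)^2 +
              \left(\frac{\lambda_2-\lambda_3}{\lambda_3}\right)^2},
 \qquad \lambda_1 \ge \lambda_2 \ge \lambda_3 > 0.$$

ΔV_air^f distributes the whole-lung air-volume change over lobes: per
expiration voxel, $\Delta V_{air} = v\,(J\,\beta_{air}^{insp}(x+u(x)) -
\beta_{air}^{exp}(x))$, the Jacobian carrying the inspiratory air of the
material region back to the expiration grid; lobar shares sum to one by
construction. A non-positive whole-lung total aborts with a hint that
inspiration and expiration are likely swapped.

The bundled `estimate_displacement()` is an intentionally simple
multi-resolution demons-style method (Thirion force, Gaussian
diffusion regularisation, trilinear warping, deterministic given its
parameters). It exists so the pipeline can run without an external
registration; any externally computed field in the same NIfTI layout can
replace it, and the package's quantitative validation never depends on
it — ground-truth fields from the phantom are the primary test path.

## The phantom generator

`generate_phantom_pair()` builds the synthetic study material. Design:

- **Anatomy** is five disjoint axis-aligned lobe blocks inside an air
  margin, labelled on the shared grid in the expiration frame. Blocks,
  not anatomical shapes: every ground truth is then an exact count or a
  closed-form value, and tests stay fast.
- **Deformation** is an affine stretch about the grid centre plus a
  diagonal sinusoidal perturbation, u_i = (A−I)(x−c) + a·sin(2π(x_i −
  c_i)/L + φ_i). Both the displacement and det(I + ∂u/∂x) are available
  in closed form, giving an analytic oracle for the finite-difference
  Jacobian. Construction rejects any specification whose
  displacement-gradient norm reaches 0.95, which guarantees
  invertibility; the inverse map is computed to 1e−9 mm by fixed-point
  iteration.
- **Intensities** are mass-consistent: each material point carries a
  prescribed inspiratory tissue fraction t; the expiration image is
  β_tissue = J·t (compression concentrates tissue), and the inspiration
  image places each material point at its deformed position via the
  exact inverse map. HU values follow from the fractions through the
  same linear mixing model the densitometry module inverts.
- **Lesions**: per lobe, exactly `round(n·pct/100)` voxels are drawn
  (seeded) and assigned β_air = 0.995 (emphysema-like) or 0.96
  (trapped-only; above the trapping threshold after compression but
  below the emphysema threshold at inspiration). Prescribed percentages
  are therefore exact voxel counts. Under identity deformation the
  whole bookkeeping is exact — that regime is used for densitometry
  recovery. Under a non-trivial field, lesion counts on the
  inspiration grid acquire a sub-voxel boundary-quantisation error
  (single-voxel lesions are all boundary), so deformation metrics are
  validated on lesion-free smooth phantoms where the construction is
  again exact. This mirrors a real property of parametric response
  mapping: its subtraction degrades when lesion scale approaches the
  registration error.
- **Noise** is additive Gaussian HU applied only after all ground truth
  is recorded, so prescribed percentages always refer to the noise-free
  field. One master seed fans out to per-component substreams, so
  adding a component never perturbs earlier draws; identical
  configurations are bit-identical.

What the phantom does *not* emulate: CT texture, reconstruction kernels,
anatomical airway geometry, sliding at lobar fissures (the prescribed
field is globally smooth), or partial-volume structure at real lung
boundaries. Passing tests therefore demonstrate correctness of the
computational pipeline on data satisfying the model assumptions, not
robustness to real-scanner artefacts.

## The cohort generator and the comparison family

`generate_cohort_metrics()` draws per-subject values of the nine
analysed metrics (Cr, WT\*, Dh\* over ten airway regions; Emph%, fSAD%,
β_tissue, ΔV_air^f, Jacobian, ADI over five lobes, plus whole-lung
values where meaningful) from Gaussian baselines with additive group
shifts, truncated to physical ranges identically for every group so a
null configuration stays exchangeable. The source material reports group
directions and significance, not per-subject variances, so the default
effect table is qualitative: shifts follow the reported directions
(asthma and COPD lose circularity and calibre; COPD gains far more
emphysema and trapping and loses tissue fraction and deformation; both
diseases shift ΔV_air^f from the right lower to the right upper lobe)
with magnitudes of roughly one to a few plausible between-subject
standard deviations, chosen once and not calibrated to the source
figures. Demographics are generated group-independent: the real cohorts'
demographic imbalance (age, BMI, smoking history) is acknowledged but
deliberately not emulated, and — as in the source design — not modelled
as covariate adjustment.

`compare_groups()` reproduces the comparison design: Kruskal–Wallis
omnibus per metric × region, two-sample rank tests (the two-group
Kruskal–Wallis, i.e. Wilcoxon–Mann–Whitney with mid-ranks and tie
correction, normal approximation) for the three pairwise contrasts, χ²
without continuity correction for categorical covariates, and one
Benjamini–Hochberg step-up across the family at q = 0.01. The exact
enumeration behind the design's "87 comparison tests" is not published,
so the package defines its default family explicitly:

| block | tests |
|---|---|
| regional omnibus (3 airway metrics × 10 regions + 6 lobar × 5 lobes) | 60 |
| whole-lung omnibus (Emph, fSAD, β_tissue, Jacobian, ADI) | 5 |
| whole-lung pairwise contrasts (5 × 3) | 15 |
| demographics (age, BMI, FEV1%pred, FEV1/FVC, pack-years; sex, race) | 7 |
| **total** | **87** |

ΔV_air^f has no whole-lung entry because its whole-lung value is
identically 1. Regional pairwise contrasts are still computed and
annotated with the `*`/`†`/`‡` footnote convention at raw p < q — the
convention used in per-region figure annotations — but join the BH
family only under `family = "all"`. The report logs its own family size
rather than asserting 87.

## Numerical choices and degenerate inputs

- Air fractions are clamped to [0, 1]; calibration overshoot cannot
  produce unphysical values.
- An all-tied Kruskal–Wallis sample (where the tie-corrected statistic
  is 0/0) is reported as H = 0, p = 1 and flagged degenerate; an
  all-tied pairwise contrast likewise returns p = 1.
- Non-positive Jacobians inside the lung (registration folding) warn
  and flag the voxels rather than silently polluting lobar means.
- Trilinear warps mark out-of-domain samples invalid; all downstream
  counts and sums exclude them from numerator and denominator alike.
- Metric × region combinations observed in fewer than two groups are
  skipped with a log message, not imputed.

## Problem sizes in the shipped validation

The test-suite and acceptance-script simulations use 32³ phantoms
(1 mm spacing), 500 global-null cohorts of 30 subjects per group for the
FDR estimate, and 100 seeded cohorts of 50 per group for the
direction-recovery check. These sizes were chosen so the complete
validation runs comfortably on a single laptop core while leaving the
binomial error of the FDR estimate (≈0.4 percentage points at 500
replicates) well below the quantity being checked. The FDR property is
sample-size-free under the null — the groups are exchangeable at any n —
so the smaller per-cohort size trades nothing but power-related
quantities that the null estimate does not involve.

## Known limitations

- The demons estimator is a convenience, not a production registration;
  mass-preserving similarity metrics used in dedicated lung registration
  are out of scope, and lobar-fissure sliding violates its smoothness
  prior.
- Lesioned phantoms under large deformations do not keep
  inspiration-grid lesion counts exact (sub-voxel quantisation, above);
  exactness claims hold in the stated regimes.
- The cohort generator's effect magnitudes are directions, not
  calibrated effect sizes; power statements transfer to real cohorts
  only qualitatively.
- ΔV_air^f per-subject draws are independent across lobes and are not
  renormalised to sum to one within a subject; the generator emulates
  marginal group differences, not the within-subject simplex
  constraint.
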