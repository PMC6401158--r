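---
title: "Regional salivary-gland dose patterns for xerostomia injury and recovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional salivary-gland dose patterns for xerostomia injury and recovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Xerostomia (dry mouth) is among the most common toxicities of head-and-neck
radiotherapy. Whole-organ mean dose to the parotid glands predicts whether
clinically significant xerostomia (CTCAE grade >= 2) occurs, but the glands
are not radiobiologically homogeneous, and whether a damaged gland *recovers*
may depend on dose to different regions than those that drive the initial
injury. This package implements a regional dose-volume analysis that asks
exactly that: across geometrically standardized subvolumes of the parotid
glands (PG), submandibular glands (SMG) and an oral-cavity (OC) surrogate,
which dose-volume-histogram (DVH) features separate patients who develop
xerostomia within 6 months of radiotherapy ("injury") from those who do not,
and, among the injured, which features separate those whose grade falls
below 2 again within 18 months ("recovery") from those with sustained
toxicity.

# The geometric pipeline

Each patient contributes five co-registered binary masks (left/right PG,
left/right SMG, mandible) and a dose grid in cGy on one voxel lattice. The
package's frame is fixed: x grows right-to-left, y anterior-to-posterior, z
inferior-to-superior; voxels are classified by their center point.

1. **Laterality mapping.** Organs on the primary-tumor side become
   *ipsilateral* (iPG, iSMG), the opposite side *contralateral*.
2. **3 mm expansion.** PGs and SMGs are expanded by a 3 mm isotropic margin
   (organ + shell), capturing setup error and the steep dose gradient at the
   organ edge. The expansion takes every voxel whose center lies within 3 mm
   of a mask voxel center, honoring anisotropic spacing — equivalent to
   thresholding the Euclidean distance transform, implemented as dilation
   with the ellipsoidal structuring element.
3. **Parotid 3 x 3 partition.** Each expanded parotid is cut into
   superior/middle/inferior thirds of equal physical z-extent and, in the
   axial plane, into three 120-degree sectors (medial/anterior/posterior)
   about the whole-gland centroid. Composing both splits yields 9 named
   sectors per parotid that tile the gland voxel-exactly.
4. **Oral-cavity surrogate.** Because the oral cavity is inconsistently
   contoured in practice, a geometric surrogate is built: the region outside
   PG/SMG/mandible bounded superiorly by the lower two thirds of the PGs,
   inferiorly by the inferior SMG extent, anterior/posterior by the mandible
   extents, and laterally by the PG extents; it is split into ipsilateral
   and contralateral halves at the plane midway between the parotid
   centroids.

That gives 18 parotid sectors + 2 SMG + 2 OC halves = **22 subvolumes**. For
each, the empirical DVH yields D10 through D90 in 10% steps: **198 dose
features** per patient. With 16 encoded clinical columns (age > 65, male,
race with white reference, chemotherapy, tumor site with "others" reference,
six structure volumes) the design matrix has **214 predictors**.

## Geometric conventions the package fixes explicitly

Several details of this partition scheme admit more than one reasonable
convention; the package fixes each explicitly and logs them in every run
manifest:

* **Radial sector frame.** Sectors use the whole-gland centroid and one
  angular frame shared by all three SI sections, with wedge boundaries at
  +/-60 degrees about the medial direction and boundary-angle voxels going
  to the first sector in the cyclic order medial -> anterior -> posterior.
  Per-slice centroids would make sectors non-convex for tilted glands, so
  the simpler global frame is used.
* **SI cut ties.** A voxel center exactly on a cut plane is assigned to the
  more inferior section.
* **OC lateral closure.** Superior/inferior/anterior/posterior bounds alone
  leave the surrogate laterally unbounded on a finite grid; the lateral extents of the expanded
  PGs are added as a closure.
* **Midsagittal split.** The OC halves split at the midpoint of the two PG
  centroids rather than the image center, robust to off-center patients.
* **Dx interpolation.** Dx is linear interpolation of the descending voxel
  sample at 0-based rank `x/100 * (N-1)`. At least four quantile
  conventions exist and they differ on small subvolumes; the tests pin this
  one against an independent quantile oracle. No dose binning is applied,
  so there is no bin-width tolerance.

# Outcome definitions

From each patient's longitudinal CTCAE timeline: **injury** is any grade
>= 2 at an assessment within 183 days of the end of radiotherapy;
**recovery**, defined only for the injured, requires the *last* assessment
within 548 days to be below grade 2. Patients with no usable assessment in
the 18-month window are signalled for exclusion rather than raising an
error. The recovery model population is the injured subset only.

# Statistical machinery

## Max-T permutation screening

For each dose feature the observed statistic is the pooled-standard-error
two-sample mean difference ("normalized" t-like statistic), one-sided:
injury tests for higher dose among the injured, recovery for higher dose
among the non-recovered (the direction in which dose is expected to impair
recovery); both directions are exposed as a flag. For each of 1000 label
permutations the maximum statistic across all features is recorded, and the
adjusted p-value of feature *j* is

> p_j = (1 + #{b : max_k T_k^(b) >= T_j}) / (1 + B),

the single-step max-T construction. The +1 correction keeps p > 0 and the
test exact-level. This controls the family-wise error rate under arbitrary
feature correlation — the property the acceptance suite verifies by
simulation. Constant features get T = 0 with a warning rather than NaN.

## Ridge logistic models with nested cross-validation

Both outcome models minimize the penalized negative log-likelihood
`-l(b0, beta) + (lambda/2)||beta||^2` with an unpenalized intercept over all
214 predictors, standardized to mean 0 / sd 1 inside each training set (the
solver is a damped Newton iteration run to gradient norm < 1e-6; with
lambda > 0 the problem is strictly convex). The penalty is selected on a
30-point log-spaced grid over [1e-3, 1e3] (a package default; only the
fact of tuning, not a grid, is prescribed by the method) by 5-fold inner cross-validation maximizing mean
validation AUC, inside 5 outer folds whose held-out scores are pooled into
one AUC per iteration; sensitivity and specificity are read at the
Youden-optimal threshold on the pooled scores (the package's threshold
convention). Means and SDs are reported over 50 resampled
iterations by default. Nothing outside an outer-training set ever touches
standardization, penalty selection, or fitting — the test suite includes a
leakage check. Ties in penalty selection resolve to the stronger penalty.

The final model per outcome is refit on the full model population at the
modal selected penalty, and its dose coefficients are mapped to
`100 * beta_j / max_k |beta_k|` over dose features only — the [-100, 100]
importance scale used for the spatial maps. Clinical coefficients are
reported separately and unnormalized, since the importance map is a
dose-visualization device.

# The synthetic cohort generator

There is no bundled patient data; every stage is exercised against a fully
synthetic cohort with a known dose-to-outcome mechanism.

* **Anatomy.** Parotids are ellipsoids with semi-axes 15 x 20 x 25 mm
  placed lateral-posterior to a mandible arc; submandibular ellipsoids
  (11 x 13 x 14 mm) sit inferior-medial; the default grid is 64 x 64 x 48
  voxels at 2 mm spacing. Per-patient jitter is uniform +/-15% on semi-axes
  and +/-4 mm on centers. Organ masks are made disjoint by construction
  (mandible over PG over SMG). The parotids' inferior extent overlaps the
  SMGs' superior extent in z, so the OC surrogate band is always nonempty.
* **Dose.** A Gaussian kernel peaking at the prescription (7000 cGy
  default) at a target near the medial-inferior aspect of the ipsilateral
  parotid, plus Gaussian noise (sd 150 cGy, truncated at 3 sd, clipped at
  0). The kernel width (30 mm default) is jittered per patient and per axis
  (+/-25%), and the target position by +/-8 mm: without this plan-to-plan
  variability the dose field is a single smooth gradient, all regional
  features collapse onto one latent variable, and no outcome model could be
  learnable — the anisotropic jitter is what makes regional ground-truth
  recovery a meaningful test. Ipsilateral structures always receive
  systematically higher dose than contralateral ones, and pooled voxel
  doses stay within 0-7900 cGy.
* **Clinical covariates** are drawn from marginals typical of a
  large head-and-neck radiotherapy cohort (78% male, 80% white, 68% chemotherapy, oropharynx the
  leading site, ...), independent of dose except through laterality;
  confounding hooks are deliberately deferred.
* **Outcomes.** Injury is Bernoulli in a logistic model whose linear
  predictor is the configured weights on chosen subvolume Dx features
  (divided by 1000, so a unit weight is one log-odds unit per 10 Gy) plus
  optional clinical terms; recovery is drawn analogously among the injured.
  The default weights plant injury in the contralateral middle parotid and
  oral cavity (positive weights) and impaired recovery under dose to the
  superior parotid sectors and contralateral OC (negative weights),
  mirroring the qualitative pattern the method is meant to detect. The
  default intercepts (-3.05 injury, 6.52 recovery) were calibrated once
  against the default feature distribution so that prevalences sit near the
  clinically reported scale of roughly two thirds injured and three
  quarters of those recovering; effect sizes are chosen for testability,
  not biological fidelity.
* **Timelines.** Visits at days 42, 90, 180, 270, 365, 450 and 548, with a
  monotone template: injured patients first reach grade >= 2 at day 42/90/
  180 with probability 0.85/0.10/0.05, recovered patients drop below grade
  2 at a uniformly drawn visit after 180 days, non-recovered patients stay
  at grade >= 2 through day 548, and the never-injured stay at grade 0-1.
  By construction `derive_outcomes()` reproduces the latent labels exactly
  (a tested round-trip), and the 18-month assessment is always present.

What the generator does *not* emulate: realistic gland shapes, IMRT fluence
structure, dose-clinical confounding, assessment noise or dropout. Passing
tests therefore demonstrate that the machinery is correct and that signals
of the planted form are recoverable — not that the pipeline's conclusions
transfer to any real cohort.

# Problem sizes used by the tests and the acceptance script

Simulation-based checks run at sizes chosen to keep the full suite fast
while leaving the conclusions unambiguous:

* family-wise error: 200 global-null datasets (n = 60, 198 features with
  0.9^|i-j| correlation), 500 permutations each;
* planted-signal recovery: 8 replicate cohorts of n = 400 with single-pass
  nested CV on an 8-point penalty grid; null calibration on 3 cohorts of
  n = 250;
* the acceptance script's main study: one cohort of n = 258 (a realistic
  single-institution cohort size), 1000 permutations, nested CV with 5 iterations on a
  10-point grid, plus 6 planted and 3 null replicate cohorts.

The full-scale settings (1000 permutations, 50 CV iterations, the 30-point
grid) remain the package defaults.

# Known limitations

## Importance localization under correlated features

The default outcome mechanism spreads the injury effect over three
subvolumes (contralateral middle-parotid sectors and the contralateral OC).
Because every regional feature is driven by one smooth dose field, a
non-planted structure (typically a submandibular gland, which sits between
the target and the midline) can correlate with the *sum* of the planted
terms more strongly than any single planted feature does. Under the heavy
ridge shrinkage the inner cross-validation tends to select, coefficients
are ranked essentially by marginal association, so the single
largest-importance feature lands in a planted subvolume in only roughly
two thirds of replicate cohorts — the planted regions dominate the top of
the importance map, but the very top feature is not guaranteed to be
planted. This is an identifiability property of correlated regional
dosimetry (and a caution for interpreting single peak features on real
cohorts), not an estimation defect; the corresponding acceptance check is
left failing rather than relaxed.

* Ellipsoid anatomy cannot probe sensitivity of the sector frame to real
  gland curvature; the sector-frame choice is logged so a sensitivity
  analysis on real contours can revisit it.
* The OC surrogate is deliberately coarse; its volume is
  only order-of-magnitude comparable to contoured oral cavities.
* Metric SDs over CV iterations are SDs of iteration means (the convention that yields
  the small SDs such tables usually show); fold-level
  dispersion is larger and available from the per-iteration table.
* The deposited-data reader maps column names case-insensitively but
  assumes the canonical 198 + 16 + 2 schema.
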