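---
title: "Seasonal distribution models with profiled pseudo-absences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal distribution models with profiled pseudo-absences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seasonsdm)
```

# The problem

Migratory crop pests such as the fall armyworm occupy very different parts
of a continent in different months: a winter refuge in the warm south, a
rapid northward expansion through spring and summer, and a contraction in
autumn.  A single year-round species distribution model (SDM) blurs these
phases together and misses the fact that the *drivers* of occurrence change
with the season — minimum temperature limits the winter range but is
irrelevant in mid-summer, while moisture and host-crop availability matter
most during outbreaks.  `seasonsdm` implements a seasonal modelling
pipeline: separate presence/pseudo-absence models per month or season,
backward AIC term selection per model, cross-validated discrimination
metrics, monthly suitability maps and response-curve optima, and a
kernel-density comparison of the occupied environmental niche between an
outbreak and a non-outbreak period.

Because the pipeline has many stochastic stages, the package also contains
a first-class synthetic-data module: a smooth seasonal landscape and a
*virtual species* whose niche is known exactly, so that every downstream
stage can be tested against a ground truth.

# The model

Each seasonal dataset pairs `n` thinned presences (label 1) with `n`
pseudo-absences (label 0).  The occurrence probability is modelled on the
logit scale as a binomial mixed model

$$\mathrm{logit}\, p_{ij} = \beta_0 + \sum_v \beta_{1v} x_{vij} +
\beta_{2v} x_{vij}^2 + u_j,\qquad u_j \sim N(0, \sigma^2_{\mathrm{yr}}),$$

with one linear and one quadratic fixed-effect term per environmental
variable and a random intercept for observation year, estimated by
Laplace-approximated maximum likelihood (`lme4::glmer`).  Quadratic terms
give the bell-shaped responses expected for a thermally limited insect;
the response-curve optimum of a retained variable is the parabola vertex
$-\beta_1/(2\beta_2)$ when the curvature is negative, otherwise the
maximizing end of the evaluated range (flagged as a boundary optimum).

**Boundary fallback.** Balanced presence/pseudo-absence designs in which
each pseudo-absence inherits its presence's year frequently estimate
$\sigma^2_{\mathrm{yr}}$ at the zero boundary.  At that boundary the
Laplace likelihood equals the plain logistic likelihood, so the fit falls
back to `glm` with a `fallback` flag.  The fallback decision is made once
per dataset, on the full model, and held fixed along the whole backward
selection path and the cross-validation refits: mixing the two flavours
within one AIC comparison would penalize mixed candidates by the 2-unit
cost of the variance parameter and bias the selection.

**Backward AIC selection** removes one term at a time, always respecting
marginality (a quadratic term may be dropped while its linear term stays,
never the reverse), choosing at each step the removal with the lowest AIC
and stopping when no removal lowers it.  Selection is performed once per
dataset, before cross-validation; the per-fold refits reuse the selected
terms.  Re-selecting inside every fold would be more conservative, but the
evaluation then scores different models per fold; the chosen convention is
stated in the cross-validation documentation and its optimism is limited
by the balanced design.  Constant covariates (for example a crop-area
layer that is zero throughout the winter bin) are removed before fitting —
they carry no information and make the design matrix rank-deficient — so a
seasonally absent resource simply cannot be retained in that season's
models, which is the ecologically correct outcome.

# Pseudo-absence generation

Two samplers share one geometry: candidate cells lie within a closed
500-km buffer of a presence (the approximate flight range of a strong
migrant), never coincide with a presence cell of the same subset, inherit
the presence's year and month, and are unique per (cell, year, month)
within a replicate set.  Five replicate sets are drawn so that no single
unlucky draw dominates the results.

* **RS (random sampling)** draws one eligible cell per presence uniformly.
* **RSEP (random sampling with environmental profiling)** draws 30
  candidate cells per presence, scores them with a one-class support
  vector machine trained on the z-standardized presence environments, and
  keeps only candidates the classifier labels dissimilar.  One-class SVMs
  emit decision values, not probabilities; the binary similarity used here
  is the sign of the decision function (inlier = similarity 1, outlier =
  similarity 0), which reproduces a "similarity 0" selection rule without
  inventing a calibration.  Classifier defaults are an RBF kernel,
  `nu = 0.1` and `gamma = 1/p` on standardized covariates; all are
  configurable and recorded.  One classifier is trained per season subset,
  because seasonal environmental envelopes differ.  If a presence has no
  dissimilar candidate after 10 redraw rounds the sampler errors — that is
  a property of the landscape (no environmental contrast within reach),
  not a numerical failure.  A fully degenerate case (all presence
  environments identical) admits no boundary at all and is treated as
  "everything similar".

The distance function is Euclidean on planar-km grids (all synthetic
landscapes) and haversine great-circle on geographic grids; nothing else
in the statistics depends on the coordinate system.

# The collinearity screen

Pearson correlation matrices are computed per replicate model dataset,
averaged (arithmetically) within each season bin — winter (Dec–Feb),
spring (Mar–May), and June…November individually, eight bins in all — and
variables are removed iteratively until no pair has an averaged
$|r| \ge 0.8$ in any bin.  Which member of an offending pair to drop is
not an algorithmic question; the screen takes an explicit, user-editable
`drop_priority` list (by default the vapour-pressure and
maximum-temperature layers go first, reflecting which covariates are less
established in armyworm SDMs), with a deterministic mean-|r|/alphabetical
tie-break so the result never depends on column order.

# Evaluation

Discrimination is summarized by the Mann–Whitney AUC (ties counted one
half), computed from midranks and therefore invariant to monotone score
transforms, plus sensitivity and specificity under three thresholding
rules: a fixed 0.5 threshold; the observed-score threshold minimizing
|sensitivity − specificity| (ties toward the lower threshold); and the
largest threshold keeping sensitivity at 0.95.  Cross-validation is
stratified 5-fold; validation folds are scored with population-level
predictions (random intercept at zero) because they may contain years
unseen in training.

# Mapping and optima

Monthly suitability maps are the cellwise inverse-logit of the linear
predictor, averaged across years *and* across the five replicate
sub-models of the month's bin (replicate averaging is on by default and
recorded in the map provenance).  Maps are binned into ten equal
suitability intervals (`floor(10v)` capped at bin 9).  The optima summary
compares, per variable and season bin, the mean response-curve optimum
over the sub-models retaining the variable (OEA), the regional mean of the
variable over all no-data-free cells of the bin's months (TEA), and the
mean value at that bin's presence points (PEA).  Boundary optima are
flagged and still included in OEA.  Partial-dependence curves fix the
other covariates at their training means — the standard choice, recorded
in the output.

# Niche dynamics

The environmental background is every cell within 500 km of any presence,
with covariates taken from each presence's own month and year and pooled
across years.  A correlation-scale PCA of the pooled background defines a
two-axis environment space; occurrence and background densities for the
outbreak (June–September) and non-outbreak (remaining months) periods are
Gaussian-kernel smoothed on a 100 × 100 grid spanning the pooled
background ranges, with normal-reference (Silverman-type) bandwidths.
Within the analog region — cells where both periods' background densities
are positive (operationally, above 0.1% of each grid's maximum, since a
Gaussian kernel never reaches exact zero) — each period's occupied niche
is binarized by dropping the thinnest 5% of its occurrence-density mass,
a configurable stabilizer for the area ratios.  With reference set A
(non-outbreak) and comparison set B (outbreak):

* stability = |A ∩ B| / |A|,
* expansion = |A \\ B| / |A| (so stability + expansion = 1 exactly),
* unfilling = |B \\ A| / |B|.

The generic API takes (reference, comparison); the orientation above is
the one used throughout the package.  Occurrence density is reported
uncorrected by availability (availability is plotted separately by
`variable_occupancy()`, with both curves rescaled to a maximum of 1).
The PCA is calibrated on the pooled background of both periods — a shared
space is required for the overlap arithmetic to be meaningful.

# The synthetic landscape and virtual species

`generate_env_stack()` builds monthly layers for MINTEMP, MAXTEMP,
PRECIPI, EVAPO, VAPOR, NDVI and RFD on a planar grid.  Each base variable
is a sinusoid of month (peaking in July by default) plus a south–north
gradient, a variable-specific smooth spatial field, and Gaussian noise.
The defaults describe a temperate region 600 km on a side (60 × 60 cells
of 10 km) over three years: minimum temperature with an 11 °C seasonal
amplitude and a −2 °C/100 km latitudinal gradient, NDVI clamped to [0, 1],
and a May–October growing season for the rainfed-corn layer, which is
exactly zero outside it and stored for a single reference year (as
cultivation datasets typically are).  MAXTEMP and VAPOR are *derived*
variables: linear functions of MINTEMP and EVAPO with noise calibrated so
the per-month sample correlation matches a target (0.9 by default), which
is what the collinearity screen must detect.  The variable-specific
spatial fields keep all other cross-correlations moderate, so exactly the
two engineered pairs exceed the 0.8 threshold.

The virtual species has logistic suitability with quadratic (bell-shaped)
responses: by default a thermal optimum of 18 °C (niche breadth 3.5 °C)
and an NDVI optimum of 0.75 (breadth 0.18), with `intercept` parameterized
as the log-odds *at the joint optimum* (0.92 peak suitability by default).
Occurrences are drawn per (year, month) without replacement with
probability proportional to suitability, which yields thinned records by
construction and concentrates presences near the optimum.  An optional
seasonal shift moves selected optima during chosen months, emulating the
phenotypic plasticity that distinguishes a *true* niche shift from a mere
availability change.  The species deliberately uses the same functional
family the models fit, so parameter recovery is a well-posed test; a
model-misspecification mode is a possible extension, not a default.

What the generator does **not** emulate: spatially autocorrelated sampling
effort, observation bias toward accessible areas, interannual climate
trends, dispersal limitation and source–sink dynamics.  Passing tests on
this landscape therefore demonstrate the correctness of the machinery and
the qualitative behaviour of the estimators, not performance on biased
real-world occurrence compilations.

# Numerical choices

* `glmer` runs with `calc.derivs = FALSE` (the post-fit Hessian is not
  needed for AIC selection); non-convergence is flagged, never silently
  ignored.  Perfect separation — common with profiled absences — is
  expected and only flagged when the IRLS iterations fail.
* The zero-variance boundary is declared below 1e-8.
* Stepwise adopts a removal only if it lowers AIC by more than 1e-8, so
  ties keep the larger model and the path terminates.
* Cell membership is half-open (boundary points belong to the lower-left
  cell); a point at exactly the buffer radius is inside (closed ball).
* Suitability bins are `[i/10, (i+1)/10)` with the top bin closed at 1.
* Kernel grids clip out-of-window scores onto the window with a warning;
  an all-constant axis falls back to a range-based bandwidth floor.

# Problem sizes

The shipped tests exercise most operations on a 24 × 24 cell, two-year
landscape with ~25 records per month, and the end-to-end checks on the
default 60 × 60 cell, three-year landscape with ~150 thinned presences per
month — the scale at which the full 2-method × 5-set × 8-bin design (80
models, with stratified 5-fold cross-validation) completes in a few
minutes on a single CPU.  `scripts/acceptance.R` re-runs the full design
and the recovery and null simulations at that same scale.

# Known limitations

* Term selection once per dataset (not per CV fold) gives mildly
  optimistic validation metrics; the shuffled-label null check confirms
  the pipeline's honesty at chance level.
* The one-class SVM's binary similarity discards the margin information in
  the decision values; a calibrated similarity would allow graded
  profiling but has no reference behaviour to validate against.
* Niche indices depend on the occupied-niche binarization; the 5%
  density-mass rule is a stabilizer, and comparisons across studies should
  use the same rule.
* Raster I/O is plain text (per-layer CSV plus a JSON grid header) and
  in-memory matrices; the statistics are format-agnostic, and users with
  GeoTIFF/NetCDF sources can bridge with any raster reader that yields
  matrices.
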