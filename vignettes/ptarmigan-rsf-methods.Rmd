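---
title: "Methods: detection-adjusted resource selection for willow ptarmigan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection-adjusted resource selection for willow ptarmigan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptarmiganRSF)
```

## The problem

Willow ptarmigan (*Lagopus lagopus*) in Norway are surveyed each August by a
national line-transect distance-sampling programme: dog handlers walk
systematically spaced straight transects (500-m map-grid interval) and record
each bird encounter with its perpendicular distance to the line. This package
implements a complete used--available habitat-selection analysis on such
data, together with a synthetic-data generator that reproduces the
statistical structure of the surveys so every stage of the pipeline can be
tested end to end with a known ground truth.

The analysis estimates an exponential resource selection function (RSF)

$$w(x) = \exp(\beta_1 x_1 + \beta_2 x_2 + \dots + \beta_n x_n),$$

a quantity proportional to the probability that a location with covariates
$x$ is selected. The coefficients are estimated by a mixed-effects logistic
regression contrasting used locations (observations) with available
locations (random points within the surveyed strips), with a random intercept
per survey area. The random intercepts absorb between-area density
differences -- the number of available points is driven by effort, not by
local abundance, so areas with more birds would otherwise bias the
intercept -- while the fixed effects stay marginal and portable, which is
what raster-wide prediction needs. Predictions deliberately exclude both the
fixed intercept (it reflects the used:available sampling ratio, not
selection) and the random intercepts.

## Covariates

Four predictors enter the candidate models:

* **Vegetation class.** A 25-code categorical vegetation raster (30-m
  resolution) is collapsed to 16 modelling classes: the five lowland
  (coniferous-dominated) forest codes are pooled, the three sub-alpine birch
  forest codes, three bog/swamp codes and nine alpine codes keep their own
  classes, and the remaining codes (water, agriculture, built-up,
  unclassified) are non-habitat, excluded from both the used and the
  available side. "Exposed alpine ridges" is the reference class.
* **Deviation from the timberline** (m): point elevation minus the regional
  empirical timberline (RET) elevation, 0 at the timberline. This replaces
  raw elevation, which is confounded with the strong latitudinal bioclimatic
  gradient.
* **Slope** (degrees), derived from the elevation raster by Horn's
  eight-neighbour finite differences.
* **Aspect**, a circular variable, as either a five-level categorical
  (north 315--45°, east 45--135°, south 135--225°, west 225--315°, flat) or
  as the continuous exposures $N = \cos r$, $E = \sin r$ with
  $r = \mathrm{aspect} \cdot 2\pi/360$.

Continuous terms are standardized to zero mean and unit sample standard
deviation on the combined used + available modelling set; the parameters are
stored with every fit so map prediction scales identically. Quadratic terms
are squares of the standardized value and are not re-standardized -- the
simplest convention that keeps the quadratic optimum
$-\beta_1 / (2\beta_2)$ well-defined on the standardized scale and
back-transformable through the stored parameters.

Two boundary conventions are made explicit because the underlying rules
conflate them: "flat" means slope at or below a configurable threshold
(default 0, exactly flat; the pipeline default is 1° so smooth synthetic
terrain has a non-empty flat class, as noisy real elevation models do), and
the aspect categories are half-open intervals $[lo, hi)$ with north wrapping.

## Quality control

Two filters are applied to observations, in order, with every step logged in
an accounting ledger:

1. observations whose geometric (computed) perpendicular distance exceeds
   the 200-m line-buffer are removed (boundary inclusive: exactly 200 m
   stays);
2. observations whose reported distance deviates from the computed one by
   strictly more than 30 m -- the vegetation-map resolution -- are removed.

Observations are only ever kept or removed, never moved. Surveys left
without observations are dropped from the used side, but their transects
still generate available locations: availability is a property of effort,
not of success.

## Detection-adjusted availability

Detection probability in line-transect sampling declines with perpendicular
distance $d$; uniformly random available points would therefore be
over-represented far from the line *relative to what the observations can
see*. The four-step procedure corrects this:

1. generate available candidates uniformly in each survey's line-buffer,
   3 per km of effort (a 4-km transect surveyed in 4 years gives
   $16 \times 3 = 48$ points; fractional expectations round to nearest, ties
   away from zero);
2. fit a half-normal detection function
   $g(d) = \exp(-d^2 / (2\sigma^2))$ to the used-location distances by
   maximum likelihood. Untruncated, $\hat\sigma = \sqrt{\sum d_i^2 / n}$ in
   closed form; the pipeline fits the likelihood normalized on the 200-m
   buffer (distances beyond it were discarded upstream), which differs
   negligibly when the buffer is more than about $3\sigma$;
3. assign each candidate $O_i = g(d_i) \in (0, 1]$;
4. keep the candidate iff an independent uniform draw $P_i < O_i$ (strict).

After thinning, available distances follow the same truncated half-normal
distribution as the observations, so the used--available contrast is driven
by habitat, not by visibility. One pooled detection function is the default
(per-area fitting is a config option); RNG substreams are derived per
survey, so adding a survey never perturbs the points of the others.

## Model selection and validation

Candidate models always contain vegetation class. The default grid crosses
timberline deviation \{absent, linear, linear + quadratic\} with slope
\{absent, linear + quadratic\} and aspect \{absent, categorical, N--S,
N--S + E--W\} -- 24 combinations including the vegetation-only model and the
four structures that dominate selection in the real data. The published
model set is not enumerated beyond its top four members, so the grid is
configurable; this default was fixed once as the smallest natural grid
containing those structures.

Fitting maximizes the Laplace-approximated marginal likelihood (lme4's
`glmer`), validated in the test suite against an adaptive-quadrature oracle
on small data and against the plain logistic MLE when the between-area
variance is zero. `K` counts fixed effects plus one for the random-intercept
variance, so the parsimonious structure (intercept + 15 vegetation dummies +
4 continuous terms + variance) has `K = 21`. Selection uses AIC with the
parsimony rule: models within 2 AIC units are equivalent and the smallest
`K` wins, ties broken by lower AIC.

Validation is Boyce-style: 5-fold cross-validation (folds stratified so each
fold's used:available ratio tracks the global one -- the source protocol
partitions "the dataset" without detail, and stratification stabilizes small
folds), 10-quantile binning of the test-set predictions (all test points by
default; available-only is a switch, since the source is ambiguous), used
counts per bin, and the Spearman rank correlation between bin rank and
count, with the t-approximation p-value conventional for 10 ranks (exact
permutation available for small n). The same machinery runs leave-one-region-out
over user-supplied geographical blocks, and an area-adjusted variant divides
per-bin counts of an independent point set by the bin's areal availability.

Mapping evaluates $w(x)$ in every raster cell, scales by the map maximum so
values lie in $(0, 1]$, and assigns bins with the same quantile cut points
used in cross-validation, computed on the modelling sample and applied
unchanged (binning is done on the unscaled RSF scale, so the map scaling
cannot shift cells across the fitted bin boundaries). Non-habitat cells carry
no value. Coverage tables report each bin's percentage of the mapped domain,
of the surveyed buffers, and of the used locations.

## The synthetic-data generator

The generator is first-class, tested code; it emulates exactly the structure
the estimator assumes:

* **Landscape.** Smoothed-Gaussian-field elevation and timberline rasters on
  a 30-m planar (UTM-like) grid, and a categorical vegetation raster built
  by thresholding a smoothed uniform field at cumulative class weights --
  exact expected shares with spatial patchiness. Default terrain parameters
  were chosen so slope (median ≈ 4.5°) and timberline deviation (SD ≈ 100 m)
  match the survey data's printed summaries. The default composition
  mirrors the availability shares of the survey data; a balanced
  composition is used by the recovery experiment (below).
* **Transects.** Parallel lines at 500-m spacing following the map grid,
  partitioned into rectangular survey areas, surveyed once per year over
  four years.
* **Observations.** Candidate points uniform in a 240-m strip around each
  line are accepted with probability
  $\propto \exp(\beta' x + b_a) \cdot g(d)$: habitat selection with the
  published coefficient estimates as the default truth (converted to the
  raw scale with the assumed dispersions above), a per-area log-density
  intercept $b_a \sim N(0, 0.5^2)$, and half-normal detection with
  $\sigma = 60$ m (no detection scale is published; 60 m is a plausible
  pointing-dog scale fixed once). Reported distances get Gaussian error
  (SD 20 m, folded at zero), so the deviation filter removes ~13% -- the
  order of the real data's 16.6% -- and the 240-m candidate strip exercises
  the buffer filter. The candidate intensity is normalized per area by the
  buffer-average acceptance, so expected counts per km are controllable
  from config (default 0.55 recorded observations per km of effort, the
  survey programme's realized rate).

What the generator does **not** emulate: covey/brood clustering (real
observations are flock centroids, so effective sample sizes are smaller
than point counts suggest), sex/age structure, observer or dog behaviour,
correlation between vegetation and elevation, multi-resolution raster
products, and real geodesy. Passing tests therefore show the estimator is
correct under its own assumptions at survey-like scale -- not that those
assumptions hold for any particular field dataset.

## The recovery experiment

`recovery_experiment()` replays the whole pipeline -- simulate, QC,
availability, covariates, fit, optionally cross-validate -- against a known
truth and summarizes per-term bias, RMSE and 95% Wald CI coverage. Truth and
estimates are compared on the standardized scale actually fitted in each
replicate, an exact linear reparameterization of the raw-scale truth (for
$z = (x - m)/s$, the raw pair $(t_1, t_2)$ maps to
$s(t_1 + 2 t_2 m)$ and $t_2 s^2$). One landscape and layout is drawn per
experiment and replicates redraw area intercepts, observations and available
points: the logistic estimand is conditional on covariates, so this isolates
exactly the sampling variability the model claims to handle.

Two design choices deserve a note:

* The default experiment size (a 25.5 × 18.6 km landscape, 37 transects,
  four years, ~2000 used locations after QC) reproduces the survey
  programme's effort-to-observation ratio at desk scale.
* The experiment uses a *balanced* vegetation composition. Under the
  survey-like composition the reference class holds ~0.5% of used locations
  (~10 per replicate), so a 50-replicate mean bias for reference contrasts
  has Monte-Carlo error of the same order as the effects of interest; the
  balanced composition keeps that error well below them. This was fixed at
  design time from a power calculation, not adjusted afterwards.

## Numerical choices

* GLMM optimizer: nloptwrap with the derivative-based convergence check
  disabled (identical log-likelihood to bobyqa on reference fits,
  substantially faster); rank-deficient designs and absent factor levels
  are rejected with named errors rather than silently dropped.
* Half-normal fitting requires at least two strictly positive distances;
  the truncated fit uses 1-D `optimize` to tolerance 1e-10 and the
  untruncated path verifies the optimizer against the closed form.
* Quantile cut points use R's default (type 7) empirical quantiles; bin
  assignment is `findInterval`, monotone with half-open intervals, and
  heavy ties that collapse cut points warn and leave degenerate bins.
* Buffer membership and the deviation rule follow the stated conventions
  literally: ≤ 200 m inside, > 30 m removed.
* Rasters are plain matrices with grid metadata; I/O uses a six-line-header
  plain-text grid format, and all geometry is Euclidean in metres.

## Problem sizes used by the test suite

The packaged checks run the recovery experiment at 50 replicates of ~2000
used locations, the null cross-validation sweep at 50 replicates of ~500
used locations on a 9 × 9 km landscape, and the remaining property checks
on small fixtures; these sizes make the Monte-Carlo error of each summary
small relative to its acceptance band while keeping a full run inside a
coffee break.

## Known limitations

* The exponential RSF is relative: absolute selection probabilities and
  densities are out of scope, as are functional responses (availability-
  dependent coefficients) and region-specific models.
* The half-normal is the only detection family; hazard-rate or
  covariate-dependent detection would need a different availability step.
* Aspect exposures are standardized after the cos/sin transform (they are
  the model terms); whether the source standardized before or after is not
  stated.
* With very small samples the 16-level vegetation factor can lose levels
  inside cross-validation folds; affected folds are reported as missing
  with a warning rather than refitted.
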