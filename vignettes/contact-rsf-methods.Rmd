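---
title: "Modeling the landscape drivers of animal contact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the landscape drivers of animal contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Direct contact between animals — two individuals co-located at the same
time — structures disease transmission, social organization, and
competition. A long-standing shortcut treats the spatial overlap of
individual habitat selection as a proxy for where contacts happen. This
package implements a framework that tests that shortcut instead of
assuming it: it fits a *contact resource selection function*
(contact-RSF), a used-available logistic model in which "used" points
are locations where a dyad actually made contact and "available" points
are locations the dyad visited without contact inside their shared
range, and compares the aggregated contact-RSF against the aggregated
individual-level RSF of the same animals.

The pipeline is: continuous-time movement models fitted per animal →
trajectories discretized to a regular 5-minute grid → direct contacts
detected as simultaneous co-locations within a 10 m buffer → dyads
classified as within-group, between-group, or temporarily merged →
between-group pairs with more than 10 contacts analyzed → individual
RSFs (30 available points per used point inside the 95% kernel home
range) → model structure selected by cumulative-log-likelihood AIC →
pair-level contact RSFs with the same structure → weighted population
averages → coefficient and prediction-surface comparison.

## Movement models

Four Gaussian-process families are supported for position: IID
(uncorrelated positions about a mean), OU (mean-reverting with position
timescale $\tau_p$, i.e. range residency), IOU (integrated OU: correlated
velocity with timescale $\tau_v$, no home-range attractor), and OUF (OU
foraging: both timescales, $\tau_p > \tau_v$). The x and y coordinates
are independent with shared timescales and one isotropic spatial
variance $\sigma^2$ — the simplest model consistent with the workflow;
anisotropy is out of scope.

Likelihoods are exact linear-Gaussian state-space likelihoods evaluated
by a Kalman filter that handles irregular sampling gaps; the filter's
innovation loop is compiled (C++) because it sits inside the optimizer.
Numerical choices:

* positive parameters are optimized on the log scale with Nelder-Mead
  and 3 multi-start restarts (initial $\tau_p$ spread over a decade),
  relative tolerance 1e-10;
* the mean location is profiled out by generalized least squares inside
  each likelihood evaluation, which removes two dimensions from the
  search;
* the OUF parameterization is symmetric in $(\tau_p,\tau_v)$, so the
  optimizer runs unconstrained and the larger estimate is reported as
  $\tau_p$; the confluent case $\tau_p = \tau_v$ is perturbed by 1e-5
  relative;
* the IOU likelihood is defined conditionally on the first fix (diffuse
  position prior), the standard treatment of nonstationary movement
  models; its parameter count reflects the conditioning (no mean
  parameters);
* measurement-error variance is fixed when a per-fix error SD is known
  (collar error is known in the systems this framework targets) and
  profiled as a free parameter otherwise. Under IID the error variance
  is not separately identifiable and is absorbed into $\sigma^2$.

Family selection minimizes AIC $= 2k - 2\log L$; ties below 1e-9 go to
the smaller family. Interpolation is the conditional mean (fixed-interval
Kalman smoother, equivalently kriging) on a regular grid anchored at the
first fix's timestamp rounded *down* to the interval. Because the anchor
is an epoch-based lattice, grids of different animals interpolated at the
same interval align automatically, which is what makes simultaneous
contact detection well defined. With zero measurement error the smoother
reproduces observations exactly at observation times. No maximum-gap cap
is applied before interpolation by default; long gaps can be handled by
clipping tracks beforehand.

## Contacts and dyad classification

A direct contact is one shared grid timestamp with Euclidean distance at
or below the buffer (10 m by default, matching reported collar error of
5-10 m). The comparison is inclusive; each co-located timestamp counts
as one contact (no merging into episodes — reported per-pair counts in
the target systems are in the hundreds, consistent with per-fix
counting); and the contact location is the midpoint of the two
simultaneous positions, an unbiased single point for covariate
extraction.

Female-male and male-male dyads are assumed between-group (solitary
adult males in the target systems). Female-female dyads are classified
from weekly core-area overlap: per ISO calendar week, a 50% kernel
isopleth per animal; the overlap index is
area$(A \cap B)/\min(\mathrm{area}(A), \mathrm{area}(B))$, bounded in
[0, 1]. The weekly series is aggregated by its mean over the tracking
period: above 0.5 the pair is within-group; a run of *more than* 12
consecutive above-threshold weeks inside an otherwise below-threshold
record marks a temporary merge (a season in the same group) and those
weeks are excluded from the pair's analysis window; otherwise the pair
is between-group. The choices of mean aggregation, the 50% core
isopleth, and the overlap index are design decisions where the method's
description is silent; all are configurable.

## Home ranges

The utilization distribution is a Gaussian-kernel density evaluated at
the cell centers of the 30 m analysis grid (one coordinate system end to
end) and renormalized to integrate to 1 over the grid. The reference
bandwidth is $\hat\sigma_j n^{-1/6}$ per coordinate. Isopleths are
defined by cumulative probability mass of ranked cells — the level-q
region is the smallest set of highest-density cells reaching mass q —
which is deterministic and nests across levels by construction. All
"polygon" operations (intersection, area, containment, uniform
sampling) are cell-mask operations on that grid; masks export to
GeoJSON. Because no GeoTIFF library is part of the supported stack,
rasters are serialized as ESRI ASCII grids (plain text) plus a JSON
manifest.

## The used-available designs

*Individual.* Used points are the interpolated fixes within the pair's
joint tracking window; availability is 30 uniform points per used point
inside the individual's 95% isopleth for that window ("individual
availability at pair level"), drawn by seeded rejection sampling from
the mask's bounding box. Each available point inherits the date of its
paired used point so daily covariates keep the temporal distribution of
use. Continuous covariates are standardized per design (mean/SD stored
for prediction); binary covariates are not. When one individual appears
in several pairs, its pair-window designs are stacked into one
per-individual design before fitting, so there is one coefficient
vector per individual and the Murtaugh weight can count its pair
multiplicity.

*Contact.* Used points are the pair's contact midpoints; candidate
available points are both members' interpolated fixes inside the dyad's
95% overlap region at non-contact timestamps (a contact timestamp
removes both animals' fixes — those fixes *are* the contact), capped by
seeded subsampling at 30 per used point, never upsampled. Available
rows use their own fix dates, since they are real fixes.

Collinearity is screened on the pooled individual design: while any
covariate pair has $|r| \ge 0.6$, the lower-priority member of the
worst pair is dropped (priority defaults to the stack's layer order).
The contact models inherit the screened, top-selected individual
structure — by design, the individual model is the null reference.

Separation handling: designs with rare binary features at 1:30 ratios
can separate; if the ML fit fails to converge or any $|\hat\beta| > 15$,
an L2-penalized refit ($\lambda = 10^{-4}$, intercept unpenalized) is
used and flagged.

## Aggregation, validation, comparison

Population coefficients are two-stage (Murtaugh) weighted means: for
individuals, weight $\propto m_i n_i$ (pair multiplicity × used-point
count); for pairs, weight $\propto$ the pair's contact count. Where the exact functional
form of two-stage weighting is a free choice, the product form is this
package's, with the weights exposed in the result (sum and
inverse-variance forms are natural alternatives). $SE(\bar\beta) = \sqrt{\sum w_i^2 SE_i^2}$ and 95% normal
intervals.

Cross-validation is fivefold on used points only — the statistic is a
used-point frequency against a fixed availability baseline
(Boyce-style area-adjusted frequency): per fold, scores
$w = e^{\beta x}$ are binned into 10 equal-interval bins of the
available-score range, the withheld-used/available count ratio is
computed per bin (zero-available bins dropped), and the Spearman rank
correlation of bin rank versus adjusted frequency is reported.

Prediction surfaces are $w = e^{\bar\beta x}$ per cell (no intercept),
min-max rescaled to [0, 1]; an all-constant surface maps to 0.5. The
comparison report contains per-covariate differences (contact minus
individual) with joint CIs assuming independence, a three-level sign
category per coefficient (+/0/− by whether its own CI excludes zero)
whose agreement defines sign concordance, and Spearman/Pearson
correlations of the two surfaces over the shared extent.

## The synthetic world

No public telemetry accompanies the method, so the package carries a
generator whose defaults state the world the framework describes:
multiple social groups moving as OU processes (exact transition sampling
at 1-minute internal steps, thinned to a 10-minute fix schedule with 2%
dropout — so interpolation tests run on genuine subsamples), isotropic
5 m GPS error (reported collar errors are 5-10 m), a 30 m covariate
stack with the standard layer semantics (binary wetland/water/road/
fence-or-trail/ditch and daily food, fractional tree canopy, daily NDVI,
spatially constant daily weather — the weather products the method uses
are far coarser than a site), and between-group co-locations created by
steering one animal from each of two groups to the same resource cell at
scheduled epochs (attractor relocation with a tight visit regime),
with the target cell drawn by log-linear attraction weights over the
day's active food sites plus one water and one linear-feature site.
Ground truth — group membership, the visit schedule, and every realized
within-buffer co-location minute — is recorded, so the contact detector
can be checked against a superset oracle and the recovered selection
coefficients against the steering weights.

What the generator does *not* emulate: mating-driven contacts (the
method's sources explicitly lack the data to model them), cattle-density
covariates beyond an optional constant layer, real geography or
reprojection, and fission-fusion within groups. A green test therefore
establishes that the statistical machinery recovers the stated
resource-driven contact process, not that it captures every social
mechanism in a field system.

### The dissociation scenario

The framework's headline pattern — the features driving contact differ
from those driving space use — is reproduced by a dedicated scenario:
two groups with heavily overlapping OU ranges and *no* steering, food
laid out as a regular provisioning lattice (one bait cell per 2×2
block, emulating grid-deployed baiting), and contact events drawn from
the dyad's visited locations with odds ×3 on food cells. Movement
ignores food entirely, so individual selection for food is null by
construction; contact, given presence, prefers food. Two design
subtleties matter for honest calibration of the null:

* a regular lattice is spatially balanced — any smooth utilization
  density samples it at its areal fraction — whereas spatially random
  food assignment leaves a persistent per-replicate imbalance between
  the cells an animal happens to concentrate in and the availability
  mask (cell-level pseudo-replication) that makes a nominal 95% CI
  anticonservative;
* a short position timescale (5 min against 10-min fixes) makes fixes
  nearly independent so logistic standard errors are calibrated, and a
  home range spanning many lattice periods (σ = 200 m against 30 m
  cells) keeps the isopleth-boundary parity imbalance small.

With those choices the individual food coefficient's CI covers zero at
its nominal rate and the contact coefficient recovers $\ln 3 \approx
1.10$; across 20 seeded replicates both conditions hold in 20/20 runs
on this package's test seeds.

## Reproducibility

All randomness flows from one root seed through named substreams per
stage, so stages are individually re-runnable with identical results.
The pipeline reloads every artifact it writes (CSV tracks at fixed
microdecimal precision, text rasters, JSON models) before using it
downstream, which makes a resumed run byte-identical to an uninterrupted
one — the determinism and stage-composition tests assert equality of
artifact hashes, not approximate agreement. Timestamps are UTC ISO-8601
throughout; coordinates are projected meters (no lon/lat ingestion).

## Known limitations

* Availability designs inherit the usual sensitivity of used-available
  inference to the availability definition; the contact-RSF availability
  (overlap region) deliberately differs in scale from the individual
  availability (full range), mirroring the framework it implements.
* Logistic SEs treat fixes as independent; strongly autocorrelated
  interpolated tracks (5-min grids of slow animals) make them
  anticonservative. The two-stage aggregation mitigates but does not
  remove this.
* The KDE is truncated to the analysis grid and renormalized; ranges
  extending beyond the mapped extent lose that mass, and fixes beyond
  the extent are dropped from designs because covariates are undefined
  there.
* Indirect (temporally lagged) contact is out of scope.
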