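---
title: "Models and methods behind dictydev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dictydev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictydev)
```

dictydev compares clonal and chimeric multicellular development in
*Dictyostelium discoideum* along four axes: differential expression at
the tight-aggregate stage, functional enrichment of the resulting gene
lists, developmental staging against a reference time course, and
shape/splitting dynamics of aggregates in photographic time series.
This vignette explains the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Differential expression

### Model

Counts $K_{gs}$ for gene $g$ in library $s$ are modelled as negative
binomial with mean $\mu_{gs} = s_s q_{gs}$ and variance
$\mu + \alpha_g \mu^2$, where $s_s$ is a library size factor and

$$\log_2 q_{gs} = \beta^{batch}_{g,b(s)} + \beta^{pair}_{g,p(s)} +
\beta^{cond}_g \cdot 1[\text{s is chimeric}].$$

Dummy coding uses the alphabetically first level of batch and pair as
reference, and *clonal* as the condition reference, so
$\beta^{cond}_g > 0$ means chimera-biased up-regulation. Because the
design contains pair but not strain, contrasting the conditions
compares each pair's chimeric library against its two clonal libraries
jointly — the paired-trio logic of the experimental design.

Per gene, the GLM is fitted by iteratively reweighted least squares
with working weights $W = \mu/(1 + \alpha\mu)$, the dispersion held
fixed, offsets $\log s_s$, a relative deviance tolerance of $10^{-8}$
and at most 100 iterations; non-convergent genes are flagged and
excluded from testing. The Wald statistic
$\beta^{cond}_g / \mathrm{SE}$ is referred to the standard normal and
BH-adjusted across tested genes. No shrinkage is applied to the
reported log2 fold changes.

### Normalization and filtering

Size factors are median-of-ratios: the median, over genes covered in
every library, of each library's ratio to the gene's geometric mean.
This estimator assumes most genes are not differentially expressed;
with strongly *asymmetric* differential expression it absorbs part of
the effect into the size factors (composition bias). The synthetic
recovery tests therefore plant balanced ±1 effects; with 15% of genes
shifted in a single direction we measure roughly 0.13 log2 units of
attenuation, which users should keep in mind for heavily one-sided
contrasts.

Low-expression filtering retains genes whose mean normalized count is
*strictly greater than* 4 reads per library (the threshold is
configurable; 4 is the default used throughout).

### Dispersion estimation

A deliberately simple two-step estimator: (1) per-gene
method-of-moments from the design-model residual variance of
normalized counts, $\hat\alpha_g = (s^2_g - \bar\mu_g \xi)/\bar\mu_g^2$
with $\xi$ the mean reciprocal size factor; (2) geometric-mean
shrinkage (weight 0.5 by default) toward a fitted trend
$\alpha_{tr}(\mu) = a_1/\mu + a_0$, with a floor of $10^{-8}$.
This is not the full empirical-Bayes machinery of dedicated DE
packages — there is no Cox-Reid adjustment and no outlier handling —
and it is validated by recovery (a planted $\alpha = 0.1$ is
re-estimated with median inside $[0.07, 0.13]$ on 2,000 genes) rather
than by numerical equality to any other implementation. An
installed-package cross-check in the test suite confirms that the
condition log2FC estimates correlate above 0.98 with an independent NB
GLM fitter on shared data.

### Regularized log transform

For distance-based staging the counts are transformed to
$\log_2(K/s + 0.5)$ and each gene's per-sample deviations from a
fitted mean are shrunk by $\lambda_g = \bar\mu_g/(\bar\mu_g + k)$,
where $k$ defaults to the $a_1$ coefficient of the dispersion trend —
the count scale below which sampling noise dominates log fold changes.
With `blind = FALSE` the fitted mean is the design-model fit, so known
structure is not shrunk away. The transform is monotone in the count
for a fixed gene, exact for high-count genes, and invariant to jointly
rescaling counts and size factors.

## Gene-set analysis

Annotation hygiene precedes everything: `NOT`-qualified rows, `ND`
evidence, and `IEA` evidence sourced from InterPro or HAMAP are
removed (electronic annotations from other sources are kept). Gene
sets are then propagated up the `is_a` DAG so every gene counts toward
all ancestors of its direct terms.

The enrichment test is the upper-tail hypergeometric
$P(X \ge \text{observed})$ with the universe partitioned by term
membership; the expected count is
$|\text{selected}| \cdot \text{term size}/|\text{universe}|$. The
universe is the set of genes tested for differential expression,
restricted to annotated genes for the hypergeometric margins (both
sizes are reported as attributes). The conditional procedure visits
terms children-before-parents and, whenever a term is significant at
$\alpha$ (0.05 by default, matching the conditioning convention of the
standard conditional-GO implementations), removes its genes from every
ancestor's list before the ancestor is tested. On a flat hierarchy, or
at $\alpha = 0$, this reduces exactly to the unconditional test — both
facts are asserted in the test suite against brute-force oracles.

For term-level expression summaries each gene contributes only at its
most specific annotated term(s): a term is dropped for a gene when one
of its descendants also annotates that gene. A gene with two
incomparable most-specific terms contributes to both, since no rule
prefers either and dropping one would bias the term medians. Terms
with 13–399 contributing members are reported. Because the overall
median of these term medians and the median over all contributing
genes are both natural "overall" summaries, the function reports both.

The permutation test for a candidate set draws $|set|$ log2FC values
without replacement from the full table, 10,000 times by default, and
reports the fraction of permutation means at or beyond the observed
mean (`<=` for direction "lesser"). There is no $+1$ correction — the
estimate is the plain relative frequency — so $p = 0$ is possible at
finite permutation counts and the resolution is $1/n_{perm}$.

## Developmental staging

Each query sample's transcriptome distance profile is the mean
Euclidean distance, on the regularized-log scale over a chosen gene
subset (typically the timing genes), to the replicates of each
reference time point. Because reference series are often sampled
unevenly, the time axis is the ordinal collection index ("hr"): the
first time point is 1, the twelfth is 12, regardless of label spacing.

Distance is regressed on hr with thin-plate regression splines, a
parametric condition offset, and a pair-level random intercept,
fitted by REML via mgcv:

```
distance ~ condition + s(hr, by = condition) + s(pair, bs = "re")
```

against the shared-smooth alternative `s(hr)`. mgcv is the canonical,
exhaustively tested implementation of exactly this model class, so the
package delegates the fit to it and keeps the staging-specific layers
— profile construction, recoding, AICc comparison, and the
finite-difference minimum finder — as its own code. AICc is computed
with the total effective degrees of freedom (including the scale) as
the parameter count, because at 19 time points the small-sample
correction is not negligible. Model choice requires both a lower AICc
for the per-condition model *and* an approximate F test (deviance
difference over edf difference, scaled by the richer model's residual
variance) to pass at $\alpha = 0.05$; otherwise the simpler shared
smooth is kept.

Local minima are found exactly as the staging procedure prescribes:
the fitted curve is evaluated on a step-0.1 grid extended one step
beyond each end of the observed range, first derivatives are slopes
between successive steps, second derivatives are changes in slope, and
a minimum is a negative-to-positive zero crossing of the first
derivative with positive second derivative, located by linear
interpolation. Minima outside the observed hr range are discarded.
The random intercept is excluded from prediction so the curve is the
population-level fit. End-to-end, query samples planted at reference
time 11 are recovered within ±0.5 hr units in over 90% of simulation
seeds at the default noise level.

The collection-timing statistic $(C - E)/(L - E)$ places a chimera's
collection time between the earlier ($E$) and later ($L$) of its two
parent strains; 0 means collected with the earlier strain, 1 with the
later, and values outside $[0, 1]$ are legitimate (a chimera collected
before both parents is negative). It is reported rounded to two
decimals alongside the raw value, and is undefined (flagged, not an
error) when the parents were collected simultaneously.

## Phenotype analysis

Aggregates are measured from integer label masks. The perimeter is
estimated by Moore-neighbour contour tracing with weighted boundary
steps (0.948 per axial, 1.340 per diagonal step), which removes most
of the staircase overestimate of the raw chain length; a rasterized
disk of radius 50 px scores circularity within $[0.95, 1.05]$. The
tracer terminates on a repeated (pixel, backtrack-direction) state, so
non-convex contours that revisit a pixel — a dumbbell waist — are
traced in full. For very small particles the discretization can push
circularity slightly above 1; this is a known rasterization artifact,
not a measurement error. Ellipse axes come from the second-moment
(inertia-equivalent) ellipse with the 1/12 per-pixel variance
correction; aspect ratio is their ratio, which is the fitted-ellipse
convention (the bounding-box convention is not used). Solidity divides
the pixel count by the number of pixels inside the convex hull of the
particle's pixel centres, so both numerator and denominator share the
same raster convention and convex shapes score 1 up to $\pm 0.02$.
Pixel coordinates are 0-based (row, col); areas are in px² with no
physical calibration.

Tracking links particles of consecutive frames when their pixel
overlap is at least a fraction (default 0.3) of the smaller area — a
rule chosen for robustness to a few pixels of drift per frame, since
the original tracking procedure is not otherwise specified; the
threshold is configurable and reported. A particle with two or more
successors split; one with two or more predecessors marks a merge;
one-to-one correspondence in both directions is intact. Reversing the
frame order maps split onto merge exactly, which the test suite
asserts on scripted scenes.

Shape is summarized by PCA of z-standardized decorrelated parameters
(greedy selection in a stated priority order, keeping parameters whose
absolute pairwise correlation with all kept ones is below 0.90). PC1's
sign is anchored so the area loading is non-negative. The mixed models

```
PC1 ~ condition:time + condition + time,        random = ~1 | strain
splitting ~ condition:time + condition + time + shape, random = ~1 | strain
```

are fitted by REML via nlme, with marginal F tests and containment
denominator degrees of freedom. The splitting model is a *linear*
probability model on the 0/1 indicator, mirroring the same linear
mixed framework as the shape model; a logistic fixed-effects variant
is available but not the default, and exact equality of the F-test
degrees of freedom to any other package's convention is not claimed.
A single strain makes the random intercept unidentifiable (the fit
falls back to fixed effects with a warning), and a constant response
returns a degenerate fit with zero variances rather than an error.
The developmental phase labels (loose / tight / tipped) are inputs;
the package does not classify stages from images.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study's data, not its
biology:

* `simulate_counts()` — the paired-trio layout (two clonal + one
  chimeric library per pair per batch, 4 pairs × 3 batches by
  default), NB counts with $Var = \mu + \alpha\mu^2$, log-uniform size
  factors in $[0.5, 2]$, log-normal baselines around 100 counts, and
  per-gene batch (SD 0.1), pair (SD 0.2) and strain (SD 0.25, log2)
  effects. Chimeric means are the average of the two parental clonal
  means times the planted effect, reflecting the observation that
  chimeric expression tends to be intermediate between parents.
  Planted effects default to balanced ±1 log2.
* `simulate_reference_timecourse()` — 19 time points × 2 replicates;
  timing genes follow Gaussian-bump (or logistic) log2 trajectories
  with amplitudes of SD 1.5 log2 and widths between a tenth and a
  third of the series; the query sampler draws fresh samples at any
  fractional time index.
* `simulate_annotations()` — a single-rooted DAG of configurable
  depth, dispersed-NB term sizes (floored at 5), a designated selected
  list, and planted over-representation at a stated odds multiplier in
  chosen terms. Note that propagation dilutes planted enrichment in
  large ancestors, exactly as in real ontologies.
* `simulate_aggregate_timeseries()` — elliptical aggregates on a
  jittered grid, drifting at most a few px per frame with greedy
  collision rejection; scripted splits place two children inside the
  parent's footprint and merges replace two adjacent parents with a
  spanning ellipse. Merge partners are placed adjacent at setup and
  hold position until their event so the script stays geometrically
  realizable.

None of the generators models cAMP signalling mechanistically,
read-level sequencing artifacts, or microscopy texture; passing tests
demonstrate that the *estimators* recover planted truth under the
stated noise model, not that the noise model is biologically complete.
Each generator consumes an independent RNG stream derived
deterministically from its seed, so outputs are bit-reproducible and
insensitive to call order.

## Numerical choices and degenerate inputs

* IRLS: deviance tolerance $10^{-8}$, 100 iterations, linear-predictor
  clamp at ±30 to prevent overflow; failures are flagged per gene.
* Dispersion floor $10^{-8}$; zero-variance genes are floored and
  flagged.
* Spline basis dimension defaults to $k = 10$ and is capped below the
  number of distinct hr values; analytic-accuracy checks in the tests
  use $k = 15$ where basis approximation error would otherwise
  dominate.
* Minima with first-derivative zero crossings outside the observed hr
  range are discarded; a monotone curve returns an empty table, not an
  error.
* Permutation p-values count ties as exceedances (within a relative
  tolerance of $10^{-12}$) and use no $+1$ correction.
* The bootstrap SE of a set's median uses 1,000 seeded resamples.
* Empty gene sets, unknown genes, cyclic term graphs, shape-mismatched
  masks and rank-deficient designs raise immediate errors with
  explicit messages.

## Problem sizes in the shipped tests

The test suite runs entirely on synthetic data at deliberately modest
sizes — 800–2,000 genes for DE recovery and test size, 50 staging
seeds at 300 genes, a 36-aggregate 7-frame tracking scene, 2,000
repeats of the permutation-calibration experiment, 100 pathway power
simulations — chosen so each property is measured with Monte-Carlo
error well inside the asserted bound. The calibration experiment uses
2,000 repeats because the Kolmogorov–Smirnov statistic of even
perfectly uniform p-values frequently exceeds a 0.05 band at a few
hundred repeats; at 2,000 its expectation (~0.02) sits comfortably
inside.

## Known limitations

* The dispersion estimator is intentionally simpler than full
  empirical-Bayes shrinkage; very small designs will show more
  variable dispersion estimates.
* Median-of-ratios normalization is biased under strongly asymmetric
  differential expression (see above).
* The conditional enrichment procedure conditions at a single
  $\alpha$; p-values of ancestors are conditional on decisions taken
  at their descendants and should be read as a decision procedure, not
  as independent hypothesis tests.
* A single random permutation of condition labels retains residual
  correlation with the true contrast in a 36-library design; negative
  controls should use balanced (orthogonal) relabellings, which is how
  the test suite phrases them.
* The linear probability model for splitting shares the usual caveats
  of linear models on binary outcomes (fitted values outside [0, 1],
  heteroscedasticity); the logistic variant is available for
  sensitivity checks.
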