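---
title: "Predicting cognition from white matter lesion maps: models and methods"
author: "WMLpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cognition from white matter lesion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(WMLpredict)
```

# Scope

WMLpredict implements a four-stage analysis relating white matter lesions
(WMLs) to multidomain cognitive performance:

1. **Lesion segmentation** -- supervised k-nearest-neighbour (KNN) voxel
   classification of hyperintense lesions from co-registered T1-like and
   FLAIR-like channels, in the style of BIANCA.
2. **Prediction** -- relevance vector regression (RVR) from voxelwise lesion
   probability maps to neuropsychological scores, evaluated by 7-fold
   cross-validation with permutation-based significance.
3. **Interpretation** -- back-projection of the linear-kernel model onto
   voxel space and aggregation over an integer-labelled white-matter atlas
   into regional contribution percentages and expected rankings (ER).
4. **Association statistics** -- partial Pearson correlations and multiple
   linear regressions linking diffusion tensor metrics (FA/MD/AD/RD) in
   high-weight regions to the scores.

Registration, bias-field correction, skull stripping and eddy-current
correction are out of scope: every volume entering the pipeline must
already live on one common grid, and `checkSameGrid()` enforces this at
each joint operation. The pipeline operates in a single common space; the
original mixture of native-space segmentation and 2 mm standard-space
prediction is a preprocessing concern that this package deliberately does
not model.

All stages are exercised on synthetic phantom cohorts produced by the
package's own generator, which is first-class, tested code.

# The phantom cohort generator

`phantomSpec()` / `generateCohort()` emulate the statistical structure the
analysis assumes, not radiological appearance. The default grid is 48 x 56
x 48 voxels at 2 mm isotropic -- a desk-scale substitute for a 2 mm
standard-space grid -- carrying a 12-region box atlas (six white-matter
structures, left/right), two periventricular ventricle boxes, a
posterior-inferior cerebellum box used as the feature-exclusion region, and
an ellipsoidal brain mask. Each region type keeps comparable contact with
the ventricle box so that lesion prevalence is balanced across the atlas;
an earlier layout in which some regions sat several voxels from the
ventricle made those regions unlearnable for the interpretation stage
simply because lesions never reached them.

**Lesions.** Each subject's lesion mask is a union of connected blobs.
Seeds are sampled from a periventricular probability field
$P(v) \propto \exp(-d(v)/\lambda)$, where $d(v)$ is the exact mm distance
to the ventricle boxes and $\lambda = 6$ mm; blobs then grow by stochastic
frontier dilation weighted by the same field (6-connectivity) until the
subject's voxel budget is met. The default mean blob size is 350 voxels,
mimicking confluent periventricular lesions and -- importantly for the
interpretation stage -- creating between-subject variance in how a given
lesion volume is allocated across regions. Per-subject volume is log-normal
(median 6 ml, log-SD 0.7, clipped to 0.5-45 ml, spanning roughly 1-40 ml
across a cohort) with log-volume increasing linearly in age; age is uniform
on 62-80 years. With the default slope (0.055 per year) the expected
age-volume correlation is about 0.3-0.4.

**Channels.** Inside the brain, each channel is tissue mean + lesion
contrast (inside the mask) + i.i.d. Gaussian noise; the ventricle carries a
CSF mean. The FLAIR-like contrast is constrained positive and the T1-like
negative. The defaults (FLAIR +90 at noise SD 3; T1 -50 at noise SD 2.5)
encode an idealized low-noise acquisition with conspicuous lesions. Note
that what limits the KNN is not the noise SD but the z-scored separation
between lesion and healthy tissue, which is dominated by the CSF-WM
intensity spread entering the per-subject z-score; the defaults put that
separation around five z-units. The phantom has no partial-volume effects,
bias fields, or spatially correlated noise -- so passing tests show the
algorithmic chain is correct under its own assumptions, not that it meets
any real-data benchmark.

**Scores.** Each test is $s_j = \text{intercept}_j + \sum_r \beta_{jr}\,
\text{load}_r + \varepsilon_j$, with $\text{load}_r$ the lesion voxel count
in region $r$ times the voxel volume (mm^3). The defaults define an
MMSE-like score (intercept 28.4, negative beta) and a TRAILB-like score
(intercept 88, positive beta, noise SD 5), both driven by the right tapetum
and right posterior corona radiata. The TRAILB-like test is the one used in
recovery demonstrations because the contribution convention (below) counts
*positive* weight mass, and a score that increases with lesion load yields
positive weights in its driving regions.

**Diffusion channels.** FA decreases inside lesions; MD/AD/RD increase. The
default effect-to-noise ratios are ordered AD > RD > MD > FA, so that
regressions of scores on regional AD/RD are stronger than on FA -- a
structural property of the generator mirroring the ordering reported for
the real cohort, not a biological claim.

# KNN lesion segmentation

Features per in-mask voxel: each configured channel z-scored within the
brain mask per subject (population-SD convention, i.e. dividing by $n$),
followed by the voxel-center coordinates in mm, each multiplied by the
spatial weighting (default 1). Z-scoring is not optional: raw intensities
and mm coordinates are incommensurate, and it buys exact invariance to
affine intensity rescaling (tested). Training points follow the fixed +
unbalanced policy -- 2000 lesion and 10000 non-lesion points sampled
uniformly without replacement from 10 labelled subjects, with a logged
warning if a class pool is smaller than its budget.

`knnProbability()` returns, for each voxel, the fraction of lesion-labelled
points among its k nearest training points (Euclidean distance, ties broken
by lower training-point index, so results are exactly reproducible). The
implementation is an exact KD-tree written for this package; its
distance accumulation order matches a plain per-dimension scan so that a
brute-force oracle reproduces it bit for bit, which the test suite checks
on randomized tied instances.

**Choice of k.** The neighbour count is not dictated by the method and
interacts sharply with the 0.9 decision threshold: a voxel exceeds
probability 0.9 only if essentially *all* k nearest points are
lesion-labelled, and with a fixed 2000-point lesion budget pooled over ten
training subjects the local density of lesion points supports only small
neighbourhoods. Measured on the default phantom, the median distance to the
5th nearest lesion point already approaches the distance to the nearest
non-lesion point. The default is therefore k = 5 (configurable); at k = 40
the strict threshold empties the mask almost everywhere.

Masks use the strict inequality (probability > threshold), so threshold 1.0
is always empty and boundary voxels at exactly 0.9 are excluded. Lesion
volume is mask count x voxel volume / 1000 (ml). Dice overlap is defined as
1.0 when both masks are empty.

# Relevance vector regression

`fitRVR()` implements sparse Bayesian regression with a linear kernel
($K_{ij} = x_i \cdot x_j$ over lesion-map feature vectors) plus a bias
basis, and type-II maximum-likelihood re-estimation: posterior
$\Sigma = (\sigma^{-2}\Phi^\top\Phi + A)^{-1}$,
$\mu = \sigma^{-2}\Sigma\Phi^\top y$, then
$\gamma_i = 1 - \alpha_i\Sigma_{ii}$, $\alpha_i \leftarrow \gamma_i/\mu_i^2$,
$\sigma^2 \leftarrow \|y - \Phi\mu\|^2/(N - \sum_i\gamma_i)$, pruning basis
functions whose precision exceeds 1e9. Initialisation is fixed
($\alpha_i = 1/N^2$, $\sigma^2 = 0.1\,\mathrm{var}(y)$, bias precision
1e-6, i.e. an effectively unpenalised bias), convergence is
$\max_i |\Delta\log\alpha_i| < 10^{-3}$, and there is no randomness. The
linear kernel is forced by the interpretation stage: only for a linear
kernel does the fitted function reduce exactly to a voxel-space predictor
$f(x) = x \cdot w_{vox} + b$ with
$w_{vox} = \sum_{n \in RV}\mu_n x_n$, which `backprojectWeights()` exploits
(tested to 1e-8 against kernel predictions).

Two numerical guards sit on top of the update equations:

* **Noise-update degeneracy.** With all $N+1$ bases active the model
  interpolates and $N - \sum\gamma$ is zero to rounding; the raw update
  then collapses or explodes $\sigma^2$ and locks the fit in a non-sparse
  interpolating fixed point. The update is applied only while
  $N - \sum\gamma > 0.5$; until then $\sigma^2$ keeps its previous
  (initially well-regularised) value and the $\alpha$ dynamics prune from
  there.
* **Basis conditioning.** The fixed $\alpha$ initialisation and prune
  threshold presuppose an O(1) basis scale, while a raw dot-product Gram
  over tens of thousands of voxels scales with the voxel count. The Gram is
  divided by its mean diagonal during fitting, and the kernel weights
  multiplied back afterwards -- an exact reparameterisation, not an
  approximation. The frozen-alpha ridge limit is defined on the raw basis
  and skips this.

The log marginal likelihood is recorded every sweep and is checked
(tolerance 1e-6) to be non-decreasing. One property worth stating plainly:
sparsity under pure noise is a property of the *feature geometry*, not of
the algorithm. When the Gram is near-orthogonal (i.i.d. features with many
more voxels than subjects) the evidence fixed points genuinely retain most
bases -- kernlab's independent RVM shows the same behaviour on the same
data -- whereas structured, low-rank features (the lesion-map regime) prune
to a handful of relevance vectors. The test suite pins the sparse regime
and cross-checks against kernlab.

`rvrControl(evidenceTol=)` offers an optional early stop on the evidence
plateau. It is off by default; the permutation-calibration test uses it
because any deterministic statistic is valid under permutation and the
evidence plateaus long before slowly-diverging precisions reach the prune
threshold.

# Cross-validation and permutation inference

`crossvalPredict()` shuffles subjects into 7 near-equal folds (sizes differ
by at most one; the fold map attaches to row positions under a fixed seed),
fits the RVR on each complement and predicts the held-out fold, then
computes CORR, MSE and norm MSE on the *pooled* out-of-fold predictions --
pooling rather than averaging per-fold metrics, matching a single
observed-vs-predicted scatter per test. Norm MSE divides MSE by the
observed score range.

`permutationTest()` shuffles the scores before the entire CV loop and
retrains everything, per permutation (1000 by default). P-values use the
one-sided add-one rule -- for CORR,
$p = (1 + \#\{CORR_{null} \ge CORR_{obs}\})/(1 + B)$; for MSE and norm MSE
the tail reverses -- so $p \ge 1/(B+1)$ and exact finite-sample validity
holds under exchangeability. Degenerate permutations whose pooled
predictions are constant yield an undefined null CORR and are excluded
from the count (they cannot count as extreme).

# Weight interpretation

Per fold, the back-projected map is aggregated over atlas regions:
contribution of region $r$ is $100 \cdot m_r / \sum_r m_r$ with $m_r$ the
region's *positive* weight mass ($\sum_v \max(w_v, 0)$); regions are ranked
1, 2, 3, ... by descending contribution with ties resolved to the lower
label. Reported contributions and the expected ranking (ER) are means
across folds. Negative weights are visible through the reported mean
weight but are excluded from contributions -- the convention matches
displaying only positive-weight voxels. Published ER values below 1 for
regions that rank first in every fold are not reproducible under any
mean-of-ranks convention with 1-based ranks; both 1-based (default) and
0-based ranks are exposed via `rankBase`, and the package's own convention
is tested on its own terms.

# Association statistics

`partialPearson()` residualises both variables on an intercept plus
covariates (sex as a 0/1 indicator, education in years) and tests the
residual correlation with $t = r\sqrt{(n-2-q)/(1-r^2)}$; with no
covariates it reduces exactly to the plain Pearson test. The
implementation is oracle-tested against the inverse-correlation-matrix
identity. "Multivariate" regression is implemented as one multiple
regression per (test, metric) pair -- one F per pair, as a per-pair table
requires -- via OLS of the score on the mean metric values in the top-5
weight regions; an optional covariate argument switches the F to a partial
F of the region block. No multiple-comparison correction is applied across
tests, matching the source analysis; permutation p-values carry the
model-level inference.

# Problem sizes and numerical choices in the test suite

The suite runs end to end on phantoms sized for a desk machine, as the
package's own reference conditions:

* Segmentation recovery: default-grid cohort of 20 (10 train / 10 eval),
  Dice >= 0.8 per subject at the 0.9 threshold.
* End-to-end recovery: 20 seeded default-grid cohorts of 45 (10 train / 35
  eval); the two designated regions must occupy the top-2 contribution rows
  in at least 18 runs, and the observed CORR must exceed the permutation
  null's 95th percentile (99 permutations).
* Permutation calibration: a 24 x 28 x 24 null phantom of 14 subjects, 200
  repetitions at 99 permutations each (reduced from the default 1000, with
  the reduced count and the evidence early stop logged here); the
  rejection rate at alpha = 0.05 must fall in the 95% binomial band.
* Oracle checks (KNN vs exhaustive search, ridge limit at 1e-8,
  back-projection at 1e-8, partial correlation at 1e-10) run at small
  randomized sizes.

Known limitations: the phantom's independence of noise across voxels makes
segmentation easier than real FLAIR; the generator's single common space
sidesteps registration error entirely; RVR sparsity claims are
regime-dependent as discussed; and contribution percentages inherit the
positive-mass convention, so scores that *decrease* with lesion load
highlight their driving regions only weakly.
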