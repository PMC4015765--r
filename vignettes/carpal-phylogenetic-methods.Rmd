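---
title: "Methods: phylogenetically integrated carpal morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically integrated carpal morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpalevo)
```

This vignette documents the statistical model behind the package, the
estimators it implements, the design of the synthetic-data generator used
to validate them, and the numerical choices and limitations a user should
know about.

## 1. Model and assumptions

Shape is represented as a vector of dimensionless ratios per species,
assumed to evolve along a dated, possibly non-ultrametric phylogeny. The
baseline evolutionary model is Brownian motion (BM): trait change along a
branch of length $t$ is Gaussian with variance $\sigma^2 t$, so the
covariance between two taxa equals $\sigma^2$ times the shared
root-to-ancestor path length. The matrix of those shared path lengths,
$C$, is the phylogenetic covariance used throughout; it is well defined
for fossil tips that end above the present.

Assumptions worth stating explicitly:

* measurements are strictly positive lengths, so geometric-mean size
  correction and log-normal noise models are natural;
* within-species specimen variation is independent, multiplicative
  measurement/individual noise, uncorrelated with the phylogeny;
* branch lengths are in consistent time units (Ma here) and are trusted —
  rate estimates divide by them directly.

## 2. Size correction before averaging

Each specimen's bone measurements $x_1,\dots,x_m$ are divided by their
geometric mean $g = (\prod_i x_i)^{1/m}$. The resulting ratios are
invariant to overall specimen scale and have unit product, which removes
one degree of freedom — the "size" axis — before any comparative analysis.

The package corrects **specimens first and averages second**
(`size_correct()` then `species_means()`), rather than averaging raw
measurements and correcting the species mean. The two differ when
specimens vary in size because the geometric mean is non-linear;
correcting per specimen keeps each individual's shape intact and makes the
species mean an unweighted average of shapes, not of sizes. Specimens
missing any variable for a bone are dropped (with a warning) rather than
imputed.

Observer repeatability is quantified by the technical error of measurement
(`technical_error()`): with $K$ sessions per specimen,
$\mathrm{TEM} = \sqrt{\sum_s\sum_k (x_{sk}-\bar x_s)^2 / (n(K-1))}$,
reported as a percentage of the grand mean.

## 3. Phylogenetically weighted PCA

Given the species-by-variable matrix $X$ and covariance $C$:

* GLS phylogenetic mean: $a = (1^\top C^{-1} 1)^{-1}\, 1^\top C^{-1} X$;
* evolutionary covariance:
  $R = (X - 1a)^\top C^{-1} (X - 1a)/(n-1)$;
* loadings are eigenvectors of $R$ (or of the corresponding correlation
  matrix in `mode = "cor"`); scores are $(X - 1a)L$.

Weighting by $C^{-1}$ discounts the pseudo-replication of closely related
species: a clade of ten near-identical taxa contributes little more than
one taxon would. On a star phylogeny with equal tip depths, $C \propto I$
and the procedure reduces exactly to ordinary covariance PCA — the test
suite asserts this identity, and `scripts/acceptance.R` recomputes it.

Eigenvector sign is arbitrary; the package fixes it by making the
largest-magnitude loading of each component positive, so outputs are
deterministic across platforms.

## 4. Ancestral states: the adaptive-peak fixed point

`estimate_ancestral_states()` assigns each internal node $k$ the
branch-length-weighted harmonic average of its neighbours,

$$x_k = \frac{\sum_{j \in \mathrm{nbr}(k)} x_j / t_{kj}}
             {\sum_{j \in \mathrm{nbr}(k)} 1 / t_{kj}},$$

with tips clamped to their observed values, solved to a fixed point by
Gauss–Seidel sweeps. The intuition is "independent evolution": each node
sits at the local adaptive peak implied by its neighbours, with short
branches pulling harder than long ones.

This system of equations is exactly the stationarity condition of the
joint Brownian-motion likelihood in the states, so the fixed point equals
the BM joint-ML reconstruction. The package also implements that
reconstruction directly via per-node re-rooting GLS
(`bm_gls_reconstruction()`, using
$C_k[i,j] = (d(k,i)+d(k,j)-d(i,j))/2$); the two independent routes
agreeing to tolerance is one of the strongest internal checks in the test
suite.

Per-branch rates are $|\Delta \mathrm{state}|/t$ with a $\pm 1$ direction.
Because under BM the state difference across a branch scales like
$\sqrt{\sigma^2 t}$, the *estimated rate* scales like $\sqrt{\sigma^2/t}$:
rate estimates on long branches are systematically attenuated, and shifts
are easiest to detect on short terminal branches, where the tip value
anchors the child state. This drives the design of the recovery experiment
below.

## 5. Synthetic-data generator

The generator is first-class, tested code, because every downstream claim
about estimator behaviour is made on its output.

* **Trees** (`simulate_tree()`): constant-rate birth–death species trees
  (`ape::rphylo`, birth 0.15, death 0.05 per lineage-Myr), rescaled to a
  root age of 47 Ma. A birth–death process is the standard generative
  model for species phylogenies; coalescent trees were rejected because
  their extreme branch-length skew (very short terminal branches near the
  root) is a population-genetic, not macroevolutionary, shape. Fossils are
  grafted onto uniformly chosen branches at uniform stem and tip ages
  within the valid interval.
* **Traits** (`simulate_traits()`): exact BM or Ornstein–Uhlenbeck
  transition sampling in preorder, with optional per-edge rate multipliers
  and a full trait covariance. True node states are retained so recovery
  can be scored.
* **Specimens** (`simulate_specimens()`): species shape ratios are
  normalized to unit geometric mean (the quantity the pipeline can
  identify), multiplied by a uniform per-specimen size factor, and
  perturbed by log-normal noise with
  $\mathrm{sdlog} = \sqrt{\log(1+\mathrm{cv}^2)}$, so `cv_noise` is the
  coefficient of variation on the natural scale.
* **Defaults** (`simulate_carpal_dataset()`): 24 extant species, 8
  single-specimen fossils, per-variable log-scale BM variance
  $\sigma^2 = 0.002$/Myr (giving realistic few-percent-per-Myr shape
  drift), specimen CV 5% (of the order of published carpal TEM values),
  and species sample sizes from 2 to 146, mirroring the extreme imbalance
  of real museum samples. These defaults are the package's study
  conditions; experiments report behaviour *at* them rather than tuning
  them to the estimator.

## 6. Recovery and calibration experiments

`rate_recovery_experiment()` fixes one 50-tip birth–death tree, designates
a rate-shifted branch, and over 200 replicates simulates BM traits with a
10× variance multiplier on that branch, then scores (a) the correlation
between true and estimated ancestral states and (b) how often the shifted
branch ranks in the top 5% of absolute rates. The designated branch is a
*terminal* branch at the lower quartile of terminal branch lengths: the
$\sqrt{\sigma^2/t}$ scaling above means long or deep internal branches
give little detection power regardless of estimator quality, so the
experiment measures the estimator under conditions where the signal is
identifiable at all. Interior placement and longer branches degrade
detection smoothly, as the scaling predicts.

`ftest_calibration()` checks the two-tailed variance-equality F-test
(`variance_equality_test()`, $p = \min(1,\,2\Pr[F_{d_1,d_2} > f])$ with
$f \ge 1$) against its nominal 5% type-I error on equal-variance Gaussian
samples over 2000 replicates.

## 7. Numerical choices

* **Fixed-point iteration**: tolerance $10^{-10}$ on the maximum state
  change per sweep, cap of 10000 sweeps; convergence is diagnosed on the
  returned object. Initialization is a post-order pass (each node set
  from already-set children), which starts close to the solution.
* **Zero-length branches** in the ancestral solver receive a floor of
  $10^{-6}$ (flagged `ridged` in the rate table) to keep the harmonic
  weights finite.
* **Covariance inversion**: if the condition number of $C$ exceeds
  $10^{12}$, a ridge of $10^{-8} \times \overline{\mathrm{diag}(C)}$ is
  added before solving, with a message.
* **Fossil grafting** is direct edge-table surgery (split the attachment
  edge at the stem age, add the fossil edge), which is exact; path lengths
  elsewhere are bit-identical before and after grafting.
* **Determinism**: all simulators take explicit seeds; pipeline outputs
  are byte-identical across reruns of one config, and the run report
  carries a hash of the analysis configuration (excluding the output
  location).

## 8. Limitations

* The rate estimator is descriptive: $|\Delta|/t$ per branch is not a
  formal test for rate heterogeneity, and its power depends strongly on
  branch length and position (Section 4). Ranked-rate detection is
  calibrated only under the generator's conditions.
* The F-test on morphospace scores treats tip and ancestor states as
  independent observations; phylogenetic non-independence inflates its
  effective sample size, so its p-values are heuristic for comparative
  inference even though the test itself is exactly calibrated on i.i.d.
  input.
* BM is the working model throughout the estimators; traits generated
  under strong OU attraction will have over-dispersed ancestral
  reconstructions near the root.
* Fossil placements (topology and ages) are taken as known; placement
  uncertainty is not propagated.
* Size correction by the geometric mean removes isometric size only;
  allometric shape–size covariation remains in the ratios.
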