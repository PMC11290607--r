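---
title: "Methods: projecting multi-facet diversity redistribution under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting multi-facet diversity redistribution under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`facetshift` implements a complete species-distribution-modelling pipeline
for asking how climate change redistributes the taxonomic (TD), functional
(FD) and phylogenetic (PD) diversity of a species assemblage, and whether
per-species range shifts carry phylogenetic signal or are explained by
functional traits. The stages are:

1. **Occurrence preparation** — cleaning (collection year, study-area
   membership, coordinate duplicates, coordinate uncertainty), greedy
   spatial thinning, and construction of a buffered accessible area per
   species.
2. **Predictors** — bioclimatic variables from monthly climate, Emberger's
   pluviometric quotient, and a two-step multicollinearity filter
   (pairwise |r|, then iterative VIF).
3. **Suitability models** — three presence–background learners (additive
   smooth model, regularized log-linear "maximum-entropy-style" classifier,
   stochastic boosted trees) plus their unweighted ensemble; 75/25
   stratified holdout scored with AUC and the continuous Boyce index;
   quality gates; refit of the best candidate on all occurrences;
   binarisation at the threshold maximising sensitivity + specificity;
   projection to current and future climate.
4. **Diversity maps** — binary maps stacked into cell-by-species
   communities; per-cell tree-based alpha diversity and temporal beta
   diversity decomposed into replacement and richness components.
5. **Range shifts** — area ratio, altitudinal and centroid displacement per
   species and scenario.
6. **Comparative analyses** — Pagel's lambda, Blomberg's K, ancestral state
   reconstruction, and PGLS of the shift responses on traits with
   lambda/kappa/delta branch-length transforms selected by maximum
   likelihood.

Every stage is driven by a synthetic world with known ground truth, so the
pipeline's statistical behaviour is testable end to end.

# The synthetic world and what it emulates

`generate_world()` builds 12 monthly minimum/maximum temperature and
precipitation fields, an elevation layer, and a water-body mask on a
regular lon/lat grid. All fields are Gaussian-filtered white noise
(`smooth_sigma` = 3 cells) superimposed on:

* a latitudinal temperature gradient (`lat_gradient`, default 1.5 °C per
  degree). The demonstration domain is only 6° tall (60 rows at 0.1°,
  roughly a 10-km working resolution), so the gradient deliberately
  compresses a continental-scale climatic span into it; one model cell
  stands for a much larger climatic step than 10 real kilometres.
* an elevational lapse (6.5 °C/km on a rolling landscape up to ~1200 m).
  Relief is kept moderate on purpose: strong alpine relief makes species
  track mountains rather than latitude, and the construction's known truth
  is a latitude-dominated, poleward shift under warming.
* a seasonal cycle (amplitude 8 °C, July warmest; winter-wet
  precipitation), which gives the quarter-based bioclim variables
  non-trivial structure.

Future scenarios are additive temperature offsets and multiplicative
precipitation factors, stored as named presets spanning roughly +1.8 to
+2.8 °C at mid-century (the 2070 horizon amplifies the anomaly by 1.4).
They are parameter presets, not circulation-model output; elevation and
water bodies are held constant in the future.

**Species.** Each synthetic species has a *known* logistic suitability
function over the predictor layers: a quadratic thermal niche on the mean
temperature of the warmest quarter (optimum drawn from the central span of
the current climate, tolerance 0.8–1.6 °C) plus a patchy aridity
(Emberger-quotient) preference, scaled by a steepness factor of 4 so that
occupancy is near-deterministic at the band edge. The steep logistic and
the aridity patchiness are what make the species *modellable*: they create
genuinely unsuitable terrain inside each species' accessible area, which is
where presence–background discrimination comes from. Presences are drawn
without replacement with probability proportional to true suitability and
jittered uniformly within their cell; a configurable fraction of dirty
records (pre-1970, duplicate, over-uncertain, out-of-area) exercises the
cleaning rules, with the injected indices tracked so tests can verify the
bookkeeping exactly.

**What the generator does not emulate:** real spatial sampling bias
(records are missing at random, not biased toward roads or cities),
observation error in the predictors, dispersal limitation, biotic
interactions, and coastlines/seas. Passing tests therefore demonstrate the
statistical correctness and directional behaviour of the pipeline, not
that any particular real assemblage would be modelled equally well.

**Phylogeny and traits.** `simulate_phylogeny_and_traits()` grows a
pure-birth tree and simulates continuous traits under Brownian motion on
the lambda-transformed covariance (off-diagonals scaled by the generating
lambda), so the downstream signal statistics have a known recovery target.
Trait columns are mapped onto the measurement scales of the functional
schema (lengths in mm, colour in RGB) by affine rescaling, which preserves
the phylogenetic signal structure.

# Stage-level notes and parameter choices

## Occurrences

* Cleaning discards records before 1970, outside the study area, with
  coordinate uncertainty above the working resolution (default 10 km), and
  coordinate duplicates. Duplicates are detected after rounding to six
  decimal places so sub-metre jitter cannot defeat deduplication, and
  records are canonically ordered first so the surviving duplicate does not
  depend on input order.
* Thinning is greedy: the record with the most neighbours within the
  minimum distance dies first, ties broken by a seeded random draw. The
  survivors satisfy the pairwise minimum-distance guarantee exactly (the
  tests verify this with an exhaustive pair scan). Thinning runs before
  accessible-area construction; the order is configurable.
* The accessible area is the convex hull of the occurrences after removing
  the `ceiling(outlier_pct * n)` points farthest from the coordinate
  centroid (default 1 %), buffered outward by
  `100000 m x flight_months / 10` — 10 km of buffer per month of flight
  period, so a 10-month flyer gets 100 km. The buffered ring is the convex
  hull of geodesic circles drawn around the hull vertices, which is exact
  for a convex core up to the 5° bearing discretisation.
* Background points double the presences, drawn uniformly over grid cells
  inside the buffered polygon with presence cells excluded; if fewer
  eligible cells exist than points requested, cells are reused with a
  warning.

## Predictors

* The bioclim quarters are the 12 wrap-around 3-month windows *centred* on
  each month, with ties resolved to the earliest window, so an
  all-rain-in-January climate assigns the wettest quarter to
  December–January–February.
* `bio15` uses the `1 + bio12/12` denominator convention to stay defined in
  fully arid cells.
* Emberger's quotient is computed in kelvin:
  `Q = 2000 P / ((Tmax + Tmin)(Tmax − Tmin))` with `P` = annual
  precipitation, `Tmax` = bio5, `Tmin` = bio6. Cells with `Tmax = Tmin`
  are masked.
* The collinearity filter clusters variables on `1 − |r|` (average
  linkage, cut at `1 − r_max` with `r_max = 0.5`), keeps the member with
  the lowest mean absolute correlation per cluster, then iteratively drops
  the highest-VIF variable until all VIF ≤ 3. A keep-list forces named
  variables through both steps; the pipeline default forces the seven
  working predictors (water, elevation, embergerQ, bio7, bio8, bio10,
  bio15) and filters the remaining candidates against them. Without the
  forced list the filter is free to discard a causally important but
  correlated variable in favour of a proxy — on synthetic worlds this can
  delete the thermal niche axis itself, which is why the override exists.

## Suitability models

* The additive learner uses penalized regression splines (`k ≤ 5` per
  predictor, REML smoothness selection), falling back to a linear term for
  predictors with too few distinct values.
* The maximum-entropy-style learner is an L1-regularized logistic
  regression on standardized linear, quadratic and pairwise-product
  features, with the penalty chosen by seeded 4-fold cross-validation.
  This is the presence–background log-linear equivalent of the classical
  maximum-entropy formulation, not a port of any particular software.
* The boosted-tree learner uses a slow learning rate (0.01) with 1000
  trees, depth 3, 70 % subsampling — the standard regime for
  presence–background data of this size. All learners are seeded and run
  single-threaded for bit-reproducibility.
* The ensemble is the unweighted pointwise mean of the three calibrated
  suitabilities and competes as a fourth candidate on the same split.
* Quality gates: species whose best test AUC < 0.7 or Boyce < 0.4 are
  flagged and excluded from the diversity and comparative stages. The best
  candidate is refitted on 100 % of the occurrences and the binarisation
  threshold re-selected on the full-data scores, with candidate thresholds
  being the observed scores themselves (the exhaustive optimum; a grid
  mode is not needed at these data sizes).

## The continuous Boyce index and its windowing

The index slides `n_windows = 101` windows of width `range/10` across the
suitability range, computes the presence-to-expected ratio P/E per window
(windows with E = 0 dropped), and reports the Spearman correlation between
P/E and the window centre. Two properties of this default deserve
attention:

* because adjacent windows overlap heavily, the P/E profile has roughly
  `range/width ≈ 10` independent values; a *null* index computed at the
  default width therefore has a standard deviation near 0.30, and one
  should not read |index| ≲ 0.3 as meaningful support.
* at an evaluation width of `range/30` the null standard deviation drops
  to ~0.18 and 95 % of null replicates fall inside ±0.35; the calibration
  tests evaluate the null at that width, while the package default remains
  the field-standard `range/10`.

## Diversity

* Alpha with a tree is Faith-style: the summed branch length of the
  minimal subtree connecting the community to the root, root path
  included, so a single-species cell scores its root-to-tip distance.
  Without a tree, alpha is the species count; the two coincide exactly on
  a unit star tree.
* Temporal beta compares each cell's present and future communities:
  with `a` the shared branch length, `b` unique to the present and `c`
  unique to the future, `beta_total = (b+c)/(a+b+c)` splits exactly into
  `beta_repl = 2 min(b,c)/(a+b+c)` and `beta_rich = |b−c|/(a+b+c)`. A
  branch counts as shared iff it lies on the root path of at least one tip
  of each community. Cells empty in both periods score 0 (not missing);
  cells occupied in only one period score `beta_total = 1` with
  `beta_repl = 0`. Note that on a genuine tree two disjoint communities
  still share ancestral branches, so `beta_total = 1` for disjoint sets is
  a star-tree/taxonomic property, not a general one.
* The functional tree is a UPGMA dendrogram (configurable linkage) on the
  group-balanced Gower matrix: traits are averaged within their group
  (1: body/abdomen/wing lengths; 2: habitat flags; 3: flight season;
  4: RGB pigmentation) and the four groups contribute equally, so the
  three correlated morphometric traits cannot dominate. Continuous traits
  use range-normalised absolute differences; the habitat trait is the mean
  mismatch of the lentic and lotic flags; pigmentation is Euclidean
  distance in the unit RGB cube divided by √3. This is the analytic
  equal-contribution form; iterative optimisation of trait weights is out
  of scope.

## Range shifts

Centroids are unweighted means of suitable cell centres (a `cos(lat)`
weighting switch exists); distances use the haversine formula on a sphere
of mean radius 6 371 008.8 m, which differs from an ellipsoidal geodesic
by well under 0.5 % at these scales. A one-row northward translation on a
0.1° grid therefore yields ≈ 11 120 m of centroid displacement.

## Comparative methods

* Pagel's lambda scales the off-diagonal Brownian covariances; the
  likelihood profiles out the rate and root mean analytically, and the
  search is capped at `min(1, pd-bound)` because the profiled likelihood
  can diverge spuriously as the covariance approaches singularity just
  beyond the Brownian case. Significance is a one-degree-of-freedom
  likelihood-ratio test against lambda = 0. On a star tree the likelihood
  is flat in lambda and the result carries an explicit flag.
* Blomberg's K is the observed `MSE0/MSE` ratio over its Brownian
  expectation `(tr(C) − n/sum(C⁻¹))/(n − 1)`; the permutation p-value
  (default 1000 seeded shuffles, with the `+1` small-sample correction) is
  computed with vectorised matrix algebra so large calibration experiments
  stay cheap.
* Ancestral states are the GLS/Brownian conditional expectations given the
  tips; the root estimate equals the phylogenetically corrected mean.
* PGLS profiles the transform parameter (lambda on [0, 1], kappa and delta
  on [0, 3]) on a 51-point grid followed by local refinement; the three
  transform families are fitted separately and the winner chosen by
  maximised likelihood. Coefficient standard errors use the residual
  variance on `n − p` degrees of freedom. Habitat enters as two binary
  indicators (lentic, lotic). Singular designs are rejected with the
  offending columns named. Responses are analysed on their raw scale; a
  transform can be applied by the caller.
* The suite runs every response × scenario × period stratum for the full
  assemblage and any named species subsets (each with its pruned tree);
  strata with fewer than four species are skipped with a log entry.

# Reproducibility

Every stochastic stage derives its seed deterministically from the master
seed and the stage name, so stages can be rerun independently and a full
run is bit-reproducible (the pipeline tests compare artefact files across
two runs byte for byte). All tabular artefacts are tidy CSV, trees are
Newick, and rasters are plain-text ESRI ASCII grids; the run manifest
records configuration, versions, per-species status and an MD5 hash per
artefact.

# Problem sizes used by the tests

The demonstration study is 15 species on a 60 × 60 grid with one warming
scenario; the test suite runs it across five master seeds for the
directional checks. Metric oracles run at n = 200 (AUC, thresholds),
n = 500–1500 (Boyce), 10 000 community pairs (beta identity), 200 random
subsets of 20-tip trees (alpha), 50 replicates × 100-tip trees (lambda
recovery), and 100 + 1000 datasets × 50-tip trees (K calibration). These
sizes were chosen so each property is measured with comfortable
statistical margin.

# Known limitations

* The buffered accessible area cannot move through time, so projected
  shifts are conservative: a species cannot colonise beyond its buffered
  hull regardless of climate.
* Spatial-block cross-validation, dispersal-explicit models and
  abundance-weighted diversity metrics are out of scope; binary stacked
  maps are used throughout.
* The MaxEnt-style learner shares the feature space, not the software, of
  the classical implementation; learners are treated as interchangeable
  candidates judged by AUC.
* Gower's dissimilarity need not satisfy the triangle inequality; the
  UPGMA dendrogram is a model of the dissimilarity structure, not an
  estimate of a true tree.
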