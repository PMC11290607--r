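# facetshift

`facetshift` is an R package for macroecologists who want to project how
climate change redistributes the **taxonomic, functional and phylogenetic
diversity** of a species assemblage, and to ask whether the resulting
per-species range shifts are phylogenetically conserved or driven by
functional traits. It implements, as a reusable and fully tested pipeline:

* per-species **presence–background distribution models** — a generalised
  additive model, a regularized log-linear (maximum-entropy-style)
  classifier and stochastic boosted trees, plus their unweighted ensemble —
  calibrated inside buffered accessible areas (minimum convex polygon with
  a 1 % outlier trim, buffered by 10 km per month of flight period),
  evaluated on a stratified 75/25 holdout with AUC and the continuous
  Boyce index, thresholded at max(sensitivity + specificity), and
  projected to current and future climates;
* **stacked diversity maps**: per-cell α diversity for each facet — species
  richness, or Faith-style summed branch length on a functional dendrogram
  (group-balanced Gower distances, UPGMA) or a phylogeny — and temporal β
  diversity decomposed as

  β_total = (b + c)/(a + b + c) = β_repl + β_rich,
  β_repl = 2·min(b, c)/(a + b + c),  β_rich = |b − c|/(a + b + c),

  where *a*, *b*, *c* are the branch lengths shared by, unique to the
  present, and unique to the future community of a cell;
* **range-shift metrics** (area ratio, altitudinal shift, great-circle
  centroid displacement) and their **phylogenetic comparative analysis**:
  Pagel's λ and Blomberg's K with likelihood-ratio / permutation tests,
  maximum-likelihood ancestral state reconstruction, and PGLS with λ, κ
  and δ branch-length transforms selected by maximum likelihood;
* a **synthetic-data module** that generates spatially autocorrelated
  climates with warming scenarios, species with known logistic suitability,
  birth–death phylogenies and Brownian traits of known signal — so every
  stage of the pipeline has a ground-truth recovery target.

Inputs are plain formats throughout: occurrence and trait tables as CSV,
trees as Newick, rasters as ESRI ASCII grids, polygons as WKT.

## Worked example

The demonstration study models 15 synthetic species on a 60 × 60 world
(0.1° cells) under a +2.8 °C mid-century scenario:

```r
library(facetshift)
res <- run_all(run_config(seed = 1), out_dir = "demo", quiet = TRUE)
print(res$shift_summary, row.names = FALSE, digits = 3)
#>        scenario period n_species mean_lat_shift se_lat_shift n_northward
#>  MIROC-ESM-CHEM   2050        11           1.47        0.101           8
#>  mean_alt_shift se_alt_shift n_upward mean_area_ratio
#>            7.42         18.9        4           0.309
```

Eleven of the 15 species pass the quality gates (best test AUC ≥ 0.7 and
Boyce ≥ 0.4); of the eight whose future range is non-empty, all eight shift
their range centroid poleward, by 1.47° latitude on average (SE 0.10), and
their suitable area contracts to about 31 % of its current extent — the
warming scenario removes the southern (warm-edge) part of every thermal
band while the fixed accessible area limits poleward colonisation. The
per-species evaluation table shows which learner won each contest:

```r
head(res$evaluation[res$evaluation$learner == res$evaluation$best,
                    c("species", "learner", "auc", "boyce", "flagged")], 5)
#>  species         learner   auc boyce flagged
#>     sp01        ensemble 0.776 0.763   FALSE
#>     sp02    maxent_style 0.790 0.870   FALSE
#>     sp03 additive_smooth 0.772 0.769   FALSE
#>     sp04    maxent_style 0.815 0.932   FALSE
#>     sp05 additive_smooth 0.726 0.339    TRUE
```

(`sp05` is flagged: its Boyce index 0.34 falls below the 0.4 gate, so it is
excluded from the diversity and comparative stages.) The comparative suite
then reports, per response and stratum, the signal statistics and PGLS
coefficients:

```r
res$comparative$signal
#>  subset       scenario period             response lambda lambda_p     K   K_p
#>     all MIROC-ESM-CHEM   2050 relative_area_change      0        1 0.203 0.860
#>     all MIROC-ESM-CHEM   2050  altitude_difference      0        1 0.448 0.665
#>     all MIROC-ESM-CHEM   2050  centroid_difference      0        1 0.424 0.720
```

Here the shift responses carry no phylogenetic signal (λ̂ = 0, K < 0.5,
all p ≫ 0.05), as expected: the synthetic species' thermal optima are
assigned independently of the simulated phylogeny. `report("demo")` prints
a digest of every artefact written to the output directory (evaluation and
shift CSVs, α/β rasters per facet, Newick trees, and a manifest with
per-file MD5 hashes).

A thin command-line wrapper over the same functions is installed at
`inst/cli/facetshift.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/facetshift.R", package="facetshift"))')" \
    run-all --seed 1 --out demo
```

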