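# adaptdr

Neighbourhood-based dimensionality reduction methods (locally linear
embedding, spectral embedding, UMAP-style fuzzy embeddings) hinge on two
hyper-parameters that are usually hand-tuned: the number of nearest
neighbours `k` and the target dimension. `adaptdr` estimates both from
the data and feeds them back into adaptive versions of the three
embedders, for analysts working with high-dimensional point clouds
(omics embeddings, image vectors, text embeddings) who want
tuning-free nonlinear projections.

## The estimator

Model the neighbourhood of each point `x_i` as a locally homogeneous
Poisson process. Counting neighbours in concentric balls with radius
ratio `tau` gives a binomial likelihood for the intrinsic dimension `d`,
maximised in closed form at

    d_hat = log(sum(k_A) / sum(k_B)) / log(tau)

while the successive hyper-spherical shell volumes
`v_ij = Omega_d (r_ij^d - r_i,j-1^d)` are i.i.d. exponential under local
homogeneity, so a likelihood-ratio deviance

    D_ik = 2k log( (V_i + V_j)^2 / (4 V_i V_j) )   ~  chi^2_1

detects, for each point, the first neighbourhood order `k*_i` at which
local uniformity breaks (threshold: the `1 - alpha` chi-squared
quantile). The two are iterated to a joint fixed point: the estimated
dimension `d_hat` (and its nearest integer `d*`) plus the per-point
neighbourhood sizes `k*_1..n`, which parameterise

* `lle_star()` — adaptive locally linear embedding (with an
  out-of-sample `predict()` rule),
* `sc_star()` — adaptive spectral clustering,
* `umap_star()` — adaptive fuzzy-graph embedding with per-point scale
  calibration to `log2(k*_i)`,

plus `generate_manifolds()` (a torus/spiral/sphere benchmark of known
de-noised dimension 3), a clustering/supervised evaluation harness, and
a command-line entry point (`inst/cli/adaptdr.R`).

## Worked example

```r
library(adaptdr)

fit <- abide(as.matrix(iris[, 1:4]))
fit$estimate
#> intrinsic dimension: d_hat = 2.666 (d* = 3, std ~ 0.065)
#>   4 iteration(s), converged: TRUE

md <- generate_manifolds(seed = 1)      # 5100 x 20, labels 1..3
emb <- umap_star(md$X, seed = 1)        # estimates d* and k*, then embeds
emb$estimate$d_star
#> [1] 3
kmeans_evaluate(emb$embedding, md$labels, seed = 1)
#> ari = 0.965, homogeneity = 0.953, completeness = 0.953, v_measure = 0.953, ...
```

The four measured iris variables have an estimated intrinsic dimension
of about 2.7 (the flowers vary along roughly two to three effective
degrees of freedom), and on the synthetic benchmark the adaptive fuzzy
embedding separates the three interleaved manifolds almost perfectly
(adjusted Rand index 0.96 against the generating shapes).

From a shell:

```sh
Rscript inst/cli/adaptdr.R synth --seed 1 --out-dir data
Rscript inst/cli/adaptdr.R fit-id data/manifolds.csv --out-dir out
Rscript inst/cli/adaptdr.R embed umap data/manifolds.csv \
    --labels data/manifolds_labels.txt --out-dir out
```

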