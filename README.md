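# svgene

Identification of **spatially variable genes (SVGs)** in spatial
transcriptomics, by ensemble spatial autocorrelation — with the full
quantitative evaluation harness and a synthetic data generator so the whole
system is testable end to end.

## Who this is for

Analysts working with spot-based spatial transcriptomics (Visium,
Slide-seq-like grids) who need to reduce tens of thousands of genes to the
spatially organized subset before embedding and spatial-domain clustering,
and methodologists who want a quantitative benchmark (clustering agreement,
domain resolution, latent-representation quality) for comparing SVG
selections on data with known ground truth.

## The method

For spots with 2-D coordinates, a sparse directed **spatial neighbor graph**
connects each spot to its *k* nearest neighbors (default *k* = 30) with
distance-decay weights

> w<sub>ij</sub> = 1 − D<sub>ij</sub> / max(D<sub>i·</sub>)

stored in O(n) memory. Every gene *x* is then scored by two spatial
autocorrelation statistics over the graph, computed together in one sparse
pass:

> **Moran's I** = (N/W) · Σ<sub>ij</sub> w<sub>ij</sub>(x<sub>i</sub>−x̄)(x<sub>j</sub>−x̄) / Σ<sub>i</sub>(x<sub>i</sub>−x̄)²  — global structure
>
> **Geary's C** = (N−1) · Σ<sub>ij</sub> w<sub>ij</sub>(x<sub>i</sub>−x<sub>j</sub>)² / (2W · Σ<sub>i</sub>(x<sub>i</sub>−x̄)²),
> rescaled C\* = 1 − C  — local structure

The **ensemble selection** is the union of the top-*n* genes by I and the
top-*n* by C\* (default *n* = 2000), integrating global and local spatial
signal; single-statistic variants are available. Selections are evaluated by
PCA embedding + Louvain/Leiden clustering (default resolution, or a binary
search on resolution toward a target cluster count), scored with AMI, ARI,
homogeneity and NMI against ground-truth domains, plus mean average
precision (K = 30), cross-validated RBF-SVM accuracy (MCVA), and the local
inverse Simpson's index (iLISI, perplexity 30).

See `vignettes/identifying-spatially-variable-genes.Rmd` for the model,
parameter meanings, numerical choices, and the generator's scope.

## Worked example

```r
library(svgene)

# a Visium-like synthetic section: 40x40 grid, 4 Voronoi domains,
# 100 planted SVGs + 1900 noise genes, 90% zeros
sim <- generate_spatial_dataset(synthetic_spec(seed = 0))
ds  <- sim$dataset
ds
#> spatial_dataset: 1600 spots x 2000 genes (sparse, 90.0% zeros)
#>   domain labels: 4 domains

sel <- identify_svgs(ds, n = 100, k = 30)   # graph -> I & C* -> ensemble union
sel
#> svg_selection: method = ensemble, n = 100, selected 101 genes
sum(sel$selected_gene_ids %in% ds$gene_ids[sim$truth])
#> [1] 100                                    # all planted genes recovered

benchmark_selection(ds, sel, seed = 0)
#> metrics_report (1600 spots, 101 SVGs, method ensemble)
#>  scenario  method resolution n_clusters    ami    ari homogeneity    nmi
#>   default louvain       1.00          4 0.6470 0.6996      0.6499 0.6477
#>   default  leiden       1.00          4 0.6748 0.7261      0.6778 0.6755
#>  target_k louvain       0.75          4 0.6668 0.7189      0.6698 0.6675
#>  target_k  leiden       0.75          4 0.6719 0.7248      0.6748 0.6726
#>   MAP = 0.7168  MCVA = 0.8962  iLISI_md = 0.5656  iLISI_m = 0.5276
```

The selection recovers every planted gene, and clustering on the SVG
embedding recovers the 4 planted domains with AMI ≈ 0.65 (a size-matched
random gene set scores AMI ≈ 0 — see the acceptance script below). The
resolution search lands on exactly 4 clusters in both methods.

Real data comes in through `load_dataset()` — either an `.h5ad`
annotated-matrix HDF5 file (expression in `X`, coordinates in
`obsm/spatial`; files written by `write_h5ad()` are readable by Python
`anndata` and vice versa) or a MatrixMarket directory (`matrix.mtx`,
`genes.tsv`, `coordinates.tsv`, optional `labels.tsv`). A thin CLI wraps the
same functions:

```sh
Rscript inst/cli/svgene.R simulate --grid 40x40 --out sim.h5ad
Rscript inst/cli/svgene.R run --input sim.h5ad --n-svgs 2000 --method ensemble --out-dir results/
```

which writes `scores.tsv`, `selection.tsv`, `metrics.json`, and a
`run_log.json` recording every resolved default and seed.

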