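# scvarcal

Calibrated analysis of single-cell transcriptome variation.

Cells of nominally identical type show surprisingly different
transcriptomes when sequenced one at a time. Deciding how much of that
spread is biology requires a technical baseline, because single-cell
measurement noise is large and depends strongly on expression level.
`scvarcal` is built for experiments that include **dilution controls**:
replicate amplifications of one bulk RNA sample diluted to single-cell
input amounts (10/50/100 pg). From those controls it derives an
expression-dependent technical-variance baseline and an
expression-matched variance ratio for every gene,

```
F_i = V_total(g_i, x_i) / V_exp(x_i)
```

where `V_total` is the sample variance of a gene's relative frequencies
across the cells of one type, and `V_exp(x)` is the sliding-window
median (500 neighbouring genes) of the per-gene variance across 10-pg
dilution replicates at matched expression level `x`. `F ≈ 1` means
purely technical variation; `F ≫ 1` flags biological variability.

Around this core the package provides:

* median-of-ratios depth normalization, sample QC, arcsine-PCA and
  saturation curves;
* a reliable-quantification expression threshold selected from
  control-based criteria (completeness, signal twice above noise,
  near-normal control variation, plus a depth–rank diagnostic);
* top-variable-gene selection, a functional-category ANCOVA of log10 F
  with Tukey-style simultaneous contrasts, within/between cell-type
  variances, and cross-species partial correlation of variability
  conditioned on expression;
* outlier-sum / Shapiro–Wilk classification of extreme vs consistent
  expression patterns, divergent genes, and the RNA half-life
  association;
* universal and per-type common-gene identification, a permutation
  Jaccard overlap test and a generic enrichment engine;
* 3' UTR termination-site calling from the antisense−sense read-start
  differential, with per-cell-type coherence classification;
* a synthetic-data generator (`synthetic_spec`, `simulate_*`) that
  emulates the full study design — 91 cells in five cell types, two
  species, 30 dilution replicates, technical noise growing as input and
  expression fall — with planted ground truth for every analysis layer.

## Worked example

```r
library(scvarcal)

spec  <- synthetic_spec(n_genes = 3000, seed = 1)
dil   <- compute_size_factors(simulate_dilution_counts(spec, 10))
cells <- simulate_cell_type_counts(spec, "Car")   # cardiomyocyte-like
nc    <- compute_size_factors(cells$matrix)

curve <- build_control_curve(dil, window_genes = 500)
thr   <- evaluate_reliability_criteria(dil, nc, curve)
thr
#> reliability_threshold (relative frequency):
#>   complete        5.2e-05
#>   variance_ratio  6.2e-05
#>   normality       1.38e-05
#>   selected        6.2e-05
#>   ~ 9.3 input molecules
threshold_to_molecules(thr$selected, 150000)$rounded
#> [1] 9

tab <- f_statistic(nc, curve, thr)
head(tab[order(-tab$f_stat), c("gene_id", "x", "f_stat")], 3)
#>      gene_id        x f_stat
#> 859   g01977 0.002784   75.8
#> 566   g01299 0.000675   50.6
#> 543   g01243 0.000581   47.5
tv <- top_variable_genes(tab, 0.05)
length(tv)
#> [1] 66
```

The selected threshold (relative frequency 6.2e-5) says quantification
is reliable from roughly nine input molecules upward (at 150,000
molecules per cell); 1,313 of the 3,000 simulated genes clear it. The
top-F genes are dominated by the generator's planted hypervariable set:
56 of the 66 selected genes are planted.

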