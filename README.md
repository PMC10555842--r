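# scdvp

Downstream analysis for **single-cell Deep Visual Proteomics (scDVP)** of
zonated liver tissue, for proteomics and spatial-biology researchers who
work with laser-microdissected single-cell ("single-shape") proteomes
measured by multiplexed DIA against a dimethyl-labeled reference channel.

The package covers the full path from a precursor-level report to spatial
biology:

1. **Quantification** — per-precursor target/reference ratios
   (back-transformed median of fragment and MS1 log-ratios), rescaling by
   the median reference intensity across runs, and MaxLFQ protein-group
   collapse: sample profiles x minimize
   Σ<sub>(s,t)</sub> (x<sub>t</sub> − x<sub>s</sub> − m<sub>st</sub>)²
   over pairwise median precursor log-ratios m<sub>st</sub>, anchored to
   the observed summed intensities.
2. **QC and normalization** — identification-count filter
   (median − 1.5·sd, median + 3·sd), 135–1350 µm² size gates, PCA outlier
   flags, and median normalization on the set of proteins quantified in
   100% of retained samples.
3. **Spatial zonation** — the lobular coordinate
   r = d<sub>PV</sub>/(d<sub>PV</sub> + d<sub>CV</sub>), 20 equidistant
   bins, moderated one-way ANOVA per protein (empirical-Bayes variance
   shrinkage, BH-FDR), Shapiro–Wilk flatness calls, bin profiles,
   center-relative log2 fold changes, compartment intensity proportions,
   and pseudo-neighbor aggregation.
4. **Imaging** — 17 image features per shape (mean/median/min/max of the
   four stain channels over the bounding box + shoelace area), contour
   decimation, landmark distances.
5. **Class prediction** — k-means proteome classes (K = 5, spatially
   ordered), a 200-tree random-forest classifier on the image features,
   and probability-weighted spatial proteome reconstruction
   x̂ = Σ<sub>c</sub> p<sub>c</sub> μ̄<sub>c</sub>.
6. **Synthetic lobule generator** — first-class, tested simulation of
   geometry, zonated proteomes (hockey-stick and linear profiles),
   fragment-level mDIA reports, and 4-channel image patches, providing
   exact round-trip oracles for the whole pipeline.

See the methods vignette (`vignettes/scdvp-methods.Rmd`) for the models,
parameter choices and limitations.

## Worked example

```r
library(scdvp)

dimethyl_channel_masses()
#>  delta0  delta4  delta8
#> 28.0313  4.0251  8.0444

truth <- simulate_lobule(n_cells = 400, seed = 1)
pm    <- simulate_proteome(truth)
pm
#> ProteinMatrix: 2000 proteins x 400 samples (76.3% complete)

norm <- median_normalize(pm, completeness = 0.9)$matrix
bins <- assign_bins(truth$cells$r_true, B = 20)
res  <- zonation_anova(norm, bins)

sum(res$tested)
#> [1] 1843
mean(res$fdr[res$tested] < 0.05)
#> [1] 0.4763972

head(res[order(res$fdr), c("protein_id", "F", "fdr", "anova_log2fc")], 3)
#>     protein_id        F fdr anova_log2fc
#> 194      P0194 129.2540   0     2.024013
#> 458      P0458 157.5497   0     2.300273
#> 530      P0530 144.9994   0     2.261083
```

The three channel masses are the light dimethyl fixed modification and the
Δ4/Δ8 spacings computed from the pinned isotope table. On the simulated
lobule (40% of proteins truly zonated, plus detection dropout), 1,843 of
2,000 proteins reach the 50% completeness needed for testing, and roughly
half of them are called zonated at FDR < 0.05; the top hits carry
portal-vs-central log2 fold changes above 2, matching the simulated
amplitudes.

A full run of every stage, including image features and class prediction,
writes its outputs and a manifest to a directory:

```r
res <- run_pipeline(output_dir = "out", seed = 1)
```

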