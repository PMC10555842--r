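---
title: "Methods: single-cell Deep Visual Proteomics downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell Deep Visual Proteomics downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`scdvp` implements the downstream analysis of single-cell Deep Visual
Proteomics (scDVP) experiments on zonated liver tissue: laser-microdissected
single hepatocyte cross-sections ("shapes") are measured by multiplexed
data-independent acquisition (mDIA) against a labeled bulk reference channel,
mapped onto the portal-to-central axis of the liver lobule, tested for spatial
zonation, and connected to microscopy through an image-feature model that
predicts proteome classes and reconstructs spatial proteomes. A synthetic
lobule generator provides data with the statistical structure these analyses
assume, so every stage is testable without access to raw measurement data.

# Quantification model

## Reference-ratio estimation

In the three-plex dimethyl design, each run carries a Δ0 bulk reference
channel and up to two single-shape channels (Δ4, Δ8). For a precursor in one
run, every fragment ion index present in both the target and the reference
channel yields a ratio, and the MS1 areas contribute one more. The overall
precursor ratio is

$$\hat\rho = \exp\left(\mathrm{median}_i \, \log \frac{t_i}{r_i}\right),$$

the back-transformed median of log-ratios over the pooled collection. The
median was chosen over more elaborate candidate-selection schemes because it
is robust to individual corrupted fragments, has a closed form that unit
tests can pin down exactly, and is pluggable should a different summary be
preferred. Whether MS1 is pooled with the fragments is a flag
(`include_ms1`, default `TRUE`); the pooled form uses all available signal.

The unit-free ratio is turned into an intensity by multiplying with the
median per-run reference intensity of that precursor across all runs, where
the per-run reference scalar is the sum of the reference fragment
intensities plus the MS1 area when pooled. A single defensible scalar per
run keeps the rescaling transparent.

## Protein-group collapse (MaxLFQ)

Per protein group, sample log2 abundances $x_s$ minimize

$$\sum_{(s,t)} \left(x_t - x_s - m_{st}\right)^2, \qquad
m_{st} = \mathrm{median}_p \left(\log_2 I_{tp} - \log_2 I_{sp}\right)$$

over sample pairs sharing at least one precursor. The normal equations form
a graph Laplacian whose null space (a common additive constant) is fixed by
a sum-zero gauge; the constant is then anchored so that the mean of $x$
over quantified samples equals the mean of the log2 summed precursor
intensities of those samples. Disconnected sample components within one
protein are solved and anchored independently. No cross-sample median
normalization happens at this stage — normalization is a separate, explicit
step. Zero or missing intensities are treated as missing (`NA`), never as
0, to avoid log singularities. The test suite checks the solver against a
brute-force least-squares oracle on all small instances.

# Sample quality control and normalization

* **Identification-count filter.** A sample is kept iff its detected
  protein count lies within `median − 1.5·sd` and `median + 3·sd` of the
  cohort counts. The spread is the ordinary standard deviation; the bounds
  are centered on the median. An absolute count window is available as
  optional configuration but is off by default: a published kept-range such
  as (806, 3362) describes the realized outcome of the relative rule on a
  particular cohort, not an independent gate, and enforcing "within" such a
  window as an exclusion rule would discard nearly everything.
* **Size gates.** Shapes outside 135–1350 µm² (inclusive) are excluded —
  the segmentation gates of the upstream cytoplasm-segmentation step.
* **PCA outliers.** Samples beyond 5 robust standard deviations (MAD) from
  the median PC1/PC2 score are flagged. The rule is deliberately loose; it
  exists to catch gross failures (empty wells, arterioles), not to trim the
  distribution. The threshold is configurable and logged.
* **Median normalization.** The normalization set is the proteins
  quantified in 100% of retained samples; each sample is shifted in log
  space so its median over that set equals the common median. Restricting
  to fully observed proteins makes the offsets insensitive to the strong
  dependence of identification counts on shape size. If no protein is
  complete, the function fails with an instruction to lower the
  completeness threshold (the pipeline falls back to 0.9).

Exclusion reasons are recorded first-triggered, so the per-reason counts
sum to the number of excluded samples.

# Spatial zonation statistics

The lobular coordinate is $r = d_{PV} / (d_{PV} + d_{CV})$, 0 at the portal
vein and 1 at the central vein. A raw quotient $d_{PV}/d_{CV}$ is unbounded
and cannot equal 1 at the CV, so the normalized form is the only definition
compatible with the stated endpoints. Binning splits $[0,1]$ into B
equidistant intervals, half-open with the last bin closed; B = 20
approximates the number of hepatocytes along the axis, and smaller B (8, 9)
reproduces coarser cross-omics layouts through the same parameter.

Zonation testing is a one-way ANOVA across bins per protein, restricted to
proteins observed in at least 50% of samples. With moderation (default),
residual variances are shrunk toward a pooled prior by empirical Bayes
(limma's `squeezeVar`, i.e. the published variance-shrinkage formulas) and
the F statistic uses the posterior variance with the prior degrees of
freedom added. Benjamini–Hochberg controls FDR across tested proteins. The
plain ANOVA path (`moderation = FALSE`) exists so permutation and hand
oracles can check the machinery without the shrinkage layer.

The "ANOVA fold change" used to order proteins along the axis is defined
here as the mean of the portal-half bin means minus the mean of the
central-half bin means (log2); it is a display ordering, not a test
statistic, and is pluggable.

**Flatness.** A protein is called "expressed equally in all zones" when the
multiple-testing-adjusted Shapiro–Wilk P of its pooled expression exceeds
0.05. This operationalizes flatness through normality of the pooled
distribution — zonated proteins become skewed or multimodal when pooled over
the axis. Note the conflation: a bin-wise equivalence test would be the
statistically natural definition; the normality surrogate is implemented
as described because it is the established convention for this analysis.

**Profiles.** `bin_profile` reports the per-bin mean linear intensity
divided by its sum (an exact simplex over observed bins);
`center_log2fc` references each bin to the median of the two middle bins
(`floor(B/2)` and `floor(B/2)+1`); `annotation_proportions` stratifies
summed linear intensity per bin by annotation sets, pooling unannotated
proteins into `other`.

**Pseudo-neighbors.** To quantify what single-shape resolution adds,
samples sorted by $r$ are combined in consecutive non-overlapping windows
of k (means of observed values; a value is missing only if missing in all
k members; a trailing partial window is dropped), and the PCA of the
combined matrix is summarized by PC1 variance fraction and PC1 score IQR.
A sliding-window mode is available; non-overlapping is the default because
it keeps combined samples independent.

**PCA policy.** Proteins are filtered to ≥70% completeness, remaining
missing values are imputed with the per-protein median, profiles are
centered (optionally scaled), and the SVD is taken. Median imputation was
chosen over model-based imputation to keep the decomposition deterministic
and conservative; the completeness filter keeps the imputed fraction small.
Each component's sign is fixed so its largest-magnitude loading is
positive, making outputs reproducible across platforms.

# Image features

Per shape, the feature vector is the mean, median, minimum and maximum
pixel intensity of the bounding box in each of the four stain channels
(425 nm phalloidin, 488 nm WGA, 568 nm E-cadherin, 647 nm Glul), plus the
shoelace area of the contour: 17 features. Statistics run over the *full*
bounding box by default — the box is the documented unit of the upstream
feature export — with an in-polygon masked variant behind a flag. The
canonical order is channels ascending by wavelength, statistics in the
order mean, median, min, max, area last. Bounding boxes take the floor of
minima and the ceiling of maxima; the 1000 px offset box captures the
surrounding tissue context, clamped to the image. Contour simplification
is uniform decimation (every n-th vertex, first vertex always kept),
matching a "remove 99% of points" specification exactly rather than a
curvature-driven scheme.

# Proteome classes and prediction

Proteomes (completeness-filtered, median-imputed, z-scored per protein) are
clustered by k-means into K = 5 classes, using k-means++ seeding with 10
restarts under a fixed seed and keeping the lowest within-cluster sum of
squares; classes are relabeled 1..K by increasing mean $r$ of their
members, so class adjacency (|label difference| = 1) means spatial
adjacency along the lobular axis. Five classes balance meaningful
separation against samples per class.

The classifier is a 200-tree random forest on the 17 features, trained on
a random 80% split (seed 23, matching the upstream convention for split
and forest). The report carries test accuracy, macro-averaged one-vs-rest
average precision (the area under the precision–recall curve by the
step-wise sum), the confusion matrix, and the fraction of misclassified
test samples whose predicted class is spatially adjacent to the truth.
Exact tree-ensemble outputs are implementation-dependent even at a fixed
seed, so all quality checks are property-based with margins rather than
bit-exact.

Spatial proteome reconstruction uses the class probabilities as weights:
$\hat x = \sum_c p_c \bar\mu_c$ per protein, where $\bar\mu_c$ is the
per-class mean of observed normalized log2 intensities. Proteins lacking a
mean in some class are predicted over the renormalized available classes;
the prediction is affine in the probability vector, which the tests verify
to machine precision. Prediction quality is the pooled Pearson correlation
between predicted and measured entries of a held-out section never used in
clustering or training.

# The synthetic lobule generator

The generator emulates the features of the real data that the analyses
rest on:

* **Geometry.** Cells placed uniformly along the segment between a PV and
  a CV landmark with ±25 µm transverse jitter in a 1000 µm field, so the
  relative distance is close to uniform on [0, 1]; `r_true` is computed
  from landmark distances with the same formula the analysis uses.
* **Zonation profiles.** Five shapes — flat, linear up/down, and
  hockey-stick toward either vein: flat until a breakpoint $r_0$, then
  rising as $((r - r_0)/(1 - r_0))^\gamma$. Defaults: 2000 proteins (a
  per-shape identification depth around 1500, the scale at which
  reference-channel mDIA of single shapes operates), 40% zonated with log2
  amplitudes drawn from [2, 4], breakpoints in [0.2, 0.7], baselines
  N(12, 1.5) on the log2 intensity scale.
* **Shape geometry.** Areas log-normal with median 600 µm² (sdlog 0.4),
  truncated at the 135–1350 µm² segmentation gates; a 10 µm slice of a
  20–30 µm hepatocyte motivates the nuclear-fraction point mass at 0
  (25% anucleate slices), the rest Beta(2, 2).
* **Measurement.** Observed log2 intensity = profile value + 1·log2(area /
  600) + histone coupling (2 log2 units per unit nuclear fraction for the
  four designated histones) + N(0, 0.5) noise — i.e. coefficients of
  variation under ~40%, consistent with sub-50% CVs for this data type.
  Detection is Bernoulli–logistic in the expected log2 intensity (midpoint
  10, scale 1.5) plus 0.8 logits per log2 unit of area. These two terms
  reproduce, by construction, the increase of completeness with protein
  intensity and the logarithmic growth of per-shape protein counts with
  area.
* **Reports.** Each protein splits over precursors with fixed shares
  summing to 1, so summed precursor intensities reconstruct the true
  protein intensity and a zero-noise report round-trips through the
  quantifier to floating-point accuracy — the key end-to-end correctness
  oracle. Q-values are drawn independently per row with a configured
  failure fraction; reference rows always pass, reflecting the high-load
  reference channel.
* **Images.** Channel means encode the axis (568 nm decreasing, 647 nm
  increasing linearly over an 8-bit-like 0–1200 intensity range, per-cell
  jitter sd 30), the 425/488 nm channels are weakly informative, pixels add
  truncated Gaussian noise (sd 80) on 16 px patches.

What the generator does **not** emulate: peptide-level sequence structure,
correlated missingness beyond the abundance/area mechanism, chromatographic
or ion-mobility artifacts, batch effects between runs or sections, spatial
correlation beyond the single lobular axis, arteriole contamination, and
segmentation errors. Tests passing on synthetic data therefore demonstrate
the correctness and calibration of the algorithms under the stated
generative assumptions — not robustness to every failure mode of real
tissue data.

# Numerical conventions and problem sizes

Q-value filters use strict inequalities; area gates are inclusive. Binning
is half-open with the last bin closed at 1. The MaxLFQ gauge is fixed by a
sum-zero constraint before anchoring. k-means ties at identical distances
resolve by the first restart with minimal inertia. All simulation-driven
tests use fixed seeds; derived seeds stay below 2^31. Test problem sizes
were chosen to make the statistical checks sharp while keeping the default
suite fast: 400 cells × 2000 proteins for calibration and power, 500 cells
for the machine-learning properties, with 100-cell held-out sections.

# Known limitations

The reference-ratio estimator is the median-of-log-ratios summary, not a
re-implementation of the full candidate-selection scheme it stands for;
the flatness call inherits the normality-as-flatness conflation discussed
above; PCA median imputation biases variance slightly downward for
low-completeness proteins; and the absolute identification-count window is
interpretation-dependent (see QC section) and therefore off by default.
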