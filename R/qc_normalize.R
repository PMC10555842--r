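#' Identification-count sample filter
#'
#' Flags samples whose number of detected proteins deviates from the
#' cohort: a sample is kept iff its count lies within
#' `median - low_k * sd` and `median + high_k * sd` of the per-sample
#' identification counts. The spread is the ordinary standard
#' deviation, centered bounds use the median. An optional absolute
#' window can additionally be enforced.
#'
#' @param counts Integer vector of detected proteins per sample.
#' @param low_k,high_k Multipliers for the lower / upper bound
#'   (defaults 1.5 and 3).
#' @param window Optional `c(lo, hi)` absolute window additionally
#'   required (inclusive). Off by default.
#' @return List with `keep` (logical), `lower`, `upper` (realized
#'   numeric bounds).
#' @export
id_count_filter <- function(counts, low_k = 1.5, high_k = 3, window = NULL) {
  if (length(counts) < 3) stop("need at least 3 samples", call. = FALSE)
  med <- stats::median(counts)
  s <- stats::sd(counts)
  if (is.na(s)) s <- 0
  lower <- med - low_k * s
  upper <- med + high_k * s
  keep <- counts >= lower & counts <= upper
  if (!is.null(window)) {
    keep <- keep & counts >= window[1] & counts <= window[2]
  }
  list(keep = keep, lower = lower, upper = upper)
}

#' Contour-size sample filter
#'
#' Keeps shapes whose microdissected area lies inside the segmentation
#' gates, 135-1350 square micrometre by default (inclusive bounds).
#'
#' @param areas_um2 Areas in square micrometre; must be positive.
#' @param min_um2,max_um2 Gates (defaults 135 and 1350).
#' @return Logical keep mask; non-positive areas are excluded (with a
#'   warning) rather than erroring the whole cohort.
#' @export
size_filter <- function(areas_um2, min_um2 = 135, max_um2 = 1350) {
  if (!length(areas_um2)) return(logical(0))
  bad <- !is.na(areas_um2) & areas_um2 <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive area excluded",
            call. = FALSE)
  }
  keep <- !is.na(areas_um2) & areas_um2 >= min_um2 & areas_um2 <= max_um2
  keep & !bad
}

#' Median normalization on the fully-quantified protein set
#'
#' Normalizes each sample by the median log2 intensity over the set of
#' proteins quantified in 100% of samples, shifting all samples to the
#' common median of that set. This corrects for the dependence of
#' recovered protein amounts on shape size while being insensitive to
#' missingness, because the normalization set has none.
#'
#' @param x `ProteinMatrix` or proteins x samples log2 matrix.
#' @param completeness Minimum per-protein completeness for membership
#'   in the normalization set (default 1 = quantified everywhere). A
#'   fallback below 1 may be supplied when no protein is complete.
#' @return List with `matrix` (normalized, same class as input),
#'   `norm_proteins` (ids of the normalization set), `offsets`
#'   (per-sample shifts subtracted), `target` (common median).
#' @export
median_normalize <- function(x, completeness = 1) {
  m <- pm_log2(x)
  compl <- rowMeans(!is.na(m))
  set <- which(compl >= completeness)
  if (!length(set)) {
    stop("no protein reaches the completeness threshold (",
         completeness, "); lower `completeness` to define a ",
         "normalization set", call. = FALSE)
  }
  sub <- m[set, , drop = FALSE]
  sample_med <- apply(sub, 2, stats::median, na.rm = TRUE)
  target <- stats::median(sample_med)
  offsets <- sample_med - target
  norm <- sweep(m, 2, offsets, "-")
  list(matrix = pm_rewrap(x, norm),
       norm_proteins = rownames(m)[set],
       offsets = offsets,
       target = target)
}

#' Flag PCA outlier samples
#'
#' Runs the package's PCA (completeness filter + median imputation,
#' see [zonation_pca()]) and flags samples whose PC1 or PC2 score lies
#' more than `n_sd` robust standard deviations (MAD) from the score
#' median.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param n_sd Robust-z threshold (default 5).
#' @param completeness_min Protein completeness filter passed to the
#'   PCA (default 0.7).
#' @return Logical vector, `TRUE` for flagged samples, named by sample.
#' @export
pca_outlier_flag <- function(x, n_sd = 5, completeness_min = 0.7) {
  m <- pm_log2(x)
  flags <- stats::setNames(rep(FALSE, ncol(m)), colnames(m))
  tot_var <- sum(apply(m, 1, stats::var, na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(tot_var) || tot_var == 0) return(flags)  # no spread, no outliers
  p <- zonation_pca(m, completeness_min = completeness_min)
  for (pc in seq_len(min(2L, ncol(p$scores)))) {
    sc <- p$scores[, pc]
    md <- stats::mad(sc)
    if (md == 0) next
    flags <- flags | abs(sc - stats::median(sc)) > n_sd * md
  }
  flags
}

#' Apply all sample-level quality filters
#'
#' Combines the identification-count filter, the size gates and the
#' PCA outlier flag into one QC table with a first-triggered exclusion
#' reason per sample.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param areas_um2 Per-sample shape areas, aligned with the columns.
#' @param low_k,high_k,id_window Passed to [id_count_filter()].
#' @param min_um2,max_um2 Passed to [size_filter()].
#' @param pca_n_sd Passed to [pca_outlier_flag()]; applied on the
#'   samples surviving the first two filters.
#' @return Data frame: `sample_id`, `n_proteins`, `area_um2`, `keep`,
#'   `excluded_reason` in `{none, id_low, id_high, size, pca_outlier}`.
#' @export
sample_qc <- function(x, areas_um2, low_k = 1.5, high_k = 3,
                      id_window = NULL, min_um2 = 135, max_um2 = 1350,
                      pca_n_sd = 5) {
  m <- pm_log2(x)
  stopifnot(length(areas_um2) == ncol(m))
  counts <- colSums(!is.na(m))
  idf <- id_count_filter(counts, low_k, high_k, window = id_window)
  reason <- rep("none", ncol(m))
  reason[counts < idf$lower] <- "id_low"
  reason[counts > idf$upper] <- "id_high"
  if (!is.null(id_window)) {
    reason[reason == "none" & counts < id_window[1]] <- "id_low"
    reason[reason == "none" & counts > id_window[2]] <- "id_high"
  }
  sz <- suppressWarnings(size_filter(areas_um2, min_um2, max_um2))
  reason[reason == "none" & !sz] <- "size"
  pre_keep <- reason == "none"
  if (sum(pre_keep) >= 3) {
    pf <- pca_outlier_flag(m[, pre_keep, drop = FALSE], n_sd = pca_n_sd)
    reason[pre_keep][pf] <- "pca_outlier"
  }
  data.frame(sample_id = colnames(m), n_proteins = as.integer(counts),
             area_um2 = areas_um2, keep = reason == "none",
             excluded_reason = reason, stringsAsFactors = FALSE)
}
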