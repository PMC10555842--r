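#' Relative position on the portal-to-central axis
#'
#' Normalized lobular coordinate from the measured distances of a
#' shape to its nearest portal vein (PV) and central vein (CV):
#' `r = d_pv / (d_pv + d_cv)`, 0 at the PV and 1 at the CV.
#'
#' @param d_pv,d_cv Distances in micrometre, both >= 0, not both 0.
#'   Vectorized.
#' @return Relative distance r in `[0, 1]`.
#' @export
relative_distance <- function(d_pv, d_cv) {
  if (any(d_pv < 0 | d_cv < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  tot <- d_pv + d_cv
  if (any(tot == 0, na.rm = TRUE)) {
    stop("d_pv and d_cv cannot both be 0", call. = FALSE)
  }
  d_pv / tot
}

#' Assign relative distances to equidistant spatial bins
#'
#' Splits `[0, 1]` into `B` equal intervals; bin i covers
#' `[(i-1)/B, i/B)` with the last bin closed at 1. Twenty bins match
#' the approximate number of hepatocytes along the PV-to-CV axis; other
#' values (e.g. 8 or 9) reproduce coarser layouts used for cross-omics
#' rebinning.
#'
#' @param r Relative distances in `[0, 1]`.
#' @param B Number of bins (default 20, must be >= 2).
#' @return Integer bin ids in `1..B`.
#' @export
assign_bins <- function(r, B = 20) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (any(r < 0 | r > 1, na.rm = TRUE)) {
    stop("r must lie in [0, 1]", call. = FALSE)
  }
  pmin.int(as.integer(floor(r * B)) + 1L, as.integer(B))
}

# Per-protein per-bin observation counts, sums and means for a
# proteins x samples matrix: all vectorized over proteins.
bin_summaries <- function(m, bins) {
  bins <- as.integer(bins)
  B <- max(bins)
  ind <- matrix(0, ncol(m), B)
  ind[cbind(seq_len(ncol(m)), bins)] <- 1
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  n_pb <- obs %*% ind
  sum_pb <- m0 %*% ind
  mean_pb <- sum_pb / n_pb
  mean_pb[n_pb == 0] <- NA_real_
  list(n = n_pb, sum = sum_pb, mean = mean_pb, B = B)
}

#' Zonation ANOVA across spatial bins
#'
#' One-way analysis of variance per protein across the spatial bins,
#' on proteins quantified in at least `completeness_min` of the
#' samples. With `moderation = TRUE` (default) the per-protein
#' residual variances are shrunk toward a common prior by empirical
#' Bayes (limma's squeezeVar) before the F statistic is formed, and p
#' comes from the F distribution with the prior degrees of freedom
#' added to the residual ones. P values are corrected by
#' Benjamini-Hochberg across all tested proteins. The ANOVA log2 fold
#' change orders proteins along the axis: mean of the portal-half bin
#' means minus the mean of the central-half bin means.
#'
#' @param x `ProteinMatrix` or proteins x samples log2 matrix.
#' @param bins Integer bin id per sample (see [assign_bins()]).
#' @param completeness_min Minimum fraction of samples in which a
#'   protein must be observed to be tested (default 0.5).
#' @param moderation Use empirical-Bayes variance shrinkage (default
#'   TRUE); FALSE gives the plain one-way ANOVA.
#' @return Data frame, one row per protein: `protein_id`, `tested`,
#'   `F`, `p`, `fdr`, `anova_log2fc`, `df1`, `df2`.
#' @export
zonation_anova <- function(x, bins, completeness_min = 0.5,
                           moderation = TRUE) {
  m <- pm_log2(x)
  stopifnot(length(bins) == ncol(m))
  bs <- bin_summaries(m, bins)
  n_tot <- rowSums(bs$n)
  compl <- n_tot / ncol(m)
  # testability: >= 2 bins with >= 2 samples, positive residual df
  g <- rowSums(bs$n > 0)
  df1 <- g - 1
  df2 <- n_tot - g
  tested <- compl >= completeness_min & rowSums(bs$n >= 2) >= 2 &
    df1 >= 1 & df2 >= 1

  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0
  grand <- rowSums(m0) / n_tot
  ss_tot <- rowSums(m0^2) - n_tot * grand^2
  ssb <- rowSums(bs$n * (bs$mean - grand)^2, na.rm = TRUE)
  ssw <- pmax(ss_tot - ssb, 0)
  msb <- ssb / df1
  s2 <- ssw / df2

  Fstat <- rep(NA_real_, nrow(m))
  p <- rep(NA_real_, nrow(m))
  df2_used <- df2
  if (any(tested)) {
    if (moderation) {
      sv <- limma::squeezeVar(s2[tested], df2[tested])
      denom <- sv$var.post
      extra_df <- sv$df.prior
      if (!is.finite(extra_df)) extra_df <- 1e6  # effectively pooled
      df2_used[tested] <- df2[tested] + extra_df
    } else {
      denom <- s2[tested]
    }
    Fv <- msb[tested] / denom
    # constant proteins: no between- or within-bin variance -> F = 0
    Fv[!is.finite(Fv)] <- 0
    Fstat[tested] <- Fv
    p[tested] <- stats::pf(Fv, df1[tested], df2_used[tested],
                           lower.tail = FALSE)
  }
  fdr <- rep(NA_real_, nrow(m))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")

  B <- bs$B
  portal_bins <- seq_len(floor(B / 2))
  central_bins <- setdiff(seq_len(B), portal_bins)
  fc <- rowMeans(bs$mean[, portal_bins, drop = FALSE], na.rm = TRUE) -
    rowMeans(bs$mean[, central_bins, drop = FALSE], na.rm = TRUE)

  data.frame(protein_id = rownames(m), tested = tested, F = Fstat, p = p,
             fdr = fdr, anova_log2fc = fc, df1 = df1, df2 = df2_used,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flatness verdict by Shapiro-Wilk normality
#'
#' Proteins whose expression across all samples is compatible with a
#' single Gaussian (multiple-testing-adjusted Shapiro-Wilk P > alpha)
#' are flagged flat, i.e. expressed equally in all zones; zonated
#' proteins produce skewed or multimodal pooled distributions that
#' fail the test. Note this operationalizes flatness through
#' normality of the pooled distribution, not through a bin-wise
#' equivalence test.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param alpha Adjusted-P threshold (default 0.05).
#' @return Data frame `protein_id`, `W`, `p`, `fdr`, `flat` (`NA` for
#'   proteins with fewer than 3 observations).
#' @export
flatness_test <- function(x, alpha = 0.05) {
  m <- pm_log2(x)
  res <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    if (length(v) < 3 || diff(range(v)) == 0 || length(v) > 5000) {
      return(c(NA_real_, NA_real_))
    }
    sw <- stats::shapiro.test(v)
    c(sw$statistic, sw$p.value)
  })
  res <- do.call(rbind, res)
  fdr <- rep(NA_real_, nrow(m))
  ok <- !is.na(res[, 2])
  fdr[ok] <- stats::p.adjust(res[ok, 2], method = "BH")
  data.frame(protein_id = rownames(m), W = res[, 1], p = res[, 2],
             fdr = fdr, flat = fdr > alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Relative expression profile over spatial bins
#'
#' Per protein: the mean linear-scale intensity in each bin, divided
#' by the sum over bins, so every profile is a simplex over the bins
#' in which the protein was observed.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param bins Integer bin id per sample.
#' @return Proteins x B matrix of fractions summing to 1 over observed
#'   bins (`NA` in unobserved bins).
#' @export
bin_profile <- function(x, bins) {
  m <- 2^pm_log2(x)
  bs <- bin_summaries(m, bins)
  prof <- bs$mean / rowSums(bs$mean, na.rm = TRUE)
  dimnames(prof) <- list(rownames(m), paste0("bin", seq_len(bs$B)))
  prof
}

#' Bin-wise log2 fold change relative to the lobule midzone
#'
#' Expresses each bin's mean intensity as log2 fold change over the
#' median of the two center bins' means, highlighting portal versus
#' central activity around a midzonal reference.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param bins Integer bin id per sample (B >= 2 bins).
#' @return Proteins x B matrix of log2 fold changes; rows where a
#'   center-bin reference cannot be formed are `NA` entirely.
#' @export
center_log2fc <- function(x, bins) {
  m <- 2^pm_log2(x)
  bs <- bin_summaries(m, bins)
  B <- bs$B
  centers <- c(floor(B / 2), floor(B / 2) + 1L)
  ref <- apply(bs$mean[, centers, drop = FALSE], 1, stats::median)
  bad <- is.na(ref) | ref <= 0
  out <- log2(bs$mean / ref)
  out[bad, ] <- NA_real_
  dimnames(out) <- list(rownames(m), paste0("bin", seq_len(B)))
  out
}

#' Proportion of summed intensity per annotation set and bin
#'
#' Stratifies total protein signal per spatial bin by annotation sets
#' (e.g. subcellular compartments): within each bin, the summed
#' linear intensity of each set divided by the bin's total. Proteins
#' not covered by any set are pooled into `"other"`.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param sets Named list of protein id vectors.
#' @param bins Integer bin id per sample.
#' @return Sets x B matrix of fractions; each non-empty bin column
#'   sums to 1. Empty bins are dropped with a message.
#' @export
annotation_proportions <- function(x, sets, bins) {
  m <- 2^pm_log2(x)
  ids <- rownames(m)
  assigned <- unique(unlist(sets))
  other <- setdiff(ids, assigned)
  if (length(other)) sets <- c(sets, list(other = other))
  bins <- as.integer(bins)
  B <- max(bins)
  out <- matrix(NA_real_, length(sets), B,
                dimnames = list(names(sets), paste0("bin", seq_len(B))))
  for (b in seq_len(B)) {
    cols <- bins == b
    if (!any(cols)) {
      message("bin ", b, " has no samples; omitted")
      next
    }
    sub <- m[, cols, drop = FALSE]
    tot <- sum(sub, na.rm = TRUE)
    if (tot == 0) next
    out[, b] <- vapply(sets, function(s) {
      sum(sub[intersect(s, ids), , drop = FALSE], na.rm = TRUE) / tot
    }, numeric(1))
  }
  out
}

#' Pseudo-neighbor aggregation along the zonation axis
#'
#' Emulates coarser sampling by combining shapes adjacent in relative
#' distance: samples are sorted by r and consecutive groups of k are
#' averaged per protein (mean of observed values; a combined value is
#' missing only when all k members are missing). A PCA on the
#' combined matrix quantifies how much axis information the
#' aggregation recovers: the fraction of variance on PC1 and the
#' interquartile range of PC1 scores.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param r Relative distance per sample.
#' @param k Group size (>= 1, <= number of samples).
#' @param mode `"blocks"` (non-overlapping consecutive windows,
#'   default; a trailing partial window is dropped) or `"sliding"`
#'   (every window of k consecutive samples).
#' @param completeness_min Passed to the PCA.
#' @return List: `matrix` (combined log2 matrix), `r` (mean r per
#'   group), `k`, `pc_variance_explained`, `pc1_iqr`.
#' @export
pseudo_neighbors <- function(x, r, k, mode = c("blocks", "sliding"),
                             completeness_min = 0.7) {
  mode <- match.arg(mode)
  m <- pm_log2(x)
  stopifnot(length(r) == ncol(m))
  if (k < 1 || k > ncol(m)) stop("k must be in 1..n samples", call. = FALSE)
  ord <- order(r)
  m <- m[, ord, drop = FALSE]
  r <- r[ord]
  if (mode == "blocks") {
    n_grp <- floor(ncol(m) / k)
    starts <- (seq_len(n_grp) - 1L) * k + 1L
  } else {
    n_grp <- ncol(m) - k + 1L
    starts <- seq_len(n_grp)
  }
  comb <- matrix(NA_real_, nrow(m), n_grp,
                 dimnames = list(rownames(m), paste0("pn", seq_len(n_grp))))
  r_comb <- numeric(n_grp)
  for (gix in seq_len(n_grp)) {
    cols <- starts[gix]:(starts[gix] + k - 1L)
    comb[, gix] <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
    r_comb[gix] <- mean(r[cols])
  }
  comb[is.nan(comb)] <- NA_real_
  p <- zonation_pca(comb, completeness_min = completeness_min)
  list(matrix = comb, r = r_comb, k = k,
       pc_variance_explained = p$variance_fraction,
       pc1_iqr = stats::IQR(p$scores[, 1]))
}

#' PCA of single-shape proteomes
#'
#' Principal component analysis over samples: proteins are filtered to
#' a minimum completeness, remaining missing values are imputed with
#' the per-protein median, profiles are centered (and optionally
#' scaled to unit variance), and the decomposition is computed by SVD.
#' The sign of each component is fixed so its largest-magnitude
#' loading is positive, making output deterministic.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param completeness_min Minimum fraction of samples in which a
#'   protein must be observed (default 0.7).
#' @param scale Scale proteins to unit variance (default FALSE).
#' @param n_components Components to return (default
#'   `min(n samples, n proteins) - 1` capped at 10).
#' @return List: `scores` (samples x components), `loadings`
#'   (proteins x components), `variance_fraction`.
#' @export
zonation_pca <- function(x, completeness_min = 0.7, scale = FALSE,
                         n_components = NULL) {
  m <- pm_log2(x)
  keep <- rowMeans(!is.na(m)) >= completeness_min
  if (sum(keep) < 2 || ncol(m) < 2) {
    stop("need >= 2 proteins passing completeness and >= 2 samples",
         call. = FALSE)
  }
  m <- m[keep, , drop = FALSE]
  # per-protein median imputation of what the completeness filter left
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    m[nas] <- med[nas[, 1]]
  }
  sds <- apply(m, 1, stats::sd)
  if (all(sds == 0)) stop("matrix is constant; PCA undefined", call. = FALSE)
  if (scale) {
    m <- m[sds > 0, , drop = FALSE]
  }
  pr <- stats::prcomp(t(m), center = TRUE, scale. = scale)
  k <- min(ncol(pr$x), if (is.null(n_components)) 10L else n_components)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varfrac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = load,
       variance_fraction = varfrac[seq_len(k)])
}
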