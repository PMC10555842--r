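test_that("relative distance normalizes PV/CV distances onto [0,1]", {
  expect_equal(relative_distance(0, 80), 0)
  expect_equal(relative_distance(40, 40), 0.5)
  expect_equal(relative_distance(30, 10), 0.75)
  expect_error(relative_distance(0, 0), "both")
  expect_error(relative_distance(-1, 5), "non-negative")
})

test_that("equidistant binning follows the half-open convention", {
  expect_equal(assign_bins(0, 20), 1L)
  expect_equal(assign_bins(1, 20), 20L)
  expect_equal(assign_bins(0.5, 20), 11L)
  # generic bin counts for cross-omics layouts
  expect_equal(assign_bins(c(0, 0.999, 1), 9), c(1L, 9L, 9L))
  expect_equal(max(assign_bins(runif(500), 9)), 9L)
  expect_error(assign_bins(1.2, 20), "\\[0, 1\\]")
  expect_error(assign_bins(0.5, 1), "B")
})

test_that("one-way ANOVA matches the hand-computed example", {
  m <- named_matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  res <- zonation_anova(m, bins = c(1, 1, 1, 2, 2, 2),
                        completeness_min = 0, moderation = FALSE)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$p, 0.0214, tolerance = 1e-2)
  # a constant protein has no between-bin variance
  m2 <- rbind(m, P0002 = rep(7, 6))
  res2 <- zonation_anova(m2, bins = c(1, 1, 1, 2, 2, 2),
                         completeness_min = 0, moderation = FALSE)
  expect_equal(res2$F[2], 0)
  expect_equal(res2$p[2], 1)
  # portal-half minus central-half log2 difference
  expect_equal(res$anova_log2fc, mean(1:3) - mean(4:6))
})

test_that("ANOVA p-values are calibrated under bin-label permutation", {
  set.seed(21)
  null_protein <- rnorm(60, 10, 1)
  perms <- t(vapply(1:1000, function(i) sample(null_protein), numeric(60)))
  dimnames(perms) <- list(sprintf("perm%04d", 1:1000), sprintf("s%03d", 1:60))
  bins <- rep(1:5, each = 12)
  res <- zonation_anova(perms, bins, completeness_min = 0, moderation = FALSE)
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("moderated F gains degrees of freedom and stays calibrated", {
  set.seed(31)
  m <- named_matrix(rnorm(200 * 40, 10, 1), 200, 40)
  bins <- rep(1:4, each = 10)
  plain <- zonation_anova(m, bins, moderation = FALSE)
  mod <- zonation_anova(m, bins, moderation = TRUE)
  expect_true(all(mod$df2 >= plain$df2))
  expect_lte(mean(mod$fdr < 0.05), 0.07)
  # fdr is never below p under BH
  expect_true(all(mod$fdr >= mod$p - 1e-12, na.rm = TRUE))
})

test_that("untestable proteins are reported, not tested", {
  m <- named_matrix(NA_real_, 2, 6)
  m[1, ] <- 1:6
  m[2, 1:2] <- c(4, 5)  # observed in one bin only
  res <- zonation_anova(m, bins = c(1, 1, 1, 2, 2, 2), completeness_min = 0)
  expect_false(res$tested[2])
  expect_true(is.na(res$F[2]))
})

test_that("flatness verdict follows adjusted Shapiro-Wilk", {
  set.seed(5)
  gauss <- rnorm(200, 10, 1)
  bimodal <- c(rnorm(100, 10, 1), rnorm(100, 16, 1))
  m <- rbind(P0001 = gauss, P0002 = bimodal)
  colnames(m) <- sprintf("s%03d", 1:200)
  res <- flatness_test(m)
  expect_true(res$flat[1])
  expect_false(res$flat[2])
  # reference implementation agreement on the bimodal row
  expect_equal(res$p[2], shapiro.test(bimodal)$p.value)
  expect_true(all(res$fdr >= res$p, na.rm = TRUE))
  # too few observations: not tested
  tiny <- named_matrix(c(1, 2, rep(NA, 4)), 1, 6)
  expect_true(is.na(flatness_test(tiny)$flat))
})

test_that("bin profiles are simplexes over observed bins", {
  m <- named_matrix(log2(c(1, 1, 2)), 1, 3)
  prof <- bin_profile(m, bins = 1:3)
  expect_equal(as.numeric(prof), c(0.25, 0.25, 0.5))
  # constant protein: uniform profile
  flatm <- named_matrix(3, 1, 6)
  expect_equal(as.numeric(bin_profile(flatm, rep(1:3, 2))), rep(1 / 3, 3))
  # scale invariance: multiplying linear intensity by a constant
  expect_equal(bin_profile(m + log2(7), bins = 1:3), prof)
  # simplex property on simulated data
  truth <- simulate_lobule(60, seed = 2, n_proteins = 40)
  pm <- simulate_proteome(truth)
  pr <- bin_profile(pm, assign_bins(truth$cells$r_true, 20))
  expect_true(all(abs(rowSums(pr, na.rm = TRUE) - 1) < 1e-12))
})

test_that("center-relative log2FC uses the median of the two middle bins", {
  m <- named_matrix(log2(c(2, 2, 4, 8)), 1, 4)
  fc <- center_log2fc(m, bins = 1:4)
  expect_equal(as.numeric(fc), log2(c(2, 2, 4, 8) / 3), tolerance = 1e-12)
  expect_equal(round(as.numeric(fc), 3), c(-0.585, -0.585, 0.415, 1.415))
  # flat protein: all-zero vector
  flatm <- named_matrix(5, 1, 4)
  expect_equal(as.numeric(center_log2fc(flatm, 1:4)), rep(0, 4))
  # adding a log-space constant cancels in the ratio
  expect_equal(center_log2fc(m + 3, bins = 1:4), fc)
})

test_that("annotation proportions stratify summed intensity per bin", {
  m <- named_matrix(log2(c(3, 1, 3, 1)), 2, 2)  # set A rows sum 3x set B
  sets <- list(A = "P0001", B = "P0002")
  props <- annotation_proportions(m, sets, bins = c(1, 2))
  expect_equal(unname(props[, 1]), c(0.75, 0.25))
  expect_equal(colSums(props), c(bin1 = 1, bin2 = 1))
  # a set holding every protein takes fraction 1
  all_in <- annotation_proportions(m, list(all = c("P0001", "P0002")),
                                   bins = c(1, 2))
  expect_equal(unname(all_in["all", ]), c(1, 1))
  # unannotated proteins pool into "other"
  part <- annotation_proportions(m, list(A = "P0001"), bins = c(1, 2))
  expect_true("other" %in% rownames(part))
  expect_equal(colSums(part), c(bin1 = 1, bin2 = 1))
  # invariant to protein order
  perm <- annotation_proportions(m[2:1, ], sets, bins = c(1, 2))
  expect_equal(perm[c("A", "B"), ], props[c("A", "B"), ])
})

test_that("pseudo-neighbors average consecutive shapes along r", {
  m <- named_matrix(c(1, 3, 5, 7), 1, 4)
  r <- c(0.1, 0.2, 0.6, 0.9)
  # k = 1 leaves the matrix unchanged (PCA needs >= 2 proteins; add one)
  m2 <- rbind(m, P0002 = c(2, 4, 8, 16))
  pn1 <- pseudo_neighbors(m2, r, k = 1)
  expect_equal(unname(pn1$matrix), unname(m2))
  pn2 <- pseudo_neighbors(m2, r, k = 2)
  expect_equal(unname(pn2$matrix[1, ]), c(2, 6))
  # grand mean conserved when k divides n
  expect_equal(rowMeans(pn2$matrix), rowMeans(m2))
  # missing only when missing in all members
  m2[1, 1] <- NA
  pn3 <- pseudo_neighbors(m2, r, k = 2)
  expect_equal(unname(pn3$matrix[1, ]), c(3, 6))
  expect_error(pseudo_neighbors(m2, r, k = 9), "k must")
})

test_that("pseudo-neighbor PC1 importance grows with k on zonated data", {
  truth <- simulate_lobule(400, seed = 13, n_proteins = 400)
  pm <- simulate_proteome(truth)
  r <- truth$cells$r_true
  v <- vapply(c(1, 2, 4), function(k) {
    pseudo_neighbors(pm, r, k)$pc_variance_explained[1]
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("PCA matches a brute-force SVD and fixes signs", {
  m <- named_matrix(c(4, 2, 1, 7, 3, 2, 1, 9, 5), 3, 3)
  res <- zonation_pca(m, completeness_min = 0)
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  sv <- svd(centered)
  scores_oracle <- sv$u %*% diag(sv$d)
  for (j in seq_len(ncol(res$scores))) {
    expect_equal(abs(unname(res$scores[, j])), abs(scores_oracle[, j]),
                 tolerance = 1e-9)
    # sign convention: the largest-magnitude loading is positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  # two perfectly correlated proteins: rank 1
  m2 <- named_matrix(c(1, 2, 3, 5, 2, 4, 6, 10, 3, 6, 9, 15), 4, 3)[1:2, ]
  m2[2, ] <- 2 * m2[1, ]
  expect_equal(zonation_pca(m2, completeness_min = 0)$variance_fraction[1], 1)
  expect_error(zonation_pca(named_matrix(1, 3, 3), completeness_min = 0),
               "constant")
})

test_that("larger hockey amplitudes yield larger F statistics", {
  base <- simulate_lobule(200, seed = 17, n_proteins = 10,
                          zonated_fraction = 0)
  f_at <- function(amp) {
    tr <- base
    tr$profiles$shape_kind[1] <- "hockey_central"
    tr$profiles$amplitude[1] <- amp
    tr$profiles$r0[1] <- 0.4
    tr$profiles$gamma[1] <- 1
    pm <- simulate_proteome(tr, seed = 99)
    res <- zonation_anova(pm, assign_bins(tr$cells$r_true, 20))
    res$F[1]
  }
  f_small <- f_at(0.5)
  f_large <- f_at(3)
  expect_gt(f_large, f_small)
})
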