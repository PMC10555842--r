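# k-means++ seeding: spread initial centers by distance-proportional
# sampling, then polish with Lloyd iterations.
kmeanspp_once <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in seq_len(K)[-1]) {
    if (all(d2 == 0)) {
      centers[k, ] <- X[sample.int(n, 1), ]
      next
    }
    centers[k, ] <- X[sample.int(n, 1, prob = d2), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

#' Proteome classes by k-means clustering
#'
#' Clusters single-shape proteomes into K classes in z-scored protein
#' space. Proteins are first reduced with the package's PCA
#' completeness/imputation policy (completeness filter + per-protein
#' median imputation, see [zonation_pca()]), then z-scored per
#' protein. k-means uses k-means++ seeding with `nstart` restarts
#' under a fixed seed, keeping the solution with the lowest total
#' within-cluster sum of squares. Classes are relabeled 1..K by
#' increasing mean relative distance of their members, so class 1 is
#' the most portal and class K the most central.
#'
#' @param x `ProteinMatrix` or log2 matrix.
#' @param r Relative distance per sample (used only for the spatial
#'   relabeling).
#' @param K Number of classes (default 5).
#' @param seed Seed for the restarts.
#' @param nstart Number of k-means++ restarts (default 10).
#' @param completeness_min Protein completeness filter (default 0.7).
#' @return Object of class `proteome_class_model`: `K`, `labels`
#'   (spatially ordered, named by sample), `centroids` (K x proteins,
#'   z-score space), `class_mean_r`, `proteins` (ids used),
#'   `scale_center`/`scale_sd` (the z-scoring parameters).
#' @export
kmeans_classes <- function(x, r, K = 5, seed = 1, nstart = 10,
                           completeness_min = 0.7) {
  m <- pm_log2(x)
  stopifnot(length(r) == ncol(m))
  if (K > ncol(m)) stop("K cannot exceed the number of samples", call. = FALSE)
  keep <- rowMeans(!is.na(m)) >= completeness_min
  m <- m[keep, , drop = FALSE]
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    m[nas] <- med[nas[, 1]]
  }
  ctr <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  sds[sds == 0] <- 1
  Z <- t((m - ctr) / sds)  # samples x proteins, z-scored
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- kmeanspp_once(Z, K)
    km <- suppressWarnings(
      stats::kmeans(Z, centers = init, iter.max = 100, algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  mean_r <- tapply(r, best$cluster, mean)
  ord <- order(mean_r)  # portal to central
  relabel <- integer(K)
  relabel[as.integer(names(mean_r))[ord]] <- seq_len(K)
  labels <- relabel[best$cluster]
  names(labels) <- colnames(pm_log2(x))
  structure(list(
    K = K,
    labels = labels,
    centroids = best$centers[as.integer(names(mean_r))[ord], , drop = FALSE],
    class_mean_r = as.numeric(sort(mean_r)),
    proteins = rownames(m),
    scale_center = ctr,
    scale_sd = sds
  ), class = "proteome_class_model")
}

#' Class mean proteomes on the normalized log2 scale
#'
#' Per class, the per-protein mean of observed normalized log2
#' intensities over that class's members: the building block of the
#' probability-weighted proteome prediction.
#'
#' @param x `ProteinMatrix` or log2 matrix (all proteins, may contain
#'   `NA`).
#' @param labels Integer class label per sample.
#' @return Proteins x K matrix of class means (`NA` where a class has
#'   no observation for a protein).
#' @export
class_mean_proteomes <- function(x, labels) {
  m <- pm_log2(x)
  stopifnot(length(labels) == ncol(m))
  K <- max(labels)
  out <- sapply(seq_len(K), function(k) {
    rowMeans(m[, labels == k, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  colnames(out) <- paste0("class", seq_len(K))
  out
}

#' Train the image-feature proteome-class classifier
#'
#' Random split into train and test at `test_fraction` under a fixed
#' seed, then a 200-tree random forest fit on the 17 image features.
#' The report carries the test accuracy, the macro-averaged
#' one-vs-rest average precision, the confusion matrix, and the
#' fraction of misclassified test samples whose predicted class is
#' spatially adjacent to the true one (|class difference| = 1 in the
#' portal-to-central class order).
#'
#' @param features Samples x 17 numeric matrix (see
#'   [extract_features()]).
#' @param labels Integer class labels per sample (spatially ordered,
#'   e.g. from [kmeans_classes()]).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Random state for split and forest (default 23).
#' @param n_trees Trees in the ensemble (default 200).
#' @return List of class `class_predictor`: `model` (the fitted
#'   forest), `train_idx`, `test_idx`, and `report` with
#'   `test_accuracy`, `average_precision`, `confusion`,
#'   `neighbor_error_fraction`.
#' @export
train_classifier <- function(features, labels, test_fraction = 0.2,
                             seed = 23, n_trees = 200) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  }
  n <- nrow(features)
  set.seed(seed)
  test_idx <- sort(sample.int(n, max(1L, round(n * test_fraction))))
  train_idx <- setdiff(seq_len(n), test_idx)
  ytr <- factor(labels[train_idx], levels = sort(unique(labels)))
  fit <- randomForest::randomForest(x = features[train_idx, , drop = FALSE],
                                    y = ytr, ntree = n_trees)
  prob <- predict(fit, features[test_idx, , drop = FALSE], type = "prob")
  pred <- as.integer(colnames(prob)[max.col(prob, ties.method = "first")])
  truth <- labels[test_idx]
  lev <- sort(unique(labels))
  confusion <- table(factor(truth, levels = lev),
                     factor(pred, levels = lev))
  acc <- mean(pred == truth)
  ap <- mean(vapply(seq_along(lev), function(j) {
    average_precision(truth == lev[j],
                      prob[, match(as.character(lev[j]), colnames(prob))])
  }, numeric(1)), na.rm = TRUE)
  mis <- pred != truth
  nef <- if (any(mis)) mean(abs(pred[mis] - truth[mis]) == 1) else NA_real_
  structure(list(
    model = fit,
    train_idx = train_idx,
    test_idx = test_idx,
    report = list(test_accuracy = acc, average_precision = ap,
                  confusion = confusion, neighbor_error_fraction = nef)
  ), class = "class_predictor")
}

# Area under the precision-recall curve by the step-wise sum
# sum_n (R_n - R_{n-1}) P_n over descending score thresholds.
average_precision <- function(is_pos, score) {
  if (!any(is_pos)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / sum(is_pos)
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Predict class probabilities from image features
#'
#' @param predictor A [train_classifier()] result.
#' @param features Samples x 17 matrix.
#' @return Samples x K matrix of class probabilities; rows sum to 1.
#'   Attribute `max_class`/`max_prob` give the argmax class and its
#'   probability (the hue used for map coloring).
#' @export
predict_probabilities <- function(predictor, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(predictor$model$importance)) {
    stop("feature dimension does not match the trained model", call. = FALSE)
  }
  prob <- predict(predictor$model, features, type = "prob")
  prob <- prob / rowSums(prob)
  structure(prob,
            max_class = as.integer(colnames(prob)[max.col(prob, "first")]),
            max_prob = apply(prob, 1, max))
}

#' Probability-weighted spatial proteome prediction
#'
#' Predicts each cell's proteome as the probability-weighted mixture
#' of the class mean proteomes: `x_hat = sum_c p_c * mu_c` per
#' protein. Proteins missing a class mean in some class are predicted
#' over the renormalized available classes; proteins with no class
#' mean at all are omitted.
#'
#' @param probabilities Cells x K probability matrix (rows sum to 1).
#' @param class_means Proteins x K matrix from
#'   [class_mean_proteomes()].
#' @return Proteins x cells matrix of predicted normalized log2
#'   intensities.
#' @export
weighted_proteome_prediction <- function(probabilities, class_means) {
  P <- as.matrix(probabilities)
  M <- as.matrix(class_means)
  stopifnot(ncol(P) == ncol(M))
  keep <- rowSums(!is.na(M)) > 0
  if (!all(keep)) {
    message(sum(!keep), " protein(s) without any class mean omitted")
  }
  M <- M[keep, , drop = FALSE]
  obs <- !is.na(M)
  M0 <- M; M0[!obs] <- 0
  num <- M0 %*% t(P)              # proteins x cells
  den <- obs %*% t(P)             # renormalization over available classes
  out <- num / den
  out[den == 0] <- NA_real_
  rownames(out) <- rownames(M)
  colnames(out) <- rownames(P)
  out
}

#' Correlation between predicted and measured proteomes
#'
#' Pooled Pearson correlation over all overlapping protein x cell
#' entries of predicted versus measured normalized log2 intensities,
#' plus the per-protein correlation distribution.
#'
#' @param predicted Proteins x cells matrix (e.g. from
#'   [weighted_proteome_prediction()]).
#' @param measured `ProteinMatrix` or matrix with shared protein and
#'   cell names.
#' @return List: `R` (pooled Pearson), `n` (overlapping entries),
#'   `per_protein` (data frame `protein_id`, `R`, `n`).
#' @export
evaluate_prediction <- function(predicted, measured) {
  meas <- pm_log2(measured)
  prots <- intersect(rownames(predicted), rownames(meas))
  cellsv <- intersect(colnames(predicted), colnames(meas))
  if (length(prots) == 0 || length(cellsv) == 0) {
    stop("no overlapping proteins/cells", call. = FALSE)
  }
  P <- predicted[prots, cellsv, drop = FALSE]
  Y <- meas[prots, cellsv, drop = FALSE]
  ok <- !is.na(P) & !is.na(Y)
  if (sum(ok) < 3) stop("fewer than 3 overlapping entries", call. = FALSE)
  pooled <- stats::cor(P[ok], Y[ok])
  per <- lapply(seq_along(prots), function(i) {
    oki <- ok[i, ]
    r <- if (sum(oki) >= 3 && stats::sd(P[i, oki]) > 0 &&
             stats::sd(Y[i, oki]) > 0) {
      stats::cor(P[i, oki], Y[i, oki])
    } else NA_real_
    data.frame(protein_id = prots[i], R = r, n = sum(oki),
               stringsAsFactors = FALSE)
  })
  list(R = pooled, n = sum(ok), per_protein = do.call(rbind, per))
}
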