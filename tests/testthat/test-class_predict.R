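test_that("k-means recovers well-separated blobs and orders them by r", {
  set.seed(2)
  # two blobs 6 sd apart in every protein, samples 1-20 portal, 21-40 central
  m <- named_matrix(c(rnorm(10 * 20, 0, 1), rnorm(10 * 20, 6, 1)), 10, 40)
  r <- c(runif(20, 0, 0.3), runif(20, 0.7, 1))
  model <- kmeans_classes(m, r, K = 2, seed = 1)
  expect_equal(unname(model$labels), rep(c(1L, 2L), each = 20))
  # identical seed and input give identical labels
  model2 <- kmeans_classes(m, r, K = 2, seed = 1)
  expect_identical(model$labels, model2$labels)
  # class 1 is the most portal
  expect_lt(model$class_mean_r[1], model$class_mean_r[2])
  expect_error(kmeans_classes(m, r, K = 41), "exceed")
})

test_that("zero inertia when K equals the number of distinct points", {
  m <- named_matrix(c(0, 0, 5, 5, 9, 9), 2, 3)
  model <- kmeans_classes(m, r = c(0.1, 0.5, 0.9), K = 3, seed = 1)
  expect_equal(sort(unique(model$labels)), 1:3)
})

test_that("classifier separates threshold-determined labels perfectly", {
  set.seed(3)
  n <- 200
  feats <- matrix(rnorm(n * 17), n, 17,
                  dimnames = list(sprintf("c%03d", 1:n), feature_names()))
  # labels fully determined by one feature, with a margin around the cut
  feats[, "ch647_mean"] <- runif(n, 0.5, 2) * sample(c(-1, 1), n, TRUE)
  labels <- ifelse(feats[, "ch647_mean"] > 0, 2L, 1L)
  clf <- train_classifier(feats, labels, seed = 23)
  expect_equal(clf$report$test_accuracy, 1.0)
  expect_true(is.na(clf$report$neighbor_error_fraction))
  # accuracy equals the confusion-matrix trace over the total
  cm <- clf$report$confusion
  expect_equal(sum(diag(cm)) / sum(cm), clf$report$test_accuracy)
  expect_error(train_classifier(feats, rep(1L, n)), "2 classes")
})

test_that("predicted probabilities are a simplex and row-aligned", {
  set.seed(4)
  n <- 120
  feats <- matrix(rnorm(n * 17), n, 17,
                  dimnames = list(sprintf("c%03d", 1:n), feature_names()))
  # three bands of one feature, separated by wide margins
  band <- sample(1:3, n, replace = TRUE)
  feats[, "ch647_mean"] <- c(-4, 0, 4)[band] + runif(n, -1, 1)
  labels <- band
  clf <- train_classifier(feats, labels, seed = 23)
  prob <- predict_probabilities(clf, feats)
  expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
  expect_true(all(prob >= 0 & prob <= 1))
  # permuting feature rows permutes outputs identically
  perm <- sample(n)
  prob_perm <- predict_probabilities(clf, feats[perm, ])
  expect_equal(prob_perm[, ], prob[perm, ][, ])
  # a sample deep inside a pure-class region gets its class as argmax
  deep <- feats[1, , drop = FALSE]
  deep[1, "ch647_mean"] <- 4
  expect_equal(attr(predict_probabilities(clf, deep), "max_class"), 3L)
  expect_error(predict_probabilities(clf, feats[, 1:5]), "dimension")
})

test_that("weighted proteome prediction is the probability mixture", {
  mu <- matrix(c(0, 2, 4, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), c("class1", "class2")))
  # one-hot recovers the class mean
  p1 <- matrix(c(1, 0), 1, dimnames = list("cellA", NULL))
  expect_equal(unname(weighted_proteome_prediction(p1, mu)[, 1]), c(0, 4))
  # uniform probabilities give the midpoint
  pu <- matrix(c(0.5, 0.5), 1, dimnames = list("cellA", NULL))
  expect_equal(unname(weighted_proteome_prediction(pu, mu)[, 1]), c(1, 6))
  # dot product: p = (0.25, 0.75) on means (4, 8) -> 7
  pq <- matrix(c(0.25, 0.75), 1, dimnames = list("cellA", NULL))
  expect_equal(unname(weighted_proteome_prediction(pq, mu)["P2", 1]), 7)
  # affine in p
  pa <- matrix(c(0.9, 0.1), 1, dimnames = list("cellA", NULL))
  pb <- matrix(c(0.2, 0.8), 1, dimnames = list("cellA", NULL))
  alpha <- 0.3
  blend <- alpha * pa + (1 - alpha) * pb
  expect_equal(weighted_proteome_prediction(blend, mu),
               alpha * weighted_proteome_prediction(pa, mu) +
                 (1 - alpha) * weighted_proteome_prediction(pb, mu))
  # missing class means renormalize over the available classes
  mu_na <- mu; mu_na["P2", 2] <- NA
  suppressMessages(
    pred <- weighted_proteome_prediction(pq, mu_na)
  )
  expect_equal(unname(pred["P2", 1]), 4)  # only class 1 available
})

test_that("class mean proteomes average observed values per class", {
  m <- named_matrix(c(1, 10, 3, 20, NA, 30, 7, 40), 2, 4)
  mu <- class_mean_proteomes(m, labels = c(1, 1, 2, 2))
  expect_equal(unname(mu["P0001", ]), c(2, 7))   # (1+3)/2, (NA,7)->7
  expect_equal(unname(mu["P0002", ]), c(15, 35))
})

test_that("prediction evaluation computes pooled Pearson R", {
  pred <- named_matrix(c(1, 2, 3, 2, 4, 6), 2, 3)
  meas_perfect <- pred
  expect_equal(evaluate_prediction(pred, meas_perfect)$R, 1)
  meas_anti <- -(pred - mean(pred))
  expect_equal(evaluate_prediction(pred, meas_anti)$R, -1)
  # exact collinearity on the toy pairs (1,2),(2,4),(3,6)
  p1 <- named_matrix(c(1, 2, 3), 1, 3)
  m1 <- named_matrix(c(2, 4, 6), 1, 3)
  expect_equal(evaluate_prediction(p1, m1)$R, 1)
  expect_error(evaluate_prediction(p1[, 1, drop = FALSE],
                                   m1[, 1, drop = FALSE]), "3")
})

test_that("image features predict proteome classes on simulated lobules", {
  truth <- simulate_lobule(500, seed = 5)
  pm <- simulate_proteome(truth)
  norm <- median_normalize(pm, completeness = 0.9)$matrix
  model <- kmeans_classes(norm, r = truth$cells$r_true, K = 5, seed = 1)
  feats <- truth_features(truth, simulate_images(truth))
  clf <- train_classifier(feats, model$labels, seed = 23)
  expect_gte(clf$report$test_accuracy, 0.85)
  nef <- clf$report$neighbor_error_fraction
  expect_true(is.na(nef) || nef == 1.0)
  # held-out section: same proteome biology, new cells and images
  ho <- simulate_lobule(100, seed = 6, profiles = truth$profiles)
  normh <- median_normalize(simulate_proteome(ho),
                            completeness = 0.9)$matrix
  prob <- predict_probabilities(clf, truth_features(ho, simulate_images(ho)))
  mu <- class_mean_proteomes(norm, model$labels)
  pred <- weighted_proteome_prediction(prob, mu)
  ev <- evaluate_prediction(pred, normh)
  expect_gte(ev$R, 0.7)
})
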