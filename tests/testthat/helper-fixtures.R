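# Shared fixtures, built in code at test time.

# Minimal report row in the TSV dialect.
report_row <- function(run = "run_001", pg = "P0001", prec = "P0001_prec1",
                       channel = 4, ms1 = NA_real_, frags = c(100, 200),
                       lib_q = 0.001, q = 0.001, ch_q = 0.01) {
  data.frame(
    Run = run, Protein.Group = pg, Precursor.Id = prec,
    Channel = channel, Ms1.Area = ms1,
    Fragment.Quant.Raw = paste(sprintf("%.15g", frags), collapse = ";"),
    Lib.PG.Q.Value = lib_q, Q.Value = q, Channel.Q.Value = ch_q,
    stringsAsFactors = FALSE
  )
}

# Proteins x samples log2 matrix with names.
named_matrix <- function(values, n_proteins, n_samples) {
  m <- matrix(values, n_proteins, n_samples)
  dimnames(m) <- list(sprintf("P%04d", seq_len(n_proteins)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# Square contour of a given area centered on (cx, cy).
square_contour <- function(area, cx = 0, cy = 0) {
  h <- sqrt(area) / 2
  cbind(x = cx + c(-1, 1, 1, -1) * h, y = cy + c(-1, -1, 1, 1) * h)
}

# 17-feature matrix for all cells of a lobule truth (square stand-in
# contours carrying the true area).
truth_features <- function(truth, images) {
  half <- sqrt(truth$cells$area_um2) / 2
  f <- t(vapply(seq_len(nrow(truth$cells)), function(i) {
    ctr <- square_contour(truth$cells$area_um2[i],
                          truth$cells$centroid_x[i],
                          truth$cells$centroid_y[i])
    extract_features(images[[i]], ctr)
  }, numeric(17)))
  rownames(f) <- truth$cells$cell_id
  f
}

# Brute-force MaxLFQ oracle: explicit least squares on the pairwise
# median log-ratio system, sum-anchored like the implementation but
# solved through an over-determined design matrix and qr.solve.
brute_maxlfq <- function(X) {
  quantified <- which(colSums(!is.na(X)) > 0)
  x <- rep(NA_real_, ncol(X))
  if (!length(quantified)) return(x)
  obs <- !is.na(X)
  # connectivity by shared precursors
  share <- function(a, b) any(obs[, a] & obs[, b])
  remaining <- quantified
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      add <- setdiff(remaining, comp)
      add <- add[vapply(add, function(b) any(vapply(comp, share, logical(1),
                                                    b = b)), logical(1))]
      if (!length(add)) break
      comp <- c(comp, add)
    }
    remaining <- setdiff(remaining, comp)
    k <- length(comp)
    lin <- log2(colSums(2^X[, comp, drop = FALSE], na.rm = TRUE))
    if (k == 1) {
      x[comp] <- lin
      next
    }
    rowsA <- list(); rhs <- numeric(0)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      sh <- obs[, comp[a]] & obs[, comp[b]]
      if (!any(sh)) next
      m_ab <- stats::median(X[sh, comp[b]] - X[sh, comp[a]])
      row <- numeric(k); row[a] <- -1; row[b] <- 1
      rowsA[[length(rowsA) + 1]] <- row
      rhs <- c(rhs, m_ab)
    }
    A <- do.call(rbind, rowsA)
    # the pairwise normal equations are orthogonal to the all-ones
    # direction, so appending a sum-zero row fixes the gauge exactly
    A <- rbind(A, rep(1, k))
    rhs <- c(rhs, 0)
    sol <- qr.solve(crossprod(A), crossprod(A, rhs))
    sol <- as.numeric(sol) + mean(lin) - mean(sol)
    x[comp] <- sol
  }
  x
}
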