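#' Filter a multiplexed-DIA precursor report on its q-value columns
#'
#' Keeps exactly the rows passing all three identification confidence
#' thresholds, with strict inequalities: library protein-group q-value
#' < 0.01, run-level q-value < 0.01 and channel q-value < 0.15.
#'
#' @param report Report data frame (see [read_report()]); must carry
#'   the columns `Lib.PG.Q.Value`, `Q.Value` and `Channel.Q.Value`.
#' @param lib_pg_q,q_value,channel_q Thresholds; defaults are the
#'   standard cutoffs for reference-channel mDIA reports.
#' @return The filtered report (same columns, subset of rows).
#' @export
filter_report <- function(report, lib_pg_q = 0.01, q_value = 0.01,
                          channel_q = 0.15) {
  need <- c("Lib.PG.Q.Value", "Q.Value", "Channel.Q.Value")
  missing_cols <- setdiff(need, names(report))
  if (length(missing_cols)) {
    stop("report is missing q-value column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- report[["Lib.PG.Q.Value"]] < lib_pg_q &
    report[["Q.Value"]] < q_value &
    report[["Channel.Q.Value"]] < channel_q
  keep[is.na(keep)] <- FALSE
  report[keep, , drop = FALSE]
}

#' Target/reference ratio for one precursor
#'
#' For a single precursor in a single run, computes per-index ratios
#' between the target channel and the Delta0 reference channel for
#' every fragment ion (index-aligned) and, optionally, the MS1 peak,
#' then summarizes the collection as the exponential of the median of
#' log-ratios. Indices where either side is missing or non-positive
#' contribute nothing.
#'
#' @param target_fragments,reference_fragments Numeric vectors of
#'   fragment intensities, index-aligned across the two channels.
#' @param target_ms1,reference_ms1 Optional MS1 areas; used as one
#'   more ratio when both are positive.
#' @return The overall ratio (a positive scalar), or `NA_real_` with a
#'   warning when no index yields a usable pair.
#' @export
precursor_ratio <- function(target_fragments, reference_fragments,
                            target_ms1 = NA_real_, reference_ms1 = NA_real_) {
  if (length(target_fragments) != length(reference_fragments)) {
    stop("fragment vectors must be index-aligned (equal length)",
         call. = FALSE)
  }
  tg <- c(target_fragments, target_ms1)
  rf <- c(reference_fragments, reference_ms1)
  ok <- !is.na(tg) & !is.na(rf) & tg > 0 & rf > 0
  if (!any(ok)) {
    warning("precursor not quantifiable: no fragment or MS1 index with ",
            "positive signal in both channels", call. = FALSE)
    return(NA_real_)
  }
  exp(stats::median(log(tg[ok] / rf[ok])))
}

#' Rescale a precursor ratio to a meaningful intensity
#'
#' Multiplies the target/reference ratio by the median reference
#' intensity of that precursor over all runs, turning a unit-free
#' channel ratio into an intensity on the reference scale.
#'
#' @param ratio Positive ratio from [precursor_ratio()].
#' @param reference_intensities Per-run reference intensities for the
#'   precursor (one scalar per run; see [quantify_report()] for how the
#'   per-run scalar is formed).
#' @return `ratio * median(reference_intensities)`.
#' @export
rescale_precursor <- function(ratio, reference_intensities) {
  refs <- reference_intensities[!is.na(reference_intensities)]
  if (!length(refs)) {
    stop("precursor not quantifiable: no reference intensity observed",
         call. = FALSE)
  }
  ratio * stats::median(refs)
}

#' Parse semicolon-separated fragment intensity strings
#'
#' @param x Character vector like `"100;200;300"`.
#' @return List of numeric vectors, one per input string.
#' @export
parse_fragments <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v)) stop("non-numeric fragment intensity: ",
                       paste(p[is.na(v)], collapse = ", "), call. = FALSE)
    v
  })
}

#' Quantify a filtered report into per-sample precursor intensities
#'
#' Runs the reference-ratio scheme over a whole report: for every
#' target-channel row (Delta4/Delta8) the ratio to the run's Delta0
#' reference row is estimated over fragments (and MS1 when
#' `include_ms1`), then rescaled by the median per-run reference
#' intensity of that precursor across runs. The per-run reference
#' intensity is the sum of the reference fragment intensities plus its
#' MS1 area when `include_ms1`.
#'
#' @param report A (filtered) report data frame.
#' @param include_ms1 Pool the MS1 ratio with the fragment ratios and
#'   include MS1 area in the per-run reference scalar (default TRUE).
#' @param sample_map Optional data frame (`run`, `channel`, `cell_id`)
#'   mapping run/target-channel pairs to biological sample ids; when
#'   omitted, sample ids are `<run>.<channel>`.
#' @return Data frame of precursor quantifications: `sample_id`,
#'   `protein_group`, `precursor_id`, `ratio`, `intensity`.
#' @export
quantify_report <- function(report, include_ms1 = TRUE, sample_map = NULL) {
  if (!nrow(report)) {
    return(data.frame(sample_id = character(), protein_group = character(),
                      precursor_id = character(), ratio = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  }
  frags <- parse_fragments(report[["Fragment.Quant.Raw"]])
  ms1 <- suppressWarnings(as.numeric(report[["Ms1.Area"]]))
  chan <- as.integer(report[["Channel"]])
  key <- paste(report[["Run"]], report[["Precursor.Id"]], sep = "\r")

  is_ref <- chan == 0L
  ref_idx <- which(is_ref)
  # one reference row per run x precursor; first wins if duplicated
  ref_lookup <- ref_idx[!duplicated(key[ref_idx])]
  names(ref_lookup) <- key[ref_lookup]

  ref_total <- vapply(ref_lookup, function(i) {
    s <- sum(frags[[i]])
    if (include_ms1 && !is.na(ms1[i])) s <- s + ms1[i]
    s
  }, numeric(1))
  med_ref <- tapply(ref_total, report[["Precursor.Id"]][ref_lookup],
                    stats::median)

  tgt_idx <- which(!is_ref)
  out <- vector("list", length(tgt_idx))
  for (j in seq_along(tgt_idx)) {
    i <- tgt_idx[j]
    ri <- ref_lookup[key[i]]
    if (is.na(ri)) next  # reference row filtered out; precursor skipped
    rho <- suppressWarnings(precursor_ratio(
      frags[[i]], frags[[ri]],
      target_ms1 = if (include_ms1) ms1[i] else NA_real_,
      reference_ms1 = if (include_ms1) ms1[ri] else NA_real_
    ))
    if (is.na(rho)) next
    prec <- as.character(report[["Precursor.Id"]][i])
    out[[j]] <- data.frame(
      run = as.character(report[["Run"]][i]),
      channel = chan[i],
      protein_group = as.character(report[["Protein.Group"]][i]),
      precursor_id = prec,
      ratio = rho,
      intensity = rho * med_ref[[prec]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    return(data.frame(sample_id = character(), protein_group = character(),
                      precursor_id = character(), ratio = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  }
  if (!is.null(sample_map)) {
    mkey <- paste(sample_map$run, sample_map$channel)
    res$sample_id <- sample_map$cell_id[match(paste(res$run, res$channel), mkey)]
  } else {
    res$sample_id <- paste(res$run, res$channel, sep = ".")
  }
  res[, c("sample_id", "protein_group", "precursor_id", "ratio", "intensity")]
}

# Connected components of the sample-sharing graph for one protein:
# samples are connected when at least one precursor is observed in both.
sample_components <- function(obs) {
  s <- ncol(obs)
  comp <- rep(NA_integer_, s)
  cid <- 0L
  for (seed in seq_len(s)) {
    if (!is.na(comp[seed])) next
    cid <- cid + 1L
    frontier <- seed
    comp[seed] <- cid
    while (length(frontier)) {
      nxt <- integer()
      for (i in frontier) {
        shared <- which(colSums(obs & obs[, i]) > 0 & is.na(comp))
        comp[shared] <- cid
        nxt <- c(nxt, shared)
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

# MaxLFQ solve for one protein: X is precursors x samples log2 matrix.
maxlfq_protein <- function(X) {
  quantified <- colSums(!is.na(X)) > 0
  x <- rep(NA_real_, ncol(X))
  if (!any(quantified)) return(x)
  obs <- !is.na(X)
  comp <- sample_components(obs)
  lin_sum <- colSums(2^X, na.rm = TRUE)  # summed precursor intensities
  for (cc in unique(comp[quantified])) {
    idx <- which(comp == cc & quantified)
    k <- length(idx)
    if (k == 1L) {
      x[idx] <- log2(lin_sum[idx])
      next
    }
    # pairwise median log-ratios over shared precursors
    L <- matrix(0, k, k)
    b <- numeric(k)
    for (a in seq_len(k - 1L)) {
      for (bb in (a + 1L):k) {
        sh <- obs[, idx[a]] & obs[, idx[bb]]
        if (!any(sh)) next
        m_ab <- stats::median(X[sh, idx[bb]] - X[sh, idx[a]])
        L[a, a] <- L[a, a] + 1; L[bb, bb] <- L[bb, bb] + 1
        L[a, bb] <- L[a, bb] - 1; L[bb, a] <- L[bb, a] - 1
        b[a] <- b[a] - m_ab
        b[bb] <- b[bb] + m_ab
      }
    }
    # sum-zero gauge fixes the Laplacian's null space
    sol <- solve(L + matrix(1 / k, k, k), b)
    sol <- sol + mean(log2(lin_sum[idx])) - mean(sol)
    x[idx] <- sol
  }
  x
}

#' Collapse precursor quantifications to protein groups (MaxLFQ)
#'
#' Reconstructs, per protein group, a sample profile of log2
#' intensities from pairwise sample ratios: for each pair of samples
#' the median over shared precursors of the per-precursor log2 ratio
#' is taken, and the profile minimizing the squared deviations from
#' all pairwise medians is solved by least squares. The free additive
#' constant is fixed so that the mean of the profile over quantified
#' samples equals the mean of the log2 summed precursor intensities of
#' those samples. Disconnected groups of samples within one protein
#' are anchored independently. No cross-sample median normalization is
#' applied.
#'
#' @param precursor_quants Output of [quantify_report()]: one row per
#'   quantified precursor x sample with positive `intensity`.
#' @param sample_ids Optional character vector fixing the column order
#'   of the output (defaults to sorted unique sample ids present).
#' @return A [protein_matrix()] of log2 intensities, `NA` where a
#'   protein group has no precursor in a sample.
#' @export
maxlfq_collapse <- function(precursor_quants, sample_ids = NULL) {
  pq <- precursor_quants
  if (!nrow(pq)) stop("no precursor quantifications to collapse", call. = FALSE)
  if (any(pq$intensity <= 0, na.rm = TRUE)) {
    pq <- pq[!is.na(pq$intensity) & pq$intensity > 0, , drop = FALSE]
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(pq$sample_id))
  groups <- sort(unique(pq$protein_group))
  out <- matrix(NA_real_, length(groups), length(sample_ids),
                dimnames = list(groups, sample_ids))
  split_pg <- split(seq_len(nrow(pq)), pq$protein_group)
  for (g in groups) {
    rows <- pq[split_pg[[g]], , drop = FALSE]
    precs <- unique(rows$precursor_id)
    X <- matrix(NA_real_, length(precs), length(sample_ids),
                dimnames = list(precs, sample_ids))
    X[cbind(match(rows$precursor_id, precs),
            match(rows$sample_id, sample_ids))] <- log2(rows$intensity)
    out[g, ] <- maxlfq_protein(X)
  }
  protein_matrix(out)
}
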