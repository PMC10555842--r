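#' Lobule geometry: vascular landmarks bounding the zonation axis
#'
#' @param pv,cv Two-column matrices of portal-vein / central-vein
#'   landmark coordinates in micrometre (>= 1 row each).
#' @param field_size `c(width, height)` of the imaged field in
#'   micrometre; all landmarks must lie inside.
#' @return Object of class `lobule_geometry`.
#' @export
lobule_geometry <- function(pv = matrix(c(0, 500), 1),
                            cv = matrix(c(1000, 500), 1),
                            field_size = c(1000, 1000)) {
  pv <- matrix(as.numeric(pv), ncol = 2)
  cv <- matrix(as.numeric(cv), ncol = 2)
  if (!nrow(pv) || !nrow(cv)) {
    stop("need at least one PV and one CV landmark", call. = FALSE)
  }
  all_pts <- rbind(pv, cv)
  if (any(all_pts[, 1] < 0 | all_pts[, 1] > field_size[1] |
          all_pts[, 2] < 0 | all_pts[, 2] > field_size[2])) {
    stop("all landmarks must lie inside the field", call. = FALSE)
  }
  structure(list(pv = pv, cv = cv, field_size = as.numeric(field_size)),
            class = "lobule_geometry")
}

#' Expected log2 intensity of a zonation profile at position r
#'
#' Evaluates the spatial expression shape of one protein:
#' * `flat`: baseline everywhere;
#' * `linear_up`: baseline + amplitude * r;
#' * `linear_down`: baseline + amplitude * (1 - r);
#' * `hockey_central`: baseline + amplitude * max(0, (r - r0)/(1 - r0))^gamma
#'   (flat until the breakpoint, then rising toward the CV -- the
#'   hockey-stick form of Wnt-controlled central markers);
#' * `hockey_portal`: the mirror image (replace r by 1 - r).
#'
#' @param profile A list/one-row data frame with `shape_kind`,
#'   `baseline`, `amplitude`, `r0`, `gamma`.
#' @param r Relative distance(s) in `[0, 1]`.
#' @return Expected log2 intensity, same length as `r`.
#' @export
profile_value <- function(profile, r) {
  if (any(r < 0 | r > 1, na.rm = TRUE)) {
    stop("r must lie in [0, 1]", call. = FALSE)
  }
  kind <- as.character(profile$shape_kind)
  b <- profile$baseline; a <- profile$amplitude
  switch(kind,
    flat = rep(b, length(r)),
    linear_up = b + a * r,
    linear_down = b + a * (1 - r),
    hockey_central = {
      r0 <- profile$r0
      b + a * pmax(0, (r - r0) / (1 - r0))^profile$gamma
    },
    hockey_portal = {
      r0 <- profile$r0
      rr <- 1 - r
      b + a * pmax(0, (rr - r0) / (1 - r0))^profile$gamma
    },
    stop("unknown shape_kind: ", kind, call. = FALSE)
  )
}

# Ground-truth zonation profiles for the simulated proteome. The
# zonated fraction is split evenly over the two hockey and two linear
# kinds; the first n_histones proteins are abundant flat histones
# whose intensity couples to nuclear content.
make_profiles <- function(n_proteins, zonated_fraction = 0.4,
                          amplitude_range = c(2, 4), baseline_mean = 12,
                          baseline_sd = 1.5, n_histones = 4) {
  n_zon <- round(n_proteins * zonated_fraction)
  kinds_z <- rep(c("hockey_portal", "hockey_central", "linear_up",
                   "linear_down"), length.out = n_zon)
  kinds <- c(rep("flat", n_proteins - n_zon), kinds_z)
  kinds <- kinds[order(c(seq_len(n_proteins - n_zon) * 2,
                         seq_len(n_zon) * 2 + 1))]  # interleave
  is_hist <- rep(FALSE, n_proteins)
  flat_idx <- which(kinds == "flat")
  hist_idx <- flat_idx[seq_len(min(n_histones, length(flat_idx)))]
  is_hist[hist_idx] <- TRUE
  amp <- ifelse(kinds == "flat", 0,
                stats::runif(n_proteins, amplitude_range[1], amplitude_range[2]))
  base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
  base[is_hist] <- baseline_mean + 3  # histones rank among the most abundant
  data.frame(
    protein_id = sprintf("P%04d", seq_len(n_proteins)),
    shape_kind = kinds,
    baseline = base,
    amplitude = amp,
    r0 = ifelse(grepl("hockey", kinds), stats::runif(n_proteins, 0.2, 0.7), 0),
    gamma = ifelse(grepl("hockey", kinds), stats::runif(n_proteins, 1, 2), 1),
    is_histone = is_hist,
    stringsAsFactors = FALSE
  )
}

#' Simulate a zonated liver lobule: geometry, cells and ground truth
#'
#' Places `n_cells` shapes along the PV-to-CV axis (uniform along the
#' segment between the first PV and first CV landmark, with a small
#' transverse jitter, so the relative distance is close to uniform),
#' draws shape areas from a log-normal with median 600 square
#' micrometre truncated at the segmentation gates, assigns nuclear
#' fractions with a point mass at 0 (anucleate slices), derives the
#' true relative distance from the landmark distances, and attaches
#' ground-truth zonation profiles.
#'
#' @param n_cells Number of shapes (>= 1).
#' @param geometry A [lobule_geometry()] (default one PV at x=0, one
#'   CV at x=1000 in a 1000x1000 micrometre field).
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @param n_proteins,zonated_fraction,amplitude_range,baseline_mean,baseline_sd,n_histones
#'   Passed to the profile generator (defaults: 2000 proteins --
#'   yielding a per-shape identification depth of around 1500, the
#'   scale reported for reference-channel mDIA of single shapes --
#'   40% zonated with log2 amplitude 2-4, baselines N(12, 1.5), 4
#'   histones).
#' @param profiles Optional pre-made profile table (to share the same
#'   proteome biology across sections).
#' @param area_meanlog,area_sdlog Log-normal area parameters (default
#'   `log(600)` and 0.4, truncated to `[135, 1350]`).
#' @param anucleate_fraction Point mass at nuclear fraction 0
#'   (default 0.25).
#' @param jitter_um Transverse placement jitter (default 25).
#' @param K Ground-truth class count: classes are equidistant splits
#'   of r (default 5).
#' @param n_sections Number of tissue sections cells are assigned to
#'   at random (default 1).
#' @return Object of class `lobule_truth`: `geometry`, `profiles`,
#'   `cells` (data frame with `cell_id`, `centroid_x`, `centroid_y`,
#'   `area_um2`, `d_pv_um`, `d_cv_um`, `r_true`, `nuclear_fraction`,
#'   `class_true`, `section`), `seed`, `params`.
#' @export
simulate_lobule <- function(n_cells, geometry = lobule_geometry(), seed = 1,
                            n_proteins = 2000, zonated_fraction = 0.4,
                            amplitude_range = c(2, 4), baseline_mean = 12,
                            baseline_sd = 1.5, n_histones = 4,
                            profiles = NULL,
                            area_meanlog = log(600), area_sdlog = 0.4,
                            anucleate_fraction = 0.25, jitter_um = 25,
                            K = 5, n_sections = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  set.seed(seed)
  if (is.null(profiles)) {
    profiles <- make_profiles(n_proteins, zonated_fraction, amplitude_range,
                              baseline_mean, baseline_sd, n_histones)
  }
  pv1 <- geometry$pv[1, ]; cv1 <- geometry$cv[1, ]
  axis <- cv1 - pv1
  perp <- c(-axis[2], axis[1]) / sqrt(sum(axis^2))
  t_pos <- stats::runif(n_cells)
  jit <- stats::runif(n_cells, -jitter_um, jitter_um)
  cx <- pv1[1] + t_pos * axis[1] + jit * perp[1]
  cy <- pv1[2] + t_pos * axis[2] + jit * perp[2]
  cx <- pmin(pmax(cx, 0), geometry$field_size[1])
  cy <- pmin(pmax(cy, 0), geometry$field_size[2])

  d <- t(vapply(seq_len(n_cells), function(i) {
    landmark_distances(c(cx[i], cy[i]), geometry)
  }, numeric(2)))
  r_true <- relative_distance(d[, 1], d[, 2])

  area <- stats::rlnorm(n_cells, area_meanlog, area_sdlog)
  redo <- which(area < 135 | area > 1350)
  while (length(redo)) {  # truncate at the segmentation gates
    area[redo] <- stats::rlnorm(length(redo), area_meanlog, area_sdlog)
    redo <- which(area < 135 | area > 1350)
  }
  nf <- ifelse(stats::runif(n_cells) < anucleate_fraction, 0,
               stats::rbeta(n_cells, 2, 2))
  cells <- data.frame(
    cell_id = sprintf("cell_%04d", seq_len(n_cells)),
    centroid_x = cx, centroid_y = cy,
    area_um2 = area,
    d_pv_um = d[, 1], d_cv_um = d[, 2],
    r_true = r_true,
    nuclear_fraction = nf,
    class_true = pmin.int(as.integer(floor(r_true * K)) + 1L, as.integer(K)),
    section = sample(rep(seq_len(n_sections), length.out = n_cells)),
    stringsAsFactors = FALSE
  )
  structure(list(geometry = geometry, profiles = profiles, cells = cells,
                 seed = seed,
                 params = list(n_cells = n_cells, K = K,
                               anucleate_fraction = anucleate_fraction,
                               area_meanlog = area_meanlog,
                               area_sdlog = area_sdlog,
                               jitter_um = jitter_um)),
            class = "lobule_truth")
}

#' @export
print.lobule_truth <- function(x, ...) {
  cat(sprintf("lobule_truth: %d cells, %d proteins (%d zonated), seed %d\n",
              nrow(x$cells), nrow(x$profiles),
              sum(x$profiles$shape_kind != "flat"), x$seed))
  invisible(x)
}

#' Simulate single-shape proteomes from a lobule ground truth
#'
#' Observed log2 intensity of protein p in cell c is the profile value
#' at the cell's true relative distance, plus a shape-size term
#' `area_coef * log2(area / 600)` (larger slices recover more
#' protein), a histone term proportional to the nuclear fraction, and
#' Gaussian noise. Detection is Bernoulli with logistic probability
#' increasing in the expected log2 intensity and in log2 area, which
#' reproduces the abundance-dependent completeness and the
#' logarithmic growth of protein counts with shape area.
#'
#' @param truth A [simulate_lobule()] result.
#' @param noise_sd Log2 measurement noise (default 0.5, i.e.
#'   coefficients of variation below ~40%).
#' @param missingness List with `midpoint`, `scale` (logistic on the
#'   expected log2 intensity) and `area_weight` (extra logit per log2
#'   unit of area), or `NULL` to disable dropout. Defaults
#'   `list(midpoint = 10, scale = 1.5, area_weight = 0.8)`.
#' @param area_coef Log2 intensity gained per log2 unit of relative
#'   area (default 1: recovered amount proportional to slice volume).
#' @param histone_coef Log2 intensity added to histone proteins per
#'   unit nuclear fraction (default 2).
#' @param seed Seed (default `truth$seed + 1`).
#' @return A [protein_matrix()] (proteins x cells, log2, `NA` =
#'   not detected) whose sample table carries `cell_id`, `r_true`,
#'   `area_um2`, `section`.
#' @export
simulate_proteome <- function(truth, noise_sd = 0.5,
                              missingness = list(midpoint = 10, scale = 1.5,
                                                 area_weight = 0.8),
                              area_coef = 1, histone_coef = 2, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(seed)) seed <- truth$seed + 1L
  set.seed(seed)
  cells <- truth$cells
  prof <- truth$profiles
  n_p <- nrow(prof); n_c <- nrow(cells)
  mu <- matrix(NA_real_, n_p, n_c,
               dimnames = list(prof$protein_id, cells$cell_id))
  for (i in seq_len(n_p)) {
    mu[i, ] <- profile_value(prof[i, ], cells$r_true)
  }
  size_term <- area_coef * log2(cells$area_um2 / 600)
  mu <- sweep(mu, 2, size_term, "+")
  if (any(prof$is_histone)) {
    mu[prof$is_histone, ] <- sweep(mu[prof$is_histone, , drop = FALSE], 2,
                                   histone_coef * cells$nuclear_fraction, "+")
  }
  y <- mu + matrix(stats::rnorm(n_p * n_c, 0, noise_sd), n_p, n_c)
  if (!is.null(missingness)) {
    lin <- (mu - missingness$midpoint) / missingness$scale +
      rep(missingness$area_weight * log2(cells$area_um2 / 600),
          each = n_p)
    pdet <- stats::plogis(lin)
    y[matrix(stats::runif(n_p * n_c), n_p, n_c) > pdet] <- NA_real_
  }
  protein_matrix(
    y,
    samples = data.frame(sample_id = cells$cell_id, cell_id = cells$cell_id,
                         r_true = cells$r_true, area_um2 = cells$area_um2,
                         section = cells$section, stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = prof$protein_id,
                          shape_kind = prof$shape_kind,
                          is_histone = prof$is_histone,
                          stringsAsFactors = FALSE)
  )
}

#' Simulate a fragment-level multiplexed-DIA report
#'
#' Emits a long-format precursor report in the mDIA design: runs carry
#' a Delta0 reference channel plus up to two sample channels (Delta4,
#' Delta8), two consecutive cells per run. Each protein is split over
#' `n_precursors` precursors with fixed intensity shares summing to 1,
#' so the summed precursor intensities reconstruct the cell's true
#' protein intensity. Reference fragment intensities derive from a
#' per-precursor reference level with multiplicative per-run noise;
#' target fragment (and MS1) intensities are the reference signal
#' times the true channel ratio times multiplicative noise. Q-value
#' columns are drawn so a configured fraction of target rows fails
#' each threshold.
#'
#' @param matrix A [simulate_proteome()] result (or compatible
#'   `ProteinMatrix` whose columns are the truth's cells).
#' @param truth The matching [simulate_lobule()] truth.
#' @param frag_per_precursor Fragments per precursor (default 3).
#' @param n_precursors Precursors per protein (default 2).
#' @param ratio_noise_sd Log-normal sd of per-fragment ratio noise
#'   (default 0.1; 0 gives exact ratios).
#' @param ref_run_noise_sd Log-normal sd of the per-run reference
#'   level (default 0.05).
#' @param q_fail Fraction of target rows drawn to fail each q-value
#'   threshold (default 0.02).
#' @param seed Seed (default `truth$seed + 2`).
#' @return List: `report` (data frame in the report TSV dialect),
#'   `ratios` (side table with the true per-run ratios), `sample_map`
#'   (`run`, `channel`, `cell_id`).
#' @export
simulate_report <- function(matrix, truth, frag_per_precursor = 3,
                            n_precursors = 2, ratio_noise_sd = 0.1,
                            ref_run_noise_sd = 0.05, q_fail = 0.02,
                            seed = NULL) {
  if (frag_per_precursor < 1) stop("frag_per_precursor must be >= 1",
                                   call. = FALSE)
  if (is.null(seed)) seed <- truth$seed + 2L
  set.seed(seed)
  y <- pm_log2(matrix)
  cells <- colnames(y)
  n_runs <- ceiling(length(cells) / 2)
  run_of <- rep(seq_len(n_runs), each = 2)[seq_along(cells)]
  chan_of <- rep(c(4L, 8L), n_runs)[seq_along(cells)]
  run_ids <- sprintf("run_%03d", seq_len(n_runs))
  sample_map <- data.frame(run = run_ids[run_of], channel = chan_of,
                           cell_id = cells, stringsAsFactors = FALSE)

  prof <- truth$profiles
  rows <- list(); ratio_rows <- list(); ri <- 0L
  q_draw <- function(n, cut, hi, fail_frac) {
    ifelse(stats::runif(n) < fail_frac,
           stats::runif(n, cut, hi), stats::runif(n, 0, cut))
  }
  for (p in seq_len(nrow(prof))) {
    pid <- prof$protein_id[p]
    shares <- stats::runif(n_precursors, 0.5, 1.5)
    shares <- shares / sum(shares)
    wfrag <- matrix(stats::runif(n_precursors * frag_per_precursor, 0.5, 1.5),
                    n_precursors)
    wfrag <- wfrag / rowSums(wfrag)
    ms1_frac <- 0.3  # of the per-run reference total
    T_ref <- shares * 2^prof$baseline[p]  # per-precursor reference level
    for (q in seq_len(n_precursors)) {
      prec_id <- sprintf("%s_prec%d", pid, q)
      ref_tot <- T_ref[q] * exp(stats::rnorm(n_runs, 0, ref_run_noise_sd))
      ref_ms1 <- ms1_frac * ref_tot
      for (rn in seq_len(n_runs)) {
        ref_fr <- (1 - ms1_frac) * ref_tot[rn] * wfrag[q, ]
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          Run = run_ids[rn], Protein.Group = pid, Precursor.Id = prec_id,
          Channel = 0L, Ms1.Area = ref_ms1[rn],
          Fragment.Quant.Raw = paste(sprintf("%.15g", ref_fr), collapse = ";"),
          Lib.PG.Q.Value = stats::runif(1, 0, 0.01),
          Q.Value = stats::runif(1, 0, 0.01),
          Channel.Q.Value = stats::runif(1, 0, 0.15),
          stringsAsFactors = FALSE
        )
        for (ci in which(run_of == rn)) {
          yv <- y[pid, ci]
          if (is.na(yv)) next
          rho <- shares[q] * 2^yv / ref_tot[rn]
          noise <- exp(stats::rnorm(frag_per_precursor + 1, 0, ratio_noise_sd))
          tg_fr <- ref_fr * rho * noise[seq_len(frag_per_precursor)]
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            Run = run_ids[rn], Protein.Group = pid, Precursor.Id = prec_id,
            Channel = chan_of[ci], Ms1.Area = ref_ms1[rn] * rho *
              noise[frag_per_precursor + 1],
            Fragment.Quant.Raw = paste(sprintf("%.15g", tg_fr),
                                       collapse = ";"),
            Lib.PG.Q.Value = q_draw(1, 0.01, 0.05, q_fail),
            Q.Value = q_draw(1, 0.01, 0.05, q_fail),
            Channel.Q.Value = q_draw(1, 0.15, 0.4, q_fail),
            stringsAsFactors = FALSE
          )
          ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
            run = run_ids[rn], channel = chan_of[ci], cell_id = cells[ci],
            protein_group = pid, precursor_id = prec_id, true_ratio = rho,
            true_intensity = shares[q] * 2^yv, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(report = do.call(rbind, rows),
       ratios = do.call(rbind, ratio_rows),
       sample_map = sample_map)
}

#' Simulate 4-channel image patches for each cell
#'
#' Channel mean intensities encode the zonation axis: the 568 nm
#' channel (PV marker E-cadherin) decreases with relative distance,
#' the 647 nm channel (CV marker Glul) increases; the 425 nm
#' (phalloidin) and 488 nm (WGA) channels are weakly informative
#' (WGA couples mildly to nuclear content). Pixels add Gaussian noise
#' truncated at 0.
#'
#' @param truth A [simulate_lobule()] result.
#' @param patch_size Patch side length in pixels (>= 4, default 16).
#' @param seed Seed (default `truth$seed + 3`).
#' @param cell_noise_sd Per-cell channel-mean jitter (default 30).
#' @param pixel_noise_sd Per-pixel noise (default 80).
#' @return Named list (by cell id) of `patch_size x patch_size x 4`
#'   arrays, channels ordered 425, 488, 568, 647.
#' @export
simulate_images <- function(truth, patch_size = 16, seed = NULL,
                            cell_noise_sd = 30, pixel_noise_sd = 80) {
  if (patch_size < 4) stop("patch_size must be >= 4", call. = FALSE)
  if (is.null(seed)) seed <- truth$seed + 3L
  set.seed(seed)
  cells <- truth$cells
  n <- nrow(cells)
  base <- cbind(
    ch425 = 600 + stats::rnorm(n, 0, cell_noise_sd * 2),
    ch488 = 500 + 200 * cells$nuclear_fraction +
      stats::rnorm(n, 0, cell_noise_sd * 2),
    ch568 = 1000 - 800 * cells$r_true + stats::rnorm(n, 0, cell_noise_sd),
    ch647 = 200 + 800 * cells$r_true + stats::rnorm(n, 0, cell_noise_sd)
  )
  out <- vector("list", n)
  names(out) <- cells$cell_id
  for (i in seq_len(n)) {
    px <- array(0, c(patch_size, patch_size, 4))
    for (ch in 1:4) {
      px[, , ch] <- pmax(0, base[i, ch] +
                           stats::rnorm(patch_size^2, 0, pixel_noise_sd))
    }
    out[[i]] <- px
  }
  out
}
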