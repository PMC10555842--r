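report_columns <- c("Run", "Protein.Group", "Precursor.Id", "Channel",
                    "Ms1.Area", "Fragment.Quant.Raw", "Lib.PG.Q.Value",
                    "Q.Value", "Channel.Q.Value")

#' Read a precursor report TSV
#'
#' Reads the minimal long-format report dialect: one row per run x
#' channel x precursor with semicolon-separated fragment intensities
#' and the three q-value columns. Malformed rows (non-numeric
#' fragments, invalid channel) are rejected with their line numbers.
#'
#' @param path TSV file with header columns `Run`, `Protein.Group`,
#'   `Precursor.Id`, `Channel`, `Ms1.Area`, `Fragment.Quant.Raw`,
#'   `Lib.PG.Q.Value`, `Q.Value`, `Channel.Q.Value`.
#' @return Data frame with those columns; `Fragment.Quant.Raw` stays
#'   a character column, parsed lazily by the quantifier.
#' @export
read_report <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  classes <- if ("Fragment.Quant.Raw" %in% header) {
    c(Fragment.Quant.Raw = "character")
  } else NA
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = classes)
  missing_cols <- setdiff(report_columns, names(df))
  if (length(missing_cols)) {
    stop("report is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) return(df[, report_columns, drop = FALSE])
  bad_chan <- !df$Channel %in% c(0, 4, 8)
  frag_ok <- vapply(strsplit(df$Fragment.Quant.Raw, ";", fixed = TRUE),
                    function(p) {
                      p <- p[nzchar(p)]
                      length(p) > 0 &&
                        !anyNA(suppressWarnings(as.numeric(p)))
                    }, logical(1))
  bad <- bad_chan | !frag_ok
  if (any(bad)) {
    stop("malformed report row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "),
         " (invalid channel or non-numeric fragment intensity)",
         call. = FALSE)
  }
  df[, report_columns, drop = FALSE]
}

#' Write a precursor report TSV
#' @param report Report data frame (see [read_report()]).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report[, report_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the per-cell table
#'
#' The cells CSV keys every shape: `cell_id`, `run`, `channel`,
#' `centroid_x`, `centroid_y`, `area_um2`, `d_pv_um`, `d_cv_um`.
#'
#' @param path CSV path.
#' @return Data frame with the columns above.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "run", "channel", "centroid_x", "centroid_y",
            "area_um2", "d_pv_um", "d_cv_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cells table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_cells
#' @param cells Cells data frame.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a ProteinMatrix as wide CSV
#'
#' Rows are protein groups, columns sample ids, values log2
#' intensities (empty = missing); an optional sidecar CSV carries the
#' sample metadata.
#'
#' @param path Matrix CSV path.
#' @param samples_path Optional sidecar CSV path.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, samples_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  samples <- if (!is.null(samples_path)) {
    utils::read.csv(samples_path, stringsAsFactors = FALSE)
  } else NULL
  protein_matrix(m, samples = samples)
}

#' @rdname read_protein_matrix
#' @param x A `ProteinMatrix`.
#' @export
write_protein_matrix <- function(x, path, samples_path = NULL) {
  m <- pm_log2(x)
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(samples_path) && inherits(x, "ProteinMatrix")) {
    utils::write.csv(x$samples, samples_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write cell contours as LMD-style XML
#'
#' Minimal laser-microdissection flavored dialect: an `<ImageData>`
#' root with three (or more) `<CalibrationPoint x= y=>` elements and
#' one `<Shape id=>` per cell holding `<Point x= y=>` vertices.
#' Coordinates are 0-based pixel coordinates with y increasing
#' downward.
#'
#' @param path XML path.
#' @return List: `calibration` (n x 2 matrix), `shapes` (named list of
#'   two-column vertex matrices).
#' @export
read_contours <- function(path) {
  doc <- xml2::read_xml(path)
  cal <- xml2::xml_find_all(doc, ".//CalibrationPoint")
  calibration <- cbind(
    x = as.numeric(xml2::xml_attr(cal, "x")),
    y = as.numeric(xml2::xml_attr(cal, "y"))
  )
  shapes <- xml2::xml_find_all(doc, ".//Shape")
  out <- lapply(shapes, function(s) {
    pts <- xml2::xml_find_all(s, ".//Point")
    cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
          y = as.numeric(xml2::xml_attr(pts, "y")))
  })
  names(out) <- xml2::xml_attr(shapes, "id")
  list(calibration = calibration, shapes = out)
}

#' @rdname read_contours
#' @param shapes Named list of two-column vertex matrices.
#' @param calibration n x 2 matrix of calibration points.
#' @export
write_contours <- function(shapes, path, calibration = NULL) {
  doc <- xml2::xml_new_root("ImageData")
  if (!is.null(calibration)) {
    for (i in seq_len(nrow(calibration))) {
      xml2::xml_add_child(doc, "CalibrationPoint",
                          x = format(calibration[i, 1], digits = 15),
                          y = format(calibration[i, 2], digits = 15))
    }
  }
  for (nm in names(shapes)) {
    sh <- xml2::xml_add_child(doc, "Shape", id = nm)
    v <- shapes[[nm]]
    for (i in seq_len(nrow(v))) {
      xml2::xml_add_child(sh, "Point",
                          x = format(v[i, 1], digits = 15),
                          y = format(v[i, 2], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds and seeds of the pipeline in one list: q-value
#' cutoffs, size gates, identification-count filter multipliers,
#' bin count B, class count K, completeness minima, classifier
#' split/seed, and the simulator parameters.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    lib_pg_q = 0.01, q_value = 0.01, channel_q = 0.15,
    size_min_um2 = 135, size_max_um2 = 1350,
    id_low_k = 1.5, id_high_k = 3, id_window = NULL,
    norm_completeness = 1, norm_completeness_fallback = 0.9,
    B = 20, K = 5,
    anova_completeness = 0.5, pca_completeness = 0.7,
    flatness_alpha = 0.05,
    test_fraction = 0.2, classifier_seed = 23, n_trees = 200,
    clustering_seed = 1,
    pixel_size = 1,
    sim = list(n_cells = 60, n_proteins = 60, noise_sd = 0.5,
               frag_per_precursor = 3, n_precursors = 2,
               ratio_noise_sd = 0.1, patch_size = 16)
  )
}

#' @rdname default_config
#' @param path YAML file of configuration overrides.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Run the full scDVP downstream pipeline
#'
#' Orchestrates quantification, QC/normalization, spatial zonation,
#' image features and class prediction, writing every stage's outputs
#' plus a machine-readable run manifest into `output_dir`. Inputs are
#' either supplied (report + cells + image patches) or generated by
#' the synthetic lobule simulator.
#'
#' @param config Configuration list (see [default_config()]).
#' @param output_dir Directory for outputs (created).
#' @param report,cells,images,contours Optional inputs: a report data
#'   frame, the cells table, a named list of 4-channel patches and a
#'   named list of contours. When `report` is `NULL` the simulator
#'   supplies everything, driven by `seed`.
#' @param seed Simulator seed (default 1).
#' @return Invisible list with all stage results (`quant`, `qc`,
#'   `normalized`, `zonation`, `features`, `classes`, `classifier`,
#'   `prediction`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile(),
                         report = NULL, cells = NULL, images = NULL,
                         contours = NULL, seed = 1) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  simulated <- is.null(report)
  if (simulated) {
    sim <- config$sim
    truth <- simulate_lobule(sim$n_cells, seed = seed,
                             n_proteins = sim$n_proteins)
    pm_true <- simulate_proteome(truth, noise_sd = sim$noise_sd)
    rep_sim <- simulate_report(pm_true, truth,
                               frag_per_precursor = sim$frag_per_precursor,
                               n_precursors = sim$n_precursors,
                               ratio_noise_sd = sim$ratio_noise_sd)
    report <- rep_sim$report
    images <- simulate_images(truth, patch_size = sim$patch_size)
    cells <- merge(truth$cells, rep_sim$sample_map, by = "cell_id",
                   sort = FALSE)
    cells <- cells[, c("cell_id", "run", "channel", "centroid_x",
                       "centroid_y", "area_um2", "d_pv_um", "d_cv_um")]
    # square stand-in contours with the true area, centered on the cell
    half <- sqrt(truth$cells$area_um2) / 2
    contours <- lapply(seq_len(nrow(truth$cells)), function(i) {
      cx <- truth$cells$centroid_x[i]; cy <- truth$cells$centroid_y[i]
      cbind(x = cx + c(-1, 1, 1, -1) * half[i],
            y = cy + c(-1, -1, 1, 1) * half[i])
    })
    names(contours) <- truth$cells$cell_id
    write_cells(cells, file.path(output_dir, "cells.csv"))
    write_report(report, file.path(output_dir, "report.tsv"))
    utils::write.csv(truth$cells, file.path(output_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  stopifnot(!is.null(cells))

  quant <- stage("quant", {
    filt <- filter_report(report, config$lib_pg_q, config$q_value,
                          config$channel_q)
    pq <- quantify_report(filt, sample_map = cells)
    maxlfq_collapse(pq, sample_ids = cells$cell_id[
      cells$cell_id %in% unique(pq$sample_id)])
  })
  write_protein_matrix(quant, file.path(output_dir, "protein_matrix.csv"))

  qc <- stage("qc_normalize", {
    ar <- cells$area_um2[match(colnames(pm_log2(quant)), cells$cell_id)]
    tab <- sample_qc(quant, ar, low_k = config$id_low_k,
                     high_k = config$id_high_k, id_window = config$id_window,
                     min_um2 = config$size_min_um2,
                     max_um2 = config$size_max_um2)
    kept <- pm_subset(quant, samples = tab$keep)
    norm <- tryCatch(
      median_normalize(kept, completeness = config$norm_completeness),
      error = function(e) median_normalize(
        kept, completeness = config$norm_completeness_fallback))
    list(table = tab, normalized = norm$matrix,
         norm_proteins = norm$norm_proteins)
  })
  utils::write.csv(qc$table, file.path(output_dir, "qc_samples.csv"),
                   row.names = FALSE)
  norm_pm <- qc$normalized

  zon <- stage("spatial_zonation", {
    ids <- colnames(pm_log2(norm_pm))
    cc <- cells[match(ids, cells$cell_id), ]
    r <- relative_distance(cc$d_pv_um, cc$d_cv_um)
    bins <- assign_bins(r, B = config$B)
    res <- zonation_anova(norm_pm, bins,
                          completeness_min = config$anova_completeness)
    flat <- flatness_test(norm_pm, alpha = config$flatness_alpha)
    prof <- bin_profile(norm_pm, bins)
    list(r = r, bins = bins, anova = res, flat = flat, profile = prof)
  })
  utils::write.table(zon$anova, file.path(output_dir, "zonation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(cell_id = colnames(pm_log2(norm_pm)),
                              r = zon$r, bin = zon$bins),
                   file.path(output_dir, "bins.csv"), row.names = FALSE)

  feats <- stage("image_features", {
    ids <- names(images)
    f <- t(vapply(ids, function(id) {
      extract_features(images[[id]], contours[[id]],
                       pixel_size = config$pixel_size)
    }, numeric(17)))
    rownames(f) <- ids
    f
  })
  utils::write.csv(data.frame(cell_id = rownames(feats), feats),
                   file.path(output_dir, "features.csv"), row.names = FALSE)

  cls <- stage("class_predict", {
    ids <- colnames(pm_log2(norm_pm))
    model <- kmeans_classes(norm_pm, r = zon$r, K = config$K,
                            seed = config$clustering_seed,
                            completeness_min = config$pca_completeness)
    fmat <- feats[ids, , drop = FALSE]
    clf <- train_classifier(fmat, model$labels,
                            test_fraction = config$test_fraction,
                            seed = config$classifier_seed,
                            n_trees = config$n_trees)
    prob <- predict_probabilities(clf, feats)
    mu <- class_mean_proteomes(norm_pm, model$labels)
    pred <- weighted_proteome_prediction(prob, mu)
    ev <- evaluate_prediction(
      pred[, ids[clf$test_idx], drop = FALSE],
      pm_subset(norm_pm, samples = clf$test_idx))
    list(model = model, classifier = clf, probabilities = prob,
         prediction = pred, evaluation = ev)
  })
  utils::write.csv(data.frame(cell_id = rownames(cls$probabilities),
                              cls$probabilities, check.names = FALSE),
                   file.path(output_dir, "class_probabilities.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(protein_id = rownames(cls$prediction),
                              cls$prediction, check.names = FALSE),
                   file.path(output_dir, "predicted_proteome.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "scdvp",
    seed = seed,
    simulated = simulated,
    config = config[setdiff(names(config), "id_window")],
    config_hash = rlang::hash(config),
    outputs = list.files(output_dir),
    n_samples_quantified = ncol(pm_log2(quant)),
    n_samples_kept = sum(qc$table$keep),
    n_proteins_tested = sum(zon$anova$tested),
    test_accuracy = cls$classifier$report$test_accuracy,
    prediction_R = cls$evaluation$R
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(quant = quant, qc = qc$table, normalized = norm_pm,
                 zonation = zon, features = feats,
                 classes = cls$model, classifier = cls$classifier,
                 prediction = cls$prediction,
                 evaluation = cls$evaluation, manifest = manifest))
}
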