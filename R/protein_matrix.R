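#' Construct a ProteinMatrix
#'
#' The central quantitative container: a proteins x samples matrix of
#' log2 intensities with missing values encoded as `NA` (never 0),
#' plus sample and protein metadata. This mirrors the convention of
#' expression containers in limma-style workflows: rows are features,
#' columns are samples.
#'
#' @param log2_intensity Numeric matrix, proteins x samples, with
#'   dimnames; `NA` marks a protein not quantified in a sample.
#' @param samples Data frame of per-sample metadata with a `sample_id`
#'   column matching `colnames(log2_intensity)`. Created minimally if
#'   omitted.
#' @param proteins Data frame of per-protein metadata with a
#'   `protein_id` column matching `rownames(log2_intensity)`.
#' @return An object of class `ProteinMatrix`.
#' @export
protein_matrix <- function(log2_intensity, samples = NULL, proteins = NULL) {
  if (!is.matrix(log2_intensity) || !is.numeric(log2_intensity)) {
    stop("`log2_intensity` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(log2_intensity))) {
    rownames(log2_intensity) <- paste0("protein_", seq_len(nrow(log2_intensity)))
  }
  if (is.null(colnames(log2_intensity))) {
    colnames(log2_intensity) <- paste0("sample_", seq_len(ncol(log2_intensity)))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(log2_intensity),
                          stringsAsFactors = FALSE)
  }
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = rownames(log2_intensity),
                           stringsAsFactors = FALSE)
  }
  stopifnot(identical(samples$sample_id, colnames(log2_intensity)),
            identical(proteins$protein_id, rownames(log2_intensity)))
  structure(list(log2 = log2_intensity, samples = samples, proteins = proteins),
            class = "ProteinMatrix")
}

#' @export
print.ProteinMatrix <- function(x, ...) {
  compl <- mean(!is.na(x$log2))
  cat(sprintf("ProteinMatrix: %d proteins x %d samples (%.1f%% complete)\n",
              nrow(x$log2), ncol(x$log2), 100 * compl))
  invisible(x)
}

#' @export
dim.ProteinMatrix <- function(x) dim(x$log2)

# Accept either a ProteinMatrix or a bare proteins x samples matrix.
pm_log2 <- function(x) {
  if (inherits(x, "ProteinMatrix")) x$log2
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a ProteinMatrix or a numeric matrix", call. = FALSE)
}

# Rebuild a ProteinMatrix around a transformed log2 matrix, keeping
# metadata when the input carried it.
pm_rewrap <- function(x, new_log2) {
  if (inherits(x, "ProteinMatrix")) {
    keep_s <- x$samples[match(colnames(new_log2), x$samples$sample_id), ,
                        drop = FALSE]
    rownames(keep_s) <- NULL
    keep_p <- x$proteins[match(rownames(new_log2), x$proteins$protein_id), ,
                         drop = FALSE]
    rownames(keep_p) <- NULL
    protein_matrix(new_log2, keep_s, keep_p)
  } else {
    new_log2
  }
}

#' Subset a ProteinMatrix by proteins and/or samples
#'
#' @param x A `ProteinMatrix`.
#' @param proteins,samples Logical, integer or character index into
#'   rows / columns; `NULL` keeps all.
#' @return A `ProteinMatrix`.
#' @export
pm_subset <- function(x, proteins = NULL, samples = NULL) {
  m <- pm_log2(x)
  if (is.null(proteins)) proteins <- seq_len(nrow(m))
  if (is.null(samples)) samples <- seq_len(ncol(m))
  pm_rewrap(x, m[proteins, samples, drop = FALSE])
}
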