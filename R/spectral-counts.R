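#' Spectral-count matrices
#'
#' A `SpectralCountMatrix` holds a protein x sample matrix of spectral-count
#' derived values together with sample metadata and a processing-stage tag.
#' Stages advance in the fixed order
#' `raw -> subtracted -> floored -> log2 -> normalized`; each processing
#' function checks the stage of its input, so the pipeline cannot be run out
#' of order. After background subtraction the control (GST) columns are
#' removed from the working matrix but retained in the `controls` slot for
#' audit.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (one of `"A"`, `"B"`, `"control"`) and `replicate` (integer), one row
#'   per column of `values`.
#' @param stage processing stage tag.
#' @param controls retained control sub-matrix (post-subtraction stages).
#' @return an object of class `SpectralCountMatrix`.
#' @export
spectral_count_matrix <- function(values, samples,
                                  stage = c("raw", "subtracted", "floored",
                                            "log2", "normalized"),
                                  controls = NULL) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!all(c("sample_id", "condition", "replicate") %in% names(samples)))
    stop_input("samples needs columns sample_id, condition, replicate")
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  if (!all(samples$condition %in% c("A", "B", "control")))
    stop_input("condition must be one of 'A', 'B', 'control'")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), samples$sample_id))
    stop_input("column names of values must match samples$sample_id, in order")
  structure(list(values = values, samples = samples, stage = stage,
                 controls = controls),
            class = "SpectralCountMatrix")
}

#' @export
print.SpectralCountMatrix <- function(x, ...) {
  cat(sprintf("SpectralCountMatrix [stage: %s] %d proteins x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$condition)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.SpectralCountMatrix <- function(x) dim(x$values)

check_stage <- function(m, expected) {
  if (!inherits(m, "SpectralCountMatrix"))
    stop_input("expected a SpectralCountMatrix")
  if (!identical(m$stage, expected))
    stop_input("matrix is at stage '", m$stage, "' but stage '", expected,
               "' is required; processing steps must be applied in order ",
               "raw -> subtracted -> floored -> log2 -> normalized")
  invisible(m)
}

#' Aggregate peptide-spectrum-match counts to the protein level
#'
#' Spectral counts are summed for each matching peptide of a given protein,
#' per sample. A peptide listed under several proteins contributes its counts
#' to every matching protein (`shared_peptides = "all"`, the default reading
#' of "each matching peptide for a given protein"); `"unique"` drops peptides
#' assigned to more than one protein before summing.
#'
#' @param psm data.frame with columns `protein_id`, `peptide_id`, `sample_id`,
#'   `spectral_count` (non-negative). Rows may repeat; they are summed.
#' @param samples sample-metadata data.frame (see
#'   [spectral_count_matrix()]); every `sample_id` in `psm` must appear here.
#' @param shared_peptides `"all"` or `"unique"`.
#' @return a `SpectralCountMatrix` at stage `"raw"`. Proteins absent from a
#'   sample get 0.
#' @export
aggregate_psm_counts <- function(psm, samples,
                                 shared_peptides = c("all", "unique")) {
  shared_peptides <- match.arg(shared_peptides)
  need <- c("protein_id", "peptide_id", "sample_id", "spectral_count")
  if (!all(need %in% names(psm)))
    stop_input("psm needs columns ", paste(need, collapse = ", "))
  if (any(psm$spectral_count < 0)) stop_input("spectral counts must be >= 0")
  unknown <- setdiff(unique(psm$sample_id), samples$sample_id)
  if (length(unknown))
    stop_input("unknown sample id(s) in psm table: ",
               paste(unknown, collapse = ", "))
  if (shared_peptides == "unique") {
    n_prot <- tapply(psm$protein_id, psm$peptide_id,
                     function(p) length(unique(p)))
    keep <- names(n_prot)[n_prot == 1L]
    psm <- psm[psm$peptide_id %in% keep, , drop = FALSE]
  }
  proteins <- sort(unique(as.character(psm$protein_id)))
  mat <- matrix(0, nrow = length(proteins), ncol = nrow(samples),
                dimnames = list(proteins, samples$sample_id))
  if (nrow(psm)) {
    agg <- tapply(psm$spectral_count,
                  list(factor(as.character(psm$protein_id), proteins),
                       factor(as.character(psm$sample_id),
                              samples$sample_id)),
                  sum)
    agg[is.na(agg)] <- 0
    mat[rownames(agg), colnames(agg)] <- agg
  }
  spectral_count_matrix(mat, samples, stage = "raw")
}

#' Subtract affinity-resin (GST) background counts
#'
#' Removes the nonspecific-binding background measured in the GST-only
#' control pull-downs from each experimental sample, per protein. With
#' `control_mode = "mean"` (default) the mean over control samples is
#' subtracted from every experimental column; `"paired"` subtracts control
#' replicate i from experimental replicate i. Resulting values may be
#' negative; they are dealt with by [log2_with_floor()]. Control columns are
#' dropped from the working matrix but kept in the `controls` slot.
#'
#' @param m `SpectralCountMatrix` at stage `"raw"`.
#' @param control_mode `"mean"` or `"paired"`.
#' @return a `SpectralCountMatrix` at stage `"subtracted"` containing only
#'   experimental columns.
#' @export
subtract_background <- function(m, control_mode = c("mean", "paired")) {
  control_mode <- match.arg(control_mode)
  check_stage(m, "raw")
  is_ctrl <- m$samples$condition == "control"
  if (!any(is_ctrl)) stop_input("no control (GST) samples present")
  ctrl <- m$values[, is_ctrl, drop = FALSE]
  expm <- m$values[, !is_ctrl, drop = FALSE]
  expsamp <- m$samples[!is_ctrl, , drop = FALSE]
  if (control_mode == "mean") {
    out <- expm - rowMeans(ctrl)
  } else {
    ctrl_rep <- m$samples$replicate[is_ctrl]
    idx <- match(expsamp$replicate, ctrl_rep)
    if (anyNA(idx))
      stop_input("paired control mode requires a control sample for every ",
                 "experimental replicate index")
    out <- expm - ctrl[, idx, drop = FALSE]
  }
  spectral_count_matrix(out, expsamp, stage = "subtracted", controls = ctrl)
}

#' Floor-to-one log2 transformation
#'
#' Background-subtracted counts at or below the counting floor are set to one
#' so that the matrix can be log2 transformed; every value below 1 is raised
#' to 1 (negative and zero values included), guaranteeing a non-negative
#' log2 matrix for any input.
#'
#' @param m `SpectralCountMatrix` at stage `"subtracted"`.
#' @return a `SpectralCountMatrix` at stage `"log2"`; all values >= 0.
#' @export
log2_with_floor <- function(m) {
  check_stage(m, "subtracted")
  out <- log2(pmax(m$values, 1))
  spectral_count_matrix(out, m$samples, stage = "log2", controls = m$controls)
}

#' Quantile normalization across experimental samples
#'
#' Classical quantile normalization: each column's ranked values are replaced
#' by the across-column mean of the values at that rank (tied ranks averaged),
#' so that afterwards all experimental columns share one common distribution.
#' Controls were removed at the subtraction step and take no part. Delegates
#' to [limma::normalizeQuantiles()].
#'
#' @param m `SpectralCountMatrix` at stage `"log2"`.
#' @return a `SpectralCountMatrix` at stage `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  check_stage(m, "log2")
  if (ncol(m$values) < 2L)
    stop_input("quantile normalization needs at least 2 experimental columns")
  out <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(out) <- dimnames(m$values)
  spectral_count_matrix(out, m$samples, stage = "normalized",
                        controls = m$controls)
}

#' Call proteins detected above background
#'
#' A protein is flagged detected in a condition when its post-subtraction
#' value is at least `min_value` in at least `min_replicates` replicates of
#' that condition. This reconstructs a "specifically TUBE-bound" set; the
#' thresholds are configurable because no single rule is canonical.
#'
#' @param m `SpectralCountMatrix` at stage `"subtracted"`.
#' @param min_value detection threshold on the subtracted scale (default 1).
#' @param min_replicates minimum supporting replicates; default all
#'   replicates of the condition.
#' @return data.frame with one row per protein x condition: `protein_id`,
#'   `condition`, `n_supporting`, `detected`; the per-condition detected-set
#'   sizes are attached as attribute `"n_detected"`.
#' @export
call_detected_proteins <- function(m, min_value = 1, min_replicates = NULL) {
  check_stage(m, "subtracted")
  conds <- setdiff(unique(m$samples$condition), "control")
  res <- list()
  for (cond in conds) {
    cols <- m$samples$condition == cond
    k <- sum(cols)
    minrep <- min_replicates %||% k
    if (minrep > k)
      stop_input("min_replicates (", minrep, ") exceeds available replicates (",
                 k, ") for condition ", cond)
    supp <- rowSums(m$values[, cols, drop = FALSE] >= min_value)
    res[[cond]] <- data.frame(protein_id = rownames(m$values),
                              condition = cond,
                              n_supporting = as.integer(supp),
                              detected = supp >= minrep,
                              row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_detected") <- vapply(split(out$detected, out$condition), sum,
                                    integer(1))
  out
}

#' Densitometry relative protein level
#'
#' Band density normalized against a housekeeping protein (beta-actin or
#' GAPDH), expressed relative to the untreated control condition:
#' `(band/housekeeping) / (control_band/control_housekeeping)`.
#'
#' @param band,housekeeping treatment-condition band densities (> 0).
#' @param control_band,control_housekeeping control-condition densities (> 0).
#' @return relative level (1 = unchanged versus control).
#' @export
densitometry_relative_level <- function(band, housekeeping,
                                        control_band, control_housekeeping) {
  for (v in list(band = band, housekeeping = housekeeping,
                 control_band = control_band,
                 control_housekeeping = control_housekeeping)) {
    if (any(!is.finite(v)) || any(v <= 0))
      stop_input("all densities must be finite and > 0")
  }
  (band / housekeeping) / (control_band / control_housekeeping)
}
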