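#' Per-replicate log2 fold changes between conditions
#'
#' Computes condition B minus condition A log2 differences on the normalized
#' matrix. `pairing = "by_index"` pairs replicate i of B with replicate i of
#' A (requires equal replicate counts); `"all_pairs"` forms one column per
#' ordered (B_j, A_i) pair and is strictly more stringent downstream.
#'
#' @param m `SpectralCountMatrix` at stage `"normalized"`.
#' @param pairing `"by_index"` or `"all_pairs"`.
#' @return object of class `FoldChangeTable`: list with `log2fc` (protein x
#'   pair matrix) and `pairing`.
#' @export
replicate_fold_changes <- function(m, pairing = c("by_index", "all_pairs")) {
  pairing <- match.arg(pairing)
  check_stage(m, "normalized")
  a_cols <- which(m$samples$condition == "A")
  b_cols <- which(m$samples$condition == "B")
  if (!length(a_cols) || !length(b_cols))
    stop_input("both conditions A and B must be present")
  a_cols <- a_cols[order(m$samples$replicate[a_cols])]
  b_cols <- b_cols[order(m$samples$replicate[b_cols])]
  if (pairing == "by_index") {
    if (length(a_cols) != length(b_cols))
      stop_input("by_index pairing requires equal replicate counts (A: ",
                 length(a_cols), ", B: ", length(b_cols), ")")
    fc <- m$values[, b_cols, drop = FALSE] - m$values[, a_cols, drop = FALSE]
    colnames(fc) <- sprintf("pair_%d", seq_along(a_cols))
  } else {
    combos <- expand.grid(a = seq_along(a_cols), b = seq_along(b_cols))
    fc <- sapply(seq_len(nrow(combos)), function(k) {
      m$values[, b_cols[combos$b[k]]] - m$values[, a_cols[combos$a[k]]]
    })
    fc <- matrix(fc, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values),
                                 sprintf("B%d_vs_A%d", combos$b, combos$a)))
  }
  structure(list(log2fc = fc, pairing = pairing), class = "FoldChangeTable")
}

#' Reproducible two-fold differential filter
#'
#' A protein is called enriched in condition B only when every replicate-pair
#' log2 difference exceeds `+log2_threshold`, and reduced only when every
#' difference is below `-log2_threshold` — the change must be reproduced in
#' all replicas. "More than two-fold" is read as a strict inequality
#' (`strict = TRUE`): a difference of exactly the threshold fails.
#'
#' @param fc `FoldChangeTable` from [replicate_fold_changes()].
#' @param log2_threshold positive log2 threshold (default 1, i.e. two-fold).
#' @param strict if `TRUE` use `>` / `<`; if `FALSE` use `>=` / `<=`.
#' @return object of class `DifferentialResult`: data.frame with
#'   `protein_id`, `status` (`enriched_in_B`, `reduced_in_B`,
#'   `not_differential`), mean log2 fold change and the per-pair differences;
#'   summary counts in attribute `"summary"`.
#' @export
reproducible_differential <- function(fc, log2_threshold = 1, strict = TRUE) {
  if (!inherits(fc, "FoldChangeTable")) stop_input("expected a FoldChangeTable")
  if (!nrow(fc$log2fc)) stop_input("empty fold-change table")
  assert_scalar_number(log2_threshold, "log2_threshold", positive = TRUE)
  x <- fc$log2fc
  if (strict) {
    up <- rowSums(x > log2_threshold) == ncol(x)
    dn <- rowSums(x < -log2_threshold) == ncol(x)
  } else {
    up <- rowSums(x >= log2_threshold) == ncol(x)
    dn <- rowSums(x <= -log2_threshold) == ncol(x)
  }
  status <- rep("not_differential", nrow(x))
  status[up] <- "enriched_in_B"
  status[dn] <- "reduced_in_B"
  out <- data.frame(protein_id = rownames(x), status = status,
                    mean_log2fc = rowMeans(x), row.names = NULL)
  out <- cbind(out, as.data.frame(x, row.names = NULL))
  attr(out, "summary") <- list(n_enriched = sum(up), n_reduced = sum(dn),
                               n_total_differential = sum(up) + sum(dn),
                               log2_threshold = log2_threshold,
                               strict = strict, pairing = fc$pairing)
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' @export
print.DifferentialResult <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("DifferentialResult: %d proteins; %d differential ",
                     "(%d enriched, %d reduced) at |log2fc| %s %g, %s pairing\n"),
              nrow(x), s$n_total_differential, s$n_enriched, s$n_reduced,
              if (s$strict) ">" else ">=", s$log2_threshold, s$pairing))
  invisible(x)
}

#' Recovery metrics against planted ground truth
#'
#' Compares a differential call set with the generator's ground truth:
#' a planted protein counts as recovered only when its called direction
#' matches the planted direction.
#'
#' @param result `DifferentialResult`.
#' @param truth `CountGroundTruth` data.frame from [generate_tube_counts()]
#'   (columns `protein_id`, `direction`).
#' @return list with `sensitivity`, `specificity`, `fdp` (planted-truth false
#'   discovery proportion, 0 when nothing is called), and the underlying
#'   counts.
#' @export
recovery_report <- function(result, truth) {
  if (!setequal(result$protein_id, truth$protein_id))
    stop_input("result and truth cover different protein universes")
  truth <- truth[match(result$protein_id, truth$protein_id), ]
  called_dir <- c(enriched_in_B = "up", reduced_in_B = "down",
                  not_differential = "null")[result$status]
  tp <- sum(truth$direction != "null" & called_dir == truth$direction)
  fp <- sum(truth$direction == "null" & called_dir != "null") +
    sum(truth$direction != "null" & called_dir != "null" &
          called_dir != truth$direction)
  pos <- sum(truth$direction != "null")
  neg <- sum(truth$direction == "null")
  tn <- sum(truth$direction == "null" & called_dir == "null")
  list(sensitivity = if (pos) tp / pos else NA_real_,
       specificity = if (neg) tn / neg else NA_real_,
       fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
       n_planted = pos, n_called = sum(called_dir != "null"),
       true_positives = tp, false_positives = fp)
}
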