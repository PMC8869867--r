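#' Read and write pipeline tables and images
#'
#' Plain-text interchange formats: spectral counts as a wide TSV
#' (`protein_id`, `peptide_id`, one count column per sample) with sample
#' metadata in a sidecar TSV; dose-response and event tables as CSV; image
#' channels as 16-bit grayscale TIFF.
#'
#' @param psm long PSM table (see [aggregate_psm_counts()]).
#' @param samples sample-metadata data.frame.
#' @param path,counts_path,samples_path file paths.
#' @return `write_*` functions return their path(s) invisibly; `read_*`
#'   functions return the parsed object.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_psm_counts <- function(psm, samples, counts_path, samples_path) {
  wide <- stats::reshape(psm, direction = "wide",
                         idvar = c("protein_id", "peptide_id"),
                         timevar = "sample_id", v.names = "spectral_count")
  names(wide) <- sub("^spectral_count\\.", "", names(wide))
  missing_cols <- setdiff(samples$sample_id, names(wide))
  for (s in missing_cols) wide[[s]] <- 0L
  wide <- wide[, c("protein_id", "peptide_id", samples$sample_id)]
  wide[is.na(wide)] <- 0L
  wide <- wide[order(wide$protein_id, wide$peptide_id), ]
  utils::write.table(wide, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' @rdname pipeline_io
#' @export
read_psm_counts <- function(counts_path, samples_path) {
  wide <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  long <- stats::reshape(wide, direction = "long",
                         idvar = c("protein_id", "peptide_id"),
                         varying = samples$sample_id,
                         v.names = "spectral_count",
                         timevar = "sample_id", times = samples$sample_id)
  rownames(long) <- NULL
  list(psm = long[long$spectral_count > 0, , drop = FALSE],
       samples = samples)
}

#' @rdname pipeline_io
#' @param m `SpectralCountMatrix`.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(protein_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param image `TwoChannelImage`.
#' @param ref_path,partner_path per-channel TIFF paths.
#' @export
write_two_channel_tiff <- function(image, ref_path, partner_path) {
  scale <- max(image$ref, image$partner, 1)
  tiff::writeTIFF(image$ref / scale, ref_path, bits.per.sample = 16)
  tiff::writeTIFF(image$partner / scale, partner_path, bits.per.sample = 16)
  invisible(c(ref_path, partner_path))
}

#' @rdname pipeline_io
#' @export
read_two_channel_tiff <- function(ref_path, partner_path) {
  two_channel_image(tiff::readTIFF(ref_path), tiff::readTIFF(partner_path))
}

#' @rdname pipeline_io
#' @param dr dose-response data.frame (see [generate_dose_response()]).
#' @export
write_dose_response <- function(dr, path) {
  utils::write.csv(dr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param ratio mixing ratio to attach when reading a dose-response CSV.
#' @export
read_dose_response <- function(path, ratio = NULL) {
  dr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(ratio)) attr(dr, "ratio") <- ratio
  dr
}

#' @rdname pipeline_io
#' @param events event table (see [generate_flow_events()]).
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_events <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
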