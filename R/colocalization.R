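#' Two-channel fluorescence images
#'
#' Container for a registered pair of single-plane channels: the reference
#' channel carries the autophagy marker (LC3B or p62) whose puncta define
#' the regions of interest, the partner channel a proteasome subunit (beta2
#' or RPN1). Both are equal-shape non-negative intensity matrices.
#'
#' @param ref,partner numeric matrices of equal dimension, intensities >= 0.
#' @param pixel_size optional pixel edge length in microns.
#' @return object of class `TwoChannelImage`.
#' @export
two_channel_image <- function(ref, partner, pixel_size = NULL) {
  ref <- as.matrix(ref); partner <- as.matrix(partner)
  if (!identical(dim(ref), dim(partner)))
    stop_input("channels must have equal dimensions")
  if (any(ref < 0) || any(partner < 0))
    stop_input("intensities must be non-negative")
  structure(list(ref = ref, partner = partner, pixel_size = pixel_size),
            class = "TwoChannelImage")
}

# Otsu threshold on an arbitrary-scale channel (EBImage::otsu works on [0,1]).
# Returns NA for a flat channel.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  y <- (x - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(y), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

resolve_threshold <- function(channel, threshold) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "otsu")) return(otsu_threshold(channel))
  stop_input("threshold must be \"otsu\" or a numeric value")
}

# 8-connectivity labeling of a logical mask via connected components of the
# king-move adjacency graph over foreground pixels.
label_components_8 <- function(mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (!length(fg)) return(labels)
  nr <- nrow(mask)
  pos <- match(seq_len(nr * ncol(mask)), fg)  # pixel index -> node id
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nrow_ <- row + off[1]; ncol_ <- col + off[2]
    ok <- nrow_ >= 1L & nrow_ <= nr & ncol_ >= 1L & ncol_ <= ncol(mask)
    nb <- pos[(ncol_[ok] - 1L) * nr + nrow_[ok]]
    has <- !is.na(nb)
    edges <- c(edges, rbind(which(ok)[has], nb[has]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  labels[fg] <- igraph::components(g)$membership
  labels
}

#' Detect fluorescent puncta as regions of interest
#'
#' Thresholds a channel (Otsu or fixed), labels connected components with
#' 8-connectivity and keeps components with `min_area <= area <= max_area`.
#' A flat channel under Otsu yields an empty ROI set with a warning, not an
#' error.
#'
#' @param channel 2-D intensity matrix.
#' @param threshold `"otsu"` or a fixed numeric intensity threshold; pixels
#'   strictly above it are foreground.
#' @param min_area,max_area component area bounds in pixels.
#' @return object of class `ROISet`: list with `labels` (integer matrix, 0 =
#'   background), `ids`, `areas`, `centroids` (x = column, y = row) and the
#'   threshold used.
#' @export
detect_puncta <- function(channel, threshold = "otsu", min_area = 4,
                          max_area = Inf) {
  channel <- as.matrix(channel)
  if (!length(channel)) stop_input("empty image")
  thr <- resolve_threshold(channel, threshold)
  if (is.na(thr)) {
    warning("flat channel: Otsu threshold undefined, returning no ROIs",
            call. = FALSE)
    return(structure(list(labels = matrix(0L, nrow(channel), ncol(channel)),
                          ids = integer(0), areas = integer(0),
                          centroids = data.frame(x = numeric(0), y = numeric(0)),
                          threshold = NA_real_), class = "ROISet"))
  }
  labels <- label_components_8(channel > thr)
  if (max(labels) > 0L) {
    areas <- tabulate(labels[labels > 0L])
    keep <- which(areas >= min_area & areas <= max_area)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    areas <- areas[keep]
  } else {
    keep <- integer(0); areas <- integer(0)
  }
  ids <- seq_along(keep)
  cent <- if (length(ids)) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    r <- (idx - 1L) %% nrow(labels) + 1L
    cc <- (idx - 1L) %/% nrow(labels) + 1L
    data.frame(x = as.numeric(tapply(cc, lab, mean)),
               y = as.numeric(tapply(r, lab, mean)))
  } else data.frame(x = numeric(0), y = numeric(0))
  structure(list(labels = labels, ids = ids, areas = as.integer(areas),
                 centroids = cent, threshold = thr), class = "ROISet")
}

#' @export
print.ROISet <- function(x, ...) {
  cat(sprintf("ROISet: %d puncta (threshold %.4g; areas %s px)\n",
              length(x$ids), x$threshold,
              if (length(x$areas)) paste(range(x$areas), collapse = "-")
              else "-"))
  invisible(x)
}

#' Manders co-localization coefficients within puncta ROIs
#'
#' Within the union of the regions of interest, M1 is the fraction of
#' reference-channel intensity lying in pixels where the partner channel
#' exceeds its threshold, and M2 the symmetric quantity with channels
#' swapped. Both per-ROI coefficients and the pooled-ROI value are returned;
#' a ROI with zero total intensity in a channel has that coefficient
#' reported as missing.
#'
#' @param image `TwoChannelImage`.
#' @param rois `ROISet` (normally puncta detected in the reference channel).
#' @param partner_threshold,ref_threshold `"otsu"` or fixed numeric
#'   thresholds applied to the partner / reference channel.
#' @return object of class `MandersResult`: list with pooled `M1`, `M2`,
#'   per-ROI data.frame and the thresholds used.
#' @export
manders <- function(image, rois, partner_threshold = "otsu",
                    ref_threshold = "otsu") {
  if (!inherits(image, "TwoChannelImage")) stop_input("expected TwoChannelImage")
  if (!inherits(rois, "ROISet")) stop_input("expected ROISet")
  if (!length(rois$ids)) stop_input("ROISet is empty: no pooled value exists")
  thr_p <- resolve_threshold(image$partner, partner_threshold)
  thr_r <- resolve_threshold(image$ref, ref_threshold)
  union_idx <- which(rois$labels > 0L)
  m_of <- function(num_ch, gate_ch, gate_thr, idx) {
    tot <- sum(num_ch[idx])
    if (tot == 0) return(NA_real_)
    sum(num_ch[idx][gate_ch[idx] > gate_thr]) / tot
  }
  per_roi <- data.frame(
    roi = rois$ids,
    M1 = vapply(rois$ids, function(i)
      m_of(image$ref, image$partner, thr_p, which(rois$labels == i)),
      numeric(1)),
    M2 = vapply(rois$ids, function(i)
      m_of(image$partner, image$ref, thr_r, which(rois$labels == i)),
      numeric(1)))
  structure(list(M1 = m_of(image$ref, image$partner, thr_p, union_idx),
                 M2 = m_of(image$partner, image$ref, thr_r, union_idx),
                 per_roi = per_roi,
                 thresholds = c(partner = thr_p, ref = thr_r)),
            class = "MandersResult")
}

#' @export
print.MandersResult <- function(x, ...) {
  cat(sprintf("MandersResult: pooled M1 = %.3f, M2 = %.3f over %d ROIs\n",
              x$M1, x$M2, nrow(x$per_roi)))
  invisible(x)
}

bilinear_at <- function(img, x, y) {
  # x = column, y = row, 1-based; coordinates clamped to the image
  x <- pmin(pmax(x, 1), ncol(img)); y <- pmin(pmax(y, 1), nrow(img))
  x0 <- pmin(floor(x), ncol(img) - 1L); y0 <- pmin(floor(y), nrow(img) - 1L)
  if (ncol(img) == 1L) x0 <- rep(1, length(x))
  if (nrow(img) == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1L, ncol(img)); y1 <- pmin(y0 + 1L, nrow(img))
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x1)] * fx * (1 - fy) +
    img[cbind(y1, x0)] * (1 - fx) * fy +
    img[cbind(y1, x1)] * fx * fy
}

#' Normalized two-channel line profile
#'
#' Samples both channels by bilinear interpolation at `n_samples` evenly
#' spaced points along the segment between two pixel coordinates, and
#' normalizes each trace by its own maximum (a zero-max trace is returned as
#' all zeros). This is the standard way to display marker co-localization
#' along a line across a cell.
#'
#' @param image `TwoChannelImage`.
#' @param from,to numeric length-2 coordinates `c(x, y)` (x = column,
#'   y = row); must differ.
#' @param n_samples number of sample points (>= 2).
#' @return data.frame with columns `position` (0..1 along the segment),
#'   `ref`, `partner`.
#' @export
line_profile <- function(image, from, to, n_samples = 100) {
  if (!inherits(image, "TwoChannelImage")) stop_input("expected TwoChannelImage")
  if (n_samples < 2) stop_input("n_samples must be >= 2")
  if (isTRUE(all.equal(from, to))) stop_input("endpoints must differ")
  dims <- dim(image$ref)
  for (p in list(from, to))
    if (p[1] < 1 || p[1] > dims[2] || p[2] < 1 || p[2] > dims[1])
      stop_input("endpoints must lie inside the image")
  tseq <- seq(0, 1, length.out = n_samples)
  xs <- from[1] + tseq * (to[1] - from[1])
  ys <- from[2] + tseq * (to[2] - from[2])
  norm1 <- function(v) { mx <- max(v); if (mx > 0) v / mx else rep(0, length(v)) }
  data.frame(position = tseq,
             ref = norm1(bilinear_at(image$ref, xs, ys)),
             partner = norm1(bilinear_at(image$partner, xs, ys)))
}

#' Compare per-cell co-localization coefficients between two groups
#'
#' Group means with standard deviations and a two-tailed unpaired t-test
#' (see [two_sample_ttest()]).
#'
#' @param values_a,values_b numeric vectors of per-cell coefficients
#'   (each of length >= 2; unequal sizes allowed).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return list with per-group `mean`/`sd`/`n` and `t`, `df`, `p_value`.
#' @export
compare_coloc <- function(values_a, values_b, variant = "student") {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_input("each group needs at least 2 values")
  tt <- two_sample_ttest(values_a, values_b, variant)
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a), n_a = length(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b), n_b = length(values_b),
       t = tt$t, df = tt$df, p_value = tt$p_value)
}
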