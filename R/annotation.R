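#' Functional-category annotation maps
#'
#' An annotation map assigns proteins to functional categories and
#' subcategories, e.g. the ubiquitin-proteasome system (20S alpha, 20S beta,
#' 19S base, 19S lid) and the autophagy-lysosome system (early signaling,
#' autophagosome formation, lysosome fusion). Assignments are many-to-many:
#' a protein may belong to several categories and then contributes to each.
#'
#' @param path TSV file with columns `protein_id`, `category`,
#'   `subcategory`.
#' @return data.frame of class `AnnotationMap`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_annotation(ann)
}

#' @rdname read_annotation
#' @param ann data.frame with at least `protein_id` and `category`
#'   (`subcategory` optional, defaults to the category).
#' @export
as_annotation <- function(ann) {
  if (!all(c("protein_id", "category") %in% names(ann)))
    stop_input("annotation needs columns protein_id, category")
  if (is.null(ann$subcategory)) ann$subcategory <- ann$category
  ann$protein_id <- as.character(ann$protein_id)
  if (any(!nzchar(ann$category))) stop_input("categories must be non-empty")
  class(ann) <- c("AnnotationMap", "data.frame")
  ann
}

#' Summarize per-protein values by functional category
#'
#' Each cell of the returned category x condition matrix is the arithmetic
#' mean of the member proteins' values in that condition (the mean of all
#' single values); proteins annotated to several categories contribute to
#' each. Categories whose members are all absent from the value table are
#' omitted with a warning.
#'
#' @param values numeric matrix, proteins (rownames) x conditions.
#' @param ann `AnnotationMap`.
#' @param by `"subcategory"` (default) or `"category"`: annotation level to
#'   summarize at.
#' @return object of class `CategoryMatrix`: list with `means` (category x
#'   condition matrix) and `n_members` (named member counts).
#' @export
category_summary <- function(values, ann, by = c("subcategory", "category")) {
  by <- match.arg(by)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_input("values must have protein rownames")
  key <- ann[[by]]
  cats <- unique(key)
  means <- matrix(NA_real_, length(cats), ncol(values),
                  dimnames = list(cats, colnames(values)))
  n_members <- setNames(integer(length(cats)), cats)
  for (cat in cats) {
    members <- intersect(unique(ann$protein_id[key == cat]), rownames(values))
    n_members[cat] <- length(members)
    if (length(members))
      means[cat, ] <- colMeans(values[members, , drop = FALSE])
  }
  empty <- n_members == 0L
  if (any(empty)) {
    warning("omitting categories with no annotated proteins in the data: ",
            paste(cats[empty], collapse = ", "), call. = FALSE)
    means <- means[!empty, , drop = FALSE]
    n_members <- n_members[!empty]
  }
  structure(list(means = means, n_members = n_members, by = by),
            class = "CategoryMatrix")
}

#' @export
print.CategoryMatrix <- function(x, ...) {
  cat(sprintf("CategoryMatrix (%s level): %d categories x %d conditions\n",
              x$by, nrow(x$means), ncol(x$means)))
  print(cbind(round(x$means, 3), n = x$n_members))
  invisible(x)
}

#' Fisher's exact category enrichment
#'
#' Tests whether a differential protein set is enriched for members of a
#' functional category, by a two-sided Fisher's exact test on the 2x2
#' cross-classification of the protein universe (differential vs not,
#' in-category vs not). The odds ratio is the sample odds ratio `ad/bc`,
#' with 0.5 added to every cell when any cell is zero (reported alongside
#' the p-value, not used in it).
#'
#' @param differential_set,category_members character vectors of protein
#'   ids; both must be subsets of `universe`.
#' @param universe character vector of all tested proteins.
#' @return list with `table` (2x2), `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(differential_set, category_members, universe) {
  universe <- unique(as.character(universe))
  differential_set <- unique(as.character(differential_set))
  category_members <- unique(as.character(category_members))
  if (length(setdiff(differential_set, universe)))
    stop_input("differential_set contains proteins outside the universe")
  if (length(setdiff(category_members, universe)))
    stop_input("category_members contains proteins outside the universe")
  a <- length(intersect(differential_set, category_members))
  b <- length(differential_set) - a
  c_ <- length(category_members) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(category = c("in", "out"),
                                differential = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(table = tab, odds_ratio = or, p_value = min(p, 1))
}

#' Enrichment of every annotated category in a differential set
#'
#' Convenience wrapper applying [fisher_enrichment()] to each category (or
#' subcategory) of an annotation map.
#'
#' @inheritParams fisher_enrichment
#' @inheritParams category_summary
#' @return data.frame with one row per category: member counts, overlap,
#'   odds ratio and two-sided p-value.
#' @export
category_enrichment <- function(differential_set, ann, universe,
                                by = c("subcategory", "category")) {
  by <- match.arg(by)
  key <- ann[[by]]
  cats <- unique(key)
  rows <- lapply(cats, function(cat) {
    members <- intersect(unique(ann$protein_id[key == cat]), universe)
    fe <- fisher_enrichment(differential_set, members, universe)
    data.frame(category = cat, n_members = length(members),
               n_overlap = fe$table["in", "yes"],
               odds_ratio = fe$odds_ratio, p_value = fe$p_value)
  })
  do.call(rbind, rows)
}

#' Matrix used for category heat maps
#'
#' Returns the plotting matrix, optionally row-scaled: `row_z` centers each
#' category row and divides by its sample standard deviation (constant rows
#' map to zeros rather than NaN). Optionally renders a heat map to file via
#' pheatmap as a side effect.
#'
#' @param cm `CategoryMatrix`.
#' @param scale `"none"` or `"row_z"`.
#' @param file optional output image path (requires the pheatmap package).
#' @return the (possibly scaled) numeric matrix.
#' @export
heatmap_matrix <- function(cm, scale = c("none", "row_z"), file = NULL) {
  scale <- match.arg(scale)
  if (!inherits(cm, "CategoryMatrix")) stop_input("expected a CategoryMatrix")
  m <- cm$means
  if (scale == "row_z") {
    m <- t(apply(m, 1, function(r) {
      s <- stats::sd(r)
      if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    dimnames(m) <- dimnames(cm$means)
  }
  if (!is.null(file)) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop_input("rendering requires the pheatmap package")
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE)
  }
  m
}
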