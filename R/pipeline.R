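#' Two-sample two-tailed t-test
#'
#' Unpaired two-tailed t-test: `variant = "student"` (default) pools the
#' variances, `"welch"` uses the Satterthwaite approximation. Degenerate
#' zero-variance inputs are handled explicitly: equal means give `t = 0`,
#' `p = 1`; unequal means with zero pooled variance report the `p -> 0`
#' limit with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop_input("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    warning("zero variance in both groups with unequal means; p reported ",
            "as the 0 limit", call. = FALSE)
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Significance stars at conventional thresholds
#'
#' @param p p-value(s).
#' @return `""`, `"*"`, `"**"`, `"***"` or `"****"` at 0.05 / 0.01 / 0.001 /
#'   0.0001.
#' @export
significance_stars <- function(p) {
  cut_pts <- c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1)
  labs <- c("****", "***", "**", "*", "")
  labs[cut(p, cut_pts, labels = FALSE, include.lowest = TRUE)]
}

default_stages <- c("simulate", "quantify", "differential", "annotate",
                    "coloc", "ci")

#' Pipeline configuration
#'
#' Assembles a validated configuration for [run_pipeline()]. Stage-specific
#' parameter lists are merged over defaults; later stages consume the
#' outputs of earlier ones, and disabling `simulate` requires file inputs
#' for the stages that remain enabled.
#'
#' @param seed global integer seed; per-stage generator seeds are derived
#'   from it.
#' @param stages character vector of enabled stages, a subset of
#'   `simulate`, `quantify`, `differential`, `annotate`, `coloc`, `ci`
#'   (executed in that fixed order).
#' @param counts arguments for [synth_count_config()] (category planting is
#'   on by default so the annotate stage has labels to work with).
#' @param image arguments for [generate_two_channel_image()].
#' @param dose list with elements `truth` (arguments for
#'   [dose_response_truth()]), `doses`, `replicates`, `noise_sd`.
#' @param flow arguments for [generate_flow_events()].
#' @param thresholds analysis thresholds: `min_detect`, `min_replicates`
#'   (detection), `log2_threshold`, `pairing`, `strict` (differential),
#'   `coloc_threshold`, `min_area` (puncta), `fa_levels`, `ci_form`
#'   (combination index), `gate` (event gate intensity).
#' @param inputs file inputs used when `simulate` is disabled: `counts_path`
#'   + `samples_path`, `annotation_path`, `ref_tiff` + `partner_tiff`,
#'   `dose_path` + `ratio`, `events_path`.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1, stages = default_stages,
                            counts = list(), image = list(), dose = list(),
                            flow = list(), thresholds = list(),
                            inputs = list()) {
  bad <- setdiff(stages, default_stages)
  if (length(bad)) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  counts <- utils::modifyList(list(plant_categories = TRUE), counts)
  image <- utils::modifyList(list(n_spots = 20, overlap_fraction = 0.5),
                             image)
  dose <- utils::modifyList(list(truth = list(), doses = c(2.5, 5, 10, 20, 40),
                                 replicates = 3, noise_sd = 0.02), dose)
  flow <- utils::modifyList(list(n_events = 10000, positive_fraction = 0.3),
                            flow)
  thresholds <- utils::modifyList(
    list(min_detect = 1, min_replicates = NULL, log2_threshold = 1,
         pairing = "by_index", strict = TRUE, coloc_threshold = "otsu",
         min_area = 4, fa_levels = 0.5, ci_form = "exclusive",
         gate = 10^2.5),
    thresholds)
  if (!"simulate" %in% stages) {
    need <- character(0)
    if ("quantify" %in% stages &&
        (is.null(inputs$counts_path) || is.null(inputs$samples_path)))
      need <- c(need, "counts_path + samples_path")
    if ("coloc" %in% stages &&
        (is.null(inputs$ref_tiff) || is.null(inputs$partner_tiff)))
      need <- c(need, "ref_tiff + partner_tiff")
    if ("ci" %in% stages && is.null(inputs$dose_path))
      need <- c(need, "dose_path")
    if (length(need))
      stop_input("simulate disabled but file inputs missing: ",
                 paste(need, collapse = "; "))
    for (p in unlist(inputs[c("counts_path", "samples_path", "ref_tiff",
                              "partner_tiff", "dose_path", "events_path",
                              "annotation_path")]))
      if (!file.exists(p)) stop_input("input path does not exist: ", p)
  }
  structure(list(seed = as.integer(seed),
                 stages = intersect(default_stages, stages),
                 counts = counts, image = image, dose = dose, flow = flow,
                 thresholds = thresholds, inputs = inputs),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path YAML configuration file mirroring the arguments of
#'   `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in the fixed order simulate -> quantify ->
#' differential -> annotate -> coloc -> ci, writes each stage's tables under
#' `out_dir`, and returns (and writes) a single JSON run report capturing
#' the configuration echo, seed, package version and per-stage summaries.
#' Identical configuration + seed yields a byte-identical report; the
#' output directory itself is not echoed so reports from different
#' directories compare equal.
#'
#' @param config `PipelineConfig`.
#' @param out_dir output directory (created if missing).
#' @return the run-report list, invisibly; written as
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("proteaphagy_run_")) {
  if (!inherits(config, "PipelineConfig"))
    stop_input("config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  report <- list(package = "proteaphagy",
                 version = as.character(utils::packageVersion("proteaphagy")),
                 seed = config$seed,
                 config = config[c("stages", "counts", "image", "dose",
                                   "flow", "thresholds")],
                 stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("stage '", name, "' failed: ", conditionMessage(e)))
  }

  sim <- NULL; ann <- NULL; truth <- NULL
  counts_raw <- NULL; normalized <- NULL; subtracted <- NULL; diff_res <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      cfg <- do.call(synth_count_config,
                     utils::modifyList(config$counts,
                                       list(seed = config$seed)))
      sim <- generate_tube_counts(cfg)
      counts_raw <- sim$counts; truth <- sim$truth
      write_psm_counts(sim$psm, counts_raw$samples,
                       file.path(out_dir, "psm_counts.tsv"),
                       file.path(out_dir, "samples.tsv"))
      utils::write.table(truth, file.path(out_dir, "count_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$simulate <- list(
        n_proteins = cfg$n_proteins, n_replicates = cfg$n_replicates,
        n_planted_up = sum(truth$direction == "up"),
        n_planted_down = sum(truth$direction == "down"))
    })
  } else if (!is.null(config$inputs$counts_path)) {
    io <- read_psm_counts(config$inputs$counts_path,
                          config$inputs$samples_path)
    counts_raw <- aggregate_psm_counts(io$psm, io$samples)
  }

  if ("quantify" %in% config$stages) {
    run_stage("quantify", {
      subtracted <- subtract_background(counts_raw)
      normalized <- quantile_normalize(log2_with_floor(subtracted))
      detect <- call_detected_proteins(subtracted, thr$min_detect,
                                       thr$min_replicates)
      write_count_matrix(normalized,
                         file.path(out_dir, "normalized_matrix.tsv"))
      report$stages$quantify <- list(
        n_proteins = nrow(normalized$values),
        n_detected = as.list(attr(detect, "n_detected")))
    })
  }

  if ("differential" %in% config$stages) {
    run_stage("differential", {
      fc <- replicate_fold_changes(normalized, thr$pairing)
      diff_res <- reproducible_differential(fc, thr$log2_threshold,
                                            thr$strict)
      utils::write.table(as.data.frame(diff_res),
                         file.path(out_dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- attr(diff_res, "summary")
      summ <- s[c("n_enriched", "n_reduced", "n_total_differential")]
      if (!is.null(truth)) {
        rec <- recovery_report(diff_res, truth)
        summ$recovery <- rec[c("sensitivity", "specificity", "fdp")]
      }
      report$stages$differential <- summ
    })
  }

  if ("annotate" %in% config$stages) {
    run_stage("annotate", {
      ann <- if (!is.null(config$inputs$annotation_path))
        read_annotation(config$inputs$annotation_path)
      else truth_annotation(truth)
      cond_means <- sapply(c("A", "B"), function(cond)
        rowMeans(normalized$values[, normalized$samples$condition == cond,
                                   drop = FALSE]))
      cm <- category_summary(cond_means, ann)
      diff_col <- cm$means[, "B"] - cm$means[, "A"]
      enr <- category_enrichment(
        diff_res$protein_id[diff_res$status != "not_differential"],
        ann, diff_res$protein_id)
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(category = rownames(cm$means), cm$means,
                   difference = diff_col, n = cm$n_members),
        file.path(out_dir, "category_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$annotate <- list(
        categories = rownames(cm$means),
        mean_A = unname(cm$means[, "A"]), mean_B = unname(cm$means[, "B"]),
        difference = unname(diff_col),
        enrichment_p = stats::setNames(enr$p_value, enr$category))
    })
  }

  if ("coloc" %in% config$stages) {
    run_stage("coloc", {
      if ("simulate" %in% config$stages) {
        img_args <- utils::modifyList(config$image,
                                      list(seed = config$seed + 1L))
        gen <- do.call(generate_two_channel_image, img_args)
        img <- gen$image
        write_two_channel_tiff(img, file.path(out_dir, "channel_ref.tiff"),
                               file.path(out_dir, "channel_partner.tiff"))
        planted <- gen$truth$overlap_fraction
      } else {
        img <- read_two_channel_tiff(config$inputs$ref_tiff,
                                     config$inputs$partner_tiff)
        planted <- NULL
      }
      rois <- detect_puncta(img$ref, thr$coloc_threshold, thr$min_area)
      mres <- manders(img, rois, thr$coloc_threshold, thr$coloc_threshold)
      utils::write.csv(mres$per_roi, file.path(out_dir, "manders_per_roi.csv"),
                       row.names = FALSE)
      report$stages$coloc <- list(n_puncta = length(rois$ids),
                                   M1 = mres$M1, M2 = mres$M2,
                                   planted_overlap = planted)
    })
  }

  if ("ci" %in% config$stages) {
    run_stage("ci", {
      if ("simulate" %in% config$stages) {
        dtruth <- do.call(dose_response_truth, config$dose$truth)
        dr <- generate_dose_response(dtruth, config$dose$doses,
                                     config$dose$replicates,
                                     config$dose$noise_sd,
                                     seed = config$seed + 2L)
        write_dose_response(dr, file.path(out_dir, "dose_response.csv"))
        events <- generate_flow_events(
          n_events = config$flow$n_events,
          positive_fraction = config$flow$positive_fraction,
          seed = config$seed + 3L)
        write_events(events, file.path(out_dir, "flow_events.csv"))
        gated <- gate_apoptosis(events, thr$gate)
      } else {
        dr <- read_dose_response(config$inputs$dose_path,
                                 config$inputs$ratio)
        gated <- if (!is.null(config$inputs$events_path))
          gate_apoptosis(read_events(config$inputs$events_path), thr$gate)
      }
      cires <- ci_analysis(dr, fa_levels = thr$fa_levels,
                           form = thr$ci_form)
      report$stages$ci <- list(
        fa_levels = cires$fa_levels, ci_mean = unname(cires$mean),
        ci_sd = unname(cires$sd),
        cooperative = unname(cires$cooperative),
        apoptosis_fraction = if (!is.null(gated)) gated$fraction)
    })
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Validate a run report against the shipped schema
#'
#' Structural validation of a pipeline run report: the required top-level
#' fields of the schema at
#' `system.file("schema", "run-report-schema.json", package = "proteaphagy")`
#' must be present with the declared types.
#'
#' @param report run-report list (from [run_pipeline()]) or path to a
#'   `report.json` file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema",
                                            "run-report-schema.json",
                                            package = "proteaphagy"))
  for (field in unlist(schema$required))
    if (is.null(report[[field]]))
      stop_input("report is missing required field '", field, "'")
  for (field in names(schema$properties)) {
    want <- schema$properties[[field]]$type
    val <- report[[field]]
    if (is.null(val)) next
    ok <- switch(want,
                 string = is.character(val) && length(val) == 1L,
                 integer = is.numeric(val) && length(val) == 1L,
                 object = is.list(val),
                 TRUE)
    if (!ok)
      stop_input("report field '", field, "' is not of type ", want)
  }
  invisible(TRUE)
}
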