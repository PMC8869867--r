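#' Configuration for synthetic TUBE pull-down count data
#'
#' Describes a two-cell-line, replicated TUBE pull-down experiment with
#' matched GST resin controls: `n_proteins` proteins quantified in
#' `n_replicates` replicates of a parental condition A and a resistant
#' condition B, with fractions `frac_up` / `frac_down` of proteins planted
#' at `+/- planted_log2fc` in B. Per-protein abundances are log-normal with
#' median `baseline_mean` and log-scale spread `baseline_sdlog` (pull-down
#' depth spans orders of magnitude across proteins); given its abundance, a
#' protein's counts are negative-binomial (gamma-Poisson) with
#' overdispersion `dispersion` (variance = mean + dispersion * mean^2, the
#' Poisson limit as dispersion -> 0; within-protein count
#' CV^2 = 1/mean + dispersion).
#' Nonspecific resin background with mean `background_mean` is added to
#' every pull-down and measured alone in the GST control samples.
#'
#' Defaults model a mid-depth spectral-counting experiment: 1000 proteins,
#' three replicates, 5% planted up and 5% down at four-fold
#' (`planted_log2fc = 2`), median depth 100 counts with overdispersion 0.03
#' (count CV about 0.2 at that depth) and a background of 5 nonspecific
#' counts.
#'
#' @param n_proteins,n_replicates positive integers.
#' @param frac_up,frac_down fractions in \[0,1\] with sum <= 1.
#' @param planted_log2fc planted absolute log2 fold change (> 0).
#' @param baseline_mean median specific counts across proteins (> 0).
#' @param baseline_sdlog log-scale SD of the per-protein abundance
#'   distribution (>= 0; 0 = every protein at `baseline_mean`).
#' @param dispersion negative-binomial overdispersion (> 0); larger =
#'   noisier, Poisson in the limit 0.
#' @param background_mean expected nonspecific (GST) counts (>= 0).
#' @param peptides_per_protein peptides a protein's counts are split over in
#'   the PSM-level table.
#' @param plant_categories if `TRUE`, planted proteins carry functional
#'   category labels (up = ALS autophagy stages, down = UPS proteasome
#'   subcomplexes) in the ground truth.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class `SynthCountConfig`.
#' @export
synth_count_config <- function(n_proteins = 1000, n_replicates = 3,
                               frac_up = 0.05, frac_down = 0.05,
                               planted_log2fc = 2, baseline_mean = 100,
                               baseline_sdlog = 1, dispersion = 0.03,
                               background_mean = 5,
                               peptides_per_protein = 3,
                               plant_categories = FALSE, seed = 1) {
  assert_scalar_number(n_proteins, "n_proteins", positive = TRUE)
  assert_scalar_number(n_replicates, "n_replicates", positive = TRUE)
  assert_scalar_number(frac_up, "frac_up", nonnegative = TRUE)
  assert_scalar_number(frac_down, "frac_down", nonnegative = TRUE)
  if (frac_up > 1 || frac_down > 1 || frac_up + frac_down > 1)
    stop_input("frac_up + frac_down must lie in [0,1]")
  assert_scalar_number(planted_log2fc, "planted_log2fc", positive = TRUE)
  assert_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  assert_scalar_number(baseline_sdlog, "baseline_sdlog", nonnegative = TRUE)
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  assert_scalar_number(background_mean, "background_mean", nonnegative = TRUE)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 frac_up = frac_up, frac_down = frac_down,
                 planted_log2fc = planted_log2fc,
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 background_mean = background_mean,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 plant_categories = plant_categories,
                 seed = as.integer(seed)),
            class = "SynthCountConfig")
}

# UPS/ALS category scheme used when planting functional categories
ups_als_scheme <- function() {
  list(UPS = c("20S alpha", "20S beta", "19S base", "19S lid"),
       ALS = c("early signaling", "autophagosome formation",
               "lysosome fusion"))
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (length(mu) == 1L && mu == 0) rep(0L, n)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic TUBE pull-down count matrix with ground truth
#'
#' Draws specific counts for each protein from a negative-binomial
#' distribution around the condition mean (baseline, shifted by
#' `+/- planted_log2fc` in condition B for regulated proteins), adds
#' negative-binomial resin background to every pull-down sample, and fills
#' the GST control samples with background counts only. Planted set sizes
#' are `round(frac * n)` with halves rounded away from zero.
#'
#' @param config `SynthCountConfig`.
#' @return list with `counts` (a `SpectralCountMatrix` at stage `"raw"`),
#'   `psm` (the matching peptide-level long table; peptide splits sum back
#'   to the protein counts exactly), and `truth` (a `CountGroundTruth`
#'   data.frame: `protein_id`, `direction`, `true_log2fc`, `category`,
#'   `subcategory`).
#' @export
generate_tube_counts <- function(config) {
  if (!inherits(config, "SynthCountConfig"))
    stop_input("config must come from synth_count_config()")
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    n_up <- round_half_up(config$frac_up * n)
    n_down <- round_half_up(config$frac_down * n)
    direction <- rep("null", n)
    if (n_up) direction[seq_len(n_up)] <- "up"
    if (n_down) direction[n_up + seq_len(n_down)] <- "down"
    true_lfc <- ifelse(direction == "up", config$planted_log2fc,
                       ifelse(direction == "down", -config$planted_log2fc, 0))
    protein_id <- sprintf("P%04d", seq_len(n))

    scheme <- ups_als_scheme()
    category <- rep(NA_character_, n); subcategory <- rep(NA_character_, n)
    if (isTRUE(config$plant_categories)) {
      if (n_up) {
        category[direction == "up"] <- "ALS"
        subcategory[direction == "up"] <-
          rep_len(scheme$ALS, n_up)
      }
      if (n_down) {
        category[direction == "down"] <- "UPS"
        subcategory[direction == "down"] <-
          rep_len(scheme$UPS, n_down)
      }
    }

    reps <- seq_len(config$n_replicates)
    samples <- data.frame(
      sample_id = c(sprintf("A_%d", reps), sprintf("B_%d", reps),
                    sprintf("GST_%d", reps)),
      condition = rep(c("A", "B", "control"), each = config$n_replicates),
      replicate = rep(reps, 3))

    abundance <- config$baseline_mean *
      exp(stats::rnorm(n, 0, config$baseline_sdlog))
    mu_a <- abundance
    mu_b <- abundance * 2^true_lfc
    vals <- matrix(0L, n, nrow(samples),
                   dimnames = list(protein_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      cond <- samples$condition[j]
      specific <- switch(cond,
        A = rnbinom_disp(n, mu_a, config$dispersion),
        B = rnbinom_disp(n, mu_b, config$dispersion),
        control = rep(0L, n))
      background <- rnbinom_disp(n, config$background_mean,
                                 config$dispersion)
      vals[, j] <- specific + background
    }

    # split protein counts over peptides so the PSM table aggregates back
    k <- max(1L, config$peptides_per_protein)
    psm <- do.call(rbind, lapply(seq_len(nrow(samples)), function(j) {
      counts <- vals[, j]
      split <- vapply(counts, function(ct) {
        if (ct == 0) rep(0L, k)
        else as.integer(stats::rmultinom(1, ct, rep(1 / k, k)))
      }, integer(k))
      data.frame(protein_id = rep(protein_id, each = k),
                 peptide_id = paste0(rep(protein_id, each = k), "_pep",
                                     seq_len(k)),
                 sample_id = samples$sample_id[j],
                 spectral_count = as.integer(split))
    }))
    psm <- psm[psm$spectral_count > 0, , drop = FALSE]
    rownames(psm) <- NULL

    truth <- data.frame(protein_id = protein_id, direction = direction,
                        true_log2fc = true_lfc, category = category,
                        subcategory = subcategory)
    class(truth) <- c("CountGroundTruth", "data.frame")
    list(counts = spectral_count_matrix(vals, samples, stage = "raw"),
         psm = psm, truth = truth)
  })
}

#' Annotation map from planted ground truth
#'
#' Builds an [as_annotation()] map from the category labels planted by
#' [generate_tube_counts()] (requires `plant_categories = TRUE`).
#'
#' @param truth `CountGroundTruth` data.frame.
#' @return `AnnotationMap`.
#' @export
truth_annotation <- function(truth) {
  ann <- truth[!is.na(truth$category),
               c("protein_id", "category", "subcategory")]
  if (!nrow(ann))
    stop_input("ground truth carries no category labels; generate with ",
               "plant_categories = TRUE")
  as_annotation(ann)
}

render_spot <- function(img, x, y, amplitude, sigma) {
  w <- ceiling(4 * sigma)
  rows <- max(1, round(y) - w):min(nrow(img), round(y) + w)
  cols <- max(1, round(x) - w):min(ncol(img), round(x) + w)
  dy <- outer(rows - y, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - x)
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  img
}

#' Generate a synthetic two-channel puncta image with ground truth
#'
#' Renders Gaussian puncta on a noisy background in two registered channels,
#' emulating a confocal plane with an autophagy marker (reference) and a
#' proteasome subunit (partner). `round(overlap_fraction * n_spots)` spot
#' centers appear in both channels; the remaining spots are placed once in
#' the reference only and once in the partner only, so each channel carries
#' `n_spots` puncta. Centers are drawn by rejection sampling with a minimum
#' pairwise separation so puncta stay resolvable.
#'
#' @param n_spots puncta per channel.
#' @param overlap_fraction fraction of shared spot centers, in \[0,1\].
#' @param spot_sigma Gaussian spot width in pixels.
#' @param amplitude peak spot intensity above background (both channels).
#' @param background background intensity level.
#' @param noise_sd Gaussian noise SD.
#' @param size image size, `c(rows, cols)`.
#' @param min_separation minimum distance between distinct spot centers in
#'   pixels (default `6 * spot_sigma`).
#' @param seed integer seed.
#' @return list with `image` (a `TwoChannelImage`) and `truth` (list:
#'   `centers` data.frame with `x`, `y`, `in_ref`, `in_partner`;
#'   `overlap_fraction` = shared spots / reference spots; `amplitude`,
#'   `spot_sigma`, `background`, `noise_sd`).
#' @export
generate_two_channel_image <- function(n_spots, overlap_fraction,
                                       spot_sigma = 2, amplitude = 1,
                                       background = 0.1, noise_sd = 0.02,
                                       size = c(256, 256),
                                       min_separation = 6 * spot_sigma,
                                       seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_input("overlap_fraction must lie in [0,1]")
  assert_scalar_number(n_spots, "n_spots", positive = TRUE)
  withr::with_seed(seed, {
    n_shared <- round_half_up(overlap_fraction * n_spots)
    n_only <- n_spots - n_shared
    n_centers <- n_shared + 2 * n_only
    margin <- ceiling(4 * spot_sigma) + 1
    if (size[1] - 2 * margin < 1 || size[2] - 2 * margin < 1)
      stop_input("spots do not fit inside the image")
    centers <- matrix(NA_real_, n_centers, 2)
    placed <- 0L; misses <- 0L
    while (placed < n_centers) {
      # a long run of rejections means the image is effectively saturated
      if (misses > 5000L)
        stop_input("placement capacity exceeded: cannot place ", n_centers,
                   " spots at separation ", min_separation, " in a ",
                   size[1], "x", size[2], " image")
      cand <- c(stats::runif(1, margin, size[2] - margin),
                stats::runif(1, margin, size[1] - margin))
      if (placed == 0L ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2))) >= min_separation) {
        placed <- placed + 1L
        centers[placed, ] <- cand
        misses <- 0L
      } else {
        misses <- misses + 1L
      }
    }
    in_ref <- c(rep(TRUE, n_shared), rep(TRUE, n_only), rep(FALSE, n_only))
    in_partner <- c(rep(TRUE, n_shared), rep(FALSE, n_only), rep(TRUE, n_only))
    ref <- matrix(background, size[1], size[2])
    partner <- matrix(background, size[1], size[2])
    for (i in seq_len(n_centers)) {
      if (in_ref[i])
        ref <- render_spot(ref, centers[i, 1], centers[i, 2], amplitude,
                           spot_sigma)
      if (in_partner[i])
        partner <- render_spot(partner, centers[i, 1], centers[i, 2],
                               amplitude, spot_sigma)
    }
    ref <- pmax(ref + matrix(stats::rnorm(length(ref), 0, noise_sd),
                             size[1]), 0)
    partner <- pmax(partner + matrix(stats::rnorm(length(partner), 0,
                                                  noise_sd), size[1]), 0)
    truth <- list(centers = data.frame(x = centers[, 1], y = centers[, 2],
                                       in_ref = in_ref,
                                       in_partner = in_partner),
                  overlap_fraction = n_shared / n_spots,
                  n_spots = n_spots, amplitude = amplitude,
                  spot_sigma = spot_sigma, background = background,
                  noise_sd = noise_sd)
    list(image = two_channel_image(ref, partner), truth = truth)
  })
}

#' Ground-truth parameters for a synthetic drug-combination experiment
#'
#' Median-effect parameters for two agents plus an interaction parameter
#' `alpha`: the combination series is generated so that the Loewe
#' interaction sum equals `alpha` at every dose, hence `alpha = 1` is
#' exactly additive (downstream CI = 1) and `alpha < 1` synergistic.
#'
#' @param m_a,dm_a,m_b,dm_b sigmoidicity and median-effect dose of agents A
#'   and B (> 0).
#' @param alpha interaction parameter (> 0).
#' @param ratio constant mixing ratio doseA:doseB of the combination.
#' @return object of class `DoseResponseTruth`.
#' @export
dose_response_truth <- function(m_a = 2, dm_a = 10, m_b = 1.5, dm_b = 5,
                                alpha = 1, ratio = 2) {
  for (nm in c("m_a", "dm_a", "m_b", "dm_b", "alpha", "ratio"))
    assert_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(m_a = m_a, dm_a = dm_a, m_b = m_b, dm_b = dm_b,
                 alpha = alpha, ratio = ratio),
            class = "DoseResponseTruth")
}

me_fa <- function(dose, m, dm) {
  x <- (dose / dm)^m
  x / (1 + x)
}

# fraction affected of the constant-ratio combination at total dose d:
# the fa at which the Loewe interaction sum equals alpha
combo_fa <- function(d_total, truth) {
  d_a <- d_total * truth$ratio / (1 + truth$ratio)
  d_b <- d_total / (1 + truth$ratio)
  g <- function(fa) {
    d_a / (truth$dm_a * (fa / (1 - fa))^(1 / truth$m_a)) +
      d_b / (truth$dm_b * (fa / (1 - fa))^(1 / truth$m_b)) - truth$alpha
  }
  stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Generate a constant-ratio dose-response data set
#'
#' Single-agent fraction-affected values follow the median-effect equation
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`; combination rows are generated at the
#' fixed mixing ratio with the effect level solving the Loewe sum
#' `dA/Dx_A(fa) + dB/Dx_B(fa) = alpha`. Gaussian noise is added on the fa
#' scale and values are clipped to \[0.005, 0.995\] (the median-effect
#' linearization is undefined at 0 and 1).
#'
#' @param truth `DoseResponseTruth`.
#' @param doses dose vector for the single agents; combination rows use the
#'   same values as total dose (or supply a list with elements `A`, `B`,
#'   `combo`).
#' @param replicates number of replicates per dose.
#' @param noise_sd Gaussian noise SD on the fa scale.
#' @param seed integer seed.
#' @return data.frame with columns `agent` (`"A"`, `"B"`, `"combo"`),
#'   `dose`, `fa`, `replicate`, with the mixing ratio and truth attached as
#'   attributes `"ratio"` and `"truth"`.
#' @export
generate_dose_response <- function(truth, doses = c(2.5, 5, 10, 20, 40),
                                   replicates = 3, noise_sd = 0.02,
                                   seed = 1) {
  if (!inherits(truth, "DoseResponseTruth"))
    stop_input("truth must come from dose_response_truth()")
  if (!is.list(doses)) doses <- list(A = doses, B = doses, combo = doses)
  if (any(unlist(doses) <= 0)) stop_input("doses must be > 0")
  withr::with_seed(seed, {
    rows <- list()
    for (agent in c("A", "B", "combo")) {
      fa0 <- switch(agent,
        A = me_fa(doses$A, truth$m_a, truth$dm_a),
        B = me_fa(doses$B, truth$m_b, truth$dm_b),
        combo = vapply(doses$combo, combo_fa, numeric(1), truth = truth))
      for (rep in seq_len(replicates)) {
        fa <- fa0 + stats::rnorm(length(fa0), 0, noise_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(agent = agent, dose = doses[[agent]],
                     fa = pmin(pmax(fa, 0.005), 0.995), replicate = rep)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ratio") <- truth$ratio
    attr(out, "truth") <- truth
    out
  })
}

#' Generate synthetic flow-cytometry events
#'
#' One fluorescence intensity per event, drawn from a two-component
#' log-normal mixture of unstained (negative) and stained (positive,
#' apoptotic) populations; the true component label is retained. The default
#' of 10^4 collected events matches common practice.
#'
#' @param n_events number of events (>= 1; default 10000).
#' @param positive_fraction probability an event is from the positive
#'   component, in \[0,1\].
#' @param neg_meanlog,pos_meanlog,sdlog log-normal component parameters;
#'   defaults give well-separated populations around intensities 100 and
#'   1000.
#' @param seed integer seed.
#' @return data.frame with columns `intensity`, `truth_positive`.
#' @export
generate_flow_events <- function(n_events = 10000, positive_fraction = 0.3,
                                 neg_meanlog = log(100),
                                 pos_meanlog = log(1000), sdlog = 0.25,
                                 seed = 1) {
  if (n_events < 1) stop_input("n_events must be >= 1")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop_input("positive_fraction must lie in [0,1]")
  withr::with_seed(seed, {
    pos <- stats::runif(n_events) < positive_fraction
    intensity <- stats::rlnorm(n_events,
                               meanlog = ifelse(pos, pos_meanlog, neg_meanlog),
                               sdlog = sdlog)
    data.frame(intensity = intensity, truth_positive = pos)
  })
}
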