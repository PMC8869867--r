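test_that("count generator honours config, ground truth and determinism", {
  cfg <- synth_count_config(n_proteins = 200, frac_up = 0.05,
                            frac_down = 0.1, seed = 3)
  sim <- generate_tube_counts(cfg)
  expect_equal(sum(sim$truth$direction == "up"), 10L)       # 0.05 * 200
  expect_equal(sum(sim$truth$direction == "down"), 20L)
  expect_equal(unique(sim$truth$true_log2fc[sim$truth$direction == "up"]), 2)
  expect_equal(ncol(sim$counts$values), 9L)                 # 3 + 3 + 3
  expect_equal(sum(sim$counts$samples$condition == "control"), 3L)
  # determinism: same config + seed -> identical output
  sim2 <- generate_tube_counts(cfg)
  expect_identical(sim$counts$values, sim2$counts$values)
  expect_identical(sim$psm, sim2$psm)
  # no planted effects -> empty regulated set
  none <- generate_tube_counts(synth_count_config(n_proteins = 50,
                                                  frac_up = 0, frac_down = 0,
                                                  seed = 1))
  expect_true(all(none$truth$direction == "null"))
  # PSM table aggregates back to the protein counts exactly
  agg <- aggregate_psm_counts(sim$psm, sim$counts$samples)
  expect_equal(agg$values[rownames(sim$counts$values), ],
               sim$counts$values + 0)
  expect_error(synth_count_config(frac_up = 0.7, frac_down = 0.6),
               "frac_up")
})

test_that("with planted categories the summary difference has the right
           signs", {
  cfg <- synth_count_config(n_proteins = 300, frac_up = 0.1, frac_down = 0.1,
                            plant_categories = TRUE, seed = 6)
  sim <- generate_tube_counts(cfg)
  ann <- truth_annotation(sim$truth)
  expect_true(all(ann$category %in% c("UPS", "ALS")))
  norm <- quantile_normalize(log2_with_floor(subtract_background(sim$counts)))
  cond_means <- sapply(c("A", "B"), function(cc)
    rowMeans(norm$values[, norm$samples$condition == cc, drop = FALSE]))
  cm <- category_summary(cond_means, ann, by = "category")
  d <- cm$means[, "B"] - cm$means[, "A"]
  expect_gt(d["ALS"], 0)
  expect_lt(d["UPS"], 0)
  expect_error(truth_annotation(generate_tube_counts(
    synth_count_config(n_proteins = 20, seed = 1))$truth), "plant_categories")
})

test_that("image generator plants the requested overlap structure", {
  gen <- generate_two_channel_image(n_spots = 20, overlap_fraction = 0.5,
                                    seed = 2)
  tru <- gen$truth$centers
  expect_equal(sum(tru$in_ref & tru$in_partner), 10L)
  expect_equal(sum(tru$in_ref), 20L)
  expect_equal(sum(tru$in_partner), 20L)
  expect_equal(gen$truth$overlap_fraction, 0.5)
  # extremes: all shared / disjoint channels
  all_in <- generate_two_channel_image(10, 1, seed = 1)$truth$centers
  expect_true(all(all_in$in_ref & all_in$in_partner))
  disj <- generate_two_channel_image(10, 0, seed = 1)$truth$centers
  expect_equal(sum(disj$in_ref & disj$in_partner), 0L)
  # determinism and separation
  g2 <- generate_two_channel_image(20, 0.5, seed = 2)
  expect_identical(g2$image$ref, gen$image$ref)
  dmat <- as.matrix(dist(tru[, c("x", "y")]))
  expect_gte(min(dmat[upper.tri(dmat)]), 12)  # 6 * spot_sigma
  expect_error(generate_two_channel_image(4000, 0, size = c(64, 64),
                                          seed = 1), "capacity")
})

test_that("dose-response generator follows the median-effect model", {
  tr <- dose_response_truth(m_a = 2, dm_a = 10, m_b = 2, dm_b = 10,
                            alpha = 1, ratio = 1)
  dr <- generate_dose_response(tr, doses = c(5, 10, 20), replicates = 1,
                               noise_sd = 0, seed = 1)
  expect_equal(dr$fa[dr$agent == "A" & dr$dose == 10], 0.5)  # D = Dm
  expect_equal(dr$fa[dr$agent == "A" & dr$dose == 20], 4 / 5)
  # an agent combined with itself at alpha 1: combo curve equals the agent
  expect_equal(dr$fa[dr$agent == "combo"], dr$fa[dr$agent == "A"],
               tolerance = 1e-9)
  expect_true(all(dr$fa > 0 & dr$fa < 1))
  # different seeds change fa but not the attached truth
  n1 <- generate_dose_response(tr, replicates = 1, noise_sd = 0.05, seed = 1)
  n2 <- generate_dose_response(tr, replicates = 1, noise_sd = 0.05, seed = 2)
  expect_false(isTRUE(all.equal(n1$fa, n2$fa)))
  expect_identical(attr(n1, "truth"), attr(n2, "truth"))
})

test_that("flow-event generator plants the positive fraction", {
  ev <- generate_flow_events(n_events = 500, positive_fraction = 1, seed = 1)
  expect_true(all(ev$truth_positive))
  ev0 <- generate_flow_events(n_events = 500, positive_fraction = 0, seed = 1)
  expect_false(any(ev0$truth_positive))
  expect_equal(nrow(generate_flow_events(seed = 2)), 10000L)
  expect_error(generate_flow_events(n_events = 0, positive_fraction = 0.5),
               ">= 1")
})

test_that("tables and images survive a round trip through disk", {
  tmp <- withr::local_tempdir()
  sim <- generate_tube_counts(synth_count_config(n_proteins = 30, seed = 1))
  write_psm_counts(sim$psm, sim$counts$samples,
                   file.path(tmp, "c.tsv"), file.path(tmp, "s.tsv"))
  back <- read_psm_counts(file.path(tmp, "c.tsv"), file.path(tmp, "s.tsv"))
  agg <- aggregate_psm_counts(back$psm, back$samples)
  expect_equal(agg$values[rownames(sim$counts$values), ],
               sim$counts$values + 0)
  gen <- generate_two_channel_image(5, 0.6, size = c(64, 64), seed = 1)
  write_two_channel_tiff(gen$image, file.path(tmp, "r.tiff"),
                         file.path(tmp, "p.tiff"))
  img <- read_two_channel_tiff(file.path(tmp, "r.tiff"),
                               file.path(tmp, "p.tiff"))
  # 16-bit quantization after rescaling to [0,1]
  scale <- max(gen$image$ref, gen$image$partner, 1)
  expect_equal(img$ref, gen$image$ref / scale, tolerance = 1e-4)
  dr <- generate_dose_response(dose_response_truth(), seed = 1)
  write_dose_response(dr, file.path(tmp, "d.csv"))
  dr2 <- read_dose_response(file.path(tmp, "d.csv"), ratio = 2)
  expect_equal(dr2$fa, dr$fa, tolerance = 1e-12)
  expect_equal(attr(dr2, "ratio"), 2)
})
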