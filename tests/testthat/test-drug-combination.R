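test_that("event gating recovers the planted positive fraction", {
  ev <- generate_flow_events(n_events = 10000, positive_fraction = 0.3,
                             seed = 4)
  g <- gate_apoptosis(ev, gate_threshold = 10^2.5)
  expect_equal(g$n, 10000L)
  # within 3 binomial SDs of 0.30
  expect_lt(abs(g$fraction - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # gate agrees with ground-truth labels for well-separated components
  expect_equal(g$n_positive, sum(ev$truth_positive), tolerance = 0.01)
  expect_equal(gate_apoptosis(ev, max(ev$intensity) + 1)$fraction, 0)
  expect_equal(gate_apoptosis(ev, 0)$fraction, 1)
  expect_error(gate_apoptosis(data.frame(), 1), "non-empty")
})

test_that("median-effect fit is exact on noise-free model data", {
  tr <- dose_response_truth(m_a = 2, dm_a = 10, m_b = 1.5, dm_b = 5,
                            alpha = 1, ratio = 2)
  dr <- generate_dose_response(tr, doses = c(2.5, 5, 10, 20, 40),
                               replicates = 1, noise_sd = 0, seed = 1)
  fa <- fit_median_effect(dr, "A")
  expect_equal(fa$m, 2, tolerance = 1e-9)
  expect_equal(fa$Dm, 10, tolerance = 1e-9)
  expect_equal(fa$r, 1, tolerance = 1e-9)
  expect_equal(ic50(fa), fa$Dm)
  fb <- fit_median_effect(dr, "B")
  expect_equal(c(fb$m, fb$Dm), c(1.5, 5), tolerance = 1e-9)
  # fa = 0.5 at D = Dm by the median-effect definition
  expect_equal(dr$fa[dr$agent == "A" & dr$dose == 10], 0.5)
  # out-of-range fa rows are rejected with a warning
  bad <- rbind(dr, data.frame(agent = "A", dose = 80, fa = 1, replicate = 1))
  expect_warning(fit_median_effect(bad, "A"), "outside")
  expect_error(fit_median_effect(dr[dr$dose == 10, ], "A"), "2 distinct")
})

test_that("fit recovers parameters within 10% under measurement noise", {
  tr <- dose_response_truth(m_a = 2, dm_a = 10)
  for (s in 1:20) {
    dr <- generate_dose_response(tr, replicates = 4, noise_sd = 0.02,
                                 seed = s)
    f <- fit_median_effect(dr, "A")
    expect_lt(abs(f$m - 2) / 2, 0.1)
    expect_lt(abs(f$Dm - 10) / 10, 0.1)
  }
})

test_that("an agent combined with itself is exactly additive", {
  set.seed(31)
  for (i in 1:10) {
    m <- runif(1, 0.5, 4); dm <- 10^runif(1, -1, 2)
    tr <- dose_response_truth(m_a = m, dm_a = dm, m_b = m, dm_b = dm,
                              alpha = 1, ratio = 1)
    dr <- generate_dose_response(tr, doses = dm * c(0.25, 0.5, 1, 2, 4),
                                 replicates = 1, noise_sd = 0, seed = i)
    ci <- combination_index(fit_median_effect(dr, "A"),
                            fit_median_effect(dr, "B"),
                            fit_median_effect(dr, "combo"),
                            ratio = 1, fa_levels = c(0.25, 0.5, 0.75))
    expect_equal(unname(ci), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("planted synergy and antagonism move CI the right way", {
  doses <- c(2.5, 5, 10, 20, 40)
  ci_at <- function(alpha) {
    tr <- dose_response_truth(m_a = 2, dm_a = 10, m_b = 1.5, dm_b = 5,
                              alpha = alpha, ratio = 2)
    dr <- generate_dose_response(tr, doses, replicates = 1, noise_sd = 0,
                                 seed = 1)
    unname(combination_index(fit_median_effect(dr, "A"),
                             fit_median_effect(dr, "B"),
                             fit_median_effect(dr, "combo"),
                             ratio = 2, fa_levels = 0.5))
  }
  expect_equal(ci_at(1), 1, tolerance = 0.02)
  expect_lt(ci_at(0.5), 1)
  expect_gt(ci_at(1.5), 1)
  # decreasing alpha strictly decreases CI
  cis <- vapply(c(1, 0.8, 0.6, 0.4), ci_at, numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("CI is invariant to dose-unit changes", {
  tr <- dose_response_truth(m_a = 2, dm_a = 10, m_b = 1.5, dm_b = 5,
                            alpha = 0.7, ratio = 2)
  dr <- generate_dose_response(tr, replicates = 1, noise_sd = 0, seed = 3)
  base_ci <- combination_index(fit_median_effect(dr, "A"),
                               fit_median_effect(dr, "B"),
                               fit_median_effect(dr, "combo"),
                               ratio = 2, fa_levels = c(0.3, 0.5, 0.7))
  # all series re-expressed in a 1000x smaller unit
  dr2 <- transform(dr, dose = dose * 1000)
  ci2 <- combination_index(fit_median_effect(dr2, "A"),
                           fit_median_effect(dr2, "B"),
                           fit_median_effect(dr2, "combo"),
                           ratio = 2, fa_levels = c(0.3, 0.5, 0.7))
  expect_equal(ci2, base_ci, tolerance = 1e-9)
  # agent A alone re-expressed: ratio and combo total rescale accordingly
  s <- 1000; r <- 2
  dr3 <- dr
  dr3$dose[dr3$agent == "A"] <- dr3$dose[dr3$agent == "A"] * s
  dr3$dose[dr3$agent == "combo"] <-
    dr3$dose[dr3$agent == "combo"] * (s * r + 1) / (r + 1)
  ci3 <- combination_index(fit_median_effect(dr3, "A"),
                           fit_median_effect(dr3, "B"),
                           fit_median_effect(dr3, "combo"),
                           ratio = s * r, fa_levels = c(0.3, 0.5, 0.7))
  expect_equal(ci3, base_ci, tolerance = 1e-9)
})

test_that("replicate-level CI analysis summarizes mean and SD", {
  tr <- dose_response_truth(alpha = 0.5)
  dr <- generate_dose_response(tr, replicates = 3, noise_sd = 0.01, seed = 8)
  res <- ci_analysis(dr, fa_levels = c(0.5, 0.75))
  expect_equal(dim(res$per_replicate), c(3L, 2L))
  expect_true(all(res$mean < 1))
  expect_true(all(res$cooperative))
  expect_equal(unname(res$mean[1]), 0.5, tolerance = 0.1)
  # nonexclusive form adds a positive cross term
  resx <- ci_analysis(dr, fa_levels = 0.5, form = "nonexclusive")
  expect_gt(resx$mean[1], res$mean[1])
})
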