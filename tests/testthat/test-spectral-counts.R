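samples3 <- data.frame(sample_id = c("A_1", "B_1", "GST_1"),
                       condition = c("A", "B", "control"),
                       replicate = c(1L, 1L, 1L))

test_that("PSM aggregation sums peptide counts per protein and sample", {
  psm <- data.frame(protein_id = c("P1", "P1", "P1", "P2"),
                    peptide_id = c("pep1", "pep1", "pep2", "pep3"),
                    sample_id = c("A_1", "A_1", "A_1", "B_1"),
                    spectral_count = c(3, 2, 4, 7))
  m <- aggregate_psm_counts(psm, samples3)
  expect_equal(m$stage, "raw")
  expect_equal(m$values["P1", "A_1"], 9)   # 3 + 2 + 4
  expect_equal(m$values["P2", "A_1"], 0)   # absent -> 0
  expect_equal(m$values["P2", "B_1"], 7)

  # peptide shared between two proteins counts toward both
  shared <- data.frame(protein_id = c("P1", "P2"), peptide_id = "pepS",
                       sample_id = "A_1", spectral_count = 5)
  ms <- aggregate_psm_counts(shared, samples3)
  expect_equal(unname(ms$values[, "A_1"]), c(5, 5))
  mu <- aggregate_psm_counts(shared, samples3, shared_peptides = "unique")
  expect_equal(nrow(mu$values), 0L)

  expect_error(aggregate_psm_counts(
    transform(psm, sample_id = "nope"), samples3), "unknown sample")
})

test_that("background subtraction removes the control mean and keeps audit", {
  vals <- cbind(A_1 = c(3, 10), A_2 = c(8, 12), B_1 = c(6, 1), B_2 = c(9, 2),
                GST_1 = c(2, 5), GST_2 = c(3, 5))
  samples <- data.frame(sample_id = colnames(vals),
                        condition = c("A", "A", "B", "B", "control", "control"),
                        replicate = c(1, 2, 1, 2, 1, 2))
  m <- spectral_count_matrix(vals, samples)
  s <- subtract_background(m)
  expect_equal(s$stage, "subtracted")
  # controls (2, 3) -> mean 2.5; cell 3 -> 0.5, cell 10 -> 7.5
  expect_equal(unname(s$values[1, "A_1"]), 0.5)
  expect_equal(unname(s$values[2, ]), c(5, 7, -4, -3))  # may go negative
  expect_equal(ncol(s$values), 4L)
  expect_equal(ncol(s$controls), 2L)

  p <- subtract_background(m, control_mode = "paired")
  expect_equal(unname(p$values[1, ]), c(3 - 2, 8 - 3, 6 - 2, 9 - 3))

  no_ctrl <- make_scm(vals[, 1:4], "raw")
  expect_error(subtract_background(no_ctrl), "no control")
})

test_that("flooring yields a non-negative log2 matrix", {
  m <- make_scm(cbind(c(-2, 8), c(0, 16)), "subtracted")
  fl <- log2_with_floor(m)
  expect_equal(unname(fl$values), cbind(c(0, 3), c(0, 4)))
  expect_gte(min(fl$values), 0)
  # stage enforcement: cannot floor twice or skip subtraction
  expect_error(log2_with_floor(fl), "stage")
  expect_error(log2_with_floor(make_scm(cbind(1:2, 3:4), "raw")), "stage")
})

test_that("quantile normalization equalizes column distributions", {
  m <- make_scm(cbind(c(1, 3), c(2, 4)), "log2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  expect_equal(qn$stage, "normalized")

  # identical columns are a fixed point
  same <- make_scm(cbind(c(5, 1, 2), c(5, 1, 2)), "log2")
  expect_equal(quantile_normalize(same)$values, same$values,
               ignore_attr = TRUE)

  # agrees with an independent rank-mean oracle on tie-free data
  set.seed(42)
  x <- matrix(rnorm(60), 15, 4)
  got <- quantile_normalize(make_scm(x, "log2"))$values
  expect_equal(unname(got), qn_oracle(x), tolerance = 1e-12)

  expect_error(quantile_normalize(make_scm(matrix(1:3), "log2")),
               "at least 2")
})

test_that("detection calls honour value and replicate thresholds", {
  vals <- rbind(P1 = c(5, 6, 4, 0, 0, 0), P2 = c(-1, 0, -3, 0, 0, 0),
                P3 = c(5, 0, 4, 2, 2, 2))
  samples <- data.frame(sample_id = paste0(rep(c("A", "B"), each = 3), "_",
                                           1:3),
                        condition = rep(c("A", "B"), each = 3),
                        replicate = rep(1:3, 2))
  colnames(vals) <- samples$sample_id
  m <- spectral_count_matrix(vals, samples, stage = "subtracted")
  det3 <- call_detected_proteins(m, min_value = 1, min_replicates = 3)
  a3 <- det3[det3$condition == "A", ]
  expect_equal(a3$detected[a3$protein_id == "P1"], TRUE)
  expect_equal(a3$detected[a3$protein_id == "P2"], FALSE)
  expect_equal(a3$detected[a3$protein_id == "P3"], FALSE)  # one replicate at 0
  det2 <- call_detected_proteins(m, min_value = 1, min_replicates = 2)
  a2 <- det2[det2$condition == "A", ]
  expect_equal(a2$detected[a2$protein_id == "P3"], TRUE)
  expect_error(call_detected_proteins(m, min_replicates = 4), "exceeds")
})

test_that("densitometry relative level is the double ratio", {
  expect_equal(densitometry_relative_level(2, 1, 1, 1), 2)
  expect_equal(densitometry_relative_level(3, 2, 3, 2), 1)  # equals control
  expect_equal(densitometry_relative_level(3, 2, 6, 4), 1)  # ratio cancels
  expect_error(densitometry_relative_level(0, 1, 1, 1), "> 0")
  expect_error(densitometry_relative_level(1, 1, -2, 1), "> 0")
})
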