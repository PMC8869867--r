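# Independent oracles used across tests; deliberately naive implementations.

# two-sided Fisher p by brute-force enumeration of all 2x2 tables with the
# observed margins: sum of hypergeometric probabilities of tables at most as
# probable as the observed one (with the conventional 1e-7 relative slack
# for ties).
fisher_p_bruteforce <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_          # category members
  n <- a + b           # differential proteins
  support <- max(0, n - (N - K)):min(n, K)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# rank-mean quantile normalization for tie-free matrices
qn_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col)])
}

# closed-form pooled-variance and Welch t-tests
t_oracle <- function(a, b, variant = "student") {
  na <- length(a); nb <- length(b)
  if (variant == "student") {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(var(a) / na + var(b) / nb)
    df <- (var(a) / na + var(b) / nb)^2 /
      ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# quick SpectralCountMatrix construction for stage-specific tests
make_scm <- function(values, stage = "raw", n_control = 0) {
  values <- as.matrix(values)
  n_exp <- ncol(values) - n_control
  half <- n_exp %/% 2
  cond <- c(rep("A", half), rep("B", n_exp - half),
            rep("control", n_control))
  samples <- data.frame(
    sample_id = paste0(cond, "_", stats::ave(seq_along(cond), cond,
                                             FUN = seq_along)),
    condition = cond,
    replicate = stats::ave(seq_along(cond), cond, FUN = seq_along))
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  spectral_count_matrix(values, samples, stage = stage)
}
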