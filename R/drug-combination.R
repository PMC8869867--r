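#' Gate apoptotic events from a flow-cytometry event table
#'
#' Classifies events as positive (e.g. annexin-V stained, apoptotic) when
#' their fluorescence intensity exceeds the gate threshold, and reports the
#' positive fraction.
#'
#' @param events data.frame with a numeric `intensity` column, one row per
#'   collected event.
#' @param gate_threshold intensity gate; events strictly above it count as
#'   positive.
#' @return list with `n`, `n_positive`, `fraction`.
#' @export
gate_apoptosis <- function(events, gate_threshold) {
  if (is.null(events$intensity) || nrow(events) < 1L)
    stop_input("events must be a non-empty table with an intensity column")
  assert_scalar_number(gate_threshold, "gate_threshold")
  npos <- sum(events$intensity > gate_threshold)
  list(n = nrow(events), n_positive = npos, fraction = npos / nrow(events))
}

#' Fit the median-effect model to a dose-response series
#'
#' Linearizes the median-effect equation `fa/(1-fa) = (D/Dm)^m` by least
#' squares of `log10(fa/(1-fa))` on `log10(dose)`: the slope is the
#' sigmoidicity `m` and the intercept `-m*log10(Dm)` gives the median-effect
#' dose `Dm` (the IC50). Rows with `fa` outside the open interval (0,1) are
#' rejected with a warning; at least two distinct usable doses are required.
#'
#' @param dr dose-response data.frame with columns `agent`, `dose`, `fa`
#'   (and optionally `replicate`).
#' @param agent which agent's rows to fit (a value of `dr$agent`).
#' @param replicate optionally restrict the fit to one replicate.
#' @return object of class `MedianEffectFit`: list with `m`, `Dm`, `r`
#'   (linear correlation of the fit), `n_points`, `agent`.
#' @export
fit_median_effect <- function(dr, agent, replicate = NULL) {
  rows <- dr[dr$agent == agent, , drop = FALSE]
  if (!is.null(replicate)) rows <- rows[rows$replicate == replicate, , drop = FALSE]
  if (!nrow(rows)) stop_input("no rows for agent '", agent, "'")
  if (any(rows$dose <= 0)) stop_input("doses must be > 0")
  bad <- rows$fa <= 0 | rows$fa >= 1
  if (any(bad)) {
    warning(sum(bad), " row(s) with fa outside (0,1) rejected for agent '",
            agent, "'", call. = FALSE)
    rows <- rows[!bad, , drop = FALSE]
  }
  if (length(unique(rows$dose)) < 2L)
    stop_input("need at least 2 distinct doses with fa in (0,1)")
  x <- log10(rows$dose)
  y <- log10(rows$fa / (1 - rows$fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m <= 0)
    stop_input("median-effect fit failed: non-positive slope m = ",
               format(m))
  structure(list(m = m, Dm = 10^(-b / m), r = stats::cor(x, y),
                 n_points = nrow(rows), agent = agent),
            class = "MedianEffectFit")
}

#' @export
print.MedianEffectFit <- function(x, ...) {
  cat(sprintf("MedianEffectFit [%s]: m = %.3f, Dm = %.4g (r = %.4f, n = %d)\n",
              x$agent, x$m, x$Dm, x$r, x$n_points))
  invisible(x)
}

#' Median-effect dose (IC50)
#'
#' The dose producing 50% effect under the median-effect model, i.e. the
#' fitted `Dm`.
#'
#' @param fit `MedianEffectFit`.
#' @return dose, in the units of the fitted series.
#' @export
ic50 <- function(fit) {
  check_fit(fit)
  fit$Dm
}

check_fit <- function(fit) {
  if (!inherits(fit, "MedianEffectFit")) stop_input("expected a MedianEffectFit")
  if (!is.finite(fit$m) || fit$m <= 0 || !is.finite(fit$Dm) || fit$Dm <= 0)
    stop_input("invalid median-effect fit (m and Dm must be > 0)")
  invisible(fit)
}

# dose producing effect fa under a median-effect fit
dose_for_fa <- function(fit, fa) fit$Dm * (fa / (1 - fa))^(1 / fit$m)

#' Chou-Talalay combination index at a constant dose ratio
#'
#' For each effect level `fa`, the total combination dose producing that
#' effect is computed from the combination fit and split into its components
#' by the fixed mixing ratio `r = doseA:doseB` (`dA = D*r/(1+r)`,
#' `dB = D/(1+r)`); the combination index is
#' `CI = dA/Dx_A + dB/Dx_B`, where `Dx_A`, `Dx_B` are the single-agent doses
#' producing the same effect (mutually exclusive form; the non-exclusive
#' form adds the cross term `dA*dB/(Dx_A*Dx_B)`). CI < 1 indicates a
#' cooperative (synergistic) effect, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param fit_a,fit_b,fit_combo `MedianEffectFit` objects for the two single
#'   agents and the constant-ratio combination (combination doses on the
#'   total-dose scale).
#' @param ratio mixing ratio doseA:doseB of the combination (> 0).
#' @param fa_levels effect levels in (0,1) at which to evaluate CI.
#' @param form `"exclusive"` (default, the CompuSyn default) or
#'   `"nonexclusive"`.
#' @return named numeric vector of CI values, one per `fa` level.
#' @export
combination_index <- function(fit_a, fit_b, fit_combo, ratio = 1,
                              fa_levels = 0.5,
                              form = c("exclusive", "nonexclusive")) {
  form <- match.arg(form)
  check_fit(fit_a); check_fit(fit_b); check_fit(fit_combo)
  assert_scalar_number(ratio, "ratio", positive = TRUE)
  if (any(fa_levels <= 0 | fa_levels >= 1))
    stop_input("fa_levels must lie strictly inside (0,1)")
  ci <- vapply(fa_levels, function(fa) {
    d_total <- dose_for_fa(fit_combo, fa)
    d_a <- d_total * ratio / (1 + ratio)
    d_b <- d_total / (1 + ratio)
    term_a <- d_a / dose_for_fa(fit_a, fa)
    term_b <- d_b / dose_for_fa(fit_b, fa)
    out <- term_a + term_b
    if (form == "nonexclusive") out <- out + term_a * term_b
    out
  }, numeric(1))
  names(ci) <- sprintf("fa_%g", fa_levels)
  ci
}

#' Replicate-level combination-index analysis
#'
#' Fits the median-effect model per replicate for both single agents and the
#' combination, computes the combination index per replicate at each effect
#' level, and summarizes as mean +/- SD — matching how CI is conventionally
#' reported with a spread.
#'
#' @param dr dose-response data.frame with columns `agent` (values `"A"`,
#'   `"B"`, `"combo"`), `dose`, `fa`, `replicate`; combination doses are
#'   total doses at a fixed ratio.
#' @param ratio mixing ratio doseA:doseB (default: the `ratio` attribute of
#'   `dr` if present).
#' @inheritParams combination_index
#' @return object of class `CIResult`: list with per-replicate CI matrix,
#'   `mean`, `sd` per fa level and a `cooperative` flag (mean CI < 1 at each
#'   level).
#' @export
ci_analysis <- function(dr, ratio = NULL, fa_levels = 0.5,
                        form = c("exclusive", "nonexclusive")) {
  form <- match.arg(form)
  ratio <- ratio %||% attr(dr, "ratio")
  if (is.null(ratio)) stop_input("ratio must be given (or set as attribute)")
  reps <- sort(unique(dr$replicate))
  per_rep <- t(vapply(reps, function(rep) {
    combination_index(fit_median_effect(dr, "A", rep),
                      fit_median_effect(dr, "B", rep),
                      fit_median_effect(dr, "combo", rep),
                      ratio = ratio, fa_levels = fa_levels, form = form)
  }, numeric(length(fa_levels))))
  per_rep <- matrix(per_rep, nrow = length(reps),
                    dimnames = list(replicate = reps,
                                    sprintf("fa_%g", fa_levels)))
  mu <- colMeans(per_rep)
  s <- apply(per_rep, 2, stats::sd)
  structure(list(per_replicate = per_rep, mean = mu, sd = s,
                 fa_levels = fa_levels, ratio = ratio, form = form,
                 cooperative = mu < 1),
            class = "CIResult")
}

#' @export
print.CIResult <- function(x, ...) {
  cat(sprintf("CIResult (%s form, ratio %g): CI < 1 indicates cooperativity\n",
              x$form, x$ratio))
  for (i in seq_along(x$fa_levels))
    cat(sprintf("  fa = %-5g CI = %.3f +/- %.3f%s\n", x$fa_levels[i],
                x$mean[i], x$sd[i],
                if (x$cooperative[i]) "  (cooperative)" else ""))
  invisible(x)
}
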