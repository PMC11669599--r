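# Two-step mediation MR: product-of-coefficients decomposition with
# delta-method intervals, mediator screening, reverse-MR guard.

coef_se <- function(x, what) {
  if (inherits(x, "mr_estimate")) list(beta = x$beta, se = x$se)
  else if (is.list(x) && all(c("beta", "se") %in% names(x))) x[c("beta", "se")]
  else medmr_stop(sprintf("`%s` must be an mr_estimate or list(beta=, se=)", what),
                  "medmr_input_error")
}

#' Two-step mediation decomposition
#'
#' Combines three MR estimates — exposure on mediator (`beta1`), mediator on
#' outcome (`beta2`), and the exposure-on-outcome total effect — into a
#' product-of-coefficients mediation decomposition on the log(-odds) scale:
#' mediated effect `beta1 * beta2`, direct effect `total - mediated`, and
#' mediated proportion `mediated / total`. The mediated effect's standard
#' error is the Sobel delta-method form
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`; the proportion's treats the
#' mediated and total effects as independent,
#' `|prop| * sqrt(se_med^2/med^2 + se_tot^2/tot^2)`. 95% confidence
#' intervals use the 1.96 normal quantile, endpoints ordered (low, high).
#'
#' When the mediated effect is within one standard error of zero the
#' proportion's delta-method interval is labelled unstable
#' (`proportion_ci_unstable`); passing `n_boot > 0` additionally computes
#' percentile bootstrap intervals by redrawing the three coefficients from
#' their normal approximations.
#'
#' @param step1 Exposure-on-mediator estimate (`mr_estimate` or
#'   `list(beta=, se=)`), log scale.
#' @param step2 Mediator-on-outcome estimate, log-OR scale.
#' @param total Exposure-on-outcome total effect, log-OR scale.
#' @param n_boot Bootstrap replicates for the optional resampling intervals
#'   (0 = delta method only).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @return A list of class `mediation_result` with the decomposition, its
#'   standard errors, confidence intervals, `p_mediated`, and flags.
#' @export
two_step_mediation <- function(step1, step2, total, n_boot = 0, seed = NULL) {
  s1 <- coef_se(step1, "step1")
  s2 <- coef_se(step2, "step2")
  tt <- coef_se(total, "total")
  if (tt$beta == 0) {
    medmr_stop("total effect is zero: mediated proportion undefined",
               "medmr_domain_error")
  }
  mediated <- s1$beta * s2$beta
  se_med <- sqrt(s2$beta^2 * s1$se^2 + s1$beta^2 * s2$se^2)
  direct <- tt$beta - mediated
  proportion <- mediated / tt$beta
  z <- stats::qnorm(0.975)
  p_mediated <- if (se_med > 0) 2 * stats::pnorm(-abs(mediated / se_med)) else as.numeric(mediated == 0)
  se_prop <- if (mediated != 0) {
    abs(proportion) * sqrt(se_med^2 / mediated^2 + tt$se^2 / tt$beta^2)
  } else {
    # first-order term vanishes with the product; propagate the product SE
    se_med / abs(tt$beta)
  }
  opposite_sign <- sign(mediated) * sign(tt$beta) < 0
  if (opposite_sign) {
    medmr_warn("mediated and total effects have opposite signs; proportion is negative",
               "medmr_opposite_sign")
  }
  unstable <- is.finite(se_med) && se_med > 0 && abs(mediated / se_med) < 1
  out <- list(
    beta1 = s1$beta, se1 = s1$se, beta2 = s2$beta, se2 = s2$se,
    total = tt$beta, se_total = tt$se,
    mediated = mediated, se_mediated = se_med,
    direct = direct, proportion = proportion, se_proportion = se_prop,
    ci_mediated = c(mediated - z * se_med, mediated + z * se_med),
    ci_proportion = sort(c(proportion - z * se_prop, proportion + z * se_prop)),
    p_mediated = p_mediated,
    proportion_ci_unstable = unstable,
    opposite_sign = opposite_sign
  )
  if (n_boot > 0) {
    if (is.null(seed)) medmr_stop("bootstrap intervals need a seed", "medmr_config_error")
    draws <- with_seed(seed, {
      b1 <- stats::rnorm(n_boot, s1$beta, s1$se)
      b2 <- stats::rnorm(n_boot, s2$beta, s2$se)
      tb <- stats::rnorm(n_boot, tt$beta, tt$se)
      list(med = b1 * b2, prop = b1 * b2 / tb)
    })
    out$ci_mediated_boot <- unname(stats::quantile(draws$med, c(0.025, 0.975)))
    out$ci_proportion_boot <- unname(stats::quantile(draws$prop, c(0.025, 0.975)))
  }
  structure(out, class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result>\n  beta1 = %.4f (se %.4f), beta2 = %.4f (se %.4f)\n",
              x$beta1, x$se1, x$beta2, x$se2))
  cat(sprintf("  total = %.5f, mediated = %.5f [%.5f, %.5f] (p = %.3g), direct = %.5f\n",
              x$total, x$mediated, x$ci_mediated[1], x$ci_mediated[2],
              x$p_mediated, x$direct))
  cat(sprintf("  proportion mediated = %.1f%% [%.1f%%, %.1f%%]%s\n",
              100 * x$proportion, 100 * x$ci_proportion[1], 100 * x$ci_proportion[2],
              if (isTRUE(x$proportion_ci_unstable)) " (delta-method CI unstable)" else ""))
  invisible(x)
}

#' Reverse-MR guard against reverse causation
#'
#' Runs the MR pipeline with roles swapped — instruments selected from the
#' outcome at genome-wide significance, effects estimated on the putative
#' exposure/mediator — and passes when the reverse IVW p-value is at or
#' above `alpha` (no reverse causation detected). A forward result should be
#' labelled unidirectional only when the guard passes. When the outcome has
#' too few instruments the guard is indeterminate (`passes = NA`), never a
#' pass.
#'
#' @param outcome Outcome [summary_stats] (instrument source).
#' @param target The trait reverse causation would act on ([summary_stats]).
#' @param ld An [ld_matrix].
#' @param p_threshold Instrument p-value threshold (default `5e-8`).
#' @param alpha Reverse-effect test level (default 0.05).
#' @param min_snps,f_threshold,r2_threshold,window_kb Selection settings as
#'   in [select_instruments()].
#' @return List of class `reverse_guard`: `estimate` (reverse IVW
#'   `mr_estimate` or `NULL`), `passes` (`TRUE`/`FALSE`/`NA`), `reason`.
#' @export
reverse_mr_guard <- function(outcome, target, ld, p_threshold = 5e-8,
                             alpha = 0.05, min_snps = 3, f_threshold = 10,
                             r2_threshold = 0.001, window_kb = 10000) {
  sel <- tryCatch(
    select_instruments(outcome, ld, p_threshold = p_threshold,
                       f_threshold = f_threshold, min_snps = min_snps,
                       r2_threshold = r2_threshold, window_kb = window_kb),
    medmr_underpowered = function(e) e
  )
  if (inherits(sel, "condition")) {
    return(structure(list(estimate = NULL, passes = NA,
                          reason = conditionMessage(sel)),
                     class = "reverse_guard"))
  }
  hh <- tryCatch(harmonize(sel$stats, target),
                 medmr_empty_harmonization = function(e) e)
  if (inherits(hh, "condition") || nrow(hh$pairs) < 2L) {
    return(structure(list(estimate = NULL, passes = NA,
                          reason = "too few harmonized reverse instruments"),
                     class = "reverse_guard"))
  }
  est <- mr_ivw(hh)
  structure(list(estimate = est, passes = est$pvalue >= alpha,
                 reason = if (est$pvalue >= alpha) "no reverse effect detected"
                          else "reverse effect detected"),
            class = "reverse_guard")
}

#' @export
print.reverse_guard <- function(x, ...) {
  cat(sprintf("<reverse_guard> passes = %s (%s)\n", x$passes, x$reason))
  invisible(x)
}

#' Screen exposure-mediator pairs for mediated causal paths
#'
#' For every (exposure, mediator) pair: estimates the exposure-on-outcome
#' total effect, the exposure-on-mediator leg (`beta1`) and the
#' mediator-on-outcome leg (`beta2`) by IVW with instrument selection and
#' harmonization (the exposure's own instruments are excluded from the
#' mediator's instrument set, since they affect the outcome through the
#' exposure path as well); keeps pairs whose two legs both reach `p < alpha`; applies
#' the reverse-MR guard to both candidate links; and emits a
#' [two_step_mediation()] decomposition per surviving pair, ranked by
#' absolute mediated proportion. Pairs failing instrument selection are
#' skipped with the reason logged in the `skipped` attribute.
#'
#' @param exposures Named list of exposure [summary_stats].
#' @param mediators Named list of mediator [summary_stats].
#' @param outcome Outcome [summary_stats].
#' @param ld An [ld_matrix].
#' @param cfg A [pipeline_config()].
#' @return Data frame (one row per surviving pair) with the decomposition,
#'   p-values and reverse-guard flags, ranked by `|proportion|`; skipped
#'   pairs recorded in `attr(, "skipped")`.
#' @export
screen_mediators <- function(exposures, mediators, outcome, ld,
                             cfg = pipeline_config()) {
  stopifnot(inherits(outcome, "summary_stats"))
  skipped <- character(0)
  ivw_leg <- function(from, to, p_threshold) {
    sel <- select_instruments(from, ld, p_threshold = p_threshold,
                              f_threshold = cfg$f_min, min_snps = cfg$min_snps,
                              r2_threshold = cfg$r2, window_kb = cfg$window_kb)
    mr_ivw(harmonize(sel$stats, to))
  }
  rows <- list()
  for (ei in names(exposures)) {
    total <- tryCatch(ivw_leg(exposures[[ei]], outcome, cfg$p_exposure),
                      medmr_error = function(e) e)
    if (inherits(total, "condition")) {
      skipped <- c(skipped, sprintf("%s -> outcome: %s", ei, conditionMessage(total)))
      next
    }
    exp_iv <- tryCatch(
      select_instruments(exposures[[ei]], ld, p_threshold = cfg$p_exposure,
                         f_threshold = cfg$f_min, min_snps = cfg$min_snps,
                         r2_threshold = cfg$r2, window_kb = cfg$window_kb)$variant_ids,
      medmr_error = function(e) character(0))
    for (mi in names(mediators)) {
      med_pruned <- mediators[[mi]]
      med_pruned$records <- med_pruned$records[
        !(med_pruned$records$SNP %in% exp_iv), , drop = FALSE]
      leg1 <- tryCatch(ivw_leg(exposures[[ei]], mediators[[mi]], cfg$p_exposure),
                       medmr_error = function(e) e)
      leg2 <- tryCatch(ivw_leg(med_pruned, outcome, cfg$p_exposure),
                       medmr_error = function(e) e)
      if (inherits(leg1, "condition") || inherits(leg2, "condition")) {
        bad <- if (inherits(leg1, "condition")) leg1 else leg2
        skipped <- c(skipped, sprintf("%s x %s: %s", ei, mi, conditionMessage(bad)))
        next
      }
      if (leg1$pvalue >= cfg$alpha || leg2$pvalue >= cfg$alpha) next
      med <- withCallingHandlers(
        two_step_mediation(leg1, leg2, total),
        medmr_opposite_sign = function(w) invokeRestart("muffleWarning")
      )
      g_exp <- reverse_mr_guard(outcome, exposures[[ei]], ld,
                                p_threshold = cfg$p_outcome_instruments,
                                alpha = cfg$alpha, min_snps = cfg$min_snps,
                                f_threshold = cfg$f_min,
                                r2_threshold = cfg$r2, window_kb = cfg$window_kb)
      g_med <- reverse_mr_guard(outcome, mediators[[mi]], ld,
                                p_threshold = cfg$p_outcome_instruments,
                                alpha = cfg$alpha, min_snps = cfg$min_snps,
                                f_threshold = cfg$f_min,
                                r2_threshold = cfg$r2, window_kb = cfg$window_kb)
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ei, mediator = mi,
        beta1 = med$beta1, se1 = med$se1, p1 = leg1$pvalue,
        beta2 = med$beta2, se2 = med$se2, p2 = leg2$pvalue,
        total = med$total, se_total = med$se_total, p_total = total$pvalue,
        mediated = med$mediated, se_mediated = med$se_mediated,
        p_mediated = med$p_mediated,
        direct = med$direct, proportion = med$proportion,
        prop_ci_low = med$ci_proportion[1], prop_ci_high = med$ci_proportion[2],
        reverse_guard_exposure = g_exp$passes, reverse_guard_mediator = g_med$passes,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    out <- out[order(-abs(out$proportion), out$exposure, out$mediator), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}
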