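# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (theta_j - theta_IVW)^2)` with the fixed-effect IVW center
#' (the standard definition, whatever random-effects model the headline
#' estimate uses); compared to a chi-square with `J - 1` degrees of freedom.
#' `Q = 0` exactly when all Wald ratios coincide.
#'
#' @param r A [ratio_estimates] or [harmonized_set] (at least 2 variants).
#' @return List with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(r) {
  r <- as_ratio_estimates(r)
  J <- length(r$theta)
  if (J < 2L) medmr_stop("Cochran's Q needs at least 2 instruments",
                         "medmr_insufficient_instruments")
  w <- r$weights
  center <- sum(w * r$theta) / sum(w)
  q <- sum(w * (r$theta - center)^2)
  list(q = q, df = J - 1L, pvalue = stats::pchisq(q, df = J - 1L, lower.tail = FALSE))
}

#' MR-PRESSO residual test for pleiotropic outliers
#'
#' Global test: for each variant `j`, the fixed-effect IVW estimate without
#' it predicts `beta_out_j`; the observed residual sum of squares over all
#' variants is compared to a null distribution built by redrawing every
#' `beta_out_j` from `Normal(theta_hat_(-j) * beta_exp_j, se_out_j)` and
#' recomputing the statistic, `n_sim` times under a fixed seed. Outlier
#' test: each variant's observed squared residual is compared to its
#' simulated distribution, with Bonferroni correction over variants at
#' `outlier_alpha`. When outliers are found, an outlier-corrected IVW
#' estimate is returned together with a distortion test: the empirical
#' two-sided p-value of the corrected-minus-full IVW shift against shifts
#' obtained by removing random variant subsets of the same size.
#'
#' @param h A [harmonized_set] (at least 4 variants).
#' @param n_sim Simulations for the null distribution (default 1000).
#' @param outlier_alpha Family-wise level for the outlier test (default 0.05).
#' @param seed Simulation seed (required).
#' @return List of class `mr_presso`: `global_p`, `outliers` (variant ids),
#'   `outlier_p` (per-variant Bonferroni-adjusted p), `distortion_p` and
#'   `corrected` (an `mr_estimate`; both `NA`/`NULL` when no outliers).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed) {
  stopifnot(inherits(h, "harmonized_set"))
  if (!is.numeric(n_sim) || n_sim < 1) {
    medmr_stop("n_sim must be a positive integer", "medmr_config_error")
  }
  r <- ratio_estimates(h)
  J <- length(r$theta)
  if (J < 4L) medmr_stop("MR-PRESSO needs at least 4 instruments",
                         "medmr_insufficient_instruments")
  # the empirical per-variant p cannot fall below 1/(n_sim+1); after the
  # Bonferroni correction over J variants the outlier test needs
  # n_sim > J/outlier_alpha to be able to flag anything at all
  if (J / (n_sim + 1) >= outlier_alpha) {
    medmr_warn(sprintf(
      "mr_presso: n_sim = %d cannot resolve outliers for %d variants at alpha = %g (need n_sim > %d)",
      n_sim, J, outlier_alpha, ceiling(J / outlier_alpha)), "medmr_presso_resolution")
  }
  w <- r$weights
  bx <- r$beta_exp
  by <- r$beta_out
  sw <- sum(w); swt <- sum(w * r$theta)
  theta_loo <- (swt - w * r$theta) / (sw - w)   # fixed-effect IVW without j
  resid_obs <- by - theta_loo * bx
  rss_obs <- sum(resid_obs^2)

  seeds <- derive_seeds(seed, 2L)
  sims <- with_seed(seeds[1], {
    # n_sim x J matrix of simulated outcome effects under the null
    matrix(stats::rnorm(n_sim * J, mean = rep(theta_loo * bx, each = n_sim),
                        sd = rep(r$se_out, each = n_sim)), nrow = n_sim)
  })
  theta_sim <- sweep(sims, 2, bx, "/")
  swt_sim <- theta_sim %*% w
  theta_loo_sim <- (matrix(swt_sim, n_sim, J) - sweep(theta_sim, 2, w, "*")) /
    matrix(sw - w, n_sim, J, byrow = TRUE)
  resid_sim <- sims - sweep(theta_loo_sim, 2, bx, "*")
  rss_sim <- rowSums(resid_sim^2)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(sweep(resid_sim^2, 2, resid_obs^2, ">="))) / (n_sim + 1)
  p_snp_adj <- pmin(1, p_snp * J)
  outliers <- r$variant_ids[p_snp_adj < outlier_alpha]

  distortion_p <- NA_real_
  corrected <- NULL
  if (length(outliers) && length(outliers) <= J - 2L) {
    keep <- !(r$variant_ids %in% outliers)
    sub <- r
    for (f in c("variant_ids", "theta", "sigma", "weights",
                "beta_exp", "se_exp", "beta_out", "se_out")) {
      sub[[f]] <- sub[[f]][keep]
    }
    corrected <- mr_ivw(sub)
    beta_full <- swt / sw
    d_obs <- corrected$beta - beta_full
    n_out <- sum(!keep)
    d_sim <- with_seed(seeds[2], {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(J, n_out)
        (swt - sum(w[drop] * r$theta[drop])) / (sw - sum(w[drop])) - beta_full
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(
    list(global_p = global_p, outliers = outliers,
         outlier_p = stats::setNames(p_snp_adj, r$variant_ids),
         distortion_p = distortion_p, corrected = corrected),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global p = %.4g; %d outlier(s)%s\n",
              x$global_p, length(x$outliers),
              if (length(x$outliers)) paste0(" (", paste(x$outliers, collapse = ", "),
                                             "); distortion p = ",
                                             signif(x$distortion_p, 3)) else ""))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates IVW with each variant removed in turn. A variant is flagged
#' as dominant when its removal flips the sign of the estimate or moves the
#' p-value across 0.05.
#'
#' @param h A [harmonized_set] (at least 3 variants).
#' @param re_model IVW error model, as in [mr_ivw()].
#' @return Data frame with one row per variant: `SNP`, `beta_without`,
#'   `se_without`, `p_without`, `dominant`.
#' @export
leave_one_out <- function(h, re_model = "multiplicative_random") {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h$pairs)
  if (J < 3L) medmr_stop("leave-one-out needs at least 3 instruments",
                         "medmr_insufficient_instruments")
  full <- mr_ivw(h, re_model = re_model)
  rows <- lapply(seq_len(J), function(j) {
    sub <- h
    sub$pairs <- h$pairs[-j, , drop = FALSE]
    est <- mr_ivw(sub, re_model = re_model)
    data.frame(SNP = h$pairs$SNP[j], beta_without = est$beta,
               se_without = est$se, p_without = est$pvalue,
               dominant = sign(est$beta) != sign(full$beta) ||
                 (est$pvalue < 0.05) != (full$pvalue < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' The family-wise threshold `alpha / n_tests` for a screen of `n_tests`
#' independent causal tests.
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Nominal level (default 0.05).
#' @return The adjusted threshold.
#' @seealso [classify_pvalue()]
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || any(n_tests < 1)) {
    medmr_stop("n_tests must be >= 1", "medmr_domain_error")
  }
  alpha / n_tests
}

#' Classify a p-value against a Bonferroni-corrected screen
#'
#' Labels a p-value `"significant_corrected"` when it clears the
#' Bonferroni threshold `alpha / n_tests`, `"suggestive"` when it is below
#' the conventional `alpha` but not the corrected threshold (a result to be
#' interpreted with caution), and `"null"` otherwise.
#'
#' @param p P-value(s).
#' @param n_tests Number of tests in the screen.
#' @param alpha Nominal level (default 0.05).
#' @return Character vector of labels.
#' @export
classify_pvalue <- function(p, n_tests, alpha = 0.05) {
  thr <- bonferroni_threshold(n_tests, alpha)
  ifelse(p < thr, "significant_corrected",
         ifelse(p < alpha, "suggestive", "null"))
}

#' Full sensitivity battery for one harmonized set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out table into one report.
#'
#' @param h A [harmonized_set] (at least 4 variants for MR-PRESSO; with 3,
#'   the PRESSO fields are `NA`).
#' @param seed Seed for MR-PRESSO (required).
#' @param n_sim MR-PRESSO simulations (default 1000).
#' @return A list of class `sensitivity_report`: `cochran_q`, `q_df`,
#'   `q_pvalue`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `presso` (an `mr_presso` or `NULL`), `loo_table`.
#' @export
sensitivity_battery <- function(h, seed, n_sim = 1000) {
  q <- cochran_q(h)
  eg <- mr_egger(h)
  presso <- if (nrow(h$pairs) >= 4L) mr_presso(h, n_sim = n_sim, seed = seed) else NULL
  structure(
    list(cochran_q = q$q, q_df = q$df, q_pvalue = q$pvalue,
         egger_intercept = eg$intercept, egger_intercept_se = eg$intercept_se,
         egger_intercept_p = eg$intercept_p,
         presso = presso, loo_table = leave_one_out(h)),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> Q = %.3f (df %d, p = %.3g); Egger intercept = %.4g (p = %.3g)\n",
              x$cochran_q, x$q_df, x$q_pvalue, x$egger_intercept, x$egger_intercept_p))
  if (!is.null(x$presso)) print(x$presso)
  flagged <- sum(x$loo_table$dominant)
  cat(sprintf("leave-one-out: %d of %d variants dominant\n", flagged, nrow(x$loo_table)))
  invisible(x)
}
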