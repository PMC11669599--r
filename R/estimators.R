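# The five causal estimators: IVW, MR-Egger, weighted median, weighted and
# simple mode, all operating on per-variant Wald ratios.

#' Per-variant Wald ratios and inverse-variance weights
#'
#' For each harmonized pair, the Wald ratio `theta = beta_out / beta_exp`
#' estimates the causal effect, with first-order standard error
#' `sigma = se_out / |beta_exp|` (the uncertainty in the exposure effect is
#' ignored, the standard two-sample convention). Weights are `sigma^-2`.
#'
#' @param h A [harmonized_set].
#' @return An object of class `ratio_estimates` with `variant_ids`, `theta`,
#'   `sigma`, `weights`, and the underlying `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @export
ratio_estimates <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  p <- h$pairs
  if (nrow(p) < 1L) medmr_stop("no pairs", "medmr_insufficient_instruments")
  if (any(p$beta_exp == 0)) {
    medmr_stop("degenerate instrument: beta_exp = 0", "medmr_degenerate_instrument")
  }
  sigma <- p$se_out / abs(p$beta_exp)
  structure(
    list(variant_ids = p$SNP,
         theta = p$beta_out / p$beta_exp,
         sigma = sigma,
         weights = sigma^-2,
         beta_exp = p$beta_exp, se_exp = p$se_exp,
         beta_out = p$beta_out, se_out = p$se_out),
    class = "ratio_estimates"
  )
}

as_ratio_estimates <- function(x) {
  if (inherits(x, "ratio_estimates")) x
  else if (inherits(x, "harmonized_set")) ratio_estimates(x)
  else medmr_stop("expected a harmonized_set or ratio_estimates", "medmr_input_error")
}

# Assemble one estimator's result. CIs use the 1.96 normal quantile; the
# odds-ratio scale is the exponential of the log-scale interval.
make_estimate <- function(method, beta, se, n_snps) {
  z <- stats::qnorm(0.975)
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = beta - z * se, ci_high = beta + z * se,
         pvalue = 2 * stats::pnorm(-abs(beta / se)),
         n_snps = as.integer(n_snps),
         or = exp(beta), or_ci_low = exp(beta - z * se),
         or_ci_high = exp(beta + z * se)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs): beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high, x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$or_ci_low, ci_high = x$or_ci_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted mean of the Wald ratios, `sum(w theta) / sum(w)` with
#' `w = sigma^-2`; equivalent to weighted least squares of the outcome
#' effects on the exposure effects through the origin with weights
#' `se_out^-2`. The fixed-effect standard error is `sum(w)^-1/2`; under the
#' default multiplicative random-effects model it is inflated by
#' `max(1, sqrt(Q / (J - 1)))` where `Q` is Cochran's Q, so the model
#' reduces to fixed effects for under-dispersed instruments.
#'
#' @param r A [ratio_estimates] or [harmonized_set] (at least 2 variants).
#' @param re_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [`mr_estimate`][ratio_estimates] with method `"IVW"`.
#' @export
mr_ivw <- function(r, re_model = c("multiplicative_random", "fixed")) {
  re_model <- match.arg(re_model)
  r <- as_ratio_estimates(r)
  J <- length(r$theta)
  if (J < 2L) medmr_stop("IVW needs at least 2 instruments", "medmr_insufficient_instruments")
  w <- r$weights
  beta <- sum(w * r$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (re_model == "multiplicative_random") {
    q <- sum(w * (r$theta - beta)^2)
    se <- se * max(1, sqrt(q / (J - 1)))
  }
  make_estimate("IVW", beta, se, J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, weights `se_out^-2`, after orienting all pairs so exposure
#' effects are non-negative. The slope is the causal estimate; the intercept
#' estimates the average directional pleiotropy of the instruments, with a
#' two-sided normal test. Standard errors carry the same multiplicative
#' residual inflation as random-effects IVW (floored at the fixed-effect
#' value).
#'
#' @param h A [harmonized_set] (at least 3 variants).
#' @return A list of class `mr_egger`: `slope` (an `mr_estimate`, method
#'   `"Egger"`), `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  p <- h$pairs
  J <- nrow(p)
  if (J < 3L) medmr_stop("MR-Egger needs at least 3 instruments", "medmr_insufficient_instruments")
  flip <- sign(p$beta_exp)
  flip[flip == 0] <- 1
  bx <- p$beta_exp * flip
  by <- p$beta_out * flip
  w <- p$se_out^-2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma_hat <- summary(fit)$sigma
  # lm's coefficient SEs already include the residual scale; flooring the
  # scale at 1 keeps SEs no smaller than the fixed-effect ones. A perfect
  # fit (residual scale 0) falls back to the unscaled weighted-LS variance.
  if (sigma_hat > 0) {
    infl <- 1 / min(sigma_hat, 1)
    slope_se <- cf["bx", "Std. Error"] * infl
    int_se <- cf["(Intercept)", "Std. Error"] * infl
  } else {
    V <- solve(crossprod(sqrt(w) * cbind(1, bx)))
    int_se <- sqrt(V[1, 1])
    slope_se <- sqrt(V[2, 2])
  }
  intercept <- cf["(Intercept)", "Estimate"]
  structure(
    list(slope = make_estimate("Egger", cf["bx", "Estimate"], slope_se, J),
         intercept = intercept, intercept_se = int_se,
         intercept_p = 2 * stats::pnorm(-abs(intercept / int_se))),
    class = "mr_egger"
  )
}

# Weighted median of values `x` with weights `w`: order x ascending, form
# normalized cumulative weights s_j = cumsum(p)_j - p_j / 2, and linearly
# interpolate x against s at 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The weighted median of the Wald ratios: consistent even when up to 50%
#' of the instrument weight comes from invalid instruments. The standard
#' error comes from a parametric bootstrap that redraws each ratio from
#' `Normal(theta_j, sigma_j)` (weights held fixed).
#'
#' @param r A [ratio_estimates] or [harmonized_set] (at least 3 variants).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required).
#' @return An `mr_estimate` with method `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(r, n_boot = 1000, seed) {
  r <- as_ratio_estimates(r)
  J <- length(r$theta)
  if (J < 3L) medmr_stop("weighted median needs at least 3 instruments",
                         "medmr_insufficient_instruments")
  beta <- weighted_median_point(r$theta, r$weights)
  se <- boot_se(r, seed, n_boot, function(th) weighted_median_point(th, r$weights))
  make_estimate("WeightedMedian", beta, se, J)
}

boot_se <- function(r, seed, n_boot, statistic) {
  if (n_boot < 2L) medmr_stop("n_boot must be at least 2", "medmr_config_error")
  J <- length(r$theta)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      statistic(stats::rnorm(J, mean = r$theta, sd = r$sigma))
    }, numeric(1))
    stats::sd(reps)
  })
}

# Mode of a Gaussian-kernel-smoothed density of x with point masses w,
# evaluated on a fixed 512-point grid spanning [min - 3h, max + 3h].
kernel_mode_point <- function(x, w, bandwidth_factor = 1) {
  spread <- min(stats::sd(x), stats::IQR(x) / 1.349)
  h <- bandwidth_factor * 0.9 * spread * length(x)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(weighted_median_point(x, w))
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - x) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the kernel-smoothed empirical density of the Wald ratios:
#' consistent when the largest cluster of instruments is valid, even if the
#' majority are not. The simple mode weighs all ratios equally; the weighted
#' mode uses the inverse-variance weights. Bandwidth is
#' `bandwidth_factor * 0.9 * min(sd, IQR/1.349) * J^(-1/5)` (a Silverman
#' rule), the density is maximised over a fixed 512-point grid, and the
#' standard error comes from the same parametric bootstrap as the weighted
#' median. When all ratios coincide the density is degenerate and that
#' common value is returned.
#'
#' @param r A [ratio_estimates] or [harmonized_set] (at least 3 variants).
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform weights.
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required).
#' @return An `mr_estimate` with method `"WeightedMode"` or `"SimpleMode"`.
#' @export
mr_mode <- function(r, weighted = TRUE, bandwidth_factor = 1, n_boot = 1000, seed) {
  r <- as_ratio_estimates(r)
  J <- length(r$theta)
  if (J < 3L) medmr_stop("mode estimator needs at least 3 instruments",
                         "medmr_insufficient_instruments")
  w <- if (weighted) r$weights / sum(r$weights) else rep(1 / J, J)
  beta <- kernel_mode_point(r$theta, w, bandwidth_factor)
  se <- boot_se(r, seed, n_boot, function(th) kernel_mode_point(th, w, bandwidth_factor))
  make_estimate(if (weighted) "WeightedMode" else "SimpleMode", beta, se, J)
}

#' Run all five causal estimators
#'
#' Computes IVW, MR-Egger, weighted median, weighted mode and simple mode on
#' one harmonized set, plus a consistency flag that is set when all five
#' point estimates share one sign — the screening convention under which the
#' four auxiliary methods "agree" with the headline IVW estimate.
#'
#' @param h A [harmonized_set] (at least 3 variants; the mode and median
#'   estimators set the floor).
#' @param seed Seed for the bootstrap standard errors (required).
#' @param n_boot Bootstrap replicates per estimator (default 1000).
#' @return A list of class `mr_result`: `estimates` (named list of
#'   `mr_estimate`), `egger` (the full `mr_egger` fit), `consistent`
#'   (logical).
#' @export
mr_all <- function(h, seed, n_boot = 1000) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- ratio_estimates(h)
  seeds <- derive_seeds(seed, 3L)
  egger_fit <- mr_egger(h)
  est <- list(
    IVW = mr_ivw(r),
    Egger = egger_fit$slope,
    WeightedMedian = mr_weighted_median(r, n_boot = n_boot, seed = seeds[1]),
    WeightedMode = mr_mode(r, weighted = TRUE, n_boot = n_boot, seed = seeds[2]),
    SimpleMode = mr_mode(r, weighted = FALSE, n_boot = n_boot, seed = seeds[3])
  )
  betas <- vapply(est, function(e) e$beta, numeric(1))
  structure(
    list(estimates = est, egger = egger_fit,
         consistent = all(sign(betas) == sign(betas[1]))),
    class = "mr_result"
  )
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, as.data.frame))
}

#' @export
print.mr_result <- function(x, ...) {
  df <- as.data.frame(x)
  rownames(df) <- NULL
  print(df, digits = 4)
  cat(sprintf("consistent sign across methods: %s\n", x$consistent))
  invisible(x)
}
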