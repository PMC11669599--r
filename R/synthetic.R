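# Seeded generator of two-sample GWAS summary statistics with a known
# exposure -> mediator -> outcome causal structure.

#' Configuration for the synthetic GWAS triplet generator
#'
#' Defaults emulate the cohorts the package targets: a quantitative
#' immune-trait exposure (n = 3757), a quantitative metabolite mediator
#' (n = 8299) and a binary disease outcome (3597 cases / 364071 controls)
#' analysed on the log odds-ratio scale. Per-variant effects are drawn on
#' the standardized scale with `effect_sd = 0.1` (about 1% of trait variance
#' per instrument, instrument F around 38 at the exposure sample size), so
#' instruments are selectable at the conventional `P < 1e-5` screen.
#'
#' The implied total effect of the exposure on the outcome is
#' `theta_direct + alpha * b` and is recorded as ground truth.
#'
#' @param n_snps_exposure Number of exposure instruments.
#' @param n_snps_mediator Number of mediator-specific instruments (the
#'   mediator has its own genetic architecture, as a metabolite GWAS does).
#' @param n_exposure,n_mediator Sample sizes of the two quantitative GWAS.
#' @param n_outcome_cases,n_outcome_controls Outcome case/control counts
#'   (binary outcome) .
#' @param outcome_type `"binary"` (default) or `"quantitative"`.
#' @param n_outcome Sample size used when `outcome_type = "quantitative"`.
#' @param theta_direct Direct exposure-on-outcome effect (log-OR).
#' @param alpha Exposure-on-mediator effect.
#' @param b Mediator-on-outcome effect (log-OR).
#' @param effect_sd SD of true per-variant standardized effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean Mean of the pleiotropy distribution (must be 0
#'   unless directional; defaults to `pleiotropy_sd` under directional).
#' @param pleiotropy_sd SD of the pleiotropic outcome effects of invalid
#'   instruments.
#' @param prop_invalid Proportion of exposure instruments with a direct
#'   (pleiotropic) path to the outcome; must be 0 when `pleiotropy_mode`
#'   is `"none"`.
#' @param maf_range Range of minor-allele frequencies, within (0, 0.5].
#' @param ld_blocks Optional `list(size =, r2 =)`: exposure instruments are
#'   grouped into consecutive blocks of `size` variants in one clumping
#'   window with block-constant r-squared `r2`; default independent.
#' @param seed Master seed; identical config + seed gives identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps_exposure = 100, n_snps_mediator = 100,
                              n_exposure = 3757, n_mediator = 8299,
                              n_outcome_cases = 3597, n_outcome_controls = 364071,
                              outcome_type = c("binary", "quantitative"),
                              n_outcome = NULL,
                              theta_direct = 0, alpha = 0, b = 0,
                              effect_sd = 0.1,
                              pleiotropy_mode = c("none", "balanced", "directional"),
                              pleiotropy_mean = NULL, pleiotropy_sd = 0,
                              prop_invalid = 0,
                              maf_range = c(0.05, 0.5),
                              ld_blocks = NULL, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (pleiotropy_mode == "none" && prop_invalid != 0) {
    medmr_stop("prop_invalid must be 0 when pleiotropy_mode is 'none'",
               "medmr_config_error")
  }
  pleiotropy_mean <- pleiotropy_mean %||%
    switch(pleiotropy_mode, none = 0, balanced = 0, directional = pleiotropy_sd)
  if (pleiotropy_mode != "directional" && pleiotropy_mean != 0) {
    medmr_stop("nonzero pleiotropy_mean requires pleiotropy_mode = 'directional'",
               "medmr_config_error")
  }
  if (prop_invalid < 0 || prop_invalid > 1) {
    medmr_stop("prop_invalid must lie in [0, 1]", "medmr_config_error")
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    medmr_stop("maf_range must be (low, high) within (0, 0.5]", "medmr_config_error")
  }
  if (n_snps_exposure < 1) medmr_stop("need at least 1 exposure SNP", "medmr_config_error")
  if (!is.null(ld_blocks)) {
    if (!is.list(ld_blocks) || !all(c("size", "r2") %in% names(ld_blocks)) ||
        ld_blocks$size < 1 || ld_blocks$r2 < 0 || ld_blocks$r2 > 1) {
      medmr_stop("ld_blocks must be list(size >= 1, r2 in [0, 1])", "medmr_config_error")
    }
  }
  structure(
    list(n_snps_exposure = as.integer(n_snps_exposure),
         n_snps_mediator = as.integer(n_snps_mediator),
         n_exposure = as.integer(n_exposure), n_mediator = as.integer(n_mediator),
         n_outcome_cases = as.integer(n_outcome_cases),
         n_outcome_controls = as.integer(n_outcome_controls),
         outcome_type = outcome_type,
         n_outcome = as.integer(n_outcome %||% (n_outcome_cases + n_outcome_controls)),
         theta_direct = theta_direct, alpha = alpha, b = b,
         true_total = theta_direct + alpha * b,
         effect_sd = effect_sd,
         pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
         pleiotropy_sd = pleiotropy_sd, prop_invalid = prop_invalid,
         maf_range = maf_range, ld_blocks = ld_blocks, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# chromosome/position layout: each clumping block gets its own 20 Mb slot so
# distinct blocks are never within the default 10 Mb clumping window.
snp_layout <- function(n, block_size = 1L) {
  i <- seq_len(n)
  block <- (i - 1L) %/% block_size
  within <- (i - 1L) %% block_size
  data.frame(
    CHR = as.character((block %% 22L) + 1L),
    POS = as.integer(1e6 + (block %/% 22L) * 2e7 + within * 1e4),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-sample GWAS summary-statistics triplet
#'
#' Generates exposure, mediator and outcome summary statistics from three
#' non-overlapping cohorts with independent sampling noise (the two-sample
#' design's no-overlap assumption), directly on the summary level — no
#' individual genotypes are simulated.
#'
#' Exposure instruments carry true standardized effects
#' `u ~ Normal(0, effect_sd^2)` on the exposure; the mediator receives
#' `alpha * u` from them plus its own instruments' effects
#' `v ~ Normal(0, effect_sd^2)`; the outcome receives
#' `(theta_direct + alpha * b) * u` from exposure instruments and `b * v`
#' from mediator instruments. Invalid exposure instruments additionally get
#' a direct pleiotropic outcome effect drawn from
#' `Normal(pleiotropy_mean, pleiotropy_sd^2)` (directional when the mean is
#' nonzero), violating the exclusion assumption. Observed effects add noise
#' with standard error `1/sqrt(n)` on the standardized scale for
#' quantitative traits and `sqrt(1/ncase + 1/ncontrol)` for the binary
#' outcome; per-allele (raw) effects and standard errors divide by
#' `sqrt(2 p (1 - p))`. P-values, allele frequencies and sample sizes are
#' filled consistently. The LD matrix is the identity unless `ld_blocks` is
#' given, in which case block members share a constant r-squared.
#'
#' @param cfg A [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` ([summary_stats]),
#'   `truth` (class `ground_truth`: `true_total`, `true_direct`,
#'   `true_mediated`, `true_proportion`, `invalid_variant_ids`) and `ld`
#'   (an [ld_matrix]).
#' @export
simulate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    Je <- cfg$n_snps_exposure
    Jm <- cfg$n_snps_mediator
    J <- Je + Jm
    ids <- sprintf("rs%d", seq_len(J))
    is_exp_snp <- c(rep(TRUE, Je), rep(FALSE, Jm))

    maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
    scale <- sqrt(2 * maf * (1 - maf))

    u <- stats::rnorm(Je, 0, cfg$effect_sd)           # exposure instrument effects
    v <- if (Jm) stats::rnorm(Jm, 0, cfg$effect_sd) else numeric(0)

    n_invalid <- round(cfg$prop_invalid * Je)
    invalid <- sort(sample.int(Je, n_invalid))
    gamma <- numeric(Je)
    if (n_invalid > 0) {
      gamma[invalid] <- stats::rnorm(n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }

    beta_exp_true <- c(u, rep(0, Jm))
    beta_med_true <- c(cfg$alpha * u, v)
    beta_out_true <- c((cfg$theta_direct + cfg$alpha * cfg$b) * u + gamma, cfg$b * v)

    se_exp_std <- rep(1 / sqrt(cfg$n_exposure), J)
    se_med_std <- rep(1 / sqrt(cfg$n_mediator), J)
    se_out_std <- rep(if (cfg$outcome_type == "binary") {
      sqrt(1 / cfg$n_outcome_cases + 1 / cfg$n_outcome_controls)
    } else 1 / sqrt(cfg$n_outcome), J)

    layout <- snp_layout(J, block_size = if (is.null(cfg$ld_blocks)) 1L
                                         else as.integer(cfg$ld_blocks$size))

    one_trait <- function(beta_true_std, se_std, n, trait_id, trait_type) {
      beta_hat_std <- beta_true_std + stats::rnorm(J, 0, se_std)
      beta <- beta_hat_std / scale
      se <- se_std / scale
      p <- 2 * stats::pnorm(-abs(beta_hat_std / se_std))
      p[p == 0] <- .Machine$double.xmin
      summary_stats(
        trait_id = trait_id,
        records = data.frame(SNP = ids, CHR = layout$CHR, POS = layout$POS,
                             EA = "A", OA = "G", EAF = maf,
                             BETA = beta, SE = se, P = p, N = n,
                             stringsAsFactors = FALSE),
        trait_type = trait_type,
        metadata = list(source = "medmr synthetic generator"),
        quiet = TRUE
      )
    }

    exposure <- one_trait(beta_exp_true, se_exp_std, cfg$n_exposure,
                          "synthetic_exposure", "quantitative")
    mediator <- one_trait(beta_med_true, se_med_std, cfg$n_mediator,
                          "synthetic_mediator", "quantitative")
    outcome <- one_trait(beta_out_true, se_out_std, cfg$n_outcome,
                         "synthetic_outcome",
                         if (cfg$outcome_type == "binary") "binary" else "quantitative")

    r2m <- diag(1, J)
    dimnames(r2m) <- list(ids, ids)
    if (!is.null(cfg$ld_blocks) && cfg$ld_blocks$size > 1L) {
      bs <- as.integer(cfg$ld_blocks$size)
      block <- (seq_len(J) - 1L) %/% bs
      same_block <- outer(block, block, "==")
      r2m[same_block] <- cfg$ld_blocks$r2
      diag(r2m) <- 1
    }

    truth <- structure(
      list(true_total = cfg$true_total, true_direct = cfg$theta_direct,
           true_mediated = cfg$alpha * cfg$b,
           true_proportion = if (cfg$true_total != 0) {
             cfg$alpha * cfg$b / cfg$true_total
           } else NA_real_,
           invalid_variant_ids = ids[seq_len(Je)][invalid],
           true_beta_exp = stats::setNames(beta_exp_true / scale, ids),
           true_alpha = cfg$alpha, true_b = cfg$b),
      class = "ground_truth"
    )

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth, ld = ld_matrix(r2m))
  })
}

#' Small deterministic triplet fixture
#'
#' A 20-instrument exposure (plus 20 mediator-specific instruments) with a
#' planted mediated path — exposure-on-mediator effect -0.3,
#' mediator-on-outcome 0.25, direct effect -0.04, so the true mediated
#' proportion is about 65% of a total of -0.115 — and one invalid
#' (directionally pleiotropic) exposure instrument. The fixture is fully
#' deterministic and is used throughout the test suite and documentation.
#'
#' @return The list returned by [simulate_triplet()].
#' @export
fixture_small <- function() {
  simulate_triplet(simulation_config(
    n_snps_exposure = 20, n_snps_mediator = 20,
    alpha = -0.3, b = 0.25, theta_direct = -0.04,
    effect_sd = 0.15,
    pleiotropy_mode = "directional", pleiotropy_mean = 0.2,
    pleiotropy_sd = 0.02, prop_invalid = 0.05,
    seed = 101L
  ))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> total = %.4f, direct = %.4f, mediated = %.4f (proportion %.1f%%); %d invalid instrument(s)\n",
              x$true_total, x$true_direct, x$true_mediated,
              100 * x$true_proportion, length(x$invalid_variant_ids)))
  invisible(x)
}
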