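# End-to-end orchestration: forward MR with verdicts, and the crossed
# exposure x mediator mediation study.

#' Pipeline configuration
#'
#' Bundles every threshold of the workflow: the exposure instrument p-value
#' screen (`p_exposure = 1e-5`, used when genome-wide significant
#' instruments are too few), the genome-wide threshold for outcome
#' instruments in reverse MR (`p_outcome_instruments = 5e-8`), LD clumping
#' (`r2 = 0.001` within `window_kb = 10000`), the weak-instrument filter
#' (`f_min = 10`), the minimum instrument count (`min_snps = 3`), the
#' nominal level (`alpha = 0.05`) and the Bonferroni test counts for the
#' exposure and mediator screens.
#'
#' @param p_exposure,p_outcome_instruments,r2,window_kb,f_min,min_snps,alpha
#'   Workflow thresholds (defaults above).
#' @param n_tests_exposures,n_tests_mediators Bonferroni denominators for
#'   the two screens (default 1: no correction).
#' @param presso_sims MR-PRESSO simulation count (default 1000).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Master seed for all stochastic steps.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_exposure = 1e-5, p_outcome_instruments = 5e-8,
                            r2 = 0.001, window_kb = 10000, f_min = 10,
                            min_snps = 3, alpha = 0.05,
                            n_tests_exposures = 1, n_tests_mediators = 1,
                            presso_sims = 1000, n_boot = 1000, seed = 1L) {
  vals <- c(p_exposure = p_exposure, p_outcome = p_outcome_instruments,
            r2 = r2, window_kb = window_kb, f_min = f_min, alpha = alpha)
  if (any(vals <= 0)) medmr_stop("all thresholds must be positive", "medmr_config_error")
  if (min_snps < 2) medmr_stop("min_snps must be >= 2", "medmr_config_error")
  structure(
    list(p_exposure = p_exposure, p_outcome_instruments = p_outcome_instruments,
         r2 = r2, window_kb = window_kb, f_min = f_min, min_snps = min_snps,
         alpha = alpha, n_tests_exposures = n_tests_exposures,
         n_tests_mediators = n_tests_mediators, presso_sims = presso_sims,
         n_boot = n_boot, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Forward two-sample MR with sensitivity verdict
#'
#' Runs instrument selection, harmonization, all five estimators and the
#' sensitivity battery for one exposure-outcome pair, then assigns a
#' verdict: `"failed_sensitivity"` when the MR-PRESSO global test or the
#' Egger intercept test falls below `alpha` (evidence of horizontal
#' pleiotropy); otherwise the IVW p-value is classified against the
#' Bonferroni screen as `"significant_corrected"`, `"suggestive"` or
#' `"null"`.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param ld An [ld_matrix].
#' @param cfg A [pipeline_config()].
#' @param n_tests Bonferroni denominator (default `cfg$n_tests_exposures`).
#' @param p_threshold Instrument screen (default `cfg$p_exposure`).
#' @param presso_correction When MR-PRESSO flags outliers, remove them and
#'   recompute the estimates and the sensitivity battery on the pruned set
#'   (one round; the default). The verdict is assigned on the final set, so
#'   an exposure whose pleiotropy is fully explained by removable outliers
#'   is not discarded — the correction MR-PRESSO exists to provide.
#' @return List of class `forward_result`: `instruments`, `harmonized`,
#'   `estimates` (an `mr_result`), `sensitivity`, `verdict`, `consistent`,
#'   `outliers_removed`.
#' @export
run_forward <- function(exposure, outcome, ld, cfg = pipeline_config(),
                        n_tests = cfg$n_tests_exposures,
                        p_threshold = cfg$p_exposure,
                        presso_correction = TRUE) {
  sel <- select_instruments(exposure, ld, p_threshold = p_threshold,
                            f_threshold = cfg$f_min, min_snps = cfg$min_snps,
                            r2_threshold = cfg$r2, window_kb = cfg$window_kb)
  h <- harmonize(sel$stats, outcome)
  if (nrow(h$pairs) < cfg$min_snps) {
    medmr_stop(sprintf("'%s' -> '%s': only %d harmonized instrument(s)",
                       exposure$trait_id, outcome$trait_id, nrow(h$pairs)),
               "medmr_underpowered")
  }
  seeds <- derive_seeds(cfg$seed, 3L)
  sens <- sensitivity_battery(h, seed = seeds[2], n_sim = cfg$presso_sims)
  outliers_removed <- character(0)
  if (presso_correction && !is.null(sens$presso) && length(sens$presso$outliers) &&
      nrow(h$pairs) - length(sens$presso$outliers) >= cfg$min_snps) {
    outliers_removed <- sens$presso$outliers
    h$pairs <- h$pairs[!(h$pairs$SNP %in% outliers_removed), , drop = FALSE]
    sens <- sensitivity_battery(h, seed = seeds[3], n_sim = cfg$presso_sims)
  }
  est <- mr_all(h, seed = seeds[1], n_boot = cfg$n_boot)
  pleio <- (!is.null(sens$presso) && sens$presso$global_p < cfg$alpha) ||
    sens$egger_intercept_p < cfg$alpha
  verdict <- if (pleio) "failed_sensitivity"
             else classify_pvalue(est$estimates$IVW$pvalue, n_tests, cfg$alpha)
  structure(
    list(instruments = sel, harmonized = h, estimates = est,
         sensitivity = sens, verdict = verdict, consistent = est$consistent,
         outliers_removed = outliers_removed),
    class = "forward_result"
  )
}

#' @export
print.forward_result <- function(x, ...) {
  ivw <- x$estimates$estimates$IVW
  cat(sprintf("<forward_result> %s -> %s: IVW OR = %.3f [%.3f, %.3f], p = %.3g; verdict: %s\n",
              x$harmonized$exposure_id, x$harmonized$outcome_id,
              ivw$or, ivw$or_ci_low, ivw$or_ci_high, ivw$pvalue, x$verdict))
  invisible(x)
}

#' Run the full two-step mediation study
#'
#' The complete workflow: forward-screens every exposure and every mediator
#' against the outcome; crosses the survivors (exposures with IVW `p <
#' alpha` whose sensitivity battery did not fail, likewise mediators);
#' estimates the exposure-on-mediator leg for each surviving pair; runs
#' [two_step_mediation()] with [reverse_mr_guard()] on both candidate
#' links; and returns a report ranked by absolute mediated proportion, with
#' Bonferroni labels at the configured screen sizes. Per-pair failures are
#' logged and the run continues.
#'
#' Shared exposure instruments are excluded from every mediator's
#' instrument set (`exclude_shared = TRUE`, the default): a variant that
#' instruments the exposure affects the outcome through the exposure's
#' direct path as well, so its mediator-leg Wald ratio is biased by
#' `theta_direct / alpha` and it violates the exclusion assumption for
#' that leg.
#'
#' @param exposures,mediators Named lists of [summary_stats].
#' @param outcome Outcome [summary_stats].
#' @param ld An [ld_matrix].
#' @param cfg A [pipeline_config()].
#' @param exclude_shared Drop the exposures' selected instruments from the
#'   mediators' summary statistics before mediator instrument selection.
#' @return List of class `mediation_study`: `report` (ranked data frame),
#'   `forward_exposures`, `forward_mediators` (per-trait verdict tables),
#'   `log` (character vector of skipped/failed steps).
#' @export
run_mediation_study <- function(exposures, mediators, outcome, ld,
                                cfg = pipeline_config(), exclude_shared = TRUE) {
  log <- character(0)

  exposure_instruments <- unique(unlist(lapply(exposures, function(e) {
    tryCatch(select_instruments(e, ld, p_threshold = cfg$p_exposure,
                                f_threshold = cfg$f_min, min_snps = cfg$min_snps,
                                r2_threshold = cfg$r2,
                                window_kb = cfg$window_kb)$variant_ids,
             medmr_error = function(e2) character(0))
  })))
  # pruned copies are used only where the mediator is the instrument
  # *source*; leg-1 harmonization still needs the mediator's associations
  # at the exposure's instruments
  mediators_iv <- mediators
  if (exclude_shared && length(exposure_instruments)) {
    mediators_iv <- lapply(mediators, function(m) {
      m$records <- m$records[!(m$records$SNP %in% exposure_instruments), ,
                             drop = FALSE]
      m
    })
  }
  screen_one <- function(stats_list, n_tests, label) {
    rows <- list()
    results <- list()
    for (id in names(stats_list)) {
      fr <- tryCatch(run_forward(stats_list[[id]], outcome, ld, cfg, n_tests = n_tests),
                     medmr_error = function(e) e)
      if (inherits(fr, "condition")) {
        log <<- c(log, sprintf("%s '%s': %s", label, id, conditionMessage(fr)))
        next
      }
      ivw <- fr$estimates$estimates$IVW
      rows[[id]] <- data.frame(
        trait = id, nsnp = ivw$n_snps, beta = ivw$beta, se = ivw$se,
        or = ivw$or, ci_low = ivw$or_ci_low, ci_high = ivw$or_ci_high,
        pvalue = ivw$pvalue, consistent = fr$consistent,
        verdict = fr$verdict, stringsAsFactors = FALSE
      )
      results[[id]] <- fr
    }
    list(table = if (length(rows)) do.call(rbind, rows) else data.frame(),
         results = results)
  }

  fe <- screen_one(exposures, cfg$n_tests_exposures, "exposure")
  fm <- screen_one(mediators_iv, cfg$n_tests_mediators, "mediator")

  surviving <- function(screen) {
    tb <- screen$table
    if (!nrow(tb)) return(character(0))
    tb$trait[tb$pvalue < cfg$alpha & tb$verdict != "failed_sensitivity"]
  }
  keep_e <- surviving(fe)
  keep_m <- surviving(fm)

  rows <- list()
  for (ei in keep_e) {
    total <- fe$results[[ei]]$estimates$estimates$IVW
    for (mi in keep_m) {
      leg1 <- tryCatch({
        sel <- select_instruments(exposures[[ei]], ld, p_threshold = cfg$p_exposure,
                                  f_threshold = cfg$f_min, min_snps = cfg$min_snps,
                                  r2_threshold = cfg$r2, window_kb = cfg$window_kb)
        mr_ivw(harmonize(sel$stats, mediators[[mi]]))
      }, medmr_error = function(e) e)
      if (inherits(leg1, "condition")) {
        log <- c(log, sprintf("pair %s x %s: %s", ei, mi, conditionMessage(leg1)))
        next
      }
      if (leg1$pvalue >= cfg$alpha) next
      leg2 <- fm$results[[mi]]$estimates$estimates$IVW
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
        beta2 = med$beta2, se2 = med$se2,
        p2 = fm$table$pvalue[fm$table$trait == mi],
        total = med$total, se_total = med$se_total,
        p_total = fe$table$pvalue[fe$table$trait == ei],
        label_total = classify_pvalue(fe$table$pvalue[fe$table$trait == ei],
                                      cfg$n_tests_exposures, cfg$alpha),
        mediated = med$mediated, se_mediated = med$se_mediated,
        p_mediated = med$p_mediated, direct = med$direct,
        proportion = med$proportion,
        prop_ci_low = med$ci_proportion[1], prop_ci_high = med$ci_proportion[2],
        reverse_guard_exposure = g_exp$passes,
        reverse_guard_mediator = g_med$passes,
        unidirectional = isTRUE(g_exp$passes) && isTRUE(g_med$passes),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(report)) {
    report <- report[order(-abs(report$proportion), report$exposure, report$mediator), ,
                     drop = FALSE]
    rownames(report) <- NULL
  } else {
    medmr_warn("mediation study: no surviving exposure-mediator pairs", "medmr_empty_report")
  }
  structure(
    list(report = report, forward_exposures = fe$table, forward_mediators = fm$table,
         log = log),
    class = "mediation_study"
  )
}

#' @export
print.mediation_study <- function(x, ...) {
  cat(sprintf("<mediation_study> %d mediated pair(s); %d exposure(s), %d mediator(s) screened; %d step(s) logged\n",
              nrow(x$report), nrow(x$forward_exposures), nrow(x$forward_mediators),
              length(x$log)))
  if (nrow(x$report)) print(utils::head(x$report[c("exposure", "mediator", "mediated",
                                                   "proportion", "p_mediated")], 5),
                            digits = 4)
  invisible(x)
}

#' Write a mediation-study report to delimited text
#'
#' Serializes the ranked mediation report and the two forward screens to
#' tab-delimited files with stable numeric formatting, so identical studies
#' produce byte-identical files.
#'
#' @param study A `mediation_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "mediation_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(df, name) {
    path <- file.path(dir, name)
    df2 <- df
    for (cn in names(df2)) {
      if (is.numeric(df2[[cn]])) df2[[cn]] <- sprintf("%.12g", df2[[cn]])
    }
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(paste(names(df2), collapse = "\t"), con)
    if (nrow(df2)) writeLines(do.call(paste, c(df2, sep = "\t")), con)
    path
  }
  paths <- c(write_one(study$report, "mediation_report.tsv"),
             write_one(study$forward_exposures, "forward_exposures.tsv"),
             write_one(study$forward_mediators, "forward_mediators.tsv"))
  invisible(paths)
}
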