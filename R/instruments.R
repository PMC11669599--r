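# Instrument selection: p-value thresholding, greedy LD clumping,
# F-statistic strength filtering.

#' Construct an LD matrix
#'
#' Square symmetric matrix of pairwise r-squared values with unit diagonal,
#' row/column names giving the variant ids.
#'
#' @param r2 Numeric square matrix.
#' @param variant_ids Character vector of ids (defaults to `rownames(r2)`).
#' @return A validated matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  attr(r2, "class") <- NULL
  if (is.null(variant_ids)) {
    medmr_stop("LD matrix needs variant ids (rownames or `variant_ids`)",
               "medmr_input_error")
  }
  dimnames(r2) <- list(variant_ids, variant_ids)
  if (nrow(r2) != ncol(r2)) {
    medmr_stop("LD matrix must be square", "medmr_input_error")
  }
  if (!isSymmetric(unname(r2), tol = 1e-8)) {
    medmr_stop("LD matrix must be symmetric", "medmr_input_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    medmr_stop("LD matrix diagonal must be 1", "medmr_input_error")
  }
  if (any(r2 < 0 | r2 > 1 + 1e-12)) {
    medmr_stop("LD r-squared values must lie in [0, 1]", "medmr_input_error")
  }
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read an LD matrix from delimited text
#'
#' Two layouts are accepted: a square matrix with a header row of variant
#' ids (tab- or comma-delimited), or a three-column triplet list
#' `id1, id2, r2` (diagonal entries implied; unlisted pairs r2 = 0).
#'
#' @param path Path to the file.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) medmr_stop(sprintf("file not found: %s", path), "medmr_input_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) == 3L && all(tolower(names(df)) %in% c("id1", "id2", "r2"))) {
    names(df) <- tolower(names(df))
    ids <- sort(unique(c(df$id1, df$id2)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(df$id1, ids); j <- match(df$id2, ids)
    m[cbind(i, j)] <- df$r2
    m[cbind(j, i)] <- df$r2
    diag(m) <- 1
    ld_matrix(m)
  } else {
    m <- as.matrix(df)
    rownames(m) <- colnames(m)
    storage.mode(m) <- "double"
    ld_matrix(m)
  }
}

#' Filter records by association p-value
#'
#' Keeps records with `P` strictly below `threshold` (a p-value exactly at
#' the threshold is excluded); input order is preserved. An empty result is
#' allowed and flagged downstream.
#'
#' @param stats A [summary_stats] object.
#' @param threshold P-value threshold in (0, 1).
#' @return A [summary_stats] object with the surviving records.
#' @export
select_by_pvalue <- function(stats, threshold) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    medmr_stop("`threshold` must lie in (0, 1)", "medmr_domain_error")
  }
  out <- stats
  out$records <- stats$records[stats$records$P < threshold, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index variant and removes all remaining variants on the same chromosome
#' within `window_kb` of it whose r-squared with the index exceeds
#' `r2_threshold`; iterates until no variants remain. Only index variants
#' are returned. P-value ties are broken by (chromosome, position, variant
#' id) so the result is invariant to input row order. Variants absent from
#' `ld` are treated as unlinked (r-squared 0) with a warning.
#'
#' @param stats A [summary_stats] object.
#' @param ld An [ld_matrix] covering (ideally) all variants in `stats`.
#' @param r2_threshold Clumping r-squared threshold (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return A [summary_stats] object containing the index variants, in
#'   selection order.
#' @export
clump <- function(stats, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  ld <- ld_matrix(ld)
  df <- stats$records
  if (nrow(df) == 0L) return(stats)

  missing_ld <- setdiff(df$SNP, rownames(ld))
  if (length(missing_ld)) {
    medmr_warn(sprintf("clump: %d variant(s) absent from LD matrix treated as unlinked",
                       length(missing_ld)), "medmr_missing_ld")
  }
  # deterministic candidate order: p, then chr, pos, id
  ord <- order(df$P, df$CHR, df$POS, df$SNP)
  df <- df[ord, , drop = FALSE]
  remaining <- seq_len(nrow(df))
  keep <- integer(0)
  while (length(remaining)) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    same_chr <- df$CHR[remaining] == df$CHR[idx]
    in_window <- same_chr &
      abs(df$POS[remaining] - df$POS[idx]) <= window_kb * 1000
    r2 <- rep(0, length(remaining))
    if (df$SNP[idx] %in% rownames(ld)) {
      present <- df$SNP[remaining] %in% rownames(ld)
      r2[present] <- ld[df$SNP[idx], df$SNP[remaining][present]]
    }
    drop <- in_window & r2 > r2_threshold
    remaining <- remaining[!drop]
  }
  out <- stats
  out$records <- df[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Variance in the trait explained by a single variant
#'
#' For a standardized trait, a variant with effect-allele frequency `p` and
#' per-allele effect `beta` explains `2 p (1 - p) beta^2 / trait_variance`
#' of the trait variance. When the allele frequency is missing the
#' approximation `beta^2 / (beta^2 + n se^2)` is used instead. Results are
#' clipped to `[0, 1)`.
#'
#' @param records Data frame of variant records (columns `EAF, BETA, SE, N`)
#'   or the `records` of a [summary_stats] object.
#' @param trait_variance Trait variance (default 1, standardized trait).
#' @return Numeric vector of per-variant r-squared values.
#' @export
per_snp_r2 <- function(records, trait_variance = 1) {
  if (inherits(records, "summary_stats")) records <- records$records
  eaf <- records$EAF; beta <- records$BETA; se <- records$SE; n <- records$N
  have_eaf <- !is.na(eaf)
  have_fallback <- is.finite(beta) & is.finite(se) & !is.na(n)
  if (any(!have_eaf & !have_fallback)) {
    medmr_stop("per_snp_r2: need EAF or (BETA, SE, N) for every record",
               "medmr_input_error")
  }
  r2 <- ifelse(have_eaf,
               2 * eaf * (1 - eaf) * beta^2 / trait_variance,
               beta^2 / (beta^2 + n * se^2))
  pmin(pmax(r2, 0), 1 - .Machine$double.eps)
}

#' Instrument-strength F-statistic
#'
#' `F = [R^2 (n - k - 1)] / [k (1 - R^2)]`, where `R^2` is the proportion of
#' exposure variance explained by the instrument(s), `n` the GWAS sample
#' size and `k` the number of variants. F below 10 conventionally flags a
#' weak instrument.
#'
#' @param r2 Proportion of variance explained, in `[0, 1)`.
#' @param n GWAS sample size (`n > k + 1`).
#' @param k Number of variants (default 1: each variant judged alone).
#' @return The F-statistic (vectorized over `r2` and `n`).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) medmr_stop("r2 must lie in [0, 1)", "medmr_domain_error")
  if (any(n <= k + 1)) medmr_stop("need n > k + 1", "medmr_domain_error")
  if (any(k < 1)) medmr_stop("need k >= 1", "medmr_domain_error")
  (r2 * (n - k - 1)) / (k * (1 - r2))
}

#' Select independent, strong instruments for an exposure
#'
#' Applies, in order: the p-value filter (`P < p_threshold`), greedy LD
#' clumping ([clump()]), and a per-variant F-statistic filter (each variant
#' judged alone, `k = 1`; variants with `F < f_threshold` removed). Counts
#' surviving variants at every stage. If fewer than `min_snps` variants
#' survive, an error of class `medmr_underpowered` is raised so callers can
#' skip the exposure, as a screen across many exposures would.
#'
#' @param stats Exposure [summary_stats].
#' @param ld An [ld_matrix].
#' @param p_threshold Association p-value threshold (e.g. `1e-5` for weakly
#'   powered exposures, `5e-8` genome-wide).
#' @param f_threshold Minimum per-variant F (default 10).
#' @param min_snps Minimum surviving instruments (default 3).
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.001, 10000).
#' @param trait_variance Passed to [per_snp_r2()].
#' @return An object of class `instrument_set`: the surviving records plus
#'   `per_snp_f`, `r2_explained`, the overall-set F (`k =` number of
#'   variants, informational) and a `selection_log` of per-stage counts.
#' @export
select_instruments <- function(stats, ld, p_threshold = 1e-5, f_threshold = 10,
                               min_snps = 3, r2_threshold = 0.001,
                               window_kb = 10000, trait_variance = 1) {
  stopifnot(inherits(stats, "summary_stats"))
  log0 <- c(input = nrow(stats$records))
  sel <- select_by_pvalue(stats, p_threshold)
  log1 <- c(log0, pvalue = nrow(sel$records))
  cl <- if (nrow(sel$records)) clump(sel, ld, r2_threshold, window_kb) else sel
  log2 <- c(log1, clump = nrow(cl$records))
  if (nrow(cl$records)) {
    r2 <- per_snp_r2(cl$records, trait_variance)
    f <- f_statistic(r2, cl$records$N, k = 1)
    keep <- f >= f_threshold
    cl$records <- cl$records[keep, , drop = FALSE]
    r2 <- r2[keep]; f <- f[keep]
    rownames(cl$records) <- NULL
  } else {
    r2 <- f <- numeric(0)
  }
  log3 <- c(log2, f_filter = nrow(cl$records))
  if (nrow(cl$records) < min_snps) {
    medmr_stop(sprintf(
      "exposure '%s': only %d instrument(s) survive selection (need >= %d) [input %d, p<%g: %d, clump: %d, F>=%g: %d]",
      stats$trait_id, nrow(cl$records), min_snps, log3[["input"]],
      p_threshold, log3[["pvalue"]], log3[["clump"]], f_threshold, log3[["f_filter"]]),
      "medmr_underpowered")
  }
  overall_r2 <- min(sum(r2), 1 - .Machine$double.eps)
  k_all <- nrow(cl$records)
  overall_f <- if (min(cl$records$N) > k_all + 1) {
    f_statistic(overall_r2, min(cl$records$N), k = k_all)
  } else NA_real_
  structure(
    list(exposure_id = stats$trait_id, stats = cl,
         variant_ids = cl$records$SNP, per_snp_f = f, r2_explained = r2,
         overall_f = overall_f, selection_log = log3),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> '%s': %d instruments (min F = %.1f)\n",
              x$exposure_id, length(x$variant_ids),
              if (length(x$per_snp_f)) min(x$per_snp_f) else NA))
  cat("  stages: ", paste(sprintf("%s=%d", names(x$selection_log), x$selection_log),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}
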