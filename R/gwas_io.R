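# Reading, validating, writing GWAS summary statistics; exposure-outcome
# harmonization.

STANDARD_COLUMNS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
MANDATORY_COLUMNS <- setdiff(STANDARD_COLUMNS, "EAF")

#' Construct a summary-statistics object
#'
#' Container for per-variant association records of one GWAS trait. Records
#' are validated against the variant-record invariants: single-base alleles
#' (A/C/G/T, upper-cased), effect allele distinct from the other allele,
#' positive standard error, p-value in (0, 1], positive sample size, and —
#' when present — effect-allele frequency strictly inside (0, 1). Rows that
#' violate an invariant are dropped and counted; indels and multi-allelic
#' records are rejected the same way.
#'
#' @param trait_id Trait identifier (string).
#' @param records `data.frame` with columns `SNP, CHR, POS, EA, OA, EAF,
#'   BETA, SE, P, N` (`EAF` may be absent or `NA`).
#' @param trait_type `"quantitative"` or `"binary"`. For binary traits
#'   `BETA` is on the log odds-ratio scale.
#' @param metadata Free-form named list (source, genome build, ...).
#' @param quiet Suppress the dropped-row message.
#' @return An object of class `summary_stats` with elements `trait_id`,
#'   `trait_type`, `records`, `metadata`, `n_dropped`.
#' @export
summary_stats <- function(trait_id, records, trait_type = c("quantitative", "binary"),
                          metadata = list(), quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(records)) {
    medmr_stop("`records` must be a data.frame", "medmr_input_error")
  }
  if (!("EAF" %in% names(records))) records$EAF <- NA_real_
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols)) {
    medmr_stop(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "medmr_config_error")
  }
  records <- records[STANDARD_COLUMNS]
  records$SNP <- as.character(records$SNP)
  records$CHR <- as.character(records$CHR)
  records$POS <- as.integer(records$POS)
  records$EA <- toupper(as.character(records$EA))
  records$OA <- toupper(as.character(records$OA))
  for (col in c("EAF", "BETA", "SE", "P")) records[[col]] <- as.numeric(records[[col]])
  records$N <- as.integer(records$N)

  ok <- valid_variant_rows(records)
  n_dropped <- sum(!ok)
  if (n_dropped > 0 && !quiet) {
    message(sprintf("summary_stats('%s'): dropped %d invalid record(s)", trait_id, n_dropped))
  }
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L) {
    medmr_stop(sprintf("trait '%s': no valid records", trait_id), "medmr_input_error")
  }
  if (anyDuplicated(records$SNP)) {
    medmr_stop(sprintf("trait '%s': duplicated variant ids", trait_id), "medmr_input_error")
  }
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         metadata = metadata, n_dropped = n_dropped),
    class = "summary_stats"
  )
}

valid_variant_rows <- function(df) {
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(df$SNP) & nzchar(df$SNP) &
    df$EA %in% bases & df$OA %in% bases & df$EA != df$OA &
    is.finite(df$BETA) &
    is.finite(df$SE) & df$SE > 0 &
    is.finite(df$P) & df$P > 0 & df$P <= 1 &
    !is.na(df$N) & df$N > 0L &
    !is.na(df$POS) & df$POS > 0L & !is.na(df$CHR)
  eaf_bad <- !is.na(df$EAF) & !(df$EAF > 0 & df$EAF < 1)
  ok & !eaf_bad
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s): %d variants (%d dropped at read)\n",
              x$trait_id, x$trait_type, nrow(x$records), x$n_dropped))
  invisible(x)
}

#' Number of variant records
#' @param x A `summary_stats` object.
#' @export
n_variants <- function(x) nrow(x$records)

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts tab- or comma-delimited text with a header. Standard column names
#' are `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`; non-standard headers are
#' remapped through `column_map`. Leading `# key: value` comment lines (as
#' written by [write_summary_stats()]) supply `trait_id`, `trait_type` and
#' metadata unless overridden by arguments. Rows failing the variant-record
#' invariants are dropped and counted.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping standard field names to
#'   the file's column names, e.g. `c(SNP = "rsid", BETA = "effect")`.
#' @param trait_id,trait_type,metadata Override values parsed from the file
#'   header (defaults: file name, `"quantitative"`).
#' @param quiet Suppress the dropped-row message.
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL,
                               trait_type = NULL, metadata = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    medmr_stop(sprintf("file not found: %s", path), "medmr_input_error")
  }
  lines <- readLines(path, n = 200L)
  header_meta <- parse_header_comments(lines)
  first_data <- grep("^[^#]", lines)[1]
  if (is.na(first_data)) medmr_stop("no data lines in file", "medmr_input_error")
  sep <- if (grepl("\t", lines[first_data])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!(src %in% names(df))) {
        medmr_stop(sprintf("column_map: column '%s' (for %s) not in file", src, std),
                   "medmr_config_error")
      }
      names(df)[names(df) == src] <- std
    }
  }
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols)) {
    medmr_stop(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "medmr_config_error")
  }
  summary_stats(
    trait_id = trait_id %||% header_meta$trait_id %||% basename(path),
    records = df,
    trait_type = (trait_type %||% header_meta$trait_type %||% "quantitative"),
    metadata = metadata %||% header_meta$metadata %||% list(),
    quiet = quiet
  )
}

parse_header_comments <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list(trait_id = NULL, trait_type = NULL, metadata = list())
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (key == "trait_id") out$trait_id <- val
      else if (key == "trait_type") out$trait_type <- val
      else out$metadata[[key]] <- val
    }
  }
  out
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes trait id, trait type and metadata as leading `# key: value`
#' comment lines, then a header and one row per variant. Numeric fields are
#' written with full precision so `read_summary_stats(write_summary_stats(x))`
#' reproduces `x` field-for-field, and rewriting the same object is
#' byte-stable.
#'
#' @param stats A [summary_stats] object.
#' @param path Output path.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    medmr_stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
               "medmr_io_error")
  })
  on.exit(close(con))
  hdr <- c(sprintf("# trait_id: %s", stats$trait_id),
           sprintf("# trait_type: %s", stats$trait_type))
  if (length(stats$metadata)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(stats$metadata),
                          vapply(stats$metadata, as.character, "")))
  }
  df <- stats$records
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  body <- paste(df$SNP, df$CHR, df$POS, df$EA, df$OA, fmt_num(df$EAF),
                fmt_num(df$BETA), fmt_num(df$SE), fmt_num(df$P), df$N,
                sep = "\t")
  writeLines(c(hdr, paste(STANDARD_COLUMNS, collapse = "\t"), body), con = con)
  invisible(path)
}

# ---- harmonization -----------------------------------------------------

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
  (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by id, aligns the outcome effect to the exposure's
#' effect allele, and drops variants whose strand cannot be resolved.
#' When the outcome's alleles are swapped relative to the exposure the
#' outcome beta is negated and its effect-allele frequency replaced by its
#' complement. Palindromic variants (A/T or C/G in either orientation) carry
#' no strand information in their allele labels and are removed when
#' `drop_palindromic` is set (the default), regardless of allele frequency.
#' Variants whose allele sets cannot be reconciled by a swap are dropped and
#' counted as unmatched.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param drop_palindromic Remove palindromic variants (default `TRUE`).
#' @return An object of class `harmonized_set` with elements `exposure_id`,
#'   `outcome_id`, `pairs` (data.frame with columns `SNP, beta_exp, se_exp,
#'   beta_out, se_out, eaf_exp, eaf_out, p_exp, p_out`),
#'   `n_dropped_palindromic` and `n_dropped_unmatched`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  ex <- exposure$records
  ou <- outcome$records
  common <- intersect(ex$SNP, ou$SNP)
  ex <- ex[match(common, ex$SNP), , drop = FALSE]
  ou <- ou[match(common, ou$SNP), , drop = FALSE]

  pal <- is_palindromic(ex$EA, ex$OA) | is_palindromic(ou$EA, ou$OA)
  same <- ex$EA == ou$EA & ex$OA == ou$OA
  swapped <- ex$EA == ou$OA & ex$OA == ou$EA

  keep_pal <- if (drop_palindromic) !pal else rep(TRUE, length(pal))
  matched <- (same | swapped) & keep_pal
  n_pal <- if (drop_palindromic) sum(pal & (same | swapped)) else 0L
  n_unmatched <- sum(!(same | swapped))

  ex <- ex[matched, , drop = FALSE]
  ou <- ou[matched, , drop = FALSE]
  sw <- swapped[matched]

  beta_out <- ifelse(sw, -ou$BETA, ou$BETA)
  eaf_out <- ifelse(sw, 1 - ou$EAF, ou$EAF)

  pairs <- data.frame(
    SNP = ex$SNP, CHR = ex$CHR, POS = ex$POS,
    EA = ex$EA, OA = ex$OA,
    beta_exp = ex$BETA, se_exp = ex$SE,
    beta_out = beta_out, se_out = ou$SE,
    eaf_exp = ex$EAF, eaf_out = eaf_out,
    p_exp = ex$P, p_out = ou$P,
    n_exp = ex$N, n_out = ou$N,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L) {
    medmr_stop(sprintf(
      "harmonize('%s','%s'): no surviving pairs (%d common, %d palindromic dropped, %d unmatched)",
      exposure$trait_id, outcome$trait_id, length(common), n_pal, n_unmatched),
      "medmr_empty_harmonization")
  }
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         pairs = pairs,
         n_dropped_palindromic = as.integer(n_pal),
         n_dropped_unmatched = as.integer(n_unmatched)),
    class = "harmonized_set"
  )
}

#' Construct a harmonized set from aligned effect estimates
#'
#' Builds a `harmonized_set` directly from vectors of already-aligned
#' exposure and outcome effects — useful for simulation studies and for
#' feeding externally harmonized data straight to the estimators. All
#' effects must refer to the same effect allele per variant; no allele
#' checking is performed here.
#'
#' @param snp Variant ids (unique).
#' @param beta_exp,se_exp Exposure effects and standard errors.
#' @param beta_out,se_out Outcome effects and standard errors.
#' @param eaf Effect-allele frequency (optional).
#' @param exposure_id,outcome_id Trait labels.
#' @return A `harmonized_set` (see [harmonize()]).
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf = NA_real_, exposure_id = "exposure",
                           outcome_id = "outcome") {
  snp <- as.character(snp)
  if (anyDuplicated(snp)) medmr_stop("duplicated variant ids", "medmr_input_error")
  if (any(se_exp <= 0) || any(se_out <= 0)) {
    medmr_stop("standard errors must be positive", "medmr_input_error")
  }
  pairs <- data.frame(
    SNP = snp, CHR = NA_character_, POS = NA_integer_, EA = "A", OA = "G",
    beta_exp = beta_exp, se_exp = se_exp, beta_out = beta_out, se_out = se_out,
    eaf_exp = eaf, eaf_out = eaf, p_exp = NA_real_, p_out = NA_real_,
    n_exp = NA_integer_, n_out = NA_integer_, stringsAsFactors = FALSE
  )
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id, pairs = pairs,
         n_dropped_palindromic = 0L, n_dropped_unmatched = 0L),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d pairs (%d palindromic, %d unmatched dropped)\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs),
              x$n_dropped_palindromic, x$n_dropped_unmatched))
  invisible(x)
}
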