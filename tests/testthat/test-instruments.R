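# Instrument selection: p-value filter, clumping, strength statistics.

test_that("select_by_pvalue uses strict inequality and preserves order", {
  df <- make_records(3)
  df$P <- c(1e-6, 1e-4, 1e-5)
  ss <- summary_stats("t", df, quiet = TRUE)
  kept <- select_by_pvalue(ss, 1e-5)
  expect_equal(kept$records$SNP, "rs1")       # 1e-5 boundary excluded
  expect_equal(n_variants(select_by_pvalue(ss, 5e-8)), 0L)
  expect_error(select_by_pvalue(ss, 0), class = "medmr_domain_error")
})

test_that("clump keeps the strongest variant in a linked window and respects chromosomes", {
  df <- make_records(2)
  df$CHR <- "1"; df$POS <- c(1000000L, 1005000L)     # 5 kb apart
  df$P <- c(1e-8, 1e-6)
  ld <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2), c("rs1", "rs2"))
  ss <- summary_stats("t", df, quiet = TRUE)
  expect_equal(clump(ss, ld)$records$SNP, "rs1")

  # different chromosomes: LD entry irrelevant, both kept
  df2 <- df; df2$CHR <- c("1", "2")
  ld2 <- ld_matrix(matrix(c(1, 0.9, 0.9, 1), 2), c("rs1", "rs2"))
  expect_setequal(clump(summary_stats("t", df2, quiet = TRUE), ld2)$records$SNP,
                  c("rs1", "rs2"))

  expect_error(ld_matrix(matrix(c(1, 0.2, 0.5, 1), 2), c("a", "b")),
               class = "medmr_input_error")   # asymmetric
  expect_error(ld_matrix(matrix(c(1, 0, 0, 0.5), 2), c("a", "b")),
               class = "medmr_input_error")   # bad diagonal
})

test_that("clump matches a brute-force greedy oracle and is row-order invariant", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- 10
    df <- make_records(n, seed = seed)
    df$CHR <- as.character(sample(1:2, n, replace = TRUE))
    df$POS <- as.integer(sample.int(3e7, n))
    df$P <- runif(n, 1e-10, 1e-3)
    A <- matrix(runif(n * n), n)
    r2 <- (A + t(A)) / 2
    diag(r2) <- 1
    ld <- ld_matrix(r2, df$SNP)
    ss <- summary_stats("t", df, quiet = TRUE)
    got <- clump(ss, ld, r2_threshold = 0.3, window_kb = 5000)$records$SNP
    expect_identical(got, oracle_clump(df, ld, 0.3, 5000))
    shuf <- summary_stats("t", df[sample.int(n), ], quiet = TRUE)
    expect_identical(clump(shuf, ld, r2_threshold = 0.3, window_kb = 5000)$records$SNP,
                     got)
  }
})

test_that("clump treats variants missing from the LD matrix as unlinked", {
  df <- make_records(3)
  df$CHR <- "1"; df$POS <- c(1e6, 1.1e6, 1.2e6); df$P <- c(1e-8, 1e-7, 1e-6)
  ld <- ld_matrix(matrix(c(1, 0.9, 0.9, 1), 2), c("rs1", "rs2"))
  ss <- summary_stats("t", df, quiet = TRUE)
  expect_warning(out <- clump(ss, ld), class = "medmr_missing_ld")
  expect_setequal(out$records$SNP, c("rs1", "rs3"))
})

test_that("per-variant r-squared follows the stated formulas", {
  rec <- make_records(3)
  rec$EAF <- c(0.5, 0.2, NA)
  rec$BETA <- c(0, 0.1, 0.1)
  rec$SE <- c(0.02, 0.02, 0.01)
  rec$N <- c(3757L, 3757L, 3757L)
  r2 <- per_snp_r2(rec)
  expect_equal(r2[1], 0)
  expect_equal(r2[2], 2 * 0.2 * 0.8 * 0.01)          # = 0.0032
  expect_equal(r2[3], 0.01 / (0.01 + 3757 * 1e-4))   # ~ 0.02594
  rec$EAF <- NA; rec$N <- NA_integer_
  expect_error(per_snp_r2(rec), class = "medmr_input_error")
})

test_that("F-statistic equals the printed formula", {
  expect_equal(f_statistic(0, 100), 0)
  expect_equal(f_statistic(0.01, 3757, 1), 0.01 * 3755 / 0.99)
  expect_equal(f_statistic(0.5, 103, 1), 101)
  expect_error(f_statistic(1, 100), class = "medmr_domain_error")
  expect_error(f_statistic(0.5, 2, 1), class = "medmr_domain_error")
})

test_that("select_instruments applies the filters in order with a monotone log", {
  trip <- simulate_triplet(simulation_config(n_snps_exposure = 50,
                                             n_snps_mediator = 0,
                                             effect_sd = 0.2, seed = 3))
  sel <- select_instruments(trip$exposure, trip$ld, p_threshold = 1e-5)
  log <- sel$selection_log
  expect_true(all(diff(log) <= 0))                 # stages only remove
  expect_true(all(sel$per_snp_f >= 10))
  expect_equal(length(sel$variant_ids), unname(log[["f_filter"]]))

  # a weak variant (per-SNP F ~ 5) is removed at the F stage
  weak <- trip$exposure
  i <- which(weak$records$SNP == sel$variant_ids[1])
  eaf <- weak$records$EAF[i]
  # choose beta so 2p(1-p)beta^2 gives F = 5 at this sample size
  r2_target <- 5 / (5 + weak$records$N[i] - 2)
  weak$records$BETA[i] <- sqrt(r2_target / (2 * eaf * (1 - eaf)))
  weak$records$P[i] <- 1e-8          # still passes the p filter
  sel2 <- select_instruments(weak, trip$ld, p_threshold = 1e-5)
  expect_false(sel$variant_ids[1] %in% sel2$variant_ids)
  expect_equal(unname(sel2$selection_log[["clump"]] - sel2$selection_log[["f_filter"]]), 1)
})

test_that("too few surviving instruments raises an underpowered condition", {
  trip <- simulate_triplet(simulation_config(n_snps_exposure = 30,
                                             n_snps_mediator = 0,
                                             effect_sd = 0.0, seed = 5))
  expect_error(select_instruments(trip$exposure, trip$ld, p_threshold = 1e-5),
               class = "medmr_underpowered")
})

test_that("LD matrix round-trips through both text layouts", {
  ids <- c("rs1", "rs2", "rs3")
  m <- matrix(c(1, 0.4, 0, 0.4, 1, 0.2, 0, 0.2, 1), 3, dimnames = list(ids, ids))
  sq <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(m, sq, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_ld_matrix(sq))[ids, ids], m)

  tr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id1,id2,r2", "rs1,rs2,0.4", "rs2,rs3,0.2"), tr)
  expect_equal(unclass(read_ld_matrix(tr))[ids, ids], m)
})
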