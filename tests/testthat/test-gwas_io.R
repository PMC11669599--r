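# Reading, validation, writing, harmonization.

test_that("summary_stats validates records and drops invalid rows", {
  df <- make_records(3)
  ss <- summary_stats("t", df, quiet = TRUE)
  expect_s3_class(ss, "summary_stats")
  expect_equal(n_variants(ss), 3L)
  expect_equal(ss$n_dropped, 0L)

  bad <- df
  bad$SE[1] <- 0                       # non-positive SE
  ss2 <- summary_stats("t", bad, quiet = TRUE)
  expect_equal(ss2$n_dropped, 1L)
  expect_false("rs1" %in% ss2$records$SNP)

  bad2 <- df
  bad2$EA[2] <- "AT"                   # indel rejected
  expect_equal(summary_stats("t", bad2, quiet = TRUE)$n_dropped, 1L)

  dup <- rbind(df, df[1, ])
  expect_error(summary_stats("t", dup, quiet = TRUE), class = "medmr_input_error")
  expect_error(summary_stats("t", df["SNP"], quiet = TRUE), class = "medmr_config_error")
})

test_that("lower-case alleles are normalized to upper case without drops", {
  df <- make_records(5)
  low <- df
  low$EA <- tolower(low$EA)
  low$OA <- tolower(low$OA)
  ss <- summary_stats("t", low, quiet = TRUE)
  expect_equal(ss$n_dropped, 0L)
  # oracle: straight toupper on the original table
  expect_identical(ss$records$EA, toupper(low$EA))
  expect_identical(ss$records$OA, toupper(low$OA))
})

test_that("write/read round-trip is the identity and rewriting is byte-stable", {
  ss <- make_stats(10, seed = 4, trait_id = "roundtrip",
                   metadata = list(source = "unit-test"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, quiet = TRUE)
  expect_equal(back$records, ss$records)
  expect_equal(back$trait_id, ss$trait_id)
  expect_equal(back$trait_type, ss$trait_type)
  expect_equal(back$metadata$source, "unit-test")

  # empty metadata still parses
  ss0 <- make_stats(3, seed = 5)
  path0 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss0, path0)
  expect_equal(read_summary_stats(path0, quiet = TRUE)$records, ss0$records)

  # byte stability on a larger synthetic set
  big <- simulate_triplet(simulation_config(n_snps_exposure = 500,
                                            n_snps_mediator = 0, seed = 9))$exposure
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_summary_stats(big, p1)
  write_summary_stats(read_summary_stats(p1, quiet = TRUE), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
})

test_that("read_summary_stats remaps columns and rejects broken input", {
  df <- make_records(4)
  names(df)[names(df) == "SNP"] <- "rsid"
  names(df)[names(df) == "BETA"] <- "effect"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  ss <- read_summary_stats(path, column_map = c(SNP = "rsid", BETA = "effect"),
                           quiet = TRUE)
  expect_equal(n_variants(ss), 4L)
  expect_error(read_summary_stats(path, quiet = TRUE), class = "medmr_config_error")

  allbad <- make_records(2)
  allbad$P <- 0                       # p-value outside (0, 1]
  pb <- withr::local_tempfile()
  utils::write.csv(allbad, pb, row.names = FALSE)
  expect_error(read_summary_stats(pb, quiet = TRUE), class = "medmr_input_error")
})

test_that("harmonize aligns, flips, and removes palindromic variants", {
  exp_df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                       CHR = "1", POS = 1:4 * 1000L,
                       EA = c("A", "A", "A", "A"), OA = c("G", "G", "T", "C"),
                       EAF = 0.2, BETA = 0.1, SE = 0.02, P = 1e-6, N = 1000L)
  out_df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                       CHR = "1", POS = 1:4 * 1000L,
                       EA = c("A", "G", "A", "C"), OA = c("G", "A", "T", "G"),
                       EAF = c(0.3, 0.7, 0.3, 0.3), BETA = 0.05, SE = 0.03,
                       P = 0.01, N = 2000L)
  ex <- summary_stats("e", exp_df, quiet = TRUE)
  ou <- summary_stats("o", out_df, quiet = TRUE)
  h <- harmonize(ex, ou)
  # rs3 (A/T) palindromic, rs4 exposure A/C vs outcome C/G unmatched
  expect_equal(h$pairs$SNP, c("rs1", "rs2"))
  expect_equal(h$n_dropped_palindromic, 1L)
  expect_equal(h$n_dropped_unmatched, 1L)
  expect_equal(h$pairs$beta_out, c(0.05, -0.05))      # rs2 allele-swapped
  expect_equal(h$pairs$eaf_out, c(0.3, 0.3))

  h_keep <- harmonize(ex, ou, drop_palindromic = FALSE)
  expect_true("rs3" %in% h_keep$pairs$SNP)

  # no overlap at all -> empty-set error with diagnostics
  ou2 <- ou; ou2$records$SNP <- paste0("x", ou2$records$SNP)
  expect_error(harmonize(ex, ou2), class = "medmr_empty_harmonization")
})

test_that("harmonization is idempotent and flip-antisymmetric", {
  set.seed(11)
  ex <- make_stats(20, seed = 2, trait_id = "e")
  ou <- make_stats(20, seed = 3, trait_id = "o")
  h1 <- harmonize(ex, ou)

  # rebuild the outcome from the harmonized pairs: harmonizing again must
  # change nothing
  rec <- ex$records[match(h1$pairs$SNP, ex$records$SNP), ]
  rec$BETA <- h1$pairs$beta_out
  rec$SE <- h1$pairs$se_out
  rec$EAF <- h1$pairs$eaf_out
  rec$P <- h1$pairs$p_out
  rec$N <- h1$pairs$n_out
  ou_aligned <- summary_stats("o", rec, quiet = TRUE)
  h2 <- harmonize(ex, ou_aligned)
  expect_equal(h2$pairs$beta_out, h1$pairs$beta_out)
  expect_equal(h2$pairs$eaf_out, h1$pairs$eaf_out)
  expect_equal(h2$n_dropped_palindromic, 0L)

  # swapping the outcome's alleles negates beta_out exactly
  swapped <- ou$records
  tmp <- swapped$EA; swapped$EA <- swapped$OA; swapped$OA <- tmp
  swapped$EAF <- 1 - swapped$EAF
  h3 <- harmonize(ex, summary_stats("o", swapped, quiet = TRUE))
  common <- intersect(h1$pairs$SNP, h3$pairs$SNP)
  expect_equal(h3$pairs$beta_out[match(common, h3$pairs$SNP)],
               -h1$pairs$beta_out[match(common, h1$pairs$SNP)])
})
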