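# The five causal estimators against closed forms and independent oracles.

test_that("Wald ratios and weights follow the first-order formulas", {
  h <- make_h(beta_exp = c(0.5, -0.5), beta_out = c(0.1, 0.1),
              se_out = c(0.05, 0.05))
  r <- ratio_estimates(h)
  expect_equal(r$theta, c(0.2, -0.2))
  expect_equal(r$sigma, c(0.1, 0.1))
  expect_equal(r$weights, r$sigma^-2)

  set.seed(21)
  bx <- runif(20, -0.4, 0.4); bx[bx == 0] <- 0.1
  by <- rnorm(20); so <- runif(20, 0.01, 0.1)
  r2 <- ratio_estimates(make_h(bx, by, so))
  expect_equal(r2$theta, by / bx)
  expect_equal(r2$sigma, so / abs(bx))

  expect_error(ratio_estimates(make_h(c(0, 0.2), c(0.1, 0.1), c(0.1, 0.1))),
               class = "medmr_degenerate_instrument")
})

test_that("IVW matches closed forms and the weighted-regression oracle", {
  # homogeneous ratios: fixed-effect closed form, Q = 0
  h <- make_h(c(1, 1), c(0.5, 0.5), c(0.1, 0.1))
  est <- mr_ivw(h, re_model = "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, sqrt(1 / 200))
  expect_equal(cochran_q(h)$q, 0)
  # under-dispersion: random-effects model reduces to the fixed one
  expect_equal(mr_ivw(h)$se, est$se)

  expect_equal(mr_ivw(make_h(c(1, 1), c(0.4, 0.6), c(0.1, 0.1)))$beta, 0.5)

  set.seed(30)
  h3 <- sim_h(30, theta = 0.2)
  p <- h3$pairs
  fit <- lm(beta_out ~ 0 + beta_exp, data = p, weights = p$se_out^-2)
  expect_equal(mr_ivw(h3)$beta, unname(coef(fit)), tolerance = 1e-10)

  expect_error(mr_ivw(make_h(1, 0.2, 0.1)), class = "medmr_insufficient_instruments")
})

test_that("MR-Egger recovers an exact line and matches the WLS oracle", {
  # exact line: intercept c, slope theta, no noise
  bx <- seq(0.1, 0.5, length.out = 5)
  by <- 0.03 + 0.4 * bx
  eg <- mr_egger(make_h(bx, by, rep(0.05, 5)))
  expect_equal(eg$intercept, 0.03, tolerance = 1e-10)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)

  set.seed(41)
  h <- sim_h(10, theta = 0.3, pleio = 0.02)
  p <- h$pairs
  ora <- oracle_wls(p$beta_exp, p$beta_out, p$se_out^-2)
  eg2 <- mr_egger(h)
  expect_equal(eg2$intercept, unname(ora[1]), tolerance = 1e-10)
  expect_equal(eg2$slope$beta, unname(ora[2]), tolerance = 1e-10)

  # negative exposure effects are re-oriented before fitting
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  h_flip <- make_h(p$beta_exp * flip, p$beta_out * flip, p$se_out)
  eg3 <- mr_egger(h_flip)
  expect_equal(eg3$slope$beta, eg2$slope$beta)
  expect_equal(eg3$intercept, eg2$intercept)

  expect_error(mr_egger(make_h(c(1, 1), c(0.1, 0.2), c(0.1, 0.1))),
               class = "medmr_insufficient_instruments")
})

test_that("Egger intercept test holds its level without pleiotropy", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    h <- sim_h(50, theta = 0.2)
    if (mr_egger(h)$intercept_p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("weighted median interpolates the cumulative-weight formula", {
  h <- make_h(rep(1, 3), c(0.3, 0.5, 0.7), rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.5)

  # 5 instruments, unequal weights: hand-computed interpolation oracle
  theta <- c(0.1, 0.25, 0.4, 0.55, 0.9)
  sigma <- c(0.05, 0.02, 0.08, 0.03, 0.1)
  h5 <- make_h(rep(1, 5), theta, sigma)
  got <- mr_weighted_median(h5, n_boot = 50, seed = 1)$beta
  expect_equal(got, oracle_weighted_median(theta, sigma^-2), tolerance = 1e-12)

  set.seed(52)
  for (i in 1:20) {
    th <- rnorm(7); sg <- runif(7, 0.01, 0.2)
    hh <- make_h(rep(1, 7), th, sg)
    expect_equal(mr_weighted_median(hh, n_boot = 50, seed = 1)$beta,
                 oracle_weighted_median(th, sg^-2), tolerance = 1e-12)
  }

  # bootstrap SE is reproducible under a fixed seed
  a <- mr_weighted_median(h5, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h5, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
})

test_that("mode estimators find the dominant cluster and degenerate cleanly", {
  # all ratios equal: mode is that value whatever the weights
  h <- make_h(c(1, 1, 1), c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 50, seed = 1)$beta, 0.4)
  expect_equal(mr_mode(h, weighted = FALSE, n_boot = 50, seed = 1)$beta, 0.4)

  # bimodal: 70% of mass near 0.2, 30% near 0.8 -> mode near 0.2
  set.seed(61)
  th <- c(rnorm(14, 0.2, 0.02), rnorm(6, 0.8, 0.02))
  hb <- make_h(rep(1, 20), th, rep(0.05, 20))
  est <- mr_mode(hb, weighted = FALSE, n_boot = 50, seed = 1)$beta
  expect_lt(abs(est - 0.2), 0.1)

  # equal weights: weighted and simple mode coincide
  he <- make_h(rep(1, 6), rnorm(6, 0.3, 0.1), rep(0.07, 6))
  expect_equal(mr_mode(he, weighted = TRUE, n_boot = 50, seed = 2)$beta,
               mr_mode(he, weighted = FALSE, n_boot = 50, seed = 2)$beta)
})

test_that("mr_all runs five estimators and flags sign consistency", {
  set.seed(71)
  h <- sim_h(30, theta = 0.4, se_out = 0.02)
  res <- mr_all(h, seed = 5, n_boot = 100)
  expect_named(res$estimates,
               c("IVW", "Egger", "WeightedMedian", "WeightedMode", "SimpleMode"))
  expect_true(res$consistent)
  df <- as.data.frame(res)
  expect_equal(nrow(df), 5L)

  # constructed counterexample: strong directional pleiotropy drags the
  # Egger slope through zero while IVW stays positive
  set.seed(3)
  bx <- runif(20, 0.1, 0.3)
  by <- 0.05 * bx + 0.08 - 0.2 * bx   # intercept + negative slope component
  hc <- make_h(bx, by + rnorm(20, 0, 0.005), rep(0.02, 20))
  res2 <- mr_all(hc, seed = 5, n_boot = 100)
  expect_false(res2$consistent)

  # null ratios: the flag is still well-defined (a logical scalar)
  set.seed(72)
  h0 <- sim_h(10, theta = 0)
  expect_type(mr_all(h0, seed = 1, n_boot = 50)$consistent, "logical")
})

test_that("all estimators are equivariant under joint sign flips", {
  set.seed(81)
  h <- sim_h(15, theta = 0.25)
  flip <- sample(c(-1, 1), 15, replace = TRUE)
  h_f <- make_h(h$pairs$beta_exp * flip, h$pairs$beta_out * flip, h$pairs$se_out)
  expect_equal(mr_ivw(h_f)$beta, mr_ivw(h)$beta)
  expect_equal(mr_egger(h_f)$slope$beta, mr_egger(h)$slope$beta)
  expect_equal(mr_weighted_median(h_f, n_boot = 50, seed = 2)$beta,
               mr_weighted_median(h, n_boot = 50, seed = 2)$beta)
  expect_equal(mr_mode(h_f, n_boot = 50, seed = 2)$beta,
               mr_mode(h, n_boot = 50, seed = 2)$beta)
})
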