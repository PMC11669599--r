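# Shared fixture builders and independent oracles.

# A small well-formed records table (non-palindromic alleles).
make_records <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    SNP = sprintf("rs%d", seq_len(n)),
    CHR = as.character(rep_len(1:22, n)),
    POS = as.integer(seq_len(n) * 1e5),
    EA = rep_len(c("A", "C", "A", "G", "T"), n),
    OA = rep_len(c("G", "T", "C", "A", "C"), n),
    EAF = round(runif(n, 0.05, 0.5), 4),
    BETA = round(rnorm(n, 0, 0.1), 6),
    SE = round(runif(n, 0.01, 0.05), 6),
    P = round(runif(n, 1e-8, 0.5), 10),
    N = rep(3757L, n),
    stringsAsFactors = FALSE
  )
}

make_stats <- function(n = 5, seed = 1, trait_id = "trait", ...) {
  summary_stats(trait_id, make_records(n, seed), quiet = TRUE, ...)
}

# Harmonized set with known ratio structure: theta_j = beta_out_j / beta_exp_j.
make_h <- function(beta_exp, beta_out, se_out, se_exp = 0.01) {
  harmonized_set(sprintf("rs%d", seq_along(beta_exp)),
                 beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
                 beta_out = beta_out, se_out = se_out)
}

# Draw a harmonized set under theta with independent outcome noise.
sim_h <- function(J, theta, se_out = 0.05, bx_range = c(0.1, 0.3), pleio = 0) {
  bx <- runif(J, bx_range[1], bx_range[2])
  by <- theta * bx + pleio + rnorm(J, 0, se_out)
  make_h(bx, by, rep(se_out, J))
}

# ---- independent oracles ----------------------------------------------

# Greedy clumping re-implemented by repeated scans over an explicit
# removal mask (no shared code with clump()).
oracle_clump <- function(df, ld, r2_threshold, window_kb) {
  removed <- rep(FALSE, nrow(df))
  chosen <- character(0)
  key <- order(df$P, df$CHR, df$POS, df$SNP)
  rank <- integer(nrow(df)); rank[key] <- seq_len(nrow(df))
  repeat {
    cand <- which(!removed & !(df$SNP %in% chosen))
    if (!length(cand)) break
    idx <- cand[which.min(rank[cand])]
    chosen <- c(chosen, df$SNP[idx])
    for (j in seq_len(nrow(df))) {
      if (j == idx || removed[j] || df$SNP[j] %in% chosen) next
      if (df$CHR[j] != df$CHR[idx]) next
      if (abs(df$POS[j] - df$POS[idx]) > window_kb * 1000) next
      r2 <- if (df$SNP[idx] %in% rownames(ld) && df$SNP[j] %in% rownames(ld)) {
        ld[df$SNP[idx], df$SNP[j]]
      } else 0
      if (r2 > r2_threshold) removed[j] <- TRUE
    }
  }
  chosen
}

# Weighted median by hand: explicit bracketing interpolation.
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(th[1])
  J <- length(th)
  if (0.5 >= s[J]) return(th[J])
  j <- max(which(s < 0.5))
  th[j] + (0.5 - s[j]) * (th[j + 1] - th[j]) / (s[j + 1] - s[j])
}

# Weighted least squares with intercept via the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  drop(solve(XtWX, t(X) %*% (w * y)))
}
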