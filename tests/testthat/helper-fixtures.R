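# Shared fixtures and independent oracles used across the test files.

# Three-instrument fixture with ratio weights (100, 400, 225); its
# fixed-effects pooled estimate and Cochran Q are known in closed form.
pairs3 <- function() {
  data.frame(snp_id = c("rs1", "rs2", "rs3"),
             beta_x = c(0.10, 0.20, 0.15), se_x = 0.01,
             beta_y = c(-0.022, -0.046, -0.030), se_y = 0.01,
             stringsAsFactors = FALSE)
}

# Quick in-memory GWAS dataset builder with sensible defaults.
make_ds <- function(snp_id, beta, se, pval = NULL, eaf = 0.3,
                    ea = "A", oa = "G", chrom = "1",
                    pos = seq_along(snp_id) * 1e6, n = 1e5,
                    trait = "trait", type = "continuous", n_cases = NULL) {
  k <- length(snp_id)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  df <- data.frame(snp_id = snp_id, chrom = rep_len(chrom, k),
                   pos = rep_len(pos, k),
                   effect_allele = rep_len(ea, k),
                   other_allele = rep_len(oa, k),
                   eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
                   pval = pval, n = rep_len(n, k),
                   stringsAsFactors = FALSE)
  if (!is.null(n_cases)) df$n_cases <- rep_len(n_cases, k)
  gwas_dataset(df, trait, type)
}

# Independent weighted-least-squares oracle via lm(); covariance taken
# unscaled (meta-analysis convention) for comparison with the package.
lm_wls_oracle <- function(X, y, w) {
  fit <- lm(y ~ 0 + X, weights = w)
  xtx_inv <- solve(t(X * w) %*% X)
  list(coef = unname(coef(fit)), se_unscaled = sqrt(diag(xtx_inv)),
       sigma = summary(fit)$sigma)
}

# Brute-force reference for the greedy clumping rule: same definition,
# written as plain nested loops over the p-ordered candidates.
clump_reference <- function(df, ld, r2_max, window_kb) {
  ord <- order(df$pval, df$chrom, df$pos, df$snp_id)
  acc <- integer(0)
  for (i in ord) {
    bad <- FALSE
    for (j in acc) {
      if (df$chrom[i] != df$chrom[j]) next
      if (abs(df$pos[i] - df$pos[j]) > window_kb * 1000) next
      r2 <- ld_lookup(ld, df$snp_id[i], df$snp_id[j])
      if (!is.na(r2) && r2 > r2_max) { bad <- TRUE; break }
    }
    if (!bad) acc <- c(acc, i)
  }
  sort(df$snp_id[acc])
}

# Exact weighted-median definition by direct percentile enumeration.
wm_reference <- function(theta, w) {
  o <- order(theta); theta <- theta[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  i <- max(which(p < 0.5))
  theta[i] + (theta[i + 1] - theta[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# Ratios with a prescribed Cochran Q (unit weights, mean zero):
# theta = (d, -d, 0, ..., 0) gives Q = 2 d^2.
ratios_with_q <- function(q, k) {
  d <- sqrt(q / 2)
  data.frame(snp_id = paste0("s", seq_len(k)),
             theta = c(d, -d, rep(0, k - 2)),
             sigma = 1, weight = 1, stringsAsFactors = FALSE)
}
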