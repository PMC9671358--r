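#' Cochran's Q heterogeneity test for Wald ratios
#'
#' `Q = sum(w_j (theta_j - theta_fe)^2)` against the fixed-effects IVW
#' estimate, referred to a chi-square distribution with k - 1 degrees of
#' freedom. The derived `I2 = max(0, (Q - df)/Q) * 100` quantifies the
#' share of variation beyond chance and is labelled on the conventional
#' four intervals: 0-25 low, 25-50 moderate, 50-75 large, 75-100 extreme.
#'
#' @param ratios Output of [wald_ratios()] (k >= 2), or an `mr_harmonized`
#'   object / pairs data frame (converted internally).
#' @return Object of class `mr_heterogeneity`: list with `q`, `df`, `pval`,
#'   `i2` (percent) and `label`.
#' @export
cochran_q <- function(ratios) {
  if (!is.data.frame(ratios) || is.null(ratios$theta)) ratios <- wald_ratios(ratios)
  k <- nrow(ratios)
  if (k < 2) stop("heterogeneity test needs at least two instruments")
  w <- ratios$weight
  theta_hat <- sum(w * ratios$theta) / sum(w)
  q <- sum(w * (ratios$theta - theta_hat)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2, label = i2_label(i2)),
            class = "mr_heterogeneity")
}

#' Heterogeneity interval label for an I-squared value
#' @param i2 I-squared percentage in \[0, 100\].
#' @return `"low"`, `"moderate"`, `"large"` or `"extreme"`.
#' @export
i2_label <- function(i2) {
  stopifnot(all(i2 >= 0 & i2 <= 100))
  as.character(cut(i2, c(0, 25, 50, 75, 100),
                   labels = c("low", "moderate", "large", "extreme"),
                   right = FALSE, include.lowest = TRUE))
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g; I2 = %.1f%% (%s)\n",
              x$q, x$df, x$pval, x$i2, x$label))
  invisible(x)
}

#' MR-PRESSO global and per-SNP outlier test
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. For each SNP j
#' the fixed-effects IVW slope is refit without it, and the observed RSS is
#' the weighted sum of squared deviations of each SNP's outcome effect from
#' its leave-one-out prediction. The null distribution is simulated by
#' drawing `beta_x* ~ N(beta_x, se_x)` and
#' `beta_y* ~ N(theta_loo_j beta_x_j, se_y)` and recomputing the RSS the
#' same way (leave-one-out slopes re-estimated within each replicate).
#' P-values use the add-one Monte-Carlo form and are therefore never zero;
#' per-SNP outlier p-values are Bonferroni-multiplied by k.
#'
#' @param pairs Harmonized pairs (k >= 4) with `se_x` present.
#' @param n_sim Number of simulated replicates (default 1000).
#' @param seed Integer seed; with the seed fixed the result is reproducible.
#' @param sig_threshold Outlier call threshold on the Bonferroni-adjusted
#'   per-SNP p-value (default 0.05).
#' @return Object of class `mr_presso`: list with `rss_obs`, `global_pval`,
#'   `per_snp` (data frame: `snp_id`, `rss_contribution`, `outlier_pval`,
#'   `outlier_pval_bonferroni`), `outliers` (SNP ids), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = NULL, sig_threshold = 0.05) {
  p <- kept_pairs(pairs)
  p <- p[p$beta_x != 0, , drop = FALSE]
  k <- nrow(p)
  if (k < 4) stop("MR-PRESSO needs at least four instruments")
  if (any(is.na(p$se_x))) stop("se_x required for MR-PRESSO simulation")
  if (is.null(p$snp_id)) p$snp_id <- paste0("snp", seq_len(k))
  w <- p$se_y^-2
  bx <- p$beta_x; by <- p$beta_y

  loo_slopes <- function(bx, by) {
    # columns = replicates when bx/by are matrices
    sxy <- colSums(w * bx * by)
    sxx <- colSums(w * bx * bx)
    (rep(sxy, each = k) - w * bx * by) / (rep(sxx, each = k) - w * bx * bx)
  }
  th_loo <- drop(loo_slopes(cbind(bx), cbind(by)))
  resid_obs <- drop(w * (by - th_loo * bx)^2)
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(k * n_sim, bx, p$se_x), nrow = k)
    bys <- matrix(stats::rnorm(k * n_sim, th_loo * bx, p$se_y), nrow = k)
    th <- loo_slopes(bxs, bys)
    w * (bys - th * bxs)^2
  })
  rss_sim <- colSums(sims)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + rowSums(sims >= resid_obs)) / (n_sim + 1)
  outlier_p_bonf <- pmin(1, outlier_p * k)
  per_snp <- data.frame(snp_id = p$snp_id, rss_contribution = resid_obs,
                        outlier_pval = outlier_p,
                        outlier_pval_bonferroni = outlier_p_bonf,
                        stringsAsFactors = FALSE)
  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 per_snp = per_snp,
                 outliers = p$snp_id[outlier_p_bonf < sig_threshold],
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSSobs = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect excluding each instrument in turn. The
#' discordance flag is set when any exclusion flips the sign of the
#' estimate or moves its 95% confidence interval across the null (OR = 1)
#' relative to the full fit.
#'
#' @param pairs Harmonized pairs (k >= 3).
#' @param method `"fe_ivw"` or `"mre_ivw"`.
#' @return Object of class `mr_loo`: list with `table` (one row per
#'   excluded SNP: `excluded_snp`, `beta`, `se`, `pval`, `or`, `ci_low`,
#'   `ci_high`), `full` (the full-sample `mr_result`) and `flag`.
#' @export
leave_one_out <- function(pairs, method = c("fe_ivw", "mre_ivw")) {
  method <- match.arg(method)
  ratios <- wald_ratios(pairs)
  k <- nrow(ratios)
  if (k < 3) stop("leave-one-out needs at least three instruments")
  fitter <- if (method == "fe_ivw") mr_ivw_fixed else mr_ivw_mre
  full <- fitter(ratios)
  rows <- lapply(seq_len(k), function(j) {
    r <- fitter(ratios[-j, , drop = FALSE])
    cbind(excluded_snp = ratios$snp_id[j], as.data.frame(r)[-(1:2)])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  crosses <- function(lo, hi) lo <= 1 & hi >= 1
  flag <- any(sign(tab$beta) != sign(full$beta) |
                crosses(tab$ci_low, tab$ci_high) !=
                crosses(full$ci_low, full$ci_high))
  structure(list(table = tab, full = full, flag = flag, method = method),
            class = "mr_loo")
}

#' @export
print.mr_loo <- function(x, digits = 4, ...) {
  cat(sprintf("Leave-one-out (%s), %d instruments; discordance flag: %s\n",
              x$method, nrow(x$table), x$flag))
  rng <- range(x$table$beta)
  cat(sprintf("  beta range across exclusions: [%.4g, %.4g] (full: %.4g)\n",
              rng[1], rng[2], x$full$beta))
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-SNP ratio estimates against their precision (1/SE), sorted by
#' precision descending; asymmetry of this cloud suggests directional
#' pleiotropy. No inference is performed.
#'
#' @param ratios Output of [wald_ratios()] (or pairs, converted).
#' @return Data frame with columns `snp_id`, `theta`, `precision`.
#' @export
funnel_data <- function(ratios) {
  if (!is.data.frame(ratios) || is.null(ratios$theta)) ratios <- wald_ratios(ratios)
  out <- data.frame(snp_id = ratios$snp_id, theta = ratios$theta,
                    precision = 1 / ratios$sigma, stringsAsFactors = FALSE)
  out[order(-out$precision), , drop = FALSE]
}
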