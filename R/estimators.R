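.z975 <- stats::qnorm(0.975)

mr_result <- function(method, beta, se, pval, k, extras = list()) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_ = exp(beta),
                 ci_low = exp(beta - .z975 * se),
                 ci_high = exp(beta + .z975 * se),
                 k = k, extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (k = %d): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$k, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, k = x$k, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' For each harmonized pair, the causal ratio `theta = beta_y / beta_x` with
#' first-order delta-method standard error `sigma = se_y / |beta_x|` and
#' inverse-variance weight `sigma^-2`. Pairs with `beta_x == 0` have an
#' undefined ratio and are excluded (their ids are recorded in
#' `attr(, "excluded")`).
#'
#' @param pairs An `mr_harmonized` object or a data frame of harmonized
#'   pairs (columns `beta_x`, `se_x`, `beta_y`, `se_y`, optionally `snp_id`).
#' @param second_order If `TRUE`, use the second-order delta SE
#'   `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)` instead of the
#'   first-order form.
#' @return Data frame with columns `snp_id`, `theta`, `sigma`, `weight`.
#' @export
wald_ratios <- function(pairs, second_order = FALSE) {
  p <- kept_pairs(pairs)
  if (is.null(p$snp_id)) p$snp_id <- paste0("snp", seq_len(nrow(p)))
  zero <- p$beta_x == 0
  excluded <- p$snp_id[zero]
  p <- p[!zero, , drop = FALSE]
  sigma <- if (second_order)
    sqrt(p$se_y^2 / p$beta_x^2 + p$beta_y^2 * p$se_x^2 / p$beta_x^4)
  else p$se_y / abs(p$beta_x)
  out <- data.frame(snp_id = p$snp_id, theta = p$beta_y / p$beta_x,
                    sigma = sigma, weight = sigma^-2,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Fixed-effects inverse-variance-weighted estimate
#'
#' Pools Wald ratios by their inverse variances:
#' `beta = sum(w theta) / sum(w)`, `se = sum(w)^(-1/2)`, two-sided normal
#' p-value. Algebraically identical to weighted least squares of `beta_y`
#' on `beta_x` through the origin with weights `se_y^-2`.
#'
#' @param ratios Output of [wald_ratios()] (k >= 1).
#' @return An `mr_result` with method `"fe_ivw"`.
#' @export
mr_ivw_fixed <- function(ratios) {
  k <- nrow(ratios)
  if (k < 1) stop("fixed-effects IVW needs at least one instrument")
  w <- ratios$weight
  beta <- sum(w * ratios$theta) / sum(w)
  se <- sum(w)^-0.5
  mr_result("fe_ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), k)
}

#' Multiplicative random-effects IVW estimate
#'
#' Same point estimate as [mr_ivw_fixed()]; the standard error is inflated
#' by the residual scale `sqrt(Q / (k - 1))` from Cochran's Q, truncated
#' below at 1 so the random-effects interval is never narrower than the
#' fixed-effects one.
#'
#' @param ratios Output of [wald_ratios()] (k >= 2).
#' @param truncate_scale If `FALSE`, the raw scale is used without the
#'   lower truncation at 1.
#' @return An `mr_result` with method `"mre_ivw"`; `extras$scale` records
#'   the applied inflation.
#' @export
mr_ivw_mre <- function(ratios, truncate_scale = TRUE) {
  k <- nrow(ratios)
  if (k < 2) stop("random-effects IVW needs at least two instruments")
  fe <- mr_ivw_fixed(ratios)
  q <- cochran_q(ratios)$q
  scale <- sqrt(q / (k - 1))
  if (truncate_scale) scale <- max(1, scale)
  se <- fe$se * scale
  mr_result("mre_ivw", fe$beta, se, 2 * stats::pnorm(-abs(fe$beta / se)), k,
            extras = list(scale = scale))
}

#' Weighted median of a set of ratio estimates
#'
#' The weighted median as used by the median-based causal estimator: order
#' the values, assign each the percentile `S_j - w'_j/2` (with `S_j` the
#' cumulative normalized weight), and linearly interpolate across the
#' bracketing percentiles at 0.5.
#'
#' @param theta Numeric vector of values.
#' @param w Positive weights.
#' @return The weighted median.
#' @export
weighted_median_point <- function(theta, w) {
  stopifnot(length(theta) == length(w), all(w > 0))
  o <- order(theta)
  theta <- theta[o]
  wn <- w[o] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5)$y
}

#' Weighted-median causal estimate
#'
#' Consistent when instruments contributing at least half of the total
#' weight are valid. The point estimate is the weighted median of the Wald
#' ratios with inverse-variance weights; its standard error is the standard
#' deviation of the estimate over parametric bootstrap resamples
#' (`beta_x* ~ N(beta_x, se_x)`, `beta_y* ~ N(beta_y, se_y)`, ratio weights
#' recomputed per resample).
#'
#' @param pairs Harmonized pairs (k >= 3) as for [wald_ratios()]; `se_x`
#'   must be present for the bootstrap.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_result` with method `"weighted_median"`; `extras` records
#'   `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = NULL) {
  p <- kept_pairs(pairs)
  p <- p[p$beta_x != 0, , drop = FALSE]
  k <- nrow(p)
  if (k < 3) stop("weighted median needs at least three instruments")
  if (any(is.na(p$se_x))) stop("se_x required for the weighted-median bootstrap")
  # orient to beta_x >= 0 so the bootstrap draws (and hence the SE) are
  # invariant to allele recoding; ratios are unaffected
  s <- ifelse(p$beta_x < 0, -1, 1)
  p$beta_x <- s * p$beta_x
  p$beta_y <- s * p$beta_y
  est <- weighted_median_point(p$beta_y / p$beta_x, (p$se_y / abs(p$beta_x))^-2)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(k * n_boot, p$beta_x, p$se_x), nrow = k)
    by <- matrix(stats::rnorm(k * n_boot, p$beta_y, p$se_y), nrow = k)
    vapply(seq_len(n_boot), function(b) {
      ok <- bx[, b] != 0
      weighted_median_point(by[ok, b] / bx[ok, b],
                            (p$se_y[ok] / abs(bx[ok, b]))^-2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_result("weighted_median", est, se, 2 * stats::pnorm(-abs(est / se)), k,
            extras = list(n_boot = n_boot, seed = seed))
}

# weighted least squares via normal equations; X is the design matrix
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  xtx <- XtW %*% X
  coef <- solve(xtx, XtW %*% y)
  list(coef = drop(coef), cov_unscaled = solve(xtx),
       fitted = drop(X %*% coef))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept;
#' the slope is a pleiotropy-robust causal estimate under the InSIDE
#' assumption and a non-zero intercept indicates directional horizontal
#' pleiotropy. Each pair is first oriented so `beta_x >= 0` (negating both
#' effects where needed), which makes the estimator invariant to allele
#' recoding. Coefficient standard errors use weights `se_y^-2` scaled by
#' `max(1, residual scale)`; p-values refer to a t distribution with k - 2
#' degrees of freedom.
#'
#' @param pairs Harmonized pairs (k >= 3).
#' @return List of class `mr_egger_fit` with elements `slope` and
#'   `intercept`, both `mr_result`s (methods `"egger_slope"`,
#'   `"egger_intercept"`); `extras$scale` records the residual scale.
#' @export
mr_egger <- function(pairs) {
  p <- kept_pairs(pairs)
  k <- nrow(p)
  if (k < 3) stop("MR-Egger needs at least three instruments")
  s <- ifelse(p$beta_x < 0, -1, 1)
  bx <- s * p$beta_x
  by <- s * p$beta_y
  if (stats::var(bx) == 0)
    stop("collinear design: all exposure effects identical after orientation")
  w <- p$se_y^-2
  X <- cbind(intercept = 1, slope = bx)
  fit <- wls_fit(X, by, w)
  df <- k - 2
  rss <- sum(w * (by - fit$fitted)^2)
  scale <- max(1, sqrt(rss / df))
  se <- sqrt(diag(fit$cov_unscaled)) * scale
  tval <- fit$coef / se
  pv <- 2 * stats::pt(-abs(tval), df)
  extras <- list(scale = scale, rss = rss)
  structure(list(
    slope = mr_result("egger_slope", fit$coef[["slope"]], se[["slope"]],
                      pv[["slope"]], k, extras),
    intercept = mr_result("egger_intercept", fit$coef[["intercept"]],
                          se[["intercept"]], pv[["intercept"]], k, extras)),
    class = "mr_egger_fit")
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  print(x$slope); print(x$intercept)
  invisible(x)
}

#' Fit two-sample Mendelian randomization models
#'
#' The central fitting function: given harmonized exposure/outcome pairs it
#' computes the requested causal estimators (fixed-effects IVW,
#' multiplicative-random-effects IVW, weighted median, MR-Egger) together
#' with Cochran's Q heterogeneity, and returns a classed fit with
#' `print`, `summary`, `coef`, `confint` and `plot` methods.
#'
#' @param pairs An `mr_harmonized` object (from [harmonize()]) or a data
#'   frame of harmonized pairs.
#' @param methods Character vector among `"fe_ivw"`, `"mre_ivw"`,
#'   `"weighted_median"`, `"egger"`.
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param seed Integer seed for the weighted-median bootstrap.
#' @return An object of class `mr_fit`: list with `results` (named list of
#'   `mr_result`), `estimates` (one row per estimate: method, k, beta, se,
#'   pval, or, ci_low, ci_high), `heterogeneity` (see [cochran_q()]),
#'   `ratios`, `pairs`.
#' @export
#' @examples
#' pairs <- data.frame(beta_x = c(0.10, 0.20, 0.15),
#'                     se_x = 0.01,
#'                     beta_y = c(-0.022, -0.046, -0.030),
#'                     se_y = 0.01)
#' fit <- mr(pairs, seed = 1)
#' fit
mr <- function(pairs, methods = c("fe_ivw", "mre_ivw", "weighted_median", "egger"),
               n_boot = 1000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  p <- kept_pairs(pairs)
  ratios <- wald_ratios(p)
  results <- list()
  if ("fe_ivw" %in% methods) results$fe_ivw <- mr_ivw_fixed(ratios)
  if ("mre_ivw" %in% methods) results$mre_ivw <- mr_ivw_mre(ratios)
  if ("weighted_median" %in% methods)
    results$weighted_median <- mr_weighted_median(p, n_boot = n_boot, seed = seed)
  if ("egger" %in% methods) {
    eg <- mr_egger(p)
    results$egger_slope <- eg$slope
    results$egger_intercept <- eg$intercept
  }
  het <- if (nrow(ratios) >= 2) cochran_q(ratios) else NULL
  estimates <- do.call(rbind, lapply(results, as.data.frame))
  rownames(estimates) <- NULL
  structure(list(results = results, estimates = estimates,
                 heterogeneity = het, ratios = ratios, pairs = p,
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit (%d instruments)\n", nrow(x$ratios)))
  print(x$estimates, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  het <- x$fit$heterogeneity
  if (!is.null(het))
    cat(sprintf("\nHeterogeneity: Q = %.4g on %d df (p = %.3g), I2 = %.1f%% (%s)\n",
                het$q, het$df, het$pval, het$i2, het$label))
  if (!is.null(x$fit$results$egger_intercept)) {
    ic <- x$fit$results$egger_intercept
    cat(sprintf("Egger intercept: %.4g (p = %.3g) - directional pleiotropy %s\n",
                ic$beta, ic$pval,
                if (ic$pval < 0.05) "indicated" else "not indicated"))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$pairs
  s <- ifelse(p$beta_x < 0, -1, 1)
  bx <- s * p$beta_x; by <- s * p$beta_y
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::segments(bx, by - .z975 * p$se_y, bx, by + .z975 * p$se_y,
                     col = "grey60")
  if (!is.null(x$results$fe_ivw))
    graphics::abline(0, x$results$fe_ivw$beta, col = "steelblue", lwd = 2)
  if (!is.null(x$results$egger_slope))
    graphics::abline(x$results$egger_intercept$beta, x$results$egger_slope$beta,
                     col = "firebrick", lwd = 2, lty = 2)
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`
# (NULL leaves the global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
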