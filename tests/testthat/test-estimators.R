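test_that("Wald ratios and their first-order errors are exact", {
  r <- wald_ratios(data.frame(beta_x = 0.1, se_x = 0.01, beta_y = 0.02, se_y = 0.01))
  expect_equal(r$theta, 0.2)
  expect_equal(r$sigma, 0.1)
  expect_equal(r$weight, 100)

  r2 <- wald_ratios(data.frame(beta_x = 0.2, se_x = 0.01, beta_y = -0.046, se_y = 0.01))
  expect_equal(r2$theta, -0.23)
  expect_equal(r2$sigma, 0.05)

  # allele-coding invariance: negating both effects leaves theta and sigma alone
  a <- wald_ratios(data.frame(beta_x = 0.1, se_x = 0.01, beta_y = 0.02, se_y = 0.01))
  b <- wald_ratios(data.frame(beta_x = -0.1, se_x = 0.01, beta_y = -0.02, se_y = 0.01))
  expect_equal(a[c("theta", "sigma")], b[c("theta", "sigma")])

  # zero exposure effect excluded with its id recorded
  r3 <- wald_ratios(data.frame(snp_id = c("a", "b"), beta_x = c(0, 0.1),
                               se_x = 0.01, beta_y = 0.02, se_y = 0.01))
  expect_equal(nrow(r3), 1)
  expect_equal(attr(r3, "excluded"), "a")
})

test_that("fixed-effects IVW matches the closed form and the WLS-through-origin oracle", {
  fit <- mr_ivw_fixed(wald_ratios(pairs3()))
  expect_equal(fit$beta, -159 / 725, tolerance = 1e-12)
  expect_equal(fit$beta, -0.21931, tolerance = 1e-4)
  expect_equal(fit$se, 1 / sqrt(725), tolerance = 1e-12)
  expect_equal(fit$or_, 0.8031, tolerance = 1e-4)

  # oracle equivalence on random fixtures
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(4:10, 1)
    p <- data.frame(beta_x = rnorm(k, 0.1, 0.05), se_x = 0.01,
                    beta_y = rnorm(k, -0.02, 0.02),
                    se_y = runif(k, 0.005, 0.02))
    p <- p[abs(p$beta_x) > 1e-3, ]
    got <- mr_ivw_fixed(wald_ratios(p))
    orc <- lm_wls_oracle(cbind(p$beta_x), p$beta_y, p$se_y^-2)
    expect_equal(got$beta, orc$coef, tolerance = 1e-10)
    expect_equal(got$se, orc$se_unscaled, tolerance = 1e-10)
  }

  # k = 1 equals the single Wald ratio; equal ratios are conserved exactly
  one <- wald_ratios(data.frame(beta_x = 0.1, se_x = 0.01, beta_y = 0.02, se_y = 0.01))
  expect_equal(mr_ivw_fixed(one)$beta, one$theta)
  expect_equal(mr_ivw_fixed(one)$se, one$sigma)
  same <- data.frame(snp_id = letters[1:3], theta = 0.4, sigma = c(0.1, 0.2, 0.5),
                     weight = c(0.1, 0.2, 0.5)^-2)
  expect_equal(mr_ivw_fixed(same)$beta, 0.4)
  expect_error(mr_ivw_fixed(same[0, ]), "at least one")
})

test_that("multiplicative random-effects IVW rescales the standard error by the residual scale", {
  r3 <- wald_ratios(pairs3())
  fe <- mr_ivw_fixed(r3)
  mre <- mr_ivw_mre(r3)
  expect_equal(cochran_q(r3)$q, 0.1297, tolerance = 1e-3)
  expect_equal(mre$beta, fe$beta)
  expect_equal(mre$se, fe$se)  # underdispersed: scale truncated to 1
  expect_equal(mre$extras$scale, 1)

  # Q/(k-1) = 4 by construction -> SE doubles
  disp <- ratios_with_q(q = 4 * 2, k = 3)
  expect_equal(mr_ivw_mre(disp)$se, 2 * mr_ivw_fixed(disp)$se, tolerance = 1e-12)
  expect_equal(mr_ivw_mre(disp, truncate_scale = FALSE)$se,
               2 * mr_ivw_fixed(disp)$se, tolerance = 1e-12)

  homo <- data.frame(theta = rep(0.3, 4), sigma = 0.1, weight = 100)
  expect_equal(mr_ivw_mre(homo)$se, mr_ivw_fixed(homo)$se)
  expect_error(mr_ivw_mre(homo[1, ]), "two")
})

test_that("the weighted median interpolates percentiles as defined", {
  expect_equal(weighted_median_point(c(0.1, 0.2, 0.3), rep(1, 3)), 0.2)
  expect_equal(weighted_median_point(c(0.1, 0.2, 0.6), c(1, 1, 2)),
               0.2 + 0.4 * (0.5 - 0.375) / (0.75 - 0.375), tolerance = 1e-12)
  expect_equal(weighted_median_point(c(0.1, 0.2, 0.6), c(1, 1, 2)), 1 / 3,
               tolerance = 1e-10)

  # permutation invariance and reduction to the sample median at equal weights
  set.seed(5)
  for (rep in 1:10) {
    k <- sample(c(3, 5, 7, 9), 1)
    th <- rnorm(k)
    w <- runif(k, 0.5, 2)
    perm <- sample(k)
    expect_equal(weighted_median_point(th[perm], w[perm]),
                 weighted_median_point(th, w))
    expect_equal(weighted_median_point(th, rep(1, k)), median(th))
    expect_equal(weighted_median_point(th, w), wm_reference(th, w))
  }
})

test_that("the weighted-median estimator is seeded, reproducible, and order invariant", {
  p <- pairs3()
  a <- mr_weighted_median(p, n_boot = 200, seed = 9)
  b <- mr_weighted_median(p, n_boot = 200, seed = 9)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  shuf <- mr_weighted_median(p[c(3, 1, 2), ], n_boot = 200, seed = 9)
  expect_equal(shuf$beta, a$beta)
  expect_error(mr_weighted_median(p[1:2, ]), "three")
})

test_that("MR-Egger recovers exact fits and matches the WLS oracle", {
  # noiseless: beta_y = theta beta_x + a
  bx <- c(0.05, 0.1, 0.15, 0.2)
  p <- data.frame(beta_x = bx, se_x = 0.01,
                  beta_y = -0.3 * bx + 0.01, se_y = 0.01)
  eg <- mr_egger(p)
  expect_equal(eg$slope$beta, -0.3, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)
  expect_equal(eg$slope$extras$rss, 0, tolerance = 1e-20)

  p0 <- transform(p, beta_y = -0.3 * bx)
  expect_equal(mr_egger(p0)$intercept$beta, 0, tolerance = 1e-12)

  # noisy 4-point fixture against the normal-equations/lm oracle
  p2 <- data.frame(beta_x = c(0.05, 0.12, 0.18, 0.25), se_x = 0.01,
                   beta_y = c(-0.012, -0.041, -0.052, -0.081),
                   se_y = c(0.01, 0.015, 0.008, 0.02))
  eg2 <- mr_egger(p2)
  X <- cbind(1, p2$beta_x)
  orc <- lm_wls_oracle(X, p2$beta_y, p2$se_y^-2)
  expect_equal(eg2$intercept$beta, orc$coef[1], tolerance = 1e-10)
  expect_equal(eg2$slope$beta, orc$coef[2], tolerance = 1e-10)
  scale <- max(1, orc$sigma)
  expect_equal(c(eg2$intercept$se, eg2$slope$se), orc$se_unscaled * scale,
               tolerance = 1e-10)

  expect_error(mr_egger(p2[1:2, ]), "three")
  pc <- data.frame(beta_x = rep(0.1, 4), se_x = 0.01,
                   beta_y = rnorm(4), se_y = 0.01)
  expect_error(mr_egger(pc), "collinear")
})

test_that("all estimators are invariant to allele recoding of any SNP", {
  set.seed(21)
  p <- data.frame(snp_id = paste0("rs", 1:6),
                  beta_x = rnorm(6, 0.15, 0.05), se_x = 0.01,
                  beta_y = rnorm(6, -0.03, 0.02), se_y = runif(6, 0.005, 0.02),
                  eaf_x = runif(6), eaf_y = runif(6))
  q <- p
  flip <- c(2, 5)
  q$beta_x[flip] <- -q$beta_x[flip]
  q$beta_y[flip] <- -q$beta_y[flip]
  q$eaf_x[flip] <- 1 - q$eaf_x[flip]
  q$eaf_y[flip] <- 1 - q$eaf_y[flip]
  f1 <- mr(p, seed = 4)
  f2 <- mr(q, seed = 4)
  expect_equal(f1$estimates$beta, f2$estimates$beta, tolerance = 1e-12)
  expect_equal(f1$estimates$se, f2$estimates$se, tolerance = 1e-12)
})

test_that("the mr() fit object carries estimates, heterogeneity and methods", {
  fit <- mr(pairs3(), seed = 2, n_boot = 200)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("fe_ivw", "mre_ivw", "weighted_median",
                    "egger_slope", "egger_intercept"))
  expect_true(all(fit$estimates$ci_low < fit$estimates$or))
  expect_true(all(fit$estimates$or < fit$estimates$ci_high))
  expect_equal(unname(coef(fit)["fe_ivw"]), -159 / 725, tolerance = 1e-10)
  ci <- confint(fit)
  expect_equal(unname(ci["fe_ivw", ]),
               -159 / 725 + c(-1, 1) * qnorm(0.975) / sqrt(725),
               tolerance = 1e-10)
  expect_output(print(fit), "fe_ivw")
  expect_output(print(summary(fit)), "Heterogeneity")
})
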