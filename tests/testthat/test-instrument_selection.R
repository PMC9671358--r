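test_that("significance and MAF screens use strict inequalities and preserve order", {
  ds <- make_ds(paste0("rs", 1:5),
                beta = rep(0.05, 5), se = 0.005,
                pval = c(1e-9, 5e-8, 1e-7, 1e-10, 1e-12),
                eaf = c(0.3, 0.3, 0.3, 0.995, 0.01))
  out <- select_significant(ds, selection_config())
  # rs2: p exactly 5e-8 (strict <); rs3: p too large; rs4: MAF 0.005; rs5: MAF exactly 0.01
  expect_equal(out$data$snp_id, c("rs1"))
  expect_equal(sum(out$dropped), 4L)

  ds2 <- make_ds(c("b", "a"), beta = c(0.05, 0.05), se = 0.005,
                 pval = c(1e-9, 1e-10))
  expect_equal(select_significant(ds2)$data$snp_id, c("b", "a"))  # order kept
})

test_that("greedy clumping follows the p-value/window/r2 rule", {
  ds <- make_ds(c("A", "B", "C"), beta = 0.05, se = 0.005,
                pval = c(1e-10, 1e-9, 1e-9),
                chrom = c("1", "1", "2"), pos = c(100000, 200000, 100000))
  ld <- ld_table(data.frame(snp_a = "A", snp_b = "B", r2 = 0.5))
  expect_equal(clump(ds, ld)$data$snp_id, c("A", "C"))

  ld_low <- ld_table(data.frame(snp_a = "A", snp_b = "B", r2 = 0.0005))
  expect_equal(clump(ds, ld_low)$data$snp_id, c("A", "B", "C"))  # below ceiling

  # outside the 10 Mb window the r2 entry is irrelevant
  ds_far <- make_ds(c("A", "B", "C"), beta = 0.05, se = 0.005,
                    pval = c(1e-10, 1e-9, 1e-9),
                    chrom = c("1", "1", "2"), pos = c(100000, 5e7, 100000))
  expect_equal(clump(ds_far, ld)$data$snp_id, c("A", "B", "C"))

  # removal report names the index SNP
  expect_equal(attr(clump(ds, ld), "removals"),
               data.frame(snp_id = "B", index_snp = "A"))
})

test_that("clumping needs positions or LD, and strict_ld drops unknown in-window pairs", {
  ds <- make_ds(c("A", "B"), beta = 0.05, se = 0.005, pval = c(1e-10, 1e-9))
  ds$data$pos <- NA_real_
  expect_error(clump(ds, NULL), "LD table")

  ds2 <- make_ds(c("A", "B"), beta = 0.05, se = 0.005, pval = c(1e-10, 1e-9),
                 chrom = "1", pos = c(1e5, 2e5))
  expect_equal(clump(ds2, NULL)$data$snp_id, c("A", "B"))  # unknown LD retained
  strict <- selection_config(strict_ld = TRUE)
  expect_equal(clump(ds2, NULL, strict)$data$snp_id, "A")
})

test_that("greedy clumping agrees with a brute-force reference on random fixtures", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    ids <- paste0("rs", 1:k)
    ds <- make_ds(ids, beta = 0.05, se = 0.005,
                  pval = 10^-runif(k, 8, 12),
                  chrom = as.character(sample(1:2, k, TRUE)),
                  pos = sample(seq(1e5, 3e7, by = 1e5), k))
    prs <- t(combn(ids, 2))
    take <- runif(nrow(prs)) < 0.5
    ld <- if (any(take))
      ld_table(data.frame(snp_a = prs[take, 1], snp_b = prs[take, 2],
                          r2 = runif(sum(take), 0, 0.01)))
    else NULL
    got <- sort(clump(ds, ld)$data$snp_id)
    want <- clump_reference(ds$data, ld, 0.001, 10000)
    expect_equal(got, want)
  }
})

test_that("variance explained uses the reduced standard form", {
  expect_equal(variance_explained(0.05, 0.005, 218796),
               0.05^2 / (0.05^2 + 218796 * 0.005^2), tolerance = 1e-12)
  expect_equal(variance_explained(0.05, 0.005, 218796), 4.569e-4,
               tolerance = 1e-3)
  expect_equal(variance_explained(0, 0.01, 100), 0)
  expect_error(variance_explained(0.1, 0.01, 2), "sample size")
  # the verbatim printed form collapses to 1/(1 + se N): audit switch only
  expect_equal(variance_explained(0.3, 0.005, 1000, formula = "verbatim"),
               1 / (1 + 0.005 * 1000))
})

test_that("F statistics are exact, monotone, and consistent with variance explained", {
  expect_equal(f_statistic(0.001, 218796), 0.001 * 218794 / 0.999,
               tolerance = 1e-12)
  expect_equal(round(f_statistic(0.001, 218796), 2), 219.01)
  expect_equal(f_statistic(0, 100), 0)
  expect_gt(f_statistic(0.002, 1000), f_statistic(0.001, 1000))
  expect_error(f_statistic(1, 100), "r2")

  ds <- make_ds(paste0("rs", 1:4), beta = c(0.02, 0.05, -0.03, 0.1), se = 0.005,
                n = 50000)
  st <- instrument_strength(ds)
  expect_equal(st$f_stat,
               st$r2_explained * (50000 - 2) / (1 - st$r2_explained),
               tolerance = 1e-12)
})

test_that("confounder filtering drops strictly associated instruments and reports traits", {
  ds <- make_ds(c("rs1", "rs2", "rs3"), beta = 0.05, se = 0.005)
  tab <- confounder_table(data.frame(
    snp_id = c("rs1", "rs1", "rs2"),
    trait = c("bmi", "sbp", "bmi"),
    pval = c(1e-9, 0.5, 5e-8)))
  out <- filter_confounders(ds, tab)
  expect_equal(out$data$snp_id, c("rs2", "rs3"))  # 5e-8 exactly is retained
  hits <- attr(out, "confounder_hits")
  expect_equal(hits$snp_id, "rs1")
  expect_match(hits$trait, "bmi")
})

test_that("selection stage conserves counts", {
  set.seed(11)
  st <- simulate_two_sample(sim_config(seed = 5, k_snps = 40))
  sel <- select_instruments(st$exposure)
  r <- sel$report
  expect_equal(r$offered - r$after_significance,
               sum(unlist(r$dropped$significance_maf)))
  expect_equal(r$after_significance - r$after_clumping, r$dropped$clumped)
  expect_equal(r$after_clumping - r$after_f_filter, r$dropped$weak_instruments)
  expect_true(all(sel$instruments$data$snp_id %in% st$exposure$data$snp_id))
})
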