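test_that("palindromic classification follows the complement rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
})

rec <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.01)
  data.frame(snp_id = id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)

test_that("pairs are aligned across swaps and strand flips", {
  # swapped alleles: outcome beta negated, EAF reflected
  h <- harmonize_pair(rec(ea = "A", oa = "G", eaf = 0.30, beta = 0.10),
                      rec(ea = "G", oa = "A", eaf = 0.72, beta = -0.05))
  expect_equal(h$status, "swapped")
  expect_equal(h$beta_y, 0.05)
  expect_equal(h$eaf_y, 0.28)

  # complementary strand, direct after flip
  h2 <- harmonize_pair(rec(ea = "A", oa = "G"),
                       rec(ea = "T", oa = "C", beta = 0.07))
  expect_equal(h2$status, "strand_flipped")
  expect_equal(h2$beta_y, 0.07)

  # complementary strand and swapped
  h3 <- harmonize_pair(rec(ea = "A", oa = "G"),
                       rec(ea = "C", oa = "T", beta = 0.07, eaf = 0.8))
  expect_equal(h3$status, "strand_flipped_swapped")
  expect_equal(h3$beta_y, -0.07)
  expect_equal(h3$eaf_y, 0.2)

  # incompatible alleles
  h4 <- harmonize_pair(rec(ea = "A", oa = "G"), rec(ea = "A", oa = "C"))
  expect_equal(h4$status, "dropped_incompatible")
})

test_that("palindromic SNPs are oriented by allele frequency or dropped", {
  # intermediate frequency: unresolvable
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.50),
                      rec(ea = "A", oa = "T", eaf = 0.30))
  expect_equal(h$status, "dropped_palindromic_ambiguous")
  h_edge <- harmonize_pair(rec(ea = "C", oa = "G", eaf = 0.42),
                           rec(ea = "C", oa = "G", eaf = 0.30))
  expect_equal(h_edge$status, "dropped_palindromic_ambiguous")

  # concordant frequencies: kept as-is
  h2 <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.20, beta = 0.1),
                       rec(ea = "A", oa = "T", eaf = 0.25, beta = 0.05))
  expect_equal(h2$status, "direct")
  expect_equal(h2$beta_y, 0.05)

  # discordant frequencies: orientation flipped
  h3 <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.20),
                       rec(ea = "T", oa = "A", eaf = 0.78, beta = 0.05))
  expect_equal(h3$status, "swapped")
  expect_equal(h3$beta_y, -0.05)
  expect_equal(h3$eaf_y, 0.22)

  # missing EAF on either side cannot be oriented
  h4 <- harmonize_pair(rec(ea = "A", oa = "T", eaf = NA), rec(ea = "A", oa = "T"))
  expect_equal(h4$status, "dropped_palindromic_ambiguous")
})

test_that("harmonizing an already-harmonized pair is idempotent and double flips restore", {
  x <- rec(beta = 0.1, eaf = 0.3)
  y <- rec(beta = 0.05, eaf = 0.4, se = 0.02)
  once <- harmonize_pair(x, y)
  expect_equal(once$status, "direct")
  y2 <- rec(beta = once$beta_y, eaf = once$eaf_y, se = 0.02)
  twice <- harmonize_pair(x, y2)
  expect_equal(twice[c("beta_y", "eaf_y", "status")],
               once[c("beta_y", "eaf_y", "status")])

  # presenting the outcome on the other allele twice restores the original
  flip <- function(r) rec(ea = r$other_allele, oa = r$effect_allele,
                          eaf = 1 - r$eaf, beta = -r$beta, se = r$se)
  expect_equal(flip(flip(y)), y)
})

test_that("dataset harmonization drops missing and duplicated SNPs and conserves counts", {
  ex <- make_ds(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3), se = 0.01)
  out <- make_ds(c("rs1", "rs3"), beta = c(0.02, 0.06), se = 0.01)
  h <- harmonize(ex, out)
  expect_equal(h$pairs$status[h$pairs$snp_id == "rs2"], "dropped_missing_outcome")
  expect_equal(h$report$kept, 2)

  ex_dup <- make_ds(c("rs1", "rs1", "rs2"), beta = c(0.1, 0.15, 0.2), se = 0.01)
  h2 <- harmonize(ex_dup, out)
  expect_equal(h2$report$counts$dropped_duplicate, 2L)
  expect_equal(sum(unlist(h2$report$counts)), 3L)

  id_err <- expect_error(harmonize_pair(rec(id = "rs1"), rec(id = "rs2")),
                         "different SNPs")
})

test_that("harmonization report counts are conserved on fuzzed datasets", {
  for (s in 1:15) {
    st <- simulate_two_sample(sim_config(seed = s, k_snps = 30,
                                         palindromic_fraction = 0.4,
                                         strand_flip_fraction = 0.6))
    # randomly remove some outcome rows to exercise dropped_missing_outcome
    set.seed(s)
    out <- st$outcome
    out$data <- out$data[runif(nrow(out$data)) > 0.2, , drop = FALSE]
    h <- harmonize(st$exposure, out)
    expect_equal(sum(unlist(h$report$counts)), h$report$offered)
    expect_equal(h$report$offered, nrow(st$exposure$data))
    kp <- kept_pairs(h)
    expect_true(all(kp$se_x > 0 & kp$se_y > 0))
  }
})
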