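#' Configuration for the two-sample summary-statistics simulator
#'
#' Defaults emulate the study design the package targets: 117 independent
#' instruments for a continuous exposure measured in 218,796 individuals,
#' a binary outcome from a biobank-scale GWAS (218,792 individuals, 14.5%
#' cases), a protective causal effect of log(0.80) on the log-odds scale,
#' and instruments jointly explaining 4% of exposure variance.
#'
#' @param k_snps Number of instrument SNPs.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction Outcome case proportion K in (0, 1).
#' @param theta True causal effect on the log-odds scale.
#' @param total_r2 Total exposure variance explained by the instruments.
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"correlated"` (the last violates the InSIDE assumption).
#' @param pleiotropy_sd SD of the per-SNP direct (pleiotropic) effect on
#'   the outcome, log-odds units.
#' @param pleiotropy_mean Mean direct effect under `"directional"`.
#' @param pleiotropy_cor Proportionality constant linking direct effects to
#'   instrument strength under `"correlated"`.
#' @param maf_range Range from which minor-allele frequencies are drawn.
#' @param ld_blocks `NULL`, or `list(n_blocks, snps_per_block, within_r2)`
#'   to append LD-tagged satellite SNPs (exercises clumping).
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G alleles.
#' @param strand_flip_fraction Fraction of outcome records presented in a
#'   scrambled orientation (allele swap, strand flip, or both) that
#'   harmonization must undo.
#' @param n_confounded Number of instruments given a strong association in
#'   the confounder table.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(k_snps = 117, n_exposure = 218796, n_outcome = 218792,
                       case_fraction = 0.145, theta = log(0.80),
                       total_r2 = 0.04,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "correlated"),
                       pleiotropy_sd = 0.01, pleiotropy_mean = 0.01,
                       pleiotropy_cor = 0.1,
                       maf_range = c(0.05, 0.5), ld_blocks = NULL,
                       palindromic_fraction = 0.2,
                       strand_flip_fraction = 0.3,
                       n_confounded = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!(total_r2 > 0 && total_r2 < 1)) stop("total_r2 must lie in (0, 1)")
  stopifnot(k_snps >= 1, n_exposure > 2, n_outcome > 2,
            case_fraction > 0, case_fraction < 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            strand_flip_fraction >= 0, strand_flip_fraction <= 1,
            n_confounded >= 0, n_confounded <= k_snps)
  structure(list(k_snps = k_snps, n_exposure = n_exposure,
                 n_outcome = n_outcome, case_fraction = case_fraction,
                 theta = theta, total_r2 = total_r2,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_cor = pleiotropy_cor,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 palindromic_fraction = palindromic_fraction,
                 strand_flip_fraction = strand_flip_fraction,
                 n_confounded = n_confounded, seed = seed),
            class = "sim_config")
}

# two-sided Wald p floored at the smallest normalized double so that
# extreme associations never underflow to an invalid p of exactly 0
wald_pval <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

.nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Derive a replicate seed from a base seed
#'
#' Deterministically folds a replicate index into a base seed, staying
#' within the 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param i Replicate index (>= 0).
#' @return Integer seed.
#' @export
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% .Machine$integer.max)
}

#' Simulate a two-sample GWAS summary-statistics study
#'
#' Generates paired exposure and outcome summary datasets with known ground
#' truth under the standardized-trait model: per-SNP instrument effects
#' `gamma_j` are rescaled so the instruments jointly explain `total_r2` of
#' exposure variance; sampling noise scales with sample size and allele
#' frequency (`se_x = 1/sqrt(2 p (1-p) N_x)`, and for the binary outcome
#' `se_y = 1/sqrt(2 p (1-p) N_y K (1-K))` on the log-odds scale); the
#' outcome mean is `theta * gamma_j` plus a per-SNP direct effect drawn
#' according to the pleiotropy mode. A configurable fraction of outcome
#' records is presented with swapped alleles and/or on the complementary
#' strand, which harmonization must undo; LD blocks append tagged satellite
#' SNPs with a pairwise LD table; a confounder-association table marks a
#' configurable subset of instruments.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `mr_simulation`: list with `exposure` and
#'   `outcome` (`gwas_dataset`s, the outcome in presented orientation),
#'   `truth` (list: `theta`, `gamma`, `alpha`, `maf`, `eaf`,
#'   `instrument_ids`, `outcome_sign` giving the presented sign of each
#'   instrument's outcome effect, `outliers`), `ld` (an `ld_table` or
#'   `NULL`), `confounders` (a `confounder_table` or `NULL`), and `config`.
#' @export
simulate_two_sample <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    k <- cfg$k_snps
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    het <- 2 * maf * (1 - maf)
    gamma <- stats::rnorm(k)
    gamma <- gamma * sqrt(cfg$total_r2 / sum(het * gamma^2))
    se_x <- 1 / sqrt(het * cfg$n_exposure)
    beta_x <- stats::rnorm(k, gamma, se_x)
    alpha <- switch(cfg$pleiotropy_mode,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      correlated = stats::rnorm(k, cfg$pleiotropy_cor * gamma, cfg$pleiotropy_sd))
    kk <- cfg$case_fraction * (1 - cfg$case_fraction)
    se_y <- 1 / sqrt(het * cfg$n_outcome * kk)
    beta_y <- stats::rnorm(k, cfg$theta * gamma + alpha, se_y)

    snp_id <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    occ <- stats::ave(seq_len(k), chrom, FUN = seq_along)
    pos <- 1e6 + (occ - 1) * 2.5e7
    pal <- stats::runif(k) < cfg$palindromic_fraction
    pick <- function(tbl, n) tbl[sample.int(nrow(tbl), n, replace = TRUE), , drop = FALSE]
    alleles <- matrix(NA_character_, k, 2)
    if (any(pal)) alleles[pal, ] <- pick(.pal_pairs, sum(pal))
    if (any(!pal)) alleles[!pal, ] <- pick(.nonpal_pairs, sum(!pal))
    # effect allele is the minor or the major allele with equal probability
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)

    exposure_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta_x, se = se_x,
      pval = wald_pval(beta_x, se_x),
      n = cfg$n_exposure, stringsAsFactors = FALSE)

    # presented outcome orientation: swap effect/other allele, flip strand,
    # or both, for a configurable fraction of SNPs
    scramble <- stats::runif(k) < cfg$strand_flip_fraction
    op <- ifelse(scramble, sample(c("swap", "flip", "flip_swap"), k, replace = TRUE),
                 "none")
    swap <- op %in% c("swap", "flip_swap")
    flip <- op %in% c("flip", "flip_swap")
    y_ea <- alleles[, 1]; y_oa <- alleles[, 2]
    y_beta <- beta_y; y_eaf <- eaf
    y_ea[swap] <- alleles[swap, 2]; y_oa[swap] <- alleles[swap, 1]
    y_beta[swap] <- -beta_y[swap]; y_eaf[swap] <- 1 - eaf[swap]
    y_ea[flip] <- unname(.complement[y_ea[flip]])
    y_oa[flip] <- unname(.complement[y_oa[flip]])
    outcome_sign <- ifelse(swap, -1, 1)

    outcome_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = y_ea, other_allele = y_oa,
      eaf = y_eaf, beta = y_beta, se = se_y,
      pval = wald_pval(y_beta, se_y),
      n = cfg$n_outcome,
      n_cases = round(cfg$case_fraction * cfg$n_outcome),
      stringsAsFactors = FALSE)

    ld <- NULL
    if (!is.null(cfg$ld_blocks)) {
      lb <- cfg$ld_blocks
      stopifnot(lb$n_blocks <= k, lb$snps_per_block >= 2)
      tags <- list(); ld_rows <- list()
      for (b in seq_len(lb$n_blocks)) {
        idx <- b  # block anchored at instrument b
        members <- sprintf("%s_tag%d", snp_id[idx], seq_len(lb$snps_per_block - 1))
        for (m in seq_along(members)) {
          tb <- stats::rnorm(1, gamma[idx] * sqrt(lb$within_r2), se_x[idx])
          tags[[length(tags) + 1L]] <- data.frame(
            snp_id = members[m], chrom = chrom[idx],
            pos = pos[idx] + m * 5e4,
            effect_allele = alleles[idx, 1], other_allele = alleles[idx, 2],
            eaf = eaf[idx], beta = tb, se = se_x[idx],
            # tag p kept above the index SNP's so the index wins clumping
            pval = pmin(1, wald_pval(tb, se_x[idx]) + exposure_df$pval[idx]),
            n = cfg$n_exposure, stringsAsFactors = FALSE)
        }
        grp <- c(snp_id[idx], members)
        pr <- t(utils::combn(grp, 2))
        ld_rows[[b]] <- data.frame(snp_a = pr[, 1], snp_b = pr[, 2],
                                   r2 = lb$within_r2, stringsAsFactors = FALSE)
      }
      exposure_df <- rbind(exposure_df, do.call(rbind, tags))
      ld <- ld_table(do.call(rbind, ld_rows))
    }

    confounders <- NULL
    if (cfg$n_confounded > 0) {
      hit <- snp_id[seq_len(cfg$n_confounded)]
      others <- setdiff(snp_id, hit)
      null_ids <- others[seq_len(min(5, length(others)))]
      confounders <- confounder_table(data.frame(
        snp_id = c(hit, null_ids),
        trait = "body mass index",
        pval = c(rep(1e-10, length(hit)),
                 stats::runif(length(null_ids), 0.05, 1)),
        stringsAsFactors = FALSE))
    }

    structure(list(
      exposure = gwas_dataset(exposure_df, "simulated exposure", "continuous",
                              source = "simulate_two_sample"),
      outcome = gwas_dataset(outcome_df, "simulated outcome", "binary",
                             source = "simulate_two_sample"),
      truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                   maf = maf, eaf = eaf, instrument_ids = snp_id,
                   outcome_sign = outcome_sign, outliers = character(0)),
      ld = ld, confounders = confounders, config = cfg),
      class = "mr_simulation")
  })
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("Simulated two-sample study: %d instruments, theta = %.4f, pleiotropy %s\n",
              x$config$k_snps, x$truth$theta, x$config$pleiotropy_mode))
  invisible(x)
}

#' Inject a pleiotropic outlier into a simulated study
#'
#' Shifts one instrument's outcome effect by a multiple of its standard
#' error (applied in the SNP's presented orientation, so downstream
#' harmonization sees a consistent record) and annotates the ground truth.
#'
#' @param study An `mr_simulation`.
#' @param snp_index Index of the instrument to perturb (1-based, among the
#'   original instruments).
#' @param offset Shift in units of the SNP's outcome standard error.
#' @return The modified `mr_simulation`.
#' @export
inject_outlier <- function(study, snp_index, offset) {
  stopifnot(inherits(study, "mr_simulation"),
            snp_index >= 1, snp_index <= length(study$truth$instrument_ids))
  id <- study$truth$instrument_ids[snp_index]
  d <- study$outcome$data
  i <- match(id, d$snp_id)
  shift <- study$truth$outcome_sign[snp_index] * offset * d$se[i]
  d$beta[i] <- d$beta[i] + shift
  d$pval[i] <- wald_pval(d$beta[i], d$se[i])
  study$outcome$data <- d
  if (offset != 0)
    study$truth$outliers <- union(study$truth$outliers, id)
  study
}
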