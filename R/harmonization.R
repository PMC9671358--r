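.kept_status <- c("direct", "swapped", "strand_flipped", "strand_flipped_swapped")
.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are complementary (A/T or C/G),
#' so the strand cannot be inferred from the alleles alone.
#'
#' @param effect_allele,other_allele Single-base alleles (vectors recycled).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele); oa <- toupper(other_allele)
  unname(.complement[ea] == oa)
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome effect to the exposure's effect allele. Resolution
#' order: (1) direct allele match; (2) swapped alleles (outcome beta
#' negated, EAF reflected); (3) complementary-strand match, then case 1 or
#' 2; (4) palindromic SNPs, for which cases 1-3 are ambiguous, are oriented
#' by allele-frequency concordance provided both EAFs lie outside the
#' ambiguity window around 0.5, and are dropped otherwise; (5) anything
#' else is incompatible.
#'
#' @param x,y Single-row data frames (or lists) with fields
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se` for the
#'   exposure and outcome respectively.
#' @param ambiguity_window Half-width of the EAF interval around 0.5 within
#'   which a palindromic SNP cannot be oriented (default 0.08, i.e.
#'   ambiguous when EAF is in \[0.42, 0.58\]).
#' @return One-row data frame with columns `snp_id`, `beta_x`, `se_x`,
#'   `eaf_x`, `beta_y`, `se_y`, `eaf_y`, `status`.
#' @export
harmonize_pair <- function(x, y, ambiguity_window = 0.08) {
  if (!identical(as.character(x$snp_id), as.character(y$snp_id)))
    stop("exposure and outcome records refer to different SNPs")
  res <- harmonize_vec(
    x_ea = x$effect_allele, x_oa = x$other_allele, eaf_x = x$eaf,
    y_ea = y$effect_allele, y_oa = y$other_allele, eaf_y = y$eaf,
    beta_y = y$beta, ambiguity_window = ambiguity_window)
  data.frame(snp_id = as.character(x$snp_id),
             beta_x = x$beta, se_x = x$se, eaf_x = x$eaf,
             beta_y = res$beta_y, se_y = y$se, eaf_y = res$eaf_y,
             status = res$status, stringsAsFactors = FALSE)
}

# Vectorized harmonization core; returns oriented beta_y/eaf_y and status.
harmonize_vec <- function(x_ea, x_oa, eaf_x, y_ea, y_oa, eaf_y, beta_y,
                          ambiguity_window = 0.08) {
  n <- length(x_ea)
  x_ea <- toupper(x_ea); x_oa <- toupper(x_oa)
  y_ea <- toupper(y_ea); y_oa <- toupper(y_oa)
  yc_ea <- unname(.complement[y_ea]); yc_oa <- unname(.complement[y_oa])
  status <- rep("dropped_incompatible", n)
  out_beta <- beta_y
  out_eaf <- eaf_y
  pal <- is_palindromic(x_ea, x_oa)

  direct <- !pal & y_ea == x_ea & y_oa == x_oa
  swapped <- !pal & y_ea == x_oa & y_oa == x_ea
  flip_direct <- !pal & !direct & !swapped & yc_ea == x_ea & yc_oa == x_oa
  flip_swap <- !pal & !direct & !swapped & yc_ea == x_oa & yc_oa == x_ea
  status[direct] <- "direct"
  status[flip_direct] <- "strand_flipped"
  status[swapped] <- "swapped"
  status[flip_swap] <- "strand_flipped_swapped"
  neg <- swapped | flip_swap
  out_beta[neg] <- -beta_y[neg]
  out_eaf[neg] <- 1 - eaf_y[neg]

  # palindromic: alleles must still form the same pair on either strand
  pal_ok <- pal & ((y_ea == x_ea & y_oa == x_oa) | (y_ea == x_oa & y_oa == x_ea))
  status[pal & !pal_ok] <- "dropped_incompatible"
  lo <- 0.5 - ambiguity_window; hi <- 0.5 + ambiguity_window
  inform <- pal_ok & !is.na(eaf_x) & !is.na(eaf_y) &
    (eaf_x < lo | eaf_x > hi) & (eaf_y < lo | eaf_y > hi)
  status[pal_ok & !inform] <- "dropped_palindromic_ambiguous"
  agree <- (eaf_x < 0.5) == (eaf_y < 0.5)
  pal_keep <- inform & agree
  pal_flip <- inform & !agree
  status[pal_keep] <- "direct"
  status[pal_flip] <- "swapped"
  out_beta[pal_flip] <- -beta_y[pal_flip]
  out_eaf[pal_flip] <- 1 - eaf_y[pal_flip]

  kept <- status %in% .kept_status
  out_beta[!kept] <- NA_real_
  out_eaf[!kept] <- NA_real_
  list(beta_y = out_beta, eaf_y = out_eaf, status = status)
}

#' Harmonize exposure and outcome summary datasets
#'
#' Matches exposure instruments to the outcome dataset by SNP id and aligns
#' every pair to the exposure's effect allele. Instruments absent from the
#' outcome are reported as `dropped_missing_outcome`; SNP ids occurring more
#' than once in either dataset are reported as `dropped_duplicate`;
#' remaining pairs run through [harmonize_pair()] logic. The report's status
#' counts always sum to the number of instruments offered.
#'
#' @param exposure,outcome `gwas_dataset` objects.
#' @param ambiguity_window See [harmonize_pair()].
#' @return Object of class `mr_harmonized`: list with `pairs` (data frame
#'   with one row per offered instrument, columns `snp_id`, `beta_x`,
#'   `se_x`, `eaf_x`, `beta_y`, `se_y`, `eaf_y`, `status`) and `report`
#'   (status counts and dropped-SNP listing).
#' @export
harmonize <- function(exposure, outcome, ambiguity_window = 0.08) {
  stopifnot(inherits(exposure, "gwas_dataset"), inherits(outcome, "gwas_dataset"))
  ex <- exposure$data
  out <- outcome$data
  dup_x <- ex$snp_id[duplicated(ex$snp_id)]
  dup_y <- out$snp_id[duplicated(out$snp_id)]
  dup <- unique(c(dup_x, dup_y))

  pairs <- data.frame(snp_id = ex$snp_id, beta_x = ex$beta, se_x = ex$se,
                      eaf_x = ex$eaf, beta_y = NA_real_, se_y = NA_real_,
                      eaf_y = NA_real_, status = NA_character_,
                      stringsAsFactors = FALSE)
  is_dup <- pairs$snp_id %in% dup
  # keep one row per duplicated exposure id so counts stay conserved
  keep_row <- !duplicated(pairs$snp_id)
  pairs <- pairs[keep_row, , drop = FALSE]
  is_dup <- is_dup[keep_row]
  pairs$status[is_dup] <- "dropped_duplicate"

  m <- match(pairs$snp_id, out$snp_id)
  missing_y <- is.na(m) & !is_dup
  pairs$status[missing_y] <- "dropped_missing_outcome"

  todo <- which(!is_dup & !is.na(m))
  if (length(todo)) {
    i <- todo; j <- m[todo]
    ex2 <- ex[keep_row, , drop = FALSE]
    res <- harmonize_vec(
      x_ea = ex2$effect_allele[i], x_oa = ex2$other_allele[i],
      eaf_x = ex2$eaf[i],
      y_ea = out$effect_allele[j], y_oa = out$other_allele[j],
      eaf_y = out$eaf[j], beta_y = out$beta[j],
      ambiguity_window = ambiguity_window)
    pairs$beta_y[i] <- res$beta_y
    pairs$se_y[i] <- out$se[j]
    pairs$eaf_y[i] <- res$eaf_y
    pairs$status[i] <- res$status
  }
  n_dup_extra <- sum(!keep_row)
  counts <- table(factor(pairs$status,
                         levels = c(.kept_status, "dropped_palindromic_ambiguous",
                                    "dropped_incompatible", "dropped_missing_outcome",
                                    "dropped_duplicate")))
  counts <- as.list(as.integer(counts) + ifelse(names(counts) == "dropped_duplicate",
                                                n_dup_extra, 0L))
  names(counts) <- c(.kept_status, "dropped_palindromic_ambiguous",
                     "dropped_incompatible", "dropped_missing_outcome",
                     "dropped_duplicate")
  dropped <- pairs[!(pairs$status %in% .kept_status), c("snp_id", "status")]
  structure(list(pairs = pairs,
                 report = list(offered = nrow(ex), counts = counts,
                               kept = sum(pairs$status %in% .kept_status),
                               dropped = dropped)),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized pairs: %d offered, %d kept\n",
              x$report$offered, x$report$kept))
  cnt <- unlist(x$report$counts)
  cnt <- cnt[cnt > 0]
  for (s in names(cnt)) cat(sprintf("  %-30s %d\n", s, cnt[[s]]))
  invisible(x)
}

#' Extract the analysis-ready harmonized pairs
#'
#' Returns the non-dropped rows of a harmonization result (or passes a
#' plain data frame of pairs through unchanged, for programmatic use).
#'
#' @param x An `mr_harmonized` object or a data frame with at least
#'   `beta_x`, `se_x`, `beta_y`, `se_y` columns.
#' @return Data frame of harmonized pairs.
#' @export
kept_pairs <- function(x) {
  if (inherits(x, "mr_harmonized"))
    return(x$pairs[x$pairs$status %in% .kept_status, , drop = FALSE])
  stopifnot(is.data.frame(x),
            all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(x)))
  x
}
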