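#' Instrument-selection configuration
#'
#' Thresholds for screening genetic instruments from an exposure GWAS:
#' genome-wide significance, minor-allele-frequency floor, LD-clumping
#' r-squared ceiling and physical window, and the weak-instrument
#' F-statistic floor. All inequalities are applied strictly.
#'
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param clump_r2_max Maximum tolerated r-squared between retained
#'   instruments within the window (default 0.001).
#' @param clump_window_kb Clumping window in kilobases (default 10000).
#' @param f_min Weak-instrument F threshold (default 10).
#' @param strict_ld If `TRUE`, SNPs within the window whose LD with an
#'   accepted SNP is unknown are dropped rather than retained.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8, maf_min = 0.01,
                             clump_r2_max = 0.001, clump_window_kb = 10000,
                             f_min = 10, strict_ld = FALSE) {
  stopifnot(p_threshold > 0, maf_min > 0, clump_r2_max > 0, clump_r2_max < 1,
            clump_window_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, maf_min = maf_min,
                 clump_r2_max = clump_r2_max, clump_window_kb = clump_window_kb,
                 f_min = f_min, strict_ld = isTRUE(strict_ld)),
            class = "selection_config")
}

#' Genome-wide significance and MAF screen
#'
#' Retains records with `pval` strictly below the significance threshold and
#' minor allele frequency (`min(eaf, 1 - eaf)`) strictly above the floor.
#' Records without an EAF cannot pass the MAF screen and are dropped.
#' Input order is preserved.
#'
#' @param dataset A `gwas_dataset`.
#' @param cfg A [selection_config()].
#' @return A filtered `gwas_dataset`; the tally of rows removed at this step
#'   is recorded in its `dropped` element.
#' @export
select_significant <- function(dataset, cfg = selection_config()) {
  stopifnot(inherits(dataset, "gwas_dataset"))
  d <- dataset$data
  maf <- pmin(d$eaf, 1 - d$eaf)
  keep_p <- !is.na(d$pval) & d$pval < cfg$p_threshold
  keep_maf <- !is.na(maf) & maf > cfg$maf_min
  tally <- c(not_significant = sum(!keep_p),
             low_maf = sum(keep_p & !keep_maf))
  dataset$data <- d[keep_p & keep_maf, , drop = FALSE]
  dataset$dropped <- tally[tally > 0]
  dataset
}

#' Greedy LD clumping
#'
#' Prunes correlated instruments: candidates are visited in order of
#' ascending p-value (ties broken by chromosome then position, so results
#' are deterministic) and a SNP is rejected if, versus any already-accepted
#' SNP, it lies on the same chromosome within the window and its known
#' r-squared exceeds the ceiling. Unknown LD within the window retains the
#' SNP by default (`strict_ld = FALSE`) and drops it otherwise.
#'
#' When positions are missing, the physical-window condition cannot be
#' evaluated: if an LD table is supplied, LD alone decides; if neither
#' positions nor an LD table are available an error asks for one of them.
#'
#' @param dataset A `gwas_dataset`.
#' @param ld An [ld_table()] or `NULL`.
#' @param cfg A [selection_config()].
#' @return The clumped `gwas_dataset`; `attr(, "removals")` is a data frame
#'   listing each removed SNP and the index SNP responsible.
#' @export
clump <- function(dataset, ld = NULL, cfg = selection_config()) {
  stopifnot(inherits(dataset, "gwas_dataset"))
  d <- dataset$data
  if (nrow(d) == 0) return(dataset)
  have_pos <- !any(is.na(d$chrom)) && !any(is.na(d$pos))
  if (!have_pos && is.null(ld))
    stop("clumping needs chromosome/position columns or an LD table; ",
         "supply one of them")
  ord <- order(d$pval, d$chrom, d$pos, d$snp_id)
  window_bp <- cfg$clump_window_kb * 1000
  accepted <- integer(0)
  removals <- list()
  for (i in ord) {
    reject_by <- NA_character_
    for (j in accepted) {
      in_window <- if (have_pos)
        d$chrom[i] == d$chrom[j] && abs(d$pos[i] - d$pos[j]) <= window_bp
      else TRUE
      if (!in_window) next
      r2 <- ld_lookup(ld, d$snp_id[i], d$snp_id[j])
      if ((!is.na(r2) && r2 > cfg$clump_r2_max) || (is.na(r2) && cfg$strict_ld)) {
        reject_by <- d$snp_id[j]
        break
      }
    }
    if (is.na(reject_by)) accepted <- c(accepted, i)
    else removals[[length(removals) + 1L]] <-
        data.frame(snp_id = d$snp_id[i], index_snp = reject_by)
  }
  accepted <- sort(accepted)  # preserve input order in the output
  removals <- if (length(removals)) do.call(rbind, removals)
              else data.frame(snp_id = character(0), index_snp = character(0))
  dataset$data <- d[accepted, , drop = FALSE]
  dataset$dropped <- c(clumped = nrow(removals))[nrow(removals) > 0]
  attr(dataset, "removals") <- removals
  dataset
}

#' Exposure variance explained by one instrument
#'
#' The proportion of trait variance explained by a SNP, computed from the
#' effect size, its standard error and the sample size in the standard
#' reduced form \eqn{R^2 = \beta^2 / (\beta^2 + N \sigma^2)}. This form
#' follows because both \eqn{\beta^2} and the sampling noise term share the
#' factor \eqn{2\,\mathrm{EAF}(1-\mathrm{EAF})}, which cancels; the result
#' does not depend on the allele frequency. `formula = "verbatim"` instead
#' evaluates the literal expression
#' \eqn{2p(1-p)\beta^2 / (2p(1-p)\beta^2 + 2p(1-p)\,\sigma N \beta^2)}
#' for auditing against sources that print it in that (degenerate) form.
#'
#' @param beta,se,n Effect size, standard error (> 0) and sample size (> 2);
#'   vectors are recycled.
#' @param formula `"standard"` (default) or `"verbatim"`.
#' @return Fraction of variance explained, in \[0, 1).
#' @export
variance_explained <- function(beta, se, n, formula = c("standard", "verbatim")) {
  formula <- match.arg(formula)
  stopifnot(all(se > 0, na.rm = TRUE))
  if (any(n <= 2, na.rm = TRUE)) stop("sample size must exceed 2")
  if (formula == "standard") beta^2 / (beta^2 + n * se^2)
  else beta^2 / (beta^2 + se * n * beta^2)
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}; values above 10 are conventionally
#' taken to indicate a sufficiently strong instrument.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size (> 2).
#' @return F statistic (>= 0).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) stop("r2 must lie in [0, 1)")
  if (any(n <= 2, na.rm = TRUE)) stop("sample size must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Per-instrument strength table
#'
#' @param dataset A `gwas_dataset` with `beta`, `se` and `n` populated.
#' @return Data frame with columns `snp_id`, `r2_explained`, `f_stat`.
#' @export
instrument_strength <- function(dataset) {
  stopifnot(inherits(dataset, "gwas_dataset"))
  d <- dataset$data
  r2 <- variance_explained(d$beta, d$se, d$n)
  data.frame(snp_id = d$snp_id, r2_explained = r2,
             f_stat = f_statistic(r2, d$n))
}

#' Drop instruments associated with measured confounders
#'
#' Removes any instrument having at least one confounder association with
#' p-value strictly below the threshold; the returned dataset carries a
#' per-SNP listing of the offending traits.
#'
#' @param instruments A `gwas_dataset` of selected instruments.
#' @param table A [confounder_table()].
#' @param p_threshold Association threshold (default 5e-8, strict `<`).
#' @return Filtered `gwas_dataset`; `attr(, "confounder_hits")` lists each
#'   dropped SNP with its associated trait(s).
#' @export
filter_confounders <- function(instruments, table, p_threshold = 5e-8) {
  stopifnot(inherits(instruments, "gwas_dataset"))
  hits <- table[table$pval < p_threshold &
                  table$snp_id %in% instruments$data$snp_id, , drop = FALSE]
  drop_ids <- unique(hits$snp_id)
  keep <- !(instruments$data$snp_id %in% drop_ids)
  instruments$data <- instruments$data[keep, , drop = FALSE]
  instruments$dropped <- c(confounder_associated = length(drop_ids))[length(drop_ids) > 0]
  attr(instruments, "confounder_hits") <-
    if (nrow(hits)) aggregate(trait ~ snp_id, hits,
                              function(t) paste(unique(t), collapse = ","))
    else data.frame(snp_id = character(0), trait = character(0))
  instruments
}

#' Full instrument-selection stage
#'
#' Applies the significance/MAF screen, greedy LD clumping, and the
#' weak-instrument F filter in sequence, returning the surviving instruments
#' together with a per-stage count report.
#'
#' @param dataset Exposure `gwas_dataset`.
#' @param ld Optional [ld_table()].
#' @param cfg A [selection_config()].
#' @return List of class `instrument_selection` with elements `instruments`
#'   (a `gwas_dataset`), `strength` (per-SNP R-squared and F), and `report`
#'   (counts at each filter; counts are conserved stage to stage).
#' @export
select_instruments <- function(dataset, ld = NULL, cfg = selection_config()) {
  offered <- nrow(dataset$data)
  sig <- select_significant(dataset, cfg)
  cl <- clump(sig, ld, cfg)
  d <- cl$data
  weak <- rep(FALSE, nrow(d))
  strength <- NULL
  if (nrow(d) && !any(is.na(d$n))) {
    strength <- instrument_strength(cl)
    weak <- strength$f_stat <= cfg$f_min
  }
  out <- cl
  out$data <- d[!weak, , drop = FALSE]
  report <- list(
    offered = offered,
    after_significance = nrow(sig$data),
    after_clumping = nrow(cl$data),
    after_f_filter = nrow(out$data),
    dropped = list(significance_maf = as.list(sig$dropped),
                   clumped = nrow(cl$data) - nrow(sig$data) + 0L,
                   weak_instruments = sum(weak)),
    clump_removals = attr(cl, "removals")
  )
  report$dropped$clumped <- nrow(sig$data) - nrow(cl$data)
  structure(list(instruments = out,
                 strength = if (is.null(strength)) strength
                            else strength[!weak, , drop = FALSE],
                 report = report),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  r <- x$report
  cat("Instrument selection\n")
  cat(sprintf("  offered: %d\n  after p/MAF screen: %d\n  after clumping: %d\n  after F filter: %d\n",
              r$offered, r$after_significance, r$after_clumping, r$after_f_filter))
  invisible(x)
}
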