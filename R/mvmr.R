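#' Assemble a multivariable MR input from several exposure datasets
#'
#' Builds the joint instrument set for multivariable MR: the union of each
#' exposure's genome-wide-significant SNPs, jointly clumped using the
#' minimum p-value across exposures, restricted to SNPs present in every
#' exposure and in the outcome, and harmonized to the first exposure's
#' allele orientation.
#'
#' @param exposures List of `gwas_dataset` objects (the first is the
#'   exposure of interest; the rest are covariate exposures).
#' @param outcome Outcome `gwas_dataset`.
#' @param ld Optional [ld_table()] for joint clumping.
#' @param cfg A [selection_config()].
#' @param ambiguity_window See [harmonize_pair()].
#' @return Object of class `mvmr_input`: list with `snp_ids` (length J),
#'   `exposure_labels` (length E), `beta_x`/`se_x` (J x E matrices),
#'   `beta_y`/`se_y` (length J), and `report` (per-stage counts).
#' @export
mvmr_harmonize <- function(exposures, outcome, ld = NULL,
                           cfg = selection_config(), ambiguity_window = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 1,
            inherits(outcome, "gwas_dataset"))
  labels <- vapply(exposures, function(d) d$trait_label, character(1))
  E <- length(exposures)

  sig_ids <- lapply(exposures, function(d) select_significant(d, cfg)$data$snp_id)
  union_ids <- unique(unlist(sig_ids))
  if (!length(union_ids)) stop("no genome-wide significant SNPs in any exposure")

  # joint clumping: one candidate row per SNP, p = min across exposures
  first_rec <- function(id) {
    for (d in exposures) {
      hit <- which(d$data$snp_id == id)
      if (length(hit)) return(d$data[hit[1], , drop = FALSE])
    }
  }
  cand <- do.call(rbind, lapply(union_ids, first_rec))
  cand$pval <- vapply(union_ids, function(id) {
    min(vapply(exposures, function(d) {
      p <- d$data$pval[d$data$snp_id == id]
      if (length(p)) min(p) else Inf
    }, numeric(1)))
  }, numeric(1))
  clumped <- clump(gwas_dataset(cand, "joint", "continuous"), ld, cfg)
  ids <- clumped$data$snp_id

  present_all <- vapply(ids, function(id) {
    all(vapply(exposures, function(d) id %in% d$data$snp_id, logical(1))) &&
      id %in% outcome$data$snp_id
  }, logical(1))
  missing_ids <- ids[!present_all]
  ids <- ids[present_all]
  if (!length(ids)) stop("joint instrument set is empty after presence filter")

  ref <- exposures[[1]]$data[match(ids, exposures[[1]]$data$snp_id), , drop = FALSE]
  orient <- function(d) {
    rec <- d[match(ids, d$snp_id), , drop = FALSE]
    harmonize_vec(x_ea = ref$effect_allele, x_oa = ref$other_allele,
                  eaf_x = ref$eaf,
                  y_ea = rec$effect_allele, y_oa = rec$other_allele,
                  eaf_y = rec$eaf, beta_y = rec$beta,
                  ambiguity_window = ambiguity_window)
  }
  beta_x <- matrix(NA_real_, length(ids), E)
  se_x <- matrix(NA_real_, length(ids), E)
  ok <- rep(TRUE, length(ids))
  for (e in seq_len(E)) {
    res <- orient(exposures[[e]]$data)
    rec <- exposures[[e]]$data[match(ids, exposures[[e]]$data$snp_id), , drop = FALSE]
    beta_x[, e] <- res$beta_y
    se_x[, e] <- rec$se
    ok <- ok & res$status %in% .kept_status
  }
  res_y <- orient(outcome$data)
  rec_y <- outcome$data[match(ids, outcome$data$snp_id), , drop = FALSE]
  ok <- ok & res_y$status %in% .kept_status
  n_unharmonizable <- sum(!ok)

  structure(list(snp_ids = ids[ok], exposure_labels = labels,
                 beta_x = beta_x[ok, , drop = FALSE],
                 se_x = se_x[ok, , drop = FALSE],
                 beta_y = res_y$beta_y[ok], se_y = rec_y$se[ok],
                 report = list(union_significant = length(union_ids),
                               after_joint_clump = length(present_all),
                               missing_somewhere = length(missing_ids),
                               unharmonizable = n_unharmonizable,
                               retained = sum(ok),
                               missing_ids = missing_ids)),
            class = "mvmr_input")
}

#' Multivariable IVW Mendelian randomization
#'
#' Weighted least squares of the outcome effects on the J x E matrix of
#' exposure effects without an intercept, weights `se_y^-2`; each
#' coefficient is the direct effect of that exposure conditional on the
#' others. Coefficient standard errors are scaled by `max(1, residual
#' scale)` and p-values refer to a t distribution with J - E degrees of
#' freedom. With a single exposure the point estimate reduces exactly to
#' the fixed-effects IVW estimate.
#'
#' @param input An `mvmr_input` (J > E), or a list with elements `beta_x`
#'   (J x E matrix), `beta_y`, `se_y` and optionally `exposure_labels`.
#' @return Object of class `mvmr_fit`: list with `results` (one
#'   `mr_result` per exposure, method `"mvmr_ivw"`), `estimates` (data
#'   frame with an `exposure` column), and `scale`.
#' @export
mvmr_ivw <- function(input) {
  X <- as.matrix(input$beta_x)
  y <- input$beta_y
  w <- input$se_y^-2
  J <- nrow(X); E <- ncol(X)
  labels <- input$exposure_labels
  if (is.null(labels)) labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("exposure", seq_len(E))
  if (J <= E) stop("multivariable IVW needs more instruments than exposures")
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < E) {
    dep <- labels[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinear exposure effects: ", paste(dep, collapse = ", "))
  }
  fit <- wls_fit(X, y, w)
  df <- J - E
  rss <- sum(w * (y - fit$fitted)^2)
  scale <- max(1, sqrt(rss / df))
  se <- sqrt(diag(fit$cov_unscaled)) * scale
  pv <- 2 * stats::pt(-abs(fit$coef / se), df)
  results <- lapply(seq_len(E), function(e)
    mr_result("mvmr_ivw", fit$coef[e], se[e], pv[e], J,
              extras = list(exposure = labels[e], scale = scale)))
  names(results) <- labels
  estimates <- do.call(rbind, lapply(results, as.data.frame))
  estimates <- cbind(exposure = labels, estimates)
  rownames(estimates) <- NULL
  structure(list(results = results, estimates = estimates, scale = scale,
                 input = input),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable IVW MR (%d instruments, %d exposures)\n",
              nrow(as.matrix(x$input$beta_x)), length(x$results)))
  print(x$estimates, digits = digits, row.names = FALSE)
  invisible(x)
}
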