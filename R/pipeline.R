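#' Run the full two-sample MR workflow
#'
#' Orchestrates the complete analysis in the standard order: instrument
#' selection (significance/MAF screen, LD clumping, F filter) ->
#' harmonization -> causal estimation (fe-IVW, mre-IVW, weighted median,
#' MR-Egger) -> sensitivity analysis (Cochran's Q, MR-PRESSO, leave-one-out,
#' funnel data). When MR-PRESSO flags outliers, all estimators and the
#' heterogeneity/PRESSO tests are re-run without them and both sets of
#' results are reported. When a confounder-association table is supplied,
#' the estimate + PRESSO cycle is repeated on the confounder-filtered
#' instrument set. Covariate exposures trigger multivariable MR, one
#' adjusted model per covariate. Power calculations use the instruments'
#' summed variance explained and the outcome's case fraction when
#' available.
#'
#' @param exposure,outcome `gwas_dataset` objects (or paths readable with
#'   the default [gwas_colmap()]).
#' @param ld Optional [ld_table()] (or path).
#' @param confounders Optional [confounder_table()] (or path).
#' @param covariates Optional list of covariate `gwas_dataset`s for
#'   multivariable MR.
#' @param cfg A [selection_config()].
#' @param ambiguity_window See [harmonize_pair()].
#' @param n_boot Weighted-median bootstrap resamples.
#' @param presso_sims MR-PRESSO simulated replicates.
#' @param seed Integer seed governing all stochastic steps.
#' @param power_or Odds ratio at which to evaluate power (default the
#'   fitted fe-IVW OR).
#' @param out_dir Optional directory; when given, `report.json`,
#'   `estimates.tsv`, `pairs.tsv`, `loo.tsv` and `funnel.tsv` are written.
#' @return Object of class `mr_report` (see [validate_report()] for its
#'   schema): all stage counts, estimates and sensitivity results.
#' @export
run_pipeline <- function(exposure, outcome, ld = NULL, confounders = NULL,
                         covariates = NULL, cfg = selection_config(),
                         ambiguity_window = 0.08, n_boot = 1000,
                         presso_sims = 1000, seed = 1, power_or = NULL,
                         out_dir = NULL) {
  if (is.character(exposure)) exposure <- read_gwas(exposure)
  if (is.character(outcome)) outcome <- read_gwas(outcome, trait_type = "binary")
  if (is.character(ld)) ld <- read_ld_table(ld)
  if (is.character(confounders)) confounders <- read_confounder_table(confounders)
  stage <- "instrument_selection"
  report <- list(package = "mrkit",
                 version = as.character(utils::packageVersion("mrkit")),
                 seed = seed,
                 config = list(p_threshold = cfg$p_threshold,
                               maf_min = cfg$maf_min,
                               clump_r2_max = cfg$clump_r2_max,
                               clump_window_kb = cfg$clump_window_kb,
                               f_min = cfg$f_min,
                               ambiguity_window = ambiguity_window,
                               n_boot = n_boot, presso_sims = presso_sims))
  tryCatch({
    sel <- select_instruments(exposure, ld, cfg)
    report$selection <- sel$report[c("offered", "after_significance",
                                     "after_clumping", "after_f_filter")]
    stopifnot(report$selection$offered >= report$selection$after_significance,
              report$selection$after_significance >= report$selection$after_clumping,
              report$selection$after_clumping >= report$selection$after_f_filter)

    stage <- "harmonization"
    harm <- harmonize(sel$instruments, outcome, ambiguity_window)
    stopifnot(sum(unlist(harm$report$counts)) == harm$report$offered)
    report$harmonization <- list(offered = harm$report$offered,
                                 kept = harm$report$kept,
                                 counts = harm$report$counts)

    stage <- "estimation"
    fit <- mr(harm, n_boot = n_boot, seed = seed)
    report$estimates <- fit$estimates

    stage <- "sensitivity"
    het <- fit$heterogeneity
    presso <- mr_presso(harm, n_sim = presso_sims, seed = seed)
    loo <- leave_one_out(harm)
    report$heterogeneity <- het[c("q", "df", "pval", "i2", "label")]
    report$presso <- list(rss_obs = presso$rss_obs,
                          global_pval = presso$global_pval,
                          outliers = as.list(presso$outliers))
    report$loo <- list(flag = loo$flag,
                       beta_range = range(loo$table$beta))
    funnel <- funnel_data(fit$ratios)

    if (length(presso$outliers)) {
      stage <- "post_outlier_reestimation"
      keep <- !(harm$pairs$snp_id %in% presso$outliers)
      harm2 <- harm
      harm2$pairs <- harm$pairs[keep, , drop = FALSE]
      fit2 <- mr(harm2, n_boot = n_boot, seed = seed)
      presso2 <- mr_presso(harm2, n_sim = presso_sims, seed = seed)
      report$post_outlier <- list(
        removed = as.list(presso$outliers),
        estimates = fit2$estimates,
        heterogeneity = fit2$heterogeneity[c("q", "df", "pval", "i2", "label")],
        presso_global_pval = presso2$global_pval)
    }

    if (!is.null(confounders)) {
      stage <- "confounder_filtering"
      filt <- filter_confounders(sel$instruments, confounders, cfg$p_threshold)
      harm_f <- harmonize(filt, outcome, ambiguity_window)
      fit_f <- mr(harm_f, n_boot = n_boot, seed = seed)
      presso_f <- mr_presso(harm_f, n_sim = presso_sims, seed = seed)
      cf <- list(kept = nrow(filt$data),
                 dropped = report$selection$after_f_filter - nrow(filt$data),
                 estimates = fit_f$estimates,
                 presso_global_pval = presso_f$global_pval,
                 outliers = as.list(presso_f$outliers))
      if (length(presso_f$outliers)) {
        keep <- !(harm_f$pairs$snp_id %in% presso_f$outliers)
        harm_f2 <- harm_f
        harm_f2$pairs <- harm_f$pairs[keep, , drop = FALSE]
        cf$post_outlier_estimates <- mr(harm_f2, n_boot = n_boot,
                                        seed = seed)$estimates
      }
      report$confounder_filtered <- cf
    }

    if (!is.null(covariates)) {
      stage <- "mvmr"
      report$mvmr <- lapply(covariates, function(cov) {
        inp <- mvmr_harmonize(list(exposure, cov), outcome, ld, cfg,
                              ambiguity_window)
        mvmr_ivw(inp)$estimates
      })
      names(report$mvmr) <- vapply(covariates, function(d) d$trait_label,
                                   character(1))
    }

    stage <- "power"
    d_out <- outcome$data
    if (!all(is.na(d_out$n_cases)) && !all(is.na(d_out$n))) {
      n_out <- stats::median(d_out$n, na.rm = TRUE)
      kf <- stats::median(d_out$n_cases / d_out$n, na.rm = TRUE)
      inst <- sel$instruments
      r2_sum <- if (!any(is.na(inst$data$n)))
        sum(variance_explained(inst$data$beta, inst$data$se, inst$data$n))
      else NA_real_
      if (is.finite(r2_sum) && r2_sum > 0 && r2_sum < 1) {
        target <- if (is.null(power_or)) exp(fit$results$fe_ivw$beta) else power_or
        det <- detectable_or(n_out, kf, r2_sum)
        report$power <- list(
          n_outcome = n_out, case_fraction = kf, r2_sum = r2_sum,
          or_evaluated = target,
          power = mr_power_binary(n_out, kf, r2_sum, target),
          detectable_or_low = det[["or_low"]],
          detectable_or_high = det[["or_high"]])
      }
    }

    report <- structure(report, class = "mr_report")
    validate_report(report)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(unclass_report(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.table(fit$estimates, file.path(out_dir, "estimates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(harm$pairs, file.path(out_dir, "pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(loo$table, file.path(out_dir, "loo.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(funnel, file.path(out_dir, "funnel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

unclass_report <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

#' @export
print.mr_report <- function(x, digits = 4, ...) {
  cat("Two-sample MR pipeline report\n")
  cat(sprintf("  selection: %d offered -> %d significant -> %d clumped -> %d strong\n",
              x$selection$offered, x$selection$after_significance,
              x$selection$after_clumping, x$selection$after_f_filter))
  cat(sprintf("  harmonization: %d offered -> %d kept\n",
              x$harmonization$offered, x$harmonization$kept))
  print(x$estimates, digits = digits, row.names = FALSE)
  cat(sprintf("  heterogeneity: Q = %.4g (p = %.3g), I2 = %.1f%% (%s)\n",
              x$heterogeneity$q, x$heterogeneity$pval, x$heterogeneity$i2,
              x$heterogeneity$label))
  cat(sprintf("  MR-PRESSO global p = %.4g; outliers: %s\n",
              x$presso$global_pval,
              if (length(x$presso$outliers))
                paste(unlist(x$presso$outliers), collapse = ", ") else "none"))
  if (!is.null(x$power))
    cat(sprintf("  power at OR %.3f: %.3f (detectable OR %.4f / %.4f)\n",
                x$power$or_evaluated, x$power$power,
                x$power$detectable_or_low, x$power$detectable_or_high))
  invisible(x)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the structural contract of an [run_pipeline()] report against
#' `inst/schema/report-schema.json`: required sections present, stage
#' counts numeric and conserved. Throws on violation.
#'
#' @param report An `mr_report`.
#' @return Invisibly `TRUE`.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report-schema.json", package = "mrkit")
  required <- if (nzchar(schema_path)) {
    sch <- jsonlite::read_json(schema_path)
    unlist(sch$required)
  } else c("package", "version", "seed", "config", "selection",
           "harmonization", "estimates", "heterogeneity", "presso", "loo")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("report is missing required sections: ",
         paste(missing, collapse = ", "))
  with(report$selection, stopifnot(
    offered >= after_significance, after_significance >= after_clumping,
    after_clumping >= after_f_filter))
  stopifnot(report$harmonization$kept <= report$harmonization$offered,
            sum(unlist(report$harmonization$counts)) ==
              report$harmonization$offered)
  invisible(TRUE)
}
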