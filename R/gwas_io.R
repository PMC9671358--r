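#' Column mapping for GWAS summary-statistics tables
#'
#' Describes how the columns of a delimited summary-statistics file map onto
#' the fields of a GWAS record. Only `snp_id`, `effect_allele`,
#' `other_allele`, `beta`, `se` and `pval` are required; the remaining fields
#' may be `NA` when the source table lacks them.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n,n_cases
#'   Source column names (character scalars), or `NA` for optional fields
#'   absent from the file.
#' @param delim Field delimiter (default tab).
#' @param na_tokens Tokens treated as missing values.
#' @return An object of class `gwas_colmap`.
#' @export
#' @examples
#' cm <- gwas_colmap(snp_id = "SNP", beta = "b", se = "se", pval = "p",
#'                   effect_allele = "A1", other_allele = "A2")
gwas_colmap <- function(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                        effect_allele = "effect_allele",
                        other_allele = "other_allele",
                        eaf = "eaf", beta = "beta", se = "se", pval = "pval",
                        n = "n", n_cases = NA_character_,
                        delim = "\t", na_tokens = c("NA", "", ".")) {
  cols <- c(snp_id = snp_id, chrom = chrom, pos = pos,
            effect_allele = effect_allele, other_allele = other_allele,
            eaf = eaf, beta = beta, se = se, pval = pval,
            n = n, n_cases = n_cases)
  req <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_req <- req[is.na(cols[req])]
  if (length(missing_req))
    stop("required fields not mapped: ", paste(missing_req, collapse = ", "))
  structure(list(cols = cols, delim = delim, na_tokens = na_tokens),
            class = "gwas_colmap")
}

.gwas_fields <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n", "n_cases")

#' Construct a GWAS summary dataset from a data frame
#'
#' Validates per-SNP association records and assembles them into a summary
#' dataset. Rows violating the record invariants (alleles not a pair of
#' distinct single bases A/C/G/T, `se <= 0`, `pval` outside (0, 1],
#' `eaf` outside \[0, 1\], `n <= 1`) are dropped and tallied by reason.
#' Alleles are upper-cased. Duplicate `snp_id`s are retained here (they are
#' handled explicitly during harmonization).
#'
#' @param data A data frame with (a subset of) columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`, `n_cases`.
#' @param trait_label Human-readable trait name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param source Provenance string (path or accession).
#' @return An object of class `gwas_dataset`: a list with elements
#'   `trait_label`, `trait_type`, `data` (the validated data frame),
#'   `source`, and `dropped` (named integer tally of dropped rows).
#' @export
gwas_dataset <- function(data, trait_label, trait_type = c("continuous", "binary"),
                         source = "in-memory") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  for (f in .gwas_fields)
    if (is.null(data[[f]]))
      data[[f]] <- if (f %in% c("snp_id", "chrom", "effect_allele", "other_allele"))
        NA_character_ else NA_real_
  data <- data[.gwas_fields]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases"))
    data[[f]] <- suppressWarnings(as.numeric(data[[f]]))

  bases <- c("A", "C", "G", "T")
  bad <- list(
    missing_required = is.na(data$snp_id) | is.na(data$beta) | is.na(data$se) |
      is.na(data$pval) | is.na(data$effect_allele) | is.na(data$other_allele),
    bad_alleles = !(data$effect_allele %in% bases) |
      !(data$other_allele %in% bases) |
      data$effect_allele == data$other_allele,
    nonpos_se = !is.na(data$se) & data$se <= 0,
    bad_pval = !is.na(data$pval) & (data$pval <= 0 | data$pval > 1),
    bad_eaf = !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1),
    bad_n = !is.na(data$n) & data$n <= 1
  )
  drop <- rep(FALSE, nrow(data))
  tally <- integer(0)
  for (reason in names(bad)) {
    hit <- bad[[reason]] & !drop
    hit[is.na(hit)] <- FALSE
    if (any(hit)) tally[reason] <- sum(hit)
    drop <- drop | hit
  }
  drop[is.na(drop)] <- FALSE
  structure(list(trait_label = trait_label, trait_type = trait_type,
                 data = data[!drop, , drop = FALSE],
                 source = source, dropped = tally),
            class = "gwas_dataset")
}

#' @export
print.gwas_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset: %s (%s)\n", x$trait_label, x$trait_type))
  cat(sprintf("  %d records from %s\n", nrow(x$data), x$source))
  if (length(x$dropped))
    cat("  dropped rows:",
        paste(sprintf("%s=%d", names(x$dropped), x$dropped), collapse = ", "),
        "\n")
  invisible(x)
}

#' Number of records in a GWAS summary dataset
#' @param x A `gwas_dataset`.
#' @export
nsnp <- function(x) {
  stopifnot(inherits(x, c("gwas_dataset", "mr_harmonized")))
  if (inherits(x, "gwas_dataset")) nrow(x$data) else sum(x$pairs$status %in% .kept_status)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP association summaries using an
#' explicit column map, validates every row against the record invariants,
#' and returns the surviving records together with a tally of dropped rows.
#'
#' @param path Path to the delimited file (with a header row).
#' @param colmap A [gwas_colmap()].
#' @param trait_label,trait_type Passed to [gwas_dataset()].
#' @return A `gwas_dataset`.
#' @export
read_gwas <- function(path, colmap = gwas_colmap(), trait_label = basename(path),
                      trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = colmap$delim,
                           colClasses = "character", quote = "",
                           na.strings = colmap$na_tokens,
                           check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0 && ncol(raw) <= 1) stop("empty input file: ", path)
  cols <- colmap$cols
  req <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (f in req)
    if (!(cols[[f]] %in% names(raw)))
      stop(sprintf("required column '%s' (field %s) not found in %s",
                   cols[[f]], f, path))
  df <- lapply(.gwas_fields, function(f) {
    src <- cols[[f]]
    if (!is.na(src) && src %in% names(raw)) raw[[src]]
    else rep(NA_character_, nrow(raw))
  })
  names(df) <- .gwas_fields
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  gwas_dataset(df, trait_label = trait_label, trait_type = trait_type,
               source = path)
}

#' Write a GWAS summary dataset to a delimited file
#'
#' Writes at full double precision so that
#' `read_gwas(write_gwas(d))` reproduces `d` field for field. Optional
#' fields that are entirely absent (all `NA`) are omitted from the output.
#'
#' @param dataset A `gwas_dataset`.
#' @param path Output path.
#' @param colmap A [gwas_colmap()] supplying output column names.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(dataset, path, colmap = gwas_colmap()) {
  stopifnot(inherits(dataset, "gwas_dataset"))
  df <- dataset$data
  cols <- colmap$cols
  out <- list()
  for (f in .gwas_fields) {
    if (f %in% c("snp_id", "chrom", "effect_allele", "other_allele")) {
      v <- df[[f]]
    } else {
      v <- ifelse(is.na(df[[f]]), NA_character_, sprintf("%.17g", df[[f]]))
    }
    name <- cols[[f]]
    if (is.na(name)) name <- f
    optional <- !(f %in% c("snp_id", "effect_allele", "other_allele",
                           "beta", "se", "pval"))
    if (optional && all(is.na(v))) next
    out[[name]] <- v
  }
  out <- as.data.frame(out, check.names = FALSE)
  utils::write.table(out, path, sep = colmap$delim, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a pairwise LD table
#'
#' Stores squared correlations between SNP pairs with symmetric lookup.
#' Duplicate pairs are collapsed to the maximum r-squared (the conservative
#' choice for clumping) with a warning; rows with r-squared outside \[0, 1\]
#' are dropped and tallied.
#'
#' @param df Data frame with columns `snp_a`, `snp_b`, `r2` (extra columns
#'   ignored; the first three columns are used if names differ).
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 3)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(df)))
    names(df)[1:3] <- c("snp_a", "snp_b", "r2")
  df <- df[c("snp_a", "snp_b", "r2")]
  df$snp_a <- as.character(df$snp_a)
  df$snp_b <- as.character(df$snp_b)
  df$r2 <- suppressWarnings(as.numeric(df$r2))
  bad <- is.na(df$r2) | df$r2 < 0 | df$r2 > 1 | is.na(df$snp_a) | is.na(df$snp_b)
  n_bad <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  key <- ifelse(df$snp_a <= df$snp_b,
                paste(df$snp_a, df$snp_b, sep = "\r"),
                paste(df$snp_b, df$snp_a, sep = "\r"))
  if (anyDuplicated(key)) {
    warning("duplicate LD pairs collapsed to maximum r2")
    r2 <- tapply(df$r2, key, max)
    key <- names(r2)
    r2 <- as.numeric(r2)
  } else {
    r2 <- df$r2
  }
  structure(list(key = key, r2 = r2, n_dropped = n_bad), class = "ld_table")
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table: %d pairs (%d invalid rows dropped)\n",
              length(x$key), x$n_dropped))
  invisible(x)
}

#' Symmetric LD lookup
#'
#' Returns the stored r-squared for each pair, or `NA` when the pair is not
#' in the table: unknown LD is an explicit state distinct from independence
#' (r2 = 0), which clumping treats according to its `strict_ld` policy.
#'
#' @param ld An `ld_table` (or `NULL`, in which case all lookups are `NA`).
#' @param a,b Character vectors of SNP ids (recycled).
#' @return Numeric vector of r-squared values with `NA` for unknown pairs.
#' @export
ld_lookup <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (is.null(ld)) return(rep(NA_real_, n))
  stopifnot(inherits(ld, "ld_table"))
  key <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  ld$r2[match(key, ld$key)]
}

#' Read a pairwise LD table from a 3-column delimited file
#' @param path Path to a delimited file with header columns `snp_a`,
#'   `snp_b`, `r2` (or any names, taken positionally).
#' @param delim Field delimiter.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                          colClasses = "character", comment.char = "")
  ld_table(df)
}

#' Read a SNP-confounder association table
#'
#' Expects one row per (SNP, confounder trait) association with its p-value,
#' as exported from a PhenoScanner-style lookup. Rows with p-values outside
#' (0, 1] are dropped and counted in the `n_dropped` attribute.
#'
#' @param path Path to a delimited file with header columns `snp_id`,
#'   `trait`, `pval` (or any names, taken positionally).
#' @param delim Field delimiter.
#' @return A data frame of class `confounder_table` with columns `snp_id`,
#'   `trait`, `pval`.
#' @export
read_confounder_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                          colClasses = "character", comment.char = "")
  confounder_table(df)
}

#' Construct a SNP-confounder association table from a data frame
#' @param df Data frame with columns `snp_id`, `trait`, `pval` (positional
#'   fallback on the first three columns).
#' @return A `confounder_table` data frame.
#' @export
confounder_table <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 3)
  if (!all(c("snp_id", "trait", "pval") %in% names(df)))
    names(df)[1:3] <- c("snp_id", "trait", "pval")
  df <- df[c("snp_id", "trait", "pval")]
  df$snp_id <- as.character(df$snp_id)
  df$trait <- as.character(df$trait)
  df$pval <- suppressWarnings(as.numeric(df$pval))
  bad <- is.na(df$pval) | df$pval <= 0 | df$pval > 1 | is.na(df$snp_id)
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  class(out) <- c("confounder_table", "data.frame")
  out
}
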