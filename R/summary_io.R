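# GWAS summary-statistics tables: constructors, file readers, validation.

#' Construct a GWAS summary-statistics table
#'
#' The basic container for one trait's per-SNP association estimates in one
#' sample. Continuous traits carry betas in SD units; binary traits on the
#' log-odds scale. Rows violating the per-SNP invariants (alleles in A/C/G/T
#' and distinct, `se > 0`, `pval` in (0, 1], `eaf` in (0, 1) when present,
#' unique rsid) are rejected and logged rather than silently kept.
#'
#' @param records Data.frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `eaf`, `n`.
#' @param trait_id Trait identifier string.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param sample_n Study-level sample size, used when per-SNP `n` is absent.
#' @return An object of class `gwas_summary_table` with elements `trait_id`,
#'   `trait_type`, `sample_n`, `records`, and a `rejected` data.frame
#'   (columns `rsid`, `reason`) describing discarded rows.
#' @export
gwas_summary_table <- function(records, trait_id, trait_type = c("continuous", "binary"),
                               sample_n = NULL) {
  trait_type <- match.arg(trait_type)
  .assert(is.data.frame(records), "records must be a data.frame")
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(need, names(records))
  .assert(length(miss) == 0,
          paste0("records is missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(records$eaf)) records$eaf <- NA_real_
  if (is.null(records$n)) records$n <- if (is.null(sample_n)) NA_real_ else sample_n

  r <- data.frame(
    rsid = as.character(records$rsid),
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele = toupper(as.character(records$other_allele)),
    eaf = as.numeric(records$eaf),
    beta = as.numeric(records$beta),
    se = as.numeric(records$se),
    pval = as.numeric(records$pval),
    n = as.numeric(records$n),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(r))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(r$rsid) | r$rsid == "", "missing rsid")
  flag(!(r$effect_allele %in% c("A", "C", "G", "T")) |
         !(r$other_allele %in% c("A", "C", "G", "T")), "invalid allele")
  flag(r$effect_allele == r$other_allele, "identical alleles")
  flag(!is.finite(r$beta), "nonfinite beta")
  flag(!is.finite(r$se) | r$se <= 0, "nonpositive SE")
  flag(!is.finite(r$pval) | r$pval <= 0 | r$pval > 1, "invalid p-value")
  flag(!is.na(r$eaf) & (r$eaf <= 0 | r$eaf >= 1), "eaf outside (0,1)")
  flag(!is.na(r$n) & r$n <= 0, "nonpositive n")
  flag(duplicated(r$rsid), "duplicate rsid")

  rejected <- data.frame(rsid = r$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- r[is.na(reason), , drop = FALSE]
  .assert(nrow(keep) > 0, paste0("no valid rows for trait '", trait_id, "'"))
  rownames(keep) <- NULL

  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         sample_n = sample_n %||% stats::median(keep$n, na.rm = TRUE),
         records = keep, rejected = rejected),
    class = "gwas_summary_table"
  )
}

#' @export
print.gwas_summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table '%s' (%s): %d SNPs, n = %s, %d rejected rows\n",
              x$trait_id, x$trait_type, nrow(x$records),
              format(x$sample_n), nrow(x$rejected)))
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (tab or comma, sniffed from the header unless
#' `sep` is given) and validates it into a [gwas_summary_table()]. Column
#' names are remapped through `column_map`; `eaf` and `n` are optional.
#'
#' @param path Path to a delimited text file with a header row.
#' @param trait_id,trait_type,sample_n Trait metadata (see
#'   [gwas_summary_table()]).
#' @param column_map Named list mapping the canonical keys `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` to the
#'   file's column names. Defaults to identity.
#' @param sep Field separator; `NULL` sniffs tab vs comma.
#' @return A `gwas_summary_table`; rejected rows are recorded in its
#'   `rejected` element with a per-row reason.
#' @export
read_summary_table <- function(path, trait_id, trait_type = c("continuous", "binary"),
                               sample_n = NULL, column_map = NULL, sep = NULL) {
  trait_type <- match.arg(trait_type)
  .assert(file.exists(path), paste0("file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- list(rsid = "rsid", effect_allele = "effect_allele",
                   other_allele = "other_allele", eaf = "eaf", beta = "beta",
                   se = "se", pval = "pval", n = "n")
  map <- utils::modifyList(defaults, as.list(column_map %||% list()))
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  for (key in required) {
    .assert(map[[key]] %in% names(raw),
            paste0("mapped column '", map[[key]], "' (", key,
                   ") not found in ", path))
  }
  rec <- data.frame(rsid = raw[[map$rsid]],
                    effect_allele = raw[[map$effect_allele]],
                    other_allele = raw[[map$other_allele]],
                    beta = raw[[map$beta]], se = raw[[map$se]],
                    pval = raw[[map$pval]], stringsAsFactors = FALSE)
  if (map$eaf %in% names(raw)) rec$eaf <- raw[[map$eaf]]
  if (map$n %in% names(raw)) rec$n <- raw[[map$n]]
  gwas_summary_table(rec, trait_id = trait_id, trait_type = trait_type,
                     sample_n = sample_n)
}

#' Read an already-harmonized per-SNP table
#'
#' Loads a delimited file whose rows are allele-aligned exposure/outcome
#' pairs (columns `rsid`, `beta_zx`, `se_zx`, `beta_zy`, `se_zy`, optionally
#' `eaf_exposure`), e.g. a published per-SNP instrument table, so the
#' estimator battery can be replayed on it directly.
#'
#' @param path Delimited text file with a header.
#' @param exposure_id,outcome_id Trait identifiers.
#' @param outcome_type `"continuous"` or `"binary"` (controls odds-ratio
#'   reporting).
#' @param sep Field separator; `NULL` sniffs tab vs comma.
#' @return A `harmonized_set` whose rows all have action `"unchanged"`.
#' @export
read_harmonized_set <- function(path, exposure_id, outcome_id,
                                outcome_type = c("continuous", "binary"),
                                sep = NULL) {
  outcome_type <- match.arg(outcome_type)
  .assert(file.exists(path), paste0("file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("rsid", "beta_zx", "se_zx", "beta_zy", "se_zy")
  miss <- setdiff(need, names(raw))
  .assert(length(miss) == 0,
          paste0(path, " is missing column(s): ", paste(miss, collapse = ", ")))
  rows <- data.frame(rsid = as.character(raw$rsid),
                     beta_zx = as.numeric(raw$beta_zx),
                     se_zx = as.numeric(raw$se_zx),
                     beta_zy = as.numeric(raw$beta_zy),
                     se_zy = as.numeric(raw$se_zy),
                     eaf_exposure = if (is.null(raw$eaf_exposure)) NA_real_ else as.numeric(raw$eaf_exposure),
                     action = "unchanged", reason = NA_character_,
                     stringsAsFactors = FALSE)
  ok <- is.finite(rows$beta_zx) & is.finite(rows$beta_zy) &
    rows$se_zx > 0 & rows$se_zy > 0
  rows <- rows[ok, , drop = FALSE]
  .assert(nrow(rows) > 0, "no usable harmonized rows")
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 exposure_type = "continuous", outcome_type = outcome_type,
                 n_exposure = NA_real_, rows = rows),
            class = "harmonized_set")
}

#' Flatten MR estimates into a results table
#'
#' @param results A single `mr_estimate`, or a list of them (nesting
#'   allowed).
#' @return Data.frame with columns `estimator`, `exposure`, `outcome`,
#'   `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or_`,
#'   `or_ci_low`, `or_ci_high`, `intercept`, `intercept_pval`. Odds-ratio
#'   columns are filled only for binary outcomes (as `exp(beta)` and
#'   exponentiated CI bounds).
#' @export
results_table <- function(results) {
  if (inherits(results, "mr_estimate")) results <- list(results)
  flat <- list()
  harvest <- function(x) {
    if (inherits(x, "mr_estimate")) {
      flat[[length(flat) + 1L]] <<- x
    } else if (is.list(x)) {
      lapply(x, harvest)
    }
  }
  harvest(results)
  .assert(length(flat) > 0, "no MR estimates to tabulate")
  do.call(rbind, lapply(flat, function(e) {
    binary <- identical(e$outcome_type, "binary")
    data.frame(
      estimator = e$method,
      exposure = paste(e$exposure_id, collapse = "+"),
      outcome = e$outcome_id,
      n_snps = e$n_snps,
      beta = e$beta, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
      pval = e$pval,
      or_ = if (binary) exp(e$beta) else NA_real_,
      or_ci_low = if (binary) exp(e$ci_low) else NA_real_,
      or_ci_high = if (binary) exp(e$ci_high) else NA_real_,
      intercept = e$intercept %||% NA_real_,
      intercept_pval = e$intercept_pval %||% NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write MR results to a delimited file
#'
#' Serializes a collection of estimates via [results_table()] to
#' tab-separated text. Values round-trip through [utils::read.delim()] at
#' better than 6 significant digits.
#'
#' @param results A (list of) `mr_estimate` or a data.frame from
#'   [results_table()].
#' @param path Output file path.
#' @export
write_results <- function(results, path) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  .assert(nrow(tab) > 0, "no results to write")
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = NA))
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
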