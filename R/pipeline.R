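# Orchestration: univariable / multivariable / bidirectional MR tests,
# FDR correction across a test battery, and report tables.

.mr_options <- function(options = list()) {
  defaults <- list(
    p_threshold = 5e-8,
    r2_threshold = 0.01,
    ld = NULL,
    palindrome_policy = "infer_by_eaf",
    eaf_ambiguity_band = c(0.42, 0.58),
    radial_alpha = 0.05,
    radial_correction = "bonferroni",
    ivw_model = "multiplicative_random",
    n_boot = 1000,
    run_simex = TRUE,
    lambda_grid = c(0, 0.5, 1, 1.5, 2),
    simex_reps = 1000,
    seed = 1L
  )
  utils::modifyList(defaults, as.list(options))
}

.failed_report <- function(id, type, exposure_id, outcome_id, err) {
  structure(list(id = id, type = type, exposure_id = exposure_id,
                 outcome_id = outcome_id, diagnostics = NULL,
                 estimates = list(), concordance_flag = NA,
                 raw_pval = NA_real_, fdr_pval = NA_real_,
                 error = conditionMessage(err)),
            class = "mr_test_report")
}

#' Run one univariable MR test
#'
#' Executes the full univariable battery: instrument selection, allele
#' harmonization, radial outlier removal, heterogeneity diagnostics, then
#' IVW plus the sensitivity estimators (MR-Egger, SIMEX-corrected Egger,
#' weighted median, weighted mode) on identical SNP rows. A failure at any
#' stage is captured as a failed report rather than an error, so a test
#' battery always completes.
#'
#' @param exposure,outcome `gwas_summary_table` objects.
#' @param options Named list overriding the defaults: `p_threshold` (5e-8),
#'   `r2_threshold` (0.01), `ld`, `palindrome_policy`, `eaf_ambiguity_band`,
#'   `radial_alpha`, `radial_correction`, `ivw_model`
#'   (`"multiplicative_random"`), `n_boot`, `run_simex`, `lambda_grid`,
#'   `simex_reps`, `seed`.
#' @param test_id Identifier recorded in the report.
#' @param instrument Optional pre-selected rsid vector (bypasses
#'   [select_instrument()]), as in a bidirectional appraisal after overlap
#'   exclusion.
#' @return An `mr_test_report`: diagnostics, the named list of estimates,
#'   `concordance_flag` (all estimator betas share the IVW's sign),
#'   `raw_pval` (the IVW p), and `fdr_pval` (NA until [fdr_adjust()]).
#' @export
run_univariable <- function(exposure, outcome, options = list(),
                            test_id = NULL, instrument = NULL) {
  opts <- .mr_options(options)
  test_id <- test_id %||% paste0(exposure$trait_id, "_on_", outcome$trait_id)
  result <- tryCatch({
    snps <- instrument %||% select_instrument(exposure, opts$p_threshold,
                                              opts$ld, opts$r2_threshold)
    h <- harmonize(exposure, outcome, snps,
                   palindrome_policy = opts$palindrome_policy,
                   eaf_ambiguity_band = opts$eaf_ambiguity_band)
    outliers <- character(0)
    if (sum(h$rows$action %in% c("unchanged", "flipped")) >= 3) {
      outliers <- as.character(radial_outliers(h, opts$radial_alpha,
                                               opts$radial_correction))
      if (length(outliers)) {
        h$rows$action[h$rows$rsid %in% outliers] <- "dropped-incompatible"
        h$rows$reason[h$rows$rsid %in% outliers] <- "radial outlier"
      }
    }
    r <- mr_rows(h)
    k <- nrow(r)
    diag <- instrument_strength(r$beta_zx, r$se_zx,
                                eafs = if (all(is.finite(r$eaf_exposure %||% NA)))
                                  r$eaf_exposure else NULL,
                                n = h$n_exposure, k = k)
    diag$outlier_rsids <- outliers
    if (k >= 2) {
      qq <- cochran_q(h)
      diag$q_stat <- qq$q_stat; diag$q_df <- qq$q_df; diag$q_pval <- qq$q_pval
    }
    est <- list(ivw = ivw(h, model = opts$ivw_model))
    if (k >= 3) {
      est$egger <- egger(h)
      if (isTRUE(opts$run_simex)) {
        est$egger_simex <- simex_egger(h, opts$lambda_grid, opts$simex_reps,
                                       seed = opts$seed + 1L)
      }
      est$weighted_median <- weighted_median(h, opts$n_boot,
                                             seed = opts$seed + 2L)
      est$weighted_mode <- weighted_mode(h, n_boot = opts$n_boot,
                                         seed = opts$seed + 3L)
    }
    betas <- vapply(est, function(e) e$beta, numeric(1))
    structure(list(id = test_id, type = "univariable",
                   exposure_id = exposure$trait_id,
                   outcome_id = outcome$trait_id,
                   diagnostics = diag, harmonized = h, estimates = est,
                   concordance_flag = all(sign(betas) == sign(betas["ivw"])),
                   raw_pval = est$ivw$pval, fdr_pval = NA_real_,
                   error = NULL),
              class = "mr_test_report")
  }, error = function(e) .failed_report(test_id, "univariable",
                                        exposure$trait_id, outcome$trait_id, e))
  result
}

#' Run one multivariable MR test
#'
#' Selects an instrument per exposure, forms the union, harmonizes all
#' tables to the first exposure's orientation, and estimates each
#' exposure's direct effect by multivariable IVW. The first exposure is the
#' exposure of interest: its mv-IVW p-value is the test's raw p.
#'
#' @param exposures List of two or more `gwas_summary_table` objects (first
#'   = exposure of interest).
#' @inheritParams run_univariable
#' @return An `mr_test_report` whose `estimates` holds one `mv_ivw`
#'   estimate per exposure.
#' @export
run_multivariable <- function(exposures, outcome, options = list(),
                              test_id = NULL) {
  opts <- .mr_options(options)
  .assert(is.list(exposures) && length(exposures) >= 2,
          "multivariable analysis needs at least two exposures")
  ids <- vapply(exposures, function(x) x$trait_id, character(1))
  test_id <- test_id %||% paste0(ids[1], "_adj_", paste(ids[-1], collapse = "_"),
                                 "_on_", outcome$trait_id)
  tryCatch({
    union_snps <- unique(unlist(lapply(exposures, function(x) {
      tryCatch(select_instrument(x, opts$p_threshold, opts$ld,
                                 opts$r2_threshold),
               error = function(e) character(0))
    })))
    .assert(length(union_snps) > 0, "no instrument SNP for any exposure")
    m <- build_mv_set(exposures, outcome, union_snps,
                      palindrome_policy = opts$palindrome_policy,
                      eaf_ambiguity_band = opts$eaf_ambiguity_band)
    est <- mv_ivw(m)
    names(est) <- paste0("mv_ivw_", m$exposure_ids)
    k <- nrow(m$rows)
    diag <- instrument_strength(m$rows$beta_zx_1, m$rows$se_zx_1,
                                eafs = NULL, n = exposures[[1]]$sample_n, k = k)
    structure(list(id = test_id, type = "multivariable",
                   exposure_id = ids, outcome_id = outcome$trait_id,
                   diagnostics = diag, mv_set = m, estimates = est,
                   concordance_flag = NA,
                   raw_pval = est[[1]]$pval, fdr_pval = NA_real_,
                   error = NULL),
              class = "mr_test_report")
  }, error = function(e) .failed_report(test_id, "multivariable", ids,
                                        outcome$trait_id, e))
}

#' Run a bidirectional MR appraisal
#'
#' Builds each trait's instrument, removes SNPs shared between (or in LD
#' across) the two instruments from both, then runs the univariable battery
#' in each direction.
#'
#' @param trait_a,trait_b `gwas_summary_table` objects.
#' @inheritParams run_univariable
#' @return List with reports `a_on_b` and `b_on_a`.
#' @export
run_bidirectional <- function(trait_a, trait_b, options = list()) {
  opts <- .mr_options(options)
  ia <- tryCatch(select_instrument(trait_a, opts$p_threshold, opts$ld,
                                   opts$r2_threshold),
                 error = function(e) character(0))
  ib <- tryCatch(select_instrument(trait_b, opts$p_threshold, opts$ld,
                                   opts$r2_threshold),
                 error = function(e) character(0))
  ex <- exclude_overlap(ia, ib, opts$ld, opts$r2_threshold)
  mk_err <- simpleError("no instrument SNP left after overlap exclusion")
  a_on_b <- if (length(ex$a)) {
    run_univariable(trait_a, trait_b, options,
                    test_id = paste0(trait_a$trait_id, "_on_", trait_b$trait_id),
                    instrument = ex$a)
  } else {
    .failed_report(paste0(trait_a$trait_id, "_on_", trait_b$trait_id),
                   "bidirectional", trait_a$trait_id, trait_b$trait_id, mk_err)
  }
  b_on_a <- if (length(ex$b)) {
    run_univariable(trait_b, trait_a, options,
                    test_id = paste0(trait_b$trait_id, "_on_", trait_a$trait_id),
                    instrument = ex$b)
  } else {
    .failed_report(paste0(trait_b$trait_id, "_on_", trait_a$trait_id),
                   "bidirectional", trait_b$trait_id, trait_a$trait_id, mk_err)
  }
  a_on_b$type <- "bidirectional"
  b_on_a$type <- "bidirectional"
  list(a_on_b = a_on_b, b_on_a = b_on_a)
}

#' Benjamini-Hochberg adjustment across a test battery
#'
#' Sets each report's `fdr_pval` from the step-up false-discovery-rate
#' adjustment of the battery's raw (IVW) p-values.
#'
#' @param reports List of `mr_test_report` objects.
#' @return The same list with `fdr_pval` filled in (failed tests keep NA).
#' @export
fdr_adjust <- function(reports) {
  .assert(is.list(reports) && length(reports) >= 1, "no reports to adjust")
  raw <- vapply(reports, function(r) r$raw_pval %||% NA_real_, numeric(1))
  adj <- rep(NA_real_, length(raw))
  ok <- is.finite(raw)
  adj[ok] <- stats::p.adjust(raw[ok], method = "BH")
  for (i in seq_along(reports)) reports[[i]]$fdr_pval <- adj[i]
  reports
}

#' @export
print.mr_test_report <- function(x, ...) {
  cat(sprintf("MR test '%s' (%s): %s -> %s\n", x$id, x$type,
              paste(x$exposure_id, collapse = "+"), x$outcome_id))
  if (!is.null(x$error)) {
    cat("  FAILED:", x$error, "\n")
    return(invisible(x))
  }
  for (e in x$estimates) print(e)
  cat(sprintf("  raw p = %.3g, FDR p = %.3g, concordant directions: %s\n",
              x$raw_pval, x$fdr_pval, format(x$concordance_flag)))
  invisible(x)
}

#' Read an analysis plan from YAML
#'
#' The file mirrors the plan structure accepted by [run_plan()]: a `tests`
#' list (each with `id`, `type` = univariable / multivariable /
#' bidirectional, `exposure` (id or list of ids), `outcome`, optional
#' per-test `options`) and an optional global `options` map.
#'
#' @param path YAML file path.
#' @return A plan list.
#' @export
read_plan <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  plan <- yaml::read_yaml(path)
  .assert(!is.null(plan$tests), "plan has no 'tests' entry")
  plan
}

#' Run an analysis plan
#'
#' Executes every test in the plan against the registered summary tables,
#' applies BH-FDR across the battery, and (optionally) writes the result
#' tables: the univariable/bidirectional estimate table, the
#' total-versus-direct comparison table pairing each multivariable test
#' with its univariable counterpart, and a run log (versions, seeds,
#' options). Individual test failures are recorded and never abort the
#' batch. Output is deterministic for fixed seeds.
#'
#' @param plan List with `tests` (each: `id`, `type`, `exposure` id(s),
#'   `outcome` id, optional `options`) and optional global `options`.
#' @param tables Named list of `gwas_summary_table` objects keyed by trait
#'   id.
#' @param out_dir Directory for `results.tsv`, `comparison.tsv`,
#'   `reports.json`, `run_log.txt`; `NULL` skips writing.
#' @return List with `reports` (named by test id) and `tables` (data.frames
#'   `results` and `comparison`).
#' @export
run_plan <- function(plan, tables, out_dir = NULL) {
  .assert(is.list(plan) && length(plan$tests %||% list()) > 0,
          "plan contains no tests")
  ids <- vapply(plan$tests, function(t) t$id %||% NA_character_, character(1))
  ids[is.na(ids)] <- paste0("test_", which(is.na(ids)))
  .assert(!anyDuplicated(ids), "test ids must be unique")
  global <- as.list(plan$options %||% list())
  get_table <- function(id) {
    .assert(id %in% names(tables),
            paste0("trait '", id, "' has no registered summary table"))
    tables[[id]]
  }

  reports <- list()
  for (i in seq_along(plan$tests)) {
    t <- plan$tests[[i]]
    opts <- utils::modifyList(global, as.list(t$options %||% list()))
    type <- match.arg(t$type, c("univariable", "multivariable", "bidirectional"))
    outcome_tab <- get_table(t$outcome)
    if (type == "univariable") {
      exposure_tab <- get_table(t$exposure[[1]])
      rep1 <- run_univariable(exposure_tab, outcome_tab, opts, test_id = ids[i])
      reports[[rep1$id]] <- rep1
    } else if (type == "multivariable") {
      exps <- lapply(unlist(t$exposure), get_table)
      rep1 <- run_multivariable(exps, outcome_tab, opts, test_id = ids[i])
      reports[[rep1$id]] <- rep1
    } else {
      exposure_tab <- get_table(t$exposure[[1]])
      br <- run_bidirectional(exposure_tab, outcome_tab, opts)
      br$a_on_b$id <- paste0(ids[i], "_forward")
      br$b_on_a$id <- paste0(ids[i], "_reverse")
      reports[[br$a_on_b$id]] <- br$a_on_b
      reports[[br$b_on_a$id]] <- br$b_on_a
    }
  }
  reports <- fdr_adjust(reports)

  est_tab <- tryCatch(
    results_table(lapply(reports, function(r) r$estimates)),
    error = function(e) NULL)
  comparison <- .comparison_table(reports)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(est_tab)) write_results(est_tab, file.path(out_dir, "results.tsv"))
    if (nrow(comparison)) {
      utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
    summary_df <- data.frame(
      id = vapply(reports, function(r) r$id, character(1)),
      type = vapply(reports, function(r) r$type, character(1)),
      raw_pval = vapply(reports, function(r) r$raw_pval %||% NA_real_, numeric(1)),
      fdr_pval = vapply(reports, function(r) r$fdr_pval %||% NA_real_, numeric(1)),
      error = vapply(reports, function(r) r$error %||% "", character(1)),
      stringsAsFactors = FALSE
    )
    jsonlite::write_json(summary_df, file.path(out_dir, "reports.json"),
                         dataframe = "rows", na = "null", digits = NA)
    log_lines <- c(
      paste0("mrpleio version: ",
             as.character(utils::packageVersion("mrpleio"))),
      paste0("tests: ", length(reports)),
      paste0("seed: ", format(.mr_options(global)$seed)),
      paste0("options: ",
             jsonlite::toJSON(.mr_options(global)[
               c("p_threshold", "r2_threshold", "palindrome_policy",
                 "ivw_model", "n_boot", "simex_reps")], auto_unbox = TRUE))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(reports = reports,
       tables = list(results = est_tab, comparison = comparison))
}

# Pair each multivariable estimate with the univariable (total) estimate of
# the same exposure/outcome when one exists in the battery.
.comparison_table <- function(reports) {
  rows <- list()
  uni <- Filter(function(r) r$type %in% c("univariable", "bidirectional") &&
                  is.null(r$error), reports)
  for (r in reports) {
    if (!identical(r$type, "multivariable") || !is.null(r$error)) next
    for (e in r$estimates) {
      match_uni <- Filter(function(u)
        identical(u$exposure_id, e$exposure_id) &&
          identical(u$outcome_id, e$outcome_id), uni)
      tot <- if (length(match_uni)) match_uni[[1]]$estimates$ivw else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        test_id = r$id,
        exposure = e$exposure_id,
        outcome = e$outcome_id,
        adjusted_for = paste(e$adjusted_for, collapse = "+"),
        total_beta = tot$beta %||% NA_real_,
        total_ci_low = tot$ci_low %||% NA_real_,
        total_ci_high = tot$ci_high %||% NA_real_,
        direct_beta = e$beta,
        direct_ci_low = e$ci_low,
        direct_ci_high = e$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(test_id = character(0), exposure = character(0),
                      outcome = character(0), adjusted_for = character(0),
                      total_beta = numeric(0), total_ci_low = numeric(0),
                      total_ci_high = numeric(0), direct_beta = numeric(0),
                      direct_ci_low = numeric(0), direct_ci_high = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
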