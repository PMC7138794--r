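# Instrument selection, strength, heterogeneity, and outlier diagnostics.

#' Construct an LD matrix object
#'
#' @param r2 Square numeric matrix of pairwise squared correlations, unit
#'   diagonal, values in \[0, 1\].
#' @param rsids Character vector naming the rows/columns (defaults to the
#'   matrix dimnames).
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r2, rsids = NULL) {
  r2 <- as.matrix(r2)
  rsids <- rsids %||% rownames(r2)
  .assert(!is.null(rsids), "rsids required (or dimnames on the matrix)")
  .assert(nrow(r2) == ncol(r2) && nrow(r2) == length(rsids),
          "LD matrix must be square with one rsid per row")
  .assert(max(abs(r2 - t(r2))) < 1e-8, "LD matrix must be symmetric")
  .assert(all(abs(diag(r2) - 1) < 1e-8), "LD matrix diagonal must be 1")
  .assert(all(r2 >= -1e-12 & r2 <= 1 + 1e-12), "LD r2 values must lie in [0,1]")
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square matrix with rsids as both the header row and the first
#' column.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @param sep Field separator; `NULL` sniffs tab vs comma.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, sep = NULL) {
  .assert(file.exists(path), paste0("file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  ld_matrix(as.matrix(m), rownames(m))
}

.ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  m <- if (inherits(ld, "ld_matrix")) ld$r2 else as.matrix(ld)
  if (!(a %in% rownames(m)) || !(b %in% colnames(m))) return(0)
  m[a, b]
}

#' Select an instrument by p-value threshold and greedy LD pruning
#'
#' Keeps SNPs associated below `p_threshold`, then prunes for independence:
#' survivors are visited in ascending p-value order (ties broken by rsid)
#' and a SNP is accepted only if its LD r-squared with every
#' already-accepted SNP is below `r2_threshold`. With no LD matrix all SNPs
#' are treated as independent.
#'
#' @param table A `gwas_summary_table`.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param ld An `ld_matrix` (or plain named matrix) of pairwise r-squared,
#'   or `NULL`.
#' @param r2_threshold LD pruning threshold (default 0.01).
#' @return Character vector of accepted rsids, in acceptance order.
#' @export
select_instrument <- function(table, p_threshold = 5e-8, ld = NULL,
                              r2_threshold = 0.01) {
  .assert(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0,1)")
  .assert(r2_threshold > 0 && r2_threshold <= 1, "r2_threshold must be in (0,1]")
  rec <- table$records
  surv <- rec[rec$pval < p_threshold, , drop = FALSE]
  if (nrow(surv) == 0) {
    stop(sprintf("no SNP in '%s' reaches p < %g: empty instrument",
                 table$trait_id, p_threshold), call. = FALSE)
  }
  surv <- surv[order(surv$pval, surv$rsid), , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(surv))) {
    cand <- surv$rsid[i]
    indep <- all(vapply(accepted, function(a)
      .ld_r2(ld, cand, a) < r2_threshold, logical(1)))
    if (indep) accepted <- c(accepted, cand)
  }
  accepted
}

#' Instrument strength (variance explained and F-statistic)
#'
#' Per-SNP variance explained is `2*eaf*(1-eaf)*beta^2` when frequencies are
#' available (trait in SD units), otherwise the summary-data approximation
#' `beta^2 / (beta^2 + n*se^2)`. The instrument R-squared is the sum over
#' SNPs (capped below 1) and `F = R2*(n-1-k) / ((1-R2)*k)`. F below 10 is
#' flagged as conventionally weak.
#'
#' @param betas,ses Per-SNP exposure effects and standard errors.
#' @param eafs Effect-allele frequencies, or `NULL` to use the fallback.
#' @param n Exposure sample size (must exceed `k + 1`).
#' @param k Number of SNPs (defaults to `length(betas)`).
#' @return An `instrument_diagnostics` list with `r2`, `f_stat`, `k`, `n`,
#'   `weak`, and empty heterogeneity slots to be filled by [cochran_q()].
#' @export
instrument_strength <- function(betas, ses, eafs = NULL, n, k = length(betas)) {
  .assert(k >= 1, "k must be at least 1")
  .assert(is.finite(n) && n > k + 1,
          "sample size must exceed k + 1 for the F-statistic")
  if (!is.null(eafs) && all(is.finite(eafs))) {
    r2j <- 2 * eafs * (1 - eafs) * betas^2
  } else {
    r2j <- betas^2 / (betas^2 + n * ses^2)
  }
  r2 <- min(sum(r2j), 1 - 1e-12)
  f <- r2 * (n - 1 - k) / ((1 - r2) * k)
  structure(
    list(r2 = r2, f_stat = f, k = as.integer(k), n = n, weak = f < 10,
         q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
         outlier_rsids = character(0)),
    class = "instrument_diagnostics"
  )
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument: k = %d, n = %s, R2 = %.4g, F = %.3g%s\n",
              x$k, format(x$n), x$r2, x$f_stat,
              if (isTRUE(x$weak)) " (weak: F < 10)" else ""))
  if (is.finite(x$q_stat %||% NA)) {
    cat(sprintf("Heterogeneity: Q = %.4g on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pval))
  }
  if (length(x$outlier_rsids)) {
    cat("Outliers removed:", paste(x$outlier_rsids, collapse = ", "), "\n")
  }
  invisible(x)
}

# First-order weights and Wald ratios shared by Q, radial, IVW, median, mode.
.ratio_weights <- function(r) {
  zero <- which(r$beta_zx == 0)
  if (length(zero)) {
    stop(paste0("zero SNP-exposure effect for ",
                paste(r$rsid[zero], collapse = ", "),
                ": Wald ratio undefined"), call. = FALSE)
  }
  list(ratio = r$beta_zy / r$beta_zx, w = r$beta_zx^2 / r$se_zy^2)
}

#' Cochran's Q heterogeneity statistic over Wald ratios
#'
#' Computes `Q = sum(w_j * (ratio_j - beta_ref)^2)` with first-order weights
#' `w_j = beta_zx_j^2 / se_zy_j^2`, compared to a chi-square distribution
#' with `k - 1` degrees of freedom.
#'
#' @param h A `harmonized_set` or data.frame of per-SNP effects.
#' @param beta_ref Reference causal estimate; defaults to the set's
#'   (fixed-effect) IVW estimate.
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h, beta_ref = NULL) {
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 2, "Cochran's Q needs at least 2 SNPs")
  rw <- .ratio_weights(r)
  beta_ref <- beta_ref %||% (sum(rw$w * rw$ratio) / sum(rw$w))
  q <- sum(rw$w * (rw$ratio - beta_ref)^2)
  list(q_stat = q, q_df = k - 1L,
       q_pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Radial-regression outlier detection
#'
#' Fits the radial IVW form (regression of `ratio*sqrt(w)` on `sqrt(w)`
#' without intercept, i.e. the IVW estimate) and flags SNPs whose
#' contribution `Q_j = w_j*(ratio_j - beta_radial)^2` is improbably large
#' against a chi-square(1) reference at level `alpha` (Bonferroni-divided by
#' k under `correction = "bonferroni"`).
#'
#' @param h A `harmonized_set` or data.frame of per-SNP effects (k >= 3).
#' @param alpha Significance level for flagging (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Character vector of flagged rsids, with attributes
#'   `q_contributions` (named per-SNP Q_j, summing to the total radial Q)
#'   and `beta_radial`.
#' @export
radial_outliers <- function(h, alpha = 0.05,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 3, "radial outlier detection needs at least 3 SNPs")
  rw <- .ratio_weights(r)
  beta_radial <- sum(rw$w * rw$ratio) / sum(rw$w)
  qj <- rw$w * (rw$ratio - beta_radial)^2
  names(qj) <- r$rsid
  thr <- if (correction == "bonferroni") alpha / k else alpha
  flagged <- r$rsid[stats::pchisq(qj, df = 1, lower.tail = FALSE) < thr]
  structure(flagged, q_contributions = qj, beta_radial = beta_radial)
}

#' Exclude overlapping or LD-linked instruments between two traits
#'
#' For a bidirectional appraisal, removes from both instrument lists any
#' rsid present in both, and any cross-list pair whose LD r-squared meets
#' `r2_threshold` (both members removed). Order is otherwise preserved.
#'
#' @param instr_a,instr_b Character vectors of rsids.
#' @param ld An `ld_matrix` or `NULL`.
#' @param r2_threshold LD threshold at or above which a cross pair is
#'   excluded.
#' @return List with `a` and `b`, the filtered instruments.
#' @export
exclude_overlap <- function(instr_a, instr_b, ld = NULL, r2_threshold = 0.01) {
  .assert(r2_threshold > 0 && r2_threshold <= 1, "r2_threshold must be in (0,1]")
  shared <- intersect(instr_a, instr_b)
  drop_a <- instr_a %in% shared
  drop_b <- instr_b %in% shared
  if (!is.null(ld)) {
    for (a in instr_a) {
      for (b in instr_b) {
        if (a != b && .ld_r2(ld, a, b) >= r2_threshold) {
          drop_a[instr_a == a] <- TRUE
          drop_b[instr_b == b] <- TRUE
        }
      }
    }
  }
  list(a = instr_a[!drop_a], b = instr_b[!drop_b])
}
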