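# Allele harmonization between exposure and outcome summary tables.

# Align one outcome record to the exposure's allele orientation.
# Returns list(action, beta, eaf, reason); beta/eaf are the outcome values
# expressed on the exposure's effect allele.
.align_alleles <- function(ea, oa, ea2, oa2, beta2, eaf2,
                           eaf1, palindrome_policy, band) {
  palin <- .is_palindromic(ea, oa)

  if (palin) {
    # Allele labels cannot distinguish strand for A/T and C/G SNPs.
    if (palindrome_policy == "drop") {
      return(list(action = "dropped-palindromic", beta = NA_real_,
                  eaf = NA_real_, reason = "palindromic SNP (policy drop)"))
    }
    # Label-level alignment first (swap means report on the exposure's
    # effect allele), then orient by allele frequency.
    if (ea2 == ea && oa2 == oa) {
      # as-is
    } else if (ea2 == oa && oa2 == ea) {
      beta2 <- -beta2
      eaf2 <- if (is.na(eaf2)) NA_real_ else 1 - eaf2
    } else {
      return(list(action = "dropped-incompatible", beta = NA_real_,
                  eaf = NA_real_, reason = "allele mismatch"))
    }
    if (is.na(eaf1) || is.na(eaf2) ||
        (eaf1 > band[1] && eaf1 < band[2]) ||
        (eaf2 > band[1] && eaf2 < band[2])) {
      return(list(action = "dropped-palindromic", beta = NA_real_,
                  eaf = NA_real_,
                  reason = "palindromic SNP with ambiguous frequency"))
    }
    if ((eaf1 - 0.5) * (eaf2 - 0.5) > 0) {
      return(list(action = "unchanged", beta = beta2, eaf = eaf2, reason = NA))
    }
    # Frequencies disagree: the outcome study reported the complementary
    # strand's allele, so the sign flips.
    return(list(action = "flipped", beta = -beta2,
                eaf = 1 - eaf2, reason = NA))
  }

  if (ea2 == ea && oa2 == oa) {
    return(list(action = "unchanged", beta = beta2, eaf = eaf2, reason = NA))
  }
  if (ea2 == oa && oa2 == ea) {
    return(list(action = "flipped", beta = -beta2,
                eaf = if (is.na(eaf2)) NA_real_ else 1 - eaf2, reason = NA))
  }
  # Try the reverse strand before declaring incompatibility.
  cea2 <- unname(.COMPLEMENT[ea2]); coa2 <- unname(.COMPLEMENT[oa2])
  if (cea2 == ea && coa2 == oa) {
    return(list(action = "unchanged", beta = beta2, eaf = eaf2, reason = NA))
  }
  if (cea2 == oa && coa2 == ea) {
    return(list(action = "flipped", beta = -beta2,
                eaf = if (is.na(eaf2)) NA_real_ else 1 - eaf2, reason = NA))
  }
  list(action = "dropped-incompatible", beta = NA_real_, eaf = NA_real_,
       reason = "irreconcilable alleles")
}

# Harmonize `other` against the orientation of `ref` records for `snps`.
# Returns a data.frame(rsid, beta, se, eaf, action, reason).
.harmonize_against <- function(ref_records, other, snps,
                               palindrome_policy, band) {
  oidx <- match(snps, other$records$rsid)
  ridx <- match(snps, ref_records$rsid)
  out <- data.frame(rsid = snps, beta = NA_real_, se = NA_real_,
                    eaf = NA_real_, action = NA_character_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(snps)) {
    if (is.na(oidx[i])) {
      out$action[i] <- "dropped-incompatible"
      out$reason[i] <- "absent from outcome table"
      next
    }
    rr <- ref_records[ridx[i], ]
    or <- other$records[oidx[i], ]
    a <- .align_alleles(rr$effect_allele, rr$other_allele,
                        or$effect_allele, or$other_allele,
                        or$beta, or$eaf, rr$eaf,
                        palindrome_policy, band)
    out$action[i] <- a$action
    out$reason[i] <- a$reason
    if (a$action %in% c("unchanged", "flipped")) {
      out$beta[i] <- a$beta
      out$se[i] <- or$se
      out$eaf[i] <- a$eaf
    }
  }
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table's per-SNP effects to the exposure's effect
#' allele: matching alleles are kept as-is; swapped alleles flip the outcome
#' beta's sign (and complement its frequency); strand-complement pairs are
#' resolved before a SNP is declared incompatible. Palindromic (A/T, C/G)
#' SNPs are dropped outright under `palindrome_policy = "drop"`, or oriented
#' by comparing effect-allele frequency to 0.5 in both studies under
#' `"infer_by_eaf"`, dropping any SNP whose frequency in either study falls
#' inside the ambiguity band.
#'
#' @param exposure,outcome `gwas_summary_table` objects.
#' @param snps Character vector of instrument rsids (must be present in the
#'   exposure table). Defaults to all exposure SNPs.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_ambiguity_band Length-2 numeric; palindromic SNPs with either
#'   study's frequency strictly inside this band are dropped as ambiguous.
#' @return A `harmonized_set`: trait metadata plus a `rows` data.frame with
#'   columns `rsid`, `beta_zx`, `se_zx`, `beta_zy`, `se_zy`, `eaf_exposure`,
#'   `action` (`unchanged` / `flipped` / `dropped-palindromic` /
#'   `dropped-incompatible`) and `reason`. Dropped rows carry NA effects and
#'   are excluded from all estimators.
#' @export
harmonize <- function(exposure, outcome, snps = NULL,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  .assert(inherits(exposure, "gwas_summary_table") &&
            inherits(outcome, "gwas_summary_table"),
          "exposure and outcome must be gwas_summary_table objects")
  snps <- snps %||% exposure$records$rsid
  missing_snps <- setdiff(snps, exposure$records$rsid)
  .assert(length(missing_snps) == 0,
          paste0("instrument SNP(s) absent from exposure table: ",
                 paste(utils::head(missing_snps, 5), collapse = ", ")))

  al <- .harmonize_against(exposure$records, outcome, snps,
                           palindrome_policy, eaf_ambiguity_band)
  eidx <- match(snps, exposure$records$rsid)
  rows <- data.frame(
    rsid = snps,
    beta_zx = exposure$records$beta[eidx],
    se_zx = exposure$records$se[eidx],
    beta_zy = al$beta,
    se_zy = al$se,
    eaf_exposure = exposure$records$eaf[eidx],
    action = al$action,
    reason = al$reason,
    stringsAsFactors = FALSE
  )
  retained <- rows$action %in% c("unchanged", "flipped")
  if (!any(retained)) {
    stop("harmonization retained no SNPs: no usable instrument", call. = FALSE)
  }
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         exposure_type = exposure$trait_type, outcome_type = outcome$trait_type,
         n_exposure = exposure$sample_n, n_outcome = outcome$sample_n,
         rows = rows),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(x$rows$action)
  cat(sprintf("Harmonized set %s -> %s: %d SNPs retained (%s)\n",
              x$exposure_id, x$outcome_id,
              sum(x$rows$action %in% c("unchanged", "flipped")),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Harmonization audit log
#'
#' @param h A `harmonized_set` or `mv_harmonized_set`.
#' @return Data.frame with columns `rsid`, `action`, `reason` (one row per
#'   requested SNP).
#' @export
harmonization_log <- function(h) {
  data.frame(rsid = h$rows$rsid, action = h$rows$action,
             reason = h$rows$reason, stringsAsFactors = FALSE)
}

#' Build a multivariable harmonized set
#'
#' Harmonizes every exposure table and the outcome table to a single
#' reference orientation (the first exposure's alleles). SNPs that fail
#' harmonization in any table — absent, incompatible, or ambiguous
#' palindromes — are dropped from the whole set and logged.
#'
#' @param exposures List of at least two `gwas_summary_table` objects.
#' @param outcome A `gwas_summary_table`.
#' @param snps Instrument rsids, typically the union of the exposures'
#'   instruments; every SNP must at least exist in the first exposure table.
#' @inheritParams harmonize
#' @return An `mv_harmonized_set`: `exposure_ids`, `outcome_id`, a `rows`
#'   data.frame with per-exposure columns `beta_zx_1..K` / `se_zx_1..K` plus
#'   `beta_zy`, `se_zy`, and a `dropped` log.
#' @export
build_mv_set <- function(exposures, outcome, snps = NULL,
                         palindrome_policy = c("infer_by_eaf", "drop"),
                         eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  .assert(is.list(exposures) && length(exposures) >= 2,
          "multivariable analysis needs at least two exposures")
  lapply(exposures, function(x)
    .assert(inherits(x, "gwas_summary_table"),
            "each exposure must be a gwas_summary_table"))
  ref <- exposures[[1]]
  snps <- snps %||% ref$records$rsid
  snps <- intersect(snps, ref$records$rsid)
  .assert(length(snps) > 0, "no instrument SNPs found in the reference exposure")

  K <- length(exposures)
  ridx <- match(snps, ref$records$rsid)
  cols <- list(
    beta_zx_1 = ref$records$beta[ridx],
    se_zx_1 = ref$records$se[ridx]
  )
  status <- rep("unchanged", length(snps))
  reason <- rep(NA_character_, length(snps))
  for (j in 2:K) {
    al <- .harmonize_against(ref$records, exposures[[j]], snps,
                             palindrome_policy, eaf_ambiguity_band)
    bad <- !(al$action %in% c("unchanged", "flipped"))
    status[bad & status == "unchanged"] <- al$action[bad & status == "unchanged"]
    reason[bad & is.na(reason)] <-
      paste0(exposures[[j]]$trait_id, ": ", al$reason[bad & is.na(reason)])
    cols[[paste0("beta_zx_", j)]] <- al$beta
    cols[[paste0("se_zx_", j)]] <- al$se
  }
  alo <- .harmonize_against(ref$records, outcome, snps,
                            palindrome_policy, eaf_ambiguity_band)
  bad <- !(alo$action %in% c("unchanged", "flipped"))
  status[bad & status == "unchanged"] <- alo$action[bad & status == "unchanged"]
  reason[bad & is.na(reason)] <-
    paste0(outcome$trait_id, ": ", alo$reason[bad & is.na(reason)])

  rows <- data.frame(rsid = snps, stringsAsFactors = FALSE)
  for (nm in names(cols)) rows[[nm]] <- cols[[nm]]
  rows$beta_zy <- alo$beta
  rows$se_zy <- alo$se
  rows$action <- status
  rows$reason <- reason

  keep <- rows$action == "unchanged" & stats::complete.cases(
    rows[, c(paste0("beta_zx_", 1:K), "beta_zy", "se_zy")])
  rows$action[!keep & rows$action == "unchanged"] <- "dropped-incompatible"
  .assert(sum(keep) > 0, "no SNP survived multivariable harmonization")

  structure(
    list(exposure_ids = vapply(exposures, function(x) x$trait_id, character(1)),
         outcome_id = outcome$trait_id,
         outcome_type = outcome$trait_type,
         K = K,
         rows = rows[keep, , drop = FALSE],
         dropped = data.frame(rsid = rows$rsid[!keep],
                              action = rows$action[!keep],
                              reason = rows$reason[!keep],
                              stringsAsFactors = FALSE)),
    class = "mv_harmonized_set"
  )
}

#' @export
print.mv_harmonized_set <- function(x, ...) {
  cat(sprintf("Multivariable harmonized set [%s] -> %s: %d SNPs (%d dropped)\n",
              paste(x$exposure_ids, collapse = ", "), x$outcome_id,
              nrow(x$rows), nrow(x$dropped)))
  invisible(x)
}
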