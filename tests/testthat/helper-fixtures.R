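# Fixture builders shared across the suite. Everything is generated in code.

# Minimal harmonized_set around explicit per-SNP vectors.
make_hset <- function(beta_zx, se_zx, beta_zy, se_zy, eaf = NA_real_,
                      outcome_type = "continuous",
                      exposure_id = "X", outcome_id = "Y") {
  k <- length(beta_zx)
  rows <- data.frame(
    rsid = sprintf("rs%03d", seq_len(k)),
    beta_zx = beta_zx, se_zx = se_zx, beta_zy = beta_zy, se_zy = se_zy,
    eaf_exposure = rep_len(eaf, k), action = "unchanged",
    reason = NA_character_, stringsAsFactors = FALSE
  )
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 exposure_type = "continuous", outcome_type = outcome_type,
                 n_exposure = 1e5, n_outcome = 1e5, rows = rows),
            class = "harmonized_set")
}

# Summary table from explicit columns, defaulting to non-palindromic A/G.
make_table <- function(rsid, beta, se, pval = NULL, eaf = 0.3,
                       effect_allele = "A", other_allele = "G",
                       trait_id = "trait", trait_type = "continuous",
                       sample_n = 1e5, n = NULL) {
  pval <- pval %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
  gwas_summary_table(
    data.frame(rsid = rsid, effect_allele = effect_allele,
               other_allele = other_allele, eaf = eaf, beta = beta, se = se,
               pval = pval, n = n %||% sample_n, stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type, sample_n = sample_n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast options for pipeline tests: same battery, smaller Monte Carlo sizes.
fast_opts <- function(...) {
  utils::modifyList(
    list(n_boot = 300, simex_reps = 100, seed = 7L), list(...))
}
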