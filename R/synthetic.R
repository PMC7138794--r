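# Seeded generator of two-sample GWAS summary statistics with known ground
# truth under vertical, horizontal, and confounding pleiotropy models.

#' Scenario configuration for the summary-statistics simulator
#'
#' Defines one generative model. Scenarios:
#' \describe{
#'   \item{V}{vertical pleiotropy only: every SNP acts on the outcome
#'     through the exposure (`alpha = 0`).}
#'   \item{H-directional}{a fraction `prop_invalid` of SNPs carry direct
#'     (horizontal) outcome effects drawn from
#'     `Normal(alpha_mean, alpha_sd^2)` with `alpha_mean != 0`.}
#'   \item{H-balanced}{as H-directional with `alpha_mean = 0`.}
#'   \item{C-inside-violation}{direct effects correlated with instrument
#'     strength (correlation `rho`), violating InSIDE.}
#'   \item{TRIANGLE}{a confounding triangle: a confounder trait with its own
#'     SNPs drives both the focal exposure (`delta1`) and the outcome
#'     (`delta2`) while the exposure's direct effect is `theta1`
#'     (see [simulate_triangle()]).}
#' }
#'
#' True SNP-exposure effects are drawn as `|Normal(0, gamma_sd^2)|`:
#' instruments are oriented to the exposure-increasing allele, as harmonized
#' real instruments are. Standard errors follow the summary-statistic form
#' `se = 1/sqrt(2*eaf*(1-eaf)*n)` for traits in SD units.
#'
#' @param scenario One of `"V"`, `"H-directional"`, `"H-balanced"`,
#'   `"C-inside-violation"`, `"TRIANGLE"`.
#' @param k Number of instrument SNPs (>= 3; default 50, between small and
#'   large real instruments).
#' @param theta True causal effect(s). Scalar for two-trait scenarios;
#'   for TRIANGLE a length-3 vector `c(theta1, delta1, delta2)`; for the
#'   bidirectional generator a length-2 vector `c(theta_ab, theta_ba)`.
#' @param gamma_sd SD of true SNP-exposure effects (default 0.08, sized so
#'   that typical SNPs reach genome-wide significance at `n_exp = 50000`).
#' @param alpha_mean,alpha_sd Mean and SD of direct SNP-outcome effects for
#'   invalid SNPs.
#' @param prop_invalid Fraction of SNPs carrying direct effects (H and C
#'   scenarios; default 1).
#' @param rho Correlation between instrument strength and direct effects
#'   (InSIDE violation; C scenario).
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes (default 50000).
#' @param maf_range Range of simulated effect-allele frequencies, within
#'   (0, 0.5].
#' @param binary_outcome If `TRUE` the outcome is labelled binary (betas
#'   interpreted on the log-odds scale; same normal sampling model).
#' @param seed RNG seed (mandatory).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("V", "H-directional", "H-balanced",
                                         "C-inside-violation", "TRIANGLE"),
                            k = 50, theta = NULL, gamma_sd = 0.08,
                            alpha_mean = NULL, alpha_sd = NULL,
                            prop_invalid = NULL, rho = NULL,
                            n_exp = 50000, n_out = 50000,
                            maf_range = c(0.05, 0.5),
                            binary_outcome = FALSE, seed) {
  scenario <- match.arg(scenario)
  theta <- theta %||% switch(scenario,
                             TRIANGLE = c(theta1 = 0, delta1 = 0.4, delta2 = 0.5),
                             0.3)
  alpha_mean <- alpha_mean %||% switch(scenario, "H-directional" = 0.05, 0)
  alpha_sd <- alpha_sd %||% switch(scenario,
                                   "H-directional" = 0.01,
                                   "H-balanced" = 0.02,
                                   "C-inside-violation" = 0.02, 0)
  prop_invalid <- prop_invalid %||%
    switch(scenario, "V" = 0, "TRIANGLE" = 0, 1)
  rho <- rho %||% switch(scenario, "C-inside-violation" = 0.5, 0)

  .assert(k >= 3, "k must be at least 3")
  .assert(n_exp > 0 && n_out > 0, "sample sizes must be positive")
  .assert(abs(rho) <= 1, "|rho| must not exceed 1")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] < maf_range[2], "maf_range must lie within (0, 0.5]")
  .assert(prop_invalid >= 0 && prop_invalid <= 1,
          "prop_invalid must be in [0,1]")
  .assert(!missing(seed) && is.finite(seed), "a seed is required")
  if (scenario == "TRIANGLE") {
    .assert(length(theta) == 3, "TRIANGLE needs theta = c(theta1, delta1, delta2)")
  }
  structure(list(scenario = scenario, k = as.integer(k), theta = theta,
                 gamma_sd = gamma_sd, alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, prop_invalid = prop_invalid, rho = rho,
                 n_exp = n_exp, n_out = n_out, maf_range = maf_range,
                 binary_outcome = binary_outcome, seed = as.integer(seed)),
            class = "scenario_config")
}

.NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                                ncol = 2, byrow = TRUE)

.snp_frame <- function(rsids, eaf, beta, se, n) {
  pairs <- .NONPALINDROMIC_PAIRS[(seq_along(rsids) - 1) %% 4 + 1, , drop = FALSE]
  data.frame(rsid = rsids, effect_allele = pairs[, 1], other_allele = pairs[, 2],
             eaf = eaf, beta = beta, se = se,
             pval = .p_norm2(beta / se), n = n, stringsAsFactors = FALSE)
}

.se_from_eaf <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

.draw_gamma <- function(k, gamma_sd) abs(stats::rnorm(k, 0, gamma_sd))

.draw_alpha <- function(cfg, gamma) {
  k <- cfg$k
  alpha <- numeric(k)
  n_invalid <- round(cfg$prop_invalid * k)
  if (n_invalid == 0 || (cfg$alpha_mean == 0 && cfg$alpha_sd == 0)) {
    return(alpha)
  }
  idx <- seq_len(n_invalid)
  if (cfg$scenario == "C-inside-violation" && cfg$rho != 0) {
    z1 <- (gamma[idx] - mean(gamma[idx])) / stats::sd(gamma[idx])
    z2 <- stats::rnorm(n_invalid)
    alpha[idx] <- cfg$alpha_mean +
      cfg$alpha_sd * (cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2)
  } else {
    alpha[idx] <- stats::rnorm(n_invalid, cfg$alpha_mean, cfg$alpha_sd)
  }
  alpha
}

#' Simulate a two-sample exposure/outcome summary-statistic pair
#'
#' Draws true SNP-exposure effects `gamma_j = |Normal(0, gamma_sd^2)|` and
#' direct SNP-outcome effects `alpha_j` according to the scenario, then
#' generates observed summary statistics in two non-overlapping samples:
#' `beta_zx_j ~ Normal(gamma_j, se_zx_j^2)` and
#' `beta_zy_j ~ Normal(theta*gamma_j + alpha_j, se_zy_j^2)`, with
#' `se = 1/sqrt(2*eaf*(1-eaf)*n)` and `eaf ~ Uniform(maf_range)`. The two
#' tables share no sampling noise.
#'
#' @param config A [scenario_config()] (scenarios V, H-*, C).
#' @return List with elements `exposure` and `outcome`
#'   (`gwas_summary_table`s) and `truth` (a `ground_truth` holding `theta`,
#'   per-SNP `gamma` and `alpha`, scenario, and seed).
#' @export
simulate_pair <- function(config) {
  .assert(inherits(config, "scenario_config"), "config must be a scenario_config")
  .assert(config$scenario != "TRIANGLE", "use simulate_triangle() for TRIANGLE")
  set.seed(config$seed)
  k <- config$k
  gamma <- .draw_gamma(k, config$gamma_sd)
  alpha <- .draw_alpha(config, gamma)
  eaf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  se_zx <- .se_from_eaf(eaf, config$n_exp)
  se_zy <- .se_from_eaf(eaf, config$n_out)
  theta <- config$theta[1]
  bx <- stats::rnorm(k, gamma, se_zx)
  by <- stats::rnorm(k, theta * gamma + alpha, se_zy)
  rsids <- sprintf("rs%06d", seq_len(k))
  exposure <- gwas_summary_table(.snp_frame(rsids, eaf, bx, se_zx, config$n_exp),
                                 trait_id = "exposure", sample_n = config$n_exp)
  outcome <- gwas_summary_table(
    .snp_frame(rsids, eaf, by, se_zy, config$n_out),
    trait_id = "outcome",
    trait_type = if (config$binary_outcome) "binary" else "continuous",
    sample_n = config$n_out)
  truth <- structure(list(theta = theta, gamma = gamma, alpha = alpha,
                          scenario = config$scenario, seed = config$seed),
                     class = "ground_truth")
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a confounding triangle
#'
#' Realizes the confounding DAG behind the education/bipolar/schizophrenia
#' analysis: a confounder trait with its own SNP set influences both the
#' focal exposure (`delta1`) and the outcome (`delta2`), while the focal
#' exposure's direct effect on the outcome is `theta1` (default 0). The
#' focal exposure's summary statistics therefore carry the confounder's
#' signal at the confounder's SNPs, so a univariable instrument selected
#' from the exposure alone picks up confounder-driven SNPs and produces an
#' artefactual causal estimate, which multivariable adjustment for the
#' confounder removes.
#'
#' Both the exposure and the confounder contribute `k` core SNPs (2k rows
#' per table).
#'
#' @param config A [scenario_config()] with `scenario = "TRIANGLE"` and
#'   `theta = c(theta1, delta1, delta2)`.
#' @return List with `exposure` (education-like), `confounder`
#'   (bipolar-like), `outcome` (schizophrenia-like) summary tables and
#'   `truth` (per-SNP effects and all three arrows).
#' @export
simulate_triangle <- function(config) {
  .assert(inherits(config, "scenario_config") && config$scenario == "TRIANGLE",
          "config must be a scenario_config with scenario TRIANGLE")
  set.seed(config$seed)
  k <- config$k
  theta1 <- config$theta[1]; delta1 <- config$theta[2]; delta2 <- config$theta[3]
  gamma_e <- .draw_gamma(k, config$gamma_sd)   # exposure's own SNPs
  gamma_c <- .draw_gamma(k, config$gamma_sd)   # confounder's own SNPs
  eaf <- stats::runif(2 * k, config$maf_range[1], config$maf_range[2])
  rsids <- c(sprintf("rsE%05d", seq_len(k)), sprintf("rsC%05d", seq_len(k)))

  # True per-SNP effects on each trait (exposure SNPs first).
  true_exp <- c(gamma_e, delta1 * gamma_c)
  true_conf <- c(numeric(k), gamma_c)
  true_out <- theta1 * true_exp + delta2 * true_conf

  se_e <- .se_from_eaf(eaf, config$n_exp)
  se_c <- .se_from_eaf(eaf, config$n_exp)
  se_o <- .se_from_eaf(eaf, config$n_out)
  b_e <- stats::rnorm(2 * k, true_exp, se_e)
  b_c <- stats::rnorm(2 * k, true_conf, se_c)
  b_o <- stats::rnorm(2 * k, true_out, se_o)

  exposure <- gwas_summary_table(.snp_frame(rsids, eaf, b_e, se_e, config$n_exp),
                                 trait_id = "education", sample_n = config$n_exp)
  confounder <- gwas_summary_table(
    .snp_frame(rsids, eaf, b_c, se_c, config$n_exp),
    trait_id = "confounder",
    trait_type = if (config$binary_outcome) "binary" else "continuous",
    sample_n = config$n_exp)
  outcome <- gwas_summary_table(
    .snp_frame(rsids, eaf, b_o, se_o, config$n_out),
    trait_id = "outcome",
    trait_type = if (config$binary_outcome) "binary" else "continuous",
    sample_n = config$n_out)
  truth <- structure(list(theta = c(theta1 = theta1, delta1 = delta1,
                                    delta2 = delta2),
                          gamma = c(gamma_e, gamma_c),
                          gamma_exposure = gamma_e, gamma_confounder = gamma_c,
                          alpha = delta2 * true_conf,
                          scenario = "TRIANGLE", seed = config$seed),
                     class = "ground_truth")
  list(exposure = exposure, confounder = confounder, outcome = outcome,
       truth = truth)
}

#' Simulate mutual causation between two traits
#'
#' Traits A and B each have a disjoint core SNP set; A causes B with effect
#' `theta_ab` and B causes A with `theta_ba`. Summary betas follow the
#' reduced form of the simultaneous structural equations (core effects
#' scaled by `1/(1 - theta_ab*theta_ba)`), so the per-SNP Wald ratio at an
#' A-core SNP for the A-to-B direction equals `theta_ab` exactly, and
#' symmetrically for B. SNPs reaching genome-wide significance for both
#' traits are flagged in the ground truth so [exclude_overlap()] has true
#' positives to remove.
#'
#' @param config A [scenario_config()] whose `theta` is
#'   `c(theta_ab, theta_ba)` with `theta_ab*theta_ba < 1` (each trait gets
#'   `k` core SNPs).
#' @return List with `table_a`, `table_b` (each over all 2k SNPs) and
#'   `truth` (core effects, both arrows, and the shared-significance flags).
#' @export
simulate_bidirectional <- function(config) {
  .assert(inherits(config, "scenario_config"), "config must be a scenario_config")
  .assert(length(config$theta) == 2,
          "bidirectional simulation needs theta = c(theta_ab, theta_ba)")
  theta_ab <- config$theta[1]; theta_ba <- config$theta[2]
  .assert(abs(theta_ab * theta_ba) < 1,
          "feedback loop theta_ab*theta_ba must be < 1 in magnitude")
  set.seed(config$seed)
  k <- config$k
  gamma_a <- .draw_gamma(k, config$gamma_sd)
  gamma_b <- .draw_gamma(k, config$gamma_sd)
  denom <- 1 - theta_ab * theta_ba
  # Reduced-form true effects over (A-core SNPs, B-core SNPs).
  true_a <- c(gamma_a, theta_ba * gamma_b) / denom
  true_b <- c(theta_ab * gamma_a, gamma_b) / denom
  eaf <- stats::runif(2 * k, config$maf_range[1], config$maf_range[2])
  se_a <- .se_from_eaf(eaf, config$n_exp)
  se_b <- .se_from_eaf(eaf, config$n_out)
  b_a <- stats::rnorm(2 * k, true_a, se_a)
  b_b <- stats::rnorm(2 * k, true_b, se_b)
  rsids <- c(sprintf("rsA%05d", seq_len(k)), sprintf("rsB%05d", seq_len(k)))
  table_a <- gwas_summary_table(.snp_frame(rsids, eaf, b_a, se_a, config$n_exp),
                                trait_id = "trait_a", sample_n = config$n_exp)
  table_b <- gwas_summary_table(.snp_frame(rsids, eaf, b_b, se_b, config$n_out),
                                trait_id = "trait_b", sample_n = config$n_out)
  shared <- rsids[.p_norm2(b_a / se_a) < 5e-8 & .p_norm2(b_b / se_b) < 5e-8]
  truth <- structure(list(theta = c(theta_ab = theta_ab, theta_ba = theta_ba),
                          gamma = c(gamma_a, gamma_b),
                          gamma_a = gamma_a, gamma_b = gamma_b,
                          alpha = numeric(2 * k),
                          shared_significant = shared,
                          scenario = "BIDIRECTIONAL", seed = config$seed),
                     class = "ground_truth")
  list(table_a = table_a, table_b = table_b, truth = truth)
}

#' Write simulated tables and ground truth to disk
#'
#' Writes each summary table as a TSV (columns `rsid`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) and the ground truth as
#' JSON. Output is deterministic: regenerating with the same seed yields
#' byte-identical files.
#'
#' @param sim Result of one of the `simulate_*` functions (any list whose
#'   `gwas_summary_table` elements should be written; the `truth` element is
#'   serialized to JSON).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(sim)) {
    x <- sim[[nm]]
    if (inherits(x, "gwas_summary_table")) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      rec <- x$records
      num <- vapply(rec, is.numeric, logical(1))
      rec[num] <- lapply(rec[num], function(v)
        format(v, digits = 15, trim = TRUE, scientific = NA))
      utils::write.table(rec, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(sim$truth)) {
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(unclass(sim$truth), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
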