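# SIMEX correction of the MR-Egger estimate for regression dilution.

#' SIMEX-corrected MR-Egger estimate
#'
#' Simulation extrapolation counters the attenuation of the MR-Egger slope
#' caused by measurement error in the SNP-exposure betas (violation of the
#' no-measurement-error assumption). For each `lambda > 0` in the grid and
#' each of `b_reps` replicates, the exposure betas are perturbed with
#' additional noise of variance `lambda * se_zx^2` and the Egger regression
#' is refit; the replicate-mean slope and intercept at each `lambda`
#' (including the unperturbed `lambda = 0` fit) are then extrapolated with a
#' quadratic in `lambda` to `lambda = -1`, the notional error-free state.
#'
#' Variance follows the simulation-extrapolation difference method: the
#' per-`lambda` difference between the mean model-based variance and the
#' between-replicate variance of the estimates is extrapolated to
#' `lambda = -1` (falling back to the `lambda = 0` model variance if the
#' extrapolated value is not positive). When all `se_zx` are zero every
#' perturbed fit equals the plain fit and the corrected estimate equals
#' [egger()] exactly.
#'
#' @inheritParams ivw
#' @param lambda_grid Ascending grid starting at 0 with at least 3 distinct
#'   values (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param b_reps Replicates per grid point (default 1000, minimum 100).
#' @param seed RNG seed (required; output is bit-reproducible for a fixed
#'   seed and grid).
#' @param extrapolation Only `"quadratic"` is implemented.
#' @return An `mr_estimate` with method `"egger_simex"`, intercept fields,
#'   and a `lambda_fit` element recording the per-lambda mean estimates.
#' @export
simex_egger <- function(h, lambda_grid = c(0, 0.5, 1, 1.5, 2), b_reps = 1000,
                        seed, extrapolation = "quadratic") {
  .assert(identical(extrapolation, "quadratic"),
          "only quadratic extrapolation is implemented")
  .assert(length(unique(lambda_grid)) >= 3,
          "lambda_grid must contain at least 3 distinct values")
  .assert(abs(lambda_grid[1]) < 1e-12 && !is.unsorted(lambda_grid),
          "lambda_grid must start at 0 and be ascending")
  .assert(b_reps >= 100, "b_reps must be at least 100")
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 3, "SIMEX-Egger needs at least 3 SNPs")
  .assert(!is.null(r$se_zx) && all(is.finite(r$se_zx)) && all(r$se_zx >= 0),
          "finite nonnegative se_zx required")

  set.seed(seed)
  base <- .egger_fit(r$beta_zx, r$beta_zy, r$se_zy)
  if (all(r$se_zx == 0)) {
    # No measurement error: every perturbed fit reproduces the plain fit,
    # so the extrapolation is the identity.
    se <- sqrt(base$var_slope)
    ise <- sqrt(base$var_intercept)
    return(.mr_estimate(
      "egger_simex", base$slope, se, .p_t2(base$slope / se, base$df), k,
      .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
      .h_meta(h, "outcome_type"),
      intercept = base$intercept, intercept_se = ise,
      intercept_pval = .p_t2(base$intercept / ise, base$df),
      extra = list(lambda_fit = data.frame(lambda = lambda_grid,
                                           slope = base$slope,
                                           intercept = base$intercept),
                   b_reps = b_reps, seed = seed)))
  }
  lambdas <- lambda_grid
  nl <- length(lambdas)
  mean_slope <- mean_int <- var_s <- var_i <- numeric(nl)
  mean_slope[1] <- base$slope
  mean_int[1] <- base$intercept
  var_s[1] <- base$var_slope        # simulation variance is 0 at lambda = 0
  var_i[1] <- base$var_intercept
  # Each replicate re-applies the full Egger estimator, orientation
  # included, so the perturbed data are treated exactly as the observed
  # data were.
  for (l in 2:nl) {
    lam <- lambdas[l]
    noise <- matrix(stats::rnorm(b_reps * k), b_reps, k)
    BX <- matrix(r$beta_zx, b_reps, k, byrow = TRUE) +
      sweep(noise, 2, sqrt(lam) * r$se_zx, `*`)
    fit <- .egger_fit(BX, r$beta_zy, r$se_zy)
    mean_slope[l] <- mean(fit$slope)
    mean_int[l] <- mean(fit$intercept)
    var_s[l] <- mean(fit$var_slope) - stats::var(fit$slope)
    var_i[l] <- mean(fit$var_intercept) - stats::var(fit$intercept)
  }

  quad_at <- function(y, x0 = -1) {
    cf <- stats::coef(stats::lm(y ~ lambdas + I(lambdas^2)))
    cf[is.na(cf)] <- 0
    unname(cf[1] + cf[2] * x0 + cf[3] * x0^2)
  }
  beta <- quad_at(mean_slope)
  intercept <- quad_at(mean_int)
  v_beta <- quad_at(var_s)
  v_int <- quad_at(var_i)
  if (!is.finite(v_beta) || v_beta <= 0) v_beta <- base$var_slope
  if (!is.finite(v_int) || v_int <= 0) v_int <- base$var_intercept
  se <- sqrt(v_beta)
  ise <- sqrt(v_int)

  .mr_estimate("egger_simex", beta, se, .p_t2(beta / se, base$df), k,
               .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
               .h_meta(h, "outcome_type"),
               intercept = intercept, intercept_se = ise,
               intercept_pval = .p_t2(intercept / ise, base$df),
               extra = list(
                 lambda_fit = data.frame(lambda = lambdas,
                                         slope = mean_slope,
                                         intercept = mean_int),
                 b_reps = b_reps, seed = seed))
}
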