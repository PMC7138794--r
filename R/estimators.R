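# Causal-effect estimators: Wald ratio, IVW, MR-Egger, weighted median,
# weighted mode, and multivariable IVW.

.mr_estimate <- function(method, beta, se, pval, n_snps,
                         exposure_id = NA_character_, outcome_id = NA_character_,
                         outcome_type = NA_character_,
                         intercept = NULL, intercept_se = NULL,
                         intercept_pval = NULL, extra = list()) {
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                pval = pval, n_snps = as.integer(n_snps),
                exposure_id = exposure_id, outcome_id = outcome_id,
                outcome_type = outcome_type),
           if (!is.null(intercept)) list(intercept = intercept,
                                         intercept_se = intercept_se,
                                         intercept_pval = intercept_pval),
           extra)
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (95%% CI %.4g, %.4g), se = %.4g, p = %.3g, k = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pval, x$n_snps))
  if (identical(x$outcome_type, "binary")) {
    cat(sprintf("  OR = %.4g (95%% CI %.4g, %.4g)\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' Wald ratio for a single SNP
#'
#' The per-SNP causal estimate `beta_zy / beta_zx` with first-order
#' delta-method standard error `se_zy / |beta_zx|`.
#'
#' @param beta_zx,se_zx SNP-exposure effect and SE.
#' @param beta_zy,se_zy SNP-outcome effect and SE.
#' @param exposure_id,outcome_id,outcome_type Optional metadata carried into
#'   the estimate.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_zx, se_zx, beta_zy, se_zy,
                       exposure_id = NA_character_, outcome_id = NA_character_,
                       outcome_type = NA_character_) {
  .assert(beta_zx != 0, "beta_zx is zero: Wald ratio undefined")
  beta <- beta_zy / beta_zx
  se <- se_zy / abs(beta_zx)
  .mr_estimate("wald_ratio", beta, se, .p_norm2(beta / se), 1L,
               exposure_id, outcome_id, outcome_type)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of per-SNP Wald ratios with first-order weights
#' `w_j = beta_zx_j^2 / se_zy_j^2`, equivalent to zero-intercept weighted
#' regression of outcome on exposure betas. The default multiplicative
#' random-effects model scales the fixed-effect SE by
#' `sqrt(max(1, Q/(k-1)))` so heterogeneity can widen but never narrow the
#' interval.
#'
#' @param h A `harmonized_set` or data.frame of per-SNP effects.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"` (a single SNP delegates to
#'   [wald_ratio()]).
#' @export
ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 1, "no SNPs available")
  if (k == 1) {
    return(wald_ratio(r$beta_zx, r$se_zx %||% NA_real_, r$beta_zy, r$se_zy,
                      .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
                      .h_meta(h, "outcome_type")))
  }
  rw <- .ratio_weights(r)
  beta <- sum(rw$w * rw$ratio) / sum(rw$w)
  se_fixed <- 1 / sqrt(sum(rw$w))
  q <- sum(rw$w * (rw$ratio - beta)^2)
  se <- if (model == "fixed") se_fixed else se_fixed * sqrt(max(1, q / (k - 1)))
  .mr_estimate("ivw", beta, se, .p_norm2(beta / se), k,
               .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
               .h_meta(h, "outcome_type"),
               extra = list(model = model, q_stat = q, q_df = k - 1L))
}

# Weighted Egger regression in closed form, vectorized over replicates.
# BX: m x k matrix of SNP-exposure betas (m parallel fits), by/se_zy: length
# k. Each row is oriented so exposure betas are nonnegative (outcome betas
# sign-flipped in step). Residual scaling is multiplicative, floored at 1.
.egger_fit <- function(BX, by, se_zy, orient = TRUE) {
  if (is.null(dim(BX))) BX <- matrix(BX, nrow = 1)
  k <- length(by)
  if (orient) {
    s <- ifelse(BX < 0, -1, 1)
    X <- BX * s
    Y <- sweep(s, 2, by, `*`)
  } else {
    X <- BX
    Y <- matrix(by, nrow(BX), k, byrow = TRUE)
  }
  w <- 1 / se_zy^2
  Sw <- sum(w)
  Sx <- drop(X %*% w)
  Sy <- drop(Y %*% w)
  Sxx <- drop((X * X) %*% w)
  Sxy <- drop((X * Y) %*% w)
  den <- Sw * Sxx - Sx^2
  slope <- (Sw * Sxy - Sx * Sy) / den
  intercept <- (Sy - slope * Sx) / Sw
  R <- Y - intercept - X * slope     # recycles the length-m vectors by row
  rss <- drop((R * R) %*% w)
  sigma2 <- pmax(1, rss / (k - 2))
  list(slope = slope, intercept = intercept,
       var_slope = sigma2 * Sw / den,
       var_intercept = sigma2 * Sxx / den,
       df = k - 2L)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_zy^2`), after orienting every SNP to a
#' nonnegative exposure effect. The slope estimates the causal effect even
#' under directional pleiotropy (given InSIDE); the intercept estimates the
#' average directional pleiotropic effect and its test is the
#' directional-pleiotropy test. Inference uses a t distribution with `k - 2`
#' degrees of freedom and multiplicative residual scaling floored at 1. The
#' regression-dilution statistic `I2_GX` (weighted, computed from the
#' exposure betas and their SEs) is attached; values well below 1 signal
#' violation of the no-measurement-error assumption and motivate the SIMEX
#' correction.
#'
#' @inheritParams ivw
#' @return An `mr_estimate` with method `"egger"`, intercept fields, and an
#'   `i2_gx` element.
#' @export
egger <- function(h) {
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 3, "MR-Egger needs at least 3 SNPs")
  fit <- .egger_fit(r$beta_zx, r$beta_zy, r$se_zy)
  se <- sqrt(fit$var_slope)
  ise <- sqrt(fit$var_intercept)
  i2 <- NA_real_
  if (!is.null(r$se_zx) && all(is.finite(r$se_zx)) && all(r$se_zx > 0)) {
    bx <- abs(r$beta_zx)
    wgx <- 1 / r$se_zx^2
    mu <- sum(wgx * bx) / sum(wgx)
    qgx <- sum((bx - mu)^2 / r$se_zx^2)
    i2 <- max(0, (qgx - (k - 1)) / qgx)
  }
  .mr_estimate("egger", fit$slope, se, .p_t2(fit$slope / se, fit$df), k,
               .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
               .h_meta(h, "outcome_type"),
               intercept = fit$intercept, intercept_se = ise,
               intercept_pval = .p_t2(fit$intercept / ise, fit$df),
               extra = list(i2_gx = i2, df = fit$df))
}

# Weighted median of `x` under weights `w`: linear interpolation of the
# cumulative weight function s_j = cumsum(w')_j - w'_j/2 at 0.5.
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  wn <- w[o] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(x[1])
  k <- length(x)
  if (s[k] <= 0.5) return(x[k])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap over summary estimates, shared by median and mode.
.boot_ratio_estimator <- function(r, n_boot, seed, estimator) {
  .assert(!is.null(r$se_zx) && all(is.finite(r$se_zx)),
          "se_zx required for the parametric bootstrap")
  set.seed(seed)
  k <- nrow(r)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(k, r$beta_zx, r$se_zx)
    by <- stats::rnorm(k, r$beta_zy, r$se_zy)
    bx[bx == 0] <- .Machine$double.eps
    est[b] <- estimator(by / bx, bx^2 / r$se_zy^2)
  }
  stats::sd(est)
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP Wald ratios (IVW weights), consistent
#' when at least half the total weight comes from valid instruments. The SE
#' is the standard deviation of the estimator over `n_boot` parametric
#' bootstrap replicates that resample the summary estimates from
#' `Normal(beta, se)`.
#'
#' @inheritParams ivw
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed) {
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 3, "weighted median needs at least 3 SNPs")
  .assert(n_boot >= 2, "n_boot too small")
  rw <- .ratio_weights(r)
  beta <- .weighted_median(rw$ratio, rw$w)
  se <- .boot_ratio_estimator(r, n_boot, seed, .weighted_median)
  .mr_estimate("weighted_median", beta, se, .p_norm2(beta / se), k,
               .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
               .h_meta(h, "outcome_type"))
}

# Mode of a weighted normal-kernel density over the ratios.
.weighted_mode_point <- function(x, w, phi = 1) {
  if (max(x) - min(x) < .Machine$double.eps^0.5) return(x[1])
  k <- length(x)
  s <- 0.9 * min(stats::sd(x), stats::IQR(x) / 1.349)
  if (s == 0) s <- 0.9 * stats::sd(x)
  bw <- phi * s * k^(-1 / 5)
  if (bw <= 0) return(.weighted_median(x, w))
  d <- stats::density(x, weights = w / sum(w), bw = bw, n = 2048,
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  d$x[which.max(d$y)]
}

#' Weighted mode estimate
#'
#' Locates the mode of a weighted normal-kernel density over the per-SNP
#' Wald ratios (bandwidth `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`),
#' consistent when the largest cluster of SNP effects comes from valid
#' instruments. SE via the same parametric bootstrap as
#' [weighted_median()]. If all ratios coincide the common ratio is returned.
#'
#' @inheritParams weighted_median
#' @param bandwidth_phi Bandwidth multiplier (default 1).
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
weighted_mode <- function(h, bandwidth_phi = 1, n_boot = 1000, seed) {
  r <- mr_rows(h)
  k <- nrow(r)
  .assert(k >= 3, "weighted mode needs at least 3 SNPs")
  .assert(bandwidth_phi > 0, "bandwidth_phi must be positive")
  rw <- .ratio_weights(r)
  beta <- .weighted_mode_point(rw$ratio, rw$w, bandwidth_phi)
  se <- .boot_ratio_estimator(r, n_boot, seed, function(x, w)
    .weighted_mode_point(x, w, bandwidth_phi))
  .mr_estimate("weighted_mode", beta, se, .p_norm2(beta / se), k,
               .h_meta(h, "exposure_id"), .h_meta(h, "outcome_id"),
               .h_meta(h, "outcome_type"))
}

#' Multivariable IVW estimate
#'
#' Weighted multivariate regression of outcome betas on the K exposures'
#' beta columns without intercept (weights `1/se_zy^2`). Each exposure's
#' coefficient is its direct effect on the outcome holding the other
#' exposures constant. SEs come from the weighted normal equations with
#' multiplicative residual scaling floored at 1; p-values are two-sided
#' normal.
#'
#' @param m An `mv_harmonized_set` from [build_mv_set()], or a data.frame
#'   with columns `beta_zx_1..K`, `se_zx_1..K`, `beta_zy`, `se_zy`.
#' @return A list of `mr_estimate` objects (method `"mv_ivw"`), one per
#'   exposure, in exposure order.
#' @export
mv_ivw <- function(m) {
  if (inherits(m, "mv_harmonized_set")) {
    rows <- m$rows
    K <- m$K
    exposure_ids <- m$exposure_ids
    outcome_id <- m$outcome_id
    outcome_type <- m$outcome_type
  } else {
    rows <- m
    K <- length(grep("^beta_zx_[0-9]+$", names(rows)))
    .assert(K >= 1, "no beta_zx_<j> columns found")
    exposure_ids <- paste0("exposure_", seq_len(K))
    outcome_id <- NA_character_
    outcome_type <- NA_character_
  }
  k <- nrow(rows)
  .assert(k >= K + 2, "multivariable IVW needs at least K + 2 SNPs")
  X <- as.matrix(rows[, paste0("beta_zx_", seq_len(K)), drop = FALSE])
  y <- rows$beta_zy
  w <- 1 / rows$se_zy^2
  Xw <- X * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < K) {
    stop(paste0("collinear exposure effects among: ",
                paste(exposure_ids, collapse = ", ")), call. = FALSE)
  }
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(X, w * y)
  beta <- unname(drop(solve(XtWX, XtWy)))
  resid <- y - drop(X %*% beta)
  sigma2 <- max(1, sum(w * resid^2) / (k - K))
  vc <- sigma2 * solve(XtWX)
  ses <- unname(sqrt(diag(vc)))
  lapply(seq_len(K), function(j) {
    .mr_estimate("mv_ivw", beta[j], ses[j], .p_norm2(beta[j] / ses[j]), k,
                 exposure_id = exposure_ids[j], outcome_id = outcome_id,
                 outcome_type = outcome_type,
                 extra = list(adjusted_for = exposure_ids[-j]))
  })
}
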