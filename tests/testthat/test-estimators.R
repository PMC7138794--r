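test_that("Wald ratio and its delta-method SE behave as expected", {
  e <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(e$beta, 2.0)
  expect_equal(e$se, 0.5)
  expect_equal(e$ci_low, 2 - 1.959964 * 0.5)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.05)$beta, 0)
  # homogeneity: scaling the outcome scales estimate and SE
  e2 <- wald_ratio(0.1, 0.02, 0.2 * 3, 0.05 * 3)
  expect_equal(e2$beta, 3 * e$beta)
  expect_equal(e2$se, 3 * e$se)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "zero")
})

test_that("IVW equals the analytic weighted mean of Wald ratios and the WLS oracle", {
  # exact proportionality: no heterogeneity, fixed and random SEs agree
  h <- make_hset(c(0.1, 0.2, 0.3), 0.01, c(0.05, 0.10, 0.15), 0.01)
  e_fix <- ivw(h, "fixed")
  e_ran <- ivw(h, "multiplicative_random")
  expect_equal(e_fix$beta, 0.5, tolerance = 1e-12)
  expect_equal(e_fix$q_stat, 0, tolerance = 1e-20)
  expect_equal(e_fix$se, e_ran$se)

  # single SNP reduces to the Wald ratio
  h1 <- make_hset(0.1, 0.02, 0.06, 0.03)
  expect_equal(ivw(h1)$beta, wald_ratio(0.1, 0.02, 0.06, 0.03)$beta)
  expect_equal(ivw(h1)$se, wald_ratio(0.1, 0.02, 0.06, 0.03)$se)

  # independent normal-equations oracle on a noisy fixture
  bx <- c(0.1, 0.2, 0.3); by <- c(0.06, 0.09, 0.16); sy <- c(0.01, 0.02, 0.01)
  h3 <- make_hset(bx, 0.01, by, sy)
  w <- 1 / sy^2
  oracle_beta <- sum(w * bx * by) / sum(w * bx^2)
  expect_equal(ivw(h3, "fixed")$beta, oracle_beta, tolerance = 1e-10)
  expect_equal(ivw(h3, "fixed")$se, 1 / sqrt(sum(w * bx^2)), tolerance = 1e-10)
  # analytic weighted mean of ratios route
  wr <- bx^2 / sy^2
  expect_equal(ivw(h3)$beta, sum(wr * (by / bx)) / sum(wr), tolerance = 1e-10)
  # random-effects scaling is floored at 1
  expect_gte(ivw(h3, "multiplicative_random")$se, ivw(h3, "fixed")$se)
})

test_that("MR-Egger recovers exact affine structure and matches the lm oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  h0 <- make_hset(bx, 0.01, 0.5 * bx, 0.02)
  e0 <- egger(h0)
  expect_equal(e0$beta, 0.5, tolerance = 1e-10)
  expect_equal(e0$intercept, 0, tolerance = 1e-10)

  ha <- make_hset(bx, 0.01, 0.5 * bx + 0.02, 0.02)
  ea <- egger(ha)
  expect_equal(ea$beta, 0.5, tolerance = 1e-10)
  expect_equal(ea$intercept, 0.02, tolerance = 1e-10)

  set.seed(9)
  by <- 0.4 * bx + 0.01 + rnorm(5, 0, 0.05)
  sy <- runif(5, 0.01, 0.03)
  h <- make_hset(bx, 0.01, by, sy)
  e <- egger(h)
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-8)
  expect_equal(e$intercept, unname(coef(fit)[1]), tolerance = 1e-8)
  # residual scale here exceeds 1, so SEs and t p-values match summary.lm
  sm <- summary(fit)$coefficients
  if (summary(fit)$sigma > 1) {
    expect_equal(e$se, sm[2, 2], tolerance = 1e-8)
    expect_equal(e$intercept_se, sm[1, 2], tolerance = 1e-8)
    expect_equal(e$pval, sm[2, 4], tolerance = 1e-8)
  }
  expect_error(egger(make_hset(c(1, 1), 0.01, c(1, 1), 0.1)), "at least 3")
})

test_that("SIMEX reduces to plain Egger without measurement error and is deterministic", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  set.seed(4)
  by <- 0.5 * bx + rnorm(5, 0, 0.02)
  h0 <- make_hset(bx, se_zx = 0, beta_zy = by, se_zy = 0.02)
  s0 <- simex_egger(h0, b_reps = 100, seed = 1)
  e0 <- egger(h0)
  expect_identical(s0$beta, e0$beta)
  expect_identical(s0$intercept, e0$intercept)
  expect_identical(s0$se, e0$se)

  h <- make_hset(bx, se_zx = 0.05, beta_zy = by, se_zy = 0.02)
  s1 <- simex_egger(h, b_reps = 150, seed = 42)
  s2 <- simex_egger(h, b_reps = 150, seed = 42)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$se, s2$se)
  expect_false(identical(s1$beta, simex_egger(h, b_reps = 150, seed = 43)$beta))
  expect_error(simex_egger(h, lambda_grid = c(0, 1), b_reps = 100, seed = 1),
               "3 distinct")
  expect_error(simex_egger(h, b_reps = 10, seed = 1), "at least 100")
})

test_that("SIMEX pulls a dilution-attenuated Egger slope back toward the truth", {
  # strong instrument measured in a small exposure sample: regression
  # dilution attenuates MR-Egger, SIMEX recovers most of it
  sim <- simulate_pair(scenario_config("V", theta = 0.5, k = 100,
                                       n_exp = 1000, seed = 77))
  h <- harmonize(sim$exposure, sim$outcome)
  e <- egger(h)
  s <- simex_egger(h, b_reps = 400, seed = 78)
  expect_lt(e$beta, 0.5)
  expect_lt(abs(s$beta - 0.5), abs(e$beta - 0.5))
  expect_lt(e$i2_gx, 0.95)
})

test_that("weighted median matches the cumulative-weight interpolation oracle", {
  # constant ratios: the estimate is that constant
  hc <- make_hset(c(1, 2, 4), 0.01, 0.7 * c(1, 2, 4), 0.1)
  expect_equal(weighted_median(hc, n_boot = 50, seed = 1)$beta, 0.7)

  # symmetric equal-weight median
  hs <- make_hset(c(1, 1, 1), 0.01, c(0.1, 0.5, 0.9), 0.1)
  expect_equal(weighted_median(hs, n_boot = 50, seed = 1)$beta, 0.5)

  # hand-enumerated unequal-weight fixture:
  # ratios (0.1, 0.2, 0.4, 0.8, 1.0), weights (1, 2, 3, 2, 2)/10
  # s = (0.05, 0.20, 0.45, 0.70, 0.90); 0.5 interpolates between
  # ratio 0.4 (s = 0.45) and 0.8 (s = 0.70): 0.4 + 0.05/0.25 * 0.4 = 0.48
  bxw <- sqrt(c(1, 2, 3, 2, 2))
  ratios <- c(0.1, 0.2, 0.4, 0.8, 1.0)
  hw <- make_hset(bxw, 0.01, ratios * bxw, 1)
  expect_equal(weighted_median(hw, n_boot = 50, seed = 1)$beta, 0.48,
               tolerance = 1e-12)
  expect_error(weighted_median(make_hset(c(1, 1), 0.01, c(1, 1), 0.1),
                               n_boot = 50, seed = 1), "at least 3")
})

test_that("weighted mode finds the dominant cluster and ignores SNP order", {
  hc <- make_hset(c(1, 2, 4), 0.01, 0.3 * c(1, 2, 4), 0.1)
  expect_equal(weighted_mode(hc, n_boot = 50, seed = 1)$beta, 0.3)

  set.seed(5)
  ratios <- c(rnorm(7, 0.5, 0.03), rnorm(3, 2.0, 0.03))
  bx <- rep(1, 10)
  h <- make_hset(bx, 0.01, ratios, 0.1)
  m <- weighted_mode(h, n_boot = 50, seed = 2)
  expect_gt(m$beta, 0.4)
  expect_lt(m$beta, 0.6)
  # independent density-argmax oracle on the same bandwidth
  s <- 0.9 * min(sd(ratios), IQR(ratios) / 1.349) * 10^(-1 / 5)
  d <- density(ratios, weights = rep(0.1, 10), bw = s, n = 2048,
               from = min(ratios) - 3 * s, to = max(ratios) + 3 * s)
  expect_equal(m$beta, d$x[which.max(d$y)], tolerance = 1e-8)

  perm <- mr_rows(h)[sample(10), ]
  m2 <- weighted_mode(perm, n_boot = 50, seed = 2)
  expect_equal(m2$beta, m$beta, tolerance = 1e-10)
})

test_that("multivariable IVW matches the generalized-least-squares oracle", {
  set.seed(11)
  k <- 10
  x1 <- runif(k, 0.05, 0.3)
  x2 <- runif(k, 0.05, 0.3)
  sy <- runif(k, 0.01, 0.05)
  y <- 0.3 * x1 - 0.2 * x2 + rnorm(k, 0, 0.05)
  rows <- data.frame(beta_zx_1 = x1, se_zx_1 = 0.01,
                     beta_zx_2 = x2, se_zx_2 = 0.01,
                     beta_zy = y, se_zy = sy)
  est <- mv_ivw(rows)
  fit <- lm(y ~ 0 + x1 + x2, weights = 1 / sy^2)
  expect_equal(est[[1]]$beta, unname(coef(fit)[1]), tolerance = 1e-8)
  expect_equal(est[[2]]$beta, unname(coef(fit)[2]), tolerance = 1e-8)
  if (summary(fit)$sigma > 1) {
    sm <- summary(fit)$coefficients
    expect_equal(est[[1]]$se, sm[1, 2], tolerance = 1e-8)
    expect_equal(est[[2]]$se, sm[2, 2], tolerance = 1e-8)
  }
  # recovery within oracle SEs
  expect_lt(abs(est[[1]]$beta - 0.3), 3 * est[[1]]$se)
  expect_lt(abs(est[[2]]$beta + 0.2), 3 * est[[2]]$se)

  # near-inert second exposure: coefficients approach (0.4, 0)
  rows2 <- rows
  rows2$beta_zx_2 <- 1e-4 * x2
  rows2$beta_zy <- 0.4 * x1
  est2 <- mv_ivw(rows2)
  expect_equal(est2[[1]]$beta, 0.4, tolerance = 1e-6)
  expect_equal(est2[[2]]$beta, 0, tolerance = 1e-3)

  # K = 1 reduces to IVW on the same rows
  rows1 <- rows[, c("beta_zx_1", "se_zx_1", "beta_zy", "se_zy")]
  est1 <- mv_ivw(rows1)
  h1 <- make_hset(x1, 0.01, y, sy)
  expect_equal(est1[[1]]$beta, ivw(h1)$beta, tolerance = 1e-10)

  # duplicated exposure column is a collinearity error
  rows3 <- rows
  rows3$beta_zx_2 <- rows3$beta_zx_1
  expect_error(mv_ivw(rows3), "collinear")
})

test_that("negating every outcome effect negates all estimates and keeps SEs", {
  sim <- simulate_pair(scenario_config("V", seed = 31))
  h <- harmonize(sim$exposure, sim$outcome)
  hneg <- h
  hneg$rows$beta_zy <- -hneg$rows$beta_zy
  for (f in list(function(x) ivw(x), function(x) egger(x))) {
    a <- f(h); b <- f(hneg)
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
  a <- simex_egger(h, b_reps = 100, seed = 5)
  b <- simex_egger(hneg, b_reps = 100, seed = 5)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$se, a$se, tolerance = 1e-12)
  expect_equal(weighted_median(hneg, n_boot = 50, seed = 3)$beta,
               -weighted_median(h, n_boot = 50, seed = 3)$beta,
               tolerance = 1e-12)
  expect_equal(weighted_mode(hneg, n_boot = 50, seed = 3)$beta,
               -weighted_mode(h, n_boot = 50, seed = 3)$beta,
               tolerance = 1e-8)
})
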