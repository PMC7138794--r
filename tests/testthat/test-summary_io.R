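test_that("a well-formed table is read with order preserved and column remapping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs3", "rs1", "rs2"), A1 = c("A", "T", "C"),
                   A2 = c("G", "C", "G"), freq = c(0.2, 0.4, 0.3),
                   b = c(0.1, -0.05, 0.02), se = c(0.01, 0.02, 0.01),
                   p = c(1e-20, 0.01, 0.04), N = 1000)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_table(
    path, trait_id = "t", column_map = list(rsid = "SNP", effect_allele = "A1",
                                            other_allele = "A2", eaf = "freq",
                                            beta = "b", se = "se", pval = "p",
                                            n = "N"))
  expect_s3_class(tab, "gwas_summary_table")
  expect_equal(tab$records$rsid, c("rs3", "rs1", "rs2"))
  expect_equal(tab$records$beta, c(0.1, -0.05, 0.02))
  expect_equal(nrow(tab$rejected), 0)
  expect_error(
    read_summary_table(path, trait_id = "t",
                       column_map = list(rsid = "SNP", effect_allele = "A1",
                                         other_allele = "A2", se = "se",
                                         pval = "p", beta = "nonexistent")),
    "nonexistent")
})

test_that("rows violating per-SNP invariants are rejected with a reason", {
  rec <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs1", "rs5", "rs6"),
    effect_allele = c("A", "A", "X", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "A", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.3, 1.2),
    beta = 0.1, se = c(0.01, 0, 0.01, 0.01, 0.01, 0.01),
    pval = 0.01, n = 1000)
  tab <- gwas_summary_table(rec, trait_id = "t")
  expect_equal(tab$records$rsid, "rs1")
  expect_setequal(tab$rejected$reason,
                  c("nonpositive SE", "invalid allele", "duplicate rsid",
                    "identical alleles", "eaf outside (0,1)"))
  expect_equal(tab$rejected$reason[tab$rejected$rsid == "rs2"],
               "nonpositive SE")
  rec_bad <- rec[2, ]
  expect_error(gwas_summary_table(rec_bad, trait_id = "t"), "no valid rows")
})

test_that("harmonization handles matching, swapped, complemented and palindromic alleles", {
  exposure <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                         beta = c(0.10, 0.10, 0.10, 0.10), se = 0.01,
                         eaf = c(0.3, 0.3, 0.3, 0.10),
                         effect_allele = c("A", "A", "A", "A"),
                         other_allele = c("G", "G", "G", "T"))
  outcome <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                        beta = c(-0.05, -0.05, -0.05, 0.02), se = 0.02,
                        eaf = c(0.3, 0.7, 0.3, 0.12),
                        effect_allele = c("A", "G", "T", "A"),
                        other_allele = c("G", "A", "C", "T"))
  h <- harmonize(exposure, outcome)
  r <- h$rows
  # matching alleles: unchanged
  expect_equal(r$action[r$rsid == "rs1"], "unchanged")
  expect_equal(r$beta_zy[r$rsid == "rs1"], -0.05)
  # swapped alleles: sign flip
  expect_equal(r$action[r$rsid == "rs2"], "flipped")
  expect_equal(r$beta_zy[r$rsid == "rs2"], 0.05)
  # strand complement (T/C is A/G on the other strand): unchanged
  expect_equal(r$action[r$rsid == "rs3"], "unchanged")
  expect_equal(r$beta_zy[r$rsid == "rs3"], -0.05)
  # palindromic, frequencies informative and concordant (0.10 vs 0.12)
  expect_equal(r$action[r$rsid == "rs4"], "unchanged")
  expect_equal(r$beta_zy[r$rsid == "rs4"], 0.02)

  h_drop <- harmonize(exposure, outcome, palindrome_policy = "drop")
  expect_equal(h_drop$rows$action[h_drop$rows$rsid == "rs4"],
               "dropped-palindromic")
  expect_false("rs4" %in% mr_rows(h_drop)$rsid)

  # ambiguous palindromic frequency inside the band is dropped
  outcome_amb <- make_table("rs4", beta = 0.02, se = 0.02, eaf = 0.5,
                            effect_allele = "A", other_allele = "T")
  exposure_amb <- make_table("rs4", beta = 0.1, se = 0.01, eaf = 0.1,
                             effect_allele = "A", other_allele = "T")
  expect_error(harmonize(exposure_amb, outcome_amb), "no usable instrument")

  # discordant palindromic frequencies flip the sign
  outcome_disc <- make_table("rs4", beta = 0.02, se = 0.02, eaf = 0.88,
                             effect_allele = "A", other_allele = "T")
  h_disc <- harmonize(exposure_amb, outcome_disc)
  expect_equal(h_disc$rows$action, "flipped")
  expect_equal(h_disc$rows$beta_zy, -0.02)
})

test_that("harmonization flips all effects when the outcome alleles are globally swapped", {
  set.seed(42)
  for (rep in 1:5) {
    k <- 8
    ea <- sample(c("A", "T"), k, replace = TRUE)
    oa <- ifelse(ea == "A", "G", "C")
    beta_y <- rnorm(k, 0, 0.05)
    exposure <- make_table(sprintf("rs%d", 1:k), beta = rnorm(k, 0.1, 0.02),
                           se = 0.01, eaf = runif(k, 0.1, 0.4),
                           effect_allele = ea, other_allele = oa)
    outcome <- make_table(sprintf("rs%d", 1:k), beta = beta_y, se = 0.02,
                          eaf = runif(k, 0.1, 0.4),
                          effect_allele = ea, other_allele = oa)
    swapped <- make_table(sprintf("rs%d", 1:k), beta = beta_y, se = 0.02,
                          eaf = runif(k, 0.1, 0.4),
                          effect_allele = oa, other_allele = ea)
    h1 <- mr_rows(harmonize(exposure, outcome))
    h2 <- mr_rows(harmonize(exposure, swapped))
    expect_equal(h2$beta_zy, -h1$beta_zy)
  }
})

test_that("every requested SNP is accounted for as retained or dropped", {
  exposure <- make_table(sprintf("rs%d", 1:6), beta = 0.1, se = 0.01,
                         eaf = 0.3)
  outcome <- make_table(sprintf("rs%d", c(1, 2, 4)), beta = 0.05, se = 0.02,
                        eaf = 0.3)
  h <- harmonize(exposure, outcome, snps = sprintf("rs%d", 1:5))
  expect_equal(nrow(h$rows), 5)
  expect_equal(sum(h$rows$action %in% c("unchanged", "flipped")) +
                 sum(grepl("^dropped", h$rows$action)), 5)
  log <- harmonization_log(h)
  expect_named(log, c("rsid", "action", "reason"))
  expect_error(harmonize(exposure, outcome, snps = "rs99"), "absent from exposure")
})

test_that("result tables serialize with odds ratios only for binary outcomes", {
  est_bin <- ivw(make_hset(c(0.1, 0.2, 0.3), 0.01, c(0, 0, 0),
                           c(0.1, 0.2, 0.3) * 1, outcome_type = "binary"))
  tab <- results_table(est_bin)
  expect_equal(tab$beta, 0)
  expect_equal(tab$or_, 1)
  est0 <- wald_ratio(1, 0.01, 0, 0.1, outcome_type = "binary")
  tab0 <- results_table(est0)
  expect_equal(tab0$or_ci_low, exp(-1.959964 * 0.1))
  expect_equal(tab0$or_ci_high, exp(1.959964 * 0.1))
  est_cont <- wald_ratio(1, 0.01, 0.5, 0.1, outcome_type = "continuous")
  expect_true(is.na(results_table(est_cont)$or_))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(list(est_bin, est_cont), path)
  back <- utils::read.delim(path)
  expect_equal(back$estimator, c("ivw", "wald_ratio"))
  expect_equal(back$beta, c(0, 0.5), tolerance = 1e-6)
  expect_equal(back$se[2], est_cont$se, tolerance = 1e-6)
  expect_equal(back$pval, c(est_bin$pval, est_cont$pval), tolerance = 1e-6)
})

test_that("multivariable harmonization aligns all tables to the first exposure", {
  rs <- sprintf("rs%d", 1:5)
  e1 <- make_table(rs, beta = c(0.1, 0.2, 0.15, 0.12, 0.3), se = 0.01,
                   eaf = 0.3, trait_id = "e1")
  e2 <- make_table(rs, beta = c(0.05, 0.1, 0.07, 0.06, 0.15), se = 0.01,
                   eaf = 0.3, trait_id = "e2")
  out <- make_table(rs, beta = c(0.02, 0.04, 0.03, 0.02, 0.06), se = 0.02,
                    eaf = 0.3, trait_id = "y")
  m <- build_mv_set(list(e1, e2), out, rs)
  expect_s3_class(m, "mv_harmonized_set")
  expect_equal(nrow(m$rows), 5)
  expect_equal(m$rows$beta_zy, out$records$beta)

  # SNP missing from exposure 2 is dropped and logged
  e2_miss <- make_table(rs[-3], beta = c(0.05, 0.1, 0.06, 0.15), se = 0.01,
                        eaf = 0.3, trait_id = "e2")
  m2 <- build_mv_set(list(e1, e2_miss), out, rs)
  expect_equal(nrow(m2$rows), 4)
  expect_true("rs3" %in% m2$dropped$rsid)

  # outcome alleles swapped for one SNP flips only that SNP's beta_zy
  out_sw <- make_table(rs, beta = c(0.02, 0.04, 0.03, 0.02, 0.06), se = 0.02,
                       eaf = 0.3,
                       effect_allele = c("A", "G", "A", "A", "A"),
                       other_allele = c("G", "A", "G", "G", "G"),
                       trait_id = "y")
  m3 <- build_mv_set(list(e1, e2), out_sw, rs)
  expect_equal(m3$rows$beta_zy, c(0.02, -0.04, 0.03, 0.02, 0.06))

  expect_error(build_mv_set(list(e1), out), "at least two exposures")
})
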