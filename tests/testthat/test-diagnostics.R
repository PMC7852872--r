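test_that("Cochran's Q vanishes under homogeneity and clamps I2", {
  hom <- insts_from_ratios(rep(0.3, 5), w = c(1, 2, 3, 4, 5))
  h <- cochran_q(hom)
  expect_equal(h$Q, 0)
  expect_equal(h$i2, 0)
  expect_equal(h$p_het, 1)

  # Q < df: I2 clamps to zero
  mild <- insts_from_ratios(c(0.30, 0.31, 0.29), w = c(100, 100, 100),
                            se_out = 0.5)
  h <- cochran_q(mild)
  expect_lt(h$Q, h$df)
  expect_equal(h$i2, 0)
})

test_that("Q equals the weighted RSS of the through-origin regression", {
  insts <- make_insts(c(0.1, 0.2, 0.3, 0.15), c(0.04, 0.05, 0.10, 0.01),
                      se_out = c(0.03, 0.04, 0.02, 0.05))
  fit <- lm(beta_out ~ 0 + beta_exp, data = insts,
            weights = 1 / insts$se_out^2)
  rss_w <- sum(residuals(fit)^2 / insts$se_out^2)
  expect_equal(cochran_q(insts)$Q, rss_w, tolerance = 1e-10)
})

test_that("per-SNP Q contributions partition the total", {
  set.seed(41)
  insts <- make_insts(runif(7, 0.05, 0.3), rnorm(7, 0.05, 0.05),
                      se_out = runif(7, 0.02, 0.06))
  w <- insts$beta_exp^2 / insts$se_out^2
  theta <- insts$beta_out / insts$beta_exp
  beta_hat <- sum(w * theta) / sum(w)
  contrib <- w * (theta - beta_hat)^2
  expect_equal(sum(contrib), cochran_q(insts)$Q, tolerance = 1e-12)
})

test_that("Rucker's Q comes from the radial fit and is nested under Q", {
  # exact radial line through the origin
  exact <- insts_from_ratios(rep(0.25, 4), w = c(1, 4, 9, 16))
  expect_equal(rucker_q(exact)$q_rucker, 0, tolerance = 1e-20)

  # independent OLS-with-intercept oracle in radial coordinates
  set.seed(23)
  insts <- make_insts(runif(5, 0.05, 0.3), rnorm(5, 0.05, 0.05),
                      se_out = runif(5, 0.02, 0.06))
  w <- insts$beta_exp^2 / insts$se_out^2
  x <- sqrt(w); y <- (insts$beta_out / insts$beta_exp) * x
  oracle <- sum(residuals(lm(y ~ x))^2)
  expect_equal(rucker_q(insts)$q_rucker, oracle, tolerance = 1e-10)

  # nested models: Q' <= Q on any instrument set
  for (rep in 1:10) {
    L <- sample(3:15, 1)
    r <- make_insts(runif(L, 0.05, 0.3), rnorm(L, 0.04, 0.05),
                    se_out = runif(L, 0.02, 0.06))
    expect_lte(rucker_q(r)$q_rucker, cochran_q(r)$Q + 1e-12)
  }
})

test_that("leave-one-out applies the count rule to each reduced set", {
  set.seed(61)
  insts <- make_insts(runif(7, 0.1, 0.3), rnorm(7, 0.05, 0.04))
  loo <- leave_one_out(insts)
  expect_equal(nrow(loo), 7)
  expect_true(all(loo$n_snps == 6))
  expect_true(all(loo$method == "ivw_fe"))

  big <- make_insts(runif(11, 0.1, 0.3), rnorm(11, 0.05, 0.04))
  expect_true(all(leave_one_out(big)$method == "ivw_re"))

  # homogeneous instruments: every LOO estimate inside every LOO CI
  hom <- insts_from_ratios(rnorm(8, 0.3, 0.005), w = rep(25, 8))
  loo_h <- leave_one_out(hom)
  expect_true(all(outer(loo_h$beta, loo_h$ci_low, `>=`) &
                    outer(loo_h$beta, loo_h$ci_high, `<=`)))

  # 6 consensus SNPs + 1 outlier: dropping the outlier moves the estimate
  # toward the consensus ratio
  out <- insts_from_ratios(c(rep(0.2, 6), 2.0), w = rep(10, 7))
  full <- mr_ivw(out, "fe")$beta
  loo_o <- leave_one_out(out)
  no_outlier <- loo_o$beta[loo_o$excluded_rsid == out$rsid[7]]
  expect_lt(abs(no_outlier - 0.2), abs(full - 0.2))
})

test_that("named-SNP exclusion recomputes estimates and heterogeneity", {
  set.seed(71)
  insts <- make_insts(runif(7, 0.1, 0.3), rnorm(7, 0.05, 0.04))

  none <- exclude_snps(insts, character(0))
  expect_equal(none$estimate_fe$beta, mr_ivw(insts, "fe")$beta)
  expect_equal(none$heterogeneity$Q, cochran_q(insts)$Q)

  all_but_one <- exclude_snps(insts, insts$rsid[-1])
  expect_equal(all_but_one$estimate_fe$beta, wald_ratio(insts[1, ])$beta)

  expect_error(exclude_snps(insts, "rs_nope"), "unknown rsid")

  # the largest-Q-contribution SNP can never increase Q when removed
  w <- insts$beta_exp^2 / insts$se_out^2
  theta <- insts$beta_out / insts$beta_exp
  contrib <- w * (theta - sum(w * theta) / sum(w))^2
  worst <- insts$rsid[which.max(contrib)]
  q_all <- vapply(insts$rsid, function(id) {
    exclude_snps(insts, id)$heterogeneity$Q
  }, numeric(1))
  expect_equal(unname(q_all[worst]), min(q_all))
  expect_lte(q_all[[worst]], cochran_q(insts)$Q)
})

test_that("composed exclusions equal exclusion of the union", {
  set.seed(81)
  insts <- make_insts(runif(8, 0.1, 0.3), rnorm(8, 0.05, 0.04))
  a <- exclude_snps(exclude_snps(insts, insts$rsid[1])$instruments,
                    insts$rsid[3])
  b <- exclude_snps(insts, insts$rsid[c(1, 3)])
  expect_equal(a$estimate_re$beta, b$estimate_re$beta)
  expect_equal(a$heterogeneity$Q, b$heterogeneity$Q)
})

test_that("the single-SNP forest table is internally consistent", {
  set.seed(91)
  insts <- make_insts(runif(7, 0.1, 0.3), rnorm(7, 0.05, 0.04))
  tab <- single_snp_table(insts, exclude_rsid = insts$rsid[1])
  expect_equal(nrow(tab), 7 + 4)
  snp_rows <- tab[tab$type == "snp", ]
  expect_equal(snp_rows$or_sd, exp(snp_rows$beta))
  expect_identical(tab$beta[tab$label == "IVW (fixed effects)"],
                   mr_ivw(insts, "fe")$beta)
  excl <- exclude_snps(insts, insts$rsid[1])
  expect_identical(
    tab$beta[grepl("without", tab$label) & grepl("random", tab$label)],
    excl$estimate_re$beta)
})

test_that("consistency requires sign agreement and nominal significance", {
  mk <- function(beta, pval) {
    structure(list(beta = beta, pval = pval), class = "mr_estimate")
  }
  prim <- mk(0.5, 0.01)
  expect_true(consistency_check(prim, list(mk(0.4, 0.02), mk(0.6, 0.001),
                                           mk(0.3, 0.04))))
  expect_false(consistency_check(prim, list(mk(0.4, 0.2), mk(0.6, 0.001),
                                            mk(0.3, 0.04))))
  expect_false(consistency_check(prim, list(mk(-0.4, 0.02), mk(0.6, 0.001),
                                            mk(0.3, 0.04))))
  expect_false(consistency_check(mk(0.5, 0.2), list(mk(0.4, 0.02))))
})

test_that("heterogeneity outputs stay in their ranges", {
  set.seed(101)
  for (rep in 1:15) {
    L <- sample(3:20, 1)
    insts <- make_insts(runif(L, 0.05, 0.3), rnorm(L, 0.04, 0.06),
                        se_out = runif(L, 0.02, 0.08))
    h <- heterogeneity(insts)
    expect_gte(h$i2, 0); expect_lte(h$i2, 100)
    expect_gt(h$p_het, 0); expect_lte(h$p_het, 1)
    expect_gte(h$Q, 0)
  }
})
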