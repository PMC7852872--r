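test_that("Wald ratio arithmetic, sign rule and boundary p-value", {
  inst <- make_insts(0.50, 0.10, se_out = 0.05)
  est <- wald_ratio(inst[1, ])
  expect_equal(est$beta, 0.20)
  expect_equal(est$se, 0.10)

  null_inst <- make_insts(0.50, 0, se_out = 0.05)
  expect_equal(wald_ratio(null_inst[1, ])$pval, 1)

  neg <- make_insts(-0.50, 0.10, se_out = 0.05)
  expect_lt(wald_ratio(neg[1, ])$beta, 0)

  zero <- make_insts(0, 0.1)
  expect_error(wald_ratio(zero[1, ]), "beta_exp = 0")
})

test_that("IVW equals a weighted-least-squares-through-origin oracle", {
  # equal weights: plain mean of the ratios
  eq <- insts_from_ratios(c(0.1, 0.3), w = c(2, 2))
  expect_equal(mr_ivw(eq, "fe")$beta, 0.2)

  # L = 2 with tiny Q: the RE inflation clamps at 1
  expect_equal(mr_ivw(eq, "re")$se, mr_ivw(eq, "fe")$se)

  insts <- make_insts(beta_exp = c(0.12, 0.08, 0.20),
                      beta_out = c(0.030, 0.010, 0.055),
                      se_out = c(0.04, 0.05, 0.03))
  fit <- lm(beta_out ~ 0 + beta_exp, data = insts,
            weights = 1 / insts$se_out^2)
  est <- mr_ivw(insts, "fe")
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(sum(insts$beta_exp^2 / insts$se_out^2)),
               tolerance = 1e-12)
})

test_that("IVW point estimate is mode-invariant and RE never tightens the SE", {
  set.seed(21)
  for (rep in 1:25) {
    L <- sample(2:30, 1)
    insts <- make_insts(rnorm(L, 0.1, 0.05), rnorm(L, 0.02, 0.05),
                        se_out = runif(L, 0.02, 0.08))
    insts <- insts[insts$beta_exp != 0, ]
    fe <- mr_ivw(insts, "fe"); re <- mr_ivw(insts, "re")
    expect_identical(fe$beta, re$beta)
    expect_gte(re$se, fe$se)
  }
})

test_that("single-instrument IVW collapses to the Wald ratio", {
  inst <- make_insts(0.4, 0.1, se_out = 0.03)
  expect_equal(mr_ivw(inst, "re")$beta, wald_ratio(inst[1, ])$beta)
  expect_equal(mr_ivw(inst, "re")$se, wald_ratio(inst[1, ])$se)
})

test_that("the primary-method rule follows the 10-SNP cut", {
  expect_equal(select_primary_method(1), "wald")
  expect_equal(select_primary_method(7), "ivw_fe")
  expect_equal(select_primary_method(9), "ivw_fe")
  expect_equal(select_primary_method(10), "ivw_re")
})

test_that("Egger matches a weighted-regression oracle and detects shifts", {
  # exact line through the origin: zero intercept, slope = IVW
  on_line <- make_insts(c(0.1, 0.2, 0.3, 0.4), 0.5 * c(0.1, 0.2, 0.3, 0.4),
                        se_out = c(0.03, 0.04, 0.05, 0.03))
  est <- mr_egger(on_line)
  expect_equal(est$aux$intercept, 0, tolerance = 1e-12)
  expect_equal(est$beta, mr_ivw(on_line, "fe")$beta, tolerance = 1e-10)

  # constant pleiotropic shift alpha on every outcome beta: intercept = alpha
  alpha <- 0.07
  shifted <- make_insts(c(0.1, 0.15, 0.2, 0.3, 0.4),
                        0.5 * c(0.1, 0.15, 0.2, 0.3, 0.4) + alpha,
                        se_out = 0.04)
  est <- mr_egger(shifted)
  expect_equal(est$aux$intercept, alpha, tolerance = 1e-10)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)

  # independent WLS oracle on noisy data
  set.seed(5)
  insts <- make_insts(runif(6, 0.05, 0.4), rnorm(6, 0.05, 0.05),
                      se_out = runif(6, 0.02, 0.06))
  fit <- lm(beta_out ~ beta_exp, data = insts, weights = 1 / insts$se_out^2)
  est <- mr_egger(insts)
  expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(est$aux$intercept, unname(coef(fit)[1]), tolerance = 1e-10)

  expect_error(mr_egger(insts[1:2, ]), "at least 3")
})

test_that("Egger with the intercept forced to zero reproduces IVW", {
  set.seed(8)
  insts <- make_insts(runif(8, 0.05, 0.4), rnorm(8, 0.05, 0.05),
                      se_out = runif(8, 0.02, 0.06))
  constrained <- lm(beta_out ~ 0 + beta_exp, data = insts,
                    weights = 1 / insts$se_out^2)
  expect_equal(unname(coef(constrained)), mr_ivw(insts, "fe")$beta,
               tolerance = 1e-10)
})

test_that("weighted median interpolates the weighted CDF at one half", {
  # equal weights: the plain sample median
  eq <- insts_from_ratios(1:5, w = rep(1, 5))
  est <- mr_weighted_median(eq, seed = 1)
  expect_equal(est$beta, 3)

  # a dominant SNP flanked symmetrically pins the estimate to its ratio
  dom <- insts_from_ratios(c(0.1, 0.5, 0.9), w = c(0.1, 0.8, 0.1))
  expect_equal(mr_weighted_median(dom, seed = 1)$beta, 0.5)

  # determinism of the bootstrap SE
  set.seed(99)
  insts <- make_insts(runif(6, 0.1, 0.4), rnorm(6, 0.05, 0.03))
  a <- mr_weighted_median(insts, n_boot = 1000, seed = 42)
  b <- mr_weighted_median(insts, n_boot = 1000, seed = 42)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(insts), "seed")
})

test_that("weighted mode finds the majority cluster and matches a grid oracle", {
  # degenerate cluster: all ratios identical
  degen <- insts_from_ratios(rep(0.4, 4), w = c(1, 2, 3, 4))
  expect_equal(mr_weighted_mode(degen, seed = 1)$beta, 0.4)
  expect_equal(mr_weighted_mode(degen, phi = 0.1, seed = 1)$beta, 0.4)

  # 5 SNPs at 0.2 vs 2 at 1.0, equal weights: mode near the majority
  clus <- insts_from_ratios(c(0.18, 0.19, 0.20, 0.21, 0.22, 0.99, 1.01),
                            w = rep(1, 7))
  est <- mr_weighted_mode(clus, seed = 1)
  expect_lt(abs(est$beta - 0.2), 0.05)

  # argmax against an independent dense-grid search of the smoothed density
  set.seed(13)
  insts <- make_insts(runif(8, 0.1, 0.4), rnorm(8, 0.06, 0.04))
  theta <- insts$beta_out / insts$beta_exp
  w <- insts$beta_exp^2 / insts$se_out^2; wn <- w / sum(w)
  h <- 0.9 * min(sd(theta), mad(theta)) / length(theta)^(1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 200000)
  dens <- colSums(wn * outer(theta, grid, function(t, x) dnorm(x, t, h)))
  oracle <- grid[which.max(dens)]
  expect_equal(mr_weighted_mode(insts, seed = 1)$beta, oracle,
               tolerance = 1e-4)
})

test_that("RAPS solves the profile score and degenerates to IVW", {
  # se_exp = 0 and tau2 = 0: the score is the IVW-FE normal equation
  insts <- make_insts(c(0.1, 0.2, 0.3, 0.15), c(0.03, 0.05, 0.08, 0.02),
                      se_exp = 0, se_out = c(0.03, 0.04, 0.02, 0.05))
  expect_equal(mr_raps(insts)$beta, mr_ivw(insts, "fe")$beta,
               tolerance = 1e-10)

  # root agrees with an independent bisection of the score
  set.seed(17)
  insts <- make_insts(runif(10, 0.05, 0.3), rnorm(10, 0.04, 0.04),
                      se_exp = 0.02, se_out = runif(10, 0.02, 0.06))
  score <- function(th) {
    v <- insts$se_out^2 + th^2 * insts$se_exp^2
    sum((insts$beta_out - th * insts$beta_exp) * insts$beta_exp / v)
  }
  lo <- -10; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(score(lo)) == sign(score(mid))) lo <- mid else hi <- mid
  }
  expect_equal(mr_raps(insts)$beta, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("RAPS recovers a simulated causal effect", {
  reps <- 60
  ests <- vapply(seq_len(reps), function(r) {
    d <- simulate_trait(sim_config(L = 50, theta = 0.3, seed = 5000 + r))
    insts <- build_instrument_set(d$exposure, d$outcome)$instruments
    mr_raps(insts)$beta
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - 0.3), 3 * mc_se + 0.01)
})

test_that("RAPS overdispersion absorbs balanced pleiotropy", {
  d <- simulate_trait(sim_config(L = 60, theta = 0.2, pleiotropy_sd = 0.03,
                                 seed = 300))
  insts <- build_instrument_set(d$exposure, d$outcome)$instruments
  od <- mr_raps(insts, overdispersion = TRUE)
  expect_gt(od$aux$tau2, 0)
  expect_gt(od$se, mr_raps(insts)$se)
})

test_that("all estimators are equivariant under a joint sign flip", {
  set.seed(31)
  insts <- make_insts(runif(8, 0.05, 0.3), rnorm(8, 0.05, 0.04),
                      se_exp = 0.01, se_out = runif(8, 0.02, 0.06))
  flipped <- insts
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_ivw(flipped, "re")$beta, mr_ivw(insts, "re")$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$beta, mr_egger(insts)$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(flipped, seed = 3)$beta,
               mr_weighted_median(insts, seed = 3)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_mode(flipped, seed = 3)$beta,
               mr_weighted_mode(insts, seed = 3)$beta, tolerance = 1e-8)
  expect_equal(mr_raps(flipped)$beta, mr_raps(insts)$beta, tolerance = 1e-10)
})

test_that("weighted median resists a directional invalid minority", {
  # 40% of instruments share a directional pleiotropic shift; the valid
  # majority still carries > half the weight, so the median is less biased
  # than random-effects IVW
  theta_true <- 0.1
  reps <- 80
  bias <- vapply(seq_len(reps), function(r) {
    set.seed(4000 + r)
    L <- 20
    gamma <- runif(L, 0.1, 0.3)
    alpha <- c(rep(0.08, 8), rep(0, 12))
    se_out <- rep(0.02, L)
    insts <- make_insts(gamma, theta_true * gamma + alpha + rnorm(L, 0, se_out),
                        se_exp = 0, se_out = se_out)
    c(mr_weighted_median(insts, n_boot = 2, seed = 1)$beta - theta_true,
      mr_ivw(insts, "re")$beta - theta_true)
  }, numeric(2))
  expect_lt(abs(mean(bias[1, ])), abs(mean(bias[2, ])))
})

test_that("the odds-ratio scale is the exponential map", {
  est <- new_est <- mr_ivw(insts_from_ratios(c(0, 0), w = c(1, 1)), "fe")
  expect_equal(est$or_sd, 1)
  est2 <- mr_ivw(insts_from_ratios(c(log(2), log(2)), w = c(1, 1)), "fe")
  expect_equal(est2$or_sd, 2)
  rescaled <- to_or_scale(est2)
  expect_lt(rescaled$or_lo, rescaled$or_sd)
  expect_gt(rescaled$or_hi, rescaled$or_sd)
})
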