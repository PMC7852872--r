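# Two-sample MR causal estimators on a harmonised instrument set.
#
# Instruments are rows with beta_exp/se_exp (trait-SD per allele) and
# beta_out/se_out (log-odds per allele).  All estimators return a causal
# log-odds ratio per exposure SD with its exponentiated counterpart (OR per
# SD).  Inverse-variance weights throughout are the first-order weights
# w_j = beta_exp_j^2 / se_out_j^2, i.e. 1 / Var(Wald ratio) ignoring
# exposure-side noise.

new_mr_estimate <- function(method, n_snps, beta, se, crit = qnorm(0.975),
                            pval = NULL, aux = list()) {
  se <- as.numeric(se)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  if (is.null(pval)) pval <- ztest_p(beta / se)
  out <- list(method = method, n_snps = as.integer(n_snps),
              beta = as.numeric(beta), se = se,
              ci_low = ci_low, ci_high = ci_high, pval = as.numeric(pval),
              or_sd = exp(beta), or_lo = exp(ci_low), or_hi = exp(ci_high),
              aux = aux)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  log-OR per SD: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR per SD: %.3f (95%% CI %.3f-%.3f)\n", x$or_sd, x$or_lo, x$or_hi))
  if (length(x$aux)) {
    flat <- x$aux[vapply(x$aux, function(v) is.numeric(v) && length(v) == 1,
                         logical(1))]
    if (length(flat))
      cat("  aux:", paste(names(flat), signif(unlist(flat), 4), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or_sd = x$or_sd, or_lo = x$or_lo, or_hi = x$or_hi,
             stringsAsFactors = FALSE)
}

check_insts <- function(insts, min_n, what) {
  stopifnot(is.data.frame(insts),
            all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(insts)))
  if (nrow(insts) < min_n)
    stop_input(what, " requires at least ", min_n, " instruments (got ",
               nrow(insts), ")")
  invisible(insts)
}

ivw_weights <- function(insts) insts$beta_exp^2 / insts$se_out^2
ratio_estimates <- function(insts) insts$beta_out / insts$beta_exp

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order delta-method standard error
#' `se_out / |beta_exp|` (the TwoSampleMR default, which ignores exposure-side
#' noise).  `second_order = TRUE` adds the exposure-uncertainty term.
#'
#' @param inst a single harmonised instrument (one-row data.frame or list).
#' @param second_order use the second-order delta SE.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  inst <- as.list(inst)
  if (inst$beta_exp == 0) stop_input("Wald ratio undefined: beta_exp = 0")
  beta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  if (second_order) {
    se <- sqrt(inst$se_out^2 / inst$beta_exp^2 +
                 inst$beta_out^2 * inst$se_exp^2 / inst$beta_exp^4)
  }
  new_mr_estimate("wald", 1L, beta, se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios with weights `beta_exp^2 / se_out^2`.  The
#' point estimate is identical between modes; `"fe"` (fixed effects, one
#' shared causal effect) uses `se = 1/sqrt(sum(w))`, while `"re"`
#' (multiplicative random effects, each SNP identifying its own effect that
#' averages to the causal one under balanced pleiotropy) inflates that SE by
#' `max(1, sqrt(Q / (L - 1)))` where Q is Cochran's statistic.
#'
#' @param insts harmonised instrument data.frame (>= 1 row; a single
#'   instrument delegates to [wald_ratio()]).
#' @param mode `"re"` or `"fe"`.
#' @return an `mr_estimate` with `aux$Q`, `aux$inflation`.
#' @export
mr_ivw <- function(insts, mode = c("re", "fe")) {
  mode <- match.arg(mode)
  check_insts(insts, 1L, "IVW")
  if (nrow(insts) == 1L) return(wald_ratio(insts[1, ]))
  L <- nrow(insts)
  w <- ivw_weights(insts)
  theta <- ratio_estimates(insts)
  beta <- sum(w * theta) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  Q <- sum(w * (theta - beta)^2)
  inflation <- max(1, sqrt(Q / (L - 1)))
  se <- if (mode == "re") se_fe * inflation else se_fe
  new_mr_estimate(paste0("ivw_", mode), L, beta, se,
                  aux = list(Q = Q, df = L - 1L, inflation = inflation,
                             se_fe = se_fe))
}

#' Primary-method rule by instrument count
#'
#' One SNP: Wald ratio.  Two to nine SNPs: fixed-effects IVW.  Ten or more:
#' multiplicative random-effects IVW.
#'
#' @param n_snps number of harmonised instruments.
#' @return `"wald"`, `"ivw_fe"` or `"ivw_re"`.
#' @export
select_primary_method <- function(n_snps) {
  stopifnot(n_snps >= 1)
  if (n_snps == 1) "wald" else if (n_snps < 10) "ivw_fe" else "ivw_re"
}

# weighted least squares of y on X with weights w; returns coefficients,
# their unit-scale SEs and the weighted RSS
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- unname(drop(V %*% (XtW %*% y)))
  resid <- y - drop(X %*% coefs)
  list(coef = coefs, cov_unit = V, rss_w = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept
#' (weights `1/se_out^2`), after orienting every pair so the exposure beta is
#' non-negative.  The slope estimates the causal effect under InSIDE; a
#' non-zero intercept indicates directional pleiotropy.  Standard errors use
#' multiplicative overdispersion `max(1, sqrt(Q' / (L - 2)))` and inference
#' uses the t distribution with L - 2 degrees of freedom.
#'
#' @param insts harmonised instrument data.frame (>= 3 rows).
#' @return an `mr_estimate` with `aux` fields `intercept`, `intercept_se`,
#'   `intercept_pval`, `q_rucker` (the weighted residual sum of squares).
#' @export
mr_egger <- function(insts) {
  check_insts(insts, 3L, "MR-Egger")
  L <- nrow(insts)
  s <- ifelse(insts$beta_exp < 0, -1, 1)
  bx <- insts$beta_exp * s
  by <- insts$beta_out * s
  w <- 1 / insts$se_out^2
  fit <- wls_fit(cbind(1, bx), by, w)
  dispersion <- max(1, sqrt(fit$rss_w / (L - 2)))
  ses <- sqrt(diag(fit$cov_unit)) * dispersion
  crit <- qt(0.975, df = L - 2)
  slope <- fit$coef[2]; slope_se <- ses[2]
  intercept <- fit$coef[1]; intercept_se <- ses[1]
  new_mr_estimate(
    "egger", L, slope, slope_se, crit = crit,
    pval = pmax(2 * pt(-abs(slope / slope_se), df = L - 2), 1e-300),
    aux = list(intercept = intercept, intercept_se = intercept_se,
               intercept_pval = pmax(2 * pt(-abs(intercept / intercept_se),
                                            df = L - 2), 1e-300),
               q_rucker = fit$rss_w, df_rucker = L - 2L,
               dispersion = dispersion))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]; wj <- w[ord] / sum(w)
  s <- cumsum(wj) - 0.5 * wj
  if (s[1] >= 0.5) return(th[1])
  below <- max(which(s < 0.5))
  if (below == length(th)) return(th[length(th)])
  th[below] + (th[below + 1] - th[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

boot_resample <- function(insts, n_boot, seed, statistic) {
  L <- nrow(insts)
  with_seed(seed, {
    bx <- matrix(rnorm(n_boot * L, mean = rep(insts$beta_exp, each = n_boot),
                       sd = rep(insts$se_exp, each = n_boot)), nrow = n_boot)
    by <- matrix(rnorm(n_boot * L, mean = rep(insts$beta_out, each = n_boot),
                       sd = rep(insts$se_out, each = n_boot)), nrow = n_boot)
    vapply(seq_len(n_boot), function(b) statistic(bx[b, ], by[b, ]), numeric(1))
  })
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP Wald ratios and interpolates the inverse-variance
#' weighted cumulative distribution at 50%; consistent when instruments
#' carrying at least half the weight are valid.  The standard error comes
#' from a parametric bootstrap (exposure and outcome betas resampled from
#' normals at their reported SEs).
#'
#' @param insts harmonised instrument data.frame (>= 3 rows).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required for reproducibility).
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000, seed) {
  check_insts(insts, 3L, "weighted median")
  if (missing(seed)) stop_input("weighted median requires an explicit bootstrap seed")
  beta <- weighted_median_point(ratio_estimates(insts), ivw_weights(insts))
  boots <- boot_resample(insts, n_boot, seed, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / insts$se_out^2)
  })
  new_mr_estimate("wme", nrow(insts), beta, sd(boots),
                  aux = list(n_boot = n_boot))
}

# Hartwig modified-Silverman bandwidth over the ratio estimates
mode_bandwidth <- function(theta, phi) {
  s <- 0.9 * min(sd(theta), mad(theta)) / length(theta)^(1 / 5)
  max(1e-8, phi * s)
}

mode_point <- function(theta, w, phi, n_grid = 1024L, refine = TRUE) {
  if (max(theta) - min(theta) < 1e-12) return(theta[1])
  h <- mode_bandwidth(theta, phi)
  wn <- w / sum(w)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens_grid <- colSums(wn * dnorm(outer(theta, grid, "-"), sd = h))
  i <- which.max(dens_grid)
  if (!refine) return(grid[i])
  dens <- function(x) sum(wn * dnorm(x, mean = theta, sd = h))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
}

#' Weighted mode-based causal estimate
#'
#' The mode of a Gaussian-kernel-smoothed, inverse-variance-weighted density
#' over the per-SNP Wald ratios; consistent when the largest group of
#' instruments sharing one ratio value is valid (ZEMPA).  Bandwidth is
#' `phi` times the modified Silverman scale `0.9 min(sd, mad) L^{-1/5}`.
#' SE from the same parametric bootstrap as [mr_weighted_median()].
#'
#' @param insts harmonised instrument data.frame (>= 3 rows).
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(insts, phi = 1, n_boot = 1000, seed) {
  check_insts(insts, 3L, "weighted mode")
  if (missing(seed)) stop_input("weighted mode requires an explicit bootstrap seed")
  beta <- mode_point(ratio_estimates(insts), ivw_weights(insts), phi)
  boots <- mode_boot(insts, phi, n_boot, seed)
  new_mr_estimate("wmbe", nrow(insts), beta, sd(boots),
                  aux = list(phi = phi, n_boot = n_boot))
}

# parametric-bootstrap replicates of the weighted mode, vectorised across
# replicates: one B x G density evaluation per instrument
mode_boot <- function(insts, phi, n_boot, seed, n_grid = 128L) {
  L <- nrow(insts)
  with_seed(seed, {
    bx <- matrix(rnorm(n_boot * L, mean = rep(insts$beta_exp, each = n_boot),
                       sd = rep(insts$se_exp, each = n_boot)), nrow = n_boot)
    by <- matrix(rnorm(n_boot * L, mean = rep(insts$beta_out, each = n_boot),
                       sd = rep(insts$se_out, each = n_boot)), nrow = n_boot)
    th <- by / bx
    w <- sweep(bx^2, 2, insts$se_out^2, "/")
    wn <- w / rowSums(w)
    ctr <- th - rowMeans(th)
    sds <- sqrt(rowSums(ctr^2) / (L - 1))
    mads <- apply(th, 1, mad)
    h <- pmax(1e-8, phi * 0.9 * pmin(sds, mads) / L^(1 / 5))
    lo <- apply(th, 1, min) - 3 * h
    step <- (apply(th, 1, max) + 3 * h - lo) / (n_grid - 1)
    grid <- lo + outer(step, 0:(n_grid - 1))
    dens <- matrix(0, n_boot, n_grid)
    for (l in seq_len(L))
      dens <- dens + wn[, l] * dnorm((grid - th[, l]) / h) / h
    grid[cbind(seq_len(n_boot), max.col(dens, ties.method = "first"))]
  })
}

raps_score <- function(theta, insts, tau2) {
  v <- insts$se_out^2 + theta^2 * insts$se_exp^2 + tau2
  sum((insts$beta_out - theta * insts$beta_exp) * insts$beta_exp / v)
}

raps_solve_theta <- function(insts, tau2, lower = -10, upper = 10) {
  grid <- seq(lower, upper, length.out = 401)
  sc <- vapply(grid, raps_score, numeric(1), insts = insts, tau2 = tau2)
  sign_change <- which(sc[-length(sc)] * sc[-1] <= 0)
  if (!length(sign_change))
    stop_input("MR-RAPS: no sign change of the profile score in [",
               lower, ", ", upper, "]")
  i <- sign_change[1]
  uniroot(raps_score, c(grid[i], grid[i + 1]), insts = insts, tau2 = tau2,
          tol = 1e-12)$root
}

#' Robust adjusted profile score (RAPS) causal estimate
#'
#' Solves the profile-score equation
#' `sum_j (beta_out_j - theta beta_exp_j) beta_exp_j /
#'   (se_out_j^2 + theta^2 se_exp_j^2 + tau^2) = 0`
#' with squared-error loss, accounting for uncertainty in the exposure
#' betas.  With `overdispersion = TRUE`, `tau^2` is solved jointly so the
#' standardized residuals have unit dispersion (floored at zero).  The SE is
#' the inverse square root of the observed information of the profile
#' log-likelihood at the root.
#'
#' @param insts harmonised instrument data.frame (>= 3 rows).
#' @param overdispersion estimate a systematic-pleiotropy variance `tau^2`.
#' @return an `mr_estimate` with `aux$tau2`.
#' @export
mr_raps <- function(insts, overdispersion = FALSE) {
  check_insts(insts, 3L, "MR-RAPS")
  L <- nrow(insts)
  tau2 <- 0
  theta <- raps_solve_theta(insts, tau2)
  if (overdispersion) {
    for (iter in 1:100) {
      resid2 <- (insts$beta_out - theta * insts$beta_exp)^2
      v0 <- insts$se_out^2 + theta^2 * insts$se_exp^2
      g <- function(t2) sum(resid2 / (v0 + t2)) - (L - 1)
      tau2_new <- if (g(0) <= 0) 0 else
        uniroot(g, c(0, max(resid2) + max(v0)), tol = 1e-12)$root
      theta_new <- raps_solve_theta(insts, tau2_new)
      converged <- abs(theta_new - theta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      theta <- theta_new; tau2 <- tau2_new
      if (converged) break
    }
  }
  # observed information of the profile log-likelihood (tau2 held fixed)
  prof_ll <- function(th) {
    v <- insts$se_out^2 + th^2 * insts$se_exp^2 + tau2
    -0.5 * sum((insts$beta_out - th * insts$beta_exp)^2 / v + log(v))
  }
  h <- 1e-4 * max(1, abs(theta))
  info <- -(prof_ll(theta + h) - 2 * prof_ll(theta) + prof_ll(theta - h)) / h^2
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  new_mr_estimate("raps", L, theta, se,
                  aux = list(tau2 = tau2, overdispersion = overdispersion))
}

#' Re-derive the odds-ratio scale fields of an estimate
#'
#' @param est an `mr_estimate`.
#' @return the estimate with `or_sd`, `or_lo`, `or_hi` recomputed as
#'   `exp(beta)`, `exp(ci_low)`, `exp(ci_high)`.
#' @export
to_or_scale <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  est$or_sd <- exp(est$beta)
  est$or_lo <- exp(est$ci_low)
  est$or_hi <- exp(est$ci_high)
  est
}

#' All applicable causal estimates for one instrument set
#'
#' Runs the primary method dictated by [select_primary_method()] together
#' with every sensitivity estimator whose instrument-count requirement is
#' met (MR-Egger, weighted median, weighted mode, RAPS need >= 3 SNPs), plus
#' both IVW modes when L >= 2.
#'
#' @param insts harmonised instrument data.frame.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param seed integer seed; median and mode bootstraps use derived streams.
#' @param phi weighted-mode bandwidth multiplier.
#' @return named list of `mr_estimate` objects (`primary` plus per-method
#'   entries).
#' @export
mr_all_estimates <- function(insts, n_boot = 1000, seed, phi = 1) {
  L <- nrow(insts)
  out <- list()
  if (L >= 2) {
    out$ivw_fe <- mr_ivw(insts, "fe")
    out$ivw_re <- mr_ivw(insts, "re")
  }
  if (L >= 3) {
    out$egger <- mr_egger(insts)
    out$wme <- mr_weighted_median(insts, n_boot = n_boot,
                                  seed = derive_seed(seed, 1))
    out$wmbe <- mr_weighted_mode(insts, phi = phi, n_boot = n_boot,
                                 seed = derive_seed(seed, 2))
    out$raps <- mr_raps(insts)
  }
  if (L == 1) out$wald <- wald_ratio(insts[1, ])
  primary_method <- select_primary_method(L)
  out$primary <- switch(primary_method,
                        wald = out$wald, ivw_fe = out$ivw_fe,
                        ivw_re = out$ivw_re)
  out
}
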