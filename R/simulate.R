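# Synthetic GWAS summary statistics with known ground truth.
#
# The generator emulates the two-sample MR structural model: true SNP
# effects gamma_j on a standardized continuous exposure, a causal log-OR
# theta per exposure SD on a case-control outcome, and a direct
# (pleiotropic) path alpha_j on the outcome scale.  Effect alleles are coded
# as the exposure-increasing alleles (the convention for curated
# instruments), so gamma_j >= 0 and "directional" pleiotropy has a
# well-defined direction.  Reported per-SNP effects are the true effects
# plus sampling noise at GWAS-realistic standard errors: for a standardized
# trait se = 1/sqrt(2 f (1-f) n), and for a case-control log-OR the
# effective sample size n_eff = n_case n_control / (n_case + n_control)
# takes the place of n.  Simulated SNPs are mutually unlinked (instruments
# are post-pruning by construction).

.sim_allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "T", "G"),
                            ncol = 2, byrow = TRUE)

#' Build a simulation configuration
#'
#' Defaults describe a typical curated-instrument scenario for a glioma-scale
#' case-control outcome: 27 independent instrument SNPs per trait, exposure
#' GWAS of 50,000, outcome GWAS of 12,488 cases and 18,169 controls, and SNP
#' effect scale `gamma_sd = 0.047`, which puts the expected trait-level PVE
#' near 2% (the typical strength of a curated continuous-trait instrument
#' panel).  No causal effect and no pleiotropy unless requested.
#'
#' @param L SNPs per trait.
#' @param theta true causal log-OR per exposure SD.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the direct SNP-outcome
#'   effects, defined relative to the exposure-increasing allele
#'   (directional pleiotropy has non-zero mean; balanced pleiotropy has mean
#'   zero and positive SD).
#' @param gamma_sd scale of the true SNP-exposure effects: effects are
#'   half-normal, `|N(0, gamma_sd^2)|`, in trait-SD per
#'   exposure-increasing allele.
#' @param n_exp exposure GWAS sample size.
#' @param n_case,n_control outcome GWAS counts.
#' @param eaf_range range of simulated effect-allele frequencies.
#' @param inside_violation correlation between pleiotropic effects and
#'   SNP-exposure effect sizes (0 preserves the InSIDE assumption).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(L = 27, theta = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0, gamma_sd = 0.047, n_exp = 50000,
                       n_case = 12488, n_control = 18169,
                       eaf_range = c(0.05, 0.95), inside_violation = 0,
                       seed = 1L) {
  stopifnot(L >= 1, pleiotropy_sd >= 0, gamma_sd >= 0,
            abs(inside_violation) <= 1,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2])
  structure(list(L = as.integer(L), theta = theta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd, gamma_sd = gamma_sd,
                 n_exp = n_exp, n_case = n_case, n_control = n_control,
                 eaf_range = eaf_range, inside_violation = inside_violation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

assoc_frame <- function(rsid, chrom, pos, pair, f, beta, se, n,
                        n_case = NA_real_, n_control = NA_real_, scale) {
  df <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                   ea = pair[, 1], oa = pair[, 2], eaf = f,
                   beta = beta, se = se, pval = ztest_p(beta / se),
                   n = n, n_case = n_case, n_control = n_control,
                   stringsAsFactors = FALSE)
  attr(df, "effect_scale") <- scale
  df
}

#' Simulate one trait's exposure/outcome summary statistics
#'
#' Draws allele frequencies uniformly on `eaf_range`, true exposure effects
#' `gamma_j = |N(0, gamma_sd^2)|` (effect alleles are exposure-increasing),
#' pleiotropic effects `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` with
#' correlation `inside_violation` to the (standardized) exposure effect
#' sizes, and reported betas `beta_exp_j ~ N(gamma_j, se_exp_j^2)`,
#' `beta_out_j ~ N(theta gamma_j + alpha_j, se_out_j^2)`, with p-values from
#' the corresponding z statistics.  Identical `(config, seed)` give
#' identical output.
#'
#' With `strata`, one outcome table is generated per stratum (e.g. glioma
#' subtypes scored against the same exposure), sharing the trait's true
#' effects but with independent outcome sampling noise at each stratum's
#' case-control precision.
#'
#' @param config a [sim_config()].
#' @param strata optional named list of `list(n_case =, n_control =)` pairs;
#'   when supplied the result carries `outcomes` (a named list) instead of a
#'   single `outcome`.
#' @return list with `exposure`, `outcome` (or `outcomes`) — canonical
#'   association data.frames that pass [read_summary_stats()] validation
#'   unchanged — and `truth` (list with `theta`, per-SNP `gamma`, `alpha`,
#'   and `valid` flags marking SNPs with no direct outcome path).
#' @export
simulate_trait <- function(config, strata = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$L
    f <- runif(L, config$eaf_range[1], config$eaf_range[2])
    gamma <- abs(rnorm(L, 0, config$gamma_sd))
    z_ind <- rnorm(L)
    rho <- config$inside_violation
    # standardize the half-normal effect sizes for the pleiotropy coupling
    hn_mean <- config$gamma_sd * sqrt(2 / pi)
    hn_sd <- config$gamma_sd * sqrt(1 - 2 / pi)
    z_g <- if (hn_sd > 0) (gamma - hn_mean) / hn_sd else rnorm(L)
    alpha <- config$pleiotropy_mean +
      config$pleiotropy_sd * (rho * z_g + sqrt(1 - rho^2) * z_ind)

    se_exp <- 1 / sqrt(2 * f * (1 - f) * config$n_exp)
    beta_exp <- rnorm(L, gamma, se_exp)

    pair <- .sim_allele_pairs[(seq_len(L) - 1L) %% nrow(.sim_allele_pairs) + 1L, ,
                              drop = FALSE]
    rsid <- sprintf("rs%07d", seq_len(L))
    chrom <- as.character((seq_len(L) - 1L) %% 22 + 1L)
    pos <- seq_len(L) * 1e5
    exposure <- assoc_frame(rsid, chrom, pos, pair, f, beta_exp, se_exp,
                            n = config$n_exp, scale = "sd")

    if (is.null(strata)) {
      strata <- list(outcome = list(n_case = config$n_case,
                                    n_control = config$n_control))
      single <- TRUE
    } else single <- FALSE
    outcomes <- lapply(strata, function(s) {
      n_eff <- s$n_case * s$n_control / (s$n_case + s$n_control)
      se_out <- 1 / sqrt(2 * f * (1 - f) * n_eff)
      beta_out <- rnorm(L, config$theta * gamma + alpha, se_out)
      assoc_frame(rsid, chrom, pos, pair, f, beta_out, se_out,
                  n = s$n_case + s$n_control, n_case = s$n_case,
                  n_control = s$n_control, scale = "log_or")
    })

    res <- list(exposure = exposure,
                truth = list(theta = config$theta, gamma = gamma,
                             alpha = alpha, valid = alpha == 0))
    if (single) res$outcome <- outcomes[[1]] else res$outcomes <- outcomes
    res
  })
}

relabel_rsids <- function(df, trait_index) {
  df$rsid <- sprintf("rs%03d%05d", trait_index, seq_len(nrow(df)))
  df
}

#' Simulate a phenome-wide exposure panel
#'
#' Generates `n_traits` traits from a template configuration:
#' `round(n_traits * frac_null)` traits get a zero causal effect and the
#' remainder draw theta from `causal_theta_dist`.  Each trait's seed is
#' derived deterministically from the master seed, so panels are
#' reproducible and any trait can be regenerated in isolation.  Trait rsids
#' are made panel-unique, and the per-stratum outcome tables of all traits
#' are concatenated into scan-ready outcome files.
#'
#' @param n_traits number of traits.
#' @param frac_null fraction of null traits in [0, 1].
#' @param causal_theta_dist function of `n` returning `n` causal effects for
#'   non-null traits (default `rnorm(n, 0, 0.2)`).
#' @param template a [sim_config()] used for every per-trait setting other
#'   than `theta` and `seed`.
#' @param seed master seed.
#' @param strata named list of `list(n_case =, n_control =)` outcome strata;
#'   defaults to a single `all` stratum at the template's counts.
#' @return list with `traits` (named list of [simulate_trait()] outputs),
#'   `exposures` (named list of exposure tables, ready for [run_phewas()]),
#'   `outcomes` (one concatenated table per stratum) and `truth`
#'   (data.frame: `trait_id`, `theta`, `null`, `seed`).
#' @export
simulate_phewas <- function(n_traits, frac_null = 1,
                            causal_theta_dist = function(n) rnorm(n, 0, 0.2),
                            template = sim_config(), seed = 1L,
                            strata = NULL) {
  stopifnot(n_traits >= 1, frac_null >= 0, frac_null <= 1)
  if (is.null(strata))
    strata <- list(all = list(n_case = template$n_case,
                              n_control = template$n_control))
  n_null <- round(n_traits * frac_null)
  thetas <- numeric(n_traits)
  if (n_traits > n_null) {
    thetas[(n_null + 1):n_traits] <-
      with_seed(derive_seed(seed, 0), causal_theta_dist(n_traits - n_null))
  }
  ids <- sprintf("trait%03d", seq_len(n_traits))
  seeds <- vapply(seq_len(n_traits), function(i) derive_seed(seed, i),
                  integer(1))
  traits <- lapply(seq_len(n_traits), function(i) {
    cfg <- template
    cfg$theta <- thetas[i]
    cfg$seed <- seeds[i]
    tr <- simulate_trait(cfg, strata = strata)
    tr$exposure <- relabel_rsids(tr$exposure, i)
    tr$outcomes <- lapply(tr$outcomes, relabel_rsids, trait_index = i)
    tr
  })
  names(traits) <- ids
  outcomes <- lapply(names(strata), function(s) {
    out <- do.call(rbind, lapply(traits, function(tr) tr$outcomes[[s]]))
    rownames(out) <- NULL
    attr(out, "effect_scale") <- "log_or"
    out
  })
  names(outcomes) <- names(strata)
  list(traits = traits,
       exposures = setNames(lapply(traits, `[[`, "exposure"), ids),
       outcomes = outcomes,
       truth = data.frame(trait_id = ids, theta = thetas,
                          null = thetas == 0, seed = seeds,
                          stringsAsFactors = FALSE))
}

#' Estimator recovery summary against simulation ground truth
#'
#' @param estimates data.frame with `trait_id`, `method`, `beta`, `ci_low`,
#'   `ci_high`, `pval` (e.g. built from [run_phewas()] output or per-trait
#'   estimates).
#' @param truth truth data.frame from [simulate_phewas()] (`trait_id`,
#'   `theta`).
#' @param alpha test level for empirical size/power (default 0.05).
#' @return data.frame with one row per method: `bias` (mean theta-hat minus
#'   theta), `rmse`, `coverage` (fraction of 95% CIs containing theta),
#'   `size` (fraction p < alpha among null traits, `NA` if none) and
#'   `power` (same among non-null traits).
#' @export
recovery_report <- function(estimates, truth, alpha = 0.05) {
  missing_keys <- setdiff(estimates$trait_id, truth$trait_id)
  if (length(missing_keys))
    stop_input("estimates contain trait_id(s) absent from truth: ",
               paste(utils::head(missing_keys, 5), collapse = ", "))
  merged <- merge(estimates, truth[, c("trait_id", "theta")], by = "trait_id")
  by_method <- split(merged, merged$method)
  rows <- lapply(names(by_method), function(m) {
    d <- by_method[[m]]
    err <- d$beta - d$theta
    is_null <- d$theta == 0
    data.frame(method = m, n = nrow(d), bias = mean(err),
               rmse = sqrt(mean(err^2)),
               coverage = mean(d$ci_low <= d$theta & d$theta <= d$ci_high),
               size = if (any(is_null)) mean(d$pval[is_null] < alpha) else NA_real_,
               power = if (any(!is_null)) mean(d$pval[!is_null] < alpha) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
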