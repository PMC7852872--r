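# Phenome-wide orchestration: scan many exposures against one or more
# case-control outcome strata, classify associations under Bonferroni and
# suggestive thresholds, and attach a-priori power.

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Classify association p-values
#'
#' `p < sig_thresh` is `"significant"`, `sig_thresh <= p < sugg_thresh` is
#' `"suggestive"`, anything else (including `p = sugg_thresh` exactly) is
#' `"null"`.  All inequalities are strict.
#'
#' @param pval p-value(s).
#' @param sig_thresh significance threshold (e.g. the Bonferroni-corrected
#'   one).
#' @param sugg_thresh suggestive threshold (default 0.05).
#' @return character vector of classifications.
#' @export
classify_association <- function(pval, sig_thresh, sugg_thresh = 0.05) {
  stopifnot(sig_thresh < sugg_thresh)
  ifelse(pval < sig_thresh, "significant",
         ifelse(pval < sugg_thresh, "suggestive", "null"))
}

#' A-priori power for MR with a binary outcome
#'
#' Asymptotic two-sided power of the IVW test of no causal effect against an
#' alternative odds ratio per exposure SD, in the mRnd style: with
#' `N = n_case + n_control`, case fraction `K = n_case/N` and non-centrality
#' `nu = N * pve * K * (1 - K) * log(or_alt)^2`, the power is
#' `pnorm(sqrt(nu) - z) + pnorm(-sqrt(nu) - z)` with `z = qnorm(1 - alpha/2)`.
#' At `or_alt = 1` this reduces exactly to the test size `alpha`.
#'
#' @param n_case,n_control outcome GWAS counts.
#' @param pve proportion of exposure variance explained by the instruments.
#' @param or_alt alternative odds ratio per exposure SD (default 1.5).
#' @param alpha significance level (default 0.05).
#' @return power in [0, 1]; vectorised over its arguments.
#' @export
power_binary <- function(n_case, n_control, pve, or_alt = 1.5, alpha = 0.05) {
  stopifnot(all(n_case > 0), all(n_control > 0), all(pve >= 0), all(pve <= 1),
            all(or_alt > 0), all(alpha > 0), all(alpha < 1))
  N <- n_case + n_control
  K <- n_case / N
  nu <- N * pve * K * (1 - K) * log(or_alt)^2
  z <- qnorm(1 - alpha / 2)
  pnorm(sqrt(nu) - z) + pnorm(-sqrt(nu) - z)
}

#' Build a scan configuration
#'
#' Collects the thresholds, seeds and analysis settings for [run_phewas()].
#' Defaults follow standard curated-instrument MR practice: genome-wide
#' significance 5e-8, MAF > 0.01, LD pruning at r^2 >= 0.01, trait gates
#' PVE > 0.1% and F > 10, the 10-SNP fixed/random-effects rule, a
#' family-wise alpha of 0.05 Bonferroni-corrected over the number of traits
#' scanned, and 1000 bootstrap replicates for the median/mode SEs.
#'
#' @param seed master seed for all scan randomness (bootstraps).
#' @param p_thresh,maf_min,r2_thresh,pve_min,f_min instrument QC settings;
#'   set a filter to `NULL` to skip it.
#' @param alpha family-wise error rate.
#' @param sugg_thresh suggestive threshold.
#' @param n_boot bootstrap replicates.
#' @param phi weighted-mode bandwidth multiplier.
#' @param or_power alternative odds ratio used for the per-trait power column.
#' @param palindrome_policy,eaf_tol harmonisation settings
#'   (see [harmonise_pair()]).
#' @param exclude_snps named-exclusion SNPs for forest tables (character).
#' @return a list of class `phewas_config`.
#' @export
phewas_config <- function(seed, p_thresh = 5e-8, maf_min = 0.01,
                          r2_thresh = 0.01, pve_min = 0.001, f_min = 10,
                          alpha = 0.05, sugg_thresh = 0.05, n_boot = 1000,
                          phi = 1, or_power = 1.5,
                          palindrome_policy = "drop", eaf_tol = 0.08,
                          exclude_snps = character(0)) {
  if (missing(seed)) stop_input("phewas_config requires an explicit seed")
  structure(list(seed = as.integer(seed), p_thresh = p_thresh,
                 maf_min = maf_min, r2_thresh = r2_thresh, pve_min = pve_min,
                 f_min = f_min, alpha = alpha, sugg_thresh = sugg_thresh,
                 n_boot = n_boot, phi = phi, or_power = or_power,
                 palindrome_policy = palindrome_policy, eaf_tol = eaf_tol,
                 exclude_snps = exclude_snps),
            class = "phewas_config")
}

#' Read a scan configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [phewas_config()].
#' @return a `phewas_config`.
#' @export
read_phewas_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(phewas_config, vals)
}

est_cols <- function(est, prefix) {
  if (is.null(est)) {
    cols <- c("beta", "se", "ci_low", "ci_high", "pval", "or_sd", "or_lo", "or_hi")
    out <- as.data.frame(as.list(setNames(rep(NA_real_, length(cols)), cols)))
  } else {
    out <- as.data.frame(est)[, c("beta", "se", "ci_low", "ci_high", "pval",
                                  "or_sd", "or_lo", "or_hi")]
  }
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Run a phenome-wide MR scan
#'
#' For every trait x outcome pair: harmonise, apply the instrument QC gates,
#' fit the primary estimator dictated by the 10-SNP rule plus all applicable
#' sensitivity estimators, compute heterogeneity and the Egger intercept,
#' classify the primary p-value against the Bonferroni and suggestive
#' thresholds, and attach a-priori power to detect `or_power`.  Traits
#' failing the QC gates are emitted with `included = FALSE` and no
#' estimates; per-trait estimator failures are logged and skipped, never
#' aborting the scan.  Output is deterministic given `config$seed`.
#'
#' @param exposures named list of exposure association data.frames (or a
#'   directory of canonical TSV files, one per trait).
#' @param outcomes named list of outcome association data.frames (or
#'   canonical TSV file paths); names label the outcome strata.
#' @param config a [phewas_config()].
#' @param ld optional pairwise LD table shared across traits.
#' @param exposure_n optional named numeric vector of exposure GWAS sizes
#'   (defaults to each file's `n` column).
#' @return data.frame with one row per trait x outcome, carrying QC
#'   (`included`, `n_snps`, `pve`, `f_stat`), the primary estimate
#'   (`method`, `beta`, ..., `or_hi`), sensitivity estimates
#'   (`wme_*`, `wmbe_*`, `raps_*`, `egger_*` including the intercept test),
#'   heterogeneity (`Q`, `i2`, `p_het`, `q_rucker`, `p_rucker`),
#'   `classification`, `consistent` and `power`.  The Bonferroni threshold
#'   used is attached as attribute `sig_thresh`.
#' @export
run_phewas <- function(exposures, outcomes, config, ld = NULL,
                       exposure_n = NULL) {
  stopifnot(inherits(config, "phewas_config"))
  if (is.character(exposures) && length(exposures) == 1 && dir.exists(exposures)) {
    paths <- list.files(exposures, pattern = "\\.tsv$", full.names = TRUE)
    exposures <- setNames(lapply(paths, read_summary_stats),
                          sub("\\.tsv$", "", basename(paths)))
  }
  outcomes <- lapply(outcomes, function(o) {
    if (is.character(o)) read_summary_stats(o, effect_scale = "log_or") else o
  })
  if (is.null(names(exposures)) || is.null(names(outcomes)))
    stop_input("exposures and outcomes must be named")
  traits <- names(exposures)
  m <- length(traits)
  sig_thresh <- bonferroni_threshold(config$alpha, m)

  rows <- list()
  for (ti in seq_along(traits)) {
    trait <- traits[ti]
    exp_raw <- exposures[[trait]]
    n_exp <- if (!is.null(exposure_n) && trait %in% names(exposure_n))
      exposure_n[[trait]] else NULL
    qc <- tryCatch(
      instrument_qc(exp_raw, ld = ld, p_thresh = config$p_thresh,
                    maf_min = config$maf_min, r2_thresh = config$r2_thresh,
                    pve_min = config$pve_min, f_min = config$f_min, n = n_exp),
      error = function(e) NULL)
    for (oi in seq_along(outcomes)) {
      outcome <- names(outcomes)[oi]
      base <- data.frame(trait_id = trait, outcome = outcome,
                         stringsAsFactors = FALSE)
      empty_row <- function(qc_report) {
        cbind(base,
              data.frame(included = FALSE,
                         n_snps = if (is.null(qc_report)) 0L else qc_report$n_after_ld,
                         pve = if (is.null(qc_report)) NA_real_ else qc_report$pve,
                         f_stat = if (is.null(qc_report)) NA_real_ else qc_report$f_stat,
                         method = NA_character_, stringsAsFactors = FALSE),
              est_cols(NULL, "primary"), est_cols(NULL, "wme"),
              est_cols(NULL, "wmbe"), est_cols(NULL, "raps"),
              est_cols(NULL, "egger"),
              data.frame(egger_intercept = NA_real_,
                         egger_intercept_pval = NA_real_,
                         Q = NA_real_, i2 = NA_real_, p_het = NA_real_,
                         q_rucker = NA_real_, p_rucker = NA_real_,
                         classification = NA_character_, consistent = NA,
                         power = NA_real_, stringsAsFactors = FALSE))
      }
      if (is.null(qc) || !qc$report$included || qc$report$n_after_ld < 1) {
        rows[[length(rows) + 1L]] <- empty_row(if (is.null(qc)) NULL else qc$report)
        next
      }
      row <- tryCatch({
        built <- build_instrument_set(qc$assocs, outcomes[[oi]],
                                      palindrome_policy = config$palindrome_policy,
                                      eaf_tol = config$eaf_tol)
        insts <- built$instruments
        if (nrow(insts) < 1) return_row <- empty_row(qc$report) else {
          seed_to <- derive_seed(config$seed, ti * 1000L + oi)
          ests <- mr_all_estimates(insts, n_boot = config$n_boot,
                                   seed = seed_to, phi = config$phi)
          het <- if (nrow(insts) >= 2) heterogeneity(insts) else NULL
          sens <- ests[intersect(c("wme", "wmbe", "raps"), names(ests))]
          nca <- (outcomes[[oi]]$n_case %||% NA_real_)[1]
          nco <- (outcomes[[oi]]$n_control %||% NA_real_)[1]
          pw <- if (!is.na(nca) && !is.na(nco))
            power_binary(nca, nco, qc$report$pve,
                         or_alt = config$or_power, alpha = config$alpha)
          else NA_real_
          return_row <- cbind(
            base,
            data.frame(included = TRUE, n_snps = nrow(insts),
                       pve = qc$report$pve, f_stat = qc$report$f_stat,
                       method = ests$primary$method, stringsAsFactors = FALSE),
            est_cols(ests$primary, "primary"),
            est_cols(ests$wme, "wme"), est_cols(ests$wmbe, "wmbe"),
            est_cols(ests$raps, "raps"), est_cols(ests$egger, "egger"),
            data.frame(
              egger_intercept = ests$egger$aux$intercept %||% NA_real_,
              egger_intercept_pval = ests$egger$aux$intercept_pval %||% NA_real_,
              Q = het$Q %||% NA_real_, i2 = het$i2 %||% NA_real_,
              p_het = het$p_het %||% NA_real_,
              q_rucker = het$q_rucker %||% NA_real_,
              p_rucker = het$p_rucker %||% NA_real_,
              classification = classify_association(ests$primary$pval,
                                                    sig_thresh,
                                                    config$sugg_thresh),
              consistent = if (length(sens) == 3)
                consistency_check(ests$primary, sens) else NA,
              power = pw, stringsAsFactors = FALSE))
        }
        return_row
      }, error = function(e) {
        message("trait ", trait, " x ", outcome, " skipped: ",
                conditionMessage(e))
        empty_row(qc$report)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sig_thresh") <- sig_thresh
  attr(out, "sugg_thresh") <- config$sugg_thresh
  out
}

#' Volcano-plot-ready table
#'
#' @param records output of [run_phewas()].
#' @return data.frame with `trait_id`, `outcome`, `x` (log OR per SD),
#'   `y` (-log10 primary p) and `classification`, plus attributes
#'   `hline_sig`, `hline_sugg` (at -log10 of the thresholds) and `vline`
#'   (at +/- log 1.5).
#' @export
volcano_table <- function(records) {
  out <- data.frame(trait_id = records$trait_id, outcome = records$outcome,
                    x = log(records$primary_or_sd),
                    y = -log10(records$primary_pval),
                    classification = records$classification,
                    stringsAsFactors = FALSE)
  attr(out, "hline_sig") <- -log10(attr(records, "sig_thresh"))
  attr(out, "hline_sugg") <- -log10(attr(records, "sugg_thresh") %||% 0.05)
  attr(out, "vline") <- c(-log(1.5), log(1.5))
  out
}

#' Write a scan result table as TSV
#'
#' @param records data.frame (e.g. from [run_phewas()] or [volcano_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phewas_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
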