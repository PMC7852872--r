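# Heterogeneity statistics, pleiotropy assessment and instrument-sensitivity
# analyses for a harmonised instrument set.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_ref)^2` over the per-SNP Wald ratios with
#' the IVW weights, compared against chi-square with L - 1 degrees of
#' freedom; `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param insts harmonised instrument data.frame (>= 2 rows).
#' @param theta_ref reference causal estimate; defaults to the IVW point
#'   estimate (identical between FE and RE modes).
#' @return list with `Q`, `df`, `p_het`, `i2`.
#' @export
cochran_q <- function(insts, theta_ref = NULL) {
  check_insts(insts, 2L, "Cochran's Q")
  w <- ivw_weights(insts)
  theta <- ratio_estimates(insts)
  if (is.null(theta_ref)) theta_ref <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_ref)^2)
  df <- nrow(insts) - 1L
  list(Q = Q, df = df,
       p_het = max(pchisq(Q, df, lower.tail = FALSE), 1e-300),
       i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

#' Rucker's Q via the radial (Galbraith) Egger fit
#'
#' In radial coordinates (`y_j = theta_j sqrt(w_j)` on `x_j = sqrt(w_j)`),
#' Cochran's Q is the residual sum of squares of the through-origin fit and
#' Rucker's Q' is the residual sum of squares once an intercept (the radial
#' Egger pleiotropy term) is added, compared against chi-square with L - 2
#' degrees of freedom.  Q' <= Q always (nested models).
#'
#' @param insts harmonised instrument data.frame (>= 3 rows).
#' @return list with `q_rucker`, `df_rucker`, `p_rucker`.
#' @export
rucker_q <- function(insts) {
  check_insts(insts, 3L, "Rucker's Q")
  w <- ivw_weights(insts)
  x <- sqrt(w)
  y <- ratio_estimates(insts) * x
  fit <- wls_fit(cbind(1, x), y, rep(1, length(x)))
  df <- nrow(insts) - 2L
  list(q_rucker = fit$rss_w, df_rucker = df,
       p_rucker = max(pchisq(fit$rss_w, df, lower.tail = FALSE), 1e-300))
}

#' Full heterogeneity summary
#'
#' @param insts harmonised instrument data.frame (>= 2 rows).
#' @param theta_ref optional reference estimate for Cochran's Q.
#' @return list combining [cochran_q()] and, when L >= 3, [rucker_q()].
#' @export
heterogeneity <- function(insts, theta_ref = NULL) {
  out <- cochran_q(insts, theta_ref)
  if (nrow(insts) >= 3) out <- c(out, rucker_q(insts))
  out
}

# estimate on a reduced set with the method the count rule dictates
estimate_by_rule <- function(insts) {
  method <- select_primary_method(nrow(insts))
  switch(method,
         wald = wald_ratio(insts[1, ]),
         ivw_fe = mr_ivw(insts, "fe"),
         ivw_re = mr_ivw(insts, "re"))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the causal estimate L times, omitting each instrument in turn.
#' The model on each reduced set follows [select_primary_method()] applied
#' to the reduced count (so 10 remaining SNPs use random effects, fewer use
#' fixed effects, one uses the Wald ratio).
#'
#' @param insts harmonised instrument data.frame (>= 2 rows).
#' @return data.frame with one row per excluded rsid: `excluded_rsid`,
#'   `method`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or_sd`,
#'   `or_lo`, `or_hi`.
#' @export
leave_one_out <- function(insts) {
  check_insts(insts, 2L, "leave-one-out")
  rows <- lapply(seq_len(nrow(insts)), function(j) {
    est <- estimate_by_rule(insts[-j, , drop = FALSE])
    cbind(data.frame(excluded_rsid = insts$rsid[j], stringsAsFactors = FALSE),
          as.data.frame(est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-estimate after excluding named SNPs
#'
#' @param insts harmonised instrument data.frame.
#' @param rsids character vector of instrument rsids to exclude (must all be
#'   present).
#' @return list with `estimate_fe`, `estimate_re` (both `NULL` replaced by a
#'   Wald ratio when one SNP remains), `heterogeneity` (when >= 2 remain,
#'   else `NULL`) and the reduced `instruments`.
#' @export
exclude_snps <- function(insts, rsids) {
  unknown <- setdiff(rsids, insts$rsid)
  if (length(unknown))
    stop_input("unknown rsid(s): ", paste(unknown, collapse = ", "))
  reduced <- insts[!(insts$rsid %in% rsids), , drop = FALSE]
  if (nrow(reduced) == 0L) stop_input("exclusion removes every instrument")
  if (nrow(reduced) == 1L) {
    est <- wald_ratio(reduced[1, ])
    return(list(estimate_fe = est, estimate_re = est, heterogeneity = NULL,
                instruments = reduced))
  }
  list(estimate_fe = mr_ivw(reduced, "fe"),
       estimate_re = mr_ivw(reduced, "re"),
       heterogeneity = heterogeneity(reduced),
       instruments = reduced)
}

#' Forest-plot-ready single-SNP table
#'
#' One Wald-ratio row per instrument plus combined IVW rows: fixed effects,
#' random effects and, when `exclude_rsid` names an instrument, both again
#' without that SNP.
#'
#' @param insts harmonised instrument data.frame (>= 1 row).
#' @param exclude_rsid optional rsid whose exclusion is summarised (e.g. a
#'   dominant variant such as a TERT telomere SNP).
#' @return data.frame with columns `label`, `type` (`"snp"` or `"summary"`),
#'   `method`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or_sd`,
#'   `or_lo`, `or_hi`.
#' @export
single_snp_table <- function(insts, exclude_rsid = NULL) {
  check_insts(insts, 1L, "single-SNP table")
  row_of <- function(label, type, est) {
    cbind(data.frame(label = label, type = type, stringsAsFactors = FALSE),
          as.data.frame(est))
  }
  rows <- lapply(seq_len(nrow(insts)), function(j) {
    row_of(insts$rsid[j], "snp", wald_ratio(insts[j, ]))
  })
  if (nrow(insts) >= 2) {
    rows <- c(rows,
              list(row_of("IVW (fixed effects)", "summary", mr_ivw(insts, "fe")),
                   row_of("IVW (random effects)", "summary", mr_ivw(insts, "re"))))
    if (!is.null(exclude_rsid)) {
      excl <- exclude_snps(insts, exclude_rsid)
      rows <- c(rows, list(
        row_of(paste0("IVW (fixed effects) without ", exclude_rsid),
               "summary", excl$estimate_fe),
        row_of(paste0("IVW (random effects) without ", exclude_rsid),
               "summary", excl$estimate_re)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consistency of sensitivity estimators with the primary estimate
#'
#' An association shows consistent evidence when the primary estimate is
#' nominally significant (p < 0.05) and every sensitivity estimate has the
#' same sign as the primary with p < 0.05.
#'
#' @param primary the primary `mr_estimate`.
#' @param sensitivity list of sensitivity `mr_estimate`s (e.g. weighted
#'   median, weighted mode, RAPS).
#' @return logical.
#' @export
consistency_check <- function(primary, sensitivity) {
  if (!length(sensitivity)) return(FALSE)
  if (primary$pval >= 0.05) return(FALSE)
  all(vapply(sensitivity, function(s) {
    sign(s$beta) == sign(primary$beta) && s$pval < 0.05
  }, logical(1)))
}
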