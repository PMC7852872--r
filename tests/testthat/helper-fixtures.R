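# Shared fixtures, all built in code.

# canonical association data.frame from parallel vectors
make_assocs <- function(rsid, beta, se, pval = NULL, eaf = 0.3,
                        ea = "A", oa = "G", n = 10000) {
  L <- length(rsid)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(rsid = rsid, chrom = "1", pos = seq_len(L) * 1000,
             ea = rep_len(ea, L), oa = rep_len(oa, L),
             eaf = rep_len(eaf, L), beta = beta, se = se, pval = pval,
             n = rep_len(n, L), n_case = NA_real_, n_control = NA_real_,
             stringsAsFactors = FALSE)
}

# harmonised instrument set from parallel vectors
make_insts <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                       rsid = NULL) {
  L <- length(beta_exp)
  data.frame(rsid = rsid %||% sprintf("rs%03d", seq_len(L)),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, L),
             beta_out = beta_out, se_out = rep_len(se_out, L),
             eaf = 0.3, flags = "", stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# instrument set whose Wald ratios and IVW weights are exactly as given
insts_from_ratios <- function(theta, w, se_out = 1) {
  # w = beta_exp^2 / se_out^2  =>  beta_exp = se_out * sqrt(w)
  beta_exp <- se_out * sqrt(w)
  make_insts(beta_exp, theta * beta_exp, se_exp = 0, se_out = se_out)
}

write_assoc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  mrphewas::write_summary_stats(df, path)
  path
}
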