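# Instrument selection and instrument-strength quality control.
#
# The filter chain mirrors standard MR practice for curated instruments:
# genome-wide significance (P < 5e-8), minor allele frequency > 0.01, greedy
# LD pruning at r^2 >= 0.01 keeping the most strongly associated SNP of each
# correlated cluster, then trait-level gates on the proportion of variance
# explained (PVE > 0.1%) and the F statistic (F > 10).

#' Keep genome-wide significant associations
#'
#' @param assocs canonical association data.frame.
#' @param p_thresh significance threshold; retained records have
#'   `pval < p_thresh` (strict).
#' @return the filtered data.frame.
#' @export
filter_significant <- function(assocs, p_thresh = 5e-8) {
  stopifnot(p_thresh > 0, p_thresh < 1)
  out <- assocs[assocs$pval < p_thresh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter on minor allele frequency
#'
#' Retains records with `min(eaf, 1 - eaf) > maf_min`.  Records lacking an
#' allele frequency are retained with a warning, since MAF cannot be
#' assessed for them.
#'
#' @param assocs canonical association data.frame.
#' @param maf_min minimum minor allele frequency (strict), in (0, 0.5).
#' @return the filtered data.frame.
#' @export
filter_maf <- function(assocs, maf_min = 0.01) {
  stopifnot(maf_min > 0, maf_min < 0.5)
  maf <- pmin(assocs$eaf, 1 - assocs$eaf)
  missing <- is.na(maf)
  if (any(missing)) {
    warning(sum(missing), " record(s) lack eaf; retained without a MAF check")
  }
  out <- assocs[missing | maf > maf_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pairwise LD table
#'
#' @param path 3-column tab-separated file: `rsid_a`, `rsid_b`, `r2`.
#' @return data.frame with those columns; values validated to lie in [0, 1].
#' @export
read_ld_table <- function(path) {
  ld <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(ld)[1:3] <- c("rsid_a", "rsid_b", "r2")
  ld$r2 <- as.numeric(ld$r2)
  if (any(is.na(ld$r2) | ld$r2 < 0 | ld$r2 > 1))
    stop_input("LD r2 values must lie in [0, 1]")
  ld
}

ld_lookup <- function(ld) {
  env <- new.env(parent = emptyenv())
  if (!is.null(ld) && nrow(ld)) {
    for (i in seq_len(nrow(ld))) {
      a <- ld$rsid_a[i]; b <- ld$rsid_b[i]
      assign(paste(a, b, sep = "\r"), ld$r2[i], envir = env)
      assign(paste(b, a, sep = "\r"), ld$r2[i], envir = env)
    }
  }
  function(a, b) {
    if (a == b) return(1)
    get0(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)
  }
}

#' Greedy LD pruning
#'
#' Ranks candidates by p-value (ties: larger absolute beta, then rsid), then
#' repeatedly accepts the best-ranked remaining SNP and discards every SNP
#' with `r2 >= r2_thresh` against any accepted SNP.  Pairs absent from the
#' LD table are treated as uncorrelated (`r2 = 0`), the usual convention for
#' sparse LD tables.
#'
#' @param assocs canonical association data.frame.
#' @param ld pairwise LD data.frame as from [read_ld_table()], or `NULL` for
#'   no known LD.
#' @param r2_thresh squared-correlation threshold in (0, 1].
#' @return the pruned data.frame; no retained pair has `r2 >= r2_thresh`.
#' @export
ld_prune <- function(assocs, ld = NULL, r2_thresh = 0.01) {
  stopifnot(r2_thresh > 0, r2_thresh <= 1)
  if (nrow(assocs) <= 1L) return(assocs)
  r2 <- ld_lookup(ld)
  ord <- order(assocs$pval, -abs(assocs$beta), assocs$rsid)
  ranked <- assocs[ord, , drop = FALSE]
  accepted <- character(0)
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    id <- ranked$rsid[i]
    correlated <- any(vapply(accepted, function(a) r2(a, id) >= r2_thresh,
                             logical(1)))
    if (!correlated) {
      keep[i] <- TRUE
      accepted <- c(accepted, id)
    }
  }
  out <- ranked[keep, , drop = FALSE]
  out <- out[order(match(out$rsid, assocs$rsid)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP proportion of variance explained
#'
#' Uses the t-statistic form `PVE_j = t^2 / (t^2 + n)` with `t = beta / se`,
#' which needs no assumption about the trait variance and is exact for
#' standardized traits.  (When the allele frequency is available the
#' frequency terms of the variance-components form cancel, giving the same
#' value.)
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), positive.
#' @param n GWAS sample size(s), > 2.
#' @param eaf effect-allele frequency (optional; unused by the t form, kept
#'   for interface symmetry).
#' @return PVE value(s) in [0, 1).
#' @export
snp_pve <- function(beta, se, n, eaf = NULL) {
  if (missing(n) || is.null(n) || all(is.na(n)))
    stop_input("insufficient statistics: sample size n is required for PVE")
  stopifnot(all(se > 0, na.rm = TRUE), all(n > 2, na.rm = TRUE))
  t2 <- (beta / se)^2
  t2 / (t2 + n)
}

#' Trait-level instrument strength
#'
#' Sums per-SNP PVEs over a mutually LD-pruned instrument set (capped at 1)
#' and computes the joint-instrument F statistic
#' `F = ((n - k - 1) / k) * (PVE / (1 - PVE))`.  A trait is included when
#' `PVE > 0.001` and `F > 10` (both strict).
#'
#' @param snp_pves per-SNP PVE values of the pruned instruments.
#' @param n exposure GWAS sample size.
#' @param k number of instrument SNPs (defaults to `length(snp_pves)`).
#' @return list with `pve`, `f_stat`, `included`, `n_snps`.
#' @export
trait_strength <- function(snp_pves, n, k = length(snp_pves)) {
  stopifnot(k >= 1)
  if (n <= k + 1) stop_input("sample size n must exceed k + 1 for the F statistic")
  pve <- min(1, sum(snp_pves))
  f_stat <- if (pve >= 1) Inf else ((n - k - 1) / k) * (pve / (1 - pve))
  list(pve = pve, f_stat = f_stat,
       included = (pve > 0.001) && (f_stat > 10), n_snps = k)
}

#' Run the full instrument QC chain for one trait
#'
#' Applies [filter_significant()], [filter_maf()] and [ld_prune()] in turn,
#' then the trait-level strength gates, recording the count surviving each
#' stage.
#'
#' @param assocs candidate exposure associations.
#' @param ld optional pairwise LD table.
#' @param p_thresh,maf_min,r2_thresh,pve_min,f_min filter parameters; any of
#'   the first three may be `NULL` to skip that stage.
#' @param n exposure GWAS sample size (defaults to the per-record `n`).
#' @return list with `assocs` (surviving records) and `report`
#'   (per-stage counts, trait `pve`, `f_stat`, `included`).
#' @export
instrument_qc <- function(assocs, ld = NULL, p_thresh = 5e-8, maf_min = 0.01,
                          r2_thresh = 0.01, pve_min = 0.001, f_min = 10,
                          n = NULL) {
  n_input <- nrow(assocs)
  if (!is.null(p_thresh)) assocs <- filter_significant(assocs, p_thresh)
  n_after_pval <- nrow(assocs)
  if (!is.null(maf_min)) assocs <- filter_maf(assocs, maf_min)
  n_after_maf <- nrow(assocs)
  if (!is.null(r2_thresh)) assocs <- ld_prune(assocs, ld, r2_thresh)
  n_after_ld <- nrow(assocs)

  if (n_after_ld == 0L) {
    report <- list(n_input = n_input, n_after_pval = n_after_pval,
                   n_after_maf = n_after_maf, n_after_ld = 0L,
                   pve = 0, f_stat = 0, included = FALSE)
    return(list(assocs = assocs, report = report))
  }
  n_trait <- n %||% suppressWarnings(max(assocs$n, na.rm = TRUE))
  pves <- snp_pve(assocs$beta, assocs$se, n_trait)
  strength <- trait_strength(pves, n_trait, k = n_after_ld)
  included <- (strength$pve > pve_min) && (strength$f_stat > f_min)
  list(assocs = assocs,
       report = list(n_input = n_input, n_after_pval = n_after_pval,
                     n_after_maf = n_after_maf, n_after_ld = n_after_ld,
                     pve = strength$pve, f_stat = strength$f_stat,
                     included = included))
}
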