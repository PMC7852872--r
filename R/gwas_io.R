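# Reading, validation and harmonisation of GWAS summary statistics.
#
# The canonical tab-separated dialect has columns
#   rsid chrom pos ea oa eaf beta se pval n [n_case n_control]
# with exposure effects in trait-SD units per effect allele and case-control
# outcome effects as log-odds per allele.  Positions are 1-based and carried
# as metadata only.

.canonical_cols <- c("rsid", "chrom", "pos", "ea", "oa", "eaf",
                     "beta", "se", "pval", "n", "n_case", "n_control")
.mandatory_cols <- c("rsid", "ea", "oa", "beta", "se", "pval")

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-separated association file into the canonical per-variant
#' layout, normalises allele codes to upper case, and drops rows that violate
#' the record invariants (positive SE, p-value in (0, 1], distinct A/C/G/T
#' alleles, effect-allele frequency in (0, 1) when present, finite beta).
#' Dropped rows are tallied by reason in the attached load report.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map optional named character vector mapping canonical column
#'   names (`rsid`, `chrom`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`,
#'   `n`, `n_case`, `n_control`) to the names used in the file.  Unmapped
#'   canonical names are looked up verbatim.
#' @param effect_scale `"sd"` for continuous exposures (trait-SD per allele)
#'   or `"log_or"` for case-control outcomes (log-odds per allele).  Stored as
#'   an attribute; no rescaling is performed.
#' @return a `data.frame` of validated associations in canonical column
#'   order, with attributes `effect_scale` and `load_report` (a list with
#'   `n_read`, `n_kept`, `n_dropped` and a per-reason `dropped` table).
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               effect_scale = c("sd", "log_or")) {
  effect_scale <- match.arg(effect_scale)
  if (!file.exists(path)) stop_input("summary-statistics file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(raw) == 0L) stop_input("empty summary-statistics file: ", path)

  map <- setNames(.canonical_cols, .canonical_cols)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .canonical_cols)
    if (length(bad)) stop_input("unknown canonical column(s) in column_map: ",
                                paste(bad, collapse = ", "))
    map[names(column_map)] <- unname(column_map)
  }
  missing_mand <- .mandatory_cols[!(map[.mandatory_cols] %in% names(raw))]
  if (length(missing_mand)) {
    stop_input("mandatory column(s) missing from ", path, ": ",
               paste(map[missing_mand], collapse = ", "))
  }

  out <- data.frame(rsid = as.character(raw[[map["rsid"]]]),
                    stringsAsFactors = FALSE)
  grab <- function(col, as_fun) {
    if (map[col] %in% names(raw)) as_fun(raw[[map[col]]]) else
      as_fun(rep(NA, nrow(raw)))
  }
  out$chrom <- grab("chrom", as.character)
  out$pos <- grab("pos", as.numeric)
  out$ea <- toupper(trimws(as.character(raw[[map["ea"]]])))
  out$oa <- toupper(trimws(as.character(raw[[map["oa"]]])))
  out$eaf <- grab("eaf", as.numeric)
  out$beta <- as.numeric(raw[[map["beta"]]])
  out$se <- as.numeric(raw[[map["se"]]])
  out$pval <- as.numeric(raw[[map["pval"]]])
  out$n <- grab("n", as.numeric)
  out$n_case <- grab("n_case", as.numeric)
  out$n_control <- grab("n_control", as.numeric)

  checks <- list(
    missing_core = !complete.cases(out[, c("rsid", "ea", "oa", "beta", "se", "pval")]),
    bad_allele = !(out$ea %in% c("A", "C", "G", "T")) |
      !(out$oa %in% c("A", "C", "G", "T")) | out$ea == out$oa,
    nonpositive_se = !is.na(out$se) & out$se <= 0,
    bad_pval = !is.na(out$pval) & (out$pval <= 0 | out$pval > 1),
    bad_eaf = !is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1),
    nonfinite_beta = !is.na(out$beta) & !is.finite(out$beta)
  )
  checks <- lapply(checks, function(x) {x[is.na(x)] <- FALSE; x})
  bad_any <- Reduce(`|`, checks)
  dropped <- vapply(checks, sum, integer(1))

  kept <- out[!bad_any, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "effect_scale") <- effect_scale
  attr(kept, "load_report") <- list(
    path = path, n_read = nrow(out), n_kept = nrow(kept),
    n_dropped = sum(bad_any), dropped = dropped)
  kept
}

#' Write summary statistics in the canonical dialect
#'
#' Inverse of [read_summary_stats()]: records written and re-read survive
#' bit-exactly (numbers serialised at full precision).
#'
#' @param assocs data.frame of associations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(assocs, path) {
  cols <- intersect(.canonical_cols, names(assocs))
  df <- assocs[, cols, drop = FALSE]
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 17,
                                                   trim = TRUE, scientific = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise one exposure/outcome variant pair
#'
#' Aligns the outcome association to the exposure's effect allele.  If the
#' outcome reports the complementary strand, alleles are complemented first;
#' if the outcome's effect allele matches the exposure's other allele, the
#' outcome beta is negated and its frequency complemented (`flipped` flag).
#' Palindromic pairs (A/T, G/C) cannot be strand-resolved by allele codes:
#' under `palindrome_policy = "drop"` they are discarded, under
#' `"infer_by_eaf"` they are aligned by allele frequency when both
#' frequencies are more than `eaf_tol` away from 0.5 (same side: keep;
#' opposite sides: flip), and dropped as ambiguous otherwise.
#'
#' @param exp,out single-row data.frames (or lists) with the canonical
#'   association fields for the same rsid.
#' @param palindrome_policy `"drop"` (default, conservative) or
#'   `"infer_by_eaf"`.
#' @param eaf_tol minimum distance of each allele frequency from 0.5 for
#'   frequency inference (default 0.08).
#' @return a list with `instrument` (one-row data.frame with `rsid`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `flags`, or `NULL`)
#'   and `verdict` (`"ok"`, `"allele_mismatch"`, `"palindromic"` or
#'   `"palindromic_ambiguous"`).
#' @export
harmonise_pair <- function(exp, out, palindrome_policy = c("drop", "infer_by_eaf"),
                           eaf_tol = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$rsid), as.character(out$rsid)))
    stop_input("harmonise_pair requires matching rsids")

  drop_verdict <- function(reason) list(instrument = NULL, verdict = reason)
  ea_e <- exp$ea; oa_e <- exp$oa
  ea_o <- out$ea; oa_o <- out$oa
  flags <- character(0)

  if (is_palindromic(ea_e, oa_e)) {
    # palindrome: allele codes cannot distinguish strand flip from swap
    if (palindrome_policy == "drop") return(drop_verdict("palindromic"))
    eaf_e <- exp$eaf %||% NA_real_; eaf_o <- out$eaf %||% NA_real_
    if (is.na(eaf_e) || is.na(eaf_o) ||
        abs(eaf_e - 0.5) <= eaf_tol || abs(eaf_o - 0.5) <= eaf_tol)
      return(drop_verdict("palindromic_ambiguous"))
    flip <- (eaf_e - 0.5) * (eaf_o - 0.5) < 0
    flags <- "palindromic"
  } else {
    aligned <- ea_o == ea_e && oa_o == oa_e
    swapped <- ea_o == oa_e && oa_o == ea_e
    if (!aligned && !swapped) {
      # try the complementary strand
      ea_c <- unname(.complement[ea_o]); oa_c <- unname(.complement[oa_o])
      aligned <- identical(ea_c, ea_e) && identical(oa_c, oa_e)
      swapped <- identical(ea_c, oa_e) && identical(oa_c, ea_e)
      if (!aligned && !swapped) return(drop_verdict("allele_mismatch"))
    }
    flip <- swapped
  }

  beta_out <- if (flip) -out$beta else out$beta
  if (flip) flags <- c(flags, "flipped")
  inst <- data.frame(
    rsid = as.character(exp$rsid),
    beta_exp = as.numeric(exp$beta), se_exp = as.numeric(exp$se),
    beta_out = as.numeric(beta_out), se_out = as.numeric(out$se),
    eaf = as.numeric(exp$eaf %||% NA_real_),
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE)
  list(instrument = inst, verdict = "ok")
}

#' Build a harmonised instrument set for one trait-outcome pair
#'
#' Deduplicates each file on rsid (keeping the record with the smallest
#' p-value), intersects exposure and outcome on rsid (no LD-proxy lookup),
#' and harmonises every shared variant with [harmonise_pair()].
#'
#' @param exp_assocs exposure associations (canonical data.frame).
#' @param out_assocs outcome associations (canonical data.frame).
#' @inheritParams harmonise_pair
#' @return a list with `instruments` (data.frame, possibly 0-row) and
#'   `report` listing `missing_in_outcome` rsids, per-reason harmonisation
#'   drops, and duplicate rsids removed from either file.
#' @export
build_instrument_set <- function(exp_assocs, out_assocs,
                                 palindrome_policy = c("drop", "infer_by_eaf"),
                                 eaf_tol = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  dedup <- function(df) {
    dup_ids <- unique(df$rsid[duplicated(df$rsid)])
    if (length(dup_ids)) {
      keep <- order(df$pval, seq_len(nrow(df)))
      df <- df[keep, , drop = FALSE]
      df <- df[!duplicated(df$rsid), , drop = FALSE]
    }
    list(df = df, duplicates = dup_ids)
  }
  de <- dedup(exp_assocs); do <- dedup(out_assocs)
  exp_assocs <- de$df; out_assocs <- do$df

  shared <- intersect(exp_assocs$rsid, out_assocs$rsid)
  missing <- setdiff(exp_assocs$rsid, out_assocs$rsid)
  if (!length(shared)) warning("no exposure SNPs present in the outcome data")

  insts <- list(); drops <- character(0)
  for (id in shared) {
    h <- harmonise_pair(exp_assocs[exp_assocs$rsid == id, ],
                        out_assocs[out_assocs$rsid == id, ],
                        palindrome_policy = palindrome_policy, eaf_tol = eaf_tol)
    if (h$verdict == "ok") insts[[id]] <- h$instrument else drops[id] <- h$verdict
  }
  instruments <- if (length(insts)) do.call(rbind, insts) else
    data.frame(rsid = character(0), beta_exp = numeric(0), se_exp = numeric(0),
               beta_out = numeric(0), se_out = numeric(0), eaf = numeric(0),
               flags = character(0), stringsAsFactors = FALSE)
  rownames(instruments) <- NULL
  list(instruments = instruments,
       report = list(n_exposure = nrow(exp_assocs),
                     n_shared = length(shared),
                     n_harmonised = nrow(instruments),
                     missing_in_outcome = missing,
                     harmonise_drops = drops,
                     duplicates_exposure = de$duplicates,
                     duplicates_outcome = do$duplicates))
}
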