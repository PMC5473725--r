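#' The SMR test from paired QTL and GWAS summary statistics
#'
#' Summary-data Mendelian randomization uses a single instrument SNP to
#' compare the QTL effect on a molecular trait (`b_qtl`) with the GWAS
#' effect on a phenotype (`b_gwas`), both on the same effect allele.
#' With `z1 = b_gwas/se_gwas` and `z2 = b_qtl/se_qtl`, the SMR statistic
#' is `chi2_smr = z1^2 z2^2 / (z1^2 + z2^2)` on 1 df; the effect estimate
#' is `b_smr = b_gwas/b_qtl` and its delta-method standard error is
#' `sqrt(se_gwas^2 b_qtl^2 + se_qtl^2 b_gwas^2) / b_qtl^2`, so that
#' `t_smr^2 = chi2_smr` identically.  The p-value is taken from the
#' chi-square tail, never from a normal approximation of `t_smr`, so
#' extreme tails are stable.
#'
#' All arguments are vectorized and recycled.
#'
#' @param b_gwas,se_gwas GWAS effect and standard error at the
#'   instrument.
#' @param b_qtl,se_qtl QTL effect and standard error at the instrument.
#' @return A `data.frame` with columns `b_smr, se_smr, t_smr, p_smr,
#'   chi2_smr`.
#' @examples
#' smr_test(0.03, 0.006, 0.5, 0.05)  # chi2 = 20, b_smr = 0.06
#' @export
smr_test <- function(b_gwas, se_gwas, b_qtl, se_qtl) {
  k <- max(length(b_gwas), length(se_gwas), length(b_qtl), length(se_qtl))
  b_gwas <- rep_len(b_gwas, k); se_gwas <- rep_len(se_gwas, k)
  b_qtl <- rep_len(b_qtl, k); se_qtl <- rep_len(se_qtl, k)
  if (any(!is.finite(se_gwas) | se_gwas <= 0 | !is.finite(se_qtl) | se_qtl <= 0))
    stop("standard errors must be positive")
  if (any(b_qtl == 0)) stop("degenerate_instrument")
  z1 <- b_gwas / se_gwas
  z2 <- b_qtl / se_qtl
  chi2 <- z1^2 * z2^2 / (z1^2 + z2^2)
  b <- b_gwas / b_qtl
  se <- sqrt(se_gwas^2 * b_qtl^2 + se_qtl^2 * b_gwas^2) / b_qtl^2
  data.frame(b_smr = b, se_smr = se, t_smr = b / se,
             p_smr = pmax(stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                          .Machine$double.xmin),
             chi2_smr = chi2)
}

#' Select the instrument SNP for a probe
#'
#' Picks the SNP with the smallest QTL p-value among SNPs shared between
#' the QTL and GWAS datasets (i.e. rows of a harmonized frame), provided
#' that p-value is below `qtl_p_threshold`; otherwise the probe is
#' untested.  Exact p ties are broken by larger `|b/se|`, residual ties
#' by smaller genomic position.
#'
#' @param frame a harmonized probe frame with columns `snp_id, pos,
#'   b_qtl, se_qtl, p_qtl` (e.g. built internally by [smr_scan()]), or
#'   `NULL`/empty if no SNPs are shared.
#' @param qtl_p_threshold instrument significance threshold on the QTL p.
#' @return The selected `snp_id`, or `NA_character_` with attribute
#'   `reason` (`"no_shared_snps"` or `"no_qtl_below_threshold"`).
#' @export
select_instrument <- function(frame, qtl_p_threshold = 1e-10) {
  if (is.null(frame) || nrow(frame) == 0L)
    return(structure(NA_character_, reason = "no_shared_snps"))
  o <- order(frame$p_qtl, -abs(frame$b_qtl / frame$se_qtl), frame$pos)
  best <- frame[o[1L], ]
  if (!is.finite(best$p_qtl) || best$p_qtl >= qtl_p_threshold)
    return(structure(NA_character_, reason = "no_qtl_below_threshold"))
  best$snp_id
}

#' Classify an SMR-tested association
#'
#' An association is `pleiotropic` when SMR-significant with a
#' non-significant HEIDI heterogeneity test (`heidi_p > heidi_threshold`),
#' `linkage` when SMR-significant with significant heterogeneity,
#' `not_significant` when the SMR p misses the threshold, and `untested`
#' when SMR-significant but the HEIDI p is missing (too few instruments
#' or no usable LD).  Vectorized.
#'
#' @param smr_p SMR p-value(s).
#' @param heidi_p HEIDI p-value(s), `NA` allowed.
#' @param smr_threshold SMR significance threshold (typically Bonferroni
#'   over the probes tested, see [bonferroni_threshold()]).
#' @param heidi_threshold HEIDI filter level (default 0.05).
#' @return Character vector of classifications.
#' @export
classify_smr <- function(smr_p, heidi_p, smr_threshold,
                         heidi_threshold = 0.05) {
  k <- max(length(smr_p), length(heidi_p))
  smr_p <- rep_len(smr_p, k); heidi_p <- rep_len(heidi_p, k)
  out <- rep(NA_character_, k)
  sig <- !is.na(smr_p) & smr_p < smr_threshold
  out[!sig] <- "not_significant"
  out[sig & is.na(heidi_p)] <- "untested"
  out[sig & !is.na(heidi_p) & heidi_p > heidi_threshold] <- "pleiotropic"
  out[sig & !is.na(heidi_p) & heidi_p <= heidi_threshold] <- "linkage"
  out[is.na(smr_p)] <- "untested"
  out
}
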