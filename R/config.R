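#' Analysis configuration
#'
#' Bundles the thresholds and windows used across the SMR/HEIDI pipeline.
#' Defaults follow the conventions of blood methylation QTL analyses: a
#' +/-500 kb cis window, an instrument significance threshold of
#' 1e-10 for the QTL arm, family-wise alpha 0.05 (Bonferroni over the
#' probes actually tested), a HEIDI filter at 0.05, and genome-wide
#' significance 5e-8 for novel-locus flagging.
#'
#' @param cis_window cis window half-width in bp around the probe position
#'   (inclusive).
#' @param qtl_p_threshold maximum QTL p-value for a SNP to serve as the
#'   instrument (e.g. 1e-10 for a well-powered blood mQTL set, 1e-8 for a
#'   smaller fetal-brain set).
#' @param alpha_fw family-wise alpha for the Bonferroni SMR threshold.
#' @param heidi_threshold HEIDI p-value above which an SMR-significant
#'   association is called pleiotropic rather than linkage.
#' @param heidi_qtl_p QTL p-value ceiling for alternative HEIDI instruments
#'   (default 1.57e-3, i.e. |z| > 3.16).
#' @param r2_min,r2_max LD r-squared bounds (inclusive) to the top SNP for
#'   alternative HEIDI instruments.
#' @param max_snps,min_snps maximum/minimum number of alternative
#'   instruments for the HEIDI test.
#' @param gwas_sig_threshold genome-wide significance level used by
#'   [flag_novel_locus()].
#' @param novel_locus_window bp window (inclusive) around the probe within
#'   which a genome-wide-significant GWAS SNP disqualifies novelty.
#' @param min_tested_sites minimum number of probes a trait must have been
#'   tested against to enter the multi-trait clustering matrix.
#' @param freq_tol palindromic-SNP frequency tolerance: both allele
#'   frequencies must lie outside \[0.5 - freq_tol, 0.5 + freq_tol\] for a
#'   palindromic pair to be orientable.
#' @param cond_max condition-number ceiling for the HEIDI LD submatrix;
#'   above it the most collinear SNP is dropped and the test retried.
#' @param heidi_mc_draws draws for the Monte-Carlo fallback of the
#'   weighted chi-square tail.
#' @return An object of class `smr_config` (a validated named list).
#' @examples
#' cfg <- smr_config(qtl_p_threshold = 1e-8)  # fetal-brain style
#' cfg$qtl_p_threshold
#' @export
smr_config <- function(cis_window = 5e5,
                       qtl_p_threshold = 1e-10,
                       alpha_fw = 0.05,
                       heidi_threshold = 0.05,
                       heidi_qtl_p = 1.57e-3,
                       r2_min = 0.05,
                       r2_max = 0.9,
                       max_snps = 20L,
                       min_snps = 3L,
                       gwas_sig_threshold = 5e-8,
                       novel_locus_window = 5e5,
                       min_tested_sites = 20000L,
                       freq_tol = 0.2,
                       cond_max = 1e8,
                       heidi_mc_draws = 1e6) {
  cfg <- list(cis_window = as.numeric(cis_window),
              qtl_p_threshold = as.numeric(qtl_p_threshold),
              alpha_fw = as.numeric(alpha_fw),
              heidi_threshold = as.numeric(heidi_threshold),
              heidi_qtl_p = as.numeric(heidi_qtl_p),
              r2_min = as.numeric(r2_min),
              r2_max = as.numeric(r2_max),
              max_snps = as.integer(max_snps),
              min_snps = as.integer(min_snps),
              gwas_sig_threshold = as.numeric(gwas_sig_threshold),
              novel_locus_window = as.numeric(novel_locus_window),
              min_tested_sites = as.integer(min_tested_sites),
              freq_tol = as.numeric(freq_tol),
              cond_max = as.numeric(cond_max),
              heidi_mc_draws = as.numeric(heidi_mc_draws))
  for (nm in c("qtl_p_threshold", "alpha_fw", "heidi_threshold",
               "heidi_qtl_p", "gwas_sig_threshold")) {
    v <- cfg[[nm]]
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("`%s` must lie in (0, 1)", nm))
  }
  if (cfg$cis_window <= 0 || cfg$novel_locus_window <= 0)
    stop("windows must be positive")
  if (cfg$r2_min < 0 || cfg$r2_max > 1 || cfg$r2_min > cfg$r2_max)
    stop("need 0 <= r2_min <= r2_max <= 1")
  if (cfg$min_snps < 1L || cfg$max_snps < cfg$min_snps)
    stop("need 1 <= min_snps <= max_snps")
  if (cfg$freq_tol < 0 || cfg$freq_tol >= 0.5)
    stop("`freq_tol` must lie in [0, 0.5)")
  structure(cfg, class = "smr_config")
}

#' @export
print.smr_config <- function(x, ...) {
  cat("SMR/HEIDI analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' Any key matching an [smr_config()] argument overrides its default;
#' unknown keys are rejected.  Column-map dialect sections named
#' `gwas_dialect` / `qtl_dialect` are returned alongside the config.
#'
#' @param path path to a YAML file.
#' @return A list with elements `config` (an `smr_config`),
#'   `gwas_dialect` and `qtl_dialect` (possibly `NULL`).
#' @export
read_smr_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dial_g <- raw$gwas_dialect
  dial_q <- raw$qtl_dialect
  raw$gwas_dialect <- NULL
  raw$qtl_dialect <- NULL
  known <- names(formals(smr_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(smr_config, raw)
  list(config = cfg,
       gwas_dialect = if (!is.null(dial_g)) do.call(ma_dialect, dial_g),
       qtl_dialect = if (!is.null(dial_q)) do.call(qtl_dialect, dial_q))
}
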