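#' Column map for GWAS summary statistics (".ma" dialect)
#'
#' Maps the canonical field names used internally onto the column headers
#' of a GWAS summary file.  The default is the GCTA-COJO `.ma` layout
#' (`SNP A1 A2 freq b se p n`), where `A1` is the effect allele.  `chrom`
#' and `pos` are optional; when present they enable novel-locus flagging.
#'
#' @param snp_id,effect_allele,other_allele,eaf,beta,se,p,n,chrom,pos
#'   column names in the file; set a name to `NULL` if the column is
#'   absent (only `eaf`, `n`, `chrom`, `pos` may be absent).
#' @return A named list of class `sumstats_dialect`.
#' @export
ma_dialect <- function(snp_id = "SNP", effect_allele = "A1",
                       other_allele = "A2", eaf = "freq", beta = "b",
                       se = "se", p = "p", n = "n",
                       chrom = "chr", pos = "bp") {
  structure(list(snp_id = snp_id, effect_allele = effect_allele,
                 other_allele = other_allele, eaf = eaf, beta = beta,
                 se = se, p = p, n = n, chrom = chrom, pos = pos),
            class = "sumstats_dialect")
}

#' Column map for long-format cis-QTL summary statistics
#'
#' One row per (probe, SNP) pair; `A1` is the allele whose dosage the QTL
#' effect `b` is reported for.
#'
#' @param probe_id,probe_chrom,probe_pos,gene probe-level column names.
#' @inheritParams ma_dialect
#' @return A named list of class `sumstats_dialect`.
#' @export
qtl_dialect <- function(probe_id = "probe", probe_chrom = "probe_chr",
                        probe_pos = "probe_bp", gene = "gene",
                        snp_id = "SNP", chrom = "chr", pos = "bp",
                        effect_allele = "A1", other_allele = "A2",
                        eaf = "freq", beta = "b", se = "se", p = "p",
                        n = NULL) {
  structure(list(probe_id = probe_id, probe_chrom = probe_chrom,
                 probe_pos = probe_pos, gene = gene, snp_id = snp_id,
                 chrom = chrom, pos = pos, effect_allele = effect_allele,
                 other_allele = other_allele, eaf = eaf, beta = beta,
                 se = se, p = p, n = n),
            class = "sumstats_dialect")
}

# pull mapped columns out of a raw table; mandatory columns must exist
.map_columns <- function(raw, dialect, mandatory, path) {
  out <- list()
  for (nm in names(dialect)) {
    col <- dialect[[nm]]
    if (is.null(col)) { out[[nm]] <- NULL; next }
    if (!col %in% names(raw)) {
      if (nm %in% mandatory)
        stop(sprintf("missing mandatory column '%s' (field %s) in %s",
                     col, nm, path))
      out[[nm]] <- NULL
      next
    }
    out[[nm]] <- raw[[col]]
  }
  out
}

# row-level validation shared by GWAS and QTL readers; returns a keep mask
# plus a p-consistency flag.  NAs in mandatory numerics are malformed.
.validate_rows <- function(df) {
  ok_allele <- .valid_allele(df$effect_allele) & .valid_allele(df$other_allele) &
    df$effect_allele != df$other_allele
  ok_se <- is.finite(df$se) & df$se > 0
  ok_p <- is.finite(df$p) & df$p > 0 & df$p <= 1
  ok_beta <- is.finite(df$beta)
  ok_eaf <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  keep <- ok_allele & ok_se & ok_p & ok_beta & ok_eaf
  keep[is.na(keep)] <- FALSE
  # p consistency against the Wald normal p (compared in log space so that
  # meta-analysis p-values far below double precision still work); a >10x
  # discrepancy is flagged, never dropped
  log_wald <- .z_to_log_p(df$beta / df$se)
  flag <- abs(log(df$p) - log_wald) > log(10)
  flag[!keep | !is.finite(flag)] <- FALSE
  list(keep = keep, p_inconsistent = flag)
}

.read_raw_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "", quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited GWAS summary table, validates each
#' row (alleles in A/C/G/T and distinct, `se > 0`, `p` in (0,1], `eaf` in
#' \[0,1\] when present) and flags rows whose stored p-value disagrees by
#' more than 10x with the two-sided normal p recomputed from `beta/se`
#' (flagged, never dropped: meta-analysis p-values legitimately deviate
#' from the Wald p).  Malformed rows are skipped and counted.
#'
#' @param path path to the summary file.
#' @param dialect a column map from [ma_dialect()].
#' @return A `data.frame` of class `gwas_sumstats` with canonical columns
#'   `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, p,
#'   n, p_inconsistent`; attributes `n_skipped` (malformed row count) and
#'   `n_flagged`.
#' @seealso [read_qtl()], [harmonize()]
#' @export
read_gwas <- function(path, dialect = ma_dialect()) {
  raw <- .read_raw_table(path)
  v <- .map_columns(raw, dialect,
                    mandatory = c("snp_id", "effect_allele", "other_allele",
                                  "beta", "se", "p"), path)
  n <- nrow(raw)
  df <- data.frame(snp_id = as.character(v$snp_id),
                   chrom = if (is.null(v$chrom)) NA_character_ else as.character(v$chrom),
                   pos = if (is.null(v$pos)) NA_integer_ else as.integer(v$pos),
                   effect_allele = toupper(as.character(v$effect_allele)),
                   other_allele = toupper(as.character(v$other_allele)),
                   eaf = if (is.null(v$eaf)) NA_real_ else suppressWarnings(as.numeric(v$eaf)),
                   beta = suppressWarnings(as.numeric(v$beta)),
                   se = suppressWarnings(as.numeric(v$se)),
                   p = suppressWarnings(as.numeric(v$p)),
                   n = if (is.null(v$n)) NA_real_ else suppressWarnings(as.numeric(v$n)),
                   stringsAsFactors = FALSE)
  chk <- .validate_rows(df)
  df$p_inconsistent <- chk$p_inconsistent
  out <- df[chk$keep, , drop = FALSE]
  rownames(out) <- NULL
  n_skipped <- sum(!chk$keep)
  if (n_skipped > 0)
    message(sprintf("read_gwas: skipped %d malformed row(s) in %s",
                    n_skipped, path))
  if (any(out$p_inconsistent))
    message(sprintf("read_gwas: %d row(s) with p inconsistent with beta/se (flagged)",
                    sum(out$p_inconsistent)))
  structure(out, class = c("gwas_sumstats", "data.frame"),
            n_skipped = n_skipped, n_flagged = sum(out$p_inconsistent))
}

#' Read cis-QTL summary statistics
#'
#' Reads a long-format tab-delimited QTL table (one row per probe-SNP
#' pair), applies the same row validation as [read_gwas()], rejects
#' duplicate (probe, SNP) pairs, and drops SNPs outside the cis window
#' around the probe position.
#'
#' @param path path to the QTL file.
#' @param dialect a column map from [qtl_dialect()].
#' @param cis_window half-width in bp of the cis window (inclusive).
#' @return A `data.frame` of class `qtl_sumstats` with probe columns
#'   (`probe_id, probe_chrom, probe_pos, gene`) plus the canonical SNP
#'   columns; attributes `n_skipped` and `n_cis_excluded`.
#' @export
read_qtl <- function(path, dialect = qtl_dialect(), cis_window = 5e5) {
  raw <- .read_raw_table(path)
  v <- .map_columns(raw, dialect,
                    mandatory = c("probe_id", "probe_chrom", "probe_pos",
                                  "snp_id", "chrom", "pos", "effect_allele",
                                  "other_allele", "beta", "se", "p"), path)
  df <- data.frame(probe_id = as.character(v$probe_id),
                   probe_chrom = as.character(v$probe_chrom),
                   probe_pos = suppressWarnings(as.integer(v$probe_pos)),
                   gene = if (is.null(v$gene)) NA_character_ else as.character(v$gene),
                   snp_id = as.character(v$snp_id),
                   chrom = as.character(v$chrom),
                   pos = suppressWarnings(as.integer(v$pos)),
                   effect_allele = toupper(as.character(v$effect_allele)),
                   other_allele = toupper(as.character(v$other_allele)),
                   eaf = if (is.null(v$eaf)) NA_real_ else suppressWarnings(as.numeric(v$eaf)),
                   beta = suppressWarnings(as.numeric(v$beta)),
                   se = suppressWarnings(as.numeric(v$se)),
                   p = suppressWarnings(as.numeric(v$p)),
                   n = if (is.null(v$n)) NA_real_ else suppressWarnings(as.numeric(v$n)),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[c("probe_id", "snp_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (probe, SNP) pair: (%s, %s) in %s",
                 df$probe_id[i], df$snp_id[i], path))
  }
  chk <- .validate_rows(df)
  df$p_inconsistent <- chk$p_inconsistent
  out <- df[chk$keep, , drop = FALSE]
  n_skipped <- sum(!chk$keep)
  in_cis <- out$chrom == out$probe_chrom &
    abs(out$pos - out$probe_pos) <= cis_window
  in_cis[is.na(in_cis)] <- FALSE
  n_cis_excluded <- sum(!in_cis)
  if (n_skipped > 0)
    message(sprintf("read_qtl: skipped %d malformed row(s) in %s",
                    n_skipped, path))
  if (n_cis_excluded > 0)
    message(sprintf("read_qtl: excluded %d SNP(s) outside the %d bp cis window",
                    n_cis_excluded, as.integer(cis_window)))
  out <- out[in_cis, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("qtl_sumstats", "data.frame"),
            n_skipped = n_skipped, n_cis_excluded = n_cis_excluded)
}

#' Write summary statistics back to disk
#'
#' Writers matching [read_gwas()] / [read_qtl()]: tab-delimited, full
#' double precision (round-trips numerics to better than 1e-12).
#'
#' @param x a `gwas_sumstats` or `qtl_sumstats` data frame (canonical
#'   columns).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gwas <- function(x, path) {
  cols <- c(SNP = "snp_id", chr = "chrom", bp = "pos",
            A1 = "effect_allele", A2 = "other_allele", freq = "eaf",
            b = "beta", se = "se", p = "p", n = "n")
  out <- stats::setNames(as.data.frame(x, stringsAsFactors = FALSE)[cols],
                         names(cols))
  .write_tsv(out, path)
}

#' @rdname write_gwas
#' @export
write_qtl <- function(x, path) {
  cols <- c(probe = "probe_id", probe_chr = "probe_chrom",
            probe_bp = "probe_pos", gene = "gene", SNP = "snp_id",
            chr = "chrom", bp = "pos", A1 = "effect_allele",
            A2 = "other_allele", freq = "eaf", b = "beta", se = "se",
            p = "p")
  out <- stats::setNames(as.data.frame(x, stringsAsFactors = FALSE)[cols],
                         names(cols))
  .write_tsv(out, path)
}

# Vectorized allele reconciliation of dataset y onto the frame of dataset
# x.  Returns per-row action: "keep", "flip" (negate y's beta, complement
# y's eaf), or an exclusion reason ("allele_mismatch",
# "ambiguous_palindrome").  Palindromic pairs (A/T, C/G) are orientable
# only by allele frequency: both eafs must lie outside
# [0.5 - freq_tol, 0.5 + freq_tol].
.harmonize_action <- function(a1x, a2x, eafx, a1y, a2y, eafy, freq_tol) {
  n <- length(a1x)
  pal <- .complement[a1x] == a2x
  same <- a1y == a1x & a2y == a2x
  swap <- a1y == a2x & a2y == a1x
  csame <- .complement[a1y] == a1x & .complement[a2y] == a2x
  cswap <- .complement[a1y] == a2x & .complement[a2y] == a1x
  action <- rep(NA_character_, n)
  np <- !pal
  action[np & same] <- "keep"
  action[np & !same & swap] <- "flip"
  action[np & !same & !swap & csame] <- "keep"
  action[np & !same & !swap & !csame & cswap] <- "flip"
  action[np & is.na(action)] <- "allele_mismatch"
  if (any(pal)) {
    letters_ok <- same | swap
    action[pal & !letters_ok] <- "allele_mismatch"
    informative <- !is.na(eafx) & !is.na(eafy) &
      abs(eafx - 0.5) > freq_tol & abs(eafy - 0.5) > freq_tol
    # candidate orientation from the letters; palindromes cannot tell a
    # swap from a strand flip, so check the frequencies and add one more
    # flip when they disagree
    eafy_cand <- ifelse(swap, 1 - eafy, eafy)
    agree <- sign(eafx - 0.5) == sign(eafy_cand - 0.5)
    cand <- ifelse(swap, "flip", "keep")
    other <- ifelse(swap, "keep", "flip")
    sel <- pal & letters_ok
    action[sel & informative & agree] <- cand[sel & informative & agree]
    action[sel & informative & !agree] <- other[sel & informative & !agree]
    action[sel & !informative] <- "ambiguous_palindrome"
  }
  action
}

#' Harmonize two association records onto one allele frame
#'
#' Aligns record `b` to the effect-allele orientation of record `a` for
#' the same SNP.  Swapped alleles negate `b`'s effect and complement its
#' frequency; strand-complementary non-palindromic pairs are resolved by
#' complementing; palindromic (A/T, C/G) pairs are resolved by allele
#' frequency only when both frequencies are informative (outside
#' `0.5 +/- freq_tol`), and are otherwise excluded.  Harmonization is
#' involutive: harmonizing an already-aligned pair is a no-op.
#'
#' @param a,b single association records: lists or one-row data frames
#'   with fields `snp_id, effect_allele, other_allele, eaf, beta` (and
#'   optionally `se, p, ...`, carried through untouched).
#' @param freq_tol palindromic frequency tolerance (default 0.2).
#' @return A list with elements `a`, `b` (aligned copy), `excluded`
#'   (logical) and `reason` (`NA`, `"allele_mismatch"` or
#'   `"ambiguous_palindrome"`).
#' @examples
#' a <- list(snp_id = "rs1", effect_allele = "A", other_allele = "G",
#'           eaf = 0.7, beta = 0.1)
#' b <- list(snp_id = "rs1", effect_allele = "G", other_allele = "A",
#'           eaf = 0.3, beta = 0.2)
#' harmonize(a, b)$b$beta   # -0.2
#' @export
harmonize <- function(a, b, freq_tol = 0.2) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(as.character(a$snp_id), as.character(b$snp_id)))
    stop("harmonize() requires the same snp_id")
  act <- .harmonize_action(a$effect_allele, a$other_allele,
                           a$eaf %||% NA_real_,
                           b$effect_allele, b$other_allele,
                           b$eaf %||% NA_real_, freq_tol)
  if (act %in% c("allele_mismatch", "ambiguous_palindrome"))
    return(list(a = a, b = b, excluded = TRUE, reason = act))
  if (act == "flip") {
    b$beta <- -b$beta
    if (!is.null(b$eaf)) b$eaf <- 1 - b$eaf
  }
  b$effect_allele <- a$effect_allele
  b$other_allele <- a$other_allele
  list(a = a, b = b, excluded = FALSE, reason = NA_character_)
}

# Merge one probe's QTL records with a GWAS table on snp_id and align the
# GWAS effects onto the QTL allele frame.  Returns the merged frame plus
# an exclusion tally.
.merge_probe_gwas <- function(qtl_probe, gwas, freq_tol) {
  idx <- match(qtl_probe$snp_id, gwas$snp_id)
  hit <- !is.na(idx)
  q <- qtl_probe[hit, , drop = FALSE]
  g <- gwas[idx[hit], , drop = FALSE]
  if (nrow(q) == 0L)
    return(list(frame = NULL, n_excluded = 0L, reasons = character(0)))
  act <- .harmonize_action(q$effect_allele, q$other_allele, q$eaf,
                           g$effect_allele, g$other_allele, g$eaf,
                           freq_tol)
  keep <- act %in% c("keep", "flip")
  flip <- act == "flip"
  b_gwas <- ifelse(flip, -g$beta, g$beta)
  frame <- data.frame(snp_id = q$snp_id, chrom = q$chrom, pos = q$pos,
                      effect_allele = q$effect_allele,
                      other_allele = q$other_allele,
                      eaf_qtl = q$eaf,
                      b_qtl = q$beta, se_qtl = q$se, p_qtl = q$p,
                      eaf_gwas = ifelse(flip, 1 - g$eaf, g$eaf),
                      b_gwas = b_gwas, se_gwas = g$se, p_gwas = g$p,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(frame) <- NULL
  list(frame = frame, n_excluded = sum(!keep), reasons = act[!keep])
}
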