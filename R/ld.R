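#' LD reference from a genotype dosage matrix
#'
#' Wraps an individuals-by-SNPs dosage matrix (values in \[0, 2\],
#' missing allowed) as a provider of pairwise allelic correlations.  The
#' per-SNP counted (effect) allele may be recorded so that correlations
#' can be signed on the harmonized orientation of a summary-statistics
#' frame.
#'
#' @param dosages numeric matrix, individuals x SNPs, with SNP ids as
#'   column names.
#' @param snp_info optional `data.frame` with columns `snp_id`,
#'   `effect_allele` (the allele counted by the dosage) and optionally
#'   `other_allele`, `chrom`, `pos`.
#' @return An object of class `ld_ref`.
#' @seealso [ld_cor()], [ld_matrix()], [read_ld_dosage()], [read_ld_vcf()]
#' @export
ld_ref <- function(dosages, snp_info = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) stop("dosage matrix needs SNP column names")
  storage.mode(dosages) <- "double"
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (!is.null(snp_info)) {
    snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
    if (!all(c("snp_id", "effect_allele") %in% names(snp_info)))
      stop("snp_info needs columns snp_id and effect_allele")
    miss <- setdiff(colnames(dosages), snp_info$snp_id)
    if (length(miss)) stop("snp_info is missing SNPs: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    snp_info <- snp_info[match(colnames(dosages), snp_info$snp_id), , drop = FALSE]
    rownames(snp_info) <- NULL
  }
  structure(list(dosages = dosages, snp_info = snp_info),
            class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat(sprintf("LD reference: %d individuals x %d SNPs%s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$snp_info)) " (no allele orientation recorded)" else ""))
  invisible(x)
}

.ld_col <- function(ref, snp) {
  j <- match(snp, colnames(ref$dosages))
  if (is.na(j)) stop("SNP not in LD reference: ", snp)
  ref$dosages[, j]
}

#' Pairwise allelic correlation between two SNPs
#'
#' Pearson correlation of dosages over individuals with complete data for
#' both SNPs, on the reference's own counted-allele orientation.
#'
#' @param ref an [ld_ref()] object.
#' @param snp_i,snp_j SNP ids.
#' @return Correlation in \[-1, 1\].
#' @export
ld_cor <- function(ref, snp_i, snp_j) {
  x <- .ld_col(ref, snp_i); y <- .ld_col(ref, snp_j)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("fewer than 2 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("monomorphic")
  stats::cor(x, y)
}

#' Signed LD correlation matrix for a set of SNPs
#'
#' Pairwise correlations (complete pairwise observations) with the sign of
#' each SNP's dosage flipped wherever the requested effect allele differs
#' from the reference's counted allele (strand complements are
#' reconciled).
#'
#' @param ref an [ld_ref()] object.
#' @param snp_ids SNP ids to extract.
#' @param effect_alleles optional character vector (parallel to
#'   `snp_ids`) giving the orientation the correlations should be signed
#'   on; requires `snp_info` in the reference.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(ref, snp_ids, effect_alleles = NULL) {
  j <- match(snp_ids, colnames(ref$dosages))
  if (anyNA(j)) stop("SNP(s) not in LD reference: ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  D <- ref$dosages[, j, drop = FALSE]
  v <- apply(D, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0))
    stop("monomorphic SNP(s) in LD reference: ",
         paste(snp_ids[!is.finite(v) | v == 0], collapse = ", "))
  if (!is.null(effect_alleles)) {
    if (is.null(ref$snp_info))
      stop("LD reference carries no allele orientation")
    ref_a1 <- ref$snp_info$effect_allele[j]
    flip <- effect_alleles != ref_a1 & effect_alleles != .complement[ref_a1]
    if (any(flip)) D[, flip] <- 2 - D[, flip]
  }
  R <- stats::cor(D, use = "pairwise.complete.obs")
  diag(R) <- 1
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

#' Read an LD reference from a tab-delimited dosage matrix
#'
#' Expects a header row of SNP ids with a leading `IID` column of sample
#' ids; one row per individual, dosages in \[0, 2\] (`NA` allowed).  An
#' optional companion SNP-info table (`snp_id`, `effect_allele`,
#' `other_allele`, `chrom`, `pos`) records the counted allele.
#'
#' @param path path to the dosage matrix.
#' @param info_path optional path to the SNP info table.
#' @return An [ld_ref()] object.
#' @export
read_ld_dosage <- function(path, info_path = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "IID") stop("dosage matrix must start with an IID column")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$IID
  info <- if (!is.null(info_path))
    utils::read.table(info_path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
  ld_ref(m, snp_info = info)
}

#' Read an LD reference from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts ALT alleles
#' in `GT`.  The counted (effect) allele is ALT.  Requires the `vcfR`
#' package.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return An [ld_ref()] object.
#' @export
read_ld_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_ld_vcf() requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  fmt <- unique(unlist(strsplit(v@gt[, 1], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      a <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
      vapply(a, function(x) {
        x <- suppressWarnings(as.integer(x))
        if (anyNA(x)) NA_real_ else sum(x > 0)
      }, numeric(1))
    }
    d <- apply(gt, 2, cnt)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  m <- t(d)
  colnames(m) <- ids
  info <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     effect_allele = fix[, "ALT"],
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  ld_ref(m, snp_info = info)
}

#' Write an LD reference as a dosage matrix plus SNP info table
#'
#' @param ref an [ld_ref()] object.
#' @param path output path for the dosage matrix.
#' @param info_path optional output path for the SNP info table.
#' @return `path`, invisibly.
#' @export
write_ld_dosage <- function(ref, path, info_path = NULL) {
  df <- data.frame(IID = rownames(ref$dosages) %||%
                     paste0("I", seq_len(nrow(ref$dosages))),
                   ref$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(info_path) && !is.null(ref$snp_info))
    .write_tsv(ref$snp_info, info_path)
  invisible(path)
}
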