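#' Bonferroni family-wise threshold
#'
#' `alpha_fw / n_tests`, the per-test significance level controlling the
#' family-wise error over the probes tested in a dataset (e.g. 0.05 over
#' 35,263 methylation sites gives 1.42e-6 at 3 significant figures).
#' The unrounded value is returned (and used in comparisons); the
#' 3-significant-figure presentation value is attached as attribute
#' `rounded`.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha_fw family-wise alpha.
#' @return The threshold, with attribute `rounded`.
#' @examples
#' signif(bonferroni_threshold(35263), 3)  # 1.42e-06
#' @export
bonferroni_threshold <- function(n_tests, alpha_fw = 0.05) {
  n_tests <- as.numeric(n_tests)
  if (length(n_tests) != 1L || !is.finite(n_tests) || n_tests < 1 ||
      n_tests != round(n_tests))
    stop("`n_tests` must be a positive integer")
  thr <- alpha_fw / n_tests
  structure(thr, rounded = signif(thr, 3))
}

#' Sign concordance between two sets of SMR results
#'
#' Counts shared (trait, probe) records whose SMR effect estimates agree
#' in sign across two runs (e.g. discovery vs replication cohort, or two
#' tissues) and tests the proportion against 0.5 with a two-sided exact
#' binomial sign test.  The p-value is computed in log space, so
#' magnitudes far below double precision (e.g. 1e-172) are representable
#' via `log10_sign_test_p`.  Records with missing or exactly zero
#' `b_smr` in either run are excluded from `n_tested`.
#'
#' @param x,y `smr_scan` objects or record data frames with columns
#'   `trait_id, probe_id, b_smr`.
#' @param only_pleiotropic if `TRUE`, restrict `x` to its pleiotropic
#'   records before matching.
#' @return An object of class `concordance_report`: `n_tested`,
#'   `n_same_sign`, `proportion`, `sign_test_p`, `log10_sign_test_p`.
#' @export
sign_concordance <- function(x, y, only_pleiotropic = FALSE) {
  rx <- if (inherits(x, "smr_scan")) x$records else x
  ry <- if (inherits(y, "smr_scan")) y$records else y
  if (only_pleiotropic)
    rx <- rx[rx$classification == "pleiotropic", , drop = FALSE]
  m <- merge(rx[c("trait_id", "probe_id", "b_smr")],
             ry[c("trait_id", "probe_id", "b_smr")],
             by = c("trait_id", "probe_id"), suffixes = c("_x", "_y"))
  m <- m[is.finite(m$b_smr_x) & is.finite(m$b_smr_y) &
           m$b_smr_x != 0 & m$b_smr_y != 0, , drop = FALSE]
  if (nrow(m) == 0L) stop("no shared records with non-missing b_smr")
  n <- nrow(m)
  same <- sum(sign(m$b_smr_x) == sign(m$b_smr_y))
  kk <- max(same, n - same)
  log_p <- log(2) + stats::pbinom(kk - 1, n, 0.5, lower.tail = FALSE,
                                  log.p = TRUE)
  log_p <- min(log_p, 0)
  structure(list(n_tested = n, n_same_sign = same, proportion = same / n,
                 sign_test_p = exp(log_p),
                 log10_sign_test_p = log_p / log(10)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("sign concordance: %d/%d (%.1f%%), sign test p = %.3g (log10 p = %.1f)\n",
              x$n_same_sign, x$n_tested, 100 * x$proportion,
              x$sign_test_p, x$log10_sign_test_p))
  invisible(x)
}

#' Replication of pleiotropic associations in a second dataset
#'
#' For each pleiotropic discovery record, an association is `replicated`
#' when its replication-run SMR p beats the replication dataset's own
#' Bonferroni threshold (alpha over the probes tested in replication)
#' and its replication HEIDI p exceeds `heidi_threshold`; `untested`
#' when the probe has no tested replication record.
#'
#' @param discovery,replication `smr_scan` objects.
#' @param config an [smr_config()] (uses `heidi_threshold`).
#' @return A data frame with one row per pleiotropic discovery
#'   association: discovery/replication statistics, the replication
#'   threshold used, and `status` in `{replicated, not_replicated,
#'   untested}`.
#' @export
replicate_scan <- function(discovery, replication, config = smr_config()) {
  d <- discovery$records
  d <- d[d$classification == "pleiotropic", , drop = FALSE]
  r <- replication$records
  thr <- replication$smr_threshold
  idx <- match(paste(d$trait_id, d$probe_id),
               paste(r$trait_id, r$probe_id))
  rep_p <- r$p_smr[idx]
  rep_h <- r$heidi_p[idx]
  status <- ifelse(is.na(idx) | is.na(rep_p), "untested",
            ifelse(rep_p < thr & !is.na(rep_h) & rep_h > config$heidi_threshold,
                   "replicated", "not_replicated"))
  out <- data.frame(trait_id = d$trait_id, probe_id = d$probe_id,
                    b_smr_discovery = d$b_smr, p_smr_discovery = d$p_smr,
                    b_smr_replication = r$b_smr[idx],
                    p_smr_replication = rep_p,
                    heidi_p_replication = rep_h,
                    replication_threshold = as.numeric(thr),
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-level overlap between methylation and expression SMR runs
#'
#' Collapses probe-level records to gene-trait level (a gene-trait pair
#' is pleiotropic when at least one of its probes is) and reports, per
#' pair, whether it was tested and pleiotropic in both the mQTL and the
#' eQTL run, the probe count, and whether the pleiotropic probes agree in
#' `b_smr` sign.
#'
#' @param mqtl,eqtl `smr_scan` objects with gene annotations in their
#'   records.
#' @return A data frame keyed by (gene, trait).
#' @export
gene_overlap <- function(mqtl, eqtl) {
  collapse <- function(rec, prefix) {
    rec <- rec[!is.na(rec$gene), , drop = FALSE]
    key <- paste(rec$gene, rec$trait_id, sep = "\r")
    out <- do.call(rbind, lapply(split(rec, key), function(r) {
      pl <- r[r$classification == "pleiotropic", , drop = FALSE]
      data.frame(gene = r$gene[1], trait_id = r$trait_id[1],
                 tested = any(!is.na(r$p_smr)),
                 pleiotropic = nrow(pl) > 0,
                 n_probes = nrow(r),
                 sign_consistent = if (nrow(pl) > 1)
                   length(unique(sign(pl$b_smr))) == 1L else NA,
                 stringsAsFactors = FALSE)
    }))
    names(out)[3:6] <- paste0(prefix, "_", names(out)[3:6])
    out
  }
  m <- collapse(mqtl$records, "mqtl")
  e <- collapse(eqtl$records, "eqtl")
  out <- merge(m, e, by = c("gene", "trait_id"), all.x = TRUE)
  out$eqtl_tested[is.na(out$eqtl_tested)] <- FALSE
  out$eqtl_pleiotropic[is.na(out$eqtl_pleiotropic)] <- FALSE
  out$tested_in_both <- out$mqtl_tested & out$eqtl_tested
  out$pleiotropic_in_both <- out$mqtl_pleiotropic & out$eqtl_pleiotropic
  out <- out[order(out$gene, out$trait_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag associations at loci without genome-wide-significant GWAS support
#'
#' An association is novel when no GWAS SNP with
#' `p < gwas_sig_threshold` lies within `novel_locus_window` bp
#' (inclusive) of the probe position on the same chromosome — the probe
#' position, not the instrument SNP, anchors the distance.  Requires
#' GWAS chromosome/position columns.
#'
#' @param probe_chrom,probe_pos probe location vectors (recycled).
#' @param gwas a `gwas_sumstats` data frame for the matching trait.
#' @param config an [smr_config()].
#' @return Logical vector: `TRUE` when novel.
#' @export
flag_novel_locus <- function(probe_chrom, probe_pos, gwas,
                             config = smr_config()) {
  if (all(is.na(gwas$chrom)) || all(is.na(gwas$pos)))
    stop("GWAS table has no chromosome/position columns")
  sig <- gwas[!is.na(gwas$p) & gwas$p < config$gwas_sig_threshold &
                !is.na(gwas$chrom) & !is.na(gwas$pos), , drop = FALSE]
  k <- max(length(probe_chrom), length(probe_pos))
  probe_chrom <- rep_len(probe_chrom, k); probe_pos <- rep_len(probe_pos, k)
  vapply(seq_len(k), function(i) {
    !any(sig$chrom == probe_chrom[i] &
           abs(sig$pos - probe_pos[i]) <= config$novel_locus_window)
  }, logical(1))
}

#' Novel-locus flags for a whole scan
#'
#' Applies [flag_novel_locus()] to every pleiotropic record of a scan,
#' using the matching trait's GWAS table.
#'
#' @param scan an `smr_scan`.
#' @param gwas a named list of `gwas_sumstats` (names = trait ids).
#' @param config an [smr_config()].
#' @return The pleiotropic records with a logical `novel` column.
#' @export
novel_loci <- function(scan, gwas, config = smr_config()) {
  r <- scan$records[scan$records$classification == "pleiotropic", , drop = FALSE]
  r$novel <- NA
  for (trait in unique(r$trait_id)) {
    i <- r$trait_id == trait
    r$novel[i] <- flag_novel_locus(r$probe_chrom[i], r$probe_pos[i],
                                   gwas[[trait]], config)
  }
  rownames(r) <- NULL
  r
}

#' Probes pleiotropically associated with multiple traits
#'
#' @param scan an `smr_scan` (or a records data frame) covering at least
#'   two traits.
#' @return A data frame of probes with >= 2 pleiotropic trait
#'   associations: `probe_id`, `n_traits`, `traits` (comma-separated).
#' @export
multi_trait_sites <- function(scan) {
  r <- if (inherits(scan, "smr_scan")) scan$records else scan
  if (length(unique(r$trait_id)) < 2L) stop("need >= 2 traits")
  pl <- r[r$classification == "pleiotropic", , drop = FALSE]
  out <- do.call(rbind, lapply(split(pl, pl$probe_id), function(x) {
    tr <- sort(unique(x$trait_id))
    data.frame(probe_id = x$probe_id[1], n_traits = length(tr),
               traits = paste(tr, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.null(out) & out$n_traits >= 2L, , drop = FALSE]
  if (is.null(out)) out <- data.frame(probe_id = character(0),
                                      n_traits = integer(0),
                                      traits = character(0))
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clustered matrix of SMR t-statistics across traits
#'
#' Builds the probes-by-traits matrix of `t_smr = b_smr/se_smr`
#' (missing cells allowed, never imputed), keeping only traits tested
#' against at least `min_tested_sites` probes, and orders rows and
#' columns by agglomerative hierarchical clustering (average linkage on
#' Euclidean distance with pairwise-complete masking of missing cells,
#' as in [stats::dist()]).  All-missing rows/columns are dropped with a
#' message.  Deterministic given its inputs.
#'
#' @param scans an `smr_scan`, a records data frame, or a list of either
#'   (rows are pooled).
#' @param seed_probes probes forming the rows; default: all probes with
#'   at least one pleiotropic classification among the retained traits.
#' @param min_tested_sites minimum tested-probe count for a trait to be
#'   retained (defaults to `config$min_tested_sites`).
#' @param config an [smr_config()].
#' @return An object of class `trait_probe_matrix`: `matrix` (t_smr),
#'   `row_order`, `col_order`, and the `hclust` objects (`NULL` when a
#'   dimension has < 3 entries, in which case the identity order is
#'   used).
#' @export
trait_probe_matrix <- function(scans, seed_probes = NULL,
                               min_tested_sites = NULL,
                               config = smr_config()) {
  recs <- function(x) if (inherits(x, "smr_scan")) x$records else x
  r <- if (is.data.frame(scans) || inherits(scans, "smr_scan")) recs(scans)
       else do.call(rbind, lapply(scans, recs))
  min_tested_sites <- min_tested_sites %||% config$min_tested_sites
  tested <- tapply(!is.na(r$p_smr), r$trait_id, sum)
  traits <- sort(names(tested)[tested >= min_tested_sites])
  if (!length(traits)) stop("no trait tested against enough sites")
  r <- r[r$trait_id %in% traits, , drop = FALSE]
  if (is.null(seed_probes))
    seed_probes <- sort(unique(r$probe_id[r$classification == "pleiotropic"]))
  if (!length(seed_probes)) stop("no seed probes")
  m <- matrix(NA_real_, length(seed_probes), length(traits),
              dimnames = list(seed_probes, traits))
  sel <- r$probe_id %in% seed_probes
  m[cbind(match(r$probe_id[sel], seed_probes),
          match(r$trait_id[sel], traits))] <- r$t_smr[sel]
  drop_r <- rowSums(!is.na(m)) == 0
  drop_c <- colSums(!is.na(m)) == 0
  if (any(drop_r)) message(sprintf("dropping %d all-missing row(s)", sum(drop_r)))
  if (any(drop_c)) message(sprintf("dropping %d all-missing column(s)", sum(drop_c)))
  m <- m[!drop_r, !drop_c, drop = FALSE]
  clust <- function(mm) {
    if (nrow(mm) < 3L) return(list(order = seq_len(nrow(mm)), hc = NULL))
    hc <- stats::hclust(stats::dist(mm), method = "average")
    list(order = hc$order, hc = hc)
  }
  cr <- clust(m)
  cc <- clust(t(m))
  structure(list(matrix = m, row_order = cr$order, col_order = cc$order,
                 row_hclust = cr$hc, col_hclust = cc$hc),
            class = "trait_probe_matrix")
}

#' @export
print.trait_probe_matrix <- function(x, ...) {
  cat(sprintf("trait-probe t_SMR matrix: %d probes x %d traits (%.0f%% missing)\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' Heatmap of a clustered trait-probe matrix
#'
#' Renders the reordered t-statistic matrix with [graphics::image()];
#' missing cells are left blank (never imputed).
#' @param x a `trait_probe_matrix`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.trait_probe_matrix <- function(x, ...) {
  m <- x$matrix[x$row_order, x$col_order, drop = FALSE]
  lim <- max(abs(m), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("navy", "white", "firebrick"))(65)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Write a clustered trait-probe matrix and its dendrogram orders
#'
#' @param x a `trait_probe_matrix`.
#' @param path output path for the matrix (tab-delimited, original
#'   orientation); the row/column dendrogram orders are written to
#'   `<path>.orders`.
#' @return `path`, invisibly.
#' @export
write_trait_probe_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x$matrix), x$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  ord <- c(paste0("rows\t", paste(rownames(x$matrix)[x$row_order], collapse = ",")),
           paste0("cols\t", paste(colnames(x$matrix)[x$col_order], collapse = ",")))
  writeLines(ord, paste0(path, ".orders"))
  invisible(path)
}
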