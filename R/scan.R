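#' Fit an SMR + HEIDI scan across traits and probes
#'
#' The central fitting function.  For every (trait, probe) pair it
#' harmonizes the probe's cis-QTL records with the trait's GWAS summary
#' statistics, selects the top shared cis-QTL SNP as the instrument
#' (provided its QTL p-value beats `config$qtl_p_threshold`), computes
#' the SMR estimate and p-value, and — for SMR-significant records — runs
#' the HEIDI heterogeneity test against alternative cis instruments.
#' The SMR significance threshold is the Bonferroni correction of
#' `config$alpha_fw` over the number of distinct probes actually tested
#' in this dataset (not per trait), reproducing the usual per-dataset
#' threshold arithmetic.
#'
#' @param gwas a `gwas_sumstats` data frame, or a named list of them
#'   (one per trait; names become trait ids).
#' @param qtl a `qtl_sumstats` data frame (see [read_qtl()]).
#' @param ld an [ld_ref()] object, or `NULL` to skip HEIDI.
#' @param config an [smr_config()].
#' @return An object of class `smr_scan`: list with `records` (one row
#'   per trait-probe, ordered by trait, probe chromosome, probe
#'   position), `smr_threshold`, `n_probes_tested`, `manifest` (per-trait
#'   counts), and `config`.
#' @examples
#' \donttest{
#' bench <- make_benchmark(tempfile("bench"), benchmark_config(
#'   n_traits = 2, n_probes = 10, n_qtl = 600, n_gwas = 1500,
#'   n_ref = 300), seed = 7)
#' gwas <- lapply(bench$gwas_paths, read_gwas)
#' qtl <- read_qtl(bench$mqtl_primary)
#' ld <- read_ld_dosage(bench$ld_dosage, bench$ld_info)
#' fit <- smr_scan(gwas, qtl, ld)
#' summary(fit)
#' }
#' @export
smr_scan <- function(gwas, qtl, ld = NULL, config = smr_config()) {
  if (is.data.frame(gwas)) gwas <- list(trait1 = gwas)
  if (is.null(names(gwas)) || any(names(gwas) == ""))
    stop("`gwas` must be a named list of traits")
  for (g in gwas) if (anyDuplicated(g$snp_id))
    stop("duplicate snp_id in a GWAS table")

  probes <- unique(qtl[c("probe_id", "probe_chrom", "probe_pos", "gene")])
  probes <- probes[order(probes$probe_chrom, probes$probe_pos,
                         probes$probe_id), , drop = FALSE]
  qtl_by_probe <- split(seq_len(nrow(qtl)), qtl$probe_id)

  rows <- vector("list", length(gwas) * nrow(probes))
  frames <- vector("list", length(gwas) * nrow(probes))
  k <- 0L
  for (trait in names(gwas)) {
    g <- gwas[[trait]]
    for (i in seq_len(nrow(probes))) {
      pr <- probes[i, ]
      q <- qtl[qtl_by_probe[[pr$probe_id]], , drop = FALSE]
      mg <- .merge_probe_gwas(q, g, config$freq_tol)
      k <- k + 1L
      base <- data.frame(trait_id = trait, probe_id = pr$probe_id,
                         probe_chrom = pr$probe_chrom,
                         probe_pos = pr$probe_pos, gene = pr$gene,
                         instrument_snp = NA_character_,
                         b_qtl = NA_real_, se_qtl = NA_real_,
                         p_qtl = NA_real_, b_gwas = NA_real_,
                         se_gwas = NA_real_, p_gwas = NA_real_,
                         b_smr = NA_real_, se_smr = NA_real_,
                         t_smr = NA_real_, p_smr = NA_real_,
                         chi2_smr = NA_real_, heidi_p = NA_real_,
                         n_heidi_snps = 0L,
                         heidi_status = NA_character_,
                         heidi_method = NA_character_,
                         n_shared_snps = if (is.null(mg$frame)) 0L else nrow(mg$frame),
                         n_excluded_alleles = mg$n_excluded,
                         reason = NA_character_,
                         stringsAsFactors = FALSE)
      inst <- select_instrument(mg$frame, config$qtl_p_threshold)
      if (is.na(inst)) {
        base$reason <- attr(inst, "reason")
        rows[[k]] <- base
        next
      }
      f <- mg$frame
      top <- f[f$snp_id == inst, ]
      s <- smr_test(top$b_gwas, top$se_gwas, top$b_qtl, top$se_qtl)
      base$instrument_snp <- inst
      base$b_qtl <- top$b_qtl; base$se_qtl <- top$se_qtl
      base$p_qtl <- top$p_qtl
      base$b_gwas <- top$b_gwas; base$se_gwas <- top$se_gwas
      base$p_gwas <- top$p_gwas
      base$b_smr <- s$b_smr; base$se_smr <- s$se_smr
      base$t_smr <- s$t_smr; base$p_smr <- s$p_smr
      base$chi2_smr <- s$chi2_smr
      rows[[k]] <- base
      frames[[k]] <- f
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  n_probes_tested <- length(unique(records$probe_id[!is.na(records$p_smr)]))
  smr_threshold <- if (n_probes_tested > 0)
    bonferroni_threshold(n_probes_tested, config$alpha_fw) else NA_real_

  # HEIDI pass over SMR-significant records only (the heterogeneity test
  # filters the significant set)
  if (!is.null(ld) && n_probes_tested > 0) {
    sig <- which(!is.na(records$p_smr) & records$p_smr < smr_threshold)
    for (k in sig) {
      f <- frames[[k]]
      inst <- records$instrument_snp[k]
      if (!inst %in% colnames(ld$dosages)) {
        records$heidi_status[k] <- "ld_unavailable"
        next
      }
      sel <- heidi_select_snps(f, inst, ld, config)
      if (sel$status != "ok") {
        records$heidi_status[k] <- sel$status
        next
      }
      ids <- c(inst, sel$snps)
      R <- tryCatch(ld_matrix(ld, ids,
                              effect_alleles = f$effect_allele[match(ids, f$snp_id)]),
                    error = function(e) NULL)
      if (is.null(R)) {
        records$heidi_status[k] <- "ld_unavailable"
        next
      }
      h <- heidi_test(f, inst, sel$snps, R, config)
      records$heidi_p[k] <- h$p_heidi
      records$n_heidi_snps[k] <- h$n_snps
      records$heidi_status[k] <- h$status
      records$heidi_method[k] <- h$method
    }
  }

  records$classification <- if (is.na(smr_threshold)) "untested" else
    classify_smr(records$p_smr, records$heidi_p, smr_threshold,
                 config$heidi_threshold)
  o <- order(records$trait_id, records$probe_chrom, records$probe_pos,
             records$probe_id)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL

  manifest <- do.call(rbind, lapply(split(records, records$trait_id),
    function(r) data.frame(
      trait_id = r$trait_id[1],
      n_probes = nrow(r),
      n_tested = sum(!is.na(r$p_smr)),
      n_significant = sum(!is.na(r$p_smr) & r$p_smr < smr_threshold),
      n_pleiotropic = sum(r$classification == "pleiotropic"),
      n_linkage = sum(r$classification == "linkage"),
      n_untested = sum(is.na(r$p_smr)),
      stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL

  structure(list(records = records, smr_threshold = smr_threshold,
                 n_probes_tested = n_probes_tested, manifest = manifest,
                 config = config),
            class = "smr_scan")
}

#' @export
print.smr_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("SMR/HEIDI scan: %d trait(s) x %d probe(s)\n",
              length(unique(r$trait_id)), length(unique(r$probe_id))))
  cat(sprintf("  probes tested: %d; SMR threshold: %.3g\n",
              x$n_probes_tested, x$smr_threshold))
  tab <- table(r$classification)
  cat("  classifications:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.smr_scan <- function(object, ...) {
  structure(list(manifest = object$manifest,
                 smr_threshold = object$smr_threshold,
                 n_probes_tested = object$n_probes_tested,
                 config = object$config),
            class = "summary.smr_scan")
}

#' @export
print.summary.smr_scan <- function(x, ...) {
  cat(sprintf("SMR threshold %.3g (alpha %.3g over %d tested probes)\n",
              x$smr_threshold, x$config$alpha_fw, x$n_probes_tested))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' @export
coef.smr_scan <- function(object, ...) {
  r <- object$records
  ok <- !is.na(r$b_smr)
  stats::setNames(r$b_smr[ok], paste(r$trait_id[ok], r$probe_id[ok], sep = ":"))
}

#' @export
as.data.frame.smr_scan <- function(x, ...) x$records

#' Volcano-style plot of a scan
#'
#' Plots `b_smr` against `-log10(p_smr)` for tested records, colored by
#' classification, with the SMR threshold drawn as a horizontal line.
#' @param x an `smr_scan`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.smr_scan <- function(x, ...) {
  r <- x$records[!is.na(x$records$p_smr), ]
  cls <- c(pleiotropic = "forestgreen", linkage = "firebrick",
           not_significant = "grey60", untested = "orange")
  graphics::plot(r$b_smr, -log10(r$p_smr), pch = 19,
                 col = cls[r$classification],
                 xlab = expression(b[SMR]),
                 ylab = expression(-log[10] ~ p[SMR]), ...)
  graphics::abline(h = -log10(x$smr_threshold), lty = 2)
  graphics::legend("topleft", legend = names(cls), col = cls, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Write scan outputs
#'
#' `write_smr_records()` writes the full record table (tab-delimited, one
#' row per trait-probe, byte-deterministic).  `write_pleiotropic_bed()`
#' writes the positions of pleiotropically associated probes as BED
#' (0-based half-open).
#'
#' @param scan an `smr_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smr_records <- function(scan, path) {
  .write_tsv(scan$records, path)
}

#' @rdname write_smr_records
#' @export
write_pleiotropic_bed <- function(scan, path) {
  r <- scan$records[scan$records$classification == "pleiotropic", , drop = FALSE]
  r <- unique(r[c("probe_chrom", "probe_pos", "probe_id")])
  bed <- data.frame(chrom = r$probe_chrom, start = r$probe_pos - 1L,
                    end = r$probe_pos, name = r$probe_id,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
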