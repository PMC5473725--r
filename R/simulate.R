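# ---- latent-Gaussian AR(1) haplotype model with LD calibration ----------
#
# Haplotype alleles are thresholded latent Gaussians.  Thresholding
# attenuates correlation (a latent rho of 0.9 yields a binary r of ~0.7
# at maf 0.5), so the latent correlation of each adjacent pair is
# calibrated by root-finding so that the *realized allelic* correlation
# matches the requested target.

# P(Z1 > t1, Z2 > t2) under a standard bivariate normal with corr rho
.bvn_upper <- function(rho, t1, t2) {
  if (abs(rho) >= 1) {
    # degenerate: Z2 = sign(rho) * Z1
    if (rho > 0) return(stats::pnorm(max(t1, t2), lower.tail = FALSE))
    return(max(0, stats::pnorm(t1, lower.tail = FALSE) -
                 stats::pnorm(-t2)))
  }
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((rho * z - t2) / sqrt(1 - rho^2))
  stats::integrate(f, lower = t1, upper = Inf, rel.tol = 1e-10)$value
}

# allelic (binary) correlation implied by latent rho at the given mafs
.binary_r <- function(rho, maf1, maf2) {
  t1 <- stats::qnorm(1 - maf1); t2 <- stats::qnorm(1 - maf2)
  p11 <- .bvn_upper(rho, t1, t2)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

.latent_rho_cache <- new.env(parent = emptyenv())

# latent rho achieving a target allelic correlation (memoised)
.latent_rho <- function(target, maf1, maf2) {
  if (target == 0) return(0)
  key <- sprintf("%.6f|%.5f|%.5f", target, maf1, maf2)
  hit <- .latent_rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  hi <- .binary_r(0.9999, maf1, maf2)
  lo <- .binary_r(-0.9999, maf1, maf2)
  out <- if (target >= hi) 0.9999 else if (target <= lo) -0.9999 else
    stats::uniroot(function(r) .binary_r(r, maf1, maf2) - target,
                   lower = -0.9999, upper = 0.9999, tol = 1e-7)$root
  .latent_rho_cache[[key]] <- out
  out
}

#' Describe a generative scenario for one cis locus
#'
#' A scenario specifies one locus of `n_snps` SNPs in autoregressive LD
#' and the causal architecture linking it to a molecular trait
#' (methylation, M-value-like and unbounded) and a phenotype:
#' * `pleiotropy` — one causal SNP drives the molecular trait
#'   (`m = b_zx g + e`) which mediates the phenotype
#'   (`y = b_xy m* + e`, with `m*` regenerated in the disjoint GWAS
#'   sample), so the GWAS effect at the causal SNP is `b_zx * b_xy` by
#'   construction;
#' * `linkage` — two distinct causal SNPs in LD `causal_r`: one drives
#'   the molecular trait, the other the phenotype directly
#'   (`y = b_zy g2 + e`);
#' * `null` — the molecular trait has a QTL but the phenotype is pure
#'   noise.
#'
#' An optional `horizontal` effect adds a direct SNP-to-phenotype path
#' alongside mediation (a robustness scenario, off by default).
#'
#' @param kind `"pleiotropy"`, `"linkage"` or `"null"`.
#' @param n_snps SNPs in the locus.
#' @param maf per-SNP minor-allele frequencies in \[0.05, 0.5\]; drawn
#'   uniformly from `maf_range` when `NULL`.
#' @param maf_range range for drawn mafs.
#' @param ld_decay target allelic correlation between adjacent SNPs.
#' @param b_zx causal-SNP effect on the molecular trait (dosage scale).
#' @param b_xy mediated effect of the molecular trait on the phenotype
#'   (pleiotropy).
#' @param b_zy direct effect of the second causal SNP on the phenotype
#'   (linkage).
#' @param causal_r target LD between the two causal SNPs (linkage only);
#'   `1` yields perfect LD (duplicated dosages).
#' @param causal_snp index of the causal QTL SNP (default: middle).
#' @param n_qtl,n_gwas sample sizes of the disjoint QTL and GWAS samples.
#' @param sd_m,sd_y residual SDs of the molecular trait and phenotype.
#' @param horizontal direct SNP-phenotype effect added under pleiotropy.
#' @param chrom,base_pos,spacing genomic placement of the locus.
#' @param seed seed for the scenario's own draws (maf, alleles); the
#'   caller's RNG state is preserved.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(kind = c("pleiotropy", "linkage", "null"),
                         n_snps = 15L, maf = NULL,
                         maf_range = c(0.1, 0.45), ld_decay = 0.8,
                         b_zx = 0.5, b_xy = 0.3, b_zy = 0.4,
                         causal_r = 0.6, causal_snp = NULL,
                         n_qtl = 2000L, n_gwas = 10000L,
                         sd_m = 1, sd_y = 1, horizontal = 0,
                         chrom = "1", base_pos = 1e6, spacing = 5000,
                         seed = 1L) {
  kind <- match.arg(kind)
  n_snps <- as.integer(n_snps)
  if (n_snps < 2L) stop("need at least 2 SNPs")
  drawn <- .with_seed(seed, {
    # SNPs in strong LD necessarily have similar allele frequencies, and
    # the requested allelic correlation is only attainable when mafs are
    # close; draw a locus-level maf and jitter per SNP
    m <- maf %||% {
      base <- stats::runif(1, maf_range[1] + 0.03, maf_range[2] - 0.03)
      pmin(pmax(base + stats::runif(n_snps, -0.03, 0.03),
                maf_range[1]), maf_range[2])
    }
    a1 <- character(n_snps); a2 <- character(n_snps)
    for (j in seq_len(n_snps)) {
      a1[j] <- sample(c("A", "C", "G", "T"), 1)
      a2[j] <- sample(setdiff(c("A", "C", "G", "T"),
                              c(a1[j], .complement[a1[j]])), 1)
    }
    list(maf = m, a1 = a1, a2 = a2)
  })
  maf <- rep_len(drawn$maf, n_snps)
  if (any(maf < 0.05 | maf > 0.5))
    stop("maf outside [0.05, 0.5]")
  causal_snp <- as.integer(causal_snp %||% ceiling(n_snps / 2))
  # the second causal variant sits two chain steps away, with an
  # intermediate SNP, as linkage pairs separated by recombination do;
  # the two latent steps are calibrated so the realized allelic LD of
  # the causal pair equals causal_r
  causal_snp2 <- if (kind == "linkage") causal_snp + 2L else NA_integer_
  adj_r <- rep(ld_decay, n_snps - 1L)
  adj_latent <- rep(NA_real_, n_snps - 1L)
  if (kind == "linkage") {
    if (causal_snp2 > n_snps) stop("no room for a second causal SNP")
    maf[causal_snp + 1L] <- maf[causal_snp]
    maf[causal_snp2] <- maf[causal_snp]   # equal mafs make causal_r attainable
    if (causal_r < 1) {
      lat_tot <- .latent_rho(causal_r, maf[causal_snp], maf[causal_snp2])
      adj_latent[causal_snp + 0:1] <- sqrt(max(lat_tot, 0))
      adj_r[causal_snp + 0:1] <- NA_real_
    }
  }
  structure(list(kind = kind, n_snps = n_snps, maf = maf,
                 ld_decay = ld_decay, adj_r = adj_r,
                 adj_latent = adj_latent,
                 b_zx = b_zx, b_xy = b_xy, b_zy = b_zy,
                 causal_r = causal_r, causal_snp = causal_snp,
                 causal_snp2 = causal_snp2,
                 n_qtl = as.integer(n_qtl), n_gwas = as.integer(n_gwas),
                 sd_m = sd_m, sd_y = sd_y, horizontal = horizontal,
                 chrom = as.character(chrom),
                 pos = as.integer(base_pos + spacing * (seq_len(n_snps) - 1L)),
                 snp_ids = sprintf("rs%d_%02d", seed, seq_len(n_snps)),
                 effect_allele = drawn$a1, other_allele = drawn$a2,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario '%s': %d SNPs, adjacent LD target %.2f, causal SNP %d%s\n",
              x$kind, x$n_snps, x$ld_decay, x$causal_snp,
              if (x$kind == "linkage")
                sprintf(" (+%d at r = %.2f)", x$causal_snp2, x$causal_r) else ""))
  invisible(x)
}

#' Simulate genotype dosages for a scenario
#'
#' Draws `n` diploid individuals: two haplotypes per individual, each a
#' first-order autoregressive latent-Gaussian chain thresholded at the
#' per-SNP maf, with the latent correlations calibrated so the realized
#' allelic correlations match the scenario's adjacent-LD targets.
#' Dosages are the sum of the two haplotypes.  Uses the caller's RNG
#' stream (seed the caller to make output reproducible).
#'
#' @param scenario a [sim_scenario()].
#' @param n_individuals individuals to draw.
#' @param sample_prefix prefix for individual ids (row names); keep it
#'   distinct between the QTL and GWAS samples.
#' @return An `n x n_snps` dosage matrix with the scenario attached as
#'   attribute `scenario`.
#' @export
simulate_genotypes <- function(scenario, n_individuals,
                               sample_prefix = "S") {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (any(scenario$maf < 0.05 | scenario$maf > 0.5))
    stop("maf outside [0.05, 0.5]")
  n <- as.integer(n_individuals)
  m <- scenario$n_snps
  rho <- vapply(seq_len(m - 1L), function(j) {
    if (!is.na(scenario$adj_latent[j])) return(scenario$adj_latent[j])
    .latent_rho(scenario$adj_r[j], scenario$maf[j], scenario$maf[j + 1L])
  }, numeric(1))
  thr <- stats::qnorm(1 - scenario$maf)
  hap <- function() {
    Z <- matrix(0, n, m)
    Z[, 1] <- stats::rnorm(n)
    for (j in seq_len(m - 1L))
      Z[, j + 1L] <- rho[j] * Z[, j] +
        sqrt(1 - rho[j]^2) * stats::rnorm(n)
    sweep(Z, 2, thr, `>`) + 0
  }
  G <- hap() + hap()
  if (identical(scenario$kind, "linkage") && scenario$causal_r >= 1)
    G[, scenario$causal_snp2] <- G[, scenario$causal_snp]
  dimnames(G) <- list(paste0(sample_prefix, seq_len(n)), scenario$snp_ids)
  attr(G, "scenario") <- scenario
  G
}

#' Simulate the molecular trait and the phenotype
#'
#' Generates the methylation vector in the QTL sample and the phenotype
#' in the (disjoint) GWAS sample under the scenario's causal model; see
#' [sim_scenario()].  Overlapping individual ids are rejected — the
#' summary-data MR construction assumes independent samples.
#'
#' @param g_qtl,g_gwas dosage matrices from [simulate_genotypes()] for
#'   the two samples (same scenario).
#' @param scenario the [sim_scenario()].
#' @return A list with `m` (methylation, QTL sample) and `y` (phenotype,
#'   GWAS sample).
#' @export
simulate_traits <- function(g_qtl, g_gwas, scenario) {
  if (length(intersect(rownames(g_qtl), rownames(g_gwas))))
    stop("sample_overlap")
  c1 <- scenario$causal_snp
  m <- scenario$b_zx * g_qtl[, c1] +
    stats::rnorm(nrow(g_qtl), 0, scenario$sd_m)
  y <- switch(scenario$kind,
    pleiotropy = {
      m_star <- scenario$b_zx * g_gwas[, c1] +
        stats::rnorm(nrow(g_gwas), 0, scenario$sd_m)
      scenario$b_xy * m_star + scenario$horizontal * g_gwas[, c1] +
        stats::rnorm(nrow(g_gwas), 0, scenario$sd_y)
    },
    linkage = scenario$b_zy * g_gwas[, scenario$causal_snp2] +
      stats::rnorm(nrow(g_gwas), 0, scenario$sd_y),
    null = stats::rnorm(nrow(g_gwas), 0, scenario$sd_y))
  list(m = m, y = y)
}

#' Per-SNP regression summary statistics
#'
#' Simple linear regression of the trait on each SNP's dosage: effect,
#' standard error and two-sided p (t distribution, n - 2 df, floored at
#' the smallest positive double).  Monomorphic SNPs are omitted with a
#' message.  The output passes the validation of [read_gwas()]
#' unchanged.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()] (carries
#'   SNP metadata).
#' @param trait numeric trait vector aligned to the genotype rows.
#' @return A `gwas_sumstats` data frame.
#' @export
summary_stats <- function(genotypes, trait) {
  if (length(trait) != nrow(genotypes))
    stop("trait vector not aligned to genotype rows")
  scn <- attr(genotypes, "scenario")
  info <- if (!is.null(scn))
    data.frame(snp_id = scn$snp_ids, chrom = scn$chrom, pos = scn$pos,
               effect_allele = scn$effect_allele,
               other_allele = scn$other_allele, stringsAsFactors = FALSE)
  else
    data.frame(snp_id = colnames(genotypes), chrom = NA_character_,
               pos = NA_integer_, effect_allele = "A", other_allele = "G",
               stringsAsFactors = FALSE)
  n <- nrow(genotypes)
  gc <- sweep(genotypes, 2, colMeans(genotypes))
  sxx <- colSums(gc^2)
  mono <- sxx == 0
  if (any(mono)) {
    message(sprintf("summary_stats: omitting %d monomorphic SNP(s)", sum(mono)))
    gc <- gc[, !mono, drop = FALSE]; sxx <- sxx[!mono]
    info <- info[!mono, , drop = FALSE]
    genotypes <- genotypes[, !mono, drop = FALSE]
  }
  yc <- trait - mean(trait)
  sxy <- colSums(gc * yc)
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- beta / se
  p <- pmax(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  out <- data.frame(snp_id = info$snp_id, chrom = info$chrom,
                    pos = info$pos, effect_allele = info$effect_allele,
                    other_allele = info$other_allele,
                    eaf = colMeans(genotypes) / 2,
                    beta = beta, se = se, p = p, n = n,
                    p_inconsistent = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gwas_sumstats", "data.frame"),
            n_skipped = 0L, n_flagged = 0L)
}

#' Configuration of the miniature benchmark study
#'
#' Defaults describe a small but fully powered study: 3 traits, 60
#' probes (each its own cis locus of 12 SNPs), 2,000-individual QTL
#' cohorts, a 10,000-individual GWAS cohort, and a 500-individual LD
#' reference panel.  Effect sizes (`b_zx = 0.5` on the dosage scale,
#' mediated effect `b_xy = 0.3`, linkage GWAS effect `b_zy = 0.4` at LD
#' `causal_r = 0.5`) are chosen so instruments clear a 1e-10 QTL
#' threshold and SMR signals clear the Bonferroni level, the regime the
#' method assumes.  A `share_frac` fraction of probes keeps the same
#' causal variant in the secondary tissue.
#'
#' @param n_traits,n_probes,n_snps study dimensions.
#' @param n_qtl,n_gwas,n_ref,n_expr cohort sizes (QTL tissues, GWAS, LD
#'   reference, expression cohort).
#' @param share_frac fraction of probes whose secondary-tissue QTL
#'   shares the primary causal variant.
#' @param frac_pleio,frac_link fractions of (non-multi-trait) probes
#'   assigned the pleiotropy / linkage architecture for their target
#'   trait; the remainder are null.
#' @param n_multi probes made pleiotropic for two traits at once.
#' @param maf_range,ld_decay,b_zx,b_xy,b_zy,causal_r,sd_m,sd_y generative
#'   parameters, see [sim_scenario()].
#' @return A named list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_traits = 3L, n_probes = 60L, n_snps = 12L,
                             n_qtl = 2000L, n_gwas = 10000L,
                             n_ref = 500L, n_expr = 2000L,
                             share_frac = 0.9, frac_pleio = 0.4,
                             frac_link = 0.3, n_multi = 4L,
                             maf_range = c(0.1, 0.45), ld_decay = 0.8,
                             b_zx = 0.5, b_xy = 0.3, b_zy = 0.4,
                             causal_r = 0.5, sd_m = 1, sd_y = 1) {
  structure(as.list(environment()), class = "benchmark_config")
}

# deterministically scramble allele orientation in a summary table so
# harmonization is exercised: every 3rd SNP swapped (beta negated),
# every 7th strand-complemented
.scramble_orientation <- function(df) {
  i <- seq_len(nrow(df))
  swap <- i %% 3L == 0L
  df[swap, c("effect_allele", "other_allele")] <-
    df[swap, c("other_allele", "effect_allele")]
  df$beta[swap] <- -df$beta[swap]
  df$eaf[swap] <- 1 - df$eaf[swap]
  comp <- i %% 7L == 0L
  df$effect_allele[comp] <- unname(.complement[df$effect_allele[comp]])
  df$other_allele[comp] <- unname(.complement[df$other_allele[comp]])
  df
}

#' Generate a complete miniature study on disk
#'
#' Writes, under one seed, everything a full pipeline run consumes:
#' per-trait GWAS summary files (`.ma` dialect with positions), primary-
#' and secondary-tissue methylation cis-QTL tables, an expression QTL
#' table (one probe per gene, driven by the gene's first methylation
#' probe's causal variant), an LD reference dosage matrix with SNP info,
#' and a truth table of generative labels per (probe, trait).  Probe
#' loci are independent genotype blocks; each probe targets one trait
#' (or two, for the `n_multi` multi-trait probes) under its assigned
#' architecture and is null for all other traits.  Allele orientation is
#' deliberately scrambled in the GWAS and secondary tables to exercise
#' harmonization.  Fixed seed implies a byte-identical fixture set.
#'
#' @param dir output directory (created).
#' @param config a [benchmark_config()].
#' @param seed integer seed.
#' @return Invisibly, a list with the file paths (`gwas_paths`,
#'   `mqtl_primary`, `mqtl_secondary`, `eqtl_expr`, `ld_dosage`,
#'   `ld_info`, `truth`), the `truth` data frame and the probe plan.
#' @export
make_benchmark <- function(dir, config = benchmark_config(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- config
  P <- cf$n_probes; Tn <- cf$n_traits
  traits <- sprintf("trait%d", seq_len(Tn))

  # probe plan: target trait round-robin; first n_multi probes are
  # pleiotropic for two traits; the rest cycle through the architecture
  # fractions
  n_rem <- P - cf$n_multi
  n_pl <- round(cf$frac_pleio * n_rem)
  n_li <- round(cf$frac_link * n_rem)
  kinds <- c(rep("pleiotropy", cf$n_multi),
             rep(c("pleiotropy", "linkage", "null"),
                 times = c(n_pl, n_li, n_rem - n_pl - n_li)))
  share_gap <- max(2L, round(1 / max(1 - cf$share_frac, 1e-9)))
  plan <- data.frame(probe_id = sprintf("cg%05d", seq_len(P)),
                     kind = kinds,
                     trait = traits[(seq_len(P) - 1L) %% Tn + 1L],
                     trait2 = NA_character_,
                     gene = sprintf("gene%03d", (seq_len(P) - 1L) %/% 2L + 1L),
                     shared = seq_len(P) %% share_gap != 0L,
                     stringsAsFactors = FALSE)
  multi <- seq_len(cf$n_multi)
  plan$trait2[multi] <- traits[match(plan$trait[multi], traits) %% Tn + 1L]

  .with_seed(seed, {
    scn <- vector("list", P)
    g_gwas <- vector("list", P); g_ref <- vector("list", P)
    mqtl1 <- vector("list", P); mqtl2 <- vector("list", P)
    eqtl <- vector("list", P %/% 2L + 1L)
    contrib <- matrix(0, cf$n_gwas, Tn, dimnames = list(NULL, traits))

    for (i in seq_len(P)) {
      s <- sim_scenario(kind = plan$kind[i], n_snps = cf$n_snps,
                        maf_range = cf$maf_range, ld_decay = cf$ld_decay,
                        b_zx = cf$b_zx, b_xy = cf$b_xy, b_zy = cf$b_zy,
                        causal_r = cf$causal_r,
                        n_qtl = cf$n_qtl, n_gwas = cf$n_gwas,
                        sd_m = cf$sd_m, sd_y = cf$sd_y,
                        chrom = as.character((i - 1L) %% 5L + 1L),
                        base_pos = 1e6 + ((i - 1L) %/% 5L) * 3e6,
                        seed = (seed %% 20000L) * 100000L + i)
      scn[[i]] <- s
      gq1 <- simulate_genotypes(s, cf$n_qtl, sample_prefix = "q1_")
      gq2 <- simulate_genotypes(s, cf$n_qtl, sample_prefix = "q2_")
      gg <- simulate_genotypes(s, cf$n_gwas, sample_prefix = "g_")
      g_gwas[[i]] <- gg
      g_ref[[i]] <- simulate_genotypes(s, cf$n_ref, sample_prefix = "ref_")
      c1 <- s$causal_snp

      m1 <- cf$b_zx * gq1[, c1] + stats::rnorm(cf$n_qtl, 0, cf$sd_m)
      c2nd <- if (plan$shared[i]) c1 else max(1L, c1 - 2L)
      m2 <- cf$b_zx * gq2[, c2nd] + stats::rnorm(cf$n_qtl, 0, cf$sd_m)

      probe_row <- function(ss) {
        ss$probe_id <- plan$probe_id[i]
        ss$probe_chrom <- s$chrom
        ss$probe_pos <- s$pos[s$causal_snp]
        ss$gene <- plan$gene[i]
        ss
      }
      mqtl1[[i]] <- probe_row(summary_stats(gq1, m1))
      mqtl2[[i]] <- probe_row(summary_stats(gq2, m2))

      # expression probe for the gene's first methylation probe
      if (i %% 2L == 1L) {
        ge <- simulate_genotypes(s, cf$n_expr, sample_prefix = "e_")
        ex <- cf$b_zx * ge[, c1] + stats::rnorm(cf$n_expr, 0, cf$sd_m)
        es <- summary_stats(ge, ex)
        es$probe_id <- sprintf("expr%03d", (i - 1L) %/% 2L + 1L)
        es$probe_chrom <- s$chrom
        es$probe_pos <- s$pos[s$causal_snp]
        es$gene <- plan$gene[i]
        eqtl[[(i - 1L) %/% 2L + 1L]] <- es
      }

      # phenotype contributions in the shared GWAS cohort
      tgt <- c(plan$trait[i], plan$trait2[i])
      tgt <- tgt[!is.na(tgt)]
      if (s$kind == "pleiotropy") {
        m_star <- cf$b_zx * gg[, c1] + stats::rnorm(cf$n_gwas, 0, cf$sd_m)
        for (tr in tgt) contrib[, tr] <- contrib[, tr] + cf$b_xy * m_star
      } else if (s$kind == "linkage") {
        for (tr in tgt) contrib[, tr] <- contrib[, tr] +
          cf$b_zy * gg[, s$causal_snp2]
      }
    }

    # per-trait GWAS summary statistics over all loci
    G_all <- do.call(cbind, g_gwas)
    info_all <- do.call(rbind, lapply(scn, function(s)
      data.frame(snp_id = s$snp_ids, chrom = s$chrom, pos = s$pos,
                 effect_allele = s$effect_allele,
                 other_allele = s$other_allele, stringsAsFactors = FALSE)))
    gwas_paths <- character(Tn); names(gwas_paths) <- traits
    for (tr in traits) {
      y <- contrib[, tr] + stats::rnorm(cf$n_gwas, 0, cf$sd_y)
      blocks <- lapply(seq_len(P), function(i)
        summary_stats(g_gwas[[i]], y))
      gs <- do.call(rbind, blocks)
      class(gs) <- c("gwas_sumstats", "data.frame")
      gs <- .scramble_orientation(gs)
      gwas_paths[tr] <- file.path(dir, paste0("gwas_", tr, ".ma"))
      write_gwas(gs, gwas_paths[tr])
    }

    qtl_cols <- function(lst, scramble = FALSE) {
      df <- do.call(rbind, lst)
      if (scramble) df <- .scramble_orientation(df)
      class(df) <- "data.frame"
      df
    }
    p1 <- file.path(dir, "mqtl_primary.tsv")
    p2 <- file.path(dir, "mqtl_secondary.tsv")
    pe <- file.path(dir, "eqtl_expr.tsv")
    write_qtl(qtl_cols(mqtl1), p1)
    write_qtl(qtl_cols(mqtl2, scramble = TRUE), p2)
    write_qtl(qtl_cols(eqtl[!vapply(eqtl, is.null, logical(1))]), pe)

    ref <- ld_ref(do.call(cbind, g_ref),
                  snp_info = info_all)
    pl <- file.path(dir, "ld_dosages.tsv")
    pi_ <- file.path(dir, "ld_snps.tsv")
    write_ld_dosage(ref, pl, pi_)

    truth <- do.call(rbind, lapply(seq_len(P), function(i) {
      lab <- ifelse(traits %in% c(plan$trait[i], plan$trait2[i]),
                    plan$kind[i], "null")
      data.frame(probe_id = plan$probe_id[i], trait_id = traits,
                 kind = lab, gene = plan$gene[i],
                 causal_snp = scn[[i]]$snp_ids[scn[[i]]$causal_snp],
                 shared_secondary = plan$shared[i],
                 stringsAsFactors = FALSE)
    }))
    pt <- file.path(dir, "truth.tsv")
    .write_tsv(truth, pt)
    yaml::write_yaml(unclass(cf), file.path(dir, "benchmark_config.yaml"))

    invisible(list(gwas_paths = gwas_paths, mqtl_primary = p1,
                   mqtl_secondary = p2, eqtl_expr = pe,
                   ld_dosage = pl, ld_info = pi_, truth_path = pt,
                   truth = truth, plan = plan))
  })
}
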