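# Builders shared across test files.  All randomness is seeded by the
# caller; fixtures are constructed in code, nothing is stored on disk.

make_assoc <- function(snp_id = "rs1", chrom = "1", pos = 100L,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.05, p = NULL,
                       n = 1000) {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, p = p, n = n,
             p_inconsistent = FALSE, stringsAsFactors = FALSE)
}

as_gwas <- function(df) structure(df, class = c("gwas_sumstats", "data.frame"))

as_qtl <- function(df) structure(df, class = c("qtl_sumstats", "data.frame"))

# attach probe metadata to a summary_stats() table, making QTL rows
probeify <- function(ss, probe_id, scenario, gene = NA_character_) {
  ss$probe_id <- probe_id
  ss$probe_chrom <- scenario$chrom
  ss$probe_pos <- scenario$pos[scenario$causal_snp]
  ss$gene <- gene
  ss
}

# simulate one locus end to end and return summary statistics plus an
# LD reference; uses the caller's RNG stream
sim_locus_stats <- function(scenario, n_ref = 0) {
  gq <- simulate_genotypes(scenario, scenario$n_qtl, sample_prefix = "q_")
  gg <- simulate_genotypes(scenario, scenario$n_gwas, sample_prefix = "g_")
  tr <- simulate_traits(gq, gg, scenario)
  ref <- if (n_ref > 0)
    ld_ref(simulate_genotypes(scenario, n_ref, sample_prefix = "r_"),
           snp_info = data.frame(snp_id = scenario$snp_ids,
                                 effect_allele = scenario$effect_allele,
                                 other_allele = scenario$other_allele,
                                 stringsAsFactors = FALSE))
  list(qtl = summary_stats(gq, tr$m), gwas = summary_stats(gg, tr$y),
       ref = ref)
}

# one SMR replicate: instrument = top QTL SNP; returns the SMR row plus
# the harmonized frame and reference for HEIDI follow-up
smr_replicate_once <- function(scenario, n_ref = 0,
                               config = smr_config(qtl_p_threshold = 1e-4)) {
  st <- sim_locus_stats(scenario, n_ref)
  frame <- data.frame(snp_id = st$qtl$snp_id, pos = st$qtl$pos,
                      effect_allele = st$qtl$effect_allele,
                      b_qtl = st$qtl$beta, se_qtl = st$qtl$se,
                      p_qtl = st$qtl$p,
                      b_gwas = st$gwas$beta, se_gwas = st$gwas$se,
                      p_gwas = st$gwas$p, stringsAsFactors = FALSE)
  inst <- select_instrument(frame, config$qtl_p_threshold)
  if (is.na(inst)) return(NULL)
  top <- frame[frame$snp_id == inst, ]
  s <- smr_test(top$b_gwas, top$se_gwas, top$b_qtl, top$se_qtl)
  list(frame = frame, instrument = inst, smr = s, ref = st$ref)
}

# HEIDI p for one replicate (NA when not testable)
heidi_replicate_once <- function(scenario, ref, config = smr_config()) {
  rep <- smr_replicate_once(scenario, n_ref = 0, config = config)
  if (is.null(rep)) return(NA_real_)
  sel <- heidi_select_snps(rep$frame, rep$instrument, ref, config)
  if (sel$status != "ok") return(NA_real_)
  ids <- c(rep$instrument, sel$snps)
  R <- ld_matrix(ref, ids,
                 effect_alleles = rep$frame$effect_allele[match(ids, rep$frame$snp_id)])
  heidi_test(rep$frame, rep$instrument, sel$snps, R, config)$p_heidi
}
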