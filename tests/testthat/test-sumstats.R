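test_that("GWAS reader returns valid rows, skips malformed ones, flags inconsistent p", {
  path <- withr::local_tempfile(fileext = ".ma")
  tab <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                    A1 = c("A", "C", "G", "A", "T"),
                    A2 = c("G", "T", "A", "C", "C"),
                    freq = c(0.3, 0.5, 0.2, 0.4, 0.1),
                    b = c(0.10, -0.05, 0.02, 0.30, 0.15),
                    se = c(0.05, 0.02, 0.01, 0, 0.05),
                    p = c(0.0455, 0.0124, 0.0455, 0.01, 2e-300),
                    n = 1000)
  write.table(tab, path, row.names = FALSE, quote = FALSE)
  expect_message(g <- read_gwas(path), "skipped 1 malformed")
  # rs4 (se = 0) dropped; rs5 retained but its stored p (2e-300) is far
  # from the Wald p of |z| = 3
  expect_equal(nrow(g), 4L)
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_false("rs4" %in% g$snp_id)
  expect_true(g$p_inconsistent[g$snp_id == "rs5"])
  expect_false(any(g$p_inconsistent[g$snp_id != "rs5"]))

  # a missing mandatory column is a hard error
  bad <- tab[, setdiff(names(tab), "se")]
  path2 <- withr::local_tempfile(fileext = ".ma")
  write.table(bad, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_gwas(path2), "mandatory column")
})

test_that("QTL reader groups by probe, rejects duplicates, enforces the cis window", {
  scn <- sim_scenario("null", n_snps = 5, n_qtl = 200, seed = 5)
  set.seed(11)
  g <- simulate_genotypes(scn, 200, "q_")
  ss <- summary_stats(g, rnorm(200))
  q <- rbind(probeify(ss, "cg01", scn), probeify(ss, "cg02", scn))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qtl(as_qtl(q), path)
  out <- read_qtl(path)
  expect_equal(sort(unique(out$probe_id)), c("cg01", "cg02"))
  expect_equal(as.vector(table(out$probe_id)), c(5L, 5L))

  # duplicate (probe, SNP) row names the offending pair
  write_qtl(as_qtl(rbind(q, q[1, ])), path)
  expect_error(read_qtl(path), "cg01.*rs5_01|rs5_01.*cg01")

  # a SNP 600 kb away from the probe falls outside a 500 kb window
  far <- probeify(ss[1, ], "cg03", scn)
  far$pos <- far$probe_pos + 600000L
  write_qtl(as_qtl(rbind(q, far)), path)
  expect_message(out <- read_qtl(path, cis_window = 5e5), "excluded 1 SNP")
  expect_false("cg03" %in% out$probe_id)
  expect_equal(attr(out, "n_cis_excluded"), 1L)
})

test_that("write/read round trip preserves ids exactly and numerics to 1e-12", {
  set.seed(21)
  df <- make_assoc(snp_id = sprintf("rs%d", 1:6),
                   effect_allele = c("A", "C", "G", "T", "A", "C"),
                   other_allele = c("G", "T", "C", "G", "C", "A"),
                   eaf = runif(6), beta = rnorm(6) * 1e-3,
                   se = runif(6, 1e-4, 1e-2), p = runif(6),
                   pos = 1:6 * 1000L)
  path <- withr::local_tempfile(fileext = ".ma")
  write_gwas(as_gwas(df), path)
  back <- read_gwas(path)
  expect_identical(back$snp_id, df$snp_id)
  expect_identical(back$effect_allele, df$effect_allele)
  expect_identical(back$other_allele, df$other_allele)
  for (col in c("eaf", "beta", "se", "p"))
    expect_equal(back[[col]], df[[col]], tolerance = 1e-12)
})

test_that("harmonize flips swapped alleles, resolves strand, excludes mismatches", {
  a <- make_assoc(effect_allele = "A", other_allele = "G", eaf = 0.7, beta = 0.1)
  b <- make_assoc(effect_allele = "G", other_allele = "A", eaf = 0.3, beta = 0.2)
  h <- harmonize(a, b)
  expect_false(h$excluded)
  expect_equal(h$b$beta, -0.2)
  expect_equal(h$b$eaf, 0.7)
  expect_equal(h$b$effect_allele, "A")

  # strand-complementary non-palindromic pair resolves by complementing
  b2 <- make_assoc(effect_allele = "T", other_allele = "C", eaf = 0.7, beta = 0.2)
  h2 <- harmonize(a, b2)
  expect_false(h2$excluded)
  expect_equal(h2$b$beta, 0.2)

  # irreconcilable allele sets
  b3 <- make_assoc(effect_allele = "A", other_allele = "C")
  expect_identical(harmonize(a, b3)$reason, "allele_mismatch")

  # harmonization is involutive in effect direction
  h_again <- harmonize(h$a, h$b)
  expect_false(h_again$excluded)
  expect_equal(h_again$b$beta, h$b$beta)
  expect_equal(h_again$b$eaf, h$b$eaf)
})

test_that("palindromic pairs are resolved by frequency only when informative", {
  a <- make_assoc(effect_allele = "A", other_allele = "T", eaf = 0.2, beta = 0.1)
  # same orientation, frequencies agree
  b <- make_assoc(effect_allele = "A", other_allele = "T", eaf = 0.22, beta = 0.3)
  expect_false(harmonize(a, b)$excluded)
  expect_equal(harmonize(a, b)$b$beta, 0.3)
  # frequencies on opposite sides of 0.5: the strand was misread, flip
  b2 <- make_assoc(effect_allele = "A", other_allele = "T", eaf = 0.8, beta = 0.3)
  h2 <- harmonize(a, b2)
  expect_false(h2$excluded)
  expect_equal(h2$b$beta, -0.3)
  expect_equal(h2$b$eaf, 0.2)
  # eaf = 0.5 on both sides is unresolvable
  a3 <- make_assoc(effect_allele = "A", other_allele = "T", eaf = 0.5)
  b3 <- make_assoc(effect_allele = "A", other_allele = "T", eaf = 0.5)
  expect_identical(harmonize(a3, b3)$reason, "ambiguous_palindrome")
  # missing frequency drops the pair
  b4 <- make_assoc(effect_allele = "A", other_allele = "T", eaf = NA)
  expect_identical(harmonize(a, b4)$reason, "ambiguous_palindrome")
})

test_that("LD correlations: identity, allele recoding, hand-computed value, symmetry", {
  x <- c(0, 1, 2, 1, 0, 2)
  y <- c(0, 1, 1, 1, 0, 2)
  ref <- ld_ref(cbind(s1 = x, s2 = x, s3 = 2 - x, s4 = y))
  expect_equal(ld_cor(ref, "s1", "s2"), 1.0)
  expect_equal(ld_cor(ref, "s1", "s3"), -ld_cor(ref, "s1", "s2"))
  # direct Pearson formula, written out
  n <- length(x)
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(ld_cor(ref, "s1", "s4"), r_hand, tolerance = 1e-12)
  expect_equal(ld_cor(ref, "s4", "s1"), ld_cor(ref, "s1", "s4"))
  # invariant to individual ordering
  perm <- c(4, 2, 6, 1, 3, 5)
  ref_p <- ld_ref(cbind(s1 = x[perm], s4 = y[perm]))
  expect_equal(ld_cor(ref_p, "s1", "s4"), r_hand, tolerance = 1e-12)
  # monomorphic SNP is an error
  ref_m <- ld_ref(cbind(s1 = x, s5 = rep(1, 6)))
  expect_error(ld_cor(ref_m, "s1", "s5"), "monomorphic")
})

test_that("VCF and dosage-matrix LD references agree", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "I1", "I2", "I3", "I4", sep = "\t"),
    paste("1", "100", "rs1", "G", "A", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "rs2", "T", "C", ".", ".", ".", "GT",
          "0/1", "0/1", "0/0", "1/1", sep = "\t")), vcf)
  ref_v <- read_ld_vcf(vcf)
  expect_equal(unname(ref_v$dosages[, "rs1"]), c(0, 1, 2, 1))
  expect_equal(ref_v$snp_info$effect_allele, c("A", "C"))
  ref_d <- ld_ref(cbind(rs1 = c(0, 1, 2, 1), rs2 = c(1, 1, 0, 2)))
  expect_equal(ld_cor(ref_v, "rs1", "rs2"), ld_cor(ref_d, "rs1", "rs2"))
})
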