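test_that("maf bounds are enforced", {
  expect_error(sim_scenario("null", maf = c(0.6, 0.3, 0.3), n_snps = 3),
               "maf outside")
  expect_error(sim_scenario("null", maf = rep(0.01, 3), n_snps = 3),
               "maf outside")
})

test_that("independent SNPs stay independent and dosage means match 2*maf", {
  set.seed(101)
  scn <- sim_scenario("null", n_snps = 6, ld_decay = 0, seed = 2)
  g <- simulate_genotypes(scn, 5000)
  r_adj <- sapply(1:5, function(j) cor(g[, j], g[, j + 1]))
  expect_lt(mean(abs(r_adj)), 0.05)
  # column means within 3 binomial SEs of 2*maf
  se3 <- 3 * sqrt(2 * scn$maf * (1 - scn$maf) / 5000)
  expect_true(all(abs(colMeans(g) - 2 * scn$maf) < se3))
})

test_that("realized LD matches a large-sample oracle of the same model", {
  set.seed(102)
  scn <- sim_scenario("null", n_snps = 10, ld_decay = 0.9, seed = 3)
  g <- simulate_genotypes(scn, 5000)
  oracle <- cor(simulate_genotypes(scn, 50000))
  expect_lt(max(abs(cor(g) - oracle)), 0.1)
  # adjacent realized r is near the requested target itself
  r_adj <- sapply(1:9, function(j) cor(g[, j], g[, j + 1]))
  expect_true(all(abs(r_adj - 0.9) < 0.1))
})

test_that("linkage scenarios realize the requested causal LD", {
  set.seed(103)
  for (r_target in c(0.3, 0.6, 0.9)) {
    scn <- sim_scenario("linkage", n_snps = 8, causal_r = r_target,
                        n_gwas = 4000, seed = 4)
    g <- simulate_genotypes(scn, 4000)
    expect_lt(abs(cor(g[, scn$causal_snp], g[, scn$causal_snp2]) - r_target),
              0.05)
  }
  # perfect LD: duplicated dosages
  scn1 <- sim_scenario("linkage", n_snps = 8, causal_r = 1, seed = 4)
  g1 <- simulate_genotypes(scn1, 500)
  expect_equal(g1[, scn1$causal_snp], g1[, scn1$causal_snp2])
})

test_that("trait generation follows the causal model", {
  set.seed(104)
  # no QTL effect: slope near zero
  scn0 <- sim_scenario("null", n_snps = 4, b_zx = 0, n_qtl = 3000, seed = 5)
  gq <- simulate_genotypes(scn0, 3000, "q_")
  gg <- simulate_genotypes(scn0, 1000, "g_")
  tr <- simulate_traits(gq, gg, scn0)
  fit <- lm(tr$m ~ gq[, scn0$causal_snp])
  expect_lt(abs(coef(fit)[2]), 3 * summary(fit)$coefficients[2, 2])

  # per-SNP OLS recovers b_zx at the causal SNP within 3 SEs
  scn <- sim_scenario("pleiotropy", b_zx = 0.5, b_xy = 0.3,
                      n_qtl = 10000, n_snps = 6, seed = 6)
  gq <- simulate_genotypes(scn, 10000, "q_")
  gg <- simulate_genotypes(scn, 1000, "g_")
  tr <- simulate_traits(gq, gg, scn)
  ss <- summary_stats(gq, tr$m)
  i <- scn$causal_snp
  expect_lt(abs(ss$beta[i] - 0.5), 3 * ss$se[i])

  # overlapping samples are rejected
  g_same <- simulate_genotypes(scn, 100, "x_")
  expect_error(simulate_traits(g_same, g_same, scn), "sample_overlap")
})

test_that("in the noiseless limit every instrument gives the same ratio", {
  set.seed(105)
  scn <- sim_scenario("pleiotropy", n_snps = 8, sd_m = 1, sd_y = 1, seed = 7)
  g <- simulate_genotypes(scn, 2000)
  m <- scn$b_zx * g[, scn$causal_snp]          # no measurement noise
  y <- scn$b_xy * m                            # same sample, pure mediation
  sm <- summary_stats(g, m)
  sy <- summary_stats(g, y)
  ld_to_causal <- cor(g)[, scn$causal_snp]
  keep <- abs(ld_to_causal) > 0.2
  expect_equal(sy$beta[keep] / sm$beta[keep],
               rep(scn$b_xy, sum(keep)), tolerance = 1e-9)
})

test_that("summary statistics are well calibrated and round-trip the reader", {
  # permuted traits give uniform p-values
  for (seed in c(201, 202)) {
    set.seed(seed)
    scn <- sim_scenario("null", n_snps = 20, ld_decay = 0, seed = seed)
    g <- simulate_genotypes(scn, 400)
    p <- unlist(lapply(1:25, function(i) summary_stats(g, sample(rnorm(400)))$p))
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  }
  # exact linear trait: beta = 2 exactly, p floored above zero
  set.seed(203)
  scn <- sim_scenario("null", n_snps = 4, seed = 8)
  g <- simulate_genotypes(scn, 500)
  ss <- summary_stats(g, 2 * g[, 2])
  expect_equal(ss$beta[2], 2, tolerance = 1e-12)
  expect_gte(ss$p[2], .Machine$double.xmin)
  expect_lt(ss$p[2], 1e-100)
  # monomorphic SNPs are omitted with a message
  g2 <- g; g2[, 3] <- 1
  expect_message(ss2 <- summary_stats(g2, rnorm(500)), "monomorphic")
  expect_equal(nrow(ss2), 3L)
  # write/read round trip with zero skips
  path <- withr::local_tempfile(fileext = ".ma")
  write_gwas(summary_stats(g, rnorm(500)), path)
  back <- read_gwas(path)
  expect_equal(nrow(back), 4L)
  expect_equal(attr(back, "n_skipped"), 0L)
})

test_that("the two synthetic tissues agree in QTL sign at shared-causal probes", {
  dir <- withr::local_tempdir()
  bench <- make_benchmark(dir, benchmark_config(
    n_traits = 2, n_probes = 20, n_qtl = 800, n_gwas = 1000,
    n_ref = 200, n_expr = 300, n_multi = 2), seed = 11)
  q1 <- suppressMessages(read_qtl(bench$mqtl_primary))
  q2 <- suppressMessages(read_qtl(bench$mqtl_secondary))
  truth <- unique(bench$truth[bench$truth$shared_secondary,
                              c("probe_id", "causal_snp")])
  agree <- logical(0)
  for (i in seq_len(nrow(truth))) {
    a <- q1[q1$probe_id == truth$probe_id[i] & q1$snp_id == truth$causal_snp[i], ]
    b <- q2[q2$probe_id == truth$probe_id[i] & q2$snp_id == truth$causal_snp[i], ]
    h <- harmonize(a, b)
    if (!h$excluded) agree <- c(agree, sign(h$a$beta) == sign(h$b$beta))
  }
  expect_gt(length(agree), 10)
  expect_gt(mean(agree), 0.95)
})
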