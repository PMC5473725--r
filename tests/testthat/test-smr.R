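test_that("SMR statistic matches its closed form and worked example", {
  # worked example: z1 = 5, z2 = 10 -> chi2 = 2500/125 = 20
  s <- smr_test(0.03, 0.006, 0.5, 0.05)
  expect_equal(s$b_smr, 0.06)
  expect_equal(s$chi2_smr, 20.0)
  # chi-square survival value frozen from an independent oracle
  expect_equal(s$p_smr, 7.744216431044088e-06, tolerance = 1e-10)

  # no GWAS effect: null estimate, p = 1
  s0 <- smr_test(0, 0.01, 0.5, 0.05)
  expect_equal(s0$b_smr, 0)
  expect_equal(s0$chi2_smr, 0)
  expect_equal(s0$p_smr, 1)

  # |z1| = |z2| = z gives chi2 = z^2 / 2
  s2 <- smr_test(0.2, 0.05, -0.4, 0.1)
  expect_equal(s2$chi2_smr, 16 / 2)

  expect_error(smr_test(0.1, 0.05, 0, 0.05), "degenerate_instrument")
  expect_error(smr_test(0.1, -0.01, 0.5, 0.05), "positive")
})

test_that("SMR invariants hold over random inputs", {
  set.seed(42)
  for (i in 1:200) {
    bg <- rnorm(1); sg <- runif(1, 0.01, 0.5)
    bq <- rnorm(1); sq <- runif(1, 0.01, 0.5)
    if (bq == 0) next
    s <- smr_test(bg, sg, bq, sq)
    z1 <- bg / sg; z2 <- bq / sq
    # t^2 equals the chi-square statistic
    expect_equal(s$t_smr^2, s$chi2_smr, tolerance = 1e-9)
    # never more significant than the weaker arm
    expect_lte(s$chi2_smr, min(z1^2, z2^2) + 1e-12)
    # sign composition
    if (bg != 0)
      expect_equal(sign(s$b_smr), sign(bg) * sign(bq))
    # scale invariance in the QTL arm
    c_ <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    s_c <- smr_test(bg, sg, c_ * bq, abs(c_) * sq)
    expect_equal(s_c$chi2_smr, s$chi2_smr, tolerance = 1e-9)
    expect_equal(s_c$p_smr, s$p_smr, tolerance = 1e-9)
    expect_equal(s_c$b_smr, s$b_smr / c_, tolerance = 1e-9)
    expect_gt(s$p_smr, 0)
    expect_lte(s$p_smr, 1)
  }
})

test_that("instrument selection applies the QTL threshold and tie-breaks", {
  frame <- data.frame(snp_id = c("a", "b", "c"), pos = c(300L, 100L, 200L),
                      b_qtl = c(0.5, 0.3, 0.2), se_qtl = c(0.05, 0.05, 0.05),
                      p_qtl = c(5e-11, 2e-9, 1e-3), stringsAsFactors = FALSE)
  # best shared SNP at p = 5e-11 clears a 1e-10 blood-style threshold
  expect_identical(select_instrument(frame, 1e-10), "a")
  # best p = 2e-9 does not
  out <- select_instrument(frame[-1, ], 1e-10)
  expect_true(is.na(out))
  expect_identical(attr(out, "reason"), "no_qtl_below_threshold")
  # exact p tie: larger |b/se| wins
  tie <- data.frame(snp_id = c("x", "y"), pos = c(2L, 1L),
                    b_qtl = c(0.30, 0.35), se_qtl = c(0.05, 0.05),
                    p_qtl = c(1e-12, 1e-12), stringsAsFactors = FALSE)
  expect_identical(select_instrument(tie, 1e-10), "y")
  # residual tie: smaller position wins
  tie2 <- tie; tie2$b_qtl <- c(0.3, 0.3)
  expect_identical(select_instrument(tie2, 1e-10), "y")
  tie2$pos <- c(1L, 2L)
  expect_identical(select_instrument(tie2, 1e-10), "x")
  # empty intersection
  out2 <- select_instrument(NULL, 1e-10)
  expect_identical(attr(out2, "reason"), "no_shared_snps")
})

test_that("classification follows the SMR/HEIDI decision rule", {
  thr <- 1.42e-6
  expect_identical(classify_smr(1e-7, 0.3, thr), "pleiotropic")
  expect_identical(classify_smr(1e-7, 0.01, thr), "linkage")
  expect_identical(classify_smr(0.5, NA, thr), "not_significant")
  expect_identical(classify_smr(1e-7, NA, thr), "untested")
  # boundary: heidi_p exactly at the threshold is linkage (rule is >)
  expect_identical(classify_smr(1e-7, 0.05, thr), "linkage")
})
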