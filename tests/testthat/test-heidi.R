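ar_corr <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

test_that("identical SMR estimates from all instruments give p = 1", {
  # noiseless single-causal construction: b_gwas exactly proportional to
  # b_qtl at every SNP, so every instrument yields the same ratio
  k <- 6
  frame <- data.frame(snp_id = paste0("s", 1:k), pos = 1:k * 100L,
                      b_qtl = c(0.5, 0.4, 0.3, 0.35, 0.25, 0.2),
                      se_qtl = 0.04,
                      b_gwas = 0.3 * c(0.5, 0.4, 0.3, 0.35, 0.25, 0.2),
                      se_gwas = 0.02, stringsAsFactors = FALSE)
  R <- ar_corr(k, 0.7); dimnames(R) <- list(frame$snp_id, frame$snp_id)
  h <- heidi_test(frame, "s1", paste0("s", 2:5), R)
  expect_identical(h$status, "ok")
  expect_true(all(h$d_stats == 0))
  expect_equal(h$p_heidi, 1)
})

test_that("too few alternative instruments skips the test", {
  frame <- data.frame(snp_id = c("s1", "s2"), pos = c(1L, 2L),
                      b_qtl = c(0.5, 0.4), se_qtl = 0.04,
                      b_gwas = c(0.1, 0.1), se_gwas = 0.02,
                      stringsAsFactors = FALSE)
  R <- ar_corr(2, 0.5); dimnames(R) <- list(frame$snp_id, frame$snp_id)
  h <- heidi_test(frame, "s1", "s2", R)
  expect_identical(h$status, "too_few_snps")
  expect_true(is.na(h$p_heidi))
})

test_that("alternative-instrument selection applies r2 bounds, QTL threshold, truncation", {
  set.seed(31)
  n <- 800
  top <- rbinom(n, 2, 0.4)
  mix <- function(w) ifelse(runif(n) < w, top, rbinom(n, 2, 0.4))
  D <- cbind(top = top, dup = top, mid1 = mix(0.75), mid2 = mix(0.7),
             mid3 = mix(0.65), mid4 = mix(0.6), far = rbinom(n, 2, 0.4))
  ref <- ld_ref(D)
  r2 <- sapply(colnames(D), function(s) ld_cor(ref, s, "top")^2)
  frame <- data.frame(snp_id = colnames(D), pos = seq_len(ncol(D)) * 10L,
                      b_qtl = 0.5, se_qtl = 0.04,
                      p_qtl = c(1e-20, 1e-12, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6),
                      b_gwas = 0.1, se_gwas = 0.02, stringsAsFactors = FALSE)
  cfg <- smr_config()
  sel <- heidi_select_snps(frame, "top", ref, cfg)
  manual <- setdiff(colnames(D), "top")
  manual <- manual[r2[manual] >= cfg$r2_min & r2[manual] <= cfg$r2_max &
                     frame$p_qtl[match(manual, frame$snp_id)] < cfg$heidi_qtl_p]
  expect_setequal(sel$snps, manual)
  expect_false("dup" %in% sel$snps)   # r2 = 1 > 0.9
  expect_false("far" %in% sel$snps)   # r2 ~ 0 < 0.05
  # ranked by QTL significance and truncated to max_snps
  cfg2 <- smr_config(max_snps = 2, min_snps = 2)
  sel2 <- heidi_select_snps(frame, "top", ref, cfg2)
  ranked <- manual[order(frame$p_qtl[match(manual, frame$snp_id)])]
  expect_identical(sel2$snps, ranked[1:2])
  # a QTL p above the inclusion threshold disqualifies
  frame2 <- frame; frame2$p_qtl[frame2$snp_id == "mid1"] <- 0.01
  expect_false("mid1" %in% heidi_select_snps(frame2, "top", ref, cfg)$snps)
})

test_that("HEIDI p is invariant to instrument ordering", {
  set.seed(7)
  k <- 8
  frame <- data.frame(snp_id = paste0("s", 1:k), pos = 1:k * 50L,
                      b_qtl = runif(k, 0.2, 0.6), se_qtl = 0.04,
                      b_gwas = rnorm(k, 0.08, 0.02), se_gwas = 0.02,
                      stringsAsFactors = FALSE)
  R <- ar_corr(k, 0.6); dimnames(R) <- list(frame$snp_id, frame$snp_id)
  alts <- paste0("s", 2:7)
  h1 <- heidi_test(frame, "s1", alts, R)
  perm <- sample(seq_len(k))
  h2 <- heidi_test(frame[perm, ], "s1", rev(alts), R)
  expect_identical(h1$status, "ok")
  expect_equal(h1$p_heidi, h2$p_heidi, tolerance = 1e-6)
  expect_equal(h1$stat, h2$stat, tolerance = 1e-9)
})

test_that("degenerate LD collapses to ld_unavailable, collinear SNPs are dropped first", {
  k <- 5
  frame <- data.frame(snp_id = paste0("s", 1:k), pos = 1:k * 50L,
                      b_qtl = c(0.5, 0.45, 0.4, 0.35, 0.3), se_qtl = 0.04,
                      b_gwas = c(0.10, 0.11, 0.09, 0.12, 0.10), se_gwas = 0.02,
                      stringsAsFactors = FALSE)
  # s4 is a perfect copy of s3: the pair makes the correlation matrix
  # singular; dropping one collinear SNP must rescue the test
  R <- ar_corr(k, 0.6)
  R[3, 4] <- R[4, 3] <- 1
  dimnames(R) <- list(frame$snp_id, frame$snp_id)
  h <- heidi_test(frame, "s1", paste0("s", 2:5), R)
  expect_identical(h$status, "ok")
  expect_equal(h$n_snps, 3L)
  # all alternatives mutually perfect copies: cannot reach min_snps
  R1 <- matrix(1, k, k); dimnames(R1) <- list(frame$snp_id, frame$snp_id)
  h1 <- heidi_test(frame, "s1", paste0("s", 2:5), R1)
  expect_identical(h1$status, "ld_unavailable")
  expect_true(is.na(h1$p_heidi))
})

test_that("weighted chi-square tail matches the single-weight exact case and Monte Carlo", {
  pw <- smrheidi:::.p_wsumchisq
  expect_equal(pw(3.84, 1)$p, pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(pw(7.68, 2)$p, pchisq(3.84, 1, lower.tail = FALSE))
  lam <- c(2, 1, 0.5)
  for (q in c(2, 5, 10)) {
    p <- pw(q, lam)
    expect_identical(p$method, "imhof")
    set.seed(99)
    draws <- matrix(rnorm(2e5 * 3)^2, ncol = 3) %*% lam
    p_mc <- mean(draws >= q)
    expect_lt(abs(p$p - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / 2e5))
  }
})
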