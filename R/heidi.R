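# Tail probability P(Q > q) for Q = sum_k lambda_k * chisq_1.
# Primary route: Imhof (1961) numerical inversion of the characteristic
# function; fallback: Monte Carlo with a fixed internal seed when the
# integration fails or returns an out-of-range value.  Returns the
# p-value with the producing method recorded.
.p_wsumchisq <- function(q, lambda, mc_draws = 1e6) {
  lambda <- lambda[is.finite(lambda)]
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (!length(lambda)) stop("no positive weights")
  if (q <= 0) return(list(p = 1, method = "boundary"))
  if (length(lambda) == 1L)
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(lu^2))
    sin(theta) / (u * exp(log_rho))
  }
  # the integrand oscillates with a slowly decaying envelope, so the
  # adaptive quadrature often exhausts its subdivisions while already at
  # full accuracy; accept on the error estimate, not the status message
  p <- NA_real_
  I <- tryCatch(stats::integrate(integrand, lower = 0, upper = Inf,
                                 rel.tol = 1e-8, abs.tol = 1e-10,
                                 subdivisions = 5000L,
                                 stop.on.error = FALSE),
                error = function(e) NULL)
  if (!is.null(I) && is.finite(I$value) && I$abs.error < 1e-5)
    p <- 0.5 + I$value / pi
  if (is.finite(p) && p > -1e-8 && p < 1 + 1e-8)
    return(list(p = min(max(p, 1e-300), 1), method = "imhof"))
  # Monte-Carlo fallback under a fixed seed (caller RNG state preserved)
  p <- .with_seed(20170518L, {
    k <- length(lambda)
    hits <- 0L
    chunk <- 1e5L
    done <- 0
    while (done < mc_draws) {
      m <- as.integer(min(chunk, mc_draws - done))
      Q <- matrix(stats::rnorm(m * k)^2, m, k) %*% lambda
      hits <- hits + sum(Q >= q)
      done <- done + m
    }
    (hits + 1) / (mc_draws + 1)
  })
  list(p = p, method = "mc")
}

#' Select alternative instruments for the HEIDI test
#'
#' Alternative instruments are cis SNPs (excluding the top SNP) whose QTL
#' p-value is below the inclusion threshold and whose LD r-squared with
#' the top SNP lies in `[r2_min, r2_max]` (inclusive) — the lower bound
#' removes essentially independent SNPs, the upper bound removes
#' near-copies of the top SNP that carry no extra information.  SNPs are
#' ranked by QTL significance and truncated to `max_snps`.
#'
#' @param frame harmonized probe frame (columns `snp_id, pos, b_qtl,
#'   se_qtl, p_qtl`, typically with GWAS columns alongside).
#' @param top_snp the instrument SNP id.
#' @param ld an [ld_ref()] object covering the SNPs.
#' @param config an [smr_config()] (fields `heidi_qtl_p`, `r2_min`,
#'   `r2_max`, `max_snps`, `min_snps`).
#' @return A list with `snps` (character vector of alternative
#'   instruments, possibly empty) and `status` (`"ok"` or
#'   `"too_few_snps"`).
#' @export
heidi_select_snps <- function(frame, top_snp, ld, config = smr_config()) {
  stopifnot(top_snp %in% frame$snp_id)
  cand <- frame[frame$snp_id != top_snp &
                  is.finite(frame$p_qtl) &
                  frame$p_qtl < config$heidi_qtl_p, , drop = FALSE]
  cand <- cand[cand$snp_id %in% colnames(ld$dosages), , drop = FALSE]
  if (nrow(cand)) {
    r2 <- vapply(cand$snp_id,
                 function(s) tryCatch(ld_cor(ld, s, top_snp)^2,
                                      error = function(e) NA_real_),
                 numeric(1))
    keep <- is.finite(r2) & r2 >= config$r2_min & r2 <= config$r2_max
    cand <- cand[keep, , drop = FALSE]
  }
  o <- order(cand$p_qtl, -abs(cand$b_qtl / cand$se_qtl), cand$pos)
  snps <- cand$snp_id[o]
  if (length(snps) > config$max_snps) snps <- snps[seq_len(config$max_snps)]
  status <- if (length(snps) >= config$min_snps) "ok" else "too_few_snps"
  list(snps = snps, status = status)
}

# Full delta-method covariance of the deviations d_i = b_smr(i) -
# b_smr(top), propagating sampling error of both arms at both the
# alternative and the top SNP.  QTL and GWAS cohorts are disjoint, so
# cross-cohort covariances vanish; within a cohort LD induces
# cov(b_a, b_b) = r_ab se_a se_b.  V = J S J' with J the gradient of the
# d vector in (b_gwas, b_qtl) and S the block-diagonal effect covariance.
.heidi_cov <- function(bg, seg, bq, seq_, R, top) {
  m <- length(bg)
  alt <- setdiff(seq_len(m), top)
  k <- length(alt)
  Jg <- matrix(0, k, m)
  Jq <- matrix(0, k, m)
  Jg[cbind(seq_len(k), alt)] <- 1 / bq[alt]
  Jg[, top] <- Jg[, top] - 1 / bq[top]
  Jq[cbind(seq_len(k), alt)] <- -bg[alt] / bq[alt]^2
  Jq[, top] <- Jq[, top] + bg[top] / bq[top]^2
  Sg <- R * outer(seg, seg)
  Sq <- R * outer(seq_, seq_)
  V <- Jg %*% Sg %*% t(Jg) + Jq %*% Sq %*% t(Jq)
  (V + t(V)) / 2
}

#' HEIDI heterogeneity test
#'
#' Tests whether SMR estimates obtained from alternative cis instruments
#' are consistent with the top-SNP estimate.  Under a single shared
#' causal variant the ratio `b_gwas/b_qtl` is the same whichever SNP in
#' LD with it serves as the instrument, so the deviations
#' `d_i = b_smr(i) - b_smr(top)` are all zero in expectation; two
#' distinct causal variants in partial LD make the deviations
#' heterogeneous.  The statistic is `sum_i (d_i / se(d_i))^2`, whose null
#' distribution is the matching weighted sum of 1-df chi-squares with
#' weights the eigenvalues of the correlation matrix of the standardized
#' deviations (LD-induced).  The tail is evaluated by Imhof's method,
#' with a fixed-seed Monte-Carlo fallback; the `method` field records
#' which path produced each p.
#'
#' @param frame harmonized probe frame with columns `snp_id, b_gwas,
#'   se_gwas, b_qtl, se_qtl` containing the top SNP and the alternatives.
#' @param top_snp instrument SNP id.
#' @param snps_used character vector of alternative instrument ids (from
#'   [heidi_select_snps()]).
#' @param R signed LD correlation matrix covering `c(top_snp,
#'   snps_used)` on the harmonized allele orientation (see
#'   [ld_matrix()]).
#' @param config an [smr_config()] (fields `min_snps`, `cond_max`,
#'   `heidi_mc_draws`).
#' @return An object of class `heidi_result`: list with `top_snp`,
#'   `snps_used`, `d_stats`, `se_d`, `stat`, `p_heidi`, `n_snps`,
#'   `status` (`"ok"`, `"too_few_snps"`, `"ld_unavailable"`) and
#'   `method`.
#' @export
heidi_test <- function(frame, top_snp, snps_used, R,
                       config = smr_config()) {
  empty <- function(status) structure(
    list(top_snp = top_snp, snps_used = character(0),
         d_stats = numeric(0), se_d = numeric(0), stat = NA_real_,
         p_heidi = NA_real_, n_snps = 0L, status = status,
         method = NA_character_), class = "heidi_result")
  snps_used <- setdiff(unique(snps_used), top_snp)
  if (length(snps_used) < config$min_snps) return(empty("too_few_snps"))
  ids <- c(top_snp, snps_used)
  if (!all(ids %in% frame$snp_id) || !all(ids %in% rownames(R)))
    return(empty("ld_unavailable"))
  f <- frame[match(ids, frame$snp_id), , drop = FALSE]
  R <- R[ids, ids, drop = FALSE]
  repeat {
    top <- 1L
    bg <- f$b_gwas; seg <- f$se_gwas; bq <- f$b_qtl; sq <- f$se_qtl
    alt <- seq_along(bg)[-top]
    bsmr <- bg / bq
    d <- bsmr[alt] - bsmr[top]
    V <- .heidi_cov(bg, seg, bq, sq, R, top)
    se_d <- sqrt(diag(V))
    ok_V <- all(is.finite(se_d)) && all(se_d > 0)
    C <- if (ok_V) V / outer(se_d, se_d) else NULL
    ev <- if (ok_V) eigen(C, symmetric = TRUE, only.values = TRUE)$values else NULL
    degenerate <- !ok_V || min(ev) <= max(ev) / config$cond_max
    if (!degenerate) {
      z_d <- d / se_d
      stat <- sum(z_d^2)
      if (all(d == 0)) {
        p <- list(p = 1, method = "boundary")
      } else {
        p <- .p_wsumchisq(stat, ev, mc_draws = config$heidi_mc_draws)
      }
      return(structure(list(top_snp = top_snp, snps_used = f$snp_id[alt],
                            d_stats = d, se_d = se_d, stat = stat,
                            p_heidi = p$p, n_snps = length(alt),
                            status = "ok", method = p$method),
                       class = "heidi_result"))
    }
    # drop the most collinear alternative SNP (largest summed r^2 to the
    # other used SNPs; ties broken by later position in the id ordering)
    # and retry
    if (length(f$snp_id) - 1L <= config$min_snps)
      return(empty("ld_unavailable"))
    coll <- rowSums(R^2) - 1
    coll[top] <- -Inf
    drop_i <- max(which(coll == max(coll)))
    f <- f[-drop_i, , drop = FALSE]
    R <- R[-drop_i, -drop_i, drop = FALSE]
  }
}

#' @export
print.heidi_result <- function(x, ...) {
  cat(sprintf("HEIDI test (top SNP %s): status %s\n", x$top_snp, x$status))
  if (x$status == "ok")
    cat(sprintf("  %d alternative instruments, stat = %.4g, p = %.4g (%s)\n",
                x$n_snps, x$stat, x$p_heidi, x$method))
  invisible(x)
}
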