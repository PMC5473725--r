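---
title: "Methods: summary-data Mendelian randomization with HEIDI filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data Mendelian randomization with HEIDI filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrheidi)
```

## The model

A cis-QTL study estimates, per SNP, the effect `b_QTL` of allele dosage
on a molecular phenotype (a CpG site's methylation, a transcript's
abundance); a GWAS estimates the effect `b_GWAS` of the same allele on
a complex trait in an independent sample. If variation in the molecular
phenotype mediates (or shares a causal variant with) the trait, the
ratio `b_SMR = b_GWAS / b_QTL` at a valid instrument SNP estimates the
effect of the molecular phenotype on the trait — the two-stage
least-squares estimator assembled from summary data.

`smr_test()` forms, with `z1 = b_GWAS/se_GWAS` and `z2 = b_QTL/se_QTL`,

\[
\chi^2_{SMR} = \frac{z_1^2 z_2^2}{z_1^2 + z_2^2}, \qquad
se_{SMR} = \frac{\sqrt{se_{GWAS}^2\, b_{QTL}^2 + se_{QTL}^2\, b_{GWAS}^2}}{b_{QTL}^2},
\]

a 1-df statistic satisfying \(t_{SMR}^2 = \chi^2_{SMR}\) exactly; the
p-value is always taken from the chi-square tail rather than a normal
approximation of \(t_{SMR}\), so deep tails are numerically stable.
The harmonic-mean form means the statistic can never be more
significant than its weaker arm — a weak instrument cannot manufacture
a trait association.

The instrument is the most significant cis-QTL SNP shared with the
GWAS, accepted only below a stringent QTL threshold
(`qtl_p_threshold`, default 1e-10 for a well-powered blood cohort;
1e-8 is the conventional choice for smaller cohorts such as fetal
brain). Exact p ties break by larger `|b/se|`, then smaller position,
making scans deterministic.

### Pleiotropy versus linkage: HEIDI

An SMR association can be an artifact of two distinct causal variants
in LD, one driving the QTL and one the trait. Under a single shared
causal variant the ratio `b_GWAS/b_QTL` is the same whichever cis SNP
in LD with it serves as the instrument; under linkage the ratios
disagree. `heidi_test()` therefore examines deviations
\(d_i = b_{SMR}(i) - b_{SMR}(top)\) over alternative instruments
(`heidi_select_snps()`: QTL p below 1.57e-3 (|z| > 3.16), LD r² to the
top SNP within [0.05, 0.9], ranked by QTL significance, at most 20, at
least 3 — the published defaults of the method family).

The covariance of the deviation vector is obtained by the full delta
method, propagating the sampling error of both arms at both the
alternative and the top SNP, with within-cohort effect covariances
\(cov(b_a, b_b) = r_{ab}\, se_a\, se_b\) induced by LD and
cross-cohort covariances zero (the QTL and GWAS samples are disjoint —
an assumption the simulator enforces by rejecting overlapping sample
ids). We deliberately do not treat the top SNP's QTL effect as fixed:
the negative covariance between an alternative's and the top's QTL
estimates cancels a large part of the QTL-arm variance, and dropping it
overstates \(var(d_i)\) by 10–20% in empirical-covariance checks,
deflating HEIDI rejection under pleiotropy to ~0.03 at nominal 0.05.
With the full gradient the model/empirical variance ratio is ~1.0 and
the test is calibrated (the acceptance suite verifies rejection within
3 Monte-Carlo SEs of 0.05 at 2,000 replicates).

The statistic \(\sum_i (d_i/se(d_i))^2\) has as null distribution a
weighted sum of 1-df chi-squares, weights the eigenvalues of the
correlation matrix of the standardized deviations. The tail is
computed by Imhof's characteristic-function inversion via adaptive
quadrature; because the integrand oscillates under a slowly decaying
envelope, results are accepted on the integrator's error estimate
(`abs.error < 1e-5`) rather than its status flag, and a Monte-Carlo
fallback (1e6 draws under a fixed internal seed, caller RNG preserved)
covers the rare failures. Each result records which path produced its
p-value. Near-singular LD submatrices (condition number above 1e8,
e.g. near-duplicate SNPs) are handled by deterministically dropping the
most collinear alternative and retrying; if that would fall below
`min_snps` the probe's HEIDI status becomes `ld_unavailable`.

An SMR-significant association with HEIDI p > 0.05 is classified
`pleiotropic`; with HEIDI p ≤ 0.05, `linkage`; HEIDI is computed only
for the SMR-significant set, which is the set the heterogeneity filter
exists to refine.

## Harmonization and thresholds

All statistics are computed on one allele frame. Swapped alleles negate
the paired effect and complement its frequency; strand-complementary
non-palindromic pairs are resolved by complementing; palindromic (A/T,
C/G) pairs are resolved by allele frequency only when both frequencies
lie outside 0.5 ± `freq_tol` (default 0.2) and are otherwise excluded
as `ambiguous_palindrome` — frequency resolution is standard practice,
and the tolerance errs toward exclusion. LD correlations are signed on
the harmonized orientation (`ld_matrix()` flips dosages where the
counted allele differs).

The SMR significance threshold is `alpha_fw` Bonferroni-corrected over
the number of distinct probes actually tested in the dataset — the
convention that yields 1.42e-6 for 35,263 methylation sites, 8.38e-6
for 5,966 expression probes and 5.40e-6 for 9,265 fetal-brain sites —
not per trait. Novel-locus flagging anchors at the probe position
(novelty is a property of the site's locus, not of the instrument) with
an inclusive 0.5 Mb window and the conventional 5e-8 genome-wide
level. Sign tests are exact two-sided binomials computed in log space,
so magnitudes around 1e-170 are representable via `log10_sign_test_p`.
Cluster matrices of `t_SMR` use average-linkage hierarchical clustering
on Euclidean distances with `stats::dist`'s pairwise-complete masking
(missing cells are rescaled out, never imputed).

## What the simulator emulates

`sim_scenario()` describes one cis locus: haplotypes are thresholded
latent-Gaussian AR(1) chains, giving directly controllable LD — the
property the HEIDI power experiments need and the reason this model was
chosen over coalescent simulation. Thresholding attenuates correlation,
so each adjacent latent correlation is calibrated by root-finding on
the implied allelic correlation; realized adjacent dosage r matches the
requested target to well within 0.1 (0.05 for the causal pair), and
mafs within a locus are drawn close together, as they must be for high
LD to be attainable at all. Methylation is generated unbounded
(M-value-like) as `m = b_zx g + e`; under pleiotropy the phenotype is
mediated, `y = b_xy m* + e` with `m*` regenerated in the disjoint GWAS
sample; under linkage a second causal variant two chain steps away
(with an intermediate SNP, as recombination-separated pairs have)
drives `y = b_zy g2 + e` at LD `causal_r` to the QTL variant — placed
adjacent instead, the informative alternative instruments fall below
the r² ≥ 0.05 inclusion bound at low `causal_r` and HEIDI power
becomes an artifact of the degenerate topology. `causal_r = 1`
duplicates the dosage column, since perfect LD is unattainable under
thresholding. An optional `horizontal` path adds a direct SNP-trait
effect for robustness experiments. Effect sizes are parameterized on
the dosage scale.

`make_benchmark()` writes a complete miniature study under one seed
(byte-identical on regeneration): 3 traits × 60 single-locus probes
(12 SNPs each) spanning all three architectures, with 4 probes
pleiotropic for two traits; QTL cohorts of 2,000, a shared GWAS cohort
of 10,000, an expression cohort per gene, a 500-individual LD panel,
and a truth table. A share_frac = 0.9 fraction of probes keeps the
same causal variant in the secondary tissue, mirroring cross-tissue
concordance designs. Allele orientation is deliberately scrambled in
the GWAS and secondary tables so harmonization is always exercised.
Default effect sizes (`b_zx = 0.5`, `b_xy = 0.3`, `b_zy = 0.4`,
`causal_r = 0.5`) put instruments far past the 1e-10 threshold — the
regime the method assumes — while leaving HEIDI's decisions
non-trivial.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, array annotation structure, bounded
beta-distributed methylation, case-control liability scales, sample
overlap between cohorts, or population stratification. Passing tests
therefore demonstrate correctness of the statistics under the stated
generative model, not robustness to those real-data complications.

## Experiment sizes and numerical choices

The calibration experiments use: 2,000 null replicates for SMR type-I
error (3-SNP loci, n = 800 per cohort); 2,000 pleiotropy replicates
for HEIDI calibration and 1,000 per point of the linkage-power grid
r ∈ {0.3, 0.6, 0.9, 1.0} (10-SNP loci, n_QTL = 3,000, n_GWAS =
3,000–5,000); 300 replicates at n = 5,000 for mediated-effect
recovery. These sizes put 3-SE Monte-Carlo bands at ±0.015 around a
0.05 rate while keeping a full run in minutes on one CPU. The HEIDI
calibration experiments use a 10,000-individual LD panel: a small
panel's sampling error is shared across replicates and biases the
weight matrix — with a 4,000-individual panel rejection drifts to
~0.03–0.04 — which is a known limitation of LD-reference-based HEIDI
in practice, distinct from the test's own calibration.

Degenerate inputs are handled explicitly: `b_QTL = 0` is a
`degenerate_instrument` error; a zero HEIDI statistic returns p = 1
exactly; SMR p-values are floored at the smallest positive double;
monomorphic SNPs error in LD queries and are omitted (with a message)
from simulated summary statistics; stored p-values that disagree with
their Wald recomputation by more than 10× are flagged but kept, since
meta-analysis p-values legitimately deviate from the normal
approximation.

## Known limitations

- Single-instrument SMR only; no multi-SNP extensions, no conditional
  analysis of secondary QTL signals, no multi-probe joint tests.
- Horizontal pleiotropy is expressible in the simulator but not
  detectable by the test — an inherent limitation of the design.
- HEIDI power vanishes as the two causal variants approach perfect LD;
  at r = 1 the scenarios are indistinguishable in principle, and the
  test correctly falls back to its nominal rejection rate.
- Genetic-correlation conditioning of trait overlaps is accepted as a
  user-supplied pass-through column, never computed internally.
- No genotype imputation, liftover, dbSNP id resolution, or
  cross-build harmonization.
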