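---
title: "Methods: latent genetic factors from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent genetic factors from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `gibnet`, the
estimators it uses, the design choices made where the protocol left room,
and what the synthetic-data validation does and does not establish.

## 1. The model

For `P` phenotypes measured by GWAS, the per-SNP Z statistics carry
information about the genetic covariance between phenotypes. Under the
LDSC model, for SNP `j` with LD score `l_j` and `M` regression SNPs,

```
E[z_aj * z_bj] = intercept_ab + sqrt(N_a N_b) * S[a,b] * l_j / M
```

with `S[a,a] = h2_a`. The matrix `S` is symmetric positive semidefinite;
its standardized version `S*` (unit diagonal) is modeled with a common
factor structure

```
S* = Lambda Phi Lambda' + Theta
```

where `Lambda` (P x k) holds standardized loadings, `Phi` (k x k, unit
diagonal) the factor correlations, and `Theta` diagonal residual genetic
variances. A factor — a "genetically informed network" — is the set of
phenotypes with retained loadings. Key assumptions: the LDSC moment
condition holds (polygenic architecture, LD scores measured on the
analysis population), confounding and sample overlap load on the
intercepts, and genetic covariance — not environmental covariance — is
what the factor structure explains (summary statistics only expose the
genetic part through the slope).

## 2. LD score regression

`estimate_h2()` / `estimate_gencov()` regress the z-product on the LD
score with a free intercept in two passes:

1. an unweighted pass gives provisional `h2` (clamped to [0, 1]) and
   `rho_g` (clamped to [-1, 1] on the covariance scale);
2. the second pass weights SNP `j` by `1 / (l_j * (v_a v_b + c_ab^2))`,
   where `v_a = intercept_a + N_a h2_a l_j / M` is the expected chi-square
   of trait `a` and `c_ab` the expected z-product. For `a = b` this is the
   classical `1 / (2 l (1 + N h2 l / M)^2)` heteroscedasticity weight; the
   shared form guarantees that a trait regressed on itself reproduces the
   heritability regression *exactly*, which the tests exploit.

The slope is rescaled by `M / mean(sqrt(N_a N_b))`; `M` is the number of
regression SNPs in the chromosome subset, a convention chosen for
self-consistency with the simulator (real-data `M` conventions differ and
absolute `h2` levels shift accordingly). Intercepts are always free:
sample overlap is absorbed rather than constrained away, the conservative
default when the overlap structure is unknown.

Standard errors come from a delete-block jackknife over contiguous
genome-order blocks, 200 by default (below 400 SNPs the count falls back
to one block per 10 SNPs). `build_gencov_matrix()` runs all `P(P+1)/2`
regressions on **one shared block partition**, so the jackknife yields the
full sampling covariance `V` of the half-vectorized `S` including
cross-element covariances — required for the weighted least squares fit
and the residual-based test statistic downstream. Within the jackknife the
second-pass weights are held fixed at their full-sample values.

## 3. Standardization and smoothing

Factor analysis operates on the standardized matrix. The delta method maps
`V` to the correlation scale (`standardize_to_correlation()`); diagonal
elements become constants with zero rows/columns in `V*`. A consequence
used throughout: on the standardized scale the residual variances `Theta`
carry no independent sampling information, so the DWLS fit profiles them
out against the unit diagonal (section 5) — the exact limit of giving the
fixed diagonal elements infinite weight.

Empirical LDSC matrices need not be positive definite. `smooth_to_pd()`
clips eigenvalues at `1e-8` and rescales to preserve the diagonal,
iterating with a doubling floor until both constraints hold. PD input is
returned bit-identically.

## 4. Exploratory stage

`run_efa()` uses minimum-residual extraction (uniquenesses optimized by
L-BFGS-B, loadings from the eigen-decomposition of the reduced
correlation matrix) for `k` in 1–10 by default. Rotation for `k >= 2` is
oblique **promax** (m = 4): the latent factors of regional brain
phenotypes are strongly correlated, and an orthogonal rotation would smear
loadings across factors, making a fixed loading threshold meaningless. The
rotation protocol itself did not specify a method; promax is the standard
oblique choice. Two determinism details:

- a fixed small Givens pre-rotation is applied before varimax/promax,
  because exactly balanced loading blocks (noise-free synthetic matrices)
  make the identity rotation a stationary point where varimax stalls;
- each factor is sign-flipped so its largest-magnitude loading is
  positive, and factors are ordered by explained variance, so the
  "positive loading > tau" rule is well defined.

`build_cfa_spec()` carries forward positive rotated loadings above `tau`
(0.3 and 0.5 are both run), keeps cross-loadings when each exceeds `tau`,
removes factors left with fewer than two regions, and candidate
specifications that imply the same sparsity pattern are deduplicated
before fitting.

## 5. Confirmatory stage

`fit_cfa()` minimizes the diagonally weighted least squares discrepancy

```
F(theta) = sum_e (s_e - sigma_e(theta))^2 / V[e,e]
```

over the off-diagonal half-vectorized elements, with factor variances
fixed to 1, factor correlations free, and `Theta` profiled as
`1 - communality` (clamped at zero with a Heywood warning). The gradient
is analytic; optimization is `nlminb` with box constraints (|loading| <=
1.5, |factor correlation| <= 0.98). A stationary point with vanishing
gradient is accepted as converged even when `nlminb` reports "false
convergence", which happens at exact-zero minima.

Parameter standard errors use the full `V` in a sandwich,
`(D'WD)^-1 D'W V W D (D'WD)^-1`, with `D` the analytic Jacobian and `W`
the inverse diagonal of `V`. The model chi-square is the residual-based
quadratic form `r' (V+ - V+ D (D'V+ D)^-1 D'V+) r` (pseudo-inverse by
eigenvalue clipping) — the asymptotically chi-square companion of DWLS
point estimation. Fit indices: `df = P(P+1)/2 - free parameters` (free
parameters count loadings, factor correlations and the P residuals),
`AIC = chi2 + 2 * free parameters` (the chi-square-based convention; a
likelihood-based AIC is not available without a likelihood),
`CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)`
against the diagonal-only independence baseline, and SRMR as the RMS
residual over all unique elements of the standardized matrix.

`prune_nonsignificant()` iteratively removes the least significant free
loading with two-sided Wald `p > 0.05` and refits, never shrinking a
factor below two regions; `0.05` is the conventional reading of
"non-significant", and the removal order (largest p first, ties by label)
makes pruning deterministic. `select_best_model()` takes the converged
candidate with minimal AIC, ties broken toward fewer factors, then fewer
free parameters.

## 6. Latent-factor GWAS

For each SNP, the standardized SNP–phenotype covariances
`(z_p / sqrt(N_p)) sqrt(2 maf (1 - maf))` extend `S*` by one row/column
(`expand_covariance_for_snp()`), with sampling variance
`2 maf (1 - maf) / N_p` and independence from the LDSC elements assumed.
SNP→factor paths for all factors are estimated simultaneously. Two modes:

- **fixed** (default): the measurement model is held at the no-SNP
  solution; the per-SNP problem reduces to a small weighted regression
  with a closed form, fast enough for panels of any size;
- **refit**: all free parameters re-estimated per SNP by the same DWLS
  criterion. For realistic (weak) per-SNP effects the two agree to well
  under 10% relative difference; refit exists to mirror the full
  structural-equation behavior.

Wald z and p per factor; genome-wide significance at `p < 5e-8`. The
effective sample size written with a factor's GWAS is the mean regional N
— a reporting convention, not an estimate. `genomic_lambda()` uses the
median-chi-square convention, `lambda = median(z^2) / 0.4549364`, and can
attach the LDSC intercept of the factor GWAS (intercept near 1 with
lambda above 1 indicates polygenicity, not confounding). A caveat worth
stating plainly: with a polygenic background every SNP carries real
signal, so null-SNP p-value uniformity is only a property of
no-background panels; calibration tests therefore inject fixed effects
into otherwise signal-free panels.

`clump_loci()` is a deterministic greedy distance clump (best p claims
everything within ±250 kb on its chromosome, repeat): a desk-scale
substitute for LD-aware locus definition tools, adequate for counting
simulated loci but not a reproduction of reference-panel-based clumping.

## 7. Overlap statistics

`dice_coefficient()` on region-label sets, optionally size-weighted; the
permutation null redraws the network uniformly without replacement from
the declared universe, holding the parcel fixed, with the add-one estimate
`p = (1 + #{null >= observed}) / (1 + n_iter)`. Because set-label Dice
takes only a handful of values, null p-values are discrete: they are
*super-uniform* (type-I error controlled at every level) rather than
exactly uniform, and the tests check exactly that. Batch corrections go
through `fdr_adjust()` (Benjamini–Hochberg). Region names are normalized
(case, whitespace, underscores) against the universe; unknown names are
errors. The 34-name cortical universe and the published network region
lists ship as plain-text fixtures.

## 8. The simulator

`generate_dataset()` draws per-SNP Z vectors directly from the LDSC
moment model: `z_j ~ MVN(0, D^{1/2} (Sigma_g l_j / M) D^{1/2} + C_e)`,
with LD scores constant within contiguous blocks (shifted gamma, mean 30,
block size 50 by default), chromosomes 1–22 receiving contiguous block
ranges, maf uniform on [0.05, 0.5], and optional error-side correlation
for sample overlap (default 0). Fixed SNP→factor effects add the implied
mean shift `sqrt(N) lambda_p a sqrt(2 maf (1-maf))` to the affected
phenotypes.

The default configuration is the reference condition used throughout the
tests: 12 phenotypes standing in for the 34 cortical regions, 2
correlated factors (`Phi_12 = 0.45`) standing in for the 6/4 reported
networks, loadings 0.5–0.8, `h2 = 0.3`, `N = 30,000`, `M = 20,000` SNPs —
a deliberate reduction that keeps every sampling distribution honest
while making a 20-seed pipeline replication run in well under a minute.
What the simulator does *not* emulate: realistic local LD (scores are
block-constant and independent of the z draws beyond the variance term),
allele-frequency-dependent architecture, population stratification, and
individual-level genotypes. Passing recovery tests therefore demonstrates
the estimators are correct *under the model they assume*, not robustness
to model violations in real cortical GWAS.

## 9. Numerical choices and degenerate inputs

- Jackknife needs at least 2 blocks and at least ~20 SNPs; fewer is an
  error, not a silent fallback.
- Weight denominators are floored (`l >= 1`, expected chi-square
  `>= 0.05`) to keep the two-pass weights finite.
- `smooth_to_pd` requires a positive diagonal and errors otherwise;
  standardization errors on nonpositive genetic variances, naming the
  phenotype.
- Nonpositive estimated `h2` in a covariance matrix is flagged with a
  warning; standardization then fails loudly rather than producing NaNs.
- Palindromic A/T and C/G SNPs are always dropped in harmonization
  (strand is unresolvable without frequencies); duplicate rsIDs keep the
  first occurrence; both are logged.
- Ties in pruning and model selection are broken by fixed label/order
  rules so every run of the protocol is reproducible.

## 10. Known limitations

- The chromosome-split protocol assumes autosomes 1–22; sex chromosomes
  are out of scope.
- Bifactor and second-order factor models are not implemented (reported
  as non-converging or non-improving in the source analyses).
- Partitioned LDSC, constrained intercepts, and MHC exclusion are not
  provided; SNP inclusion lists are the caller's responsibility.
- The latent GWAS does not compute per-SNP heterogeneity (Q) statistics.
- Weighted Dice accepts per-region sizes but the permutation null draws
  regions uniformly, not size-weighted — the null of the label-set
  statistic, not of a volumetric one.
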