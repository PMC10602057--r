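#' @title LD score regression for heritability and genetic covariance
#' @name ldsc
#' @description
#' The regression model is the LDSC moment condition: for SNP j with LD
#' score l_j, E[z_aj z_bj] = intercept + sqrt(N_a N_b) * rho_g / M * l_j,
#' which reduces to E[z_j^2] = intercept + N h2 / M * l_j for a = b. The
#' slope is estimated by a two-pass weighted regression of the z-product on
#' the LD score with a free intercept, and standard errors come from a
#' delete-block jackknife over contiguous genome-order blocks. One shared
#' block partition is used for every element of a covariance matrix so the
#' jackknife also yields cross-element sampling covariances.
NULL

# Resolve the block count: default 200, fall back to floor(m/10) when the
# SNP count is under twice the default.
resolve_n_blocks <- function(m, n_blocks) {
  if (m < 2 * n_blocks) n_blocks <- floor(m / 10)
  if (n_blocks < 2) stop("too few SNPs for a jackknife (need >= 20)")
  if (n_blocks > m) stop("more jackknife blocks than SNPs")
  as.integer(n_blocks)
}

# Contiguous equal-size block assignment over m SNPs (genome order assumed).
block_ids <- function(m, n_blocks) {
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

# Weighted regression of y on (1, x) with per-block sufficient statistics,
# returning full-sample coefficients and leave-one-block-out coefficients.
wls_with_blocks <- function(y, x, w, blocks) {
  mat <- cbind(w, w * x, w * x * x, w * y, w * x * y)
  s_blk <- rowsum(mat, blocks)
  s_tot <- colSums(s_blk)
  solve_coef <- function(s) {
    a <- matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
    solve(a, c(s[4], s[5]))
  }
  coef <- solve_coef(s_tot)
  nb <- nrow(s_blk)
  loo <- matrix(NA_real_, nb, 2)
  for (b in seq_len(nb)) loo[b, ] <- solve_coef(s_tot - s_blk[b, ])
  list(coef = coef, loo = loo)
}

# Unweighted first pass for one z-product response: intercept + raw slope.
pass1_fit <- function(y, x) {
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  c(intercept = co[[1]], slope = co[[2]])
}

# LDSC heteroscedasticity weight for the product z_a * z_b:
#   var(z_a z_b) ~ v_a * v_b + c_ab^2, all on the expected-chi2 scale,
# divided again by l to correct for SNP over-counting in LD.
ldsc_weight <- function(l2, va, vb, cab) {
  denom <- pmax(va * vb + cab^2, 1e-3)
  1 / (pmax(l2, 1) * denom)
}

# Shared core: two-pass (or single-pass unit-weight) regression of
# z_a * z_b on l2, slope rescaled to the variance scale via M / mean(N).
ldsc_pair_core <- function(za, zb, na, nb, l2, blocks, m_snps,
                           two_pass = TRUE) {
  y <- za * zb
  neff <- sqrt(na * nb)
  scale <- m_snps / mean(neff)
  if (two_pass) {
    p1_aa <- pass1_fit(za^2, l2)
    p1_bb <- pass1_fit(zb^2, l2)
    p1_ab <- pass1_fit(y, l2)
    h2a <- min(max(p1_aa[["slope"]] * m_snps / mean(na), 0), 1)
    h2b <- min(max(p1_bb[["slope"]] * m_snps / mean(nb), 0), 1)
    rho <- min(max(p1_ab[["slope"]] * scale, -1), 1)
    va <- pmax(p1_aa[["intercept"]] + na * h2a * l2 / m_snps, 0.05)
    vb <- pmax(p1_bb[["intercept"]] + nb * h2b * l2 / m_snps, 0.05)
    cab <- p1_ab[["intercept"]] + neff * rho * l2 / m_snps
    w <- ldsc_weight(l2, va, vb, cab)
  } else {
    w <- rep(1, length(y))
  }
  fit <- wls_with_blocks(y, l2, w, blocks)
  list(intercept = fit$coef[1], slope_raw = fit$coef[2],
       estimate = fit$coef[2] * scale,
       loo_estimate = fit$loo[, 2] * scale,
       loo_intercept = fit$loo[, 1], weights = w)
}

new_ldsc_fit <- function(quantity, core, n_blocks, m) {
  jk <- function(loo) {
    nb <- length(loo)
    sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  }
  structure(list(quantity = quantity,
                 estimate = core$estimate,
                 intercept = core$intercept,
                 se = jk(core$loo_estimate),
                 se_intercept = jk(core$loo_intercept),
                 n_blocks = n_blocks, m = m,
                 loo_estimate = core$loo_estimate),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("ldsc_fit [%s]: %.4f (SE %.4f), intercept %.4f (SE %.4f), %d SNPs, %d blocks\n",
              x$quantity, x$estimate, x$se, x$intercept, x$se_intercept,
              x$m, x$n_blocks))
  invisible(x)
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-SNP z^2 on LD scores with a free intercept. The first pass
#' is unweighted and provides a provisional heritability for the
#' heteroscedasticity weights 1 / (2 l (intercept + N h2 l / M)^2) of the
#' second pass; the slope is rescaled to h2 by M / mean(N). Standard errors
#' are delete-block jackknife over contiguous blocks.
#'
#' @param z,n Per-SNP signed Z statistics and sample sizes (aligned vectors).
#' @param l2 LD scores aligned with `z`.
#' @param n_blocks Jackknife block count (default 200; falls back to
#'   floor(m/10) below 400 SNPs).
#' @param two_pass If `FALSE`, a single unit-weight pass is run (useful for
#'   cross-checks against closed-form weighted least squares).
#' @return An `ldsc_fit` with fields `estimate` (h2), `intercept`, `se`,
#'   `se_intercept`, `n_blocks`, `m` and the leave-one-block-out estimates.
#' @export
estimate_h2 <- function(z, n, l2, n_blocks = 200, two_pass = TRUE) {
  stopifnot(length(z) == length(l2), length(n) == length(z))
  m <- length(z)
  nb <- resolve_n_blocks(m, n_blocks)
  core <- ldsc_pair_core(z, z, n, n, l2, block_ids(m, nb), m, two_pass)
  new_ldsc_fit("h2", core, nb, m)
}

#' Estimate genetic covariance between two traits by cross-trait LDSC
#'
#' Regresses the per-SNP product z_a * z_b on LD scores. The free intercept
#' absorbs phenotypic sample overlap; the slope is rescaled to the genetic
#' covariance rho_g by M / mean(sqrt(N_a N_b)). With `za` identical to `zb`
#' this is exactly the heritability regression of [estimate_h2()].
#'
#' @param za,zb Aligned Z statistics of the two traits (same SNPs, same
#'   allele orientation — see [harmonize_panel()]).
#' @param na,nb Per-SNP sample sizes.
#' @inheritParams estimate_h2
#' @return An `ldsc_fit` with `quantity = "gencov"`.
#' @export
estimate_gencov <- function(za, zb, na, nb, l2, n_blocks = 200,
                            two_pass = TRUE) {
  stopifnot(length(za) == length(zb), length(za) == length(l2))
  m <- length(za)
  nb_ <- resolve_n_blocks(m, n_blocks)
  core <- ldsc_pair_core(za, zb, na, nb, l2, block_ids(m, nb_), m, two_pass)
  new_ldsc_fit("gencov", core, nb_, m)
}

#' Delete-block jackknife covariance of a set of estimators
#'
#' Given leave-one-block-out estimates theta_(b) for E estimators sharing
#' the same B blocks, returns the E x E jackknife sampling covariance
#' v[e, f] = (B-1)/B * sum_b (theta_e(b) - mean_e)(theta_f(b) - mean_f).
#'
#' @param loo B x E matrix of leave-one-block-out estimates (columns are
#'   estimators, rows are deleted blocks).
#' @return E x E sampling covariance matrix.
#' @export
jackknife_cov <- function(loo) {
  loo <- as.matrix(loo)
  b <- nrow(loo)
  if (b < 2) stop("jackknife needs at least 2 blocks")
  centered <- sweep(loo, 2, colMeans(loo))
  (b - 1) / b * crossprod(centered)
}

# vech index bookkeeping: column-major lower triangle including diagonal.
vech_index <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

vech <- function(m) m[lower.tri(m, diag = TRUE)]

unvech <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Build the full genetic covariance matrix S with jackknife sampling covariance V
#'
#' Runs the LDSC regression for every pair of phenotypes in the panel
#' (diagonal: z^2, heritability; off-diagonal: z-products, genetic
#' covariance), restricted to the requested chromosome subset. A single
#' shared block partition is used across all P(P+1)/2 regressions so the
#' delete-block jackknife yields a coherent sampling covariance V of the
#' half-vectorized elements of S (column-major lower triangle, diagonal
#' included).
#'
#' @param panel A `sumstats_panel` whose SNPs carry chromosome labels.
#' @param ldscores LD-score table from [read_ldscores()].
#' @param chrom_subset `"odd"`, `"even"`, or `"all"`.
#' @param n_blocks Jackknife block count (see [estimate_h2()]).
#' @return A `genetic_covariance`: list with `labels`, `s` (P x P), `v`
#'   (sampling covariance of vech(S)), `intercepts` (P x P), `chrom_subset`,
#'   `n_blocks`, `m`, `loo` (block-by-element leave-one-out estimates) and
#'   `h2_nonpositive` flags. Phenotypes with nonpositive estimated h2 are
#'   flagged with a warning, not an error.
#' @export
build_gencov_matrix <- function(panel, ldscores, chrom_subset = c("all", "odd", "even"),
                                n_blocks = 200) {
  chrom_subset <- match.arg(chrom_subset)
  stopifnot(inherits(panel, "sumstats_panel"))
  if (anyNA(panel$snps$chrom)) stop("panel SNPs must carry chromosome labels")
  if (chrom_subset != "all") {
    want_odd <- chrom_subset == "odd"
    keep <- (panel$snps$chrom %% 2 == 1) == want_odd
    if (!any(keep)) stop("no SNPs on ", chrom_subset, " chromosomes")
    panel <- subset_panel(panel, keep)
  }
  joined <- join_panel_ldscores(panel, ldscores)
  panel <- joined$panel
  # genome order so jackknife blocks are contiguous in the genome
  ord <- order(panel$snps$chrom, panel$snps$bp)
  panel <- subset_panel(panel, ord)
  l2 <- joined$l2[ord]

  p <- length(panel$phenotypes)
  m <- nrow(panel$snps)
  nb <- resolve_n_blocks(m, n_blocks)
  blocks <- block_ids(m, nb)
  idx <- vech_index(p)
  n_elem <- nrow(idx)

  # provisional pass-1 fits for every phenotype (for the weights)
  p1 <- lapply(seq_len(p), function(i) pass1_fit(panel$z[, i]^2, l2))
  h2_prov <- vapply(seq_len(p), function(i) {
    min(max(p1[[i]][["slope"]] * m / mean(panel$n[, i]), 0), 1)
  }, numeric(1))
  vexp <- lapply(seq_len(p), function(i) {
    pmax(p1[[i]][["intercept"]] + panel$n[, i] * h2_prov[i] * l2 / m, 0.05)
  })

  s <- matrix(0, p, p, dimnames = list(panel$phenotypes, panel$phenotypes))
  intercepts <- s
  loo <- matrix(NA_real_, nb, n_elem)
  for (e in seq_len(n_elem)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    y <- panel$z[, i] * panel$z[, j]
    neff <- sqrt(panel$n[, i] * panel$n[, j])
    scale <- m / mean(neff)
    p1_ij <- if (i == j) p1[[i]] else pass1_fit(y, l2)
    rho <- min(max(p1_ij[["slope"]] * scale, -1), 1)
    cab <- p1_ij[["intercept"]] + neff * rho * l2 / m
    w <- ldsc_weight(l2, vexp[[i]], vexp[[j]], cab)
    fit <- wls_with_blocks(y, l2, w, blocks)
    est <- fit$coef[2] * scale
    s[i, j] <- s[j, i] <- est
    intercepts[i, j] <- intercepts[j, i] <- fit$coef[1]
    loo[, e] <- fit$loo[, 2] * scale
  }
  v <- jackknife_cov(loo)
  labels_elem <- paste(panel$phenotypes[idx[, 1]], panel$phenotypes[idx[, 2]],
                       sep = ":")
  dimnames(v) <- list(labels_elem, labels_elem)
  h2_bad <- diag(s) <= 0
  if (any(h2_bad)) {
    warning("nonpositive estimated h2 for: ",
            paste(panel$phenotypes[h2_bad], collapse = ", "))
  }
  structure(list(labels = panel$phenotypes, s = s, v = v,
                 intercepts = intercepts, chrom_subset = chrom_subset,
                 n_blocks = nb, m = m, loo = loo,
                 h2_nonpositive = h2_bad, standardized = FALSE),
            class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat(sprintf("genetic_covariance: %d phenotypes, chrom subset '%s', %d SNPs, %d jackknife blocks%s\n",
              length(x$labels), x$chrom_subset, x$m, x$n_blocks,
              if (isTRUE(x$standardized)) ", standardized" else ""))
  print(round(x$s, 4))
  invisible(x)
}

#' Cross-trait genetic correlation from two GWAS
#'
#' Harmonizes two summary-statistic record sets against each other, then
#' estimates h2 for each trait and their genetic covariance on one shared
#' block partition. The genetic correlation is rg = rho_g / sqrt(h2_a h2_b);
#' its SE comes from jackknifing the ratio itself (the leave-one-block-out
#' rg recomputed from the leave-one-out components), and the p-value is
#' two-sided normal. Estimates outside [-1, 1] are flagged, not truncated.
#'
#' @param gwas_a,gwas_b Record data.frames from [read_sumstats()].
#' @param ldscores LD-score table.
#' @param n_blocks Jackknife block count.
#' @return An `rg_estimate`: list with `rg`, `se`, `p`, `h2_a`, `h2_b`,
#'   `gencov`, `m`, `n_blocks`, `out_of_bounds` flag. FDR adjustment across
#'   a batch of estimates is the caller's job via [fdr_adjust()].
#' @export
estimate_rg <- function(gwas_a, gwas_b, ldscores, n_blocks = 200) {
  panel <- harmonize_panel(list(gwas_a, gwas_b), c("a", "b"))
  joined <- join_panel_ldscores(panel, ldscores)
  panel <- joined$panel
  l2 <- joined$l2
  m <- nrow(panel$snps)
  nb <- resolve_n_blocks(m, n_blocks)
  blocks <- block_ids(m, nb)
  fa <- ldsc_pair_core(panel$z[, 1], panel$z[, 1], panel$n[, 1], panel$n[, 1],
                       l2, blocks, m)
  fb <- ldsc_pair_core(panel$z[, 2], panel$z[, 2], panel$n[, 2], panel$n[, 2],
                       l2, blocks, m)
  fab <- ldsc_pair_core(panel$z[, 1], panel$z[, 2], panel$n[, 1], panel$n[, 2],
                        l2, blocks, m)
  if (fa$estimate <= 0 || fb$estimate <= 0) {
    stop("genetic correlation undefined: nonpositive h2 estimate")
  }
  rg <- fab$estimate / sqrt(fa$estimate * fb$estimate)
  loo_rg <- fab$loo_estimate /
    sqrt(pmax(fa$loo_estimate, 1e-12) * pmax(fb$loo_estimate, 1e-12))
  se <- sqrt((nb - 1) / nb * sum((loo_rg - mean(loo_rg))^2))
  pval <- 2 * stats::pnorm(-abs(rg / se))
  structure(list(rg = rg, se = se, p = pval,
                 h2_a = fa$estimate, h2_b = fb$estimate,
                 gencov = fab$estimate, m = m, n_blocks = nb,
                 out_of_bounds = abs(rg) > 1),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("rg = %.3f (SE %.3f, p = %.3g)%s\n", x$rg, x$se, x$p,
              if (x$out_of_bounds) " [outside +/-1]" else ""))
  invisible(x)
}

#' Write a genetic covariance estimate to plain-text files
#'
#' Emits `<prefix>_S.tsv` (the matrix), `<prefix>_V.tsv` (half-vectorized
#' sampling covariance with element labels) and `<prefix>_meta.json`
#' (labels, chromosome subset, block count, SNP count).
#'
#' @param gencov A `genetic_covariance`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_gencov <- function(gencov, prefix) {
  s_path <- paste0(prefix, "_S.tsv")
  v_path <- paste0(prefix, "_V.tsv")
  j_path <- paste0(prefix, "_meta.json")
  utils::write.table(gencov$s, s_path, sep = "\t", quote = FALSE)
  utils::write.table(gencov$v, v_path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(labels = gencov$labels,
                            chrom_subset = gencov$chrom_subset,
                            n_blocks = gencov$n_blocks, m = gencov$m,
                            standardized = isTRUE(gencov$standardized)),
                       j_path, auto_unbox = TRUE, digits = NA)
  invisible(c(s_path, v_path, j_path))
}
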