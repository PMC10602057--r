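#' @title Multivariate GWAS of latent genetic factors
#' @name latent_gwas
#' @description
#' Each SNP's standardized covariance with every phenotype,
#' (z_p / sqrt(N_p)) * sqrt(2 maf (1 - maf)), is appended to the genetic
#' correlation matrix and SNP-to-factor regressions are estimated for all
#' factors simultaneously by diagonally weighted least squares. In the
#' default "fixed" mode the measurement model (loadings, factor
#' correlations) is held at the no-SNP solution, which reduces the per-SNP
#' problem to a small weighted regression; "refit" re-estimates all free
#' parameters per SNP.
NULL

# Genotype variance under Hardy-Weinberg on the 0/1/2 allele-count scale.
snp_variance <- function(maf) 2 * maf * (1 - maf)

#' Append one SNP to a standardized genetic covariance matrix
#'
#' Builds the (P+1) x (P+1) covariance used by the per-SNP structural
#' model: the SNP's variance is 2 maf (1 - maf) and its standardized
#' covariance with phenotype p is (z_p / sqrt(N_p)) sqrt(2 maf (1 - maf)).
#' The expanded sampling covariance treats the SNP elements as independent
#' of the LDSC elements, with var(s_gp) = 2 maf (1 - maf) / N_p and the SNP
#' variance itself a known constant.
#'
#' @param model_cov A standardized `genetic_covariance`.
#' @param z,n Per-phenotype Z statistics and sample sizes for the SNP.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return List with `s` (the augmented matrix, SNP last), `v` (sampling
#'   covariance of its half-vectorized elements) and `var_snp`.
#' @export
expand_covariance_for_snp <- function(model_cov, z, n, maf) {
  stopifnot(inherits(model_cov, "genetic_covariance"))
  p <- length(model_cov$labels)
  if (length(z) != p || length(n) != p) {
    stop("need one z and n per phenotype")
  }
  if (is.na(maf) || maf <= 0 || maf > 0.5) {
    stop("maf must be available and in (0, 0.5]")
  }
  var_g <- snp_variance(maf)
  s_gp <- z / sqrt(n) * sqrt(var_g)
  s_aug <- rbind(cbind(model_cov$s, s_gp), c(s_gp, var_g))
  labs <- c(model_cov$labels, "SNP")
  dimnames(s_aug) <- list(labs, labs)

  idx <- vech_index(p + 1)
  n_elem <- nrow(idx)
  v_aug <- matrix(0, n_elem, n_elem)
  base <- vech_index(p)
  # embed the existing V (elements not involving the SNP keep their order)
  old <- which(idx[, 1] <= p & idx[, 2] <= p)
  v_aug[old, old] <- model_cov$v
  snp_elem <- which(idx[, 1] == p + 1 & idx[, 2] <= p)
  v_aug[cbind(snp_elem, snp_elem)] <- var_g / n[idx[snp_elem, 2]]
  list(s = s_aug, v = v_aug, var_snp = var_g)
}

# Fast fixed-mode estimator: gamma_hat = (L' D L)^-1 L' sqrt(D) z / sqrt(vg)
# with D = diag(N_p), the exact DWLS solution for the SNP paths when the
# measurement model is held fixed.
fixed_mode_fit <- function(lambda, z, n, var_g) {
  a <- crossprod(lambda, lambda * n)
  b <- drop(crossprod(lambda, sqrt(n) * z))
  ainv <- solve(a)
  gamma <- drop(ainv %*% b) / sqrt(var_g)
  se <- sqrt(diag(ainv) / var_g)
  list(beta = gamma, se = se)
}

# Full per-SNP refit: loadings, factor correlations and SNP paths estimated
# jointly on the augmented matrix by the same DWLS criterion.
refit_mode_fit <- function(model, gencov, z, n, maf) {
  aug <- expand_covariance_for_snp(gencov, z, n, maf)
  p <- length(gencov$labels)
  k <- ncol(model$lambda)
  pidx <- param_index(model$spec)
  n_load <- nrow(pidx$load)
  n_phi <- nrow(pidx$phi)
  od <- vech_offdiag(p)
  w_od <- 1 / pmax(diag(gencov$v[od$mask, od$mask, drop = FALSE]), 1e-12)
  w_snp <- n / aug$var_snp  # inverse sampling variance of s_gp
  s_od <- gencov$s[od$idx]
  s_gp <- aug$s[p + 1, seq_len(p)]

  start <- c(model$lambda[pidx$load],
             if (n_phi > 0) model$phi[pidx$phi] else numeric(0),
             rep(0, k))
  objective <- function(par) {
    mp <- unpack_params(par[seq_len(n_load + n_phi)], pidx)
    gamma <- par[n_load + n_phi + seq_len(k)]
    sig <- tcrossprod(mp$lambda %*% mp$phi, mp$lambda)
    r1 <- s_od - sig[od$idx]
    r2 <- s_gp - aug$var_snp * drop(mp$lambda %*% gamma)
    sum(w_od * r1^2) + sum(w_snp * r2^2)
  }
  opt <- stats::nlminb(start, objective,
                       lower = c(rep(-1.5, n_load), rep(-0.98, n_phi),
                                 rep(-5, k)),
                       upper = c(rep(1.5, n_load), rep(0.98, n_phi),
                                 rep(5, k)),
                       control = list(iter.max = 300))
  gamma <- opt$par[n_load + n_phi + seq_len(k)]
  # SE from the fixed-mode information at the refitted measurement model
  mp <- unpack_params(opt$par[seq_len(n_load + n_phi)], pidx)
  se <- fixed_mode_fit(mp$lambda, z, n, aug$var_snp)$se
  list(beta = gamma, se = se, converged = opt$convergence == 0)
}

#' Multivariate GWAS of the latent factors
#'
#' Estimates, for every SNP in the panel, the SNP-to-factor effects for all
#' factors of a fitted measurement model simultaneously, with Wald tests
#' and genome-wide significance flags at p < 5e-8.
#'
#' @param model A converged `factor_model`.
#' @param panel A `sumstats_panel` whose SNPs carry `maf` (required for the
#'   genotype-variance scaling).
#' @param gencov Standardized `genetic_covariance` (required for
#'   `mode = "refit"`; unused in fixed mode).
#' @param mode `"fixed"` (default: measurement model held at the no-SNP
#'   solution, fast) or `"refit"` (all free parameters re-estimated per
#'   SNP).
#' @param gws_threshold Genome-wide significance threshold (default 5e-8).
#' @return data.frame with one row per SNP x factor: `snp_id`, `chrom`,
#'   `bp`, `a1`, `a2`, `factor`, `beta`, `se`, `z`, `p`, `gws`, `n_eff`
#'   (mean per-phenotype N) and `locus_id` (NA until [clump_loci()]).
#' @export
snp_factor_gwas <- function(model, panel, gencov = NULL,
                            mode = c("fixed", "refit"),
                            gws_threshold = 5e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "factor_model"), inherits(panel, "sumstats_panel"))
  if (!isTRUE(model$converged)) stop("measurement model did not converge")
  if (mode == "refit" && is.null(gencov)) {
    stop("refit mode needs the standardized genetic covariance")
  }
  ord <- match(rownames(model$lambda), panel$phenotypes)
  if (anyNA(ord)) stop("model phenotypes missing from panel")
  maf <- panel$snps$maf
  if (anyNA(maf)) stop("maf required for every SNP in the latent GWAS")
  z <- panel$z[, ord, drop = FALSE]
  n <- panel$n[, ord, drop = FALSE]
  k <- ncol(model$lambda)
  m <- nrow(z)
  var_g <- snp_variance(maf)

  beta <- matrix(NA_real_, m, k)
  se <- matrix(NA_real_, m, k)
  if (mode == "fixed") {
    const_n <- all(abs(sweep(n, 2, n[1, ])) < 1e-9)
    if (const_n) {
      a <- crossprod(model$lambda, model$lambda * n[1, ])
      proj <- solve(a, t(model$lambda * sqrt(n[1, ])))  # k x P
      beta <- t(proj %*% t(z)) / sqrt(var_g)
      se <- outer(1 / sqrt(var_g), sqrt(diag(solve(a))))
    } else {
      for (j in seq_len(m)) {
        f <- fixed_mode_fit(model$lambda, z[j, ], n[j, ], var_g[j])
        beta[j, ] <- f$beta
        se[j, ] <- f$se
      }
    }
  } else {
    for (j in seq_len(m)) {
      f <- refit_mode_fit(model, gencov, z[j, ], n[j, ], maf[j])
      beta[j, ] <- f$beta
      se[j, ] <- f$se
    }
  }
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  res <- data.frame(
    snp_id = rep(panel$snps$snp_id, k),
    chrom = rep(panel$snps$chrom, k),
    bp = rep(panel$snps$bp, k),
    a1 = rep(panel$snps$a1, k),
    a2 = rep(panel$snps$a2, k),
    factor = rep(colnames(model$lambda), each = m),
    beta = as.vector(beta), se = as.vector(se),
    z = as.vector(zstat), p = as.vector(pval),
    gws = as.vector(pval) < gws_threshold,
    n_eff = rep(rowMeans(n), k),
    locus_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

# Median of the chi-square(1) distribution; lambda_GC divides the median
# observed z^2 by this reference value.
CHISQ1_MEDIAN <- 0.4549364

#' Genomic inflation diagnostics for one factor's GWAS
#'
#' lambda_GC = median(z^2) / 0.45494 (the chi-square-1 median). When an
#' LD-score table is supplied the LDSC intercept of the factor GWAS is also
#' estimated — an intercept near 1 with lambda above 1 indicates
#' polygenicity rather than confounding.
#'
#' @param results Rows of a [snp_factor_gwas()] table for a single factor.
#' @param ldscores Optional LD-score table for the intercept.
#' @return An `inflation_report`: `lambda_gc`, `ldsc_intercept` (NA without
#'   LD scores), `factor`, `m`.
#' @export
genomic_lambda <- function(results, ldscores = NULL) {
  if (length(unique(results$factor)) > 1) {
    stop("genomic_lambda expects results for a single factor")
  }
  lam <- stats::median(results$z^2) / CHISQ1_MEDIAN
  icpt <- NA_real_
  if (!is.null(ldscores)) {
    idx <- match(results$snp_id, ldscores$snp_id)
    keep <- !is.na(idx)
    fit <- estimate_h2(results$z[keep], results$n_eff[keep],
                       ldscores$l2[idx[keep]])
    icpt <- fit$intercept
  }
  structure(list(lambda_gc = lam, ldsc_intercept = icpt,
                 factor = results$factor[1], m = nrow(results)),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("inflation_report [%s]: lambda = %.3f, LDSC intercept = %s (m = %d)\n",
              x$factor, x$lambda_gc,
              ifelse(is.na(x$ldsc_intercept), "NA",
                     sprintf("%.3f", x$ldsc_intercept)), x$m))
  invisible(x)
}

#' Greedy distance-based clumping of genome-wide significant SNPs
#'
#' Sorts GWS SNPs by ascending p; the most significant remaining SNP
#' becomes a locus lead and claims every GWS SNP within the window on the
#' same chromosome; repeat until all GWS SNPs are assigned. When the same
#' SNP appears for several factors, its smallest p is used for ordering and
#' all its rows receive the same locus.
#'
#' @param results A [snp_factor_gwas()] table with `chrom` and `bp`.
#' @param window_kb Clump half-window in kilobases (default 250).
#' @return `results` with `locus_id` filled for GWS rows (NA elsewhere),
#'   with attribute `loci`: data.frame of lead SNPs (locus_id, lead snp,
#'   chrom, bp range, min p).
#' @export
clump_loci <- function(results, window_kb = 250) {
  window <- window_kb * 1000
  gws <- results[results$gws, , drop = FALSE]
  results$locus_id <- NA_integer_
  if (nrow(gws) == 0) {
    attr(results, "loci") <- data.frame(locus_id = integer(0),
                                        lead_snp = character(0),
                                        chrom = integer(0),
                                        bp_min = numeric(0),
                                        bp_max = numeric(0),
                                        min_p = numeric(0))
    return(results)
  }
  if (anyNA(gws$chrom) || anyNA(gws$bp)) {
    stop("clumping needs chrom and bp for every GWS SNP")
  }
  snp <- stats::aggregate(p ~ snp_id + chrom + bp, data = gws, FUN = min)
  snp <- snp[order(snp$p, snp$snp_id), , drop = FALSE]
  snp$locus <- NA_integer_
  lead <- character(0)
  locus <- 0L
  while (anyNA(snp$locus)) {
    locus <- locus + 1L
    top <- which(is.na(snp$locus))[1]
    claim <- is.na(snp$locus) & snp$chrom == snp$chrom[top] &
      abs(snp$bp - snp$bp[top]) <= window
    snp$locus[claim] <- locus
    lead <- c(lead, snp$snp_id[top])
  }
  results$locus_id[results$gws] <-
    snp$locus[match(gws$snp_id, snp$snp_id)]
  loci <- do.call(rbind, lapply(seq_len(locus), function(lc) {
    rows <- snp[snp$locus == lc, , drop = FALSE]
    data.frame(locus_id = lc, lead_snp = lead[lc], chrom = rows$chrom[1],
               bp_min = min(rows$bp), bp_max = max(rows$bp),
               min_p = min(rows$p))
  }))
  attr(results, "loci") <- loci
  results
}

#' Write one factor's GWAS in the .sumstats dialect
#'
#' Columns SNP, A1, A2, N, Z, P; N is the effective sample size convention
#' (mean per-phenotype N).
#'
#' @param results Rows of a [snp_factor_gwas()] table for one factor.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factor_gwas <- function(results, path) {
  if (length(unique(results$factor)) > 1) {
    stop("write one factor at a time")
  }
  out <- data.frame(SNP = results$snp_id, CHR = results$chrom,
                    BP = results$bp, A1 = results$a1, A2 = results$a2,
                    N = results$n_eff, Z = results$z, P = results$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
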