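#' @title Synthetic GWAS summary statistics with known factor structure
#' @name synthetic_data
#' @description
#' Simulates per-SNP Z statistics directly from the LDSC moment model: for
#' SNP j with LD score l_j, z_j is multivariate normal with mean zero and
#' covariance C_j = D^(1/2) (Sigma_g l_j / M) D^(1/2) + C_e, where D is the
#' diagonal of sample sizes, Sigma_g the factor-structured genetic
#' covariance and C_e a unit-diagonal error correlation whose off-diagonal
#' encodes sample overlap. This is a model-level simulator (no genotypes):
#' it gives exact control over Sigma_g at desk scale, at the price of not
#' emulating realistic local LD or annotation-dependent architecture.
NULL

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Ground-truth configuration for the simulator
#'
#' The genetic covariance implied by the configuration is
#' Sigma_g = D_h^(1/2) (Lambda Phi Lambda' + Theta) D_h^(1/2), where
#' Lambda/Phi are the standardized loadings and factor correlation,
#' Theta = 1 - diag(Lambda Phi Lambda') the standardized residual genetic
#' variances, and D_h the per-phenotype heritabilities. The default mirrors
#' the study design at reduced scale: 12 regional phenotypes, 2 correlated
#' factors with 6 markers each, loadings 0.5-0.8, h2 = 0.3, N = 30,000,
#' M = 20,000 SNPs over chromosomes 1-22.
#'
#' @param p Number of phenotypes.
#' @param m Number of SNPs.
#' @param n Per-phenotype sample size (scalar or length-p).
#' @param lambda P x k standardized loading matrix (default: two 6-marker
#'   blocks with loadings 0.5-0.8).
#' @param phi k x k factor correlation (default off-diagonal 0.45).
#' @param h2 Per-phenotype SNP heritability (scalar or length-p).
#' @param overlap_rho Error-side correlation from phenotypic sample overlap
#'   (default 0; absorbed by the LDSC intercept downstream).
#' @param ld_block_size SNPs per LD-score block.
#' @param ld_mean Mean LD score of the shifted-gamma block model.
#' @param injected_effects Optional data.frame(snp_id, factor, a) of fixed
#'   SNP-to-factor effects for [inject_fixed_snp_effects()].
#' @param seed Integer seed controlling all randomness of the dataset.
#' @return A `truth_config` with fields including `sigma_g` (the implied
#'   genetic covariance) and `resid_h2`.
#' @export
truth_config <- function(p = 12, m = 20000, n = 30000,
                         lambda = NULL, phi = NULL, h2 = 0.3,
                         overlap_rho = 0, ld_block_size = 50, ld_mean = 30,
                         injected_effects = NULL, seed = 1) {
  if (is.null(lambda)) {
    stopifnot(p %% 2 == 0)
    half <- p / 2
    load <- seq(0.5, 0.8, length.out = half)
    lambda <- matrix(0, p, 2)
    lambda[seq_len(half), 1] <- load
    lambda[half + seq_len(half), 2] <- load
  }
  lambda <- as.matrix(lambda)
  k <- ncol(lambda)
  if (is.null(phi)) {
    phi <- diag(k)
    phi[phi == 0] <- 0.45
  }
  stopifnot(nrow(lambda) == p, nrow(phi) == k, all(diag(phi) == 1))
  h2 <- rep_len(h2, p)
  n <- rep_len(n, p)
  stopifnot(all(h2 >= 0), all(h2 <= 1), all(n > 0), ld_mean >= 1)
  comm <- diag(tcrossprod(lambda %*% phi, lambda))
  if (any(comm > 1 + 1e-12)) {
    stop("configuration error: communalities exceed 1 (loadings too large)")
  }
  theta_std <- pmax(1 - comm, 0)
  corr_g <- tcrossprod(lambda %*% phi, lambda) + diag(theta_std, p)
  ev <- eigen(corr_g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("configuration error: implied Sigma_g not PSD")
  if (overlap_rho < -1 / (p - 1) || overlap_rho >= 1) {
    stop("configuration error: overlap_rho makes the error correlation non-PSD")
  }
  sigma_g <- corr_g * tcrossprod(sqrt(h2))
  labels <- sprintf("region%02d", seq_len(p))
  dimnames(sigma_g) <- list(labels, labels)
  structure(list(p = p, m = m, n_per_phenotype = n,
                 lambda_true = lambda, phi_true = phi,
                 resid_h2 = h2 * theta_std, h2 = h2,
                 sigma_g = sigma_g, overlap_rho = overlap_rho,
                 ld_block_size = ld_block_size, ld_mean = ld_mean,
                 injected_effects = injected_effects,
                 phenotype_names = labels, seed = as.integer(seed)),
            class = "truth_config")
}

#' Block LD-score model across chromosomes 1-22
#'
#' Contiguous blocks of `block_size` SNPs share one LD score drawn from a
#' shifted gamma, l = 1 + Gamma(shape = 4, mean = ld_mean - 1), so every
#' l >= 1. Chromosomes 1-22 each receive a contiguous share of the blocks;
#' base positions are sequential within chromosome (10 kb spacing).
#'
#' @param m Number of SNPs.
#' @param block_size SNPs per block.
#' @param ld_mean Target mean LD score (>= 1).
#' @param seed Integer seed.
#' @return LD-score data.frame (`snp_id`, `chrom`, `bp`, `l2`).
#' @export
ldscore_block_model <- function(m, block_size = 50, ld_mean = 30, seed = 1) {
  stopifnot(m >= 1, block_size >= 1, ld_mean >= 1)
  n_blocks <- ceiling(m / block_size)
  block <- rep(seq_len(n_blocks), each = block_size)[seq_len(m)]
  l_block <- run_seeded(seed, {
    if (ld_mean > 1) {
      shape <- 4
      1 + stats::rgamma(n_blocks, shape = shape,
                        scale = (ld_mean - 1) / shape)
    } else {
      rep(1, n_blocks)
    }
  })
  chrom_block <- as.integer(cut(seq_len(n_blocks), breaks = 22,
                                labels = FALSE))
  chrom <- chrom_block[block]
  bp <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    10000 * seq_along(i)
  }), use.names = FALSE)
  data.frame(snp_id = paste0("rs", seq_len(m)), chrom = chrom,
             bp = bp, l2 = l_block[block], stringsAsFactors = FALSE)
}

#' Simulate a Z-statistic panel from the LDSC moment model
#'
#' @param truth A `truth_config`.
#' @param ldscores LD-score table from [ldscore_block_model()] with
#'   `truth$m` SNPs.
#' @return A `sumstats_panel`; alleles fixed to A1 = A, A2 = G, per-SNP maf
#'   uniform in [0.05, 0.5], fully determined by `truth$seed`.
#' @export
simulate_z_panel <- function(truth, ldscores) {
  stopifnot(inherits(truth, "truth_config"), nrow(ldscores) == truth$m)
  p <- truth$p
  m <- truth$m
  d_sqrt <- sqrt(truth$n_per_phenotype)
  c_e <- matrix(truth$overlap_rho, p, p)
  diag(c_e) <- 1
  sig_base <- truth$sigma_g * tcrossprod(d_sqrt) / m
  run_seeded(truth$seed, {
    z <- matrix(NA_real_, m, p)
    for (l2 in unique(ldscores$l2)) {
      rows <- which(ldscores$l2 == l2)
      c_j <- sig_base * l2 + c_e
      ch <- tryCatch(chol(c_j), error = function(e) {
        stop("configuration error: per-SNP covariance not PSD")
      })
      z[rows, ] <- matrix(stats::rnorm(length(rows) * p),
                          length(rows), p) %*% ch
    }
    maf <- stats::runif(m, 0.05, 0.5)
    snps <- data.frame(snp_id = ldscores$snp_id, chrom = ldscores$chrom,
                       bp = ldscores$bp, a1 = "A", a2 = "G", maf = maf,
                       stringsAsFactors = FALSE)
    n <- matrix(rep(truth$n_per_phenotype, each = m), m, p)
    colnames(z) <- colnames(n) <- truth$phenotype_names
    new_sumstats_panel(snps, z, n, truth$phenotype_names)
  })
}

#' Inject fixed SNP-to-factor effects into a panel
#'
#' For each configured (snp_id, factor, a), adds
#' sqrt(N_p) * lambda_p * a * sqrt(2 maf (1 - maf)) to phenotype p's Z,
#' where lambda_p is the phenotype's standardized loading on that factor —
#' the mean shift a true standardized SNP-to-factor effect of size `a`
#' induces under the measurement model. A zero effect is a no-op.
#'
#' @param panel A `sumstats_panel` from [simulate_z_panel()].
#' @param truth The `truth_config` carrying `injected_effects`.
#' @return The panel with shifted Z statistics.
#' @export
inject_fixed_snp_effects <- function(panel, truth) {
  eff <- truth$injected_effects
  if (is.null(eff) || nrow(eff) == 0) return(panel)
  k <- ncol(truth$lambda_true)
  for (r in seq_len(nrow(eff))) {
    j <- match(eff$snp_id[r], panel$snps$snp_id)
    if (is.na(j)) stop("injection at unknown snp_id: ", eff$snp_id[r])
    f <- eff$factor[r]
    if (is.character(f)) f <- match(f, paste0("F", seq_len(k)))
    if (is.na(f) || f < 1 || f > k) {
      stop("injection at unknown factor: ", eff$factor[r])
    }
    maf <- panel$snps$maf[j]
    shift <- sqrt(panel$n[j, ]) * truth$lambda_true[, f] * eff$a[r] *
      sqrt(snp_variance(maf))
    panel$z[j, ] <- panel$z[j, ] + shift
  }
  panel
}

#' Generate a complete synthetic dataset
#'
#' LD scores, Z panel and any injected effects in one call, all controlled
#' by `truth$seed`.
#'
#' @param truth A `truth_config`.
#' @return A `synthetic_dataset`: list with `panel`, `ldscores`, `truth`.
#' @export
generate_dataset <- function(truth) {
  ldscores <- ldscore_block_model(truth$m, truth$ld_block_size,
                                  truth$ld_mean, seed = truth$seed)
  panel <- simulate_z_panel(truth, ldscores)
  panel <- inject_fixed_snp_effects(panel, truth)
  structure(list(panel = panel, ldscores = ldscores, truth = truth),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' One `.sumstats` file per phenotype, one LD-score table, one truth JSON;
#' reading the files back through the panel reader reproduces the panel.
#'
#' @param dataset A `synthetic_dataset`.
#' @param directory Output directory (must not exist unless `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (dir.exists(directory) && !overwrite) {
    stop("directory exists (use overwrite = TRUE): ", directory)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (ph in dataset$panel$phenotypes) {
    write_sumstats(dataset$panel, ph,
                   file.path(directory, paste0(ph, ".sumstats")))
  }
  write_ldscores(dataset$ldscores, file.path(directory, "ldscores.tsv"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(p = tr$p, m = tr$m, n_per_phenotype = tr$n_per_phenotype,
         lambda_true = tr$lambda_true, phi_true = tr$phi_true,
         h2 = tr$h2, resid_h2 = tr$resid_h2,
         overlap_rho = tr$overlap_rho,
         ld_block_size = tr$ld_block_size, ld_mean = tr$ld_mean,
         injected_effects = tr$injected_effects,
         phenotype_names = tr$phenotype_names, seed = tr$seed),
    file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Re-parse a truth JSON written by [write_synthetic_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return An equivalent `truth_config`.
#' @export
read_truth_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  inj <- j$injected_effects
  if (!is.null(inj)) inj <- as.data.frame(inj)
  truth_config(p = j$p, m = j$m, n = j$n_per_phenotype,
               lambda = as.matrix(j$lambda_true),
               phi = as.matrix(j$phi_true),
               h2 = j$h2, overlap_rho = j$overlap_rho,
               ld_block_size = j$ld_block_size, ld_mean = j$ld_mean,
               injected_effects = inj, seed = j$seed)
}
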