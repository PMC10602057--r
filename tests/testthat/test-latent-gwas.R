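test_that("covariance expansion appends the SNP with the stated arithmetic", {
  fx <- true_model_fixture()
  p <- length(fx$gencov$labels)
  z <- rep(5, p); n <- rep(10000, p)
  aug <- expand_covariance_for_snp(fx$gencov, z, n, maf = 0.3)
  expect_equal(dim(aug$s), c(p + 1, p + 1))
  expect_equal(aug$s, t(aug$s), tolerance = 1e-14)
  # standardized beta z / sqrt(N) = 0.05 before genotype-variance scaling
  expect_equal(aug$s[p + 1, 1], 0.05 * sqrt(2 * 0.3 * 0.7))
  expect_equal(expand_covariance_for_snp(fx$gencov, z, n, 0.5)$var_snp, 0.5)
  expect_error(expand_covariance_for_snp(fx$gencov, z, n, NA), "maf")
  expect_error(expand_covariance_for_snp(fx$gencov, z[-1], n[-1], 0.3),
               "per phenotype")
})

test_that("a single-indicator factor reproduces the univariate standardized beta", {
  labels <- "only"
  spec <- structure(list(factor_map = list(F1 = labels),
                         threshold_used = 0.3, labels = labels),
                    class = "cfa_spec")
  model <- structure(list(lambda = matrix(1, 1, 1,
                                          dimnames = list(labels, "F1")),
                          lambda_se = matrix(0.01, 1, 1), phi = diag(1),
                          theta = 0, spec = spec, converged = TRUE,
                          heywood = FALSE, n_free_params = 2),
                     class = "factor_model")
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = 1L, bp = c(1e5, 2e5),
                     a1 = "A", a2 = "G", maf = c(0.2, 0.4))
  z <- matrix(c(3.1, -1.4), 2, 1, dimnames = list(NULL, labels))
  n <- matrix(25000, 2, 1, dimnames = list(NULL, labels))
  panel <- structure(list(snps = snps, z = z, n = n, phenotypes = labels),
                     class = "sumstats_panel")
  res <- snp_factor_gwas(model, panel)
  var_g <- 2 * snps$maf * (1 - snps$maf)
  expect_equal(res$beta, z[, 1] / (sqrt(25000) * sqrt(var_g)))
  expect_equal(res$z, z[, 1], tolerance = 1e-12)
})

test_that("genome-wide significance flips exactly at p = 5e-8", {
  labels <- "only"
  spec <- structure(list(factor_map = list(F1 = labels),
                         threshold_used = 0.3, labels = labels),
                    class = "cfa_spec")
  model <- structure(list(lambda = matrix(1, 1, 1,
                                          dimnames = list(labels, "F1")),
                          lambda_se = matrix(0.01, 1, 1), phi = diag(1),
                          theta = 0, spec = spec, converged = TRUE,
                          heywood = FALSE, n_free_params = 2),
                     class = "factor_model")
  z_above <- -qnorm(4.9e-9 / 2)   # p = 4.9e-9 -> GWS
  z_below <- -qnorm(5.1e-8 / 2)   # p = 5.1e-8 -> not GWS
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = 1L, bp = c(1e5, 2e5),
                     a1 = "A", a2 = "G", maf = 0.25)
  panel <- structure(list(snps = snps,
                          z = matrix(c(z_above, z_below), 2, 1,
                                     dimnames = list(NULL, labels)),
                          n = matrix(10000, 2, 1,
                                     dimnames = list(NULL, labels)),
                          phenotypes = labels),
                     class = "sumstats_panel")
  res <- snp_factor_gwas(model, panel)
  expect_identical(res$gws, c(TRUE, FALSE))
  expect_identical(res$gws, res$p < 5e-8)
})

test_that("an injected SNP-to-factor effect is recovered and null p-values are uniform", {
  inj <- data.frame(snp_id = paste0("rs", seq(100, 5000, by = 100)),
                    factor = "F1", a = 0.05)
  tc <- truth_config(m = 20000, h2 = 0, injected_effects = inj, seed = 11)
  ds <- generate_dataset(tc)
  fx <- true_model_fixture(truth_config(m = 100))
  res <- snp_factor_gwas(fx$model, ds$panel)
  r1 <- res[res$factor == "F1", ]
  hit <- r1$snp_id %in% inj$snp_id
  # SNP with ~zero covariance to every region -> beta near 0
  expect_lt(median(abs(r1$beta[!hit])), 3 * median(r1$se[!hit]))
  mc_se <- sd(r1$beta[hit]) / sqrt(sum(hit))
  expect_lt(abs(mean(r1$beta[hit]) - 0.05), 3 * mc_se)
  expect_gt(ks.test(r1$p[!hit], "punif")$p.value, 0.01)
})

test_that("refit and fixed modes agree for weak SNP effects", {
  inj <- data.frame(snp_id = paste0("rs", 1:10), factor = "F2", a = 0.02)
  tc <- truth_config(m = 400, h2 = 0, injected_effects = inj,
                     ld_block_size = 10, seed = 13)
  ds <- generate_dataset(tc)
  fx <- true_model_fixture(truth_config(m = 100))
  keep <- ds$panel$snps$snp_id %in% paste0("rs", 1:30)
  small <- ds$panel
  small$snps <- small$snps[keep, ]
  small$z <- small$z[keep, , drop = FALSE]
  small$n <- small$n[keep, , drop = FALSE]
  fixed <- snp_factor_gwas(fx$model, small)
  refit <- snp_factor_gwas(fx$model, small, gencov = fx$gencov, mode = "refit")
  rel <- abs(refit$beta - fixed$beta) / pmax(abs(fixed$beta), 0.01)
  expect_lt(max(rel), 0.1)
})

test_that("genomic lambda follows the median chi-square convention", {
  res0 <- data.frame(factor = "F1", z = c(-sqrt(0.4549364), 0, sqrt(0.4549364)),
                     snp_id = paste0("rs", 1:3), n_eff = 1000)
  expect_equal(genomic_lambda(res0)$lambda_gc, 1.0, tolerance = 1e-6)
  res1 <- data.frame(factor = "F1", z = c(1, 1, 1),
                     snp_id = paste0("rs", 1:3), n_eff = 1000)
  expect_equal(genomic_lambda(res1)$lambda_gc, 1 / 0.4549364,
               tolerance = 1e-6)
  expect_equal(round(genomic_lambda(res1)$lambda_gc, 3), 2.198)
  two <- rbind(res0, transform(res1, factor = "F2"))
  expect_error(genomic_lambda(two), "single factor")
})

test_that("greedy clumping merges within the window and splits beyond it", {
  base <- data.frame(factor = "F1", a1 = "A", a2 = "G", n_eff = 1e4,
                     beta = 1, se = 0.1, z = 10, stringsAsFactors = FALSE)
  mk <- function(snp, chrom, bp, p) {
    cbind(base, data.frame(snp_id = snp, chrom = chrom, bp = bp, p = p,
                           gws = p < 5e-8, locus_id = NA_integer_))
  }
  near <- rbind(mk("rs1", 1, 1e6, 1e-10), mk("rs2", 1, 1.1e6, 1e-9))
  res_near <- clump_loci(near, window_kb = 250)
  expect_equal(nrow(attr(res_near, "loci")), 1)
  far <- rbind(mk("rs1", 1, 1e6, 1e-10), mk("rs2", 1, 1.3e6, 1e-9))
  res_far <- clump_loci(far, window_kb = 250)
  expect_equal(nrow(attr(res_far, "loci")), 2)
})

test_that("clumping matches brute-force enumeration of the greedy rule", {
  set.seed(4)
  snps <- data.frame(snp_id = paste0("rs", 1:8),
                     chrom = c(1, 1, 1, 1, 1, 2, 2, 2),
                     bp = c(1e6, 1.2e6, 1.35e6, 2.0e6, 2.2e6,
                            5e5, 6e5, 1.5e6),
                     p = c(1e-12, 1e-9, 1e-10, 1e-11, 1e-9,
                           1e-13, 1e-8 / 2, 1e-9))
  res <- cbind(snps, data.frame(factor = "F1", a1 = "A", a2 = "G",
                                n_eff = 1e4, beta = 1, se = 0.1, z = 9,
                                gws = TRUE, locus_id = NA_integer_))
  out <- clump_loci(res, window_kb = 250)
  # independent brute-force implementation of the same rule
  todo <- snps[order(snps$p, snps$snp_id), ]
  locus <- setNames(rep(NA_integer_, 8), todo$snp_id)
  lid <- 0
  for (i in seq_len(8)) {
    id <- todo$snp_id[i]
    if (!is.na(locus[id])) next
    lid <- lid + 1
    for (j in seq_len(8)) {
      jd <- todo$snp_id[j]
      if (is.na(locus[jd]) && todo$chrom[j] == todo$chrom[i] &&
          abs(todo$bp[j] - todo$bp[i]) <= 250000) {
        locus[jd] <- lid
      }
    }
  }
  expect_equal(out$locus_id, unname(locus[out$snp_id]))
  expect_equal(nrow(attr(out, "loci")), max(locus))
})

test_that("factor GWAS of a pure-noise panel yields no genome-wide hits", {
  tc <- truth_config(m = 20000, h2 = 0, seed = 19)
  ds <- generate_dataset(tc)
  fx <- true_model_fixture(truth_config(m = 100))
  res <- snp_factor_gwas(fx$model, ds$panel)
  expect_equal(sum(res$gws), 0)
  lam <- genomic_lambda(res[res$factor == "F1", ], ds$ldscores)
  expect_gt(lam$lambda_gc, 0.95)
  expect_lt(lam$lambda_gc, 1.05)
  expect_lt(abs(lam$ldsc_intercept - 1), 0.05)
})
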