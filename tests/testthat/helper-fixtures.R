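# Shared fixtures built in code: tiny record sets, a ground-truth
# measurement model, and a standardized covariance with known structure.

make_records <- function(snp_id, a1, a2, z, n = 10000, chrom = 1,
                         bp = seq_along(snp_id) * 1e5, maf = 0.3,
                         phenotype = "ph") {
  rec <- data.frame(snp_id = snp_id, chrom = chrom, bp = bp,
                    a1 = a1, a2 = a2, n = n, z = z, maf = maf,
                    stringsAsFactors = FALSE)
  attr(rec, "phenotype") <- phenotype
  rec
}

write_sumstats_text <- function(lines) {
  path <- tempfile(fileext = ".sumstats")
  writeLines(lines, path)
  path
}

# Exact two-factor measurement structure used across CFA / latent-GWAS
# tests: the model-implied correlation matrix with a tiny diagonal V so the
# DWLS fit is exact.
true_model_fixture <- function(tc = truth_config(m = 100)) {
  p <- tc$p
  corr <- tcrossprod(tc$lambda_true %*% tc$phi_true, tc$lambda_true)
  diag(corr) <- 1
  dimnames(corr) <- list(tc$phenotype_names, tc$phenotype_names)
  n_elem <- p * (p + 1) / 2
  gencov <- structure(list(labels = tc$phenotype_names, s = corr,
                           v = diag(1e-4, n_elem), intercepts = NULL,
                           chrom_subset = "all", n_blocks = 2, m = 100,
                           standardized = TRUE),
                      class = "genetic_covariance")
  spec <- structure(list(factor_map = list(F1 = tc$phenotype_names[1:(p / 2)],
                                           F2 = tc$phenotype_names[(p / 2 + 1):p]),
                         threshold_used = 0.3,
                         labels = tc$phenotype_names),
                    class = "cfa_spec")
  model <- fit_cfa(spec, gencov)
  list(tc = tc, gencov = gencov, spec = spec, model = model)
}

# Small universe for overlap tests.
toy_universe <- c("alpha", "beta", "gamma", "delta", "epsilon")
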