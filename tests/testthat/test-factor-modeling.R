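test_that("standardization rescales S to unit diagonal and V by the delta method", {
  s <- matrix(c(4, 2, 2, 4), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- structure(list(labels = c("a", "b"), s = s, v = diag(0.01, 3),
                      chrom_subset = "all", n_blocks = 10, m = 100,
                      standardized = FALSE),
                 class = "genetic_covariance")
  std <- standardize_to_correlation(g)
  expect_equal(diag(std$s), c(a = 1, b = 1))
  expect_equal(std$s[1, 2], 0.5)
  # diagonal elements become constants: zero sampling variance
  expect_equal(std$v[1, 1], 0)
  expect_equal(std$v[3, 3], 0)
  # already unit-diagonal input: matrix unchanged
  g2 <- g
  g2$s <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = dimnames(s))
  std2 <- standardize_to_correlation(g2)
  expect_equal(std2$s, g2$s)
  g3 <- g
  g3$s[1, 1] <- -1
  expect_error(standardize_to_correlation(g3), "a")
})

test_that("delta-method V scaling agrees with re-jackknifing the standardized estimator", {
  tc <- truth_config(p = 3, m = 8000, n = 30000,
                     lambda = matrix(c(0.7, 0.6, 0.5), 3, 1), phi = diag(1),
                     h2 = 0.3, seed = 8)
  ds <- generate_dataset(tc)
  g <- build_gencov_matrix(ds$panel, ds$ldscores, "all")
  std <- standardize_to_correlation(g)
  # brute force: standardize every leave-one-block-out replicate, jackknife
  p <- 3
  lt <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 2], lt[, 1]), ]
  off <- which(lt[, 1] != lt[, 2])
  loo_std <- t(apply(g$loo, 1, function(row) {
    m <- matrix(0, p, p)
    m[lower.tri(m, diag = TRUE)] <- row
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    cov2cor(m)[lower.tri(m, diag = TRUE)]
  }))
  v_jack <- jackknife_cov(loo_std)
  se_delta <- sqrt(diag(std$v))[off]
  se_jack <- sqrt(diag(v_jack))[off]
  expect_lt(max(abs(se_delta / se_jack - 1)), 0.1)
})

test_that("smoothing is a no-op on PD input and repairs an indefinite correlation", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_identical(smooth_to_pd(r), r)
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  fixed <- smooth_to_pd(bad)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8)
  expect_equal(diag(fixed), c(1, 1))
  expect_equal(fixed, t(fixed), tolerance = 1e-12)
})

test_that("EFA finds no shared variance in an identity correlation", {
  r <- diag(12)
  sols <- run_efa(r, 1)
  expect_true(sols[[1]]$converged)
  expect_lt(max(abs(sols[[1]]$loadings)), 0.1)
})

test_that("EFA recovers a clean two-factor block structure", {
  tc <- truth_config(p = 12)
  r <- tcrossprod(tc$lambda_true %*% tc$phi_true, tc$lambda_true)
  diag(r) <- 1
  dimnames(r) <- list(tc$phenotype_names, tc$phenotype_names)
  sols <- run_efa(r, 1:3)
  cong <- factor_congruence(tc$lambda_true, sols[[2]]$loadings)
  expect_true(all(cong >= 0.95))
  expect_equal(sols[[2]]$rotation, "promax")
  # eigenvalues reported non-increasing
  expect_true(all(diff(sols[[2]]$eigenvalues) <= 1e-10))
  expect_error(run_efa(r, 1:12), "smaller")
})

test_that("threshold carry-forward keeps 0.31, drops 0.29, honors cross-loadings", {
  l <- matrix(c(0.31, 0.29, 0.6, 0.55, 0.0,
                0.0, 0.0, 0.6, 0.0, 0.45), 5, 2,
              dimnames = list(paste0("r", 1:5), c("F1", "F2")))
  efa <- structure(list(k = 2, loadings = l, rotation = "promax",
                        eigenvalues = rep(1, 5), converged = TRUE),
                   class = "efa_solution")
  spec <- build_cfa_spec(efa, tau = 0.3)
  expect_true("r1" %in% spec$factor_map$F1)
  expect_false("r2" %in% spec$factor_map$F1)
  # r3 loads 0.6 on both factors: retained on both
  expect_true("r3" %in% spec$factor_map$F1 && "r3" %in% spec$factor_map$F2)
})

test_that("factors reduced to a single region are removed; zero factors is an error", {
  l <- matrix(c(0.7, 0.6, 0.5, 0.0, 0.0,
                0.0, 0.0, 0.0, 0.8, 0.2), 5, 2,
              dimnames = list(paste0("r", 1:5), c("F1", "F2")))
  efa <- structure(list(k = 2, loadings = l, rotation = "promax",
                        eigenvalues = rep(1, 5), converged = TRUE),
                   class = "efa_solution")
  expect_message(spec <- build_cfa_spec(efa, tau = 0.3), "removed")
  expect_equal(length(spec$factor_map), 1)
  expect_equal(spec$factor_map$F1, c("r1", "r2", "r3"))
  l0 <- matrix(c(0.2, 0.1, 0.05, 0.1), 4, 1,
               dimnames = list(paste0("r", 1:4), "F1"))
  efa0 <- structure(list(k = 1, loadings = l0, rotation = "none",
                         eigenvalues = rep(1, 4), converged = TRUE),
                    class = "efa_solution")
  expect_error(suppressMessages(build_cfa_spec(efa0, tau = 0.3)), "no factor")
})

test_that("DWLS fit is exact on data generated from the model", {
  fx <- true_model_fixture()
  expect_true(fx$model$converged)
  expect_lt(fx$model$fmin, 1e-10)
  nz <- fx$tc$lambda_true > 0
  expect_equal(fx$model$lambda[nz], fx$tc$lambda_true[nz], tolerance = 1e-6)
  expect_equal(fx$model$phi[1, 2], fx$tc$phi_true[1, 2], tolerance = 1e-6)
  expect_equal(unname(fx$model$theta),
               1 - diag(tcrossprod(fx$tc$lambda_true %*% fx$tc$phi_true,
                                   fx$tc$lambda_true)),
               tolerance = 1e-6)
  expect_false(fx$model$heywood)
})

test_that("DWLS estimates match an independent Nelder-Mead minimizer of the same loss", {
  labels <- c("x1", "x2", "x3")
  lam_true <- c(0.8, 0.7, 0.6)
  s <- tcrossprod(lam_true)
  diag(s) <- 1
  # perturb the off-diagonals
  s[1, 2] <- s[2, 1] <- s[1, 2] + 0.04
  s[1, 3] <- s[3, 1] <- s[1, 3] - 0.03
  s[2, 3] <- s[3, 2] <- s[2, 3] + 0.02
  dimnames(s) <- list(labels, labels)
  w <- c(2, 1, 4)  # explicit diagonal weights, vech off-diagonal order
  g <- structure(list(labels = labels, s = s, v = diag(0.1, 6),
                      standardized = TRUE),
                 class = "genetic_covariance")
  spec <- structure(list(factor_map = list(F1 = labels),
                         threshold_used = 0.3, labels = labels),
                    class = "cfa_spec")
  fit <- fit_cfa(spec, g, weights = w)
  # independent oracle: same discrepancy, generic simplex minimizer
  loss <- function(l) {
    sig <- tcrossprod(l)
    r <- c(s[2, 1] - sig[2, 1], s[3, 1] - sig[3, 1], s[3, 2] - sig[3, 2])
    sum(w * r^2)
  }
  oracle <- optim(c(0.5, 0.5, 0.5), loss, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$lambda[, 1]), oracle$par, tolerance = 1e-4)
  expect_equal(fit$fmin, oracle$value, tolerance = 1e-8)
})

test_that("fit statistics behave at the perfect-fit point and match hand SRMR", {
  fx <- true_model_fixture()
  expect_lt(fx$model$fit$srmr, 1e-6)
  expect_equal(fx$model$fit$cfi, 1)
  expect_equal(fx$model$fit$aic,
               fx$model$fit$chi2 + 2 * fx$model$fit$n_free_params)
  expect_gte(fx$model$fit$df, 0)

  # 2x2 toy: single off-diagonal residual of 0.1 over 3 unique elements
  labels <- c("a", "b")
  lam <- c(0.8, 0.5)
  s <- tcrossprod(lam); diag(s) <- 1
  s[1, 2] <- s[2, 1] <- s[1, 2] + 0.1
  dimnames(s) <- list(labels, labels)
  g <- structure(list(labels = labels, s = s, v = diag(0.01, 3),
                      standardized = TRUE),
                 class = "genetic_covariance")
  spec <- structure(list(factor_map = list(F1 = labels),
                         threshold_used = 0.3, labels = labels),
                    class = "cfa_spec")
  model <- structure(list(lambda = matrix(lam, 2, 1,
                                          dimnames = list(labels, "F1")),
                          lambda_se = matrix(0.1, 2, 1),
                          phi = diag(1), theta = 1 - lam^2, spec = spec,
                          n_free_params = 4, converged = TRUE,
                          heywood = FALSE),
                     class = "factor_model")
  fit <- compute_fit_stats(model, g)
  expect_equal(fit$srmr, sqrt(0.1^2 / 3), tolerance = 1e-12)
})

test_that("AIC adds exactly 2 per free parameter at fixed chi-square", {
  fx <- true_model_fixture()
  f <- fx$model$fit
  aic_with_extra_param <- f$chi2 + 2 * (f$n_free_params + 1)
  expect_equal(aic_with_extra_param, f$aic + 2)
})

test_that("pruning is a fixed point when all loadings are significant", {
  fx <- true_model_fixture()
  pruned <- prune_nonsignificant(fx$model, fx$gencov)
  expect_identical(pruned$spec$factor_map, fx$model$spec$factor_map)
  expect_lte(ncol(pruned$lambda), ncol(fx$model$lambda))
})

test_that("a true-zero cross-loading is pruned away in most seeds", {
  removed <- 0
  for (seed in 1:20) {
    tc <- truth_config(p = 12, m = 10000, seed = 300 + seed)
    ds <- generate_dataset(tc)
    ge <- build_gencov_matrix(ds$panel, ds$ldscores, "even")
    corr <- standardize_to_correlation(ge)
    # spec with a spurious cross-loading of region07 on F1
    spec <- structure(list(
      factor_map = list(F1 = tc$phenotype_names[c(1:6, 7)],
                        F2 = tc$phenotype_names[7:12]),
      threshold_used = 0.3, labels = tc$phenotype_names),
      class = "cfa_spec")
    fit <- suppressWarnings(fit_cfa(spec, corr))
    if (!fit$converged) next
    pruned <- suppressWarnings(prune_nonsignificant(fit, corr))
    if (!("region07" %in% pruned$spec$factor_map$F1)) removed <- removed + 1
  }
  expect_gte(removed, 18)
})

test_that("model selection minimizes AIC with deterministic tie-breaking", {
  mk <- function(aic, k, nf, converged = TRUE) {
    structure(list(lambda = matrix(0, 4, k), converged = converged,
                   fit = structure(list(aic = aic, n_free_params = nf),
                                   class = "fit_stats")),
              class = "factor_model")
  }
  picked <- select_best_model(list(mk(12, 3, 10), mk(10, 2, 8), mk(11, 1, 5)))
  expect_equal(picked$fit$aic, 10)
  # exact tie: fewer factors wins
  tie <- select_best_model(list(mk(10, 3, 9), mk(10, 2, 9)))
  expect_equal(ncol(tie$lambda), 2)
  # non-converged candidates are ignored; none converged is an error
  only_bad <- list(mk(1, 1, 3, converged = FALSE))
  expect_error(select_best_model(only_bad), "no converged")
  skipped <- select_best_model(list(mk(1, 1, 3, converged = FALSE),
                                    mk(50, 2, 8)))
  expect_equal(skipped$fit$aic, 50)
})

test_that("duplicate candidate specifications are deduplicated", {
  sp <- function(map) structure(list(factor_map = map, threshold_used = 0.3,
                                     labels = letters[1:6]),
                                class = "cfa_spec")
  a <- sp(list(F1 = c("a", "b"), F2 = c("c", "d")))
  b <- sp(list(F1 = c("c", "d"), F2 = c("b", "a")))  # same pattern
  c_ <- sp(list(F1 = c("a", "b", "c")))
  out <- dedupe_specs(list(a, b, c_))
  expect_equal(length(out), 2)
})
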