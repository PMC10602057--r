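#' Build a confirmatory model specification from an EFA solution
#'
#' Carries forward every positive rotated loading exceeding the threshold
#' tau; cross-loadings are kept whenever each exceeds tau on its factor.
#' Factors left with fewer than two regions do not constitute networks and
#' are removed (with a message).
#'
#' @param efa An `efa_solution` with loadings.
#' @param tau Carry-forward threshold, conventionally 0.3 or 0.5.
#' @return A `cfa_spec`: list with `factor_map` (named list of region-label
#'   vectors), `threshold_used`, and `labels` (the full phenotype set).
#' @export
build_cfa_spec <- function(efa, tau) {
  stopifnot(inherits(efa, "efa_solution"), is.numeric(tau), tau > 0)
  if (is.null(efa$loadings)) stop("EFA solution did not converge; no loadings")
  l <- efa$loadings
  labels <- rownames(l)
  fmap <- lapply(seq_len(ncol(l)), function(f) labels[l[, f] > tau])
  keep <- vapply(fmap, length, integer(1)) >= 2
  if (any(!keep)) {
    message(sum(!keep), " factor(s) with fewer than 2 regions above tau = ",
            tau, " removed")
  }
  fmap <- fmap[keep]
  if (length(fmap) == 0) stop("no factor retains >= 2 regions at tau = ", tau)
  names(fmap) <- paste0("F", seq_along(fmap))
  structure(list(factor_map = fmap, threshold_used = tau, labels = labels),
            class = "cfa_spec")
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat("cfa_spec (tau =", x$threshold_used, "):\n")
  for (f in names(x$factor_map)) {
    cat(" ", f, ":", paste(x$factor_map[[f]], collapse = ", "), "\n")
  }
  invisible(x)
}

# Canonical signature used to deduplicate redundant candidate models that
# arise from different (k, tau) combinations.
spec_signature <- function(spec) {
  sets <- vapply(spec$factor_map,
                 function(r) paste(sort(r), collapse = ","), character(1))
  paste(sort(sets), collapse = " | ")
}

#' Deduplicate candidate model specifications
#'
#' Two specifications are redundant when they imply the same loading
#' sparsity pattern (same region sets, factor order ignored); only the
#' first of each is kept.
#'
#' @param specs List of `cfa_spec`.
#' @return The deduplicated list.
#' @export
dedupe_specs <- function(specs) {
  specs[!duplicated(vapply(specs, spec_signature, character(1)))]
}

# --- model-implied covariance and its analytic Jacobian ---------------------

implied_sigma <- function(lambda, phi, theta) {
  tcrossprod(lambda %*% phi, lambda) + diag(theta, length(theta))
}

# Free-parameter bookkeeping for a spec: loadings (lambda), then factor
# correlations (phi off-diagonal, column-major), theta handled separately.
param_index <- function(spec) {
  k <- length(spec$factor_map)
  load_idx <- do.call(rbind, lapply(seq_len(k), function(f) {
    rows <- match(spec$factor_map[[f]], spec$labels)
    if (anyNA(rows)) {
      stop("spec region not among covariance labels: ",
           paste(spec$factor_map[[f]][is.na(rows)], collapse = ", "))
    }
    cbind(row = rows, col = f)
  }))
  phi_idx <- if (k >= 2) {
    ij <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
    ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
  } else {
    matrix(integer(0), 0, 2)
  }
  list(load = load_idx, phi = phi_idx, k = k, p = length(spec$labels))
}

unpack_params <- function(par, pidx) {
  nl <- nrow(pidx$load)
  lambda <- matrix(0, pidx$p, pidx$k)
  lambda[pidx$load] <- par[seq_len(nl)]
  phi <- diag(pidx$k)
  if (nrow(pidx$phi) > 0) {
    ph <- par[nl + seq_len(nrow(pidx$phi))]
    phi[pidx$phi] <- ph
    phi[pidx$phi[, c(2, 1), drop = FALSE]] <- ph
  }
  list(lambda = lambda, phi = phi)
}

# Jacobian of the off-diagonal implied elements w.r.t. (lambda, phi) free
# parameters. Rows ordered like the off-diagonal subset of vech.
offdiag_jacobian <- function(lambda, phi, pidx, od_idx) {
  lp <- lambda %*% phi
  n_par <- nrow(pidx$load) + nrow(pidx$phi)
  jac <- matrix(0, nrow(od_idx), n_par)
  for (e in seq_len(nrow(od_idx))) {
    i <- od_idx[e, 1]; j <- od_idx[e, 2]
    for (q in seq_len(nrow(pidx$load))) {
      pr <- pidx$load[q, 1]; f <- pidx$load[q, 2]
      val <- 0
      if (i == pr) val <- val + lp[j, f]
      if (j == pr) val <- val + lp[i, f]
      jac[e, q] <- val
    }
    if (nrow(pidx$phi) > 0) {
      for (q in seq_len(nrow(pidx$phi))) {
        f <- pidx$phi[q, 1]; g <- pidx$phi[q, 2]
        jac[e, nrow(pidx$load) + q] <-
          lambda[i, f] * lambda[j, g] + lambda[i, g] * lambda[j, f]
      }
    }
  }
  jac
}

# Moore-Penrose pseudo-inverse via eigen clipping (V is symmetric PSD).
psd_pinv <- function(v, tol = 1e-10) {
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) stop("sampling covariance has no positive spectrum")
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Indices of off-diagonal entries within the vech ordering.
vech_offdiag <- function(p) {
  idx <- vech_index(p)
  list(mask = idx[, 1] != idx[, 2], idx = idx[idx[, 1] != idx[, 2], , drop = FALSE])
}

#' Fit a confirmatory factor model by diagonally weighted least squares
#'
#' Minimizes F(theta) = sum_e w_e (s_e - sigma_e(theta))^2 over the
#' off-diagonal half-vectorized elements of the standardized genetic
#' covariance matrix, with w_e = 1 / V[e, e] (the inverse diagonal of the
#' jackknife sampling covariance). Factor variances are fixed to 1 for
#' identification and factor covariances are free. Residual variances are
#' profiled against the unit diagonal (theta_p = 1 - communality_p), which
#' is the exact DWLS limit for the standardized matrix whose diagonal
#' elements are constants; negative values are a Heywood condition, flagged
#' and clamped to zero. Standard errors use a sandwich with the full V.
#'
#' @param spec A `cfa_spec`.
#' @param gencov A standardized `genetic_covariance` (see
#'   [standardize_to_correlation()]).
#' @param weights Optional explicit weight vector for the off-diagonal
#'   elements (in vech order); default inverse diagonal of V.
#' @param start Optional starting parameter vector (loadings then factor
#'   correlations).
#' @return A `factor_model`: `lambda` and `lambda_se` (P x k), `phi` and
#'   `phi_se` (k x k, unit diagonal), `theta` (length P), `fit` (a
#'   `fit_stats`), `converged`, `heywood`, `fmin`, plus the spec.
#' @export
fit_cfa <- function(spec, gencov, weights = NULL, start = NULL) {
  stopifnot(inherits(spec, "cfa_spec"), inherits(gencov, "genetic_covariance"))
  if (!isTRUE(gencov$standardized)) {
    stop("fit_cfa expects a standardized genetic covariance; ",
         "call standardize_to_correlation() first")
  }
  if (!identical(spec$labels, gencov$labels)) {
    if (!all(unlist(spec$factor_map) %in% gencov$labels)) {
      stop("spec regions missing from covariance labels")
    }
    spec$labels <- gencov$labels
  }
  p <- length(gencov$labels)
  od <- vech_offdiag(p)
  s_od <- gencov$s[od$idx]
  v_od <- gencov$v[od$mask, od$mask, drop = FALSE]
  if (is.null(weights)) {
    dv <- pmax(diag(v_od), 1e-12)
    weights <- 1 / dv
  }
  stopifnot(length(weights) == length(s_od))

  pidx <- param_index(spec)
  n_load <- nrow(pidx$load)
  n_phi <- nrow(pidx$phi)
  if (is.null(start)) start <- c(rep(0.5, n_load), rep(0.3, n_phi))
  lower <- c(rep(-1.5, n_load), rep(-0.98, n_phi))
  upper <- c(rep(1.5, n_load), rep(0.98, n_phi))

  objective <- function(par) {
    mp <- unpack_params(par, pidx)
    sig <- tcrossprod(mp$lambda %*% mp$phi, mp$lambda)
    r <- s_od - sig[od$idx]
    sum(weights * r^2)
  }
  gradient <- function(par) {
    mp <- unpack_params(par, pidx)
    sig <- tcrossprod(mp$lambda %*% mp$phi, mp$lambda)
    r <- s_od - sig[od$idx]
    jac <- offdiag_jacobian(mp$lambda, mp$phi, pidx, od$idx)
    -2 * drop(crossprod(jac, weights * r))
  }
  opt <- stats::nlminb(start, objective, gradient = gradient,
                       lower = lower, upper = upper,
                       control = list(iter.max = 500, eval.max = 1000))
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  if (!converged && is.finite(opt$objective)) {
    # nlminb reports "false convergence" at an exact-zero minimum; accept
    # any stationary point with a vanishing gradient relative to scale
    gnorm <- max(abs(gradient(opt$par)))
    converged <- gnorm <= 1e-6 * max(1, sum(weights * s_od^2))
  }
  mp <- unpack_params(opt$par, pidx)
  lambda <- mp$lambda
  phi <- mp$phi
  comm <- diag(tcrossprod(lambda %*% phi, lambda))
  theta_raw <- diag(gencov$s) - comm
  heywood <- any(theta_raw < -1e-6)
  theta <- pmax(theta_raw, 0)
  if (heywood) warning("Heywood case: negative residual variance clamped to 0")

  # sandwich covariance of the free parameters with the full V
  jac <- offdiag_jacobian(lambda, phi, pidx, od$idx)
  wjac <- weights * jac
  bread <- tryCatch(solve(crossprod(jac, wjac)), error = function(e) NULL)
  if (is.null(bread)) {
    par_se <- rep(NA_real_, length(opt$par))
    converged <- FALSE
  } else {
    meat <- crossprod(wjac, v_od %*% wjac)
    pcov <- bread %*% meat %*% bread
    par_se <- sqrt(pmax(diag(pcov), 0))
  }
  lambda_se <- matrix(NA_real_, p, pidx$k)
  lambda_se[pidx$load] <- par_se[seq_len(n_load)]
  phi_se <- matrix(NA_real_, pidx$k, pidx$k)
  if (n_phi > 0) {
    se_phi <- par_se[n_load + seq_len(n_phi)]
    phi_se[pidx$phi] <- se_phi
    phi_se[pidx$phi[, c(2, 1), drop = FALSE]] <- se_phi
  }
  dimnames(lambda) <- dimnames(lambda_se) <-
    list(gencov$labels, names(spec$factor_map))
  names(theta) <- gencov$labels

  model <- structure(list(lambda = lambda, lambda_se = lambda_se,
                          phi = phi, phi_se = phi_se, theta = theta,
                          spec = spec, fmin = opt$objective,
                          converged = converged, heywood = heywood,
                          n_free_params = n_load + n_phi + p),
                     class = "factor_model")
  model$fit <- compute_fit_stats(model, gencov)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors, converged = %s%s\n",
              ncol(x$lambda), x$converged,
              if (x$heywood) ", Heywood" else ""))
  print(round(x$lambda, 3))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Fit statistics for a fitted factor model
#'
#' The model chi-square is the residual-based quadratic form
#' T = r' (V+ - V+ D (D' V+ D)^-1 D' V+) r over the off-diagonal residuals
#' r, with V the full jackknife sampling covariance (pseudo-inverted) and D
#' the model Jacobian — the asymptotically chi-square residual test that
#' pairs with DWLS point estimation. df = P(P+1)/2 - free parameters;
#' AIC = chi2 + 2 * free parameters; CFI compares against the independence
#' (diagonal-only) baseline; SRMR is the RMS residual over all unique
#' elements of the standardized matrix.
#'
#' @param model A `factor_model`.
#' @param gencov The standardized `genetic_covariance` the model was fit to.
#' @return A `fit_stats`: `chi2`, `df`, `aic`, `cfi`, `srmr`,
#'   `n_free_params`.
#' @export
compute_fit_stats <- function(model, gencov) {
  stopifnot(inherits(model, "factor_model"))
  p <- length(gencov$labels)
  od <- vech_offdiag(p)
  v_od <- gencov$v[od$mask, od$mask, drop = FALSE]
  sig <- implied_sigma(model$lambda, model$phi, model$theta)
  r_od <- gencov$s[od$idx] - sig[od$idx]

  vinv <- psd_pinv(v_od)
  pidx <- param_index(model$spec)
  jac <- offdiag_jacobian(model$lambda, model$phi, pidx, od$idx)
  chi2 <- browne_residual_stat(r_od, vinv, jac)
  n_free <- model$n_free_params
  df <- p * (p + 1) / 2 - n_free
  # independence baseline: diagonal-only model, all off-diagonals are
  # residuals and no free parameter touches them
  chi2_b <- browne_residual_stat(gencov$s[od$idx], vinv, NULL)
  df_b <- p * (p - 1) / 2
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  idx_all <- vech_index(p)
  r_all <- gencov$s[idx_all] - sig[idx_all]
  srmr <- sqrt(mean(r_all^2))
  structure(list(chi2 = chi2, df = df, aic = chi2 + 2 * n_free,
                 cfi = cfi, srmr = srmr, n_free_params = n_free),
            class = "fit_stats")
}

browne_residual_stat <- function(r, vinv, jac) {
  if (is.null(jac) || ncol(jac) == 0) {
    proj <- vinv
  } else {
    vj <- vinv %*% jac
    inner <- tryCatch(solve(crossprod(jac, vj)), error = function(e) NULL)
    proj <- if (is.null(inner)) vinv else vinv - vj %*% inner %*% t(vj)
  }
  max(drop(t(r) %*% proj %*% r), 0)
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("chi2 = %.2f (df = %d), AIC = %.2f, CFI = %.3f, SRMR = %.4f\n",
              x$chi2, x$df, x$aic, x$cfi, x$srmr))
  invisible(x)
}

#' Prune non-significant factor loadings
#'
#' Iteratively removes the least-significant free loading with two-sided
#' Wald p above `alpha` and refits, stopping when all remaining loadings
#' are significant. A loading is never removed if that would leave its
#' factor with fewer than two regions. Removal order is deterministic:
#' largest p first, ties broken by factor then region label order.
#'
#' @param model A fitted `factor_model`.
#' @param gencov The standardized `genetic_covariance` it was fit to.
#' @param alpha Significance level (default 0.05).
#' @return The pruned (possibly unchanged) `factor_model`.
#' @export
prune_nonsignificant <- function(model, gencov, alpha = 0.05) {
  repeat {
    est <- model$lambda
    se <- model$lambda_se
    pmat <- 2 * stats::pnorm(-abs(est / se))
    fmap <- model$spec$factor_map
    worst_p <- -Inf; worst <- NULL
    for (f in seq_along(fmap)) {
      if (length(fmap[[f]]) <= 2) next  # would drop the factor below 2 regions
      for (region in sort(fmap[[f]])) {
        i <- match(region, rownames(est))
        pv <- pmat[i, f]
        if (is.finite(pv) && pv > alpha && pv > worst_p) {
          worst_p <- pv
          worst <- c(f, i)
        }
      }
    }
    if (is.null(worst)) return(model)
    f <- worst[1]
    region <- rownames(est)[worst[2]]
    fmap[[f]] <- setdiff(fmap[[f]], region)
    spec <- model$spec
    spec$factor_map <- fmap
    model <- fit_cfa(spec, gencov)
  }
}

#' Select the best candidate model by AIC
#'
#' Among converged candidates, picks minimal AIC; exact ties are broken
#' toward fewer factors, then fewer free parameters.
#'
#' @param candidates List of `factor_model`.
#' @return The selected `factor_model`.
#' @export
select_best_model <- function(candidates) {
  ok <- vapply(candidates, function(m) isTRUE(m$converged), logical(1))
  if (!any(ok)) stop("no converged candidate model")
  cand <- candidates[ok]
  aic <- vapply(cand, function(m) m$fit$aic, numeric(1))
  k <- vapply(cand, function(m) ncol(m$lambda), numeric(1))
  nf <- vapply(cand, function(m) m$fit$n_free_params, numeric(1))
  cand[[order(aic, k, nf)[1]]]
}

#' Region sets of a fitted factor model
#'
#' @param model A `factor_model`.
#' @param prefix Name prefix for the factors (e.g. `"SA"`).
#' @return Named list of region-label vectors, one per factor.
#' @export
factor_regions <- function(model, prefix = "F") {
  fmap <- model$spec$factor_map
  names(fmap) <- paste0(prefix, seq_along(fmap))
  fmap
}

#' Discover latent genetic factors from a harmonized panel
#'
#' The full split-half protocol: LDSC genetic covariance of the odd
#' chromosomes feeds the EFA, that of the even chromosomes the CFA.
#' Candidate specifications arise from every (k, tau) combination, are
#' deduplicated, fit by DWLS, optionally pruned, and the minimum-AIC
#' converged model is selected.
#'
#' @param panel A `sumstats_panel` with chromosome labels.
#' @param ldscores LD-score table.
#' @param k_range EFA factor counts (default 1:10, capped below P).
#' @param thresholds Carry-forward thresholds (default c(0.3, 0.5)).
#' @param n_blocks Jackknife block count.
#' @param prune Prune non-significant loadings before selection
#'   (default TRUE).
#' @return List with `gencov_odd`, `gencov_even`, `efa` (solutions),
#'   `candidates` (list of models), `table` (candidate fit summary
#'   data.frame) and `selected`.
#' @export
discover_factors <- function(panel, ldscores, k_range = 1:10,
                             thresholds = c(0.3, 0.5), n_blocks = 200,
                             prune = TRUE) {
  gencov_odd <- build_gencov_matrix(panel, ldscores, "odd", n_blocks)
  gencov_even <- build_gencov_matrix(panel, ldscores, "even", n_blocks)
  corr_odd <- standardize_to_correlation(gencov_odd)
  corr_even <- standardize_to_correlation(gencov_even)
  k_range <- k_range[k_range < length(panel$phenotypes)]
  efa <- run_efa(corr_odd, k_range)

  specs <- list(); meta <- list()
  for (sol in efa) {
    if (!sol$converged) next
    for (tau in thresholds) {
      sp <- tryCatch(build_cfa_spec(sol, tau), error = function(e) NULL)
      if (!is.null(sp)) {
        specs[[length(specs) + 1]] <- sp
        meta[[length(meta) + 1]] <- c(k = sol$k, tau = tau)
      }
    }
  }
  if (length(specs) == 0) stop("no viable candidate specification")
  sig <- vapply(specs, spec_signature, character(1))
  keep <- !duplicated(sig)
  specs <- specs[keep]; meta <- meta[keep]

  candidates <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    m <- tryCatch(suppressWarnings(fit_cfa(specs[[i]], corr_even)),
                  error = function(e) NULL)
    if (!is.null(m) && prune && isTRUE(m$converged)) {
      m <- tryCatch(suppressWarnings(prune_nonsignificant(m, corr_even)),
                    error = function(e) m)
    }
    candidates[[i]] <- m
  }
  fitted <- !vapply(candidates, is.null, logical(1))
  candidates <- candidates[fitted]; meta <- meta[fitted]

  table <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    m <- candidates[[i]]
    data.frame(k_efa = meta[[i]][["k"]], tau = meta[[i]][["tau"]],
               n_factors = ncol(m$lambda), n_free = m$fit$n_free_params,
               chi2 = m$fit$chi2, df = m$fit$df, aic = m$fit$aic,
               cfi = m$fit$cfi, srmr = m$fit$srmr,
               converged = m$converged)
  }))
  selected <- select_best_model(candidates)
  list(gencov_odd = gencov_odd, gencov_even = gencov_even,
       corr_even = corr_even, efa = efa, candidates = candidates,
       table = table, selected = selected)
}

#' Write a fitted factor model to plain-text files
#'
#' Emits `<prefix>_loadings.tsv` (region, factor, estimate, SE) and
#' `<prefix>_model.json` (factor map, estimates, fit statistics).
#'
#' @param model A `factor_model`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_factor_model <- function(model, prefix) {
  pidx <- param_index(model$spec)
  tab <- data.frame(region = rownames(model$lambda)[pidx$load[, 1]],
                    factor = colnames(model$lambda)[pidx$load[, 2]],
                    loading = model$lambda[pidx$load],
                    se = model$lambda_se[pidx$load])
  t_path <- paste0(prefix, "_loadings.tsv")
  j_path <- paste0(prefix, "_model.json")
  utils::write.table(tab, t_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(factor_map = model$spec$factor_map,
                            threshold_used = model$spec$threshold_used,
                            phi = model$phi, theta = model$theta,
                            fit = unclass(model$fit),
                            converged = model$converged,
                            heywood = model$heywood),
                       j_path, auto_unbox = TRUE, digits = NA)
  invisible(c(t_path, j_path))
}
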