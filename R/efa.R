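#' Standardize a genetic covariance matrix to a genetic correlation matrix
#'
#' Rescales S to unit diagonal and transforms the sampling covariance V of
#' the half-vectorized elements by the delta method: the standardized
#' element r_ij = s_ij / sqrt(s_ii s_jj) has gradient 1/sqrt(s_ii s_jj)
#' w.r.t. s_ij and -r_ij / (2 s_kk) w.r.t. each diagonal s_kk, so
#' V* = G V G' with G the (sparse) gradient matrix. Diagonal elements of
#' the standardized matrix are constants, so their rows/columns of V* are
#' zero.
#'
#' @param gencov A `genetic_covariance` with positive diagonal.
#' @return The standardized `genetic_covariance` (field `standardized = TRUE`).
#' @export
standardize_to_correlation <- function(gencov) {
  stopifnot(inherits(gencov, "genetic_covariance"))
  s <- gencov$s
  d <- diag(s)
  if (any(d <= 0)) {
    stop("cannot standardize: nonpositive genetic variance for ",
         paste(gencov$labels[d <= 0], collapse = ", "))
  }
  p <- nrow(s)
  idx <- vech_index(p)
  n_elem <- nrow(idx)
  r <- stats::cov2cor(s)
  g <- matrix(0, n_elem, n_elem)
  # map (i, j) with i >= j to vech position
  pos <- matrix(0L, p, p)
  for (e in seq_len(n_elem)) pos[idx[e, 1], idx[e, 2]] <- e
  diag_pos <- vapply(seq_len(p), function(i) pos[i, i], integer(1))
  for (e in seq_len(n_elem)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    if (i == j) next  # constant 1 after standardization
    g[e, e] <- 1 / sqrt(d[i] * d[j])
    g[e, diag_pos[i]] <- -r[i, j] / (2 * d[i])
    g[e, diag_pos[j]] <- -r[i, j] / (2 * d[j])
  }
  v_std <- g %*% gencov$v %*% t(g)
  dimnames(v_std) <- dimnames(gencov$v)
  out <- gencov
  out$s <- r
  out$v <- v_std
  out$standardized <- TRUE
  out$raw_diag <- d
  out
}

#' Smooth a symmetric matrix to positive definiteness
#'
#' Eigenvalue clipping with diagonal preservation: already-PD input is
#' returned unchanged; otherwise eigenvalues are floored, the matrix is
#' reassembled, and rescaled so the original diagonal is restored, iterating
#' until the minimum eigenvalue is at least `min_eig`.
#'
#' @param m Symmetric matrix (e.g. an empirical genetic correlation matrix).
#' @param min_eig Eigenvalue floor (default 1e-8).
#' @return Symmetric matrix with `min(eigen) >= min_eig` and the input's
#'   diagonal.
#' @export
smooth_to_pd <- function(m, min_eig = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    m <- (m + t(m)) / 2
  }
  d0 <- diag(m)
  if (any(d0 <= 0)) stop("smoothing requires a positive diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= min_eig) return(m)
  floor_ <- min_eig
  out <- m
  for (iter in 1:60) {
    e <- eigen(out, symmetric = TRUE)
    vals <- pmax(e$values, floor_)
    out <- e$vectors %*% (vals * t(e$vectors))
    sc <- sqrt(d0 / diag(out))
    out <- out * tcrossprod(sc)
    out <- (out + t(out)) / 2
    diag(out) <- d0
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= min_eig) return(out)
    floor_ <- floor_ * 2
  }
  stop("positive-definite smoothing failed to converge")
}

# Minimum-residual factor extraction: optimize uniquenesses psi so that the
# rank-k eigen-approximation of R - diag(psi) minimizes the off-diagonal
# residual sum of squares.
minres_extract <- function(r, k) {
  p <- nrow(r)
  loadings_for <- function(psi) {
    e <- eigen(r - diag(psi, p), symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  }
  objective <- function(psi) {
    l <- loadings_for(psi)
    res <- r - tcrossprod(l)
    sum(res[lower.tri(res)]^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(r)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.005), 0.995)
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 0.001, upper = 1,
                      control = list(maxit = 500))
  l <- loadings_for(opt$par)
  list(loadings = l, uniquenesses = opt$par, criterion = opt$value,
       converged = opt$convergence == 0)
}

# Deterministic orientation: flip each factor so its largest-|loading| entry
# is positive, and order factors by decreasing sum of squared loadings.
orient_loadings <- function(l) {
  for (f in seq_len(ncol(l))) {
    if (l[which.max(abs(l[, f])), f] < 0) l[, f] <- -l[, f]
  }
  l[, order(colSums(l^2), decreasing = TRUE), drop = FALSE]
}

#' Exploratory factor analysis over a range of factor counts
#'
#' Minimum-residual extraction on the (smoothed) genetic correlation
#' matrix, one solution per requested k, with an oblique promax rotation
#' for k >= 2 (latent genetic factors of regional brain phenotypes are
#' strongly correlated, so an orthogonal rotation would spread loadings
#' across factors and defeat threshold-based model building). Eigenvalues
#' of the smoothed matrix are attached once for scree inspection.
#'
#' @param corr A standardized `genetic_covariance` or a plain correlation
#'   matrix with unit diagonal.
#' @param k_range Factor counts to fit (default 1:10). Every k must be < P.
#' @return List of `efa_solution`: each has `k`, `loadings` (P x k rotated
#'   standardized pattern matrix, sign-oriented), `rotation`, `eigenvalues`,
#'   `uniquenesses` and `converged`. Non-converging k are flagged and
#'   their loadings set to `NA`.
#' @export
run_efa <- function(corr, k_range = 1:10) {
  if (inherits(corr, "genetic_covariance")) {
    if (!isTRUE(corr$standardized)) corr <- standardize_to_correlation(corr)
    labels <- corr$labels
    r <- corr$s
  } else {
    r <- as.matrix(corr)
    labels <- rownames(r)
    if (is.null(labels)) labels <- paste0("V", seq_len(nrow(r)))
  }
  p <- nrow(r)
  if (max(k_range) >= p) {
    stop("factor count must be smaller than the number of phenotypes (",
         max(k_range), " >= ", p, ")")
  }
  r <- smooth_to_pd(r)
  dimnames(r) <- list(labels, labels)
  eigenvalues <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  lapply(k_range, function(k) {
    ext <- tryCatch(minres_extract(r, k), error = function(e) NULL)
    if (is.null(ext) || !ext$converged) {
      return(structure(list(k = k, loadings = NULL, rotation = "none",
                            eigenvalues = eigenvalues, uniquenesses = NULL,
                            converged = FALSE),
                       class = "efa_solution"))
    }
    l <- ext$loadings
    rotation <- "none"
    if (k >= 2) {
      # a fixed small Givens pre-rotation breaks the symmetric saddle
      # points where the varimax gradient vanishes (exactly balanced
      # loading blocks leave the identity rotation stationary)
      pre <- diag(k)
      for (f in seq_len(k - 1)) {
        theta <- 0.3 / f
        g <- diag(k)
        g[f, f] <- cos(theta); g[f + 1, f + 1] <- cos(theta)
        g[f, f + 1] <- -sin(theta); g[f + 1, f] <- sin(theta)
        pre <- pre %*% g
      }
      rot <- tryCatch(stats::promax(l %*% pre, m = 4),
                      error = function(e) NULL)
      if (!is.null(rot)) {
        l <- unclass(rot$loadings)
        rotation <- "promax"
      }
    }
    l <- orient_loadings(l)
    dimnames(l) <- list(labels, paste0("F", seq_len(k)))
    structure(list(k = k, loadings = l, rotation = rotation,
                   eigenvalues = eigenvalues,
                   uniquenesses = ext$uniquenesses, converged = TRUE),
              class = "efa_solution")
  })
}

#' @export
print.efa_solution <- function(x, ...) {
  cat(sprintf("efa_solution: k = %d, rotation = %s, converged = %s\n",
              x$k, x$rotation, x$converged))
  if (!is.null(x$loadings)) print(round(x$loadings, 3))
  invisible(x)
}

#' Tucker congruence coefficients between two loading matrices
#'
#' Column-wise congruence after greedy matching (each factor of `a` paired
#' with its best-matching unsigned factor of `b`); used to compare a
#' recovered EFA solution with a known generating structure.
#'
#' @param a,b P x k loading matrices.
#' @return Vector of |congruence| values, one per factor of `a`.
#' @export
factor_congruence <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  cong <- abs(crossprod(a, b) /
                outer(sqrt(colSums(a^2)), sqrt(colSums(b^2))))
  out <- numeric(ncol(a))
  used <- integer(0)
  for (f in seq_len(ncol(a))) {
    cands <- setdiff(seq_len(ncol(b)), used)
    best <- cands[which.max(cong[f, cands])]
    out[f] <- cong[f, best]
    used <- c(used, best)
  }
  out
}
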