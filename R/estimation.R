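## Covariance estimation under symmetry (orbit pooling) and sparsity
## (Markov-banded irreducible blocks), with an EM loop for missing cells.

#' Sample moments of complete pedigree data
#'
#' Mean and biased (1/n) covariance of the `n x p` trait matrix. No
#' structure is imposed at this stage.
#'
#' @param Y an `n x p` numeric matrix (rows = pedigrees, columns = positions
#'   in canonical order) with no missing entries, or a complete pedigree
#'   table.
#' @return a list with `ybar` (p-vector), `S` (`p x p`, biased), `n`.
#' @export
sample_moments <- function(Y) {
  if (is.data.frame(Y)) Y <- trait_matrix(Y)
  if (anyNA(Y)) stop("`Y` has missing entries; use fit_lineage() for EM",
                     call. = FALSE)
  n <- nrow(Y)
  if (n == 0) stop("no replicates", call. = FALSE)
  ybar <- colMeans(Y)
  S <- crossprod(Y) / n - tcrossprod(ybar)
  S <- (S + t(S)) / 2
  list(ybar = ybar, S = S, n = n)
}

#' Pool a mean vector over generations
#'
#' In an unordered tree all positions within a generation share one mean, so
#' the structured mean is the per-generation average `q_g`, expanded back to
#' all positions by [expand_mean()].
#'
#' @param ybar p-vector of position means (canonical order).
#' @return numeric vector `q` of length `G` (named by generation).
#' @export
pool_mean <- function(ybar) {
  G <- check_G(round(log2(length(ybar) + 1)))
  gens <- nchar(lineage_positions(G))
  q <- tapply(ybar, gens, mean)
  stats::setNames(as.numeric(q), seq_len(G))
}

#' @rdname pool_mean
#' @param q per-generation mean vector.
#' @return `expand_mean()` returns the p-vector assigning `q[g]` to every
#'   generation-`g` position.
#' @export
expand_mean <- function(q) {
  G <- check_G(length(q))
  pos <- lineage_positions(G)
  stats::setNames(as.numeric(q)[nchar(pos)], pos)
}

#' Pool a covariance matrix over 3-index orbits
#'
#' Replaces every entry of a symmetric `p x p` matrix by the unweighted
#' average of all entries sharing its 3-index orbit (generation pair +
#' MRCA generation). This equals the group average (Reynolds operator) over
#' all daughter-subtree permutations, but runs in `O(p^2)` instead of
#' enumerating the super-exponentially large group. Idempotent.
#'
#' @param S symmetric `p x p` matrix in canonical position order.
#' @return the orbit-structured matrix, same dimensions, position dimnames.
#' @export
pool_covariance <- function(S) {
  p <- nrow(S)
  G <- check_G(round(log2(p + 1)))
  orb <- orbit_factor(G)
  f <- orb$factor
  means <- as.numeric(tapply(as.numeric(S), as.vector(f), mean))
  out <- matrix(means[f], p, p)
  dimnames(out) <- list(orb$positions, orb$positions)
  out
}

#' Markov-banded fit of one irreducible spectral block
#'
#' Within an irreducible subspace the natural variables form a time series
#' over generations. Bounding its Markov order at `M` makes the precision
#' matrix of the block banded with bandwidth `M`, a decomposable model whose
#' moment fit proceeds by sequential regressions: each variable `j` is
#' regressed on its `min(M, j - 1)` predecessors using the sample block, the
#' innovation variance is the Schur complement, and the fitted block is
#' reassembled from the modified Cholesky factors `L Phi L'`. With
#' `M >= dim - 1` the fit is saturated and returns the sample block exactly.
#'
#' @param xi symmetric sample block (`k x k`).
#' @param M Markov order, >= 1.
#' @param variance_floor smallest admissible innovation variance; smaller
#'   fitted innovations are floored (with a warning recorded).
#' @param label block name used in error messages.
#' @return list with `L` (unit lower-triangular), `Phi` (innovation
#'   variances), `B` (`= solve(L)`, banded), `beta` (matrix of regression
#'   coefficients, `beta[j, j']` for `j' < j` within the band), `xi_hat`
#'   (`= L diag(Phi) L'`), and `floored` (logical).
#' @export
fit_block_markov <- function(xi, M, variance_floor = 0, label = "block") {
  k <- nrow(xi)
  stopifnot(k == ncol(xi), M >= 1)
  L <- diag(k)
  B <- diag(k)
  beta <- matrix(0, k, k)
  Phi <- numeric(k)
  floored <- FALSE
  Phi[1] <- xi[1, 1]
  for (j in seq_len(k)[-1]) {
    J <- seq(max(1L, j - M), j - 1L)
    A <- xi[J, J, drop = FALSE]
    b <- xi[J, j]
    bj <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
    if (is.null(bj)) {
      # Degenerate (rank-deficient) predictor block. For PSD input b lies in
      # the range of A, so the minimum-norm least-squares solution is exact;
      # directions with zero variance carry no signal and get zero weight.
      sv <- svd(A)
      keep <- sv$d > max(sv$d[1] * 1e-12, 1e-300)
      bj <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                         (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep]))
      if (max(abs(A %*% bj - b)) > 1e-8 * max(abs(xi), 1)) {
        stop(sprintf("singular normal equations in %s (generation index %d)",
                     label, j), call. = FALSE)
      }
    }
    beta[j, J] <- bj
    B[j, J] <- -bj
    Phi[j] <- xi[j, j] - sum(bj * b)
  }
  if (any(Phi < variance_floor)) {
    Phi <- pmax(Phi, variance_floor)
    floored <- TRUE
  }
  L <- solve(B)
  xi_hat <- L %*% diag(Phi, k) %*% t(L)
  xi_hat <- (xi_hat + t(xi_hat)) / 2
  dimnames(xi_hat) <- dimnames(xi)
  list(L = L, Phi = Phi, B = B, beta = beta, xi_hat = xi_hat,
       floored = floored)
}

# One maximization step: from unstructured moments to the constrained
# estimate. Pool -> spectral transform -> per-block Markov fit -> assemble.
# The covariance is pooled about the STRUCTURED mean (S plus the outer
# product of ybar minus its generation-pooled expansion): that is the exact
# Gaussian MLE under the symmetry constraint, and it is what makes the EM
# loop monotone. The correction term is O(1/n) relative to S.
fit_from_moments <- function(ybar, S, basis, M, variance_floor = 0) {
  G <- basis$G
  q <- pool_mean(ybar)
  r <- ybar - expand_mean(q)
  S_G <- pool_covariance(S + tcrossprod(r))
  # pooling-first, then transform; exact block-diagonalization is guaranteed
  # for pooled input so the tolerance here is only a numerical guard
  S_Omega <- as_spectral(S_G, basis, tol = 1e-6)
  block_fits <- purrr::imap(S_Omega$blocks, function(xi, nm) {
    k <- nrow(xi)
    fit_block_markov(xi, M = min(M, max(k - 1L, 1L)),
                     variance_floor = variance_floor,
                     label = sprintf("spectral block ell = %s", nm))
  })
  spectral <- S_Omega
  spectral$blocks <- purrr::map(block_fits, "xi_hat")
  Sigma <- from_spectral(spectral, basis)
  list(q = q, mu = expand_mean(q), Sigma = Sigma, spectral = spectral,
       sample_spectral = S_Omega, block_fits = block_fits,
       floored = any(purrr::map_lgl(block_fits, "floored")))
}

#' Observed-data Gaussian log-likelihood of a pedigree table
#'
#' Sums, over pedigrees, the log-density of the observed coordinates under
#' `N(mu, Sigma)` (missing coordinates are marginalized out, which for a
#' Gaussian is just dropping them).
#'
#' @param data a pedigree table (or `n x p` matrix with `NA`s).
#' @param mu p-vector mean.
#' @param Sigma `p x p` positive-definite covariance.
#' @return scalar log-likelihood.
#' @export
lineage_loglik <- function(data, mu, Sigma) {
  Y <- if (is.data.frame(data)) trait_matrix(data) else data
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (length(o) == 0) next
    r <- Y[i, o] - mu[o]
    R <- tryCatch(chol(Sigma[o, o, drop = FALSE]),
                  error = function(e) stop("`Sigma` is not positive definite on an observed subset",
                                           call. = FALSE))
    z <- backsolve(R, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  }
  ll
}

# E-step: expected sufficient statistics of N(mu, Sigma) given the observed
# coordinates of each pedigree. Missing coordinates are imputed by Gaussian
# conditioning, E[y_m | y_o] = mu_m + S_mo S_oo^-1 (y_o - mu_o), and second
# moments accumulate the conditional covariance S_mm - S_mo S_oo^-1 S_om.
expected_moments <- function(Y, mu, Sigma) {
  n <- nrow(Y)
  p <- ncol(Y)
  sum_y <- numeric(p)
  sum_yy <- matrix(0, p, p)
  imputed <- Y
  ridged <- FALSE
  for (i in seq_len(n)) {
    yi <- Y[i, ]
    m <- which(is.na(yi))
    o <- which(!is.na(yi))
    yhat <- yi
    C <- matrix(0, p, p)
    if (length(m) > 0) {
      Soo <- Sigma[o, o, drop = FALSE]
      Smo <- Sigma[m, o, drop = FALSE]
      sol <- tryCatch(solve(Soo, cbind(yi[o] - mu[o], t(Smo))),
                      error = function(e) NULL)
      if (is.null(sol)) {
        ridged <- TRUE
        Soo <- Soo + diag(1e-8 * sum(diag(Soo)) / length(o), length(o))
        sol <- solve(Soo, cbind(yi[o] - mu[o], t(Smo)))
      }
      yhat[m] <- mu[m] + Smo %*% sol[, 1]
      C[m, m] <- Sigma[m, m, drop = FALSE] - Smo %*% sol[, -1, drop = FALSE]
    }
    imputed[i, ] <- yhat
    sum_y <- sum_y + yhat
    sum_yy <- sum_yy + tcrossprod(yhat) + C
  }
  ybar <- sum_y / n
  S <- sum_yy / n - tcrossprod(ybar)
  list(ybar = ybar, S = (S + t(S)) / 2, imputed = imputed, ridged = ridged)
}

#' Fit the symmetry- and Markov-constrained lineage covariance model
#'
#' Estimates the structured mean (one value per generation) and the
#' orbit-structured covariance of a single trait over a complete
#' `G`-generation tree from replicate pedigrees. The covariance is
#' constrained to be invariant under daughter-subtree permutations and, in
#' the spectral domain, each irreducible block is fitted as a Markov chain
#' of order `M`, so that only `n >= M + 2` pedigrees are needed for a
#' positive-definite estimate regardless of depth.
#'
#' With complete data the fit is a single pass: biased sample moments,
#' orbit pooling, spectral transform, per-block banded fit, inverse
#' transform. With missing cells the same machinery forms the M-step of an
#' EM algorithm whose E-step imputes each pedigree's missing coordinates by
#' Gaussian conditioning (with the conditional-covariance correction to the
#' second moments); the observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param data a pedigree table (long format; `NA` or absent rows are
#'   missing cells) or a complete `n x p` matrix.
#' @param M Markov order of each spectral block (default 1).
#' @param G analysis depth; defaults to the table's depth.
#' @param em_tol relative change in observed-data log-likelihood declaring
#'   EM convergence.
#' @param em_max_iter maximum EM iterations.
#' @param variance_floor smallest admissible innovation variance.
#' @return an object of class `lineage_fit`: list with `G`, `M`, `n`, `q`,
#'   `mu`, `Sigma`, `spectral` (fitted blocks), `block_fits` (`L`, `Phi`,
#'   `beta` per block), `basis`, `iterations`, `loglik` (trace),
#'   `converged`, `warnings`.
#' @examples
#' tbl <- simulate_branching(n = 10, G = 4, h = 0.8, seed = 1)
#' fit <- fit_lineage(tbl, M = 1)
#' fit
#' @export
fit_lineage <- function(data, M = 1, G = NULL, em_tol = 1e-8,
                        em_max_iter = 500, variance_floor = 0) {
  if (is.data.frame(data)) {
    if (is.null(G)) G <- pedigree_depth(data)
    Y <- trait_matrix(data, G = G)
  } else {
    Y <- as.matrix(data)
    if (is.null(G)) G <- check_G(round(log2(ncol(Y) + 1)))
  }
  G <- check_G(G)
  stopifnot(ncol(Y) == 2^G - 1)
  if (M < 1) stop("`M` must be >= 1", call. = FALSE)
  if (em_tol <= 0) stop("`em_tol` must be > 0", call. = FALSE)
  n <- nrow(Y)
  basis <- spectral_basis(G)
  warnings <- character()

  if (!anyNA(Y)) {
    mom <- sample_moments(Y)
    fit <- fit_from_moments(mom$ybar, mom$S, basis, M, variance_floor)
    if (fit$floored) warnings <- c(warnings, "innovation variance floored")
    ll <- tryCatch(lineage_loglik(Y, fit$mu, fit$Sigma), error = function(e) NA_real_)
    return(new_lineage_fit(fit, basis, G, M, n, iterations = 1L,
                           loglik = ll, converged = TRUE, warnings = warnings))
  }

  obs_per_pos <- colSums(!is.na(Y))
  if (any(obs_per_pos == 0)) {
    stop(sprintf("position(s) never observed: %s",
                 paste(colnames(Y)[obs_per_pos == 0], collapse = ", ")),
         call. = FALSE)
  }

  p <- ncol(Y)
  # deterministic initialization: generation means of observed entries;
  # pooled covariance of mean-imputed data plus a small scale-aware ridge
  gens <- nchar(colnames(Y))
  q0 <- vapply(seq_len(G), function(g) mean(Y[, gens == g], na.rm = TRUE),
               numeric(1))
  mu <- expand_mean(q0)
  Y0 <- Y
  for (j in seq_len(p)) Y0[is.na(Y0[, j]), j] <- mu[j]
  S0 <- pool_covariance(sample_moments(Y0)$S)
  Sigma <- S0 + diag(1e-6 * mean(diag(S0)) + 1e-12, p)

  ll_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  fit <- NULL
  for (it in seq_len(em_max_iter)) {
    iterations <- it
    es <- expected_moments(Y, mu, Sigma)
    if (es$ridged) {
      warnings <- unique(c(warnings, "ridge applied to singular observed block"))
    }
    # M-step: constrained MLE from the expected moments
    fit <- fit_from_moments(es$ybar, es$S, basis, M, variance_floor)
    mu <- fit$mu
    Sigma <- fit$Sigma
    ll <- lineage_loglik(Y, mu, Sigma)
    ll_trace <- c(ll_trace, ll)
    if (it > 1) {
      rel <- abs(ll - ll_trace[it - 1]) / (abs(ll_trace[it - 1]) + 1e-300)
      if (rel < em_tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warnings <- c(warnings, sprintf("EM did not converge in %d iterations",
                                    em_max_iter))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  if (fit$floored) warnings <- unique(c(warnings, "innovation variance floored"))
  new_lineage_fit(fit, basis, G, M, n, iterations = iterations,
                  loglik = ll_trace, converged = converged,
                  warnings = warnings)
}

new_lineage_fit <- function(fit, basis, G, M, n, iterations, loglik,
                            converged, warnings) {
  structure(list(
    G = G, M = M, n = n,
    q = fit$q, mu = fit$mu, Sigma = fit$Sigma,
    spectral = fit$spectral, sample_spectral = fit$sample_spectral,
    block_fits = fit$block_fits, basis = basis,
    iterations = iterations, loglik = loglik, converged = converged,
    warnings = warnings
  ), class = "lineage_fit")
}

#' @export
print.lineage_fit <- function(x, ...) {
  cat(sprintf(
    "<lineage_fit> G = %d (p = %d), n = %d pedigrees, Markov order M = %d\n",
    x$G, 2^x$G - 1, x$n, x$M))
  cat(sprintf("  per-generation means: %s\n",
              paste(sprintf("%.3g", x$q), collapse = ", ")))
  ll <- x$loglik[length(x$loglik)]
  cat(sprintf("  iterations: %d; log-likelihood: %s; converged: %s\n",
              x$iterations, ifelse(is.na(ll), "NA", sprintf("%.4f", ll)),
              x$converged))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
logLik.lineage_fit <- function(object, ...) {
  ll <- object$loglik[length(object$loglik)]
  attr(ll, "df") <- tree_complexity(object$G,
                                    if (object$M >= object$G - 1 || object$G == 1)
                                      "symmetric" else "markov",
                                    M = if (object$M >= object$G - 1 || object$G == 1)
                                      NULL else object$M)$n_params + object$G
  class(ll) <- "logLik"
  ll
}

#' Serialize a lineage fit to plain-text artifacts
#'
#' Writes labeled CSVs for the structured mean and covariance, per-block
#' CSVs for the fitted spectral blocks and their modified-Cholesky factors,
#' and a JSON fit log (iterations, log-likelihood trace, warnings).
#'
#' @param fit a `lineage_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(generation = seq_len(fit$G), q = as.numeric(fit$q)),
                   file.path(dir, "mean.csv"))
  readr::write_csv(matrix_to_tibble(fit$Sigma, "position"),
                   file.path(dir, "sigma_structured.csv"))
  for (nm in names(fit$spectral$blocks)) {
    readr::write_csv(matrix_to_tibble(fit$spectral$blocks[[nm]], "generation"),
                     file.path(dir, sprintf("xi_ell%s.csv", nm)))
    bf <- fit$block_fits[[nm]]
    k <- length(bf$Phi)
    L <- bf$L
    dimnames(L) <- dimnames(fit$spectral$blocks[[nm]])
    readr::write_csv(matrix_to_tibble(L, "generation"),
                     file.path(dir, sprintf("L_ell%s.csv", nm)))
    readr::write_csv(tibble::tibble(
      generation = as.integer(rownames(fit$spectral$blocks[[nm]])),
      phi = bf$Phi), file.path(dir, sprintf("phi_ell%s.csv", nm)))
  }
  jsonlite::write_json(list(
    G = fit$G, M = fit$M, n = fit$n,
    iterations = fit$iterations, loglik = fit$loglik,
    converged = fit$converged, warnings = fit$warnings
  ), file.path(dir, "fit_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

matrix_to_tibble <- function(M, id_col) {
  out <- tibble::as_tibble(M, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(M)), out)
  out
}
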