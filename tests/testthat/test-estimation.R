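# Moments, orbit pooling, banded block fits, complete-data fits and EM.

test_that("sample moments use the biased 1/n covariance", {
  Y1 <- matrix(rnorm(7), 1)
  expect_equal(unname(sample_moments(Y1)$S), matrix(0, 7, 7))
  Y2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(sample_moments(Y2)$S), matrix(0, 3, 3))
  set.seed(3)
  Y <- matrix(rnorm(15), 5, 3)
  mom <- sample_moments(Y)
  expect_equal(mom$S, cov(Y) * 4 / 5, ignore_attr = TRUE)
  expect_equal(mom$ybar, colMeans(Y))
  expect_error(sample_moments(matrix(c(1, NA), 1)), "missing")
})

test_that("mean pooling averages within generations and is idempotent", {
  expect_equal(unname(pool_mean(rep(2.5, 7))), rep(2.5, 3))
  expect_equal(unname(pool_mean(c(1, 2, 4))), c(1, 3))
  q <- pool_mean(c(1, 2, 4))
  expect_equal(pool_mean(expand_mean(q)), q)
  expect_equal(unname(expand_mean(c(1, 3))), c(1, 3, 3))
})

test_that("orbit pooling equals the Reynolds group average (G <= 4)", {
  for (G in 2:4) {
    S <- random_psd(G, seed = 30 + G)
    expect_equal(pool_covariance(S), reynolds_pool(S, G),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("orbit pooling is idempotent and fixes structured matrices", {
  S <- random_psd(4, seed = 77)
  P1 <- pool_covariance(S)
  expect_equal(pool_covariance(P1), P1, tolerance = 1e-14)
  expect_equal(pool_covariance(branching_covariance(4, 0.6)),
               branching_covariance(4, 0.6), tolerance = 1e-14)
  expect_equal(unname(pool_covariance(diag(7))), diag(7))
})

test_that("banded block fit solves the sequential regressions", {
  # diagonal block: no regression, innovations are the variances
  d <- diag(c(2, 3, 4))
  bf <- fit_block_markov(d, M = 1)
  expect_equal(bf$beta, matrix(0, 3, 3))
  expect_equal(bf$Phi, c(2, 3, 4))
  expect_equal(bf$xi_hat, d, ignore_attr = TRUE)

  # saturated fit returns the sample block exactly
  xi <- unname(random_structured(2, seed = 9))[1:3, 1:3] + diag(3)
  expect_equal(fit_block_markov(xi, M = 2)$xi_hat, xi, tolerance = 1e-12)

  # AR(1) block: recovered coefficients equal the autoregression parameter
  phi <- 0.6
  C <- stats::toeplitz(phi^(0:3)) / (1 - phi^2)
  bf <- fit_block_markov(C, M = 1)
  expect_equal(bf$beta[cbind(2:4, 1:3)], rep(phi, 3), tolerance = 1e-12)
  expect_equal(bf$Phi, c(1 / (1 - phi^2), 1, 1, 1), tolerance = 1e-12)
  expect_equal(bf$xi_hat, C, tolerance = 1e-12) # AR(1) is Markov-1 already

  # modified Cholesky identities
  expect_equal(bf$L %*% diag(bf$Phi) %*% t(bf$L), C, tolerance = 1e-12)
  expect_equal(unname(bf$B %*% bf$L), diag(4), tolerance = 1e-12)

  # an all-zero block is a valid degenerate fit (no variation at this source)
  bf0 <- fit_block_markov(matrix(0, 2, 2), M = 1)
  expect_equal(bf0$Phi, c(0, 0))
  expect_equal(unname(bf0$xi_hat), matrix(0, 2, 2))
  # inconsistent singular normal equations are an error naming the block
  expect_error(fit_block_markov(rbind(c(0, 1), c(1, 1)), M = 1,
                                label = "spectral block ell = 9"),
               "singular.*ell = 9")
})

test_that("banded precision: the inverse of the fitted block is M-banded", {
  xi <- unname(random_structured(3, seed = 5))[1:5, 1:5] + 2 * diag(5)
  for (M in 1:3) {
    bf <- fit_block_markov(xi, M = M)
    K <- solve(bf$xi_hat)
    out_of_band <- abs(row(K) - col(K)) > M
    expect_lt(max(abs(K[out_of_band])), 1e-10)
  }
})

test_that("complete-data fit is positive definite and consistent", {
  tbl <- simulate_branching(n = 5, G = 4, h = 0.8, seed = 2)
  fit <- fit_lineage(tbl, M = 1)
  expect_gt(min(eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_s3_class(fit, "lineage_fit")
  expect_equal(fit$iterations, 1L)

  # consistency at large n against the generating covariance
  big <- simulate_branching(n = 2000, G = 4, h = 0.8, seed = 4)
  fit <- fit_lineage(big, M = 1)
  expect_lt(max(abs(fit$Sigma - branching_covariance(4, 0.8))), 0.1)
  expect_equal(mean(md_correlations(fit)), 0.8, tolerance = 0.03 / 0.8)
})

test_that("saturated fit reproduces the pooled covariance exactly", {
  tbl <- simulate_branching(n = 12, G = 4, h = 0.7, seed = 8)
  Y <- trait_matrix(tbl)
  fit <- fit_lineage(Y, M = 3)
  mom <- sample_moments(Y)
  r <- mom$ybar - expand_mean(pool_mean(mom$ybar))
  expect_equal(fit$Sigma, pool_covariance(mom$S + tcrossprod(r)),
               tolerance = 1e-12)
})

test_that("fitted spectral diagonal equals the sample spectral diagonal", {
  tbl <- simulate_branching(n = 15, G = 5, h = 0.8, seed = 21)
  for (M in 1:2) {
    fit <- fit_lineage(tbl, M = M)
    d_fit <- unlist(lapply(fit$spectral$blocks, diag))
    d_sam <- unlist(lapply(fit$sample_spectral$blocks, diag))
    expect_equal(d_fit, d_sam, tolerance = 1e-12)
  }
})

test_that("constant-per-pedigree data put all variance in the ell = 0 block", {
  offsets <- c(-1, 0.5, 2, 3, -0.25)
  tbl <- purrr::list_rbind(lapply(seq_along(offsets), function(i) {
    tibble::tibble(pedigree = i, position = lineage_positions(3),
                   value = offsets[i])
  }))
  fit <- fit_lineage(tbl, M = 2)
  expect_gt(fit$spectral$blocks[["0"]][3, 3], 0)
  expect_lt(max(abs(fit$spectral$blocks[["1"]])), 1e-12)
  expect_lt(max(abs(fit$spectral$blocks[["2"]])), 1e-12)
})

test_that("daughter-order scrambling leaves the fit exactly unchanged", {
  tbl <- simulate_branching(n = 8, G = 4, h = 0.8, seed = 13)
  scr <- scramble_ordering(tbl, seed = 99)
  expect_false(identical(trait_matrix(tbl), trait_matrix(scr)))
  f1 <- fit_lineage(tbl, M = 1)
  f2 <- fit_lineage(scr, M = 1)
  expect_equal(f1$q, f2$q, tolerance = 1e-12)
  expect_equal(f1$Sigma, f2$Sigma, tolerance = 1e-12)
})

test_that("n = M + 2 pedigrees give positive-definite fits; n = M + 1 do not", {
  eigs3 <- vapply(1:60, function(s) fit_min_eigenvalue(3, G = 4, seed = s),
                  numeric(1))
  expect_true(all(!is.na(eigs3) & eigs3 > 0))
  eigs2 <- vapply(1:60, function(s) fit_min_eigenvalue(2, G = 4, seed = s),
                  numeric(1))
  expect_true(any(is.na(eigs2) | eigs2 <= 1e-12))
})

test_that("EM on complete data equals the one-pass fit", {
  tbl <- simulate_branching(n = 10, G = 3, h = 0.8, seed = 17)
  Y <- trait_matrix(tbl)
  direct <- fit_lineage(Y, M = 1)
  mu <- direct$mu
  es <- lineagemap:::expected_moments(Y, mu, direct$Sigma)
  mom <- sample_moments(Y)
  expect_equal(es$ybar, mom$ybar, tolerance = 1e-12)
  expect_equal(es$S, mom$S, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("E-step imputes the analytic Gaussian conditional mean", {
  G <- 3
  Sigma <- branching_covariance(G, 0.8)
  mu <- rep(0, 7)
  set.seed(31)
  Y <- matrix(rnorm(7), 1)
  miss <- 4L
  Ym <- Y
  Ym[, miss] <- NA
  es <- lineagemap:::expected_moments(Ym, mu, Sigma)
  o <- setdiff(1:7, miss)
  expected <- Sigma[miss, o] %*% solve(Sigma[o, o], Y[1, o])
  expect_equal(es$imputed[1, miss], as.numeric(expected), tolerance = 1e-12)
})

test_that("EM increases the observed-data log-likelihood monotonically", {
  tbl <- simulate_branching(n = 20, G = 5, h = 0.8,
                            missing_fraction = 0.2, seed = 23)
  fit <- fit_lineage(tbl, M = 1)
  expect_true(fit$converged)
  expect_gt(fit$iterations, 1)
  ll <- fit$loglik
  expect_true(all(diff(ll) > -1e-9 * pmax(abs(ll[-length(ll)]), 1)))
})

test_that("EM rejects positions that are never observed", {
  tbl <- simulate_branching(n = 4, G = 2, h = 0.5, seed = 1)
  tbl$value[tbl$position == "10"] <- NA
  expect_error(fit_lineage(tbl, M = 1), "never observed")
})

test_that("observed-data log-likelihood matches a direct density oracle", {
  skip_if_not_installed("mvtnorm")
  G <- 3
  Sigma <- branching_covariance(G, 0.7) * 1.3
  mu <- expand_mean(c(1, 2, 3))
  tbl <- simulate_branching(n = 6, G = G, h = 0.5,
                            missing_fraction = 0.15, seed = 41)
  Y <- trait_matrix(tbl)
  oracle <- sum(vapply(seq_len(nrow(Y)), function(i) {
    o <- which(!is.na(Y[i, ]))
    mvtnorm::dmvnorm(Y[i, o], mean = mu[o],
                     sigma = Sigma[o, o, drop = FALSE], log = TRUE)
  }, numeric(1)))
  expect_equal(lineage_loglik(Y, mu, Sigma), oracle, tolerance = 1e-10)
  # block-diagonal covariance: likelihood adds over blocks
  expect_equal(lineage_loglik(matrix(c(0, 0), 1), c(0, 0), diag(2)),
               2 * lineage_loglik(matrix(0, 1), 0, matrix(1)))
})

test_that("fit serialization writes labeled artifacts", {
  tbl <- simulate_branching(n = 6, G = 3, h = 0.8, seed = 55)
  fit <- fit_lineage(tbl, M = 1)
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(
    dir, c("mean.csv", "sigma_structured.csv", "xi_ell0.csv", "L_ell1.csv",
           "phi_ell2.csv", "fit_log.json")))))
  log <- jsonlite::read_json(file.path(dir, "fit_log.json"))
  expect_equal(log$G, 3)
  expect_true(log$converged)
})
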