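# Fate profiles: variance components by subtree and ancestral predictability.

test_that("variance components reproduce the hand-derived G = 2 profile", {
  vc <- variance_components(branching_covariance(2, 0.8))
  expect_equal(vc$xi_GG, c(1.64, 0.36), tolerance = 1e-12)
  expect_equal(vc$eta2, c(0.82, 0.18), tolerance = 1e-12)
  expect_equal(vc$eta2_cml, c(0.82, 1), tolerance = 1e-12)
})

test_that("white noise distributes variance as d_ell / n_sources", {
  for (G in 2:5) {
    vc <- variance_components(diag(2^G - 1))
    expect_equal(vc$eta2, d_ell(0:(G - 1)) / n_sources(G), tolerance = 1e-12)
  }
})

test_that("pure inter-pedigree variation concentrates in ell = 0", {
  offsets <- c(-2, 0, 1, 3)
  tbl <- purrr::list_rbind(lapply(seq_along(offsets), function(i) {
    tibble::tibble(pedigree = i, position = lineage_positions(3),
                   value = offsets[i])
  }))
  vc <- variance_components(fit_lineage(tbl, M = 2))
  expect_equal(vc$eta2, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(vc$eta2_cml, rep(1, 3), tolerance = 1e-12)
})

test_that("cumulative components are a nondecreasing running total ending at 1", {
  for (seed in 1:5) {
    S <- random_structured(4, seed = 40 + seed)
    vc <- variance_components(S)
    expect_true(all(vc$eta2 >= 0))
    expect_equal(sum(vc$eta2), 1, tolerance = 1e-12)
    expect_equal(vc$eta2_cml, cumsum(vc$eta2), tolerance = 1e-12)
    expect_true(all(diff(vc$eta2_cml) >= -1e-15))
    expect_equal(vc$eta2_cml[length(vc$eta2_cml)], 1, tolerance = 1e-12)
  }
})

test_that("last-generation variance is reconstructed from the components", {
  # sum(xi_GG * d) / n_sources equals sigma_GG of the structured matrix
  for (seed in 1:5) {
    G <- 5
    S <- random_structured(G, seed = 50 + seed)
    vc <- variance_components(S)
    expect_equal(sum(vc$component) / n_sources(G), S[2^G - 1, 2^G - 1],
                 tolerance = 1e-10)
  }
  # and for a fitted model against the fitted covariance diagonal
  fit <- fit_lineage(simulate_branching(10, 4, 0.8, seed = 3), M = 1)
  vc <- variance_components(fit)
  expect_equal(sum(vc$component) / n_sources(4), unname(fit$Sigma[15, 15]),
               tolerance = 1e-10)
})

test_that("fitted components equal the single-generation ANOVA components", {
  # with complete data the fitted xi_GG equal the sample spectral diagonal,
  # i.e. a variance-components analysis of generation G alone
  tbl <- simulate_branching(n = 25, G = 4, h = 0.8, seed = 67)
  fit <- fit_lineage(tbl, M = 1)
  vc_fit <- variance_components(fit)
  vc_sample <- vapply(fit$sample_spectral$blocks,
                      function(b) b[nrow(b), ncol(b)], numeric(1))
  expect_equal(vc_fit$xi_GG, unname(vc_sample), tolerance = 1e-12)
})

test_that("fate expression follows the branching closed form h^(2(G-g))", {
  for (G in 2:5) {
    fe <- fate_expression(branching_covariance(G, 0.8))
    expect_equal(fe$R2, 0.8^(2 * (G - seq_len(G - 1))))
    # nearest ancestor is sufficient for a Markov tree
    expect_equal(fe$R2_cml, fe$R2, tolerance = 1e-12)
  }
  # independent generations: nothing is predictable
  fe0 <- fate_expression(diag(15))
  expect_equal(fe0$R2, rep(0, 3))
  expect_equal(fe0$R2_cml, rep(0, 3))
})

test_that("cumulative expression tracks pointwise expression for M = 1 fits", {
  # exact equality holds when the ancestor chain itself is Markov (as in the
  # branching model, tested above); a Markov-1 fit of noisy data makes the
  # chain only approximately Markov, so the two profiles agree closely but
  # not identically
  tbl <- simulate_branching(n = 30, G = 5, h = 0.8, seed = 73)
  fit <- fit_lineage(tbl, M = 1)
  fe <- fate_expression(fit)
  expect_lt(max(abs(fe$R2_cml - fe$R2)), 0.05)
  expect_true(all(fe$R2 >= 0 & fe$R2 <= 1))
  expect_true(all(fe$R2_cml >= 0 & fe$R2_cml <= 1))
  # single-ancestor cumulative value is the marginal one by definition
  expect_equal(fe$R2_cml[1], fe$R2[1], tolerance = 1e-12)
})

test_that("fate profile bundles both measures and tidies cleanly", {
  pr <- fate_profile(branching_covariance(4, 0.8))
  expect_s3_class(pr, "fate_profile")
  td <- tidy(pr)
  expect_setequal(unique(td$measure), c("eta2", "R2"))
  expect_equal(nrow(td), 4 + 3)
  gl <- glance(pr)
  expect_equal(gl$eta2_interpedigree_pct, 100 * pr$restriction$eta2[1])
  dir <- withr::local_tempdir()
  write_fate_profile(pr, dir)
  back <- readr::read_csv(file.path(dir, "restriction.csv"),
                          show_col_types = FALSE)
  expect_equal(back$eta2, pr$restriction$eta2)
})

test_that("plot methods return ggplot objects", {
  fit <- fit_lineage(simulate_branching(8, 3, 0.8, seed = 81), M = 1)
  expect_s3_class(autoplot(fate_profile(fit)), "ggplot")
  expect_s3_class(autoplot(correlation_map(fit)), "ggplot")
  expect_s3_class(autoplot(dynamic_map(fit)), "ggplot")
})
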