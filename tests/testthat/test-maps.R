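# Undirected correlation / partial-correlation maps, directed dynamic maps,
# and graph export.

test_that("correlation map carries Pearson correlations on all pairs", {
  cm <- correlation_map(branching_covariance(3, 0.8))
  expect_s3_class(cm, "lineage_map")
  expect_equal(nrow(cm), choose(7, 2))
  md <- cm[cm$node_a == "1" & cm$node_b == "10", ]
  expect_equal(md$weight, 0.8)
  # orbit symmetry: equal-orbit pairs share a weight
  orb <- orbit_index(cm$node_a, cm$node_b)
  key <- paste(orb$g_early, orb$g_late, orb$g_mrca)
  spread <- tapply(cm$weight, key, function(w) diff(range(w)))
  expect_lt(max(spread), 1e-12)
  # diagonal covariance: no associations
  expect_equal(max(abs(correlation_map(diag(7))$weight)), 0)
  expect_error(correlation_map(diag(c(0, 1, 1))), "variance")
})

test_that("partial-correlation map of a branching process is a binary tree", {
  pm <- partial_correlation_map(branching_covariance(5, 0.8))
  is_md <- startsWith(pm$node_b, pm$node_a) &
    nchar(pm$node_b) == nchar(pm$node_a) + 1
  expect_lt(max(abs(pm$weight[!is_md])), 1e-10)
  expect_true(all(abs(pm$weight[is_md]) > 0.1))
  expect_equal(max(abs(partial_correlation_map(diag(7))$weight)), 0)
  expect_error(partial_correlation_map(matrix(1, 7, 7)), "singular")
})

test_that("partial correlations match the precision-matrix formula at G = 2", {
  S <- branching_covariance(2, 0.6)
  K <- solve(S)
  pm <- partial_correlation_map(S)
  w <- pm$weight[pm$node_a == "10" & pm$node_b == "11"]
  expect_equal(w, -K[2, 3] / sqrt(K[2, 2] * K[3, 3]), tolerance = 1e-12)
})

test_that("dynamic map reads off the modified Cholesky factors", {
  # hand-computed G = 2 branching: beta = sqrt(2) * 0.8, innovations (1, .36)
  sp <- as_spectral(branching_covariance(2, 0.8))
  dm <- dynamic_map(sp, M = 1)
  e <- dm$edges[dm$edges$ell == 0, ]
  expect_equal(e$from_g, 1)
  expect_equal(e$to_g, 2)
  expect_equal(e$beta, sqrt(2) * 0.8, tolerance = 1e-12)
  n0 <- dm$nodes[dm$nodes$ell == 0, ]
  expect_equal(n0$innovation, c(1, 0.36), tolerance = 1e-12)
  # 1 x 1 block: single node, no edges
  expect_equal(nrow(dm$edges[dm$edges$ell == 1, ]), 0L)
  expect_equal(dm$nodes$innovation[dm$nodes$ell == 1], 0.36, tolerance = 1e-12)
  # diagonal blocks give no edges at all
  dm_id <- dynamic_map(as_spectral(diag(7)), M = 2)
  expect_equal(nrow(dm_id$edges), 0L)
})

test_that("dynamic map reconstruction round-trips the spectral blocks", {
  tbl <- simulate_branching(n = 10, G = 5, h = 0.8, seed = 61)
  fit <- fit_lineage(tbl, M = 2)
  dm <- dynamic_map(fit)
  for (nm in names(fit$spectral$blocks)) {
    xi <- fit$spectral$blocks[[nm]]
    k <- nrow(xi)
    gs <- as.integer(rownames(xi))
    Phi <- dm$nodes$innovation[dm$nodes$ell == as.integer(nm)]
    B <- diag(k)
    e <- dm$edges[dm$edges$ell == as.integer(nm), ]
    if (nrow(e) > 0) {
      B[cbind(match(e$to_g, gs), match(e$from_g, gs))] <- -e$beta
    }
    L <- solve(B)
    expect_lt(max(abs(L %*% diag(Phi, k) %*% t(L) - xi)), 1e-10)
  }
  # amplification (|beta| > 1) must pass through unclipped
  xi_amp <- matrix(c(1, 1.5, 1.5, 2.5), 2, dimnames = list(1:2, 1:2))
  bf <- fit_block_markov(xi_amp, M = 1)
  expect_gt(abs(bf$beta[2, 1]), 1)
})

test_that("graph export round-trips and honours formats", {
  fit <- fit_lineage(simulate_branching(n = 8, G = 3, h = 0.8, seed = 71), M = 1)
  cm <- correlation_map(fit)
  dir <- withr::local_tempdir()

  gml <- file.path(dir, "map.graphml")
  export_graph(cm, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 7)
  expect_equal(sort(igraph::E(g)$weight), sort(cm$weight), tolerance = 1e-12)

  dot <- file.path(dir, "map.dot")
  export_graph(cm, dot, "dot")
  txt <- readLines(dot)
  expect_true(any(grepl("graph", txt)))
  expect_gt(length(txt), 7)

  csv <- file.path(dir, "map.csv")
  export_graph(cm, csv, "edgelist")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$weight, cm$weight, tolerance = 1e-12)
  expect_named(back, c("node_a", "node_b", "weight", "kind"))

  # an all-zero map still exports a valid graph with isolated nodes
  zm <- correlation_map(diag(7))
  export_graph(zm, gml, "graphml", prune = 0.5)
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g0), 7)
  expect_equal(igraph::gsize(g0), 0)

  # dynamic maps export as directed graphs
  dm <- dynamic_map(fit)
  export_graph(dm, gml, "graphml")
  gd <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_directed(gd))
  expect_equal(igraph::gsize(gd), nrow(dm$edges))

  expect_error(export_graph(cm, gml, "gexf"))
})
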