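## Lineage variability maps: undirected correlation / partial-correlation
## graphs over lineal positions, and directed dynamic maps over the natural
## variables of each subtree source.

get_sigma <- function(x) {
  if (inherits(x, "lineage_fit")) x$Sigma
  else if (is.matrix(x)) x
  else stop("expected a `lineage_fit` or a covariance matrix", call. = FALSE)
}

new_lineage_map <- function(edges, kind, G) {
  structure(edges, kind = kind, G = G,
            class = c("lineage_map", class(edges)))
}

#' Lineage correlation map (marginal associations)
#'
#' Undirected graph over lineal positions with edge weights given by the
#' Pearson correlation `sigma_jj' / sqrt(sigma_jj sigma_j'j')` from the
#' fitted structured covariance. All pairs sharing a 3-index orbit have
#' equal weight by construction.
#'
#' @param x a `lineage_fit` or an orbit-structured covariance matrix.
#' @return a tibble of class `lineage_map` with columns `node_a`, `node_b`,
#'   `weight`, `kind` (one row per unordered pair, `node_a` before `node_b`
#'   in canonical order).
#' @examples
#' correlation_map(branching_covariance(3, 0.8))
#' @export
correlation_map <- function(x) {
  Sigma <- get_sigma(x)
  v <- diag(Sigma)
  if (any(v <= 0)) stop("zero or negative variance on the diagonal", call. = FALSE)
  R <- Sigma / sqrt(tcrossprod(v))
  edge_table(R, kind = "marginal")
}

#' Lineage partial-correlation map (conditional associations)
#'
#' Undirected graph with edge weights given by the partial correlation
#' `-kappa_jj' / sqrt(kappa_jj kappa_j'j')` where `kappa` are entries of the
#' precision matrix (the inverse of the fitted covariance). An absent edge
#' means the two positions are conditionally independent given all others;
#' for a pure branching process only mother-daughter edges survive.
#'
#' @inheritParams correlation_map
#' @return a `lineage_map` tibble (`kind = "partial"`).
#' @export
partial_correlation_map <- function(x) {
  Sigma <- get_sigma(x)
  K <- tryCatch(chol2inv(chol(Sigma)), error = function(e) {
    stop("covariance is singular; a positive-definite fit needs n >= M + 2 pedigrees",
         call. = FALSE)
  })
  R <- -K / sqrt(tcrossprod(diag(K)))
  edge_table(R, kind = "partial")
}

edge_table <- function(R, kind) {
  pos <- rownames(R)
  if (is.null(pos)) pos <- lineage_positions(check_G(round(log2(nrow(R) + 1))))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  edges <- tibble::tibble(
    node_a = pos[idx[, 1]],
    node_b = pos[idx[, 2]],
    weight = R[idx],
    kind = kind
  )
  new_lineage_map(edges, kind, check_G(round(log2(nrow(R) + 1))))
}

#' Dynamic lineage map (directed, per-subtree dynamics)
#'
#' For each source `ell`, the natural variables over generations
#' `g = ell + 1 .. G` form a time series modeled by a structural equation:
#' each variable is a banded regression on up to `M` predecessors plus an
#' independent innovation. The parameters come from the modified Cholesky
#' decomposition of each fitted spectral block
#' (`xi = L Phi L'`, `B = solve(L)`, regression weights
#' `beta_jj' = -b_jj'`). Edge weights `beta` represent transmission of
#' variation (values with `|beta| > 1` flag amplification and are never
#' clipped); node sizes `Phi` represent innovations.
#'
#' @param x a `lineage_fit` or a `spectral_cov`.
#' @param M Markov order (taken from the fit when `x` is a `lineage_fit`).
#' @return an object of class `dynamic_map`: list of two tibbles, `nodes`
#'   (`ell`, `g`, `innovation`) and `edges` (`ell`, `from_g`, `to_g`,
#'   `beta`), plus `G` and `M`.
#' @examples
#' fit <- fit_lineage(simulate_branching(10, 4, 0.8, seed = 1), M = 1)
#' dynamic_map(fit)
#' @export
dynamic_map <- function(x, M = NULL) {
  if (inherits(x, "lineage_fit")) {
    spectral <- x$spectral
    if (is.null(M)) M <- x$M
  } else if (inherits(x, "spectral_cov")) {
    spectral <- x
    if (is.null(M)) stop("`M` is required when passing a spectral_cov", call. = FALSE)
  } else {
    stop("expected a `lineage_fit` or `spectral_cov`", call. = FALSE)
  }
  G <- spectral$G
  res <- purrr::imap(spectral$blocks, function(xi, nm) {
    ell <- as.integer(nm)
    k <- nrow(xi)
    gs <- seq(ell + 1L, G)
    bf <- fit_block_markov(xi, M = min(M, max(k - 1L, 1L)),
                           label = sprintf("spectral block ell = %d", ell))
    if (any(bf$Phi < 0)) {
      stop(sprintf("spectral block ell = %d is not positive definite", ell),
           call. = FALSE)
    }
    nodes <- tibble::tibble(ell = ell, g = gs, innovation = bf$Phi)
    idx <- which(lower.tri(bf$beta) & bf$beta != 0, arr.ind = TRUE)
    edges <- tibble::tibble(
      ell = ell,
      from_g = gs[idx[, 2]],
      to_g = gs[idx[, 1]],
      beta = bf$beta[idx]
    )
    list(nodes = nodes, edges = edges)
  })
  structure(list(
    nodes = purrr::list_rbind(purrr::map(res, "nodes")),
    edges = purrr::list_rbind(purrr::map(res, "edges")),
    G = G, M = M
  ), class = "dynamic_map")
}

#' @export
print.dynamic_map <- function(x, ...) {
  cat(sprintf("<dynamic_map> G = %d, M = %d; %d nodes, %d directed edges\n",
              x$G, x$M, nrow(x$nodes), nrow(x$edges)))
  amp <- sum(abs(x$edges$beta) > 1)
  if (amp > 0) cat(sprintf("  %d edge(s) with |beta| > 1 (amplification)\n", amp))
  invisible(x)
}

## ---- graph export --------------------------------------------------------

map_to_igraph <- function(map, prune = 0) {
  if (inherits(map, "dynamic_map")) {
    nodes <- map$nodes |>
      dplyr::transmute(name = sprintf("(%d,%d)", .data$ell, .data$g),
                       ell = .data$ell, g = .data$g,
                       innovation = .data$innovation)
    edges <- map$edges |>
      dplyr::transmute(from = sprintf("(%d,%d)", .data$ell, .data$from_g),
                       to = sprintf("(%d,%d)", .data$ell, .data$to_g),
                       weight = .data$beta)
    if (prune > 0) edges <- dplyr::filter(edges, abs(.data$weight) >= prune)
    igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  } else {
    G <- attr(map, "G")
    nodes <- tibble::tibble(name = lineage_positions(G))
    edges <- tibble::tibble(from = map$node_a, to = map$node_b,
                            weight = map$weight)
    if (prune > 0) edges <- dplyr::filter(edges, abs(.data$weight) >= prune)
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  }
}

#' Export a lineage map as a graph file
#'
#' Writes a [correlation_map()], [partial_correlation_map()] or
#' [dynamic_map()] to GraphML, DOT or edge-list CSV. The optional pruning
#' threshold applies to the exported display file only; it never feeds back
#' into any computation.
#'
#' @param map a `lineage_map` or `dynamic_map`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"edgelist"`.
#' @param prune drop edges with `|weight|` below this value (display only;
#'   default 0 keeps everything).
#' @return `path`, invisibly.
#' @export
export_graph <- function(map, path, format = c("graphml", "dot", "edgelist"),
                         prune = 0) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- if (inherits(map, "dynamic_map")) {
      dplyr::transmute(map$edges,
                       node_a = sprintf("(%d,%d)", .data$ell, .data$from_g),
                       node_b = sprintf("(%d,%d)", .data$ell, .data$to_g),
                       weight = .data$beta, kind = "dynamic")
    } else {
      tibble::as_tibble(map)[c("node_a", "node_b", "weight", "kind")]
    }
    if (prune > 0) edges <- dplyr::filter(edges, abs(.data$weight) >= prune)
    readr::write_csv(edges, path)
  } else {
    g <- map_to_igraph(map, prune = prune)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
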