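## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted lineage covariance model
#'
#' Returns one row per 3-index orbit of the structured covariance with the
#' shared estimate, the implied correlation, and the number of matrix
#' entries pooled into it.
#'
#' @param x a `lineage_fit`.
#' @param ... unused.
#' @return a tibble with columns `g_early`, `g_late`, `g_mrca`, `estimate`,
#'   `correlation`, `n_entries`.
#' @method tidy lineage_fit
#' @export
tidy.lineage_fit <- function(x, ...) {
  orb <- orbit_factor(x$G)
  f <- as.vector(orb$factor)
  est <- as.numeric(tapply(as.numeric(x$Sigma), f, mean))
  counts <- as.integer(table(f))
  keys <- do.call(rbind, strsplit(orb$levels, ".", fixed = TRUE))
  out <- tibble::tibble(
    g_early = as.integer(keys[, 1]),
    g_late = as.integer(keys[, 2]),
    g_mrca = as.integer(keys[, 3]),
    estimate = est,
    n_entries = counts
  )
  vars <- stats::setNames(
    out$estimate[out$g_early == out$g_late & out$g_early == out$g_mrca],
    out$g_early[out$g_early == out$g_late & out$g_early == out$g_mrca])
  out$correlation <- out$estimate /
    sqrt(vars[as.character(out$g_early)] * vars[as.character(out$g_late)])
  dplyr::arrange(out, .data$g_early, .data$g_late, .data$g_mrca)[
    c("g_early", "g_late", "g_mrca", "estimate", "correlation", "n_entries")]
}

#' Glance at a fitted lineage covariance model
#'
#' @param x a `lineage_fit`.
#' @param ... unused.
#' @return a one-row tibble: `G`, `p`, `n`, `M`, `n_params`, `iterations`,
#'   `logLik`, `converged`, `min_eigenvalue`.
#' @method glance lineage_fit
#' @export
glance.lineage_fit <- function(x, ...) {
  saturated <- x$G == 1 || x$M >= x$G - 1
  cx <- if (saturated) tree_complexity(x$G, "symmetric")
        else tree_complexity(x$G, "markov", M = x$M)
  tibble::tibble(
    G = x$G, p = 2^x$G - 1, n = x$n, M = x$M,
    n_params = cx$n_params,
    iterations = x$iterations,
    logLik = x$loglik[length(x$loglik)],
    converged = x$converged,
    min_eigenvalue = min(eigen(x$Sigma, symmetric = TRUE,
                               only.values = TRUE)$values)
  )
}

#' @method tidy fate_profile
#' @export
tidy.fate_profile <- function(x, ...) {
  dplyr::bind_rows(
    x$restriction |>
      dplyr::transmute(measure = "eta2", index = .data$ell,
                       value = .data$eta2, cumulative = .data$eta2_cml),
    x$expression |>
      dplyr::transmute(measure = "R2", index = .data$g,
                       value = .data$R2, cumulative = .data$R2_cml)
  )
}

#' @method glance fate_profile
#' @export
glance.fate_profile <- function(x, ...) {
  tibble::tibble(
    G = x$G,
    eta2_founder = x$restriction$eta2[1],
    eta2_interpedigree_pct = 100 * x$restriction$eta2[1],
    R2_mother = x$expression$R2[nrow(x$expression)]
  )
}

#' Plot a fate profile
#'
#' Explained variance (top) and cumulative explained variance (bottom) for
#' fate restriction by subtree level (`eta^2`) and fate expression by
#' ancestral generation (`R^2`).
#'
#' @param object a `fate_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fate_profile
#' @export
autoplot.fate_profile <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("value", "cumulative"), names_to = "panel") |>
    dplyr::mutate(panel = factor(.data$panel, c("value", "cumulative"),
                                 c("explained variance",
                                   "cumulative explained variance")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::scale_colour_manual(
      values = c(eta2 = "#2166ac", R2 = "#e08214"),
      labels = c(eta2 = expression(eta^2 * "(l | G)"),
                 R2 = expression(R^2 * "(g | G)"))) +
    ggplot2::labs(x = "subtree level l  /  ancestor generation g",
                  y = "fraction of fate variance", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a lineage correlation map as a matrix heat map
#'
#' @param object a `lineage_map` from [correlation_map()] or
#'   [partial_correlation_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lineage_map
#' @export
autoplot.lineage_map <- function(object, ...) {
  G <- attr(object, "G")
  pos <- lineage_positions(G)
  df <- dplyr::bind_rows(
    tibble::as_tibble(object),
    dplyr::rename(tibble::as_tibble(object), node_a = "node_b", node_b = "node_a")
  ) |>
    dplyr::mutate(node_a = factor(.data$node_a, pos),
                  node_b = factor(.data$node_b, rev(pos)))
  ggplot2::ggplot(df, ggplot2::aes(.data$node_a, .data$node_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (attr(object, "kind") == "partial")
                    "partial\ncorrelation" else "correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a dynamic lineage map
#'
#' One horizontal track per subtree level `ell`: nodes at generations
#' `g > ell` sized by innovation variance, arrows weighted by the
#' transmission coefficients `beta`.
#'
#' @param object a `dynamic_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dynamic_map
#' @export
autoplot.dynamic_map <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$g, y = -.data$ell))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$from_g, xend = .data$to_g,
                   y = -.data$ell, yend = -.data$ell,
                   linewidth = abs(.data$beta), colour = .data$beta),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$innovation),
                        colour = "grey30") +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey80",
                                    high = "#b2182b") +
    ggplot2::scale_y_continuous(breaks = -unique(nodes$ell),
                                labels = unique(nodes$ell)) +
    ggplot2::labs(x = "generation g", y = "subtree level l",
                  size = "innovation", colour = "transmission",
                  linewidth = "|beta|") +
    ggplot2::theme_minimal()
}
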