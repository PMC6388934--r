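## Fate profiles: variance components by subtree (fate restriction) and
## ancestral predictability by generation (fate expression).

get_spectral <- function(x) {
  if (inherits(x, "lineage_fit")) x$spectral
  else if (inherits(x, "spectral_cov")) x
  else if (is.matrix(x)) as_spectral(x)
  else stop("expected a `lineage_fit`, `spectral_cov` or covariance matrix",
            call. = FALSE)
}

#' Fate restriction: variance components by subtree level
#'
#' Decomposes the variance of a cell at the deepest generation `G` ("cell
#' fate") into independent contributions from the sources of variation at
#' each subtree level `ell` (with `ell = 0` the inter-pedigree source).
#' The component of variance for level `ell` is `xi_GG(ell) * d_ell`,
#' where `xi_GG(ell)` is the last diagonal entry of the fitted spectral
#' block and `d_ell` the number of subtrees at that level, and
#' `eta^2(ell | G)` is its share of the total. The function also verifies
#' the reconstruction identity: the generation-`G` variance of the
#' structured covariance equals `sum(xi_GG(ell) d_ell) / n_sources(G)`.
#'
#' Negative `xi_GG(ell)` estimates (possible under sampling noise in
#' saturated fits) are floored at 0 before normalizing, with a warning.
#'
#' @param x a `lineage_fit`, a `spectral_cov`, or an orbit-structured
#'   covariance matrix.
#' @return a tibble with columns `ell`, `d`, `xi_GG`, `component`
#'   (`xi_GG * d`), `eta2`, `eta2_cml`.
#' @examples
#' variance_components(branching_covariance(2, 0.8)) # 0.82 / 0.18
#' @export
variance_components <- function(x) {
  spectral <- get_spectral(x)
  G <- spectral$G
  ells <- 0:(G - 1L)
  xi_GG <- vapply(spectral$blocks, function(b) b[nrow(b), ncol(b)], numeric(1))
  if (any(xi_GG < 0)) {
    warning("negative spectral variance component(s) floored at 0", call. = FALSE)
    xi_GG <- pmax(xi_GG, 0)
  }
  d <- d_ell(ells)
  comp <- xi_GG * d
  total <- sum(comp)
  if (total <= 0) stop("all generation-G spectral components are zero", call. = FALSE)
  # reconstruction identity against the structured covariance diagonal
  Sigma <- if (inherits(x, "lineage_fit")) x$Sigma
           else if (is.matrix(x)) x
           else from_spectral(spectral)
  sigma_GG <- Sigma[2^G - 1, 2^G - 1]
  recon <- total / n_sources(G)
  if (abs(recon - sigma_GG) > 1e-8 * max(abs(sigma_GG), 1)) {
    warning(sprintf(
      "variance reconstruction mismatch: sum(xi_GG d)/N_src = %.10g vs sigma_GG = %.10g",
      recon, sigma_GG), call. = FALSE)
  }
  tibble::tibble(
    ell = ells, d = d, xi_GG = unname(xi_GG), component = unname(comp),
    eta2 = unname(comp / total), eta2_cml = cumsum(unname(comp / total))
  )
}

# representative labels on the all-zero descent path: generation g ancestor
# of the deepest all-zero cell
chain_label <- function(g) paste0("1", strrep("0", g - 1L))

#' Fate expression: predictability of fate from direct ancestors
#'
#' Correlates the trait of a cell at the deepest generation `G` with the
#' traits of its direct ancestors. `R2[g]` is the squared Pearson
#' correlation between a generation-`G` cell and its ancestor at generation
#' `g` (the orbit entry with 3-index `(g, G, g)`); `R2_cml[g]` is the
#' explained-variance fraction from regressing the fate on the whole
#' ancestor chain of generations `1 .. g`, which accounts for dependencies
#' among ancestors. For a first-order Markov fit the two coincide.
#'
#' @param x a `lineage_fit` or an orbit-structured covariance matrix.
#' @return a tibble with columns `g`, `R2`, `R2_cml`, for `g = 1 .. G - 1`.
#' @examples
#' fate_expression(branching_covariance(3, 0.8)) # h^(2(G - g))
#' @export
fate_expression <- function(x) {
  Sigma <- get_sigma(x)
  G <- check_G(round(log2(nrow(Sigma) + 1)))
  if (G < 2) stop("fate expression needs G >= 2", call. = FALSE)
  pos <- rownames(Sigma)
  if (is.null(pos)) {
    pos <- lineage_positions(G)
    dimnames(Sigma) <- list(pos, pos)
  }
  leaf <- chain_label(G)
  sigma_GG <- Sigma[leaf, leaf]
  gs <- seq_len(G - 1L)
  anc <- vapply(gs, chain_label, character(1))
  R2 <- vapply(gs, function(g) {
    Sigma[anc[g], leaf]^2 / (Sigma[anc[g], anc[g]] * sigma_GG)
  }, numeric(1))
  R2_cml <- vapply(gs, function(g) {
    A <- Sigma[anc[seq_len(g)], anc[seq_len(g)], drop = FALSE]
    b <- Sigma[anc[seq_len(g)], leaf]
    val <- tryCatch(sum(b * solve(A, b)) / sigma_GG,
                    error = function(e) stop(
                      "singular ancestor-chain covariance submatrix",
                      call. = FALSE))
    val
  }, numeric(1))
  tibble::tibble(g = gs, R2 = R2, R2_cml = R2_cml)
}

#' Full fate profile of a fitted lineage model
#'
#' Bundles fate restriction ([variance_components()]) and fate expression
#' ([fate_expression()]) for a fitted model: how much fate is restricted by
#' each subtree level, and how early fate is visible in ancestral
#' phenotypes.
#'
#' @param x a `lineage_fit` or an orbit-structured covariance matrix.
#' @return an object of class `fate_profile`: list with `restriction`
#'   (tibble over `ell`), `expression` (tibble over `g`) and `G`.
#' @examples
#' fate_profile(branching_covariance(4, 0.8))
#' @export
fate_profile <- function(x) {
  restriction <- variance_components(x)
  expression <- fate_expression(x)
  structure(list(restriction = restriction, expression = expression,
                 G = nrow(restriction)), class = "fate_profile")
}

#' @export
print.fate_profile <- function(x, ...) {
  cat(sprintf("<fate_profile> G = %d\n", x$G))
  cat("  fate restriction eta^2(ell | G):",
      paste(sprintf("%.3f", x$restriction$eta2), collapse = " "), "\n")
  cat("  fate expression  R^2(g | G):  ",
      paste(sprintf("%.3f", x$expression$R2), collapse = " "), "\n")
  invisible(x)
}

#' Write a fate profile to CSV files
#'
#' Writes `restriction.csv` (`ell`, `eta2`, `eta2_cml`) and
#' `expression.csv` (`g`, `R2`, `R2_cml`).
#'
#' @param profile a `fate_profile`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fate_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(profile$restriction[c("ell", "eta2", "eta2_cml")],
                   file.path(dir, "restriction.csv"))
  readr::write_csv(profile$expression, file.path(dir, "expression.csv"))
  invisible(dir)
}
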