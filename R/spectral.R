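## Generalized spectral (Haar-type) analysis of a complete binary tree.
##
## The natural variables of an unordered tree are bifurcated subtrees: basis
## vectors supported on a single generation g, uniform with sign +1 over the
## generation-g descendants of one daughter of a subtree root and -1 over the
## other, normalized to unit length. They are labeled by (ell, tau, g) where
## (ell, tau) locates the subtree root and g > ell the observation
## generation; ell = 0 carries the pedigree-wide (inter-pedigree) averages.

#' A single natural-variable (bifurcated-subtree) basis vector
#'
#' @param ell,tau source subtree coordinates (`tau` is ignored for
#'   `ell = 0`).
#' @param g observation generation, `ell < g <= G`.
#' @param G number of generations of the tree.
#' @return a unit-norm numeric vector of length `2^G - 1`, named by position,
#'   supported only on generation-`g` positions.
#' @examples
#' natural_variable(1, 0, 2, G = 3) # contrast of the two daughters
#' @export
natural_variable <- function(ell, tau, g, G) {
  G <- check_G(G)
  if (g <= ell || g > G) stop("require ell < g <= G", call. = FALSE)
  if (ell < 0 || ell > G - 1) stop("require 0 <= ell <= G - 1", call. = FALSE)
  if (tau < 0 || tau >= d_ell(ell)) stop("invalid `tau` for this `ell`", call. = FALSE)
  pos <- lineage_positions(G)
  v <- stats::setNames(numeric(length(pos)), pos)
  if (ell == 0L) {
    idx <- nchar(pos) == g
    v[idx] <- 1 / sqrt(2^(g - 1))
  } else {
    r <- subtree_root(ell, tau)
    c0 <- 1 / sqrt(2^(g - ell))
    plus  <- nchar(pos) == g & startsWith(pos, paste0(r, "0"))
    minus <- nchar(pos) == g & startsWith(pos, paste0(r, "1"))
    v[plus] <- c0
    v[minus] <- -c0
  }
  v
}

#' Orthonormal change-of-basis matrix for a complete tree
#'
#' Builds the `p x p` matrix `T` whose columns are the natural variables of a
#' `G`-generation tree, ordered lexicographically by `(ell, tau, g)`. This is
#' the generalization of the Haar wavelet transform to all nodes of a binary
#' tree: conjugation by `T` block-diagonalizes any covariance matrix that is
#' invariant under daughter-subtree permutations, with one irreducible block
#' per source `(ell, tau)` and identical blocks across `tau`.
#'
#' The sign convention puts `+` on the daughter whose label ends in 0; any
#' fixed choice yields the same spectral covariance because blocks are
#' pooled over `tau` and invariant under column negation.
#'
#' @param G number of generations.
#' @return an object of class `spectral_basis`: a list with elements `G`,
#'   `T` (the matrix, rows named by position, columns by
#'   `"(ell,tau,g)"`), and `labels`, a tibble with columns `ell`, `tau`,
#'   `g`, `column`.
#' @examples
#' b <- spectral_basis(3)
#' crossprod(b$T) # identity
#' @export
spectral_basis <- function(G) {
  G <- check_G(G)
  labels <- tidyr::expand_grid(ell = 0:(G - 1L)) |>
    dplyr::mutate(data = purrr::map(.data$ell, function(l) {
      tidyr::expand_grid(tau = 0:(d_ell(l) - 1L), g = seq(l + 1L, G))
    })) |>
    tidyr::unnest("data") |>
    dplyr::arrange(.data$ell, .data$tau, .data$g) |>
    dplyr::mutate(column = dplyr::row_number())
  cols <- purrr::pmap(labels[c("ell", "tau", "g")], natural_variable, G = G)
  T_mat <- do.call(cbind, cols)
  rownames(T_mat) <- lineage_positions(G)
  colnames(T_mat) <- sprintf("(%d,%d,%d)", labels$ell, labels$tau, labels$g)
  structure(list(G = G, T = T_mat, labels = labels), class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> G = %d, %d natural variables\n",
              x$G, ncol(x$T)))
  invisible(x)
}

# Column indices of each irreducible (ell, tau) subspace, in (ell, tau)
# lexicographic order, with the ell of each group attached.
block_columns <- function(basis) {
  gid <- cumsum(!duplicated(basis$labels[c("ell", "tau")]))
  groups <- split(basis$labels$column, gid)
  attr(groups, "ell") <- basis$labels$ell[!duplicated(basis$labels[c("ell", "tau")])]
  groups
}

#' Transform a structured covariance into the spectral domain
#'
#' Conjugates a permutation-invariant (orbit-structured) covariance matrix by
#' the tree basis, checks that the result is block-diagonal over the
#' `(ell, tau)` partition and that the `d_ell` copies of each `ell`-block
#' agree, and returns one irreducible block per `ell` (the `tau`-average).
#'
#' @param Sigma symmetric `p x p` matrix, orbit-structured (equal entries
#'   within each 3-index orbit).
#' @param basis a [spectral_basis()]; built from the matching `G` if omitted.
#' @param tol relative tolerance for the block-diagonality and copy-agreement
#'   checks.
#' @return an object of class `spectral_cov`: list with `G`, `blocks` (one
#'   `(G - ell) x (G - ell)` symmetric matrix per `ell`, dimnames = the
#'   generations `g > ell`), and `d` (the multiplicities `d_ell`).
#' @examples
#' s <- as_spectral(branching_covariance(3, 0.8))
#' s$blocks[[1]]
#' @export
as_spectral <- function(Sigma, basis = NULL, tol = 1e-8) {
  if (is.null(basis)) basis <- spectral_basis(round(log2(nrow(Sigma) + 1)))
  G <- basis$G
  p <- 2^G - 1
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  Omega <- crossprod(basis$T, Sigma %*% basis$T)
  scale <- max(abs(Sigma), 1e-300)
  groups <- block_columns(basis)
  mask <- matrix(FALSE, p, p)
  for (idx in groups) mask[idx, idx] <- TRUE
  off <- max(abs(Omega[!mask]))
  if (off > tol * scale) {
    stop(sprintf(
      "input not orbit-structured: off-block spectral mass %.3g exceeds %.3g",
      off, tol * scale), call. = FALSE)
  }
  ells <- 0:(G - 1L)
  group_ell <- attr(groups, "ell")
  blocks <- lapply(ells, function(l) {
    idx_list <- groups[group_ell == l]
    copies <- lapply(idx_list, function(idx) Omega[idx, idx, drop = FALSE])
    ref <- copies[[1]]
    for (cp in copies[-1]) {
      if (max(abs(cp - ref)) > tol * scale) {
        stop(sprintf("tau-copies of block ell = %d disagree beyond tolerance", l),
             call. = FALSE)
      }
    }
    B <- Reduce(`+`, copies) / length(copies)
    B <- (B + t(B)) / 2
    gs <- seq(l + 1L, G)
    dimnames(B) <- list(gs, gs)
    B
  })
  names(blocks) <- ells
  structure(list(G = G, blocks = blocks, d = d_ell(ells)),
            class = "spectral_cov")
}

#' @export
print.spectral_cov <- function(x, ...) {
  cat(sprintf("<spectral_cov> G = %d; block dims: %s\n", x$G,
              paste(vapply(x$blocks, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

# Full block-diagonal spectral matrix (each ell-block repeated d_ell times).
expand_spectral <- function(spectral, basis) {
  p <- 2^spectral$G - 1
  Omega <- matrix(0, p, p)
  groups <- block_columns(basis)
  ell_of_group <- attr(groups, "ell")
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    Omega[idx, idx] <- spectral$blocks[[as.character(ell_of_group[k])]]
  }
  dimnames(Omega) <- list(colnames(basis$T), colnames(basis$T))
  Omega
}

#' Reconstruct a structured covariance from its spectral blocks
#'
#' Inverse of [as_spectral()]: expands the irreducible blocks into the full
#' block-diagonal spectral covariance and conjugates back,
#' `Sigma = T Omega T'`. Exact round-trip with [as_spectral()] up to
#' floating-point error.
#'
#' @param spectral a `spectral_cov` object.
#' @param basis matching [spectral_basis()]; built if omitted.
#' @return symmetric `p x p` matrix with position dimnames.
#' @export
from_spectral <- function(spectral, basis = NULL) {
  if (is.null(basis)) basis <- spectral_basis(spectral$G)
  stopifnot(basis$G == spectral$G)
  Omega <- expand_spectral(spectral, basis)
  S <- basis$T %*% Omega %*% t(basis$T)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(basis$T), rownames(basis$T))
  S
}

## ---- reference decompositions -------------------------------------------

#' Reference spectra: circulant (Fourier) and nested-pair (Haar) systems
#'
#' Two classical 4-variable sanity checks for the tree decomposition.
#' `circulant_spectrum()` diagonalizes the circulant covariance
#' `toeplitz(c(a, b, c, b))` with the discrete Fourier transform matrix and
#' returns the spectrum `a + 2b + c, a - c, a - 2b + c, a - c`.
#' `nested_pair_spectrum()` diagonalizes the two-batches-of-two covariance
#' (within-pair covariance `b`, between-pair `c`) with the Haar matrix and
#' returns the variance components
#' `a + b + 2c, a + b - 2c, a - b, a - b`. Both verify numerically that the
#' off-diagonal entries vanish.
#'
#' @param a,b,c covariance parameters (variance `a`).
#' @return numeric vector of 4 eigenvalues, in transform-column order.
#' @examples
#' circulant_spectrum(2, 1, 0.5)
#' nested_pair_spectrum(2, 1, 0.5)
#' @export
circulant_spectrum <- function(a, b, c) {
  Sigma <- stats::toeplitz(c(a, b, c, b))
  w <- exp(-2i * pi / 4)
  F_mat <- outer(0:3, 0:3, function(j, k) w^(j * k)) / 2
  Omega <- Conj(t(F_mat)) %*% Sigma %*% F_mat
  off <- Omega - diag(diag(Omega))
  stopifnot(max(abs(off)) < 1e-10 * max(abs(Sigma), 1))
  ev <- Re(diag(Omega))
  stopifnot(max(abs(Im(diag(Omega)))) < 1e-10 * max(abs(Sigma), 1))
  ev
}

#' @rdname circulant_spectrum
#' @export
nested_pair_spectrum <- function(a, b, c) {
  Sigma <- rbind(
    c(a, b, c, c),
    c(b, a, c, c),
    c(c, c, a, b),
    c(c, c, b, a)
  )
  s2 <- sqrt(2)
  H <- cbind(c(1, 1, 1, 1) / 2,
             c(1, 1, -1, -1) / 2,
             c(s2, -s2, 0, 0) / 2,
             c(0, 0, s2, -s2) / 2)
  Omega <- crossprod(H, Sigma %*% H)
  off <- Omega - diag(diag(Omega))
  stopifnot(max(abs(off)) < 1e-10 * max(abs(Sigma), 1))
  diag(Omega)
}
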