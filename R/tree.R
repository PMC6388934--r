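## ---- label algebra -------------------------------------------------------

#' Validate lineal-position labels
#'
#' A lineal position in a complete binary tree is labeled by the binary path
#' from the founder: the founder is `"1"`, its daughters `"10"` and `"11"`,
#' and so on. The generation of a cell is the number of characters in its
#' label (founder = generation 1).
#'
#' @param label character vector of candidate labels.
#' @return `is_position()` returns a logical vector; `generation()` the
#'   integer generation of each label.
#' @examples
#' is_position(c("1", "10", "02"))
#' generation(c("1", "110"))
#' @export
is_position <- function(label) {
  grepl("^1[01]*$", label)
}

#' @rdname is_position
#' @export
generation <- function(label) {
  assert_positions(label)
  nchar(label)
}

assert_positions <- function(label, arg = "label") {
  bad <- !is_position(label)
  if (any(bad)) {
    stop(sprintf(
      "invalid lineal position label(s) in `%s`: %s (must match ^1[01]*$)",
      arg, paste(unique(label[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(label)
}

#' Lineal positions of a complete binary tree
#'
#' Returns all `2^G - 1` position labels of a `G`-generation complete binary
#' tree in the canonical order used throughout the package: generation-major,
#' numeric within a generation (`1, 10, 11, 100, 101, 110, 111, ...`). This
#' ordering is the contract for every matrix indexed by lineal position.
#'
#' @param G number of generations (integer, >= 1).
#' @return character vector of `2^G - 1` labels.
#' @examples
#' lineage_positions(3)
#' @export
lineage_positions <- function(G) {
  G <- check_G(G)
  unlist(lapply(seq_len(G), positions_in_generation))
}

positions_in_generation <- function(g) {
  if (g == 1L) return("1")
  tails <- vapply(0:(2^(g - 1L) - 1L), function(k) {
    paste(rev(as.integer(intToBits(k))[seq_len(g - 1L)]), collapse = "")
  }, character(1))
  paste0("1", tails)
}

check_G <- function(G) {
  if (length(G) != 1L || is.na(G) || G < 1 || G != as.integer(G)) {
    stop("`G` must be a single integer >= 1", call. = FALSE)
  }
  as.integer(G)
}

#' Most recent common ancestor of two lineal positions
#'
#' The MRCA of two positions is the longest common prefix of their labels.
#' Vectorized over `a` and `b`.
#'
#' @param a,b position labels.
#' @return character vector of MRCA labels.
#' @examples
#' mrca("10", "110") # founder "1"
#' @export
mrca <- function(a, b) {
  assert_positions(a, "a")
  assert_positions(b, "b")
  mapply(function(x, y) {
    n <- min(nchar(x), nchar(y))
    xs <- substring(x, 1L, seq_len(n))
    ys <- substring(y, 1L, seq_len(n))
    k <- max(which(xs == ys))
    substring(x, 1L, k)
  }, a, b, USE.NAMES = FALSE)
}

#' Lineage distance between two positions
#'
#' The number of mother-daughter links separating two cells through their
#' most recent common ancestor: `D = g(a) + g(b) - 2 g(mrca(a, b))`.
#' Sisters are at distance 2, cousins at distance 4.
#'
#' @inheritParams mrca
#' @return integer vector of distances.
#' @examples
#' lineage_distance("100", "101") # sisters
#' @export
lineage_distance <- function(a, b) {
  nchar(a) + nchar(b) - 2L * nchar(mrca(a, b))
}

#' 3-index orbit of a pair of lineal positions
#'
#' In an unordered tree a pair of cells is characterized, up to the allowed
#' daughter-subtree permutations, by the generations of the two cells and the
#' generation of their MRCA. All covariance entries sharing this 3-index are
#' constrained to be equal. The index is returned in canonical form
#' (earlier generation first), so it is symmetric in its arguments.
#'
#' @inheritParams mrca
#' @return a tibble with columns `g_early`, `g_late`, `g_mrca`, one row per
#'   input pair.
#' @examples
#' orbit_index("10", "110") # the '231' orbit
#' @export
orbit_index <- function(a, b) {
  ga <- generation(a)
  gb <- generation(b)
  tibble::tibble(
    g_early = pmin(ga, gb),
    g_late  = pmax(ga, gb),
    g_mrca  = nchar(mrca(a, b))
  )
}

## ---- subtree coordinates -------------------------------------------------

#' Transverse multiplicity of subtree sources
#'
#' Sources of variation sit at the roots of subtrees, indexed by a
#' longitudinal coordinate `ell` (0 .. G-1) and a transverse coordinate
#' `tau` (0 .. d_ell - 1). `ell = 1` is the whole tree; `ell = 0` is the
#' virtual source outside the tree representing variation among pedigrees.
#' `d_ell` counts the subtrees at a given depth: 1 for `ell = 0`, otherwise
#' `2^(ell - 1)`. The total number of sources in a `G`-generation tree is
#' `n_sources(G) = sum(d_ell) = 2^(G-1)`.
#'
#' @param ell longitudinal coordinate(s), integer(s) in 0 .. G-1.
#' @param G number of generations.
#' @return integer vector of multiplicities.
#' @examples
#' d_ell(0:3)
#' n_sources(4)
#' @export
d_ell <- function(ell) {
  if (any(ell < 0)) stop("`ell` must be >= 0", call. = FALSE)
  ifelse(ell == 0L, 1L, 2L^(pmax(ell, 1L) - 1L))
}

#' @rdname d_ell
#' @export
n_sources <- function(G) {
  G <- check_G(G)
  sum(d_ell(0:(G - 1L)))
}

#' Root position of the subtree with coordinates (ell, tau)
#'
#' For `ell >= 1` the root is the `tau`-th node (0-based, numeric order)
#' of generation `ell`. The virtual source `(0, 0)` has no root in the tree
#' and is rejected.
#'
#' @param ell,tau subtree coordinates.
#' @return a position label.
#' @export
subtree_root <- function(ell, tau) {
  if (ell < 1) stop("the virtual source (0, 0) has no root position", call. = FALSE)
  roots <- positions_in_generation(ell)
  if (tau < 0 || tau >= length(roots)) {
    stop(sprintf("`tau` must be in 0 .. %d for ell = %d", length(roots) - 1L, ell),
         call. = FALSE)
  }
  roots[tau + 1L]
}

## ---- complexity ----------------------------------------------------------

#' Complexity of covariance models on a tree
#'
#' Reports, for a `G`-generation tree, the effective dimension `p_eff`, the
#' number of free variance-covariance parameters `n_params`, and the minimum
#' number of replicate pedigrees `n_min` needed for a positive-definite
#' estimate, under three models:
#'
#' * `"unstructured"`: no constraints; `p_eff = p = 2^G - 1`,
#'   `n_params = p(p+1)/2`, `n_min = p + 1` (exponential in `G`).
#' * `"symmetric"`: covariance constrained to be invariant under
#'   daughter-subtree permutations; `p_eff = G(G+1)/2`,
#'   `n_params = G(G+1)(G+2)/6`, `n_min = G + 1` (polynomial in `G`).
#' * `"markov"`: symmetric plus a Markov band of order `M` inside each
#'   irreducible spectral block; `n_min = M + 2`, independent of `G`.
#'
#' @param G number of generations.
#' @param model one of `"unstructured"`, `"symmetric"`, `"markov"`.
#' @param M Markov order (required for `model = "markov"`, `1 <= M <= G-1`
#'   unless `G == 1`).
#' @return a one-row tibble with columns `model`, `G`, `M`, `p_eff`,
#'   `n_params`, `n_min`.
#' @examples
#' tree_complexity(4, "symmetric")
#' tree_complexity(8, "markov", M = 1)
#' @export
tree_complexity <- function(G, model = c("unstructured", "symmetric", "markov"),
                            M = NULL) {
  G <- check_G(G)
  model <- match.arg(model)
  p <- 2L^G - 1L
  if (model == "unstructured") {
    out <- list(p_eff = p, n_params = p * (p + 1) / 2, n_min = p + 1L)
    M <- NA_integer_
  } else {
    p_eff <- G * (G + 1L) / 2L
    if (model == "symmetric") {
      out <- list(p_eff = p_eff, n_params = G * (G + 1) * (G + 2) / 6,
                  n_min = G + 1L)
      M <- NA_integer_
    } else {
      if (is.null(M)) stop("`M` is required for the markov model", call. = FALSE)
      if (M < 1 || (G > 1 && M > G - 1)) {
        stop("markov model requires 1 <= M <= G - 1", call. = FALSE)
      }
      n_params <- sum(vapply(0:(G - 1L), function(ell) {
        k <- G - ell
        band <- pmin(M, k - 1L)
        k + sum(k - seq_len(band))
      }, numeric(1)))
      out <- list(p_eff = p_eff, n_params = n_params, n_min = as.integer(M) + 2L)
    }
  }
  tibble::tibble(model = model, G = G, M = as.integer(M),
                 p_eff = out$p_eff, n_params = out$n_params, n_min = out$n_min)
}

## ---- permutation group (oracle) ------------------------------------------

#' Enumerate the daughter-subtree permutation group of a tree
#'
#' The symmetry group of an unordered complete binary tree is generated by
#' swapping the two daughter subtrees at any internal node; its order is
#' `2^(2^(G-1) - 1)` (one binary swap choice per internal node). Every
#' element preserves all kinship relations, so all 3-index orbits are
#' invariant. Enumeration is exponential and intended only as a brute-force
#' oracle, so it is restricted to `G <= 4`.
#'
#' @param G number of generations (at most 4).
#' @return a list of permutations, each a named character vector mapping each
#'   position label to its image label.
#' @examples
#' length(tree_permutations(3)) # 8
#' @export
tree_permutations <- function(G) {
  G <- check_G(G)
  if (G > 4) {
    stop("tree_permutations() is a brute-force oracle and refuses G > 4",
         call. = FALSE)
  }
  pos <- lineage_positions(G)
  internal <- pos[nchar(pos) < G]
  if (length(internal) == 0L) {
    return(list(stats::setNames(pos, pos)))
  }
  choices <- expand.grid(rep(list(c(FALSE, TRUE)), length(internal)),
                         KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(choices)), function(i) {
    swap <- stats::setNames(as.logical(choices[i, ]), internal)
    apply_subtree_swaps(pos, swap)
  })
}

# Apply an automorphism given swap choices at internal nodes: walking down a
# label's path, flip each bit whenever the swap is set at the ORIGINAL node
# being left. Returns a named map original label -> image label.
apply_subtree_swaps <- function(labels, swap) {
  img <- vapply(labels, function(lab) {
    bits <- strsplit(lab, "")[[1]]
    orig <- "1"
    out <- "1"
    for (b in bits[-1]) {
      flip <- isTRUE(swap[[orig]])
      out <- paste0(out, if (flip) as.character(1L - as.integer(b)) else b)
      orig <- paste0(orig, b)
    }
    out
  }, character(1))
  stats::setNames(img, labels)
}

## ---- cached layout helpers ----------------------------------------------

.layout_cache <- new.env(parent = emptyenv())

# orbit factor over all ordered position pairs of a G-tree, cached; used by
# pool_covariance() and the orbit parameter tidiers.
orbit_factor <- function(G) {
  key <- as.character(G)
  if (!is.null(.layout_cache[[key]])) return(.layout_cache[[key]])
  pos <- lineage_positions(G)
  p <- length(pos)
  gens <- nchar(pos)
  pre <- outer(pos, pos, function(a, b) nchar(mrca(a, b)))
  g1 <- outer(gens, gens, pmin)
  g2 <- outer(gens, gens, pmax)
  key_mat <- matrix(paste(g1, g2, pre, sep = "."), p, p)
  f <- factor(key_mat)
  res <- list(positions = pos, factor = matrix(as.integer(f), p, p),
              levels = levels(f))
  .layout_cache[[key]] <- res
  res
}
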