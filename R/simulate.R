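## Synthetic pedigrees: the stationary branching process used as the
## benchmark lineage, general tree-Gaussians from an arbitrary structured
## covariance, missingness masks, and daughter-order scrambling.

# Derive a per-pedigree substream seed from one base seed so that extending
# n does not reshuffle earlier pedigrees. Kept below 2^31.
substream_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483563
}

#' Covariance of the stationary branching process
#'
#' In the benchmark branching process the trait of each daughter is
#' conditionally independent of its sister given the mother, with
#' mother-daughter correlation `h` and stationary unit marginal variance.
#' The correlation between any two lineal positions is then `h^D` where `D`
#' is their lineage distance: sisters `h^2`, cousins `h^4`, and so on.
#'
#' @param G number of generations.
#' @param h mother-daughter correlation, `|h| < 1`.
#' @return `p x p` correlation matrix with position dimnames; it is
#'   orbit-structured by construction.
#' @examples
#' branching_covariance(3, 0.8)["10", "11"] # sisters: 0.64
#' @export
branching_covariance <- function(G, h) {
  G <- check_G(G)
  if (abs(h) >= 1) stop("require |h| < 1", call. = FALSE)
  pos <- lineage_positions(G)
  D <- outer(pos, pos, lineage_distance)
  Sigma <- h^D
  dimnames(Sigma) <- list(pos, pos)
  Sigma
}

#' Simulate pedigrees from the stationary branching process
#'
#' The founder trait is drawn standard normal; each daughter is
#' `h * mother + sqrt(1 - h^2) * N(0, 1)`, giving stationary unit variance
#' at every generation and correlation `h^D` between any two positions.
#' The result is rescaled to the requested trait mean and standard
#' deviation, and an optional missing-completely-at-random mask applied.
#' Each pedigree uses its own random substream derived from `seed`, so
#' increasing `n` leaves earlier pedigrees unchanged.
#'
#' @param n number of replicate pedigrees.
#' @param G number of generations.
#' @param h mother-daughter correlation (the benchmark uses 0.8).
#' @param mean,sd trait mean and standard deviation after rescaling.
#' @param missing_fraction probability that each cell is missing, in
#'   `[0, 1)`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a pedigree table tibble (`pedigree`, `position`, `value`).
#' @examples
#' tbl <- simulate_branching(n = 20, G = 6, h = 0.8,
#'                           missing_fraction = 0.2, seed = 1)
#' @export
simulate_branching <- function(n, G, h = 0.8, mean = 0, sd = 1,
                               missing_fraction = 0, seed = NULL) {
  G <- check_G(G)
  if (abs(h) >= 1) stop("require |h| < 1", call. = FALSE)
  pos <- lineage_positions(G)
  sim_one <- function(i) {
    if (!is.null(seed)) set.seed(substream_seed(seed, i))
    v <- stats::setNames(numeric(length(pos)), pos)
    v["1"] <- stats::rnorm(1)
    for (lab in pos[-1]) {
      parent <- substr(lab, 1, nchar(lab) - 1)
      v[lab] <- h * v[parent] + sqrt(1 - h^2) * stats::rnorm(1)
    }
    tibble::tibble(pedigree = i, position = pos, value = mean + sd * unname(v))
  }
  out <- purrr::list_rbind(lapply(seq_len(n), sim_one))
  if (missing_fraction > 0) {
    out <- apply_missingness(out, missing_fraction,
                             seed = if (is.null(seed)) NULL else seed + 1L)
  }
  structure(out, G = G)
}

#' Simulate pedigrees from an arbitrary structured covariance
#'
#' Draws `n` independent pedigrees from the multivariate Gaussian whose mean
#' assigns `q[g]` to every generation-`g` position and whose covariance is
#' the given orbit-structured, positive-definite matrix. Used for
#' parameter-recovery experiments beyond the branching process.
#'
#' @param n number of pedigrees.
#' @param q per-generation means (length `G`).
#' @param Sigma orbit-structured positive-definite `p x p` covariance.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a pedigree table tibble.
#' @export
simulate_lineage <- function(n, q, Sigma, seed = NULL) {
  G <- check_G(length(q))
  p <- 2^G - 1
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  pooled <- pool_covariance(Sigma)
  if (max(abs(pooled - Sigma)) > 1e-8 * max(abs(Sigma), 1)) {
    stop("`Sigma` is not orbit-structured", call. = FALSE)
  }
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("`Sigma` is not positive definite",
                                         call. = FALSE))
  pos <- lineage_positions(G)
  mu <- q[nchar(pos)]
  if (n == 0) {
    return(structure(tibble::tibble(pedigree = integer(), position = character(),
                                    value = numeric()), G = G))
  }
  sim_one <- function(i) {
    if (!is.null(seed)) set.seed(substream_seed(seed, i))
    z <- stats::rnorm(p)
    tibble::tibble(pedigree = i, position = pos,
                   value = mu + as.numeric(crossprod(R, z)))
  }
  structure(purrr::list_rbind(lapply(seq_len(n), sim_one)), G = G)
}

#' Mask cells missing completely at random
#'
#' Marks each cell missing independently with the given probability. A guard
#' rejects draws that would leave any pedigree without a single observed
#' cell (re-drawing is not attempted: the error signals that the requested
#' fraction is unreasonable for the tree size).
#'
#' @param data a pedigree table.
#' @param fraction missingness probability in `[0, 1)`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return the pedigree table with masked `value`s set to `NA`.
#' @export
apply_missingness <- function(data, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)", call. = FALSE)
  if (fraction == 0) return(data)
  if (!is.null(seed)) set.seed(seed %% 2147483647)
  mask <- stats::runif(nrow(data)) < fraction
  out <- data
  out$value[mask] <- NA_real_
  empty <- tapply(is.na(out$value), out$pedigree, all)
  if (any(empty)) {
    stop(sprintf(
      "missingness guard: pedigree(s) %s would have no observed cells",
      paste(names(empty)[empty], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Randomly scramble daughter order within pedigrees
#'
#' Independently for each pedigree and each internal node, swaps the two
#' daughter subtrees with probability 1/2 (relabeling all descendants).
#' Kinship structure is preserved, so any orbit-pooled estimate is exactly
#' invariant; this is how unordered data arrive in practice.
#'
#' @param data a pedigree table.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return the pedigree table with relabeled positions (canonical row order).
#' @export
scramble_ordering <- function(data, seed = NULL) {
  tbl <- as_pedigree_table(data, quiet = TRUE)
  G <- pedigree_depth(tbl)
  pos <- lineage_positions(G)
  internal <- pos[nchar(pos) < G]
  if (!is.null(seed)) set.seed(seed %% 2147483647)
  scr_one <- function(ped) {
    swap <- stats::setNames(stats::runif(length(internal)) < 0.5, internal)
    map <- apply_subtree_swaps(pos, swap)
    ped$position <- unname(map[ped$position])
    ped[match(pos, ped$position), ]
  }
  out <- purrr::list_rbind(lapply(split(tbl, tbl$pedigree), scr_one))
  structure(out, G = G)
}
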