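# Shared helpers: independent oracles and small fixture builders.

# Reynolds-operator pooling oracle: average S over every daughter-subtree
# permutation (conjugation by index permutation). Independent of
# pool_covariance(), which pools by orbit averaging.
reynolds_pool <- function(S, G) {
  pos <- lineage_positions(G)
  perms <- tree_permutations(G)
  acc <- matrix(0, nrow(S), ncol(S))
  for (pm in perms) {
    idx <- match(unname(pm[pos]), pos)
    acc <- acc + S[idx, idx]
  }
  acc / length(perms)
}

# A random symmetric PSD matrix of tree size p = 2^G - 1.
random_psd <- function(G, seed) {
  set.seed(seed)
  p <- 2^G - 1
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p
  dimnames(S) <- list(lineage_positions(G), lineage_positions(G))
  S
}

# A random orbit-structured PSD matrix (pooling preserves PSD because the
# Reynolds operator is an average of congruences).
random_structured <- function(G, seed) {
  pool_covariance(random_psd(G, seed))
}

# Structured mother-daughter correlations of a fit, one per generation pair.
md_correlations <- function(fit) {
  td <- tidy(fit)
  md <- td[td$g_late == td$g_early + 1 & td$g_mrca == td$g_early, ]
  md$correlation
}

# Smallest eigenvalue of the fitted covariance; NA when the fit itself fails
# (a singular fit is reported either way).
fit_min_eigenvalue <- function(n, G, seed, M = 1) {
  tbl <- simulate_branching(n = n, G = G, h = 0.8, seed = seed)
  fit <- tryCatch(fit_lineage(tbl, M = M), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  min(eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values)
}
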