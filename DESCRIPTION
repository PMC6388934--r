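Package: lineagemap
Title: Lineage Variability Maps for Cell Pedigree Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of symmetry- and Markov-constrained covariance
    structure on complete binary cell-lineage trees from a small number of
    replicate pedigrees. Implements the generalized spectral (Haar-type)
    decomposition for trees, orbit pooling of means and covariances under the
    daughter-subtree permutation group, banded (Markov) estimation within
    irreducible spectral blocks, an EM algorithm for missing cells, undirected
    lineage correlation maps, directed dynamic lineage maps, and fate profiles
    (variance components by subtree and ancestral predictability by
    generation). Includes a stationary branching-process simulator for
    benchmarking and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    mvtnorm,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
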