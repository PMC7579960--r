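#' Assemble a random network with a target number of interacting genes
#'
#' A single uniform gene draw of size `g` from a sparse interactome usually
#' contains few genes that interact with each other, so its degree table is
#' a poor size-matched null for a phenotype with many non-zero interacting
#' genes. This routine repeatedly draws gene sets of size `g`, harvests from
#' each draw the genes having at least one interaction with another gene of
#' the same draw, and accumulates them (deduplicated) until at least
#' `n_required` genes are collected. The combined set is the assembled
#' random network.
#'
#' @param network A `global_network`.
#' @param g Size of each uniform draw (the query's effective network size).
#' @param n_required Minimum number of harvested non-zero interacting genes.
#' @param max_draws Cap on draws per assembly (default 10000); exceeding it
#'   signals a pathologically sparse network.
#' @param set_id Identifier for the returned set.
#' @return A [gene_set()] with category `"random"`; by construction every
#'   member has internal degree >= 1 within the combined set.
#' @export
assemble_random_network <- function(network, g, n_required,
                                    max_draws = 10000, set_id = "random_assembly") {
  stopifnot(g <= length(network$nodes), n_required >= 1)
  n_nodes <- length(network$nodes)
  member <- logical(n_nodes)
  harvested <- integer(0)
  for (d in seq_len(max_draws)) {
    draw <- sample.int(n_nodes, g)
    member[draw] <- TRUE
    nz <- draw[internal_degrees(network, draw, member) > 0L]
    member[draw] <- FALSE
    harvested <- union(harvested, nz)
    if (length(harvested) >= n_required) {
      return(gene_set(set_id, network$nodes[harvested], category = "random"))
    }
  }
  stop("assembly error: fewer than ", n_required,
       " non-zero interacting genes harvested in ", max_draws,
       " draws of size ", g)
}

#' Permutation test of a phenotype slope
#'
#' Tests whether the observed through-origin slope differs from slopes of
#' assembled random networks matched to the phenotype's draw size `g` and
#' number of non-zero interacting genes `n_required`. For each of `n_perm`
#' permutations, a random network is assembled
#' ([assemble_random_network()]), its degree table computed against the same
#' global network, and its slope recorded. The p-value uses add-one
#' smoothing, `p = (count + 1) / (n_perm + 1)`, so it is never zero.
#'
#' Two tail conventions are available. `tail = "coherent"` (default) counts
#' random slopes less than or equal to the observed slope, so a small
#' p-value means the phenotype's slope is smaller — i.e. the network is more
#' coherent — than random. `tail = "larger"` counts random slopes strictly
#' greater than the observed slope (the indicator-of-larger-slopes
#' convention); the two conventions are complementary and both are kept for
#' audit. See the methods vignette for why "coherent" is the default.
#'
#' @param beta_obs Observed raw slope.
#' @param network A `global_network`.
#' @param g Effective size of the phenotype network (genes present in the
#'   global network).
#' @param n_required Number of non-zero interacting genes of the phenotype.
#' @param n_perm Number of permutations (default 10000).
#' @param tail `"coherent"` or `"larger"`; see above.
#' @param keep_slopes Retain the vector of random slopes in the result.
#' @param max_draws Per-assembly draw cap (see [assemble_random_network()]).
#' @return An object of class `permutation_result`: `p_value`,
#'   `n_permutations`, `n_exceeding` (count on the significant side),
#'   `tail`, and optionally `random_slopes`.
#' @export
permutation_test <- function(beta_obs, network, g, n_required,
                             n_perm = 10000, tail = c("coherent", "larger"),
                             keep_slopes = FALSE, max_draws = 10000) {
  tail <- match.arg(tail)
  stopifnot(n_perm >= 1)
  betas <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    rs <- assemble_random_network(network, g, n_required, max_draws = max_draws)
    tab <- compute_degrees(network, rs)
    betas[j] <- fit_origin_slope(tab)$beta
  }
  count <- if (tail == "coherent") sum(betas <= beta_obs) else sum(betas > beta_obs)
  structure(
    list(p_value = (count + 1) / (n_perm + 1),
         n_permutations = n_perm,
         n_exceeding = count,
         tail = tail,
         random_slopes = if (keep_slopes) betas else NULL),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> p = %.4g (%d/%d on the %s side)\n",
              x$p_value, x$n_exceeding, x$n_permutations, x$tail))
  invisible(x)
}

#' Greedy modularity of a gene set's internal network
#'
#' Runs greedy agglomerative modularity maximization (the
#' Clauset-Newman-Moore algorithm, via [igraph::cluster_fast_greedy()]) on
#' the subgraph induced by the set's internal edges only, and returns the
#' modularity Q of the partition found. Modularity and coherence capture
#' different properties: a set made of several well-separated dense modules
#' can have high modularity yet mediocre overall coherence.
#'
#' @param network A `global_network`.
#' @param gene_set A [gene_set()] or character vector; the induced subgraph
#'   must contain at least one edge.
#' @return An object of class `modularity_result`: `q`, `n_communities`,
#'   `method = "greedy"`.
#' @export
greedy_modularity <- function(network, gene_set) {
  ig <- induced_internal_graph(network, gene_set)
  if (igraph::ecount(ig) == 0L) {
    stop("undefined modularity: the induced internal subgraph has no edges")
  }
  cl <- igraph::cluster_fast_greedy(ig)
  structure(
    list(q = igraph::modularity(cl),
         n_communities = length(unique(igraph::membership(cl))),
         method = "greedy"),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result> Q = %.4g over %d communities (%s)\n",
              x$q, x$n_communities, x$method))
  invisible(x)
}
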