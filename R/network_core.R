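#' Build the global interactome
#'
#' Constructs a simple undirected graph over gene symbols from an edge
#' list. Self-loops and duplicate undirected edges are removed; the node set
#' is the union of edge endpoints. The object stores an integer adjacency
#' list so repeated internal/external degree computations (reference panels,
#' permutations) are cheap.
#'
#' @param edges data.frame with character columns `gene_a`, `gene_b` (extra
#'   columns, e.g. `score`, are ignored: downstream computations use edge
#'   presence only).
#' @return An object of class `global_network` with fields `nodes`
#'   (character), `edges` (two-column integer matrix indexing `nodes`,
#'   endpoint order `i < j`), `adj` (list of integer neighbor indices) and
#'   `degree` (integer vector).
#' @examples
#' net <- build_global_network(data.frame(gene_a = c("A", "B"),
#'                                        gene_b = c("B", "C")))
#' net$degree
#' @export
build_global_network <- function(edges) {
  if (is.matrix(edges)) {
    edges <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0L) {
    stop("empty edge list: cannot build a degree universe from no interactions")
  }
  ed <- canonicalize_edges(edges[[1]], edges[[2]])
  if (nrow(ed) == 0L) {
    stop("no edges left after removing self-loops and duplicates")
  }
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  i <- match(ed$gene_a, nodes)
  j <- match(ed$gene_b, nodes)
  em <- cbind(pmin(i, j), pmax(i, j))
  both_from <- c(em[, 1], em[, 2])
  both_to <- c(em[, 2], em[, 1])
  adj <- unname(split(both_to, factor(both_from, levels = seq_along(nodes))))
  adj <- lapply(adj, as.integer)
  structure(
    list(nodes = nodes, edges = em, adj = adj,
         degree = lengths(adj)),
    class = "global_network"
  )
}

#' @export
print.global_network <- function(x, ...) {
  cat(sprintf("<global_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Integer indices of a gene set's members that are present in the network.
present_indices <- function(network, gene_set) {
  idx <- match(as_gene_vector(gene_set), network$nodes)
  idx[!is.na(idx)]
}

# Internal degrees for node indices `idx` given a logical membership vector.
internal_degrees <- function(network, idx, member) {
  vapply(network$adj[idx], function(nb) sum(member[nb]), integer(1))
}

#' Internal and external degrees of a gene set
#'
#' For every gene of the set that is present in the global network, counts
#' its interaction partners inside the set (internal degree) and outside the
#' set (external degree). Set genes absent from the network have no
#' interaction annotation and are dropped (their count is recorded in the
#' `n_dropped` attribute). Genes with zero internal but positive external
#' degree are retained: they contribute to the external degree
#' distribution.
#'
#' @param network A `global_network`.
#' @param gene_set A [gene_set()] or character vector of symbols.
#' @return A data.frame with columns `gene`, `k_int`, `k_ext`, one row per
#'   set gene present in the network, with attributes `set_id` and
#'   `n_dropped`. For every row `k_int + k_ext` equals the gene's global
#'   degree.
#' @export
compute_degrees <- function(network, gene_set) {
  stopifnot(inherits(network, "global_network"))
  genes <- as_gene_vector(gene_set)
  idx <- match(genes, network$nodes)
  dropped <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  member <- logical(length(network$nodes))
  member[idx] <- TRUE
  k_int <- internal_degrees(network, idx, member)
  out <- data.frame(gene = network$nodes[idx],
                    k_int = k_int,
                    k_ext = network$degree[idx] - k_int,
                    stringsAsFactors = FALSE)
  attr(out, "set_id") <- if (inherits(gene_set, "gene_set")) gene_set$set_id else NA_character_
  attr(out, "n_dropped") <- dropped
  out
}

#' Eligibility of a phenotype degree table
#'
#' A phenotype network supports a slope fit only if it has enough non-zero
#' interacting genes (genes with at least one interaction with another set
#' member) and its internal degrees are not all identical (identical
#' internal degrees mean there is no internal degree distribution to
#' regress). The degeneracy test covers all retained genes, including those
#' with zero internal degree.
#'
#' @param table Degree table from [compute_degrees()].
#' @param min_nonzero Minimum number of non-zero interacting genes
#'   (default 10; a larger threshold gives more stable fits on small sets).
#' @return A list with fields `n_in_network`, `n_nonzero`, `eligible`, and
#'   `reason` (one of `"ok"`, `"too_few_nonzero"`,
#'   `"degenerate_internal_degrees"`).
#' @export
assess_eligibility <- function(table, min_nonzero = 10) {
  n_in_network <- nrow(table)
  n_nonzero <- sum(table$k_int >= 1L)
  reason <- if (n_nonzero < min_nonzero) {
    "too_few_nonzero"
  } else if (length(unique(table$k_int)) <= 1L) {
    "degenerate_internal_degrees"
  } else {
    "ok"
  }
  list(n_in_network = n_in_network, n_nonzero = n_nonzero,
       eligible = reason == "ok", reason = reason)
}

# igraph view of the subgraph induced by a gene set's internal edges,
# including internally isolated members as vertices. Used for modularity.
induced_internal_graph <- function(network, gene_set) {
  idx <- present_indices(network, gene_set)
  member <- logical(length(network$nodes))
  member[idx] <- TRUE
  keep <- member[network$edges[, 1]] & member[network$edges[, 2]]
  ed <- network$edges[keep, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = network$nodes[ed[, 1]], to = network$nodes[ed[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes[idx], stringsAsFactors = FALSE)
  )
}
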