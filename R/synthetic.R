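#' Generate a synthetic background interactome
#'
#' Random simple undirected graph over genes named `G000001 ...` used as the
#' global interactome in simulations. Two models: `erdos_renyi` (each pair
#' connected independently with probability `density_param`) and `powerlaw`
#' (preferential attachment with `round(density_param)` edges per new node,
#' mimicking the heavy-tailed degree distributions of real interactomes).
#' Nodes left without any edge are dropped (a gene with no interaction
#' annotation is not part of the degree universe).
#'
#' @param n_genes Number of genes (>= 100).
#' @param model `"erdos_renyi"` or `"powerlaw"`.
#' @param density_param Edge probability (Erdos-Renyi) or edges per node
#'   (power law).
#' @param seed Optional integer seed.
#' @return A `global_network`.
#' @export
generate_background <- function(n_genes = 2000,
                                model = c("erdos_renyi", "powerlaw"),
                                density_param = 0.005, seed = NULL) {
  model <- match.arg(model)
  if (n_genes < 100) stop("n_genes must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model,
    erdos_renyi = igraph::sample_gnp(n_genes, density_param),
    powerlaw = igraph::sample_pa(n_genes, m = max(1L, round(density_param)),
                                 directed = FALSE)
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) {
    stop("parameters produced an empty edge set; increase density_param")
  }
  nm <- sprintf("G%06d", seq_len(n_genes))
  build_global_network(data.frame(gene_a = nm[el[, 1]], gene_b = nm[el[, 2]],
                                  stringsAsFactors = FALSE))
}

# sample() treats a length-1 numeric vector as 1:n; guard against that.
sample_from <- function(v, n, replace = FALSE) {
  if (length(v) == 1L) return(rep(v, n))
  sample(v, n, replace = replace)
}

# Wire a chosen member set: internal pairs Bernoulli(p_in), member-outside
# pairs Bernoulli(p_out). Returns data.frame(gene_a, gene_b).
wire_module <- function(members, outside, p_in, p_out) {
  size <- length(members)
  pairs <- utils::combn(size, 2L)
  keep <- stats::runif(ncol(pairs)) < p_in
  ed <- data.frame(gene_a = members[pairs[1, keep]],
                   gene_b = members[pairs[2, keep]],
                   stringsAsFactors = FALSE)
  if (p_out > 0 && length(outside) > 0L) {
    for (m in members) {
      k <- stats::rbinom(1L, length(outside), p_out)
      if (k > 0L) {
        ed <- rbind(ed, data.frame(gene_a = m,
                                   gene_b = sample(outside, k),
                                   stringsAsFactors = FALSE))
      }
    }
  }
  ed
}

# Draw the edges of a planted module without rebuilding the network.
# Returns list(members, edges = data.frame(gene_a, gene_b)).
plant_module_edges <- function(nodes, size, p_in, p_out, exclude = character()) {
  stopifnot(p_in > 0)
  fresh <- setdiff(nodes, exclude)
  if (length(fresh) < size) {
    stop("insufficient unused genes: need ", size, ", have ", length(fresh))
  }
  members <- sample(fresh, size)
  list(members = members,
       edges = wire_module(members, setdiff(nodes, members), p_in, p_out))
}

#' Plant a dense module into a network
#'
#' Wires a member set internally with per-pair probability `p_in` and to
#' outside genes with per-pair probability `p_out`, then returns the
#' enlarged network and the member set. With `p_in` well above the
#' background density and `p_out` at or below it, the planted set is a
#' community: dense inside, sparse towards the rest — the ground truth for
#' high coherence.
#'
#' By default members are sampled from the network's existing genes (those
#' in `exclude` — typically members of previously planted modules — may not
#' be reused), so members keep whatever background edges they already had
#' and the realized external rate is `p_out` on top of the background
#' density. With `fresh_symbols = TRUE`, brand-new gene symbols are minted
#' instead; the members then carry exactly the wired edges, which gives
#' exact controlled constructions: `p_in = 1, p_out = 0` yields a perfect
#' clique with zero external edges (slope 0), and `p_in = p_out =`
#' background density yields a module statistically indistinguishable from
#' a random draw.
#'
#' @param network A `global_network`.
#' @param size Module size (when drawing existing genes, at most the number
#'   of unused genes).
#' @param p_in Internal edge probability (> 0).
#' @param p_out Per-pair external attachment probability.
#' @param exclude Genes that may not be reused.
#' @param set_id,category Labels for the returned [gene_set()].
#' @param fresh_symbols Mint new gene symbols instead of reusing existing
#'   network genes.
#' @return A list: `network` (updated `global_network`), `set` (the planted
#'   [gene_set()]).
#' @export
plant_module <- function(network, size, p_in, p_out = 0,
                         exclude = character(),
                         set_id = "planted", category = "planted",
                         fresh_symbols = FALSE) {
  if (fresh_symbols) {
    stopifnot(p_in > 0)
    members <- character(0)
    counter <- length(network$nodes)
    while (length(members) < size) {
      counter <- counter + 1L
      cand <- sprintf("G%06d", counter)
      if (!cand %in% network$nodes) members <- c(members, cand)
    }
    pl <- list(members = members,
               edges = wire_module(members, network$nodes, p_in, p_out))
    if (nrow(pl$edges) == 0L) {
      stop("planted module produced no edges; increase p_in or p_out")
    }
  } else {
    pl <- plant_module_edges(network$nodes, size, p_in, p_out, exclude)
  }
  all_edges <- rbind(
    data.frame(gene_a = network$nodes[network$edges[, 1]],
               gene_b = network$nodes[network$edges[, 2]],
               stringsAsFactors = FALSE),
    pl$edges
  )
  list(network = build_global_network(all_edges),
       set = gene_set(set_id, pl$members, category = category))
}

#' Generate a synthetic world for end-to-end validation
#'
#' Builds a background interactome, plants dense reference modules grouped
#' into named collections (standing in for curated pathway collections),
#' and plants phenotype gene sets at controlled coherence levels:
#' `"high"` (dense, `p_in` = `phenotype_p_in["high"]`), `"medium"`, and
#' `"random"` (a plain uniform draw, no planting). Planted member sets are
#' disjoint. Defaults give a desk-scale world: 2000 genes, Erdos-Renyi edge
#' probability 0.005, 3 collections of 10 modules with sizes 20-80 and
#' internal density 0.6, and two phenotypes per level with sizes 20-100.
#'
#' @param n_genes Background size.
#' @param background_p Background edge probability.
#' @param model Background model (see [generate_background()]).
#' @param n_collections,modules_per_collection Reference collection layout.
#' @param module_size_range Integer range reference module sizes are drawn
#'   from.
#' @param module_p_in Internal density of reference modules.
#' @param module_p_out External attachment of planted modules (defaults to
#'   the background density).
#' @param phenotype_levels Vector of levels drawn from
#'   `c("high", "medium", "random")`, one phenotype per entry.
#' @param phenotype_sizes Matching sizes; `NULL` draws them from
#'   `phenotype_size_range`.
#' @param phenotype_size_range Range for phenotype sizes.
#' @param phenotype_p_in Named internal densities for planted levels.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_world`: `network`,
#'   `reference_collections` (named list of lists of [gene_set()]s),
#'   `phenotypes` (list of [gene_set()]s whose `category` is the planted
#'   level), `params`, `seed`.
#' @export
generate_world <- function(n_genes = 2000, background_p = 0.005,
                           model = "erdos_renyi",
                           n_collections = 3, modules_per_collection = 10,
                           module_size_range = c(20, 80),
                           module_p_in = 0.6,
                           module_p_out = background_p,
                           phenotype_levels = c("high", "high", "medium",
                                                "medium", "random", "random"),
                           phenotype_sizes = NULL,
                           phenotype_size_range = c(20, 100),
                           phenotype_p_in = c(high = 0.8, medium = 0.3),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  network <- generate_background(n_genes, model, background_p)
  base_edges <- data.frame(
    gene_a = network$nodes[network$edges[, 1]],
    gene_b = network$nodes[network$edges[, 2]],
    stringsAsFactors = FALSE)
  nodes <- network$nodes
  used <- character(0)
  new_edges <- list()

  collections <- list()
  coll_names <- paste0("collection_", LETTERS[seq_len(n_collections)])
  for (ci in seq_len(n_collections)) {
    sets <- vector("list", modules_per_collection)
    for (k in seq_len(modules_per_collection)) {
      size <- sample_from(seq(module_size_range[1], module_size_range[2]), 1L)
      pl <- plant_module_edges(nodes, size, module_p_in, module_p_out, used)
      used <- c(used, pl$members)
      new_edges[[length(new_edges) + 1L]] <- pl$edges
      sets[[k]] <- gene_set(sprintf("%s_set%02d", coll_names[ci], k),
                            pl$members, category = coll_names[ci])
    }
    collections[[coll_names[ci]]] <- sets
  }

  if (is.null(phenotype_sizes)) {
    phenotype_sizes <- sample_from(seq(phenotype_size_range[1],
                                       phenotype_size_range[2]),
                                   length(phenotype_levels), replace = TRUE)
  }
  stopifnot(length(phenotype_sizes) == length(phenotype_levels),
            all(phenotype_levels %in% c("high", "medium", "random")))
  phenotypes <- vector("list", length(phenotype_levels))
  for (i in seq_along(phenotype_levels)) {
    lev <- phenotype_levels[i]
    id <- sprintf("pheno_%s_%02d", lev, i)
    if (lev == "random") {
      phenotypes[[i]] <- gene_set(id, sample(nodes, phenotype_sizes[i]),
                                  category = "random")
    } else {
      pl <- plant_module_edges(nodes, phenotype_sizes[i],
                               phenotype_p_in[[lev]], background_p, used)
      used <- c(used, pl$members)
      new_edges[[length(new_edges) + 1L]] <- pl$edges
      phenotypes[[i]] <- gene_set(id, pl$members, category = lev)
    }
  }

  network <- build_global_network(rbind(base_edges,
                                        do.call(rbind, new_edges)))
  structure(
    list(network = network,
         reference_collections = collections,
         phenotypes = phenotypes,
         params = list(n_genes = n_genes, background_p = background_p,
                       model = model, n_collections = n_collections,
                       modules_per_collection = modules_per_collection,
                       module_size_range = module_size_range,
                       module_p_in = module_p_in,
                       module_p_out = module_p_out,
                       phenotype_levels = phenotype_levels,
                       phenotype_sizes = phenotype_sizes,
                       phenotype_p_in = as.list(phenotype_p_in)),
         seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d-node network, %d collections, %d phenotypes\n",
    length(x$network$nodes), length(x$reference_collections),
    length(x$phenotypes)))
  invisible(x)
}

#' Write a synthetic world as on-disk fixtures
#'
#' Emits the world in exactly the dialects the readers consume: a
#' STRING-style links file (`links.txt`, both edge directions, confidence
#' scores drawn uniformly from 501-1000 so the default filter keeps every
#' edge), one GMT file per reference collection, a phenotype TSV
#' (`phenotypes.tsv` with DISEASE/TRAIT, CATEGORY and MAPPED_GENE columns),
#' and a JSON manifest of ground-truth parameters.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- world$network
  a <- net$nodes[net$edges[, 1]]
  b <- net$nodes[net$edges[, 2]]
  score <- sample(501:1000, length(a), replace = TRUE)
  links <- file.path(dir, "links.txt")
  utils::write.table(
    data.frame(protein1 = c(a, b), protein2 = c(b, a),
               combined_score = c(score, score)),
    links, sep = " ", quote = FALSE, row.names = FALSE)

  gmt_paths <- character(0)
  for (cname in names(world$reference_collections)) {
    p <- file.path(dir, paste0(cname, ".gmt"))
    lines <- vapply(world$reference_collections[[cname]], function(s) {
      paste(c(s$set_id, s$category, s$genes), collapse = "\t")
    }, character(1))
    writeLines(lines, p)
    gmt_paths <- c(gmt_paths, p)
  }

  pheno <- file.path(dir, "phenotypes.tsv")
  ptab <- data.frame(
    trait = vapply(world$phenotypes, function(s) s$set_id, character(1)),
    category = vapply(world$phenotypes, function(s) s$category, character(1)),
    genes = vapply(world$phenotypes, function(s) paste(s$genes, collapse = ", "),
                   character(1)),
    stringsAsFactors = FALSE)
  names(ptab) <- c("DISEASE/TRAIT", "CATEGORY", "MAPPED_GENE")
  utils::write.table(ptab, pheno, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- file.path(dir, "manifest.json")
  truth <- list(
    params = world$params,
    seed = world$seed,
    sets = lapply(c(unlist(world$reference_collections, recursive = FALSE),
                    world$phenotypes), function(s) {
      list(set_id = s$set_id, category = s$category, size = length(s$genes))
    })
  )
  jsonlite::write_json(truth, manifest, auto_unbox = TRUE, digits = NA)

  invisible(c(links = links, stats::setNames(gmt_paths, rep("gmt", length(gmt_paths))),
              phenotypes = pheno, manifest = manifest))
}
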