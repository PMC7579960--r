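# Shared fixtures and independent oracles. Everything is built in code;
# expensive objects are computed once per test run and cached.

# Default desk-scale synthetic world (2000 genes, ER p = 0.005, 3 x 10
# planted reference modules, two phenotypes per coherence level).
test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(seed = 20260929)
    cache
  }
})

# Smaller world for tests that regenerate many replicates.
small_world <- function(seed) {
  generate_world(n_genes = 1000, background_p = 0.01,
                 n_collections = 2, modules_per_collection = 5,
                 module_size_range = c(15, 40),
                 phenotype_levels = c("high", "medium", "random"),
                 phenotype_sizes = c(30, 30, 30),
                 seed = seed)
}

ring_edges <- function(n, prefix = "R") {
  nm <- sprintf("%s%02d", prefix, seq_len(n))
  data.frame(gene_a = nm, gene_b = nm[c(2:n, 1)], stringsAsFactors = FALSE)
}

clique_edges <- function(n, prefix = "K") {
  nm <- sprintf("%s%02d", prefix, seq_len(n))
  idx <- utils::combn(n, 2)
  data.frame(gene_a = nm[idx[1, ]], gene_b = nm[idx[2, ]],
             stringsAsFactors = FALSE)
}

# Brute-force internal/external degrees by explicit edge enumeration,
# independent of the adjacency-list implementation.
brute_degrees <- function(edges, set_genes) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  present <- intersect(set_genes, nodes)
  rows <- lapply(present, function(g) {
    nb <- c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g])
    data.frame(gene = g,
               k_int = sum(nb %in% present),
               k_ext = sum(!nb %in% present),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brute-force through-origin least squares: 1-D minimization of the RSS.
brute_slope <- function(table) {
  x <- sqrt(table$k_int)
  y <- sqrt(table$k_ext)
  f <- function(b) sum((y - b * x)^2)
  upper <- max(1, 10 * max(y) / max(x[x > 0]))
  stats::optimize(f, c(0, upper), tol = 1e-12)$minimum
}

# All set partitions of n elements as membership vectors (restricted
# growth strings). Bell(8) = 4140, fine for brute force.
all_partitions <- function(n) {
  grow <- function(m) {
    if (length(m) == n) return(list(m))
    k <- if (length(m) == 0L) 0L else max(m)
    do.call(c, lapply(seq_len(k + 1L), function(b) grow(c(m, b))))
  }
  grow(integer(0))
}

# Exhaustive-search maximum modularity of an igraph graph.
brute_max_modularity <- function(ig) {
  n <- igraph::vcount(ig)
  max(vapply(all_partitions(n),
             function(m) igraph::modularity(ig, m), numeric(1)))
}

random_degree_table <- function(n) {
  k_int <- sample(0:12, n, replace = TRUE)
  if (all(k_int == 0)) k_int[1] <- 1L
  data.frame(gene = sprintf("g%03d", seq_len(n)),
             k_int = k_int,
             k_ext = sample(0:30, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Manually assembled panel for normalization arithmetic tests.
manual_panel <- function(beta_min, beta_max) {
  structure(list(target_size = 50,
                 high_slopes = rep(beta_min, 3),
                 random_slopes = rep(beta_max, 3),
                 beta_min = beta_min, beta_max = beta_max),
            class = "reference_panel")
}

write_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
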