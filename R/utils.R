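`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' A single user seed drives several independent stochastic stages (world
#' generation, reference-panel sampling, permutation draws). Each stage gets
#' its own deterministic seed so stages can be rerun in isolation.
#'
#' @param seed Integer master seed.
#' @param stage Stage label, one of `"world"`, `"panel"`, `"permutation"`,
#'   `"random"`.
#' @param offset Optional extra integer offset (e.g. a panel target size).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage = c("world", "panel", "permutation", "random"),
                       offset = 0L) {
  stage <- match.arg(stage)
  base <- c(world = 101L, panel = 211L, permutation = 307L, random = 401L)[[stage]]
  # modular arithmetic keeps the result well inside 32-bit integer range
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + base +
                as.numeric(offset)) %% 2147483647)
}

# Canonicalize an undirected edge list: drop self-loops, order endpoints
# lexicographically, drop duplicates. Returns a data.frame(gene_a, gene_b)
# plus any extra columns of the first surviving occurrence.
canonicalize_edges <- function(gene_a, gene_b, extra = NULL) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]
  gene_b <- gene_b[keep]
  if (!is.null(extra)) extra <- extra[keep, , drop = FALSE]
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  dup <- duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra[!dup, , drop = FALSE])
  rownames(out) <- NULL
  out
}
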