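#' Construct a gene set
#'
#' A named collection of gene symbols with a free-text category label
#' (phenotype category, reference collection name, or `"random"`). Symbols
#' are deduplicated and empty strings dropped.
#'
#' @param set_id Identifier for the set (phenotype/trait or pathway name).
#' @param genes Character vector of gene symbols; duplicates are collapsed.
#' @param category Category label; `NA` if none.
#' @return An object of class `gene_set` with fields `set_id`, `category`,
#'   `genes`.
#' @examples
#' gene_set("S1", c("A", "B", "A"))
#' @export
gene_set <- function(set_id, genes, category = NA_character_) {
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0L) {
    stop("gene_set '", set_id, "': no genes after deduplication")
  }
  structure(
    list(set_id = as.character(set_id),
         category = as.character(category),
         genes = genes),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d genes\n", x$set_id,
              ifelse(is.na(x$category), "-", x$category), length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Accept either a gene_set or a bare character vector of symbols.
as_gene_vector <- function(gene_set) {
  if (inherits(gene_set, "gene_set")) return(gene_set$genes)
  unique(as.character(gene_set))
}
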