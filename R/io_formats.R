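#' Read a STRING-style protein-links file
#'
#' Parses a whitespace- or tab-delimited interaction file with a header row,
#' two identifier columns and an integer confidence score column in
#' \[0, 1000\] (the `protein.links` dialect). Records are kept only when the
#' score is strictly greater than `score_threshold`; self-loops and
#' symmetric duplicates are removed. Identifiers are passed through
#' verbatim — mapping to canonical symbols is a separate step
#' ([apply_alias_map()]).
#'
#' @param path Path to the links file.
#' @param score_threshold Keep records with `score > score_threshold`
#'   (strict inequality). Default 500, the midpoint of the bimodal
#'   confidence-score distribution commonly used to select high-confidence
#'   interactions. Use 0 to keep everything.
#' @param id_columns Names of the two identifier columns; `NULL` (default)
#'   takes the first two columns.
#' @param score_column Name of the confidence score column.
#' @return A data.frame with columns `gene_a`, `gene_b`, `score`; one row
#'   per undirected edge.
#' @export
read_string_links <- function(path, score_threshold = 500,
                              id_columns = NULL,
                              score_column = "combined_score") {
  tab <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!score_column %in% names(tab)) {
    stop("format error: score column '", score_column, "' not found in ", path)
  }
  if (is.null(id_columns)) {
    id_columns <- setdiff(names(tab), score_column)[1:2]
  }
  if (anyNA(id_columns) || !all(id_columns %in% names(tab))) {
    stop("format error: identifier columns not found in ", path)
  }
  score <- suppressWarnings(as.numeric(tab[[score_column]]))
  bad <- which(is.na(score) & nzchar(tab[[score_column]]))
  bad <- union(bad, which(!nzchar(tab[[score_column]])))
  if (length(bad) > 0L) {
    stop("unparseable score on line ", bad[1] + 1L, " of ", path)
  }
  keep <- score > score_threshold
  canonicalize_edges(tab[[id_columns[1]]][keep], tab[[id_columns[2]]][keep],
                     extra = data.frame(score = score[keep]))
}

#' Read a BioGrid TAB-style interaction file
#'
#' Tab-delimited file with official-symbol columns and per-interactor
#' organism (taxon) ID columns. Rows are kept when both interactors match
#' `taxon_id`; all interaction types are kept; no confidence score is
#' attached. Self-loops and duplicate undirected pairs (e.g. the same pair
#' reported as both physical and genetic) are removed.
#'
#' @param path Path to the TSV file.
#' @param taxon_id Organism ID both interactors must match (default "9606",
#'   human).
#' @param symbol_columns Names of the two interactor symbol columns.
#' @param taxon_columns Names of the two organism-ID columns.
#' @return A data.frame with columns `gene_a`, `gene_b`, `score` (all `NA`).
#' @export
read_biogrid_tab <- function(path, taxon_id = "9606",
                             symbol_columns = c("Official Symbol Interactor A",
                                                "Official Symbol Interactor B"),
                             taxon_columns = c("Organism ID Interactor A",
                                               "Organism ID Interactor B")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(taxon_columns %in% names(tab))) {
    stop("format error: taxon columns ",
         paste(setdiff(taxon_columns, names(tab)), collapse = ", "),
         " not found in ", path)
  }
  if (!all(symbol_columns %in% names(tab))) {
    stop("format error: symbol columns ",
         paste(setdiff(symbol_columns, names(tab)), collapse = ", "),
         " not found in ", path)
  }
  keep <- tab[[taxon_columns[1]]] == taxon_id & tab[[taxon_columns[2]]] == taxon_id
  out <- canonicalize_edges(tab[[symbol_columns[1]]][keep],
                            tab[[symbol_columns[2]]][keep])
  out$score <- rep(NA_real_, nrow(out))
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then one or more gene symbols,
#' tab-delimited (the MSigDB exchange format). Duplicate symbols within a
#' line are collapsed; a non-empty description is stored as the set's
#' category.
#'
#' @param path Path to the GMT file.
#' @return A list of [gene_set()] objects in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("format error: line ", i, " of ", path, " has fewer than 3 fields")
    }
    category <- if (nzchar(fields[2])) fields[2] else NA_character_
    out[[i]] <- gene_set(fields[1], fields[-(1:2)], category = category)
  }
  out
}

#' Read phenotype gene sets from a trait table
#'
#' Reads a GWAS-catalog-style TSV with a trait-name column and a
#' mapped-genes column whose cells may list several symbols. One gene set is
#' returned per distinct trait, pooling the genes of all its rows. Cells are
#' split on `delimiters`, tokens trimmed, empty tokens dropped. Symbols in
#' `exclude` or matching any regular expression in `exclude_patterns` are
#' removed (use this for non-protein-coding, antisense or readthrough
#' transcripts that carry no interaction annotation). Traits whose pooled
#' gene list is empty after filtering are dropped.
#'
#' @param path Path to the TSV file.
#' @param gene_column Name of the mapped-genes column (default
#'   "MAPPED_GENE").
#' @param trait_column Name of the trait column (default "DISEASE/TRAIT").
#' @param category_column Optional column giving the trait category; when
#'   `NULL` the category is `NA`.
#' @param delimiters Literal strings separating symbols within a cell.
#' @param exclude Character vector of symbols to drop exactly.
#' @param exclude_patterns Character vector of regular expressions; matching
#'   symbols are dropped.
#' @return A list of [gene_set()] objects, one per trait, in first-appearance
#'   order.
#' @export
read_phenotype_table <- function(path,
                                 gene_column = "MAPPED_GENE",
                                 trait_column = "DISEASE/TRAIT",
                                 category_column = NULL,
                                 delimiters = c(";", ",", " - ", " x "),
                                 exclude = character(),
                                 exclude_patterns = character()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c(gene_column, trait_column, category_column)
  if (!all(need %in% names(tab))) {
    stop("format error: column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "),
         " not found in ", path)
  }
  split_re <- paste(vapply(delimiters,
                           function(d) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", d),
                           character(1)),
                    collapse = "|")
  traits <- unique(tab[[trait_column]])
  out <- list()
  for (tr in traits) {
    rows <- tab[[trait_column]] == tr
    tokens <- unlist(strsplit(tab[[gene_column]][rows], split_re))
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    tokens <- setdiff(tokens, exclude)
    for (pat in exclude_patterns) {
      tokens <- tokens[!grepl(pat, tokens)]
    }
    if (length(tokens) == 0L) next
    category <- if (is.null(category_column)) NA_character_ else
      tab[[category_column]][rows][1]
    out[[length(out) + 1L]] <- gene_set(tr, tokens, category = category)
  }
  out
}

#' Read an alias-to-symbol mapping table
#'
#' Two-column TSV mapping alias symbols to canonical symbols. Canonical
#' symbols are added as identity mappings so that `map[x]` is defined for
#' every canonical symbol seen.
#'
#' @param path Path to the TSV.
#' @param alias_column,symbol_column Column names.
#' @return A named character vector: `names()` are aliases, values canonical
#'   symbols.
#' @export
read_alias_map <- function(path, alias_column = "alias",
                           symbol_column = "symbol") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c(alias_column, symbol_column) %in% names(tab))) {
    stop("format error: alias/symbol columns not found in ", path)
  }
  map <- stats::setNames(tab[[symbol_column]], tab[[alias_column]])
  canon <- setdiff(unique(tab[[symbol_column]]), names(map))
  c(map, stats::setNames(canon, canon))
}

#' Replace aliases by canonical gene symbols
#'
#' Applies an alias map to every gene set. Symbols absent from the map are
#' kept verbatim unless `strict = TRUE`, in which case they are dropped
#' (mirroring the exclusion of genes that cannot be mapped to symbols).
#' Each set is re-deduplicated after mapping, so its size can shrink. Sets
#' left empty under strict mapping are dropped with a warning.
#'
#' @param sets List of [gene_set()] objects.
#' @param aliases Named character vector, alias -> canonical symbol.
#' @param strict Drop unmapped symbols instead of keeping them verbatim.
#' @return The mapped list of gene sets.
#' @export
apply_alias_map <- function(sets, aliases, strict = FALSE) {
  out <- list()
  for (s in sets) {
    hit <- s$genes %in% names(aliases)
    mapped <- ifelse(hit, unname(aliases[s$genes]), s$genes)
    if (strict) mapped <- mapped[hit]
    mapped <- unique(mapped)
    if (length(mapped) == 0L) {
      warning("gene set '", s$set_id, "' empty after strict alias mapping; dropped")
      next
    }
    out[[length(out) + 1L]] <- gene_set(s$set_id, mapped, category = s$category)
  }
  out
}

results_columns <- c("set_id", "category", "n_genes", "n_nonzero",
                     "slope", "ci_low", "ci_high",
                     "coherence", "coherence_ci_low", "coherence_ci_high",
                     "perm_p", "modularity")

#' Write a coherence results table
#'
#' Writes one TSV row per phenotype with columns `set_id`, `category`,
#' `n_genes`, `n_nonzero`, `slope`, `ci_low`, `ci_high`, `coherence`,
#' `coherence_ci_low`, `coherence_ci_high`, `perm_p`, `modularity` (plus a
#' trailing `reason` column when present in `results`). Missing values are
#' written as "NA"; numeric values are written at 6 significant digits.
#'
#' @param results data.frame of results (see [run_coherence()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_results_table()]
#' @export
write_results_table <- function(results, path) {
  cols <- results_columns
  if (nrow(results) == 0L && length(setdiff(cols, names(results))) > 0L) {
    results <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  if ("reason" %in% names(results)) cols <- c(cols, "reason")
  missing_cols <- setdiff(cols, names(results))
  for (mc in missing_cols) results[[mc]] <- NA
  results <- results[, cols, drop = FALSE]
  for (j in seq_along(results)) {
    if (is.numeric(results[[j]]) && !is.integer(results[[j]])) {
      results[[j]] <- signif(results[[j]], 6)
    }
  }
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a coherence results table
#'
#' @param path Path to a TSV written by [write_results_table()].
#' @return A data.frame with "NA" cells as `NA`.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
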