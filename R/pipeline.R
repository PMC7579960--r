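#' Load and normalize a run configuration
#'
#' Accepts either a path to a YAML file or a list, fills in documented
#' defaults, and validates ranges. The single `seed` drives every
#' stochastic stage through per-stage sub-streams (see [stage_seed()]), so
#' reruns with the same config and seed are byte-identical.
#'
#' Recognized fields (dots denote nesting):
#' \describe{
#'   \item{ppi.path, ppi.dialect}{Interaction file; dialect `"string"`
#'     (default) or `"biogrid"`.}
#'   \item{ppi.score_threshold}{STRING confidence filter, default 500.}
#'   \item{ppi.taxon_id}{BioGrid organism filter, default "9606".}
#'   \item{references}{Character vector of GMT paths; each file is one
#'     collection named after its base name.}
#'   \item{phenotypes.path, phenotypes.trait_column,
#'     phenotypes.gene_column, phenotypes.category_column}{Phenotype table.}
#'   \item{alias.path, alias.strict}{Optional alias map.}
#'   \item{min_nonzero}{Eligibility threshold, default 10.}
#'   \item{per_collection}{Reference sets per collection, default 10.}
#'   \item{n_random}{Random sets per panel, default 1000.}
#'   \item{n_perm}{Permutations, default 10000.}
#'   \item{tail}{Permutation tail, default "coherent".}
#'   \item{ci_level}{Default 0.95.}
#'   \item{seed}{Mandatory integer.}
#'   \item{output_dir}{Where result files are written.}
#'   \item{simulate}{Sub-list of [generate_world()] arguments for
#'     [run_simulate()].}
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "run_config")) return(config)
  stopifnot(is.list(config))
  cfg <- config
  cfg$ppi <- cfg$ppi %||% list()
  cfg$ppi$dialect <- cfg$ppi$dialect %||% "string"
  cfg$ppi$score_threshold <- cfg$ppi$score_threshold %||% 500
  cfg$ppi$taxon_id <- as.character(cfg$ppi$taxon_id %||% "9606")
  cfg$phenotypes <- cfg$phenotypes %||% list()
  cfg$phenotypes$trait_column <- cfg$phenotypes$trait_column %||% "DISEASE/TRAIT"
  cfg$phenotypes$gene_column <- cfg$phenotypes$gene_column %||% "MAPPED_GENE"
  cfg$min_nonzero <- cfg$min_nonzero %||% 10
  cfg$per_collection <- cfg$per_collection %||% 10
  cfg$n_random <- cfg$n_random %||% 1000
  cfg$n_perm <- cfg$n_perm %||% 10000
  cfg$tail <- cfg$tail %||% "coherent"
  cfg$ci_level <- cfg$ci_level %||% 0.95
  cfg$output_dir <- cfg$output_dir %||% "."
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$ppi$dialect %in% c("string", "biogrid"),
            cfg$ppi$score_threshold >= 0, cfg$ppi$score_threshold <= 1000,
            cfg$min_nonzero >= 1, cfg$n_random >= 1, cfg$n_perm >= 1,
            cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$tail %in% c("coherent", "larger"))
  class(cfg) <- "run_config"
  cfg
}

# Load the global network, reference collections, and phenotype sets
# named by a config.
load_inputs <- function(cfg) {
  edges <- switch(cfg$ppi$dialect,
    string = read_string_links(cfg$ppi$path,
                               score_threshold = cfg$ppi$score_threshold),
    biogrid = read_biogrid_tab(cfg$ppi$path, taxon_id = cfg$ppi$taxon_id)
  )
  network <- build_global_network(edges)
  collections <- list()
  for (p in cfg$references) {
    collections[[sub("\\.gmt$", "", basename(p))]] <- read_gmt(p)
  }
  phenos <- read_phenotype_table(
    cfg$phenotypes$path,
    gene_column = cfg$phenotypes$gene_column,
    trait_column = cfg$phenotypes$trait_column,
    category_column = cfg$phenotypes$category_column,
    exclude = cfg$phenotypes$exclude %||% character(),
    exclude_patterns = cfg$phenotypes$exclude_patterns %||% character())
  if (!is.null(cfg$alias$path)) {
    aliases <- read_alias_map(cfg$alias$path)
    phenos <- apply_alias_map(phenos, aliases,
                              strict = isTRUE(cfg$alias$strict))
    collections <- lapply(collections, apply_alias_map, aliases = aliases,
                          strict = isTRUE(cfg$alias$strict))
  }
  list(network = network, collections = collections, phenotypes = phenos)
}

#' Generate and write a synthetic world from a config
#'
#' Wraps [generate_world()] + [write_world()]. World parameters come from
#' the config's `simulate` sub-list; the world seed is derived from the
#' config seed.
#'
#' @param config Config list or YAML path (see [load_run_config()]).
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- load_run_config(config)
  sim <- cfg$simulate %||% list()
  sim$seed <- stage_seed(cfg$seed, "world")
  world <- do.call(generate_world, sim)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(cfg$seed, "world", offset = 1L))  # link scores
  write_world(world, cfg$output_dir)
}

#' Run the coherence pipeline over all phenotypes
#'
#' For every phenotype in the configured table: computes the degree table
#' against the global interactome, checks eligibility, fits the
#' through-origin slope, builds (or reuses) a reference panel matched to the
#' phenotype's effective network size, and reports the normalized coherence
#' with normalized CI and greedy modularity. Ineligible phenotypes appear
#' with their reason and NA values. Panels are cached per target size;
#' panel sampling is seeded per size so results are reproducible and
#' independent of phenotype order.
#'
#' @param config Config list or YAML path.
#' @return Invisibly, a list with `results` (data.frame, one row per
#'   phenotype), `summary` (mean coherence per category), and the written
#'   `paths`. `n_genes` in the results is the effective (in-network) set
#'   size.
#' @export
run_coherence <- function(config) {
  cfg <- load_run_config(config)
  inputs <- load_inputs(cfg)
  network <- inputs$network
  panel_base <- stage_seed(cfg$seed, "panel")
  panel_cache <- new.env(parent = emptyenv())
  get_panel <- function(target_size) {
    key <- as.character(target_size)
    if (!is.null(panel_cache[[key]])) return(panel_cache[[key]])
    set.seed((panel_base + target_size) %% 2147483647L)
    panel <- build_reference_panel(network, inputs$collections, target_size,
                                   n_random = cfg$n_random,
                                   per_collection = cfg$per_collection)
    panel_cache[[key]] <- panel
    panel
  }
  rows <- vector("list", length(inputs$phenotypes))
  for (i in seq_along(inputs$phenotypes)) {
    ph <- inputs$phenotypes[[i]]
    tab <- compute_degrees(network, ph)
    if (attr(tab, "n_dropped") > 0L) {
      message(ph$set_id, ": ", attr(tab, "n_dropped"),
              " gene(s) without interaction annotation dropped")
    }
    elig <- assess_eligibility(tab, min_nonzero = cfg$min_nonzero)
    row <- data.frame(
      set_id = ph$set_id, category = ph$category,
      n_genes = elig$n_in_network, n_nonzero = elig$n_nonzero,
      slope = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      coherence = NA_real_, coherence_ci_low = NA_real_,
      coherence_ci_high = NA_real_,
      perm_p = NA_real_, modularity = NA_real_,
      reason = elig$reason, stringsAsFactors = FALSE)
    if (elig$eligible) {
      fit <- fit_origin_slope(tab, ci_level = cfg$ci_level)
      panel <- get_panel(elig$n_in_network)
      nci <- normalize_ci(fit, panel)
      row$slope <- fit$beta
      row$ci_low <- fit$ci_low
      row$ci_high <- fit$ci_high
      row$coherence <- normalize_slope(fit$beta, panel)
      row$coherence_ci_low <- nci[["low"]]
      row$coherence_ci_high <- nci[["high"]]
      row$modularity <- tryCatch(greedy_modularity(network, ph)$q,
                                 error = function(e) NA_real_)
      message(sprintf("%s: size %d, beta = %.4g (panel %.4g..%.4g), coherence = %.4g",
                      ph$set_id, elig$n_in_network, fit$beta,
                      panel$beta_min, panel$beta_max, row$coherence))
    } else {
      message(ph$set_id, ": ineligible (", elig$reason, ")")
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows) %||%
    data.frame()
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  results_path <- file.path(cfg$output_dir, "results.tsv")
  write_results_table(results, results_path)
  summary <- summarize_by_category(results)
  summary_path <- file.path(cfg$output_dir, "summary.tsv")
  utils::write.table(
    transform(summary, mean_coherence = signif(mean_coherence, 6)),
    summary_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(list(results = results, summary = summary,
                 paths = c(results = results_path, summary = summary_path)))
}

#' Mean coherence per phenotype category
#'
#' Unweighted mean of normalized coherence over the phenotypes of each
#' category, with counts of estimated networks.
#'
#' @param results Results data.frame (see [run_coherence()]).
#' @return data.frame with `category`, `n_phenotypes`, `n_estimated`,
#'   `mean_coherence`.
#' @export
summarize_by_category <- function(results) {
  if (nrow(results) == 0L) {
    return(data.frame(category = character(0), n_phenotypes = integer(0),
                      n_estimated = integer(0), mean_coherence = numeric(0)))
  }
  cats <- unique(results$category)
  do.call(rbind, lapply(cats, function(cc) {
    sub <- results[results$category == cc, , drop = FALSE]
    est <- sub$coherence[!is.na(sub$coherence)]
    data.frame(category = cc, n_phenotypes = nrow(sub),
               n_estimated = length(est),
               mean_coherence = if (length(est)) mean(est) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Add permutation p-values to a results table
#'
#' For every eligible phenotype in an existing results table, runs the
#' permutation test ([permutation_test()]) at the configured `n_perm` and
#' `tail`, using the phenotype's effective size and non-zero gene count from
#' the table. Permutation draws are seeded per phenotype from the config
#' seed.
#'
#' @param config Config list or YAML path.
#' @param results_path Path to the results TSV written by [run_coherence()];
#'   defaults to `results.tsv` in the config's output directory.
#' @param out Output path for the augmented TSV (default: overwrite
#'   `results_path`).
#' @return Invisibly, the augmented results data.frame.
#' @export
run_permtest <- function(config, results_path = NULL, out = NULL) {
  cfg <- load_run_config(config)
  results_path <- results_path %||% file.path(cfg$output_dir, "results.tsv")
  results <- read_results_table(results_path)
  inputs <- load_inputs(cfg)
  known <- vapply(inputs$phenotypes, function(s) s$set_id, character(1))
  if (!all(results$set_id %in% known)) {
    stop("set_id mismatch: results table contains phenotypes absent from ",
         "the configured phenotype table: ",
         paste(setdiff(results$set_id, known), collapse = ", "))
  }
  perm_base <- stage_seed(cfg$seed, "permutation")
  for (i in seq_len(nrow(results))) {
    if (!identical(results$reason[i], "ok")) next
    set.seed((perm_base + i) %% 2147483647L)
    pt <- permutation_test(results$slope[i], inputs$network,
                           g = results$n_genes[i],
                           n_required = results$n_nonzero[i],
                           n_perm = cfg$n_perm, tail = cfg$tail)
    results$perm_p[i] <- pt$p_value
    message(sprintf("%s: perm_p = %.4g (%s tail, n = %d)", results$set_id[i],
                    pt$p_value, cfg$tail, cfg$n_perm))
  }
  write_results_table(results, out %||% results_path)
  invisible(results)
}

#' Print the category report for a results table
#'
#' @param results_path Path to a results TSV.
#' @param plot_path Optional path for a simple coherence dot plot (PDF).
#' @return Invisibly, the category summary data.frame.
#' @export
run_report <- function(results_path, plot_path = NULL) {
  results <- read_results_table(results_path)
  summary <- summarize_by_category(results)
  print(summary, row.names = FALSE)
  if (!is.null(plot_path)) {
    ok <- results[!is.na(results$coherence), , drop = FALSE]
    grDevices::pdf(plot_path, width = 6,
                   height = max(2, 0.3 * nrow(ok) + 1))
    graphics::dotchart(ok$coherence, labels = ok$set_id,
                       xlab = "normalized coherence")
    graphics::abline(v = c(0, 1), lty = 2, col = "grey50")
    grDevices::dev.off()
  }
  invisible(summary)
}
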