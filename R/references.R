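#' Draw a uniform random gene set
#'
#' Samples `size` genes uniformly without replacement from a pool (normally
#' the global network's node set). Random gene sets anchor the low end of
#' the coherence scale. Uses the current RNG state; call `set.seed()` (or go
#' through the pipeline seeding) for reproducibility.
#'
#' @param pool Character vector of gene symbols, or a `global_network`
#'   (whose nodes are used).
#' @param size Number of genes to draw; must not exceed the pool size.
#' @param set_id Identifier for the resulting set.
#' @return A [gene_set()] with category `"random"`.
#' @export
sample_random_geneset <- function(pool, size, set_id = NULL) {
  if (inherits(pool, "global_network")) pool <- pool$nodes
  if (size > length(pool)) {
    stop("requested size ", size, " exceeds pool of ", length(pool), " genes")
  }
  gene_set(set_id %||% paste0("random_", size),
           sample(pool, size), category = "random")
}

#' Select size-matched reference gene sets
#'
#' From each reference collection, picks the `per_collection` sets whose
#' effective size — the number of member genes present in the global
#' network — is nearest (absolute difference) to `target_size`. Ties are
#' broken by lexicographic `set_id`. Collections smaller than
#' `per_collection` contribute all their sets, with a warning.
#'
#' @param collections Named list; each element a list of [gene_set()]s
#'   (one element per collection).
#' @param network A `global_network` (defines effective sizes).
#' @param target_size Effective size of the query phenotype network.
#' @param per_collection Sets taken per collection (default 10; with 3
#'   collections this gives the 30-network high-coherence reference).
#' @return A list of gene sets (union over collections).
#' @export
select_size_matched_reference <- function(collections, network, target_size,
                                          per_collection = 10) {
  out <- list()
  for (cname in names(collections)) {
    sets <- collections[[cname]]
    if (length(sets) == 0L) stop("reference collection '", cname, "' is empty")
    eff <- vapply(sets, function(s) sum(s$genes %in% network$nodes), integer(1))
    ids <- vapply(sets, function(s) s$set_id, character(1))
    ord <- order(abs(eff - target_size), ids)
    if (length(sets) < per_collection) {
      warning("collection '", cname, "' has only ", length(sets),
              " sets (< ", per_collection, "); using all")
    }
    take <- ord[seq_len(min(per_collection, length(sets)))]
    best_dev <- abs(eff[take[1]] - target_size)
    if (best_dev > 0.25 * target_size) {
      message("collection '", cname, "': best size match deviates ",
              best_dev, " from target ", target_size)
    }
    out <- c(out, sets[take])
  }
  out
}

#' Build a size-matched reference panel
#'
#' Computes through-origin slopes for (a) size-matched sets from the
#' high-coherence reference collections and (b) `n_random` uniform random
#' gene sets of the target size drawn from the network. The medians of the
#' two slope lists give the normalization anchors: `beta_min` (median
#' reference slope, high coherence) and `beta_max` (median random slope,
#' chance-level coherence). Reference sets whose degree table admits no
#' slope (no internal edges) are dropped with a warning; random draws are
#' redrawn.
#'
#' @param network A `global_network`.
#' @param collections Named list of reference collections (lists of
#'   [gene_set()]s).
#' @param target_size Effective size of the query network.
#' @param n_random Number of random reference sets (default 1000).
#' @param per_collection Reference sets per collection (default 10).
#' @param max_attempts Cap on total random draws while collecting
#'   `n_random` usable slopes.
#' @return An object of class `reference_panel`: `target_size`,
#'   `high_slopes`, `random_slopes`, `beta_min`, `beta_max`.
#' @export
build_reference_panel <- function(network, collections, target_size,
                                  n_random = 1000, per_collection = 10,
                                  max_attempts = 50 * n_random) {
  refs <- select_size_matched_reference(collections, network, target_size,
                                        per_collection)
  high_slopes <- numeric(0)
  for (s in refs) {
    tab <- compute_degrees(network, s)
    if (nrow(tab) == 0L || all(tab$k_int == 0L)) {
      warning("reference set '", s$set_id, "' has no internal edges; dropped")
      next
    }
    high_slopes <- c(high_slopes, fit_origin_slope(tab)$beta)
  }
  if (length(high_slopes) < 3L) {
    stop("reference panel error: fewer than 3 usable reference slopes ",
         "at target size ", target_size)
  }
  size <- min(target_size, length(network$nodes))
  random_slopes <- numeric(0)
  attempts <- 0L
  while (length(random_slopes) < n_random) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("reference panel error: could not collect ", n_random,
           " random slopes in ", max_attempts, " draws (network too sparse)")
    }
    tab <- compute_degrees(network, sample(network$nodes, size))
    if (all(tab$k_int == 0L)) next
    random_slopes <- c(random_slopes, fit_origin_slope(tab)$beta)
  }
  structure(
    list(target_size = target_size,
         high_slopes = high_slopes,
         random_slopes = random_slopes,
         beta_min = stats::median(high_slopes),
         beta_max = stats::median(random_slopes)),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "<reference_panel> size %d: beta_min = %.4g (%d refs), beta_max = %.4g (%d random)\n",
    x$target_size, x$beta_min, length(x$high_slopes),
    x$beta_max, length(x$random_slopes)))
  invisible(x)
}

#' Min-max normalize a slope into a coherence value
#'
#' Maps a raw slope onto the coherence scale anchored by the panel:
#' `(beta - beta_max) / (beta_min - beta_max)`. A slope at the random
#' median maps to 0, a slope at the high-coherence median maps to 1.
#' Values are deliberately not clamped: coherence above 1 (more coherent
#' than the median reference pathway) is meaningful and does occur.
#'
#' @param beta Numeric vector of raw slopes.
#' @param panel A `reference_panel` with `beta_min != beta_max`.
#' @return Normalized coherence value(s).
#' @export
normalize_slope <- function(beta, panel) {
  bmin <- panel$beta_min
  bmax <- panel$beta_max
  if (!is.finite(bmin) || !is.finite(bmax) || bmin == bmax) {
    stop("degenerate reference panel: beta_min equals beta_max, ",
         "coherence is undefined")
  }
  (beta - bmax) / (bmin - bmax) + 0  # + 0 normalizes IEEE negative zero
}

#' Normalize a slope confidence interval
#'
#' Transforms both CI bounds of a fit with [normalize_slope()]. Because the
#' normalization map is decreasing, the transformed bounds swap order; the
#' returned pair is sorted so `low <= high`. Note that normalization alters
#' the usual CI interpretation — the permutation test is the instrument for
#' comparing coherences.
#'
#' @param fit A `slope_fit`.
#' @param panel A non-degenerate `reference_panel`.
#' @return Numeric vector `c(low, high)` on the coherence scale.
#' @export
normalize_ci <- function(fit, panel) {
  v <- sort(normalize_slope(c(fit$ci_low, fit$ci_high), panel))
  stats::setNames(v, c("low", "high"))
}
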