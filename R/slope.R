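#' Through-origin slope of external on internal degree
#'
#' The raw coherence statistic. With `x = sqrt(k_int)` and `y = sqrt(k_ext)`
#' over the genes of a phenotype degree table, fits the least-squares
#' regression of `y` on `x` forced through the origin:
#' `beta = sum(x * y) / sum(x^2)`. A perfectly coherent network (full
#' internal connectivity, no external edges) has slope 0 (a horizontal
#' line); random gene sets have large slopes. Both degrees are square-root
#' transformed, which keeps the slope-1 identity for networks whose internal
#' and external degrees coincide.
#'
#' Genes with `k_int = 0` contribute nothing to the slope algebraically but
#' are retained in the fit's point count, so they widen the residual-based
#' confidence interval.
#'
#' @param table Degree table from [compute_degrees()]; at least one gene
#'   must have positive internal degree.
#' @param ci_level Confidence level for the normal-theory through-origin
#'   interval (t quantile, `df = n - 1`). Default 0.95.
#' @return An object of class `slope_fit`: `beta`, `ci_low`, `ci_high`,
#'   `n_points`, `residual_df`.
#' @examples
#' tab <- data.frame(gene = c("a", "b"), k_int = c(1, 4), k_ext = c(4, 1))
#' fit_origin_slope(tab)$beta  # (1*2 + 2*1) / (1 + 4) = 0.8
#' @export
fit_origin_slope <- function(table, ci_level = 0.95) {
  if (nrow(table) == 0L || all(table$k_int == 0L)) {
    stop("undefined slope: no gene has positive internal degree ",
         "(degenerate table; should have been filtered by assess_eligibility)")
  }
  x <- sqrt(table$k_int)
  y <- sqrt(table$k_ext)
  sxx <- sum(x^2)
  beta <- sum(x * y) / sxx
  n <- length(x)
  df <- n - 1L
  rss <- sum((y - beta * x)^2)
  se <- if (df > 0L) sqrt(rss / df / sxx) else NA_real_
  half <- stats::qt(1 - (1 - ci_level) / 2, df) * se
  structure(
    list(beta = beta,
         ci_low = beta - half,
         ci_high = beta + half,
         n_points = n,
         residual_df = df),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> beta = %.4g [%.4g, %.4g], n = %d\n",
              x$beta, x$ci_low, x$ci_high, x$n_points))
  invisible(x)
}

#' Correlation between network size and raw slope
#'
#' Diagnostic for the size dependence of the raw slope statistic: raw
#' slopes of both pathway-like and random networks shrink as networks grow,
#' which is why slopes are not comparable across sizes and must be
#' normalized against size-matched references.
#'
#' @param sizes Numeric vector of network sizes (>= 3 values).
#' @param fits Matching list of `slope_fit` objects, or a numeric vector of
#'   slopes.
#' @return Pearson correlation between sizes and slopes.
#' @export
slope_size_diagnostic <- function(sizes, fits) {
  betas <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$beta, numeric(1))
  stopifnot(length(sizes) == length(betas))
  if (length(sizes) < 3L) stop("need at least 3 fits")
  if (stats::sd(sizes) == 0 || stats::sd(betas) == 0) {
    stop("undefined correlation: constant input vector")
  }
  stats::cor(sizes, betas)
}
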