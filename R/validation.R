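#' Matching cells between two gridded datasets
#'
#' Cells where both datasets hold a defined value at or above the
#' threshold (the published comparisons exclude cells below 50 mm). The
#' matching fraction is reported relative to the cells defined in `a`.
#'
#' @param a,b Numeric vectors or matrices on the same grid (NA = missing).
#' @param threshold Minimum value for inclusion.
#' @return `list(index, fraction)` — matched positions and the percentage
#'   of `a`'s defined cells they represent.
#' @export
matching_cells <- function(a, b, threshold = 0) {
  if (length(a) != length(b)) abort("grids do not match")
  defined_a <- !is.na(a)
  ok <- defined_a & !is.na(b) & a >= threshold & b >= threshold
  frac <- if (!any(defined_a)) NA_real_ else 100 * sum(ok) / sum(defined_a)
  list(index = which(ok), fraction = frac)
}

#' (Weighted) Pearson correlation
#'
#' Standard product-moment correlation; with weights, the weighted
#' covariance over the product of weighted standard deviations. Undefined
#' (NA) when either variance is zero.
#'
#' @param x,y Numeric vectors (>= 2 pairs).
#' @param weights Optional non-negative weights.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
wf_pearson <- function(x, y, weights = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(weights)) keep <- keep & !is.na(weights) & weights > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) abort("at least two pairs required")
  if (is.null(weights)) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    return(stats::cor(x, y))
  }
  w <- weights[keep] / sum(weights[keep])
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  cxy / sqrt(vx * vy)
}

#' Median of grid-level relative differences
#'
#' The median over matched cells of `100 (ours - theirs) / theirs` (%),
#' relative to the reference dataset. Cells where the reference is zero
#' are excluded.
#'
#' @param ours,theirs Matched cell values.
#' @return Median relative difference, %.
#' @export
median_relative_difference <- function(ours, theirs) {
  keep <- !is.na(ours) & !is.na(theirs) & theirs != 0
  if (!any(keep)) return(NA_real_)
  median(100 * (ours[keep] - theirs[keep]) / theirs[keep])
}

#' Compare two gridded datasets
#'
#' The technical-validation statistics for comparing a simulated grid
#' against a reference: matching-cell fraction (with a minimum-value
#' exclusion threshold), Pearson correlation (optionally weighted, e.g.
#' by harvested area), and the median of grid-level relative differences.
#' An optional symmetric percentile clip filters extreme values before
#' correlation.
#'
#' @param ours,theirs Numeric vectors/matrices on the same grid.
#' @param threshold Minimum value for the matching-cell filter (50 mm in
#'   the published CWU comparisons).
#' @param weights Optional weights for the correlation.
#' @param clip Optional two-sided percentile clip (e.g. `c(0.01, 0.99)`);
#'   `NULL` disables it.
#' @return A one-row tibble: `matching_fraction`, `pearson_r`,
#'   `weighted_pearson_r`, `median_relative_difference`, `n_matched`.
#' @export
compare_grids <- function(ours, theirs, threshold = 0, weights = NULL,
                          clip = NULL) {
  m <- matching_cells(ours, theirs, threshold)
  x <- as.numeric(ours)[m$index]; y <- as.numeric(theirs)[m$index]
  w <- if (is.null(weights)) NULL else as.numeric(weights)[m$index]
  if (!is.null(clip) && length(x) > 2) {
    qx <- stats::quantile(x, clip); qy <- stats::quantile(y, clip)
    keep <- x >= qx[1] & x <= qx[2] & y >= qy[1] & y <= qy[2]
    x <- x[keep]; y <- y[keep]
    if (!is.null(w)) w <- w[keep]
  }
  tibble(
    matching_fraction = m$fraction,
    pearson_r = if (length(x) >= 2) wf_pearson(x, y) else NA_real_,
    weighted_pearson_r = if (!is.null(w) && length(x) >= 2)
      wf_pearson(x, y, w) else NA_real_,
    median_relative_difference = median_relative_difference(x, y),
    n_matched = length(m$index)
  )
}
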