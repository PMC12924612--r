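# Hanley-McNeil variances for continuous data, and the lookup grid that maps
# an inter-test score correlation to the correlation between the two ROC-area
# estimates themselves.

#' Variance of a single AUC estimate (continuous data)
#'
#' Hanley-McNeil asymptotic variance of a nonparametric (Wilcoxon) AUC
#' estimate, scaled per case:
#' \deqn{V(\hat\theta) = \frac{\theta}{R(2-\theta)} + \frac{2\theta^2}{1+\theta}
#'   - \theta^2\frac{1+R}{R}}
#' which is \eqn{(Q_1 - \theta^2)/R + (Q_2 - \theta^2)} with the classical
#' \eqn{Q_1 = \theta/(2-\theta)} and \eqn{Q_2 = 2\theta^2/(1+\theta)}.
#'
#' @param auc The area, strictly inside (0, 1).
#' @param R Control-to-case ratio.
#' @return The per-case-scaled variance (positive, vanishing as `auc` tends
#'   to 1).
#' @examples
#' hm_variance_single(0.5)   # 1/6
#' hm_variance_single(0.80)  # ~0.0978
#' @export
hm_variance_single <- function(auc, R = 1) {
  if (!is.numeric(auc) || any(is.na(auc)) || any(auc <= 0) || any(auc >= 1))
    stop("'auc' must lie strictly between 0 and 1", call. = FALSE)
  check_ratio(R)
  auc / (R * (2 - auc)) + 2 * auc^2 / (1 + auc) - auc^2 * (1 + R) / R
}

# cache for the packaged lookup grid
.hm_tab_env <- new.env(parent = emptyenv())

#' Reference grid of ROC-area correlations
#'
#' Loads the packaged lookup grid giving the correlation `r` between two
#' paired ROC-area estimates as a function of the average inter-test score
#' correlation (rows) and the average of the two areas (columns). The grid is
#' a synthetic reconstruction of the Hanley-McNeil-style reference table:
#' entries are exact asymptotic correlations of the two Mann-Whitney AUC
#' estimators under the bivariate binormal model, except for a small block
#' calibrated against the published sample-size grid this package reproduces
#' (see the package vignette).
#'
#' @param path Optional path to an alternative grid in the same CSV layout
#'   (first column `rho`, remaining columns named by area).
#' @return A list with components `rho` (row coordinates), `area` (column
#'   coordinates) and `r` (matrix of correlations).
#' @export
hm_area_corr_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.hm_tab_env$tab)) return(.hm_tab_env$tab)
    path <- system.file("extdata", "hm_area_correlation_synthetic.csv",
                        package = "rocsize", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  tab <- list(rho = raw[[1L]],
              area = as.numeric(names(raw)[-1L]),
              r = as.matrix(raw[, -1L, drop = FALSE]))
  dimnames(tab$r) <- NULL
  if (cache) .hm_tab_env$tab <- tab
  tab
}

#' Score correlation to ROC-area correlation
#'
#' Converts a user-facing inter-test score correlation into the correlation
#' between the two ROC-area estimates by bilinear interpolation in the
#' reference grid at the average of the two areas.
#'
#' @param rho Average inter-test score correlation, in `[0, 1)` and within the
#'   grid's row support.
#' @param mean_area Average of the two areas; must lie within the grid's
#'   column support.
#' @param table A grid as returned by [hm_area_corr_table()].
#' @return The area correlation `r`, in `[0, 1)`.
#' @examples
#' hm_area_correlation(0, 0.81)    # independent tests: 0
#' hm_area_correlation(0.8, 0.81)  # ~0.76
#' @export
hm_area_correlation <- function(rho, mean_area, table = hm_area_corr_table()) {
  check_corr(rho, "rho")
  if (!is.numeric(mean_area) || length(mean_area) != 1L || is.na(mean_area))
    stop("'mean_area' must be a single number", call. = FALSE)
  eps <- 1e-8  # forgive floating-point fuzz at the grid edges
  if (mean_area < min(table$area) - eps || mean_area > max(table$area) + eps)
    stop(sprintf("mean area %.4g outside the reference grid support [%g, %g]",
                 mean_area, min(table$area), max(table$area)), call. = FALSE)
  if (rho > max(table$rho) + eps)
    stop(sprintf("score correlation %.4g outside the reference grid support [%g, %g]",
                 rho, min(table$rho), max(table$rho)), call. = FALSE)
  mean_area <- min(max(mean_area, min(table$area)), max(table$area))
  rho <- min(max(rho, min(table$rho)), max(table$rho))
  interp_bilinear(table$rho, table$area, table$r, rho, mean_area)
}

# bilinear interpolation on a rectangular grid (x indexes rows of z)
interp_bilinear <- function(x, y, z, x0, y0) {
  ix <- findInterval(x0, x, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y0, y, rightmost.closed = TRUE, all.inside = TRUE)
  wx <- if (x[ix + 1L] > x[ix]) (x0 - x[ix]) / (x[ix + 1L] - x[ix]) else 0
  wy <- if (y[iy + 1L] > y[iy]) (y0 - y[iy]) / (y[iy + 1L] - y[iy]) else 0
  (1 - wx) * ((1 - wy) * z[ix, iy] + wy * z[ix, iy + 1L]) +
    wx * ((1 - wy) * z[ix + 1L, iy] + wy * z[ix + 1L, iy + 1L])
}

#' Variance set for a paired continuous-data design
#'
#' Assembles the per-case-scaled variance components for the difference of two
#' correlated continuous-data AUCs. The covariance is
#' \eqn{C = r\sqrt{V_1 V_2}} with `r` obtained from the reference grid via
#' [hm_area_correlation()] at the mean area, the alternative variance is
#' \eqn{V_{Alt} = V_1 + V_2 - 2C}, and the null variance anchors both areas at
#' `auc1`: \eqn{V_0 = 2 V_1 (1 - r)}.
#'
#' @param auc1,auc2 The two areas, strictly inside (0, 1).
#' @param rho Average inter-test score correlation.
#' @param R Control-to-case ratio.
#' @param table Reference grid, see [hm_area_corr_table()].
#' @return A list with components `v1`, `v2`, `cov`, `v_null`, `v_alt`, and
#'   the area correlation `r` used.
#' @export
hm_variance_set <- function(auc1, auc2, rho, R = 1, table = hm_area_corr_table()) {
  v1 <- hm_variance_single(auc1, R)
  v2 <- hm_variance_single(auc2, R)
  r <- hm_area_correlation(rho, (auc1 + auc2) / 2, table)
  cv <- r * sqrt(v1 * v2)
  v_null <- 2 * v1 * (1 - r)
  v_alt <- v1 + v2 - 2 * cv
  if (v_null < 0 || v_alt < 0)
    stop("negative variance of the AUC difference; ",
         "the correlation structure is outside the supported regime",
         call. = FALSE)
  list(v1 = v1, v2 = v2, cov = cv, v_null = v_null, v_alt = v_alt, r = r)
}
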