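# Obuchowski-McClish variances and covariance of correlated AUC estimates
# for discrete (rating) data under the binormal model. All quantities are
# scaled per case: Var(theta-hat) ~ om_variance_single(...) / n_pos.

#' Variance of a single binormal AUC estimate (rating data)
#'
#' Delta-method variance of a rating-data AUC estimate under the binormal
#' model, scaled per case:
#' \deqn{V(\hat\theta) = f^2\left(1 + \frac{B^2}{R} + \frac{A^2}{2}\right)
#'   + g^2\, B^2 \frac{1+R}{2R}}
#' with constants `f`, `g` from [roc_constants()] and `R` the control-to-case
#' allocation ratio. Divide by the number of cases to obtain the variance of
#' the estimate itself.
#'
#' @param curve A [binormal_curve()].
#' @param R Control-to-case ratio (number of controls / number of cases).
#' @return The per-case-scaled variance (a positive number).
#' @examples
#' om_variance_single(binormal_from_auc(0.80), R = 1)  # ~0.1200
#' @export
om_variance_single <- function(curve, R = 1) {
  stopifnot(inherits(curve, "binormal_curve"))
  check_ratio(R)
  k <- roc_constants(curve)
  k$f^2 * (1 + curve$B^2 / R + curve$A^2 / 2) +
    k$g^2 * (curve$B^2 * (1 + R) / (2 * R))
}

#' Covariance of two correlated binormal AUC estimates (rating data)
#'
#' Per-case-scaled covariance between the AUC estimates of two tests applied
#' to the same subjects, with within-group score correlations `r_pos` (cases)
#' and `r_neg` (controls):
#' \deqn{C = f_1 f_2\left(r_+ + r_-\frac{B_1 B_2}{R} + r_+^2\frac{A_1 A_2}{2}\right)
#'   + \frac{g_1 g_2 B_1 B_2 (r_-^2 + R r_+^2)}{2R}
#'   + \frac{f_1 g_2 A_1 B_2 r_+^2}{2} + \frac{f_2 g_1 A_2 B_1 r_+^2}{2}.}
#' It vanishes when both correlations are zero and is symmetric in the two
#' curves.
#'
#' @param curve1,curve2 [binormal_curve()] objects for the two tests.
#' @param r_pos,r_neg Inter-test score correlations among cases and controls,
#'   each in `[0, 1)`.
#' @param R Control-to-case ratio.
#' @return The per-case-scaled covariance.
#' @export
om_covariance <- function(curve1, curve2, r_pos, r_neg = r_pos, R = 1) {
  stopifnot(inherits(curve1, "binormal_curve"), inherits(curve2, "binormal_curve"))
  check_corr(r_pos, "r_pos"); check_corr(r_neg, "r_neg"); check_ratio(R)
  k1 <- roc_constants(curve1); k2 <- roc_constants(curve2)
  A1 <- curve1$A; B1 <- curve1$B; A2 <- curve2$A; B2 <- curve2$B
  k1$f * k2$f * (r_pos + r_neg * B1 * B2 / R + r_pos^2 * A1 * A2 / 2) +
    k1$g * k2$g * B1 * B2 * (r_neg^2 + R * r_pos^2) / (2 * R) +
    k1$f * k2$g * A1 * B2 * r_pos^2 / 2 +
    k2$f * k1$g * A2 * B1 * r_pos^2 / 2
}

#' Variance set for a paired rating-data design
#'
#' Assembles the per-case-scaled variance components for the difference of two
#' correlated rating-data AUCs: the two single-curve variances, their
#' covariance, the alternative-hypothesis variance
#' \eqn{V_{Alt} = V_1 + V_2 - 2C_{12}}, and the null-hypothesis variance with
#' *both* tests at the first curve's parameters,
#' \eqn{V_0 = 2V_1 - 2C_{11}} (the null anchors at the baseline test).
#'
#' @param curve1,curve2 [binormal_curve()] objects for the two tests.
#' @param r_pos,r_neg Within-group inter-test score correlations.
#' @param R Control-to-case ratio.
#' @return A list with components `v1`, `v2`, `cov`, `v_null`, `v_alt`.
#' @export
om_variance_set <- function(curve1, curve2, r_pos, r_neg = r_pos, R = 1) {
  v1 <- om_variance_single(curve1, R)
  v2 <- om_variance_single(curve2, R)
  cv <- om_covariance(curve1, curve2, r_pos, r_neg, R)
  v_null <- 2 * v1 - 2 * om_covariance(curve1, curve1, r_pos, r_neg, R)
  v_alt <- v1 + v2 - 2 * cv
  if (v_null < 0 || v_alt < 0)
    stop("negative variance of the AUC difference; ",
         "the correlation structure is outside the supported regime",
         call. = FALSE)
  list(v1 = v1, v2 = v2, cov = cv, v_null = v_null, v_alt = v_alt)
}

# shared argument checks
check_ratio <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' (control-to-case ratio) must be a single positive number",
         call. = FALSE)
  invisible(R)
}

check_corr <- function(r, name) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r >= 1)
    stop(sprintf("'%s' must lie in [0, 1)", name), call. = FALSE)
  invisible(r)
}
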