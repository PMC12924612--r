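# Binormal ROC model: location/scale parameterization, (partial) AUC,
# and the intermediate constants feeding the rating-data variance formulas.

#' Binormal ROC curve
#'
#' Constructs a binormal ROC curve from its location parameter `A` (separation
#' between case and control score distributions in case-SD units) and scale
#' ratio `B` (control SD divided by case SD), optionally restricted to a
#' false-positive-rate window.
#'
#' Under the binormal model the ROC curve is
#' \eqn{TPR(t) = \Phi(A + B\,\Phi^{-1}(t))} for false-positive rate `t`, so the
#' full area under the curve is \eqn{\Phi(A/\sqrt{1+B^2})}.
#'
#' @param A Location parameter; any finite number.
#' @param B Scale ratio (control SD / case SD); finite and positive.
#' @param fpr_lo,fpr_hi Lower and upper false-positive-rate integration limits,
#'   with `0 <= fpr_lo < fpr_hi <= 1`. Defaults cover the full range.
#' @return An object of class `"binormal_curve"`.
#' @examples
#' binormal_curve(A = 1.19, B = 1)
#' @export
binormal_curve <- function(A, B = 1, fpr_lo = 0, fpr_hi = 1) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A))
    stop("'A' must be a single finite number", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B <= 0)
    stop("'B' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(fpr_lo) || !is.numeric(fpr_hi) ||
      length(fpr_lo) != 1L || length(fpr_hi) != 1L ||
      is.na(fpr_lo) || is.na(fpr_hi) ||
      fpr_lo < 0 || fpr_hi > 1 || fpr_lo >= fpr_hi)
    stop("FPR limits must satisfy 0 <= fpr_lo < fpr_hi <= 1", call. = FALSE)
  structure(list(A = A, B = B, fpr_lo = fpr_lo, fpr_hi = fpr_hi),
            class = "binormal_curve")
}

#' @export
print.binormal_curve <- function(x, ...) {
  cat(sprintf("Binormal ROC curve: A = %.6g, B = %.6g", x$A, x$B))
  if (x$fpr_lo > 0 || x$fpr_hi < 1)
    cat(sprintf(", FPR range (%.3g, %.3g)", x$fpr_lo, x$fpr_hi))
  cat(sprintf("\n  AUC over range: %.6f\n", auc_binormal(x)))
  invisible(x)
}

#' Area under a binormal ROC curve
#'
#' Computes the (partial) area under the curve,
#' \eqn{\theta = \int_{c_1}^{c_2} \Phi(A + Bv)\,\phi(v)\,dv} with
#' \eqn{c_j = \Phi^{-1}(FPR_j)}. Over the full false-positive-rate range the
#' closed form \eqn{\Phi(A/\sqrt{1+B^2})} is used; partial ranges are handled
#' by adaptive quadrature with absolute tolerance `1e-12`.
#'
#' @param curve A [binormal_curve()].
#' @return The area, a probability.
#' @examples
#' auc_binormal(binormal_curve(0, 1))             # chance line: 0.5
#' auc_binormal(binormal_curve(sqrt(2) * qnorm(0.8), 1))  # 0.8
#' @export
auc_binormal <- function(curve) {
  stopifnot(inherits(curve, "binormal_curve"))
  if (curve$fpr_lo == 0 && curve$fpr_hi == 1)
    return(stats::pnorm(curve$A / sqrt(1 + curve$B^2)))
  lo <- stats::qnorm(curve$fpr_lo)
  hi <- stats::qnorm(curve$fpr_hi)
  stats::integrate(function(v) stats::pnorm(curve$A + curve$B * v) * stats::dnorm(v),
                   lower = lo, upper = hi,
                   rel.tol = 1e-12, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Binormal curve with a prescribed full-range AUC
#'
#' Inverts the full-range closed form: `A = sqrt(1 + B^2) * qnorm(auc)`.
#' The returned curve carries the requested FPR limits, but the location
#' parameter always corresponds to the *full-range* area, which is how designs
#' are specified (a nominal AUC plus an FPR window of interest).
#'
#' @param auc Target full-range area, in (0, 1).
#' @param B Scale ratio, positive.
#' @param fpr_lo,fpr_hi Optional FPR limits carried by the curve.
#' @return A [binormal_curve()].
#' @examples
#' binormal_from_auc(0.80)  # A = 1.190232
#' @export
binormal_from_auc <- function(auc, B = 1, fpr_lo = 0, fpr_hi = 1) {
  if (!is.numeric(auc) || length(auc) != 1L || is.na(auc) || auc <= 0 || auc >= 1)
    stop("'auc' must lie strictly between 0 and 1", call. = FALSE)
  binormal_curve(A = sqrt(1 + B^2) * stats::qnorm(auc), B = B,
                 fpr_lo = fpr_lo, fpr_hi = fpr_hi)
}

#' Location parameter from an operating point
#'
#' Recovers the binormal location parameter from one (TNR, FPR) operating
#' point: `A = B * qnorm(tnr) - qnorm(fpr)`.
#'
#' @param tnr True-negative rate (specificity), strictly inside (0, 1).
#' @param fpr False-positive rate, strictly inside (0, 1).
#' @param B Scale ratio.
#' @return The location parameter `A`.
#' @examples
#' a_from_rates(0.8, 0.2)  # 2 * qnorm(0.8)
#' @export
a_from_rates <- function(tnr, fpr, B = 1) {
  if (!is.numeric(tnr) || !is.numeric(fpr) ||
      any(is.na(tnr)) || any(is.na(fpr)) ||
      any(tnr <= 0) || any(tnr >= 1) || any(fpr <= 0) || any(fpr >= 1))
    stop("'tnr' and 'fpr' must lie strictly between 0 and 1", call. = FALSE)
  B * stats::qnorm(tnr) - stats::qnorm(fpr)
}

#' Intermediate constants for the rating-data variance formulas
#'
#' Evaluates the constants used by the Obuchowski-McClish variance of a
#' binormal AUC estimate:
#' \deqn{E_1 = \exp(-A^2 / (2 + 2B^2)), \quad E_2 = 1 + B^2,}
#' \deqn{E_3 = \Phi(c_2) - \Phi(c_1), \quad E_4 = e^{-c_1^2/2} - e^{-c_2^2/2},}
#' \deqn{f = E_1 E_3 / \sqrt{2\pi E_2}, \quad
#'       g = E_1 E_4 / \sqrt{2\pi E_2} - A B E_1 E_3 / \sqrt{2\pi E_2^3},}
#' where the z-scale thresholds embed the location/scale adjustment
#' \eqn{c_j = (\Phi^{-1}(FPR_j) + AB/(1+B^2)) / \sqrt{1+B^2}}. Over the full
#' FPR range `E3 = 1` and `E4 = 0` exactly, so only `A` and `B` matter.
#'
#' @param curve A [binormal_curve()].
#' @return A list with components `f`, `g`, `E1`, `E2`, `E3`, `E4`, `c1`, `c2`.
#' @export
roc_constants <- function(curve) {
  stopifnot(inherits(curve, "binormal_curve"))
  A <- curve$A; B <- curve$B
  E1 <- exp(-A^2 / (2 + 2 * B^2))
  E2 <- 1 + B^2
  if (curve$fpr_lo == 0 && curve$fpr_hi == 1) {
    c1 <- -Inf; c2 <- Inf
    E3 <- 1; E4 <- 0
  } else {
    shift <- A * B / (1 + B^2)
    scale <- sqrt(1 + B^2)
    c1 <- (stats::qnorm(curve$fpr_lo) + shift) / scale
    c2 <- (stats::qnorm(curve$fpr_hi) + shift) / scale
    E3 <- stats::pnorm(c2) - stats::pnorm(c1)
    E4 <- exp(-c1^2 / 2) - exp(-c2^2 / 2)
  }
  f <- E1 * E3 / sqrt(2 * pi * E2)
  g <- E1 * E4 / sqrt(2 * pi * E2) - A * B * E1 * E3 / sqrt(2 * pi * E2^3)
  list(f = f, g = g, E1 = E1, E2 = E2, E3 = E3, E4 = E4, c1 = c1, c2 = c2)
}
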