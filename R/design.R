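# Design specification object: one power/sample-size question for comparing
# two correlated ROC AUCs, plus its S3 methods.

#' Specify a paired ROC-AUC comparison design
#'
#' Builds the full parameterization of one power/sample-size question: two
#' tests applied to the same cases and controls, compared on their areas under
#' the ROC curve with a (one- or two-sided) Z test.
#'
#' For `data_type = "discrete"` (ordinal rating scores) the variance of the
#' AUC difference uses the Obuchowski-McClish formulas under the binormal
#' model; for `data_type = "continuous"` it uses the Hanley-McNeil formulas,
#' with the score correlation translated to an ROC-area correlation through
#' the packaged reference grid. Continuous-data calculations are defined for
#' the full false-positive-rate range only.
#'
#' @param auc1 Baseline (null-anchor) area, strictly inside (0, 1).
#' @param auc2 Alternative area, strictly inside (0, 1).
#' @param data_type `"discrete"` (rating data) or `"continuous"`.
#' @param rho Inter-test score correlation applied to both groups; the
#'   convenience default for `rho_pos`/`rho_neg`.
#' @param rho_pos,rho_neg Within-case and within-control inter-test score
#'   correlations, each in `[0, 1)`. The continuous engine uses their average.
#' @param B1,B2 Binormal scale ratios (control SD / case SD) of the two tests.
#' @param R Control-to-case allocation ratio (controls per case).
#' @param alpha Type-I error rate, in (0, 1).
#' @param sides 1 or 2 (sidedness of the Z test).
#' @param target_power Default power used by [required_n()], in (alpha, 1).
#' @param fpr_lo,fpr_hi False-positive-rate limits (discrete engine only;
#'   the full range is required for continuous data).
#' @param dropout_rate Anticipated attrition fraction, in `[0, 1)`; used for
#'   the dropout-inflated enrollment figures.
#' @return An object of class `"roc_design"`.
#' @examples
#' d <- roc_design(0.80, 0.82, data_type = "discrete", rho = 0.3)
#' required_n(d)
#' @seealso [required_n()], [power_at_n()], [estimate_actual_power()]
#' @export
roc_design <- function(auc1, auc2,
                       data_type = c("discrete", "continuous"),
                       rho = 0.3, rho_pos = rho, rho_neg = rho,
                       B1 = 1, B2 = 1, R = 1,
                       alpha = 0.05, sides = 2,
                       target_power = 0.80,
                       fpr_lo = 0, fpr_hi = 1,
                       dropout_rate = 0.2) {
  data_type <- match.arg(data_type)
  for (a in list(auc1, auc2))
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a >= 1)
      stop("AUC values must lie strictly between 0 and 1", call. = FALSE)
  check_corr(rho_pos, "rho_pos"); check_corr(rho_neg, "rho_neg")
  check_ratio(R)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  if (!sides %in% c(1, 2)) stop("'sides' must be 1 or 2", call. = FALSE)
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      is.na(target_power) || target_power <= alpha || target_power >= 1)
    stop("'target_power' must lie strictly between alpha and 1", call. = FALSE)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must lie in [0, 1)", call. = FALSE)
  if (data_type == "continuous" && (fpr_lo != 0 || fpr_hi != 1))
    stop("continuous-data calculations are defined for the full FPR range only",
         call. = FALSE)
  design <- structure(
    list(data_type = data_type, auc1 = auc1, auc2 = auc2,
         rho_pos = rho_pos, rho_neg = rho_neg,
         B1 = B1, B2 = B2, R = R,
         alpha = alpha, sides = sides, target_power = target_power,
         fpr_lo = fpr_lo, fpr_hi = fpr_hi,
         dropout_rate = dropout_rate),
    class = "roc_design")
  # validate the FPR window through the curve constructor
  if (data_type == "discrete") invisible(design_curves(design))
  design
}

# the two binormal curves implied by a discrete design
design_curves <- function(design) {
  list(binormal_from_auc(design$auc1, design$B1, design$fpr_lo, design$fpr_hi),
       binormal_from_auc(design$auc2, design$B2, design$fpr_lo, design$fpr_hi))
}

#' Variance components of a design
#'
#' Per-case-scaled variance components of the AUC difference for a design:
#' single-curve variances, covariance, and the null/alternative variances of
#' the difference, computed by the engine matching the design's data type.
#'
#' @param design An [roc_design()].
#' @return A list with components `v1`, `v2`, `cov`, `v_null`, `v_alt` (and
#'   `r`, the area correlation, for continuous designs).
#' @export
variance_set <- function(design) {
  stopifnot(inherits(design, "roc_design"))
  if (design$data_type == "discrete") {
    cv <- design_curves(design)
    om_variance_set(cv[[1L]], cv[[2L]], design$rho_pos, design$rho_neg, design$R)
  } else {
    hm_variance_set(design$auc1, design$auc2,
                    (design$rho_pos + design$rho_neg) / 2, design$R)
  }
}

#' @export
print.roc_design <- function(x, ...) {
  cat("Paired ROC-AUC comparison design\n")
  cat(sprintf("  data type    : %s\n", x$data_type))
  cat(sprintf("  AUC1 vs AUC2 : %.3f vs %.3f  (delta = %+.3f)\n",
              x$auc1, x$auc2, x$auc2 - x$auc1))
  cat(sprintf("  correlations : rho+ = %.2f, rho- = %.2f\n", x$rho_pos, x$rho_neg))
  cat(sprintf("  allocation   : R = %.3g controls per case\n", x$R))
  if (x$data_type == "discrete")
    cat(sprintf("  scale ratios : B1 = %.3g, B2 = %.3g; FPR range (%.2g, %.2g)\n",
                x$B1, x$B2, x$fpr_lo, x$fpr_hi))
  cat(sprintf("  test         : %d-sided Z, alpha = %.3g; target power %.3g\n",
              x$sides, x$alpha, x$target_power))
  cat(sprintf("  dropout rate : %.0f%%\n", 100 * x$dropout_rate))
  invisible(x)
}

#' @export
summary.roc_design <- function(object, ...) {
  vs <- variance_set(object)
  out <- list(design = object, variances = vs,
              n = tryCatch(required_n(object), error = function(e) NULL))
  class(out) <- "summary.roc_design"
  out
}

#' @export
print.summary.roc_design <- function(x, ...) {
  print(x$design)
  vs <- x$variances
  cat("\nPer-case-scaled variance components of the AUC difference:\n")
  cat(sprintf("  V(theta1) = %.6f   V(theta2) = %.6f   C = %.6f\n",
              vs$v1, vs$v2, vs$cov))
  cat(sprintf("  V0 = %.6f   VAlt = %.6f", vs$v_null, vs$v_alt))
  if (!is.null(vs$r)) cat(sprintf("   (area correlation r = %.4f)", vs$r))
  cat("\n")
  if (!is.null(x$n)) { cat("\n"); print(x$n) }
  invisible(x)
}

#' @export
coef.roc_design <- function(object, ...) {
  c(A1 = sqrt(1 + object$B1^2) * stats::qnorm(object$auc1),
    A2 = sqrt(1 + object$B2^2) * stats::qnorm(object$auc2),
    B1 = object$B1, B2 = object$B2,
    auc1 = object$auc1, auc2 = object$auc2,
    rho_pos = object$rho_pos, rho_neg = object$rho_neg, R = object$R)
}

#' Predicted power at given group sizes
#'
#' `predict()` on a design returns the analytic power at the supplied number
#' of cases per group (a convenience wrapper around [power_at_n()]).
#'
#' @param object An [roc_design()].
#' @param n_pos Number(s) of cases; vectorized.
#' @param ... Unused.
#' @return A numeric vector of powers.
#' @export
predict.roc_design <- function(object, n_pos, ...) {
  vapply(n_pos, function(n) power_at_n(object, n), numeric(1L))
}
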