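# Sample-size solve, analytic power, and attrition arithmetic.

z_crit <- function(design) {
  if (design$sides == 2) stats::qnorm(1 - design$alpha / 2)
  else stats::qnorm(1 - design$alpha)
}

#' Required sample size for a paired AUC comparison
#'
#' Solves the closed-form sample-size formula for the number of cases needed
#' to detect the design's AUC difference with a Z test:
#' \deqn{N_+ = \left\lceil \frac{(z_{1-\alpha/2}\sqrt{V_0} +
#'   z_{power}\sqrt{V_{Alt}})^2}{\Delta^2} \right\rceil}
#' with the per-case-scaled null and alternative variances from
#' [variance_set()] (one-sided tests use \eqn{z_{1-\alpha}}). Controls follow
#' as \eqn{N_- = \lceil R N_+ \rceil}, and the dropout-inflated enrollment
#' figures are attached via [attrition_adjust()].
#'
#' @param design An [roc_design()]; `auc1` and `auc2` must differ.
#' @param power Target power; defaults to the design's `target_power`.
#' @return An object of class `"roc_samplesize"`: a list with group sizes
#'   (`n_pos`, `n_neg`, `n_total`), the target power `tp`, the analytic power
#'   achieved at the integer sizes (`achieved_power`), expected dropouts
#'   (`ed_pos`, `ed_neg`, `ed_total`) and dropout-inflated enrollment
#'   (`diss_pos`, `diss_neg`, `diss_total`).
#' @examples
#' required_n(roc_design(0.80, 0.82, "discrete", rho = 0.3))  # 3709 cases
#' @export
required_n <- function(design, power = design$target_power) {
  stopifnot(inherits(design, "roc_design"))
  if (design$auc1 == design$auc2)
    stop("infeasible design: auc1 equals auc2 (required n is infinite)",
         call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || is.na(power) ||
      power <= design$alpha || power >= 1)
    stop("'power' must lie strictly between alpha and 1", call. = FALSE)
  vs <- variance_set(design)
  delta <- design$auc2 - design$auc1
  n_pos <- ceiling((z_crit(design) * sqrt(vs$v_null) +
                      stats::qnorm(power) * sqrt(vs$v_alt))^2 / delta^2)
  n_pos <- max(n_pos, 2L)
  n_neg <- ceiling(design$R * n_pos)
  att_p <- attrition_adjust(n_pos, design$dropout_rate)
  att_n <- attrition_adjust(n_neg, design$dropout_rate)
  out <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_total = as.integer(n_pos + n_neg),
              tp = power,
              achieved_power = power_at_n(design, n_pos),
              ed_pos = att_p$ed, ed_neg = att_n$ed,
              ed_total = att_p$ed + att_n$ed,
              diss_pos = att_p$diss, diss_neg = att_n$diss,
              diss_total = att_p$diss + att_n$diss,
              design = design)
  class(out) <- "roc_samplesize"
  out
}

#' Analytic power at a given number of cases
#'
#' Inverts the sample-size formula: with `n_pos` cases (and `R * n_pos`
#' controls), the power of the Z test is
#' \deqn{\Phi\!\left(\frac{|\Delta|\sqrt{N_+} - z_{1-\alpha/2}\sqrt{V_0}}
#'   {\sqrt{V_{Alt}}}\right).}
#'
#' @param design An [roc_design()].
#' @param n_pos Number of cases, at least 2.
#' @return The power, a probability.
#' @examples
#' power_at_n(roc_design(0.80, 0.82, "discrete", rho = 0.3), 2793)  # 0.680
#' @export
power_at_n <- function(design, n_pos) {
  stopifnot(inherits(design, "roc_design"))
  if (!is.numeric(n_pos) || length(n_pos) != 1L || is.na(n_pos) || n_pos < 2)
    stop("'n_pos' must be a single number >= 2", call. = FALSE)
  vs <- variance_set(design)
  delta <- abs(design$auc2 - design$auc1)
  stats::pnorm((delta * sqrt(n_pos) - z_crit(design) * sqrt(vs$v_null)) /
                 sqrt(vs$v_alt))
}

#' Dropout-inflated enrollment
#'
#' Inflates a per-group sample size for anticipated attrition:
#' `diss = ceiling(n / (1 - dropout_rate))` participants must be enrolled so
#' that `n` remain, and `ed = diss - n` dropouts are expected.
#'
#' @param n Required per-group size(s); vectorized, each at least 1.
#' @param dropout_rate Attrition fraction, in `[0, 1)`.
#' @return A list with integer components `ed` and `diss`.
#' @examples
#' attrition_adjust(3709, 0.2)  # diss 4637, ed 928
#' @export
attrition_adjust <- function(n, dropout_rate) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1))
    stop("'n' must be at least 1", call. = FALSE)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must lie in [0, 1)", call. = FALSE)
  diss <- as.integer(ceiling(n / (1 - dropout_rate)))
  list(ed = diss - as.integer(n), diss = diss)
}

#' @export
print.roc_samplesize <- function(x, ...) {
  d <- x$design
  cat(sprintf("Required sample size (%s data, AUC %.3f vs %.3f, rho+ = %.2f)\n",
              d$data_type, d$auc1, d$auc2, d$rho_pos))
  cat(sprintf("  cases n+ = %d, controls n- = %d, total n = %d\n",
              x$n_pos, x$n_neg, x$n_total))
  cat(sprintf("  target power %.3f; analytic power at these sizes %.4f\n",
              x$tp, x$achieved_power))
  if (d$dropout_rate > 0)
    cat(sprintf("  with %.0f%% dropout: enroll n+' = %d, n-' = %d (n' = %d); expected dropouts D = %d\n",
                100 * d$dropout_rate, x$diss_pos, x$diss_neg, x$diss_total,
                x$ed_total))
  invisible(x)
}
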