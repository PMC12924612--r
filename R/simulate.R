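# Monte-Carlo validator: simulate paired binormal scores, estimate empirical
# AUCs, and measure the achieved ("actual") power of the Z test.

#' Simulate paired diagnostic test scores
#'
#' Draws one synthetic study from the design's binormal model. Controls come
#' from a bivariate normal with unit SDs, zero means and correlation
#' `rho_neg`; cases from a bivariate normal with correlation `rho_pos` and,
#' for test i, mean `A_i / B_i` and SD `1 / B_i` (so that with the control SD
#' fixed at 1 the full-range AUC equals the design's nominal value; with
#' `B = 1` cases simply have mean `A_i` and unit SD).
#'
#' @param design An [roc_design()].
#' @param n_pos Number of cases to draw.
#' @param n_neg Number of controls; defaults to `ceiling(R * n_pos)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with two `n x 2` matrices, `cases` and `controls`
#'   (columns = tests).
#' @examples
#' sc <- simulate_paired_scores(roc_design(0.8, 0.82, rho = 0.3), 100, seed = 1)
#' @export
simulate_paired_scores <- function(design, n_pos,
                                   n_neg = ceiling(design$R * n_pos),
                                   seed = NULL) {
  stopifnot(inherits(design, "roc_design"))
  if (n_pos < 1 || n_neg < 1) stop("group sizes must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- c(sqrt(1 + design$B1^2) * stats::qnorm(design$auc1),
         sqrt(1 + design$B2^2) * stats::qnorm(design$auc2))
  b <- c(design$B1, design$B2)
  draw <- function(n, rho) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    cbind(z1, z2, deparse.level = 0)
  }
  controls <- draw(n_neg, design$rho_neg)            # N(0, 1) marginals
  zc <- draw(n_pos, design$rho_pos)
  cases <- sweep(sweep(zc, 2L, 1 / b, `*`), 2L, a / b, `+`)
  list(cases = cases, controls = controls)
}

#' Empirical AUC (Mann-Whitney estimator)
#'
#' Nonparametric AUC: the proportion of case/control pairs in which the case
#' scores higher, counting ties one half. Computed from midranks, so it is
#' exact under ties.
#'
#' @param case_scores,control_scores Numeric score vectors; both nonempty.
#' @return The empirical AUC, in `[0, 1]`.
#' @examples
#' empirical_auc(c(2, 3), c(1, 2.5))  # 0.75
#' @export
empirical_auc <- function(case_scores, control_scores) {
  n1 <- as.numeric(length(case_scores)); n0 <- as.numeric(length(control_scores))
  if (n1 == 0 || n0 == 0) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# cutpoints giving equiprobable categories under the control distribution
# (controls are standard normal by construction)
rating_cutpoints <- function(levels) {
  stats::qnorm(seq_len(levels - 1L) / levels)
}

#' Monte-Carlo estimate of achieved power
#'
#' Replicates the design's study many times: each replication simulates paired
#' scores via [simulate_paired_scores()], computes the two empirical AUCs, and
#' rejects the null when
#' \eqn{|\hat\Delta| \sqrt{N_+} / \sqrt{V_0} > z_{1-\alpha/2}},
#' using the design's analytic null variance (plug-in at the baseline AUC) —
#' the statistic whose power the analytic formulas describe. The rejection
#' proportion is the achieved ("actual") power. For discrete designs the
#' latent scores are first discretized into `rating_levels` categories that
#' are equiprobable under the control distribution.
#'
#' @param design An [roc_design()].
#' @param n_pos Cases per replication; defaults to the size required for the
#'   design's target power.
#' @param n_neg Controls per replication; defaults to `ceiling(R * n_pos)`.
#' @param replications Number of Monte-Carlo replications (at least 1).
#' @param seed Optional integer seed; one seeded stream is consumed
#'   sequentially across replications, so results are reproducible given
#'   (config, seed).
#' @param rating_levels Number of ordinal categories for discrete designs
#'   (default 5); `NULL` leaves scores continuous.
#' @return An object of class `"roc_sim"`: rejection rate (`rejection_rate`),
#'   its binomial standard error (`mc_se`), mean empirical AUCs, the
#'   replication count, seed, group sizes and RNG algorithm.
#' @examples
#' estimate_actual_power(roc_design(0.8, 0.9, "continuous", rho = 0.8),
#'                       replications = 200, seed = 1)
#' @export
estimate_actual_power <- function(design, n_pos = NULL,
                                  n_neg = NULL,
                                  replications = 1000L, seed = NULL,
                                  rating_levels = if (design$data_type == "discrete") 5L else NULL) {
  stopifnot(inherits(design, "roc_design"))
  if (replications < 1) stop("'replications' must be at least 1", call. = FALSE)
  if (!is.null(rating_levels) && rating_levels < 2)
    stop("'rating_levels' must be at least 2", call. = FALSE)
  if (is.null(n_pos)) n_pos <- required_n(design)$n_pos
  if (is.null(n_neg)) n_neg <- ceiling(design$R * n_pos)
  if (!is.null(seed)) set.seed(seed)
  vs <- variance_set(design)
  zc <- z_crit(design)
  sd_null <- sqrt(vs$v_null / n_pos)
  reject <- logical(replications)
  auc_sum <- c(0, 0)
  for (i in seq_len(replications)) {
    sc <- simulate_paired_scores(design, n_pos, n_neg)
    if (!is.null(rating_levels)) {
      cuts <- rating_cutpoints(rating_levels)
      sc$cases <- matrix(findInterval(sc$cases, cuts), nrow = n_pos)
      sc$controls <- matrix(findInterval(sc$controls, cuts), nrow = n_neg)
    }
    th1 <- empirical_auc(sc$cases[, 1L], sc$controls[, 1L])
    th2 <- empirical_auc(sc$cases[, 2L], sc$controls[, 2L])
    z <- (th2 - th1) / sd_null
    reject[i] <- if (design$sides == 2) abs(z) > zc else
      sign(design$auc2 - design$auc1) * z > zc
    auc_sum <- auc_sum + c(th1, th2)
  }
  ap <- mean(reject)
  out <- list(rejection_rate = ap,
              mc_se = sqrt(ap * (1 - ap) / replications),
              mean_auc = auc_sum / replications,
              replications = as.integer(replications),
              seed = seed, n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg),
              rating_levels = rating_levels,
              rng = RNGkind()[1L],
              design = design)
  class(out) <- "roc_sim"
  out
}

#' @export
print.roc_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf("Monte-Carlo achieved power (%s data, AUC %.3f vs %.3f)\n",
              d$data_type, d$auc1, d$auc2))
  cat(sprintf("  n+ = %d, n- = %d, %d replications%s\n",
              x$n_pos, x$n_neg, x$replications,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  cat(sprintf("  rejection rate (AP) = %.4f  (binomial SE %.4f)\n",
              x$rejection_rate, x$mc_se))
  cat(sprintf("  mean empirical AUCs = %.4f, %.4f\n",
              x$mean_auc[1L], x$mean_auc[2L]))
  invisible(x)
}

#' Simulate method for designs
#'
#' `simulate()` on a design runs the Monte-Carlo power validator; it is a
#' thin wrapper around [estimate_actual_power()] with `nsim` replications.
#'
#' @param object An [roc_design()].
#' @param nsim Number of replications.
#' @param seed Optional integer seed.
#' @param ... Passed to [estimate_actual_power()] (`n_pos`, `rating_levels`, ...).
#' @return An object of class `"roc_sim"`.
#' @export
simulate.roc_design <- function(object, nsim = 1000L, seed = NULL, ...) {
  estimate_actual_power(object, replications = nsim, seed = seed, ...)
}
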