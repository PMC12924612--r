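# Factorial scenario grids, power curves, and serialization.

#' Factorial grid of AUC-comparison scenarios
#'
#' Defines a factorial set of designs sharing a baseline AUC and test
#' parameters, crossed over AUC differences, correlation levels, data types
#' and target power levels. The defaults span the canonical evaluation grid:
#' baseline AUC 0.80, differences 0.02-0.10, correlations 0.3/0.5/0.8, both
#' data types, and power levels 0.80/0.90/0.95/0.999, with a 20% dropout rate.
#'
#' @param auc1 Baseline AUC shared by all cells.
#' @param delta AUC differences (each cell compares `auc1` vs `auc1 + delta`).
#' @param rho Inter-test score correlations (applied to both groups).
#' @param data_type Data types to cross (`"discrete"`, `"continuous"` or both).
#' @param power_levels Target powers evaluated in every cell.
#' @param alpha,sides,R,B,dropout_rate Shared design parameters; `B` is used
#'   for both tests' scale ratios in discrete cells.
#' @return An object of class `"scenario_grid"`.
#' @examples
#' g <- scenario_grid(power_levels = 0.8)
#' res <- run_grid(g)
#' @export
scenario_grid <- function(auc1 = 0.80,
                          delta = c(0.02, 0.04, 0.06, 0.08, 0.10),
                          rho = c(0.3, 0.5, 0.8),
                          data_type = c("discrete", "continuous"),
                          power_levels = c(0.80, 0.90, 0.95, 0.999),
                          alpha = 0.05, sides = 2, R = 1, B = 1,
                          dropout_rate = 0.2) {
  data_type <- match.arg(data_type, several.ok = TRUE)
  if (length(delta) == 0L || length(rho) == 0L || length(power_levels) == 0L)
    stop("grid axes must be nonempty", call. = FALSE)
  structure(list(auc1 = auc1, delta = delta, rho = rho, data_type = data_type,
                 power_levels = power_levels, alpha = alpha, sides = sides,
                 R = R, B = B, dropout_rate = dropout_rate),
            class = "scenario_grid")
}

#' Evaluate every cell of a scenario grid
#'
#' Runs [required_n()] for every (data type, AUC difference, correlation)
#' cell at every target power level, returning one row per cell and power.
#' Infeasible cells are recorded as error rows (with the message in the
#' `error` column) rather than dropped. The result is deterministic.
#'
#' @param grid A [scenario_grid()].
#' @return A data frame of class `"scenario_result"` with the design axes and
#'   the columns `n_pos`, `n_neg`, `n_total`, `ed_pos`, `ed_neg`, `ed_total`,
#'   `diss_pos`, `diss_neg`, `diss_total`, `tp` (target power), `power`
#'   (analytic power at the integer sizes) and `error`.
#' @seealso [grid_summary()] for the min/max/fold summary.
#' @export
run_grid <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  cells <- expand.grid(target_power = grid$power_levels, rho = grid$rho,
                       delta = grid$delta, data_type = grid$data_type,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    base <- data.frame(data_type = cell$data_type, auc1 = grid$auc1,
                       auc2 = grid$auc1 + cell$delta, delta = cell$delta,
                       rho = cell$rho, target_power = cell$target_power,
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      design <- roc_design(grid$auc1, grid$auc1 + cell$delta,
                           data_type = cell$data_type, rho = cell$rho,
                           B1 = grid$B, B2 = grid$B, R = grid$R,
                           alpha = grid$alpha, sides = grid$sides,
                           target_power = cell$target_power,
                           dropout_rate = grid$dropout_rate)
      n <- required_n(design)
      cbind(base,
            data.frame(n_pos = n$n_pos, n_neg = n$n_neg, n_total = n$n_total,
                       ed_pos = n$ed_pos, ed_neg = n$ed_neg,
                       ed_total = n$ed_total,
                       diss_pos = n$diss_pos, diss_neg = n$diss_neg,
                       diss_total = n$diss_total,
                       tp = n$tp, power = n$achieved_power,
                       error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base,
            data.frame(n_pos = NA_integer_, n_neg = NA_integer_,
                       n_total = NA_integer_, ed_pos = NA_integer_,
                       ed_neg = NA_integer_, ed_total = NA_integer_,
                       diss_pos = NA_integer_, diss_neg = NA_integer_,
                       diss_total = NA_integer_, tp = cell$target_power,
                       power = NA_real_, error = conditionMessage(e),
                       stringsAsFactors = FALSE))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Extremes of a scenario grid result
#'
#' Minimum and maximum per-group case sample size across the cells at one
#' target power level, and their (rounded) fold ratio.
#'
#' @param result A [run_grid()] result.
#' @param power Target power level to summarize (default 0.80).
#' @return A list with `n_min`, `n_max`, and `fold` (rounded ratio).
#' @export
grid_summary <- function(result, power = 0.80) {
  stopifnot(inherits(result, "scenario_result"))
  sub <- result[result$tp == power & is.na(result$error), ]
  if (nrow(sub) == 0L) stop("no feasible cells at that power level", call. = FALSE)
  list(n_min = min(sub$n_pos), n_max = max(sub$n_pos),
       fold = round(max(sub$n_pos) / min(sub$n_pos)))
}

#' Percent reduction between two sample sizes
#'
#' Efficiency gain of the smaller design relative to the larger one,
#' `round(100 * (1 - n_strong / n_weak))`.
#'
#' @param n_strong,n_weak Per-group sizes of the more and less efficient
#'   designs.
#' @return Integer percent reduction.
#' @examples
#' percent_reduction(1899, 3709)  # 49
#' @export
percent_reduction <- function(n_strong, n_weak) {
  round(100 * (1 - n_strong / n_weak))
}

#' Power curve over a range of sample sizes
#'
#' Analytic power of the design's Z test at each candidate number of cases.
#'
#' @param design An [roc_design()].
#' @param n_range Increasing vector of case counts (each at least 2).
#' @return A data frame with columns `n_pos` and `power` (nondecreasing).
#' @examples
#' pc <- power_curve(roc_design(0.80, 0.84, "discrete", rho = 0.3),
#'                   seq(100, 1200, by = 100))
#' @export
power_curve <- function(design, n_range) {
  stopifnot(inherits(design, "roc_design"))
  if (length(n_range) == 0L || any(diff(n_range) <= 0))
    stop("'n_range' must be a nonempty increasing vector", call. = FALSE)
  data.frame(n_pos = n_range, power = predict(design, n_range))
}

#' Plot the power curve of a design
#'
#' @param x An [roc_design()].
#' @param n_range Case counts at which to evaluate the curve; defaults to an
#'   even spread up to about 1.6 times the size required for the design's
#'   target power.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted [power_curve()] data frame.
#' @export
plot.roc_design <- function(x, n_range = NULL, ...) {
  if (is.null(n_range)) {
    n80 <- required_n(x)$n_pos
    n_range <- unique(pmax(2L, round(seq(max(2, n80 * 0.1), n80 * 1.6,
                                         length.out = 60L))))
  }
  pc <- power_curve(x, n_range)
  graphics::plot(pc$n_pos, pc$power, type = "l",
                 xlab = "cases per group (n+)", ylab = "power",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$target_power, lty = 3)
  invisible(pc)
}

#' Write / read scenario results
#'
#' `write_scenario_csv()` and `read_scenario_csv()` round-trip a
#' [run_grid()] result losslessly through CSV; `write_scenario_json()` writes
#' a JSON document nested by scenario cell, with the engine conventions
#' recorded in a metadata block.
#'
#' @param result A `"scenario_result"` data frame.
#' @param path Output (or input) file path.
#' @return `read_scenario_csv()` returns the restored `"scenario_result"`;
#'   the writers return `path` invisibly.
#' @export
write_scenario_csv <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  utils::write.csv(result, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(error = "character"))
  out$error[!nzchar(out$error)] <- NA_character_
  int_cols <- c("n_pos", "n_neg", "n_total", "ed_pos", "ed_neg", "ed_total",
                "diss_pos", "diss_neg", "diss_total")
  for (cl in intersect(int_cols, names(out))) out[[cl]] <- as.integer(out[[cl]])
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' @rdname write_scenario_csv
#' @export
write_scenario_json <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  key <- interaction(result$data_type, result$delta, result$rho, drop = TRUE)
  scenarios <- lapply(split(as.data.frame(result), key), function(df) {
    list(data_type = df$data_type[1L], auc1 = df$auc1[1L], auc2 = df$auc2[1L],
         rho = df$rho[1L],
         rows = df[, setdiff(names(df), c("data_type", "auc1", "auc2",
                                          "delta", "rho"))])
  })
  doc <- list(metadata = list(package = "rocsize",
                              version = as.character(utils::packageVersion("rocsize")),
                              conventions = list(
                                null_anchor = "auc1",
                                hm_covariance = "r * sqrt(V1 * V2)",
                                area_correlation = "bilinear interpolation at mean area")),
              scenarios = unname(scenarios))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
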