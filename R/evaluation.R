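#' Rank methods by MSPE across units
#'
#' Within each unit (participant or simulation replicate), methods are ranked
#' by ascending MSPE — rank 1 is best — with ties receiving the average of
#' the tied ranks. Ranks and MSPEs are then averaged across units.
#'
#' @param per_unit_mspe Data frame with columns `unit`, `method`, `mspe`;
#'   every unit must have every method.
#' @return Data frame with one row per method: `method`, `mean_mspe`,
#'   `mean_rank`, sorted by `mean_rank`.
#' @export
#' @examples
#' tab <- data.frame(unit = c(1, 1, 2, 2),
#'                   method = c("a", "b", "a", "b"),
#'                   mspe = c(1, 2, 2, 1))
#' rank_methods(tab)  # both methods: mean rank 1.5
rank_methods <- function(per_unit_mspe) {
  stopifnot(all(c("unit", "method", "mspe") %in% names(per_unit_mspe)))
  counts <- table(per_unit_mspe$unit, per_unit_mspe$method)
  if (any(counts != 1))
    stop("every unit must have exactly one MSPE per method", call. = FALSE)
  per_unit_mspe$rank <- ave(per_unit_mspe$mspe, per_unit_mspe$unit,
                            FUN = function(v) rank(v, ties.method = "average"))
  out <- aggregate(cbind(mean_mspe = mspe, mean_rank = rank) ~ method,
                   data = per_unit_mspe, FUN = mean)
  out[order(out$mean_rank), , drop = FALSE]
}

#' Summarize MSPE across replicates and conditions
#'
#' Averages per-replicate MSPEs within each simulation cell, yielding the
#' condition-level summary (mean MSPE per study length, sampling frequency,
#' rate of change and method) used to compare selection methods across the
#' design grid.
#'
#' @param results Data frame with columns `days`, `beeps`, `rate`, `method`,
#'   `mspe` (and optionally `replicate`).
#' @return Data frame with `days`, `beeps`, `rate`, `method`, `mean_mspe`
#'   and `n_replicates`.
#' @export
summarize_conditions <- function(results) {
  need <- c("days", "beeps", "rate", "method", "mspe")
  stopifnot(all(need %in% names(results)))
  agg <- aggregate(mspe ~ days + beeps + rate + method, data = results,
                   FUN = mean)
  names(agg)[names(agg) == "mspe"] <- "mean_mspe"
  n <- aggregate(mspe ~ days + beeps + rate + method, data = results,
                 FUN = length)
  agg$n_replicates <- n$mspe
  agg[order(agg$days, agg$beeps, agg$rate, agg$method), , drop = FALSE]
}

#' Best-possible selection benchmark
#'
#' The realized lower bound on prediction error for a window-selection
#' procedure: at every outer validation point, take the smallest squared
#' error achieved by any evaluated method. Its MSPE is, by construction, no
#' larger than any single method's MSPE in the same replicate — the gap
#' measures how much error comes from not knowing the ideal window at each
#' moment. Computed for OLS libraries in the simulation study (random-forest
#' libraries are compared against each other only).
#'
#' @param fv An `fv_result` from [run_outer_loop()], or a matrix of
#'   per-point squared errors (points x methods).
#' @param methods Optional subset of method columns to minimize over
#'   (default: all).
#' @return List with `per_point_sq_error` and `outer_mspe`.
#' @export
truth_benchmark <- function(fv, methods = NULL) {
  sq <- if (inherits(fv, "fv_result")) fv$sq_error else as.matrix(fv)
  if (!is.null(methods)) sq <- sq[, methods, drop = FALSE]
  per_point <- apply(sq, 1, min)
  list(per_point_sq_error = per_point, outer_mspe = mean(per_point))
}

#' Write the three evaluation tables as CSVs
#'
#' @param per_unit Data frame of per-unit MSPEs (`unit`, `method`, `mspe`,
#'   plus any condition columns).
#' @param condition_summary Output of [summarize_conditions()].
#' @param rank_table Output of [rank_methods()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_evaluation_csvs <- function(per_unit, condition_summary, rank_table,
                                  dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("raw_results.csv", "condition_summary.csv",
                            "rank_table.csv"))
  write.csv(per_unit, paths[1], row.names = FALSE)
  write.csv(condition_summary, paths[2], row.names = FALSE)
  write.csv(rank_table, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Plot a condition summary in the style of a rate-of-change panel
#'
#' Mean MSPE against the rate of change, one line per method, faceted by
#' study days and beeps per day. Requires \pkg{ggplot2}.
#'
#' @param condition_summary Output of [summarize_conditions()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(condition_summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(condition_summary,
                  ggplot2::aes(x = .data$rate, y = .data$mean_mspe,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(beeps ~ days,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "rate of change (oscillations per series)",
                  y = "mean MSPE", colour = "method") +
    ggplot2::theme_minimal()
}
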