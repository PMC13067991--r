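#' The 21-point rate-of-change grid
#'
#' Equally spaced rates from 0 (stationary) to 1 (one full coefficient
#' oscillation over the series).
#'
#' @param n Number of grid points (default 21).
#' @return Numeric vector of rates.
#' @export
paper_rate_grid <- function(n = 21) seq(0, 1, length.out = n)

#' Simulation-study configuration
#'
#' The full factorial design of the simulation study: study durations x
#' beeps per day x rates of change x replicates, for one learner kind.
#' Replicate seeds are derived deterministically from `master_seed` and
#' bound to the cell's position in the canonical grid enumeration (days,
#' then beeps, then rate, then replicate), so results do not depend on
#' execution order.
#'
#' @param days_grid,beeps_grid,rate_grid Design grids (non-empty).
#' @param n_replicates Replicates per cell.
#' @param learner A [learner_spec()] (default OLS).
#' @param snr Signal-to-noise ratio of the generating process.
#' @param n_covariates Number of covariates (default 4).
#' @param frac_lo,frac_hi,frac_step Candidate-library fraction grid.
#' @param methods Combiners evaluated alongside the candidates.
#' @param master_seed Integer master seed.
#' @param output_dir Optional directory for CSV outputs.
#' @return An object of class `study_config`.
#' @export
study_config <- function(days_grid = c(14, 28, 56),
                         beeps_grid = c(6, 8, 12),
                         rate_grid = paper_rate_grid(),
                         n_replicates = 200,
                         learner = learner_spec("ols"),
                         snr = 4, n_covariates = 4,
                         frac_lo = 0.05, frac_hi = 0.25, frac_step = 0.01,
                         methods = c("avg", "dsl", "esl", "rolling_mean"),
                         master_seed = 1L, output_dir = NULL) {
  stopifnot(length(days_grid) > 0, length(beeps_grid) > 0,
            length(rate_grid) > 0, n_replicates >= 1)
  structure(list(days_grid = days_grid, beeps_grid = beeps_grid,
                 rate_grid = rate_grid, n_replicates = n_replicates,
                 learner = learner, snr = snr, n_covariates = n_covariates,
                 frac_lo = frac_lo, frac_hi = frac_hi,
                 frac_step = frac_step, methods = methods,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [study_config()]; `learner` may be
#' `"ols"` or `"random_forest"` with optional `num_trees`.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  lrn <- learner_spec(cfg$learner %||% "ols",
                      num_trees = cfg$num_trees %||% 500L)
  study_config(
    days_grid = unlist(cfg$days_grid %||% c(14, 28, 56)),
    beeps_grid = unlist(cfg$beeps_grid %||% c(6, 8, 12)),
    rate_grid = unlist(cfg$rate_grid %||% paper_rate_grid()),
    n_replicates = cfg$n_replicates %||% 200,
    learner = lrn, snr = cfg$snr %||% 4,
    n_covariates = cfg$n_covariates %||% 4,
    frac_lo = cfg$frac_lo %||% 0.05, frac_hi = cfg$frac_hi %||% 0.25,
    frac_step = cfg$frac_step %||% 0.01,
    methods = unlist(cfg$methods %||% c("avg", "dsl", "esl",
                                        "rolling_mean")),
    master_seed = cfg$master_seed %||% 1L,
    output_dir = cfg$output_dir)
}

#' Run the simulation study
#'
#' For every cell of the design grid and every replicate: simulate a dataset,
#' build the candidate library, run the nested forward validation, and record
#' each method's outer MSPE. Cell failures are caught, reported as warnings
#' and skipped, so a long run is not lost to one bad cell. When
#' `include_truth = TRUE` (default for OLS learners) the best-possible
#' selection benchmark is recorded per replicate under method `"truth"`.
#'
#' @param config A [study_config()].
#' @param include_truth Record the per-point best-method benchmark
#'   (default: `TRUE` for OLS, `FALSE` for random forest).
#' @param verbose Print per-cell progress.
#' @return An object of class `evaluation_report`: list with `per_unit`
#'   (days, beeps, rate, replicate, unit, method, mspe), `condition_summary`
#'   and `rank_table`. If `config$output_dir` is set, the three tables are
#'   also written as CSVs.
#' @export
run_study <- function(config, include_truth = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(include_truth))
    include_truth <- config$learner$kind == "ols"

  cells <- expand.grid(replicate = seq_len(config$n_replicates),
                       rate = config$rate_grid, beeps = config$beeps_grid,
                       days = config$days_grid,
                       KEEP.OUT.ATTRS = FALSE)
  # canonical order: days, beeps, rate, replicate
  cells <- cells[order(cells$days, cells$beeps, cells$rate,
                       cells$replicate), , drop = FALSE]
  set.seed(config$master_seed)
  cells$seed <- sample.int(2147483646L, nrow(cells))

  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows[[i]] <- tryCatch({
      dgp <- dgp_config(cell$days, cell$beeps, cell$rate,
                        n_covariates = config$n_covariates,
                        snr = config$snr, seed = cell$seed)
      dat <- simulate_dataset(dgp)
      lib <- build_candidate_library(length(dat$y), cell$beeps,
                                     config$frac_lo, config$frac_hi,
                                     config$frac_step)
      lrn <- config$learner
      lrn$seed <- cell$seed
      fv <- run_outer_loop(dat, lib, lrn, methods = config$methods)
      mspe <- fv$mspe
      if (include_truth)
        mspe <- c(mspe, truth = truth_benchmark(fv)$outer_mspe)
      if (verbose)
        message(sprintf("cell %d/%d: days=%d beeps=%d rate=%.2f rep=%d",
                        i, nrow(cells), cell$days, cell$beeps, cell$rate,
                        cell$replicate))
      data.frame(days = cell$days, beeps = cell$beeps, rate = cell$rate,
                 replicate = cell$replicate, method = names(mspe),
                 mspe = unname(mspe), row.names = NULL)
    }, error = function(e) {
      warning(sprintf(
        "cell failed (days=%d beeps=%d rate=%.2f rep=%d): %s",
        cell$days, cell$beeps, cell$rate, cell$replicate,
        conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  per_unit <- do.call(rbind, rows)
  if (is.null(per_unit)) stop("all study cells failed", call. = FALSE)
  per_unit$unit <- interaction(per_unit$days, per_unit$beeps,
                               per_unit$rate, per_unit$replicate,
                               drop = TRUE)

  condition_summary <- summarize_conditions(per_unit)
  rank_table <- rank_methods(per_unit)
  report <- structure(list(per_unit = per_unit,
                           condition_summary = condition_summary,
                           rank_table = rank_table, config = config),
                      class = "evaluation_report")
  if (!is.null(config$output_dir))
    write_evaluation_csvs(per_unit, condition_summary, rank_table,
                          config$output_dir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d cells x methods = %d rows\n",
              nlevels(x$per_unit$unit), nrow(x$per_unit)))
  print(x$rank_table, row.names = FALSE)
  invisible(x)
}
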