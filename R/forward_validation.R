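#' Fold schedule for nested forward validation
#'
#' Determines which time points are eligible as outer validation points. The
#' largest nominal candidate window covers `max_window_fraction` of the
#' series and an additional `buffer_fraction` is reserved so candidate error
#' estimates have stabilized; evaluation therefore starts after a burn-in of
#' `ceil((max_window_fraction + buffer_fraction) * T)` points and every
#' subsequent point is a one-step-ahead outer validation point. With the
#' defaults (25% + 5%) the final 70% of the series is evaluated.
#'
#' The same fraction is reused as `inner_start_fraction`: at outer training
#' size `tau`, inner validation points run from
#' `ceil(inner_start_fraction * tau) + 1` through `tau`.
#'
#' @param T_len Series length.
#' @param max_window_fraction Largest nominal fraction window (default 0.25).
#' @param buffer_fraction Additional stabilization buffer (default 0.05).
#' @return An object of class `fold_schedule`: list with `burn_in`,
#'   `outer_points` and `inner_start_fraction`.
#' @export
#' @examples
#' make_fold_schedule(100)  # burn-in 30, outer points 31..100
make_fold_schedule <- function(T_len, max_window_fraction = 0.25,
                               buffer_fraction = 0.05) {
  if (max_window_fraction + buffer_fraction >= 1)
    stop("max_window_fraction + buffer_fraction must be < 1", call. = FALSE)
  burn_in <- as.integer(ceiling((max_window_fraction + buffer_fraction) *
                                T_len))
  if (burn_in + 1L > T_len)
    stop("series too short: no outer validation points left", call. = FALSE)
  structure(list(burn_in = burn_in,
                 outer_points = (burn_in + 1L):as.integer(T_len),
                 inner_start_fraction = max_window_fraction +
                   buffer_fraction),
            class = "fold_schedule")
}

inner_validation_range <- function(tau, inner_start_fraction) {
  (as.integer(ceiling(inner_start_fraction * tau)) + 1L):tau
}

#' Inner rolling-origin loop: candidate predictions on past data
#'
#' For each inner validation index `v` in `inner_start .. up_to` and each
#' candidate window rule, fits the learner on the window ending at `v - 1`
#' and predicts `y[v]`. This is plain time-series cross-validation on the
#' data available at `up_to`; its output feeds the super learners.
#'
#' @param y,X Outcome and covariates for the full series (only indices
#'   `<= up_to` are used as responses; fraction windows resolve against
#'   `series_length`).
#' @param up_to Last index of the available (outer-training) data.
#' @param library List of [window_spec()] candidates.
#' @param learner A [learner_spec()].
#' @param inner_start First inner validation index (`> 1`).
#' @param beeps_per_day Assessments per day.
#' @param series_length Full series length used to resolve fraction windows
#'   (defaults to `length(y)`).
#' @return A [prediction_matrix()] with one row per inner validation point.
#' @export
run_inner_loop <- function(y, X, up_to, library, learner, inner_start,
                           beeps_per_day, series_length = length(y)) {
  if (inner_start >= up_to + 1L || inner_start < 2L)
    stop("need 2 <= inner_start <= up_to", call. = FALSE)
  v_range <- inner_start:up_to
  P <- predict_grid(y, X, library, learner, v_range, beeps_per_day,
                    series_length)
  prediction_matrix(P, y[v_range], v_range)
}

#' Outer forward-validation loop: honest evaluation of the complete library
#'
#' The nested procedure: for each outer validation point `tau + 1`,
#' \enumerate{
#'   \item an inner rolling-origin loop on data `1..tau` estimates each
#'     candidate's MSPE, from which the discrete super learner's selection
#'     and the ensemble super learner's simplex weights are constructed;
#'   \item every candidate is refit on its window ending at `tau` and
#'     predicts `y[tau + 1]`;
#'   \item the average / dSL / eSL predictions are formed from those
#'     candidate predictions using the step-1 fits;
#'   \item squared errors against the realized `y[tau + 1]` are recorded.
#' }
#' The combiners are reconstructed at every outer point by default, so they
#' adapt as candidates' relative performance drifts (`refresh_every` trades
#' this off against compute for expensive learners).
#'
#' Because a candidate's prediction at index `v` depends only on data before
#' `v`, the engine precomputes a single prediction grid and slices it per
#' fold; this is numerically identical to naive refitting (random-forest
#' fits are seeded per (index, candidate) so the equivalence holds for both
#' learner kinds).
#'
#' @param dataset A `ts_dataset`, or any list with `y` and `X`.
#' @param library List of [window_spec()] candidates.
#' @param learner A [learner_spec()].
#' @param schedule A [make_fold_schedule()]; defaults to the standard
#'   25% + 5% rule.
#' @param methods Combiners to evaluate alongside the candidates: any subset
#'   of `"avg"`, `"dsl"`, `"esl"`, `"rolling_mean"`.
#' @param beeps_per_day Assessments per day; taken from `dataset$meta` when
#'   present.
#' @param esl_solver Passed to [fit_ensemble_sl()].
#' @param rolling_days Window (in days) of the rolling-mean baseline, which
#'   predicts the next outcome by the mean outcome over the last
#'   `rolling_days` days (default 1).
#' @param refresh_every Rebuild the super learners every k-th outer point,
#'   reusing the latest fits in between (default 1 = every point).
#' @return An object of class `fv_result`: list with `outer_points`,
#'   `actuals`, `predictions` (points x methods), `sq_error`, `mspe` (named
#'   vector, mean squared error per method), `dsl_selected`, `esl_weights`
#'   and `schedule`.
#' @export
run_outer_loop <- function(dataset, library, learner, schedule = NULL,
                           methods = c("avg", "dsl", "esl", "rolling_mean"),
                           beeps_per_day = NULL, esl_solver = "qp",
                           rolling_days = 1, refresh_every = 1L) {
  y <- dataset$y
  X <- dataset$X
  T_len <- length(y)
  beeps_per_day <- beeps_per_day %||% dataset$meta$beeps_per_day
  if (is.null(beeps_per_day))
    stop("beeps_per_day not given and not in dataset$meta", call. = FALSE)
  if (is.null(schedule)) schedule <- make_fold_schedule(T_len)
  stopifnot(inherits(schedule, "fold_schedule"))
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- library_labels(library)
  K <- length(library)

  outer <- schedule$outer_points
  f_in <- schedule$inner_start_fraction
  v_min <- min(inner_validation_range(outer[1] - 1L, f_in))
  v_all <- v_min:T_len
  P <- predict_grid(y, X, library, learner, v_all, beeps_per_day, T_len)
  row_of <- function(v) v - v_min + 1L

  all_methods <- c(labels, methods)
  preds <- matrix(NA_real_, length(outer), length(all_methods),
                  dimnames = list(NULL, all_methods))
  dsl_selected <- character(length(outer))
  esl_weights <- if ("esl" %in% methods)
    matrix(NA_real_, length(outer), K, dimnames = list(NULL, labels))
  sl_fit <- NULL

  need_sl <- any(c("dsl", "esl") %in% methods)
  for (i in seq_along(outer)) {
    o <- outer[i]
    tau <- o - 1L
    cand_row <- P[row_of(o), ]
    preds[i, labels] <- cand_row

    if (need_sl && (i == 1L || (i - 1L) %% refresh_every == 0L)) {
      vr <- inner_validation_range(tau, f_in)
      pm <- prediction_matrix(P[row_of(vr), , drop = FALSE], y[vr], vr)
      sl_fit <- fit_ensemble_sl(pm, solver = esl_solver)
    }
    if ("avg" %in% methods) preds[i, "avg"] <- average_predict(cand_row)
    if ("dsl" %in% methods) {
      preds[i, "dsl"] <- predict_with_fit(sl_fit, "dsl", cand_row)
      dsl_selected[i] <- sl_fit$selected
    }
    if ("esl" %in% methods) {
      preds[i, "esl"] <- predict_with_fit(sl_fit, "esl", cand_row)
      esl_weights[i, ] <- sl_fit$weights
    }
    if ("rolling_mean" %in% methods) {
      w <- max(1L, as.integer(rolling_days * beeps_per_day))
      preds[i, "rolling_mean"] <- mean(y[max(1L, tau - w + 1L):tau])
    }
  }

  actuals <- y[outer]
  sq_error <- (actuals - preds)^2
  structure(list(outer_points = outer, actuals = actuals,
                 predictions = preds, sq_error = sq_error,
                 mspe = colMeans(sq_error),
                 dsl_selected = if ("dsl" %in% methods) dsl_selected,
                 esl_weights = esl_weights,
                 schedule = schedule, candidate_labels = labels),
            class = "fv_result")
}

#' @export
print.fv_result <- function(x, ...) {
  cat(sprintf("<fv_result> %d outer points (%d..%d), %d methods\n",
              length(x$outer_points), min(x$outer_points),
              max(x$outer_points), ncol(x$predictions)))
  m <- sort(x$mspe)
  cat("outer MSPE (best 5):\n")
  print(round(utils::head(m, 5), 4))
  invisible(x)
}

#' Tidy per-point results of a forward-validation run
#'
#' @param fv An `fv_result` from [run_outer_loop()].
#' @return A data frame with columns `method`, `outer_point`, `y`, `y_hat`,
#'   `sq_error`, suitable for CSV export.
#' @export
tidy_fv_result <- function(fv) {
  stopifnot(inherits(fv, "fv_result"))
  methods <- colnames(fv$predictions)
  do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m, outer_point = fv$outer_points, y = fv$actuals,
               y_hat = fv$predictions[, m], sq_error = fv$sq_error[, m],
               row.names = NULL)
  }))
}
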