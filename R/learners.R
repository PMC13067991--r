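#' Learner specification
#'
#' The model family fitted inside each training window. Two kinds are
#' supported, matching common practice in digital-phenotyping prediction:
#' ordinary least squares and random forest regression (via \pkg{ranger}).
#'
#' @param kind `"ols"` or `"random_forest"`.
#' @param intercept For OLS: include an intercept (default `TRUE`; turn off
#'   when the generating process is known to have none).
#' @param ridge_epsilon For OLS: ridge penalty used as a fallback when the
#'   windowed design is rank-deficient (e.g. fewer rows than columns in a
#'   one-day window); default `1e-6`.
#' @param num_trees,min_node_size Random-forest size parameters. Defaults
#'   (500 trees, minimum node size 5) are standard regression defaults;
#'   random forests need little tuning for this task.
#' @param mtry Covariates sampled per split; default `ceiling(p / 3)`,
#'   resolved at fit time.
#' @param clip_predictions Clip each one-step forecast to the range of the
#'   outcomes observed before the predicted point (default `TRUE`). Least
#'   squares on the shortest windows (a handful of observations for five
#'   parameters) interpolates its training points and can extrapolate
#'   arbitrarily far off-scale; bounding forecasts by the historically
#'   observed outcome range is the standard guard for such forecasts, and
#'   psychological outcomes are scale-bounded to begin with. Uses only past
#'   outcomes, so the no-leakage contract is unaffected. Turn off for exact
#'   algebraic checks against the unclipped least-squares solution.
#' @param seed Base seed for the forest; each (time point, candidate) fit
#'   derives its own sub-seed so runs are reproducible and cache-stable.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("ols", "random_forest"),
                         intercept = TRUE, ridge_epsilon = 1e-6,
                         num_trees = 500L, min_node_size = 5L, mtry = NULL,
                         clip_predictions = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, intercept = intercept,
                 ridge_epsilon = ridge_epsilon,
                 num_trees = as.integer(num_trees),
                 min_node_size = as.integer(min_node_size), mtry = mtry,
                 clip_predictions = isTRUE(clip_predictions),
                 seed = as.integer(seed)),
            class = "learner_spec")
}

# OLS fit on window rows + prediction for one new covariate row.
# Rank-deficient designs fall back to ridge with penalty `eps`.
ols_predict_one <- function(yw, Xw, xnew, intercept = TRUE, eps = 1e-6,
                            warn = TRUE) {
  A <- if (intercept) cbind(1, Xw) else Xw
  a_new <- if (intercept) c(1, xnew) else xnew
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    if (warn) warning("rank-deficient OLS design; ridge fallback", call. = FALSE)
    AtA <- crossprod(A) + eps * diag(ncol(A))
    coef <- solve(AtA, crossprod(A, yw))
    return(drop(a_new %*% coef))
  }
  coef <- qr.coef(qrA, yw)
  drop(sum(a_new * coef))
}

rf_predict_one <- function(yw, Xw, xnew, learner, seed) {
  p <- ncol(Xw)
  mtry <- learner$mtry %||% ceiling(p / 3)
  df <- as.data.frame(Xw)
  names(df) <- paste0("x", seq_len(p))
  df$.y <- yw
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = learner$num_trees,
    mtry = min(mtry, p),
    min.node.size = min(learner$min_node_size, nrow(df)),
    seed = seed, num.threads = 1, verbose = FALSE)
  nd <- as.data.frame(matrix(xnew, nrow = 1))
  names(nd) <- paste0("x", seq_len(p))
  unname(predict(fit, nd, num.threads = 1)$predictions)
}

# Deterministic per-(time point, candidate) sub-seed, cache-stable.
fit_seed <- function(base_seed, t_next, k) {
  (abs(base_seed) * 7919L + t_next * 131L + k) %% 2147483647L + 1L
}

#' Fit on a window and predict one step ahead
#'
#' Fits the learner on rows `window$start .. window$end` of `(y, X)` and
#' predicts the outcome at `t_next = window$end + 1` from the covariate row
#' `X[t_next, ]`. No row with index `>= t_next` other than that single
#' covariate row is touched, which is the no-leakage contract of one-step-
#' ahead forecasting.
#'
#' @param learner A [learner_spec()].
#' @param y,X Outcome vector and covariate matrix for the full series.
#' @param window A [resolve_window()] range with `end == t_next - 1`.
#' @param t_next Index being predicted.
#' @param candidate_label Optional label recorded in the result.
#' @param candidate_index Candidate position in the library (seeds the
#'   forest; default 1).
#' @return An object of class `one_step_prediction`: list with
#'   `t_predicted`, `candidate_label`, `y_hat`, `window_used`.
#' @export
fit_predict_one_step <- function(learner, y, X, window, t_next,
                                 candidate_label = NULL,
                                 candidate_index = 1L) {
  stopifnot(inherits(learner, "learner_spec"))
  if (window$end != t_next - 1L)
    stop("window must end at t_next - 1", call. = FALSE)
  if (window$size < 2L)
    stop("degenerate window: need at least 2 observations", call. = FALSE)
  if (t_next > nrow(X)) stop("covariate row for t_next not available",
                             call. = FALSE)
  idx <- window$start:window$end
  yw <- y[idx]
  Xw <- X[idx, , drop = FALSE]
  xnew <- X[t_next, ]
  y_hat <- switch(learner$kind,
    ols = ols_predict_one(yw, Xw, xnew, learner$intercept,
                          learner$ridge_epsilon),
    random_forest = rf_predict_one(yw, Xw, xnew, learner,
                                   fit_seed(learner$seed, t_next,
                                            candidate_index)))
  if (learner$clip_predictions) {
    past <- y[seq_len(t_next - 1L)]
    y_hat <- min(max(y_hat, min(past)), max(past))
  }
  structure(list(t_predicted = as.integer(t_next),
                 candidate_label = candidate_label %||% learner$kind,
                 y_hat = y_hat, window_used = window),
            class = "one_step_prediction")
}

# Predictions for every (validation index, candidate) pair.
# Row v holds the prediction of y[v] from the window ending at v - 1 —
# independent of any outer fold that contains v, so this grid is computed
# once and sliced by the forward-validation loops.
predict_grid <- function(y, X, library, learner, v_range, beeps_per_day,
                         series_length, warn_rank = FALSE) {
  labels <- library_labels(library)
  P <- matrix(NA_real_, length(v_range), length(library),
              dimnames = list(NULL, labels))
  for (i in seq_along(v_range)) {
    v <- v_range[i]
    for (k in seq_along(library)) {
      win <- resolve_window(library[[k]], v - 1L, beeps_per_day,
                            series_length)
      idx <- win$start:win$end
      if (win$size < 2L)
        stop("degenerate window for candidate ", labels[k], " at t = ", v,
             call. = FALSE)
      P[i, k] <- switch(learner$kind,
        ols = ols_predict_one(y[idx], X[idx, , drop = FALSE], X[v, ],
                              learner$intercept, learner$ridge_epsilon,
                              warn = warn_rank),
        random_forest = rf_predict_one(y[idx], X[idx, , drop = FALSE],
                                       X[v, ], learner,
                                       fit_seed(learner$seed, v, k)))
    }
    if (learner$clip_predictions) {
      past <- y[seq_len(v - 1L)]
      P[i, ] <- pmin(pmax(P[i, ], min(past)), max(past))
    }
  }
  P
}
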