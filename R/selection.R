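#' Prediction matrix for a set of candidate models
#'
#' The raw material of every combiner: one-step-ahead predictions of each
#' candidate at a set of validation time points, together with the realized
#' outcomes at those points.
#'
#' @param pred Numeric matrix, rows = validation time points, columns =
#'   candidates (column names are the candidate labels).
#' @param actuals Observed outcomes aligned with the rows.
#' @param indices Optional integer time indices of the rows.
#' @return An object of class `prediction_matrix`.
#' @export
prediction_matrix <- function(pred, actuals, indices = NULL) {
  pred <- as.matrix(pred)
  if (anyNA(pred)) stop("prediction matrix must have no missing entries",
                        call. = FALSE)
  if (length(actuals) != nrow(pred))
    stop("actuals must align with prediction rows", call. = FALSE)
  if (is.null(colnames(pred)))
    colnames(pred) <- paste0("cand", seq_len(ncol(pred)))
  structure(list(pred = pred, actuals = as.numeric(actuals),
                 indices = indices),
            class = "prediction_matrix")
}

#' Simple average of candidate predictions
#'
#' The equal-weight combiner: the arithmetic mean of all candidate
#' predictions at one time point. Averaging across training windows hedges
#' against picking a single wrong window.
#'
#' @param row Numeric vector of candidate predictions at one time point.
#' @return The mean prediction.
#' @export
#' @examples
#' average_predict(c(1, 2, 3))  # 2
average_predict <- function(row) {
  if (length(row) == 0) stop("no candidate predictions", call. = FALSE)
  mean(row)
}

#' Per-candidate mean squared prediction error on validation rows
#'
#' @param pm A [prediction_matrix()].
#' @return Named numeric vector of MSPEs, one per candidate, in library
#'   (column) order.
#' @export
estimate_inner_mspe <- function(pm) {
  stopifnot(inherits(pm, "prediction_matrix"))
  colMeans((pm$actuals - pm$pred)^2)
}

#' Discrete super learner: the cross-validation selector
#'
#' Selects the candidate with the lowest estimated MSPE. Ties are broken by
#' library order (the order of the names in `inner_mspe`).
#'
#' @param inner_mspe Named numeric vector of per-candidate MSPEs.
#' @return The selected candidate label.
#' @export
fit_discrete_sl <- function(inner_mspe) {
  if (length(inner_mspe) == 0) stop("empty candidate map", call. = FALSE)
  names(inner_mspe)[which.min(inner_mspe)]
}

# squared-error objective of simplex weights w on a prediction matrix
esl_objective <- function(w, pred, actuals) sum((actuals - pred %*% w)^2)

#' Ensemble super learner: convex combination of candidates
#'
#' Finds weights on the unit simplex (non-negative, summing to one)
#' minimizing the squared prediction error over the validation rows,
#' \deqn{\min_{\omega \in \Delta^{K-1}} \sum_v \big(y_v - \textstyle\sum_k
#'   \omega_k \hat y_v^{(k)}\big)^2.}
#'
#' Two solvers are available. `"qp"` (default) solves the simplex-constrained
#' least-squares problem exactly as a quadratic program, which guarantees the
#' ensemble's in-sample objective is no worse than any single candidate's.
#' `"nnls"` is the classical meta-learner: non-negative least squares followed
#' by normalization to sum one; it is guarded so that if the normalized
#' solution is worse than the best single candidate, that candidate's vertex
#' solution is returned instead (preserving the same guarantee).
#'
#' If all candidates produce identical predictions the problem is degenerate
#' and uniform weights are returned with a message.
#'
#' @param pm A [prediction_matrix()].
#' @param solver `"qp"` or `"nnls"`.
#' @return An object of class `superlearner_fit`: list with `weights` (named,
#'   on the simplex), `selected` (the discrete super learner's choice) and
#'   `inner_mspe`.
#' @export
fit_ensemble_sl <- function(pm, solver = c("qp", "nnls")) {
  stopifnot(inherits(pm, "prediction_matrix"))
  solver <- match.arg(solver)
  P <- pm$pred
  yv <- pm$actuals
  K <- ncol(P)
  inner_mspe <- estimate_inner_mspe(pm)
  selected <- fit_discrete_sl(inner_mspe)

  if (K == 1L) {
    w <- setNames(1, colnames(P))
  } else if (max(apply(P, 1, function(r) diff(range(r)))) < 1e-12) {
    message("all candidates identical; returning uniform weights")
    w <- setNames(rep(1 / K, K), colnames(P))
  } else {
    w <- switch(solver, qp = esl_solve_qp(P, yv), nnls = esl_solve_nnls(P, yv))
    # guard: never worse in-sample than the best single candidate
    vertex <- which.min(inner_mspe)
    w_vertex <- replace(rep(0, K), vertex, 1)
    if (esl_objective(w, P, yv) > esl_objective(w_vertex, P, yv)) w <- w_vertex
    names(w) <- colnames(P)
  }
  structure(list(weights = w, selected = selected, inner_mspe = inner_mspe),
            class = "superlearner_fit")
}

esl_solve_qp <- function(P, yv) {
  K <- ncol(P)
  C <- crossprod(P)
  # tiny jitter keeps the QP solvable when candidates are nearly collinear
  C <- C + 1e-10 * mean(diag(C)) * diag(K)
  d <- as.vector(-crossprod(P, yv))
  sol <- tryCatch(
    pracma::quadprog(C, d, Aeq = matrix(1, 1, K), beq = 1, lb = rep(0, K)),
    error = function(e) NULL)
  if (is.null(sol)) return(esl_solve_nnls(P, yv))
  w <- pmax(sol$xmin, 0)
  w / sum(w)
}

esl_solve_nnls <- function(P, yv) {
  w <- tryCatch(pracma::lsqnonneg(P, yv)$x, error = function(e) rep(0, ncol(P)))
  if (sum(w) <= 0) return(rep(1 / ncol(P), ncol(P)))
  w / sum(w)
}

#' Predict with a fitted combiner
#'
#' Dispatches one of the three combination rules on a row of candidate
#' predictions: equal-weight average, the discrete super learner's selected
#' candidate, or the ensemble super learner's weighted sum.
#'
#' @param fit A [fit_ensemble_sl()] result (ignored for `method = "avg"`).
#' @param method `"avg"`, `"dsl"` or `"esl"`.
#' @param candidate_row Named numeric vector of candidate predictions at the
#'   point being predicted; names must cover the fit's candidates.
#' @return The combined prediction.
#' @export
predict_with_fit <- function(fit, method = c("avg", "dsl", "esl"),
                             candidate_row) {
  method <- match.arg(method)
  if (method == "avg") return(average_predict(candidate_row))
  stopifnot(inherits(fit, "superlearner_fit"))
  labs <- names(fit$weights)
  if (!all(labs %in% names(candidate_row)))
    stop("candidate_row labels do not match the fit", call. = FALSE)
  switch(method,
    dsl = unname(candidate_row[[fit$selected]]),
    esl = sum(fit$weights * candidate_row[labs]))
}
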