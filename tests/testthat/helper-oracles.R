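# Independent reference implementations used as oracles. These deliberately
# re-derive everything with plain loops and textbook formulas rather than
# calling into the package's engine.

# OLS prediction by explicit normal equations (X'X)^{-1} X'y.
normal_equations_predict <- function(yw, Xw, xnew, intercept = TRUE) {
  A <- if (intercept) cbind(1, Xw) else Xw
  an <- if (intercept) c(1, xnew) else xnew
  beta <- solve(crossprod(A), crossprod(A, yw))
  drop(an %*% beta)
}

# Naive nested forward validation: loops over outer folds, refits every
# candidate from scratch at every inner and outer point. Mirrors the
# documented contracts (burn-in ceil(0.30 T), inner validation from
# ceil(0.30 tau) + 1 through tau, dSL ties to first minimum, forecasts
# clipped to the past outcome range) without sharing any engine code.
naive_forward_validation <- function(y, X, specs, beeps,
                                     intercept = TRUE, clip = TRUE,
                                     rolling_days = 1) {
  T_len <- length(y)
  labels <- vapply(specs, function(s) s$label, "")
  win_size <- function(spec, t) {
    switch(spec$kind,
           expanding   = t,
           fixed_count = spec$value,
           last_n_days = spec$value * beeps,
           fraction    = max(1, floor(spec$value * T_len)))
  }
  pred_at <- function(v, spec) {
    w <- win_size(spec, v - 1)
    idx <- max(1, v - w):(v - 1)
    ph <- normal_equations_predict(y[idx], X[idx, , drop = FALSE], X[v, ],
                                   intercept)
    if (clip) {
      past <- y[1:(v - 1)]
      ph <- min(max(ph, min(past)), max(past))
    }
    ph
  }
  burn <- ceiling(0.30 * T_len)
  outer <- (burn + 1):T_len
  methods <- c(labels, "avg", "dsl", "rolling_mean")
  preds <- matrix(NA_real_, length(outer), length(methods),
                  dimnames = list(NULL, methods))
  for (i in seq_along(outer)) {
    o <- outer[i]
    tau <- o - 1
    cand <- vapply(specs, function(s) pred_at(o, s), numeric(1))
    preds[i, labels] <- cand
    vr <- (ceiling(0.30 * tau) + 1):tau
    inner_mspe <- vapply(specs, function(s) {
      mean(vapply(vr, function(v) (y[v] - pred_at(v, s))^2, numeric(1)))
    }, numeric(1))
    sel <- which(inner_mspe == min(inner_mspe))[1]
    preds[i, "avg"] <- sum(cand) / length(cand)
    preds[i, "dsl"] <- cand[sel]
    w <- rolling_days * beeps
    preds[i, "rolling_mean"] <- mean(y[max(1, tau - w + 1):tau])
  }
  sq <- (y[outer] - preds)^2
  list(outer_points = outer, predictions = preds, sq_error = sq,
       mspe = colMeans(sq))
}

# Dense grid search over the 2-simplex at the given step (K = 3 only).
grid_search_simplex3 <- function(P, y, step = 0.01) {
  best <- Inf
  for (a in seq(0, 1, step)) {
    for (b in seq(0, 1 - a + 1e-12, step)) {
      w <- c(a, b, 1 - a - b)
      o <- sum((y - P %*% w)^2)
      if (o < best) best <- o
    }
  }
  best
}

# Small well-conditioned dataset for engine tests: p = 2 so even the
# shortest inner windows keep the OLS design full rank.
make_small_dataset <- function(T_len = 40, p = 2, rate = 0.5, seed = 42,
                               snr = 4, beeps = 4) {
  n_days <- T_len / beeps
  simulate_dataset(dgp_config(n_days, beeps, rate, n_covariates = p,
                              snr = snr, seed = seed))
}
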