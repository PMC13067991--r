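#' Configuration for the time-varying linear data-generating process
#'
#' Bundles the design parameters of a simulated intensive-longitudinal study:
#' its duration, sampling frequency, number of covariates, the rate of change
#' of the outcome-covariate relationship, and the noise model.
#'
#' The simulated outcome follows \deqn{y_t = x_t^\top \beta_t + \epsilon_t,}
#' where the coefficient vector \eqn{\beta_t} drifts along a sine curve (see
#' [generate_coefficient_paths()]) and \eqn{\epsilon_t \sim N(0, \sigma_t^2)}.
#'
#' @param n_days Number of study days (integer, >= 1).
#' @param beeps_per_day Number of assessments ("beeps") per day (integer, >= 1).
#'   Total series length is `n_days * beeps_per_day`.
#' @param rate Fraction of a full sine oscillation the true coefficients
#'   complete over the series, in \[0, 1\]. `rate = 0` gives a stationary
#'   (constant-coefficient) process; `rate = 1` a full cycle.
#' @param n_covariates Number of covariates `p` (default 4).
#' @param snr Signal-to-noise ratio, `Var(signal) / Var(noise)` at each time
#'   point (default 4, a strong-signal regime in which roughly 80% of the
#'   outcome variance is predictable and window choice matters). Used in
#'   `constant_snr` mode.
#' @param noise_variance_mode Either `"constant_snr"` (noise variance tracks
#'   the time-varying signal variance so the SNR is constant over time) or
#'   `"fixed_sigma"` (homoskedastic noise with standard deviation `sigma`).
#' @param sigma Noise standard deviation in `fixed_sigma` mode (default 1).
#' @param seed Integer RNG seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `dgp_config`.
#' @seealso [simulate_dataset()], [generate_coefficient_paths()]
#' @export
#' @examples
#' cfg <- dgp_config(n_days = 14, beeps_per_day = 6, rate = 0.5, seed = 1)
#' dat <- simulate_dataset(cfg)
#' length(dat$y)  # 84
dgp_config <- function(n_days, beeps_per_day, rate,
                       n_covariates = 4L, snr = 4,
                       noise_variance_mode = c("constant_snr", "fixed_sigma"),
                       sigma = 1, seed = 1L) {
  noise_variance_mode <- match.arg(noise_variance_mode)
  n_days <- as.integer(n_days)
  beeps_per_day <- as.integer(beeps_per_day)
  if (n_days < 1L || beeps_per_day < 1L)
    stop("n_days and beeps_per_day must be >= 1", call. = FALSE)
  if (rate < 0 || rate > 1)
    stop("rate must lie in [0, 1]", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(
    list(n_days = n_days, beeps_per_day = beeps_per_day,
         n_covariates = as.integer(n_covariates), rate = rate, snr = snr,
         noise_variance_mode = noise_variance_mode, sigma = sigma,
         seed = as.integer(seed)),
    class = "dgp_config")
}

#' Total series length of a study design
#'
#' @param n_days Number of study days.
#' @param beeps_per_day Assessments per day.
#' @return `n_days * beeps_per_day` as an integer.
#' @export
#' @examples
#' dataset_length(14, 6)   # 84
#' dataset_length(56, 12)  # 672
dataset_length <- function(n_days, beeps_per_day) {
  stopifnot(n_days >= 1, beeps_per_day >= 1)
  as.integer(n_days) * as.integer(beeps_per_day)
}

#' Sine-varying coefficient paths
#'
#' Generates the true coefficient trajectories
#' \deqn{\beta_{t,j} = 0.5 + 0.5 \sin\!\big(2\pi\, \mathrm{rate}\,(t-1)/(T-1)
#'   + \phi_j\big),}
#' so every coefficient is bounded in \[0, 1\] and completes `rate` full
#' oscillations over the series. Each coefficient gets its own phase offset
#' \eqn{\phi_j}, drawn uniformly on \eqn{[0, 2\pi)} from the seeded RNG, so
#' the columns are not collinear over time. With `rate = 0` every column is
#' constant at its phase-determined level.
#'
#' @param rate Oscillation fraction in \[0, 1\].
#' @param T_len Series length (>= 2).
#' @param p Number of coefficients (>= 1).
#' @param seed Integer seed used to draw the phases (ignored when `phases`
#'   is supplied).
#' @param phases Optional numeric vector of `p` phase offsets in radians;
#'   bypasses the RNG.
#' @return An object of class `coef_path`: a list with `beta` (a `T_len` x
#'   `p` matrix) and `phases`.
#' @export
#' @examples
#' cp <- generate_coefficient_paths(rate = 0.5, T_len = 3, p = 1, phases = 0)
#' cp$beta[, 1]  # 0.5, 1.0, 0.5
generate_coefficient_paths <- function(rate, T_len, p, seed = 1L,
                                       phases = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (T_len < 2) stop("T_len must be >= 2", call. = FALSE)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (is.null(phases)) {
    set.seed(as.integer(seed))
    phases <- runif(p, 0, 2 * pi)
  }
  stopifnot(length(phases) == p)
  tt <- (seq_len(T_len) - 1) / (T_len - 1)
  beta <- 0.5 + 0.5 * sin(outer(2 * pi * rate * tt, phases, `+`))
  colnames(beta) <- paste0("beta", seq_len(p))
  structure(list(beta = beta, phases = phases), class = "coef_path")
}

#' Simulate a non-stationary time series dataset
#'
#' Draws covariates as independent standard normal variables and generates the
#' outcome from the time-varying linear model \eqn{y_t = x_t^\top \beta_t +
#' \epsilon_t}. In `constant_snr` mode the noise variance at time `t` is
#' \eqn{\sigma_t^2 = \sum_j \beta_{t,j}^2 / \mathrm{snr}} — the signal
#' variance for unit-variance independent covariates divided by the target
#' SNR — so the signal-to-noise ratio is the same at every time point even
#' though the coefficients (and hence the signal variance) drift. In
#' `fixed_sigma` mode \eqn{\sigma_t \equiv \sigma}.
#'
#' The RNG is seeded once from `config$seed`; phases, covariates and noise are
#' drawn from that single stream, so a given config reproduces bit-identically.
#'
#' @param config A [dgp_config()] object.
#' @return An object of class `ts_dataset`: list with `y` (length-`T`
#'   outcome), `X` (`T x p` covariate matrix), `beta_true` (a `coef_path`),
#'   `sigma_t` (length-`T` noise SDs) and `meta` (the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  T_len <- dataset_length(config$n_days, config$beeps_per_day)
  p <- config$n_covariates
  path <- generate_coefficient_paths(config$rate, T_len, p,
                                     seed = config$seed)
  X <- matrix(rnorm(T_len * p), T_len, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  signal <- rowSums(X * path$beta)
  sigma_t <- switch(config$noise_variance_mode,
    constant_snr = sqrt(rowSums(path$beta^2) / config$snr),
    fixed_sigma  = rep(config$sigma, T_len))
  y <- signal + rnorm(T_len, 0, sigma_t)
  structure(
    list(y = y, X = X, beta_true = path, sigma_t = sigma_t, meta = config),
    class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<ts_dataset> T = %d (%d days x %d beeps), p = %d, rate = %g, %s\n",
    length(x$y), m$n_days, m$beeps_per_day, m$n_covariates, m$rate,
    if (m$noise_variance_mode == "constant_snr")
      sprintf("snr = %g", m$snr) else sprintf("sigma = %g", m$sigma)))
  invisible(x)
}

#' @export
as.data.frame.ts_dataset <- function(x, ...) {
  data.frame(t = seq_along(x$y), y = x$y, x$X, x$beta_true$beta,
             sigma_t = x$sigma_t)
}

#' Write / read a simulated dataset as tidy CSV
#'
#' Columns: `t`, `y`, `x1..xp`, `beta1..betap`, `sigma_t`. The read side
#' returns a plain list with `y` and `X` suitable for [run_outer_loop()];
#' true-coefficient columns are retained when present.
#'
#' @param dataset A `ts_dataset` (or compatible list).
#' @param path File path.
#' @return `read_dataset_csv` returns a list with `y`, `X`, and (if present)
#'   `beta_true`.
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  bcols <- grep("^beta[0-9]+$", names(df), value = TRUE)
  out <- list(y = df$y, X = as.matrix(df[xcols]))
  if (length(bcols)) out$beta_true <- as.matrix(df[bcols])
  out
}
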