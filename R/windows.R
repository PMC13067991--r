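#' Training-window specifications
#'
#' A window spec is a rule for how much recent data a candidate model trains
#' on. Four kinds are supported:
#' \describe{
#'   \item{`expanding`}{all data up to the current time point;}
#'   \item{`last_n_days`}{the most recent `value` days, i.e.
#'     `value * beeps_per_day` assessments;}
#'   \item{`fixed_count`}{the most recent `value` assessments;}
#'   \item{`fraction`}{the most recent `floor(value * series_length)`
#'     assessments (minimum 1), `value` in (0, 1\].}
#' }
#'
#' @param kind One of `"expanding"`, `"last_n_days"`, `"fixed_count"`,
#'   `"fraction"`.
#' @param value Window size parameter (see above); ignored for `expanding`.
#' @param label Short name; defaults to a descriptive label.
#' @return An object of class `window_spec`.
#' @export
#' @examples
#' window_spec("last_n_days", 1)
#' window_spec("fraction", 0.05)
window_spec <- function(kind = c("expanding", "last_n_days", "fixed_count",
                                 "fraction"),
                        value = NA_real_, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "fraction" && (is.na(value) || value <= 0 || value > 1))
    stop("fraction window needs 0 < value <= 1", call. = FALSE)
  if (kind == "fixed_count" &&
      (is.na(value) || value < 1 || value != round(value)))
    stop("fixed_count window needs an integer value >= 1", call. = FALSE)
  if (kind == "last_n_days" && (is.na(value) || value < 1))
    stop("last_n_days window needs value >= 1", call. = FALSE)
  if (is.null(label)) {
    label <- switch(kind,
      expanding   = "expanding",
      last_n_days = sprintf("last_%g_day%s", value, if (value == 1) "" else "s"),
      fixed_count = sprintf("count_%d", as.integer(value)),
      fraction    = sprintf("frac_%03d", as.integer(round(value * 100))))
  }
  structure(list(kind = kind, value = value, label = label),
            class = "window_spec")
}

#' Resolve a window rule to a concrete index range
#'
#' Training always ends at (and includes) time `t`; the model fitted on the
#' resolved range predicts `t + 1`. Nominal windows that would start before
#' the beginning of the series are truncated to start at index 1.
#'
#' @param spec A [window_spec()].
#' @param t Current time point (1-based); training uses indices `<= t`.
#' @param beeps_per_day Assessments per day (converts day-based windows to
#'   counts).
#' @param series_length Full series length `T` (resolves fraction windows).
#' @return An object of class `window_range`: list with `start`, `end`
#'   (both inclusive) and `size`.
#' @export
#' @examples
#' resolve_window(window_spec("expanding"), t = 6, 6, 84)          # (1, 6)
#' resolve_window(window_spec("fixed_count", 4), t = 6, 6, 84)     # (3, 6)
resolve_window <- function(spec, t, beeps_per_day, series_length) {
  stopifnot(inherits(spec, "window_spec"))
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  if (t > series_length) stop("t exceeds series_length", call. = FALSE)
  w <- switch(spec$kind,
    expanding   = t,
    fixed_count = as.integer(spec$value),
    last_n_days = as.integer(spec$value * beeps_per_day),
    fraction    = max(1L, floor(spec$value * series_length)))
  start <- max(1L, t - w + 1L)
  structure(list(start = as.integer(start), end = as.integer(t),
                 size = as.integer(t - start + 1L)),
            class = "window_range")
}

#' Build the candidate library of training windows
#'
#' Constructs the default library: fraction-of-series windows on a grid from
#' `frac_lo` to `frac_hi` in steps of `frac_step` (inclusive, stepped on
#' integer percents so floating-point drift cannot drop a grid point),
#' followed by the three standard heuristics — last one day, last two days,
#' and the expanding window — in that order. With the defaults (5% to 25% by
#' 1%) this yields 21 fraction windows and 24 candidates in total.
#'
#' Duplicate resolved sizes (e.g. a fraction window that happens to equal the
#' last-day window) are retained as distinct labelled candidates.
#'
#' @param series_length Full series length `T` (recorded for reference; the
#'   fraction windows are resolved against it at fit time).
#' @param beeps_per_day Assessments per day.
#' @param frac_lo,frac_hi,frac_step Fraction grid parameters.
#' @param standard Include the last-day / last-two-days / expanding windows
#'   (default `TRUE`).
#' @return A list of [window_spec()] objects, in library order (the order
#'   used for tie-breaking by the discrete super learner).
#' @export
#' @examples
#' length(build_candidate_library(84, 6))  # 24
build_candidate_library <- function(series_length, beeps_per_day,
                                    frac_lo = 0.05, frac_hi = 0.25,
                                    frac_step = 0.01, standard = TRUE) {
  if (frac_lo <= 0 || frac_lo > frac_hi || frac_step <= 0)
    stop("invalid fraction grid", call. = FALSE)
  # step on scaled integers to keep the grid exact
  scale <- 1 / frac_step
  grid <- seq(round(frac_lo * scale), round(frac_hi * scale)) / scale
  if (length(grid) == 0) stop("empty window grid", call. = FALSE)
  lib <- lapply(grid, function(q) window_spec("fraction", q))
  if (standard) {
    lib <- c(lib,
             list(window_spec("last_n_days", 1),
                  window_spec("last_n_days", 2),
                  window_spec("expanding")))
  }
  lib
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s (%s%s)\n", x$label, x$kind,
              if (is.na(x$value)) "" else sprintf(", value = %g", x$value)))
  invisible(x)
}

library_labels <- function(library) vapply(library, `[[`, "", "label")

#' Read a window-library block from a YAML config
#'
#' Expects a top-level `windows:` mapping with optional keys `frac_lo`,
#' `frac_hi`, `frac_step` and `standard` (logical), mirroring
#' [build_candidate_library()].
#'
#' @param path YAML file path.
#' @param series_length,beeps_per_day Passed through to
#'   [build_candidate_library()].
#' @return A list of [window_spec()] objects.
#' @export
read_windows_yaml <- function(path, series_length, beeps_per_day) {
  cfg <- yaml::read_yaml(path)
  w <- cfg$windows %||% list()
  build_candidate_library(
    series_length, beeps_per_day,
    frac_lo = w$frac_lo %||% 0.05,
    frac_hi = w$frac_hi %||% 0.25,
    frac_step = w$frac_step %||% 0.01,
    standard = w$standard %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
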