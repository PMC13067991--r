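#' Sensor event stream
#'
#' A long-format table of passive-sensing events: each row is one event with
#' a start time (hours since study start), a channel (e.g. an app category or
#' location class) and a duration in hours. Events are sorted by timestamp
#' within channel.
#'
#' @param timestamps Numeric event start times in hours.
#' @param channel Character channel identifiers.
#' @param value Numeric event durations in hours (non-negative).
#' @return An object of class `sensor_stream` (a data frame).
#' @export
sensor_stream <- function(timestamps, channel, value) {
  n <- length(timestamps)
  if (length(channel) == 1L) channel <- rep(channel, n)
  if (length(value) == 1L) value <- rep(value, n)
  stopifnot(length(channel) == n, length(value) == n)
  if (any(value < 0)) stop("event durations must be non-negative",
                           call. = FALSE)
  df <- data.frame(timestamp = as.numeric(timestamps),
                   channel = as.character(channel),
                   value = as.numeric(value))
  df <- df[order(df$channel, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sensor_stream", "data.frame")
  df
}

# overlap of event [ts, ts + dur) with window (a, b], clipped proportionally
event_overlap <- function(ts, dur, a, b) {
  pmax(0, pmin(ts + dur, b) - pmax(ts, a))
}

#' Aggregate sensor events into trailing-window features at EMA times
#'
#' For each questionnaire timestamp `s`, each channel and each aggregation
#' window of `h` hours, computes the total event duration falling in the
#' mode's interval:
#' \describe{
#'   \item{`detection`}{`(s - h, s]` — up to and including the beep;}
#'   \item{`time_shifted`}{`(s - h - gap, s - gap]` — ends `gap` hours before
#'     the beep, leaving room to intervene;}
#'   \item{`lagged`}{`(s_prev - h, s_prev]` — up to and including the
#'     previous beep (the first row, having no previous beep, is `NA`).}
#' }
#' Events spanning an interval boundary contribute their overlap duration.
#' No interval ever extends past its anchor, so features never use
#' information from after the moment they are attached to.
#'
#' @param stream A [sensor_stream()].
#' @param ema_times Sorted numeric questionnaire times (hours).
#' @param windows_hours Aggregation window lengths in hours
#'   (default `c(3, 6, 12, 24)`).
#' @param mode `"detection"`, `"time_shifted"` or `"lagged"`.
#' @param gap_hours Gap for `time_shifted` mode, in hours (default 1;
#'   must be non-negative).
#' @return An `aligned_design` data frame: column `ema_time` plus one feature
#'   column per (channel, window), named `<channel>_w<h>h`.
#' @export
aggregate_features <- function(stream, ema_times,
                               windows_hours = c(3, 6, 12, 24),
                               mode = c("detection", "time_shifted",
                                        "lagged"),
                               gap_hours = 1) {
  mode <- match.arg(mode)
  if (gap_hours < 0) stop("gap_hours must be non-negative", call. = FALSE)
  if (is.unsorted(ema_times))
    stop("ema_times must be sorted", call. = FALSE)
  channels <- sort(unique(stream$channel))
  if (length(channels) == 0 || nrow(stream) == 0)
    stop("empty sensor stream: no features to aggregate", call. = FALSE)

  anchors <- switch(mode,
    detection    = ema_times,
    time_shifted = ema_times - gap_hours,
    lagged       = c(NA_real_, ema_times[-length(ema_times)]))

  out <- data.frame(ema_time = ema_times)
  for (ch in channels) {
    ev <- stream[stream$channel == ch, , drop = FALSE]
    for (h in windows_hours) {
      col <- vapply(anchors, function(b) {
        if (is.na(b)) return(NA_real_)
        sum(event_overlap(ev$timestamp, ev$value, b - h, b))
      }, numeric(1))
      out[[sprintf("%s_w%gh", ch, h)]] <- col
    }
  }
  class(out) <- c("aligned_design", "data.frame")
  out
}

# Items defining the two affect composites (11-point 0-10 scale).
PA_ITEMS <- c("happy", "energetic", "relaxed")
NA_ITEMS <- c("sad", "anxious", "stressed", "irritated")

#' Positive- and negative-affect composites from EMA items
#'
#' Positive affect is the mean of the happy / energetic / relaxed items;
#' negative affect the mean of sad / anxious / stressed / irritated. All
#' items are scored 0-10. A row missing any constituent item yields a
#' missing composite (such rows are dropped downstream).
#'
#' @param records Long-format data frame with columns `timestamp`, `item`,
#'   `score`. Item names must come from the two composite sets; unknown
#'   names are an error.
#' @return Data frame with `timestamp`, `positive_affect`,
#'   `negative_affect`.
#' @export
#' @examples
#' r <- data.frame(timestamp = 0,
#'                 item = c("happy", "energetic", "relaxed"),
#'                 score = 6)
#' compute_affect_composites(r)$positive_affect  # 6
compute_affect_composites <- function(records) {
  stopifnot(all(c("timestamp", "item", "score") %in% names(records)))
  known <- c(PA_ITEMS, NA_ITEMS)
  bad <- setdiff(unique(records$item), known)
  if (length(bad))
    stop("unknown EMA item name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(records$score < 0 | records$score > 10, na.rm = TRUE))
    stop("scores must lie on the 0-10 scale", call. = FALSE)
  times <- sort(unique(records$timestamp))
  comp <- function(s, items) {
    sc <- records$score[records$timestamp == s &
                          records$item %in% items]
    if (length(sc) < length(items) || anyNA(sc)) return(NA_real_)
    mean(sc)
  }
  data.frame(
    timestamp = times,
    positive_affect = vapply(times, comp, numeric(1), items = PA_ITEMS),
    negative_affect = vapply(times, comp, numeric(1), items = NA_ITEMS))
}

#' Filter near-constant features and impute missing values
#'
#' Drops feature columns whose variance (over available values) falls below
#' `variance_threshold`, then imputes each remaining missing value with the
#' median of the *earlier* observed values in its column. Restricting the
#' median to past rows keeps the design usable for one-step-ahead evaluation:
#' a value imputed from the whole series would quietly carry future
#' information into the training data. Rows whose column has no past
#' observation remain missing.
#'
#' @param design An `aligned_design` (or plain data frame); columns named
#'   `ema_time` or ending in `_affect` are carried through untouched.
#' @param variance_threshold Minimum variance to keep a column
#'   (default `1e-8`).
#' @return The filtered, imputed design; dropped columns are reported via
#'   `message()`.
#' @export
preprocess_design <- function(design, variance_threshold = 1e-8) {
  meta_cols <- names(design)[names(design) == "ema_time" |
                               grepl("_affect$", names(design))]
  feat_cols <- setdiff(names(design), meta_cols)
  if (length(feat_cols) == 0)
    stop("design has no feature columns", call. = FALSE)
  vars <- vapply(design[feat_cols],
                 function(v) stats::var(v, na.rm = TRUE), numeric(1))
  drop <- feat_cols[is.na(vars) | vars < variance_threshold]
  keep <- setdiff(feat_cols, drop)
  if (length(keep) == 0)
    stop("all feature columns dropped by the variance filter", call. = FALSE)
  if (length(drop))
    message("dropping near-constant feature(s): ",
            paste(drop, collapse = ", "))
  out <- design[c(meta_cols, keep)]
  for (j in keep) {
    v <- out[[j]]
    for (i in which(is.na(v))) {
      past <- v[seq_len(i - 1L)]
      past <- past[!is.na(past)]
      if (length(past)) v[i] <- median(past)
    }
    out[[j]] <- v
  }
  class(out) <- class(design)
  out
}

#' Synthetic EMA + sensor fixture with known ground truth
#'
#' Generates, per participant, (a) Poisson-process sensor event streams for
#' `n_channels` channels and (b) EMA item responses whose affect composites
#' follow a time-varying linear function of the detection-mode aggregated
#' features, with sine-varying coefficients at the given rate plus Gaussian
#' noise. Because the items are generated from the same aggregation the
#' pipeline later performs, the full empirical-style pipeline has a known
#' coefficient path to recover.
#'
#' Beeps are placed between 09:00 and 21:00 each day. The composites are
#' `0.5 + f_t^T beta_t + noise`, clipped to the 0-10 response scale; with the
#' default event intensity the features stay small enough that clipping is
#' inactive. Each EMA item of a composite is set to that composite's value;
#' `round_items = TRUE` (default) rounds items to the integer 11-point scale,
#' `FALSE` keeps them continuous (useful for exact recovery checks).
#'
#' @param participants Number of participants.
#' @param days,beeps_per_day Study design.
#' @param n_channels Number of sensor channels (0 gives an EMA-only fixture
#'   whose feature aggregation then fails cleanly).
#' @param rate Coefficient oscillation rate in \[0, 1\].
#' @param noise_sd Composite noise standard deviation (0 = noiseless).
#' @param window_hours Detection window used to generate the truth
#'   (default 3).
#' @param events_per_hour Poisson intensity of sensor events per channel.
#' @param round_items Round item scores to integers (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `sensors` (participant, timestamp, channel, value),
#'   `ema` (participant, timestamp, item, score) and `truth` (per
#'   participant: the `beta` paths for both composites and the generating
#'   feature matrix).
#' @export
generate_ema_fixture <- function(participants = 1, days = 28,
                                 beeps_per_day = 5, n_channels = 3,
                                 rate = 0, noise_sd = 0.5,
                                 window_hours = 3, events_per_hour = 0.4,
                                 round_items = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  horizon <- days * 24
  sensors <- list(); ema <- list(); truth <- list()
  beep_hours <- 9 + (seq_len(beeps_per_day) - 1) *
    (12 / max(1, beeps_per_day - 1))
  if (beeps_per_day == 1) beep_hours <- 15
  for (pid in seq_len(participants)) {
    ema_times <- as.vector(outer(beep_hours, (seq_len(days) - 1) * 24, `+`))
    ema_times <- sort(ema_times)
    T_len <- length(ema_times)

    if (n_channels > 0) {
      sens <- do.call(rbind, lapply(seq_len(n_channels), function(ch) {
        n_ev <- rpois(1, events_per_hour * horizon)
        data.frame(participant = pid,
                   timestamp = sort(runif(n_ev, 0, horizon)),
                   channel = sprintf("ch%02d", ch),
                   value = runif(n_ev, 0.1, 0.9))
      }))
      stream <- sensor_stream(sens$timestamp, sens$channel, sens$value)
      feats <- aggregate_features(stream, ema_times,
                                  windows_hours = window_hours,
                                  mode = "detection")
      Fm <- as.matrix(feats[-1])
    } else {
      sens <- data.frame(participant = integer(0), timestamp = numeric(0),
                         channel = character(0), value = numeric(0))
      Fm <- matrix(0, T_len, 0)
    }

    p <- max(1L, n_channels)
    beta_pa <- generate_coefficient_paths(rate, T_len, p,
                                          seed = seed + 101L * pid)$beta
    beta_na <- generate_coefficient_paths(rate, T_len, p,
                                          seed = seed + 101L * pid + 50L)$beta
    lin <- function(B) {
      if (n_channels == 0) return(rep(0.5, T_len))
      0.5 + rowSums(Fm * B)
    }
    y_pa <- pmin(10, pmax(0, lin(beta_pa) + rnorm(T_len, 0, noise_sd)))
    y_na <- pmin(10, pmax(0, lin(beta_na) + rnorm(T_len, 0, noise_sd)))

    item_rows <- do.call(rbind, c(
      lapply(PA_ITEMS, function(it)
        data.frame(participant = pid, timestamp = ema_times, item = it,
                   score = if (round_items) round(y_pa) else y_pa)),
      lapply(NA_ITEMS, function(it)
        data.frame(participant = pid, timestamp = ema_times, item = it,
                   score = if (round_items) round(y_na) else y_na))))

    sensors[[pid]] <- sens
    ema[[pid]] <- item_rows
    truth[[pid]] <- list(beta_pa = beta_pa, beta_na = beta_na,
                         features = Fm, ema_times = ema_times)
  }
  list(sensors = do.call(rbind, sensors), ema = do.call(rbind, ema),
       truth = truth)
}

#' Read long-format sensor / EMA CSVs
#'
#' Sensor CSV columns: `timestamp`, `channel`, `value` (optionally
#' `participant`). EMA CSV columns: `timestamp`, `item`, `score`
#' (optionally `participant`).
#'
#' @param path CSV file path.
#' @return `read_sensor_csv`: a [sensor_stream()] (participant column, if
#'   any, is preserved as an attribute); `read_ema_csv`: a data frame.
#' @export
read_sensor_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("timestamp", "channel", "value") %in% names(df)))
  out <- sensor_stream(df$timestamp, df$channel, df$value)
  if ("participant" %in% names(df))
    attr(out, "participant") <- df$participant
  out
}

#' @rdname read_sensor_csv
#' @export
read_ema_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("timestamp", "item", "score") %in% names(df)))
  df
}
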