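#' Post-processing configuration
#'
#' Controls the voting window over per-frame predictions and the
#' tolerance-based assembly of events into activities. Frames arrive every
#' 0.5 s (1-second clips, 50% overlap), so the default 7-frame window spans
#' 3.5 s and the default continuous tolerance of 10 windows spans 5 s; the
#' instant tolerance defaults to 4 counts.
#'
#' @param threshold Per-frame probability threshold.
#' @param window_size Voting window length in frames; odd, >= 3.
#' @param tolerance_continuous,tolerance_instant Number of consecutive
#'   event-absent windows tolerated before an open activity closes.
#' @param min_duration,min_confidence Log-filtering floors (see
#'   [filter_logs()]).
#' @param event_types Named map label -> `"continuous"`/`"instant"`.
#' @return A `post_config` list.
#' @export
post_config <- function(threshold = 0.5, window_size = 7L,
                        tolerance_continuous = 10L, tolerance_instant = 4L,
                        min_duration = 0, min_confidence = 0,
                        event_types = adl_event_types()) {
  stopifnot(
    window_size >= 3L, window_size %% 2L == 1L,
    tolerance_continuous >= 0L, tolerance_instant >= 0L,
    threshold >= 0, threshold <= 1
  )
  structure(
    list(
      threshold = threshold, window_size = as.integer(window_size),
      tolerance_continuous = as.integer(tolerance_continuous),
      tolerance_instant = as.integer(tolerance_instant),
      min_duration = min_duration, min_confidence = min_confidence,
      event_types = event_types
    ),
    class = "post_config"
  )
}

check_prediction_stream <- function(predictions) {
  stopifnot(is.data.frame(predictions), "time" %in% names(predictions))
  if (is.unsorted(predictions$time, strictly = TRUE)) {
    stop("prediction frames must have strictly increasing timestamps",
      call. = FALSE
    )
  }
  setdiff(names(predictions), "time")
}

#' Sliding voting windows over a prediction stream
#'
#' The first window is emitted once `window_size` frames have arrived;
#' thereafter the window slides by one frame, so a stream of n frames yields
#' `n - window_size + 1` windows (zero when the buffer never fills).
#'
#' @param predictions Tibble with a `time` column (strictly increasing,
#'   nominally 0.5 s apart) and one probability column per label.
#' @param window_size Window length in frames.
#' @return List of window tibbles, each of `window_size` rows.
#' @export
stream_windows <- function(predictions, window_size = 7L) {
  check_prediction_stream(predictions)
  n <- nrow(predictions)
  if (n < window_size) {
    return(list())
  }
  purrr::map(
    seq_len(n - window_size + 1L),
    ~ predictions[.x:(.x + window_size - 1L), , drop = FALSE]
  )
}

#' Per-label voting decision on one full window
#'
#' Each label is judged independently, so multiple labels may co-occur in one
#' window. For a continuous label the event occurred iff the number of frames
#' with probability above the threshold strictly exceeds half the window
#' size, and the confidence is the mean probability over the whole buffer.
#' For an instant label a single supra-threshold frame suffices, and the
#' confidence is the mean of only the supra-threshold probabilities.
#'
#' @param window One window tibble from [stream_windows()].
#' @param config A [post_config()].
#' @return Tibble with one row per label: `label`, `kind`, `count`,
#'   `occurred`, `confidence`, `window_time` (time of the newest frame).
#' @export
#' @examples
#' w <- tibble::tibble(
#'   time = seq(0.5, 3.5, by = 0.5),
#'   watering1 = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.1, 0.1)
#' )
#' vote(w, post_config())
vote <- function(window, config = post_config()) {
  labels <- check_prediction_stream(window)
  stopifnot(nrow(window) == config$window_size)
  p <- as.matrix(window[, labels, drop = FALSE])
  kinds <- config$event_types[labels]
  counts <- colSums(p > config$threshold)
  occurred <- logical(length(labels))
  confidence <- numeric(length(labels))
  for (j in seq_along(labels)) {
    if (identical(unname(kinds[j]), "instant")) {
      occurred[j] <- counts[j] >= 1L
      confidence[j] <- if (occurred[j]) {
        mean(p[p[, j] > config$threshold, j])
      } else {
        0
      }
    } else {
      occurred[j] <- counts[j] > config$window_size / 2
      confidence[j] <- if (occurred[j]) mean(p[, j]) else 0
    }
  }
  tibble::tibble(
    label = labels,
    kind = unname(kinds),
    count = as.integer(counts),
    occurred = occurred,
    confidence = confidence,
    window_time = window$time[nrow(window)]
  )
}

#' Voting over a whole prediction stream
#'
#' Applies [vote()] to every sliding window. Because consecutive windows
#' overlap, the same supra-threshold frame of an instant label would be
#' counted up to `window_size` times; an instant occurrence is therefore
#' attributed once, at the first window containing it (tracked by frame
#' index), and suppressed afterwards.
#'
#' @inheritParams stream_windows
#' @param config A [post_config()].
#' @return Tibble of event records ordered by `window_time` then `label`.
#' @export
vote_stream <- function(predictions, config = post_config()) {
  labels <- check_prediction_stream(predictions)
  n <- nrow(predictions)
  ws <- config$window_size
  if (n < ws) {
    return(tibble::tibble(
      label = character(), kind = character(), count = integer(),
      occurred = logical(), confidence = double(), window_time = double()
    ))
  }
  p <- as.matrix(predictions[, labels, drop = FALSE])
  kinds <- config$event_types[labels]
  consumed <- purrr::map(labels, ~ logical(n))
  names(consumed) <- labels

  out <- vector("list", n - ws + 1L)
  for (w in seq_len(n - ws + 1L)) {
    idx <- w:(w + ws - 1L)
    pw <- p[idx, , drop = FALSE]
    counts <- colSums(pw > config$threshold)
    occurred <- logical(length(labels))
    confidence <- numeric(length(labels))
    for (j in seq_along(labels)) {
      if (identical(unname(kinds[j]), "instant")) {
        supra <- idx[pw[, j] > config$threshold]
        new <- supra[!consumed[[labels[j]]][supra]]
        occurred[j] <- length(new) > 0L
        if (occurred[j]) {
          confidence[j] <- mean(p[supra, j])
          consumed[[labels[j]]][supra] <- TRUE
        }
      } else {
        occurred[j] <- counts[j] > ws / 2
        if (occurred[j]) confidence[j] <- mean(pw[, j])
      }
    }
    out[[w]] <- tibble::tibble(
      label = labels,
      kind = unname(kinds),
      count = as.integer(counts),
      occurred = occurred,
      confidence = confidence,
      window_time = predictions$time[idx[ws]]
    )
  }
  dplyr::bind_rows(out)
}

#' Assemble voted events into activity records
#'
#' Per label: an activity opens at the first occurred event (start time =
#' that window's time), accumulates the event count and summed confidence on
#' every occurred window and resets its tolerance counter; every non-occurred
#' window decrements the counter, and when it drops below zero the activity
#' closes with end time = the last occurred window's time, duration =
#' end - start, and confidence = summed confidence / event count. The end of
#' the stream flushes open activities.
#'
#' @param events Event records from [vote_stream()] (or [vote()] rows),
#'   ordered by `window_time`.
#' @param config A [post_config()].
#' @param location Node location string attached to each record.
#' @return Tibble of activity records: `label`, `start_time`, `end_time`,
#'   `duration`, `location`, `confidence`, `event_count`.
#' @export
accumulate_activities <- function(events, config = post_config(),
                                  location = "unknown") {
  stopifnot(is.data.frame(events))
  empty <- tibble::tibble(
    label = character(), start_time = double(), end_time = double(),
    duration = double(), location = character(), confidence = double(),
    event_count = integer()
  )
  if (nrow(events) == 0) {
    return(empty)
  }
  if (is.unsorted(events$window_time)) {
    stop("events must be ordered by window_time", call. = FALSE)
  }
  records <- list()
  for (lab in unique(events$label)) {
    ev <- events[events$label == lab, , drop = FALSE]
    kind <- ev$kind[1]
    tol0 <- if (identical(kind, "instant")) {
      config$tolerance_instant
    } else {
      config$tolerance_continuous
    }
    open <- FALSE
    start <- NA_real_
    last <- NA_real_
    count <- 0L
    sum_conf <- 0
    tol <- tol0
    close_activity <- function() {
      tibble::tibble(
        label = lab, start_time = start, end_time = last,
        duration = last - start, location = location,
        confidence = sum_conf / count, event_count = count
      )
    }
    for (i in seq_len(nrow(ev))) {
      if (ev$occurred[i]) {
        if (!open) {
          open <- TRUE
          start <- ev$window_time[i]
          count <- 0L
          sum_conf <- 0
        }
        count <- count + 1L
        sum_conf <- sum_conf + ev$confidence[i]
        last <- ev$window_time[i]
        tol <- tol0
      } else if (open) {
        tol <- tol - 1L
        if (tol < 0L) {
          records[[length(records) + 1L]] <- close_activity()
          open <- FALSE
          tol <- tol0
        }
      }
    }
    if (open) records[[length(records) + 1L]] <- close_activity()
  }
  out <- dplyr::bind_rows(records)
  if (nrow(out) == 0) {
    return(empty)
  }
  dplyr::arrange(out, .data$start_time, .data$label)
}

#' Filter an activity log
#'
#' Drops records with too short a duration, too low a confidence, or a label
#' that cannot occur at the node's location (e.g., no TV in a bathroom).
#' Order is preserved.
#'
#' @param records Activity records from [accumulate_activities()].
#' @param config A [post_config()] providing `min_duration` and
#'   `min_confidence`.
#' @param allowed_labels Labels permitted at this node's location; `NULL`
#'   allows everything.
#' @return Filtered activity tibble.
#' @export
filter_logs <- function(records, config = post_config(),
                        allowed_labels = NULL) {
  stopifnot(is.data.frame(records))
  keep <- records$duration >= config$min_duration &
    records$confidence >= config$min_confidence
  if (!is.null(allowed_labels)) {
    keep <- keep & records$label %in% allowed_labels
  }
  records[keep, , drop = FALSE]
}

#' Plot an activity log against optional ground truth
#'
#' @param log Activity tibble (columns `label`, `start_time`, `end_time`).
#' @param truth Optional ground-truth tibble (`label`, `start`, `end`).
#' @return A ggplot object.
#' @export
plot_activity_log <- function(log, truth = NULL) {
  gg <- ggplot2::ggplot(log) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start_time, xend = .data$end_time,
        y = .data$label, yend = .data$label, color = .data$confidence
      ),
      linewidth = 4
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "activity log")
  if (!is.null(truth)) {
    gg <- gg + ggplot2::geom_segment(
      data = truth,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$label, yend = .data$label
      ),
      linewidth = 1, color = "black"
    )
  }
  gg
}
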