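#' Per-location label exclusions
#'
#' Some labels cannot occur at some locations (no TV in a bathroom); the hub
#' drops them from that node's logs. The table is a plain named list and can
#' be edited or loaded from YAML.
#'
#' @return Named list: location -> labels excluded there.
#' @export
location_exclusions <- function() {
  list(bathroom = c("tv", "microwave", "cooking"))
}

#' Node configuration
#'
#' Describes one edge node: its name, location, which labels its location
#' admits, and the capture/post-processing parameters it runs with.
#'
#' @param name Node name.
#' @param location Location string (nonempty); used for location-based label
#'   exclusion and attached to every activity record.
#' @param allowed_labels Labels this node may log; defaults to all labels
#'   minus the [location_exclusions()] entry for `location`.
#' @param wake_threshold,stop_silence_s Capture gating parameters (see
#'   [gate_stream()]).
#' @param post A [post_config()].
#' @return A `node_config` object.
#' @export
node_config <- function(name = "node1", location = "bathroom",
                        allowed_labels = NULL, wake_threshold = 0.01,
                        stop_silence_s = 5, post = post_config()) {
  stopifnot(nzchar(location))
  if (is.null(allowed_labels)) {
    allowed_labels <- setdiff(
      adl_labels(),
      location_exclusions()[[location]]
    )
  }
  bad <- setdiff(allowed_labels, adl_labels())
  if (length(bad)) {
    stop("allowed_labels outside the class list: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      name = name, location = location, allowed_labels = allowed_labels,
      wake_threshold = wake_threshold, stop_silence_s = stop_silence_s,
      post = post
    ),
    class = "node_config"
  )
}

#' Read/write a node configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_node_config()`: a [node_config()].
#' @export
read_node_config <- function(path) {
  y <- yaml::read_yaml(path)
  post_args <- y$post
  if (!is.null(post_args$event_types)) {
    post_args$event_types <- unlist(post_args$event_types)
  }
  node_config(
    name = y$name %||% "node1",
    location = y$location %||% "unknown",
    allowed_labels = unlist(y$allowed_labels),
    wake_threshold = y$wake_threshold %||% 0.01,
    stop_silence_s = y$stop_silence_s %||% 5,
    post = do.call(post_config, post_args %||% list())
  )
}

#' @param node A [node_config()].
#' @rdname read_node_config
#' @export
write_node_config <- function(node, path) {
  yaml::write_yaml(
    list(
      name = node$name, location = node$location,
      allowed_labels = node$allowed_labels,
      wake_threshold = node$wake_threshold,
      stop_silence_s = node$stop_silence_s,
      post = list(
        threshold = node$post$threshold,
        window_size = node$post$window_size,
        tolerance_continuous = node$post$tolerance_continuous,
        tolerance_instant = node$post$tolerance_instant,
        min_duration = node$post$min_duration,
        min_confidence = node$post$min_confidence,
        event_types = as.list(node$post$event_types)
      )
    ),
    path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full per-node pipeline on a recording
#'
#' Executes the node's processing chain: energy gating, 1-second framing at a
#' 0.5 s hop within each active segment, log-Mel feature extraction,
#' classification (float or emulated int8), voting, tolerance accumulation,
#' and location filtering. Frame times are the centers of the one-second
#' clips, in seconds from the start of the recording. Deterministic given the
#' model.
#'
#' @param wav Path to a 16 kHz mono PCM16 WAV file, or an [audio_clip()].
#' @param node A [node_config()].
#' @param model A trained `adl_cnn` or `adl_cnn_quant`.
#' @return Activity log tibble (see [accumulate_activities()]).
#' @export
run_node <- function(wav, node, model) {
  if (!inherits(model, c("adl_cnn", "adl_cnn_quant"))) {
    stop("a trained model is required", call. = FALSE)
  }
  stopifnot(inherits(node, "node_config"))
  clip <- if (inherits(wav, "audio_clip")) wav else read_wav(wav)
  segments <- gate_stream(clip, node$wake_threshold, node$stop_silence_s)
  logs <- purrr::pmap(segments, function(start_sample, length) {
    if (length < 16000L) {
      return(NULL)
    }
    seg <- extract_segment(clip, start_sample, length)
    preds <- predict_stream(seg, model, t0 = start_sample / 16000)
    events <- vote_stream(preds, node$post)
    accumulate_activities(events, node$post, location = node$location)
  })
  log <- dplyr::bind_rows(logs)
  if (nrow(log) == 0) {
    return(accumulate_activities(
      tibble::tibble(
        label = character(), kind = character(),
        occurred = logical(), confidence = double(), window_time = double()
      ),
      node$post, node$location
    ))
  }
  filter_logs(
    dplyr::arrange(log, .data$start_time, .data$label),
    node$post, node$allowed_labels
  )
}

#' Per-frame predictions over a continuous clip
#'
#' Slides 1-second clips at a 0.5 s hop over the signal and classifies each,
#' producing the prediction stream the post-processor consumes. The trailing
#' partial second is dropped. Frame time = clip center + `t0`.
#'
#' @param clip An [audio_clip()] of duration >= 1 s.
#' @param model A trained `adl_cnn` or `adl_cnn_quant`.
#' @param t0 Offset of the clip start in stream seconds.
#' @return Tibble with `time` and one probability column per class.
#' @export
predict_stream <- function(clip, model, t0 = 0) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  stopifnot(n >= 16000L)
  starts <- seq(0L, n - 16000L, by = 8000L)
  feats <- purrr::map(starts, function(s) {
    clip_mel(clip$samples[(s + 1L):(s + 16000L)])
  })
  probs <- predict(model, feats, type = "prob")
  dplyr::bind_cols(
    tibble::tibble(time = t0 + starts / 16000 + 0.5),
    probs
  )
}

#' Merge per-node activity logs chronologically
#'
#' Stable merge of per-node logs sharing a common time base, ordered by start
#' time with ties broken by (location, label). No records are created or
#' lost.
#'
#' @param logs List of activity tibbles (each with a `location` column).
#' @return One household-level activity tibble.
#' @export
merge_logs <- function(logs) {
  stopifnot(is.list(logs), length(logs) >= 1L)
  for (lg in logs) {
    if (!is.data.frame(lg) || !all(c("start_time", "location") %in%
      names(lg)) || !is.numeric(lg$start_time)) {
      stop("every log needs a numeric start_time and a location column",
        call. = FALSE
      )
    }
  }
  dplyr::bind_rows(logs) |>
    dplyr::arrange(.data$start_time, .data$location, .data$label)
}

#' Score an activity log against ground truth
#'
#' Event-level precision/recall/F1: a truth interval counts as detected if a
#' same-label activity overlaps it by at least `overlap_fraction` of the
#' truth duration, with one-to-one greedy matching by overlap. The
#' `"background"` null class is ignored by default (truth scripts do not
#' contain it).
#'
#' @param log Activity tibble (`label`, `start_time`, `end_time`).
#' @param truth Ground-truth tibble (`label`, `start`, `end`).
#' @param overlap_fraction Required overlap as a fraction of the truth
#'   interval's duration.
#' @param ignore_labels Labels excluded from scoring.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_log <- function(log, truth, overlap_fraction = 0.5,
                      ignore_labels = "background") {
  stopifnot(is.data.frame(log), is.data.frame(truth))
  log <- log[!log$label %in% ignore_labels, , drop = FALSE]
  truth <- truth[!truth$label %in% ignore_labels, , drop = FALSE]
  tp <- 0L
  matched_log <- 0L
  for (lab in unique(truth$label)) {
    tr <- truth[truth$label == lab, , drop = FALSE]
    lg <- log[log$label == lab, , drop = FALSE]
    if (nrow(lg) == 0) next
    ov <- outer(seq_len(nrow(tr)), seq_len(nrow(lg)), function(i, j) {
      pmax(
        0,
        pmin(tr$end[i], lg$end_time[j]) - pmax(tr$start[i], lg$start_time[j])
      )
    })
    need <- overlap_fraction * (tr$end - tr$start)
    used_t <- logical(nrow(tr))
    used_l <- logical(nrow(lg))
    repeat {
      ok <- sweep(ov >= need & !used_t, 2, used_l, function(a, b) a & !b)
      if (!any(ok)) break
      cand <- which(ok, arr.ind = TRUE)
      best <- cand[which.max(ov[cand]), , drop = FALSE]
      used_t[best[1]] <- TRUE
      used_l[best[2]] <- TRUE
      tp <- tp + 1L
    }
    matched_log <- matched_log + sum(used_l)
  }
  fn <- nrow(truth) - tp
  fp <- nrow(log) - matched_log
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1
  )
}

#' Read/write activity logs in the hub's CSV or JSONL layout
#'
#' Columns follow the hub log layout: `start`, `end`, `label`, `duration`,
#' `location`, `reliability`.
#'
#' @param log Activity tibble from [accumulate_activities()]/[run_node()].
#' @param path Output path; format chosen by `format`.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path` (write) or an activity tibble in internal column names
#'   (read).
#' @export
write_activity_log <- function(log, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- tibble::tibble(
    start = log$start_time, end = log$end_time, label = log$label,
    duration = log$duration, location = log$location,
    reliability = log$confidence
  )
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' @rdname write_activity_log
#' @export
read_activity_log <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  raw <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    dplyr::bind_rows(purrr::map(
      readLines(path),
      ~ as.data.frame(jsonlite::fromJSON(.x))
    ))
  }
  tibble::tibble(
    label = raw$label, start_time = raw$start, end_time = raw$end,
    duration = raw$duration, location = raw$location,
    confidence = raw$reliability
  )
}
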