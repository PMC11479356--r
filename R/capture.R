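#' Mean-absolute frame energy
#'
#' The edge node's wake criterion: the mean absolute amplitude of a 512-sample
#' buffer, `sum(|x|) / N`. Cheap enough for an always-on low-power core.
#'
#' @param frame Numeric vector of exactly 512 amplitudes.
#' @return Nonnegative scalar energy.
#' @export
#' @examples
#' frame_energy(rep(0.25, 512))
frame_energy <- function(frame) {
  if (inherits(frame, "audio_clip")) frame <- frame$samples
  if (length(frame) != 512L) {
    stop("frame must contain exactly 512 samples, got ", length(frame),
      call. = FALSE
    )
  }
  sum(abs(frame)) / 512
}

#' Event-driven gating of a long recording into active segments
#'
#' Software twin of the node's wake/sleep logic. The clip is scanned in
#' consecutive 512-sample frames (a trailing partial frame is dropped,
#' mirroring buffer-granularity hardware). A segment opens at the first frame
#' whose mean-absolute energy reaches `wake_threshold` and closes once
#' sub-threshold frames persist for more than `stop_silence_s`; the trailing
#' silence is trimmed from the emitted segment. Segments are disjoint and
#' ordered.
#'
#' @param clip An [audio_clip()].
#' @param wake_threshold Energy threshold in mean-absolute units
#'   (full scale 1.0).
#' @param stop_silence_s Silence run, in seconds, that closes a segment.
#' @return Tibble with columns `start_sample` (0-based index into the clip)
#'   and `length` (samples); zero rows for an all-quiet clip.
#' @export
#' @examples
#' sc <- session_script(
#'   data.frame(label = "flushing", onset = 4, duration = 3),
#'   total_duration = 20, noise_floor_db = -Inf
#' )
#' gate_stream(synth_session(sc, seed = 2)$clip)
gate_stream <- function(clip, wake_threshold = 0.01, stop_silence_s = 5) {
  stopifnot(inherits(clip, "audio_clip"), wake_threshold > 0)
  x <- clip$samples
  n_frames <- length(x) %/% 512L
  if (n_frames == 0L) {
    return(tibble::tibble(start_sample = integer(), length = integer()))
  }
  fm <- matrix(x[seq_len(n_frames * 512L)], nrow = 512L)
  energy <- colSums(abs(fm)) / 512
  active <- energy >= wake_threshold
  max_silence <- as.integer(ceiling(stop_silence_s * 16000 / 512))

  starts <- integer()
  lengths <- integer()
  open <- FALSE
  seg_start <- 0L
  last_active <- 0L
  silence_run <- 0L
  for (i in seq_len(n_frames)) {
    if (active[i]) {
      if (!open) {
        open <- TRUE
        seg_start <- i
      }
      last_active <- i
      silence_run <- 0L
    } else if (open) {
      silence_run <- silence_run + 1L
      if (silence_run > max_silence) {
        starts <- c(starts, (seg_start - 1L) * 512L)
        lengths <- c(lengths, (last_active - seg_start + 1L) * 512L)
        open <- FALSE
        silence_run <- 0L
      }
    }
  }
  if (open) {
    starts <- c(starts, (seg_start - 1L) * 512L)
    lengths <- c(lengths, (last_active - seg_start + 1L) * 512L)
  }
  tibble::tibble(start_sample = starts, length = lengths)
}

#' Extract a gated segment from its source clip
#'
#' @param clip Source [audio_clip()].
#' @param start_sample 0-based start index (as reported by [gate_stream()]).
#' @param length Segment length in samples.
#' @return An [audio_clip()] holding the segment.
#' @export
extract_segment <- function(clip, start_sample, length) {
  stopifnot(
    inherits(clip, "audio_clip"), start_sample >= 0, length > 0,
    start_sample + length <= base::length(clip$samples)
  )
  audio_clip(clip$samples[(start_sample + 1):(start_sample + length)])
}
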