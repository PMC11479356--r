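#' HTK Mel scale conversions
#'
#' `hz_to_mel()` implements the HTK mapping m = 2595 log10(1 + f/700);
#' `mel_to_hz()` is its inverse.
#'
#' @param f Frequency in Hz (>= 0).
#' @param m Mel value (>= 0).
#' @return Numeric vector of converted values.
#' @export
#' @examples
#' hz_to_mel(700) # 2595 * log10(2)
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequencies must be nonnegative", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel values must be nonnegative", call. = FALSE)
  700 * (10^(m / 2595) - 1)
}

#' Hop-synchronous windowless power spectrogram
#'
#' Streaming spectrogram exactly as computed on the edge node: the audio
#' buffer size equals the FFT hop (512 samples, 50% overlap of 1024-point
#' frames) and no window function is applied, so each incoming buffer is
#' simply concatenated with the previous one and transformed. The first frame
#' uses 512 zeros of prehistory (at stream start the "previous buffer" is
#' empty) and the final partial hop is zero-padded, so one second of audio
#' always yields ceil(16000/512) = 32 frames. Bins k = 0..511 of the
#' 1024-point power spectrum |X_k|^2 are kept.
#'
#' @param samples An [audio_clip()] or numeric vector; at most 16000 samples
#'   (shorter inputs are zero-padded at the tail when `pad = TRUE`).
#' @param pad Zero-pad inputs shorter than 16000 samples?
#' @return 512 x 32 nonnegative matrix (frequency bins x time frames).
#' @export
#' @examples
#' dim(hop_spectrogram(synth_clip("peeing", 1, seed = 1)))
hop_spectrogram <- function(samples, pad = TRUE) {
  if (inherits(samples, "audio_clip")) samples <- samples$samples
  n <- length(samples)
  if (n != 16000L) {
    if (!pad || n > 16000L) {
      stop("expected exactly 16000 samples, got ", n, call. = FALSE)
    }
    samples <- c(samples, numeric(16000L - n))
  }
  # 33 consecutive 512-sample buffers: zero prehistory + 31 full + 1 padded
  buffers <- matrix(c(numeric(512L), samples, numeric(32L * 512L - 16000L)),
    nrow = 512L
  )
  frames <- matrix(0, nrow = 1024L, ncol = 32L)
  frames[1:512, ] <- buffers[, 1:32]
  frames[513:1024, ] <- buffers[, 2:33]
  spec <- Mod(stats::mvfft(frames))^2
  spec[1:512, , drop = FALSE]
}

#' Triangular Mel filter bank on the 512-bin spectrum
#'
#' 48 triangular filters with centers equally spaced on the HTK Mel scale
#' between 0 Hz and Nyquist (8 kHz), evaluated at the 512 spectrogram bin
#' frequencies (k * 16000/1024). Filters are unnormalized (HTK convention):
#' nonnegative weights, a single maximum, adjacent filters overlapping.
#'
#' @param n_mels Number of filters.
#' @param sr Sampling rate in Hz.
#' @param n_fft FFT length (bins kept: `n_fft / 2`).
#' @return `n_mels` x `n_fft/2` weight matrix.
#' @export
mel_filterbank <- function(n_mels = 48L, sr = 16000L, n_fft = 1024L) {
  stopifnot(n_mels >= 1L)
  n_bins <- n_fft %/% 2L
  f_bins <- (seq_len(n_bins) - 1) * sr / n_fft
  f_pts <- mel_to_hz(seq(0, hz_to_mel(sr / 2), length.out = n_mels + 2))
  fb <- matrix(0, nrow = n_mels, ncol = n_bins)
  for (i in seq_len(n_mels)) {
    lo <- f_pts[i]
    ce <- f_pts[i + 1]
    hi <- f_pts[i + 2]
    up <- (f_bins - lo) / (ce - lo)
    down <- (hi - f_bins) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0)) {
    stop("n_mels = ", n_mels, " produces filters with no spectrogram bin; ",
      "use fewer filters",
      call. = FALSE
    )
  }
  fb
}

#' Log-Mel feature extraction
#'
#' Applies the Mel filter bank to a power spectrogram and converts to
#' decibels referenced to the matrix maximum, floored at `db_floor`
#' (the convention of common reference extraction libraries). A silent
#' spectrogram maps to a matrix filled with the floor value.
#'
#' @param spec 512 x 32 power spectrogram from [hop_spectrogram()].
#' @param filterbank Filter bank from [mel_filterbank()]; defaults to the
#'   standard 48-filter bank.
#' @param db_floor Decibel floor relative to the maximum.
#' @param amin Power clamp avoiding log of zero.
#' @return 48 x 32 single-precision-range matrix of log-Mel values.
#' @export
log_mel <- function(spec, filterbank = NULL, db_floor = -80, amin = 1e-10) {
  if (is.null(filterbank)) filterbank <- default_filterbank()
  stopifnot(ncol(filterbank) == nrow(spec))
  m <- filterbank %*% spec
  ref <- max(m)
  if (ref <= amin) {
    return(matrix(db_floor, nrow(m), ncol(m)))
  }
  db <- 10 * log10(pmax(m, amin)) - 10 * log10(ref)
  pmax(db, db_floor)
}

.adl_cache <- new.env(parent = emptyenv())

default_filterbank <- function() {
  if (is.null(.adl_cache$fb)) .adl_cache$fb <- mel_filterbank()
  .adl_cache$fb
}

#' One-second clip to 48 x 32 log-Mel feature
#'
#' Convenience wrapper chaining [hop_spectrogram()] and [log_mel()].
#'
#' @inheritParams hop_spectrogram
#' @inheritParams log_mel
#' @return 48 x 32 log-Mel matrix.
#' @export
clip_mel <- function(samples, db_floor = -80) {
  log_mel(hop_spectrogram(samples), db_floor = db_floor)
}

# --- 8-bit affine feature quantization --------------------------------------

#' Calibrate, apply and invert 8-bit affine feature quantization
#'
#' Affine scheme `q = clamp(round(x / scale) + zero_point, -128, 127)` with
#' `dequantized = scale * (q - zero_point)`. Calibration maps the observed
#' `[min, max]` over a collection of features onto the full int8 range, as in
#' fixed-scale deployment where the quantization parameters are frozen after
#' training. Round-trip error for in-range values is bounded by `scale / 2`.
#'
#' @param features A feature matrix or list of feature matrices.
#' @param eps Scale used when the calibration range is degenerate
#'   (`min == max`).
#' @return `calibrate_quantization()`: list with `scale` and `zero_point`.
#' @export
#' @examples
#' x <- clip_mel(synth_clip("speech", 1, seed = 5))
#' qp <- calibrate_quantization(x)
#' q <- quantize_feature(x, qp$scale, qp$zero_point)
#' max(abs(dequantize_feature(q) - x)) <= qp$scale / 2
calibrate_quantization <- function(features, eps = 1e-8) {
  if (is.list(features)) features <- unlist(features)
  if (length(features) == 0) stop("empty calibration set", call. = FALSE)
  mn <- min(features)
  mx <- max(features)
  scale <- if (mx > mn) (mx - mn) / 255 else eps
  zp <- as.integer(max(-128, min(127, round(-128 - mn / scale))))
  list(scale = scale, zero_point = zp)
}

#' @param x Feature matrix to quantize.
#' @param scale Positive quantization step.
#' @param zero_point Integer in \[-128, 127\].
#' @rdname calibrate_quantization
#' @return `quantize_feature()`: a `quantized_feature` (int8 value matrix plus
#'   `scale`, `zero_point`).
#' @export
quantize_feature <- function(x, scale, zero_point) {
  stopifnot(scale > 0, zero_point >= -128, zero_point <= 127)
  q <- pmax(-128, pmin(127, round(x / scale) + zero_point))
  structure(
    list(
      values = matrix(as.integer(q), nrow(x), ncol(x)),
      scale = scale, zero_point = as.integer(zero_point)
    ),
    class = "quantized_feature"
  )
}

#' @param q A `quantized_feature`.
#' @rdname calibrate_quantization
#' @return `dequantize_feature()`: numeric matrix.
#' @export
dequantize_feature <- function(q) {
  stopifnot(inherits(q, "quantized_feature"))
  q$scale * (q$values - q$zero_point)
}

#' @export
print.quantized_feature <- function(x, ...) {
  cat(sprintf(
    "<quantized_feature> %d x %d int8, scale %.5g, zero_point %d\n",
    nrow(x$values), ncol(x$values), x$scale, x$zero_point
  ))
  invisible(x)
}

#' Serialize a feature to its deployment payload
#'
#' Writes the feature exactly as the edge node would transmit it: 4-byte IEEE
#' single precision for float features (48 x 32 x 4 = 6144 bytes per second)
#' or one byte per cell for int8 features (1536 bytes per second).
#'
#' @param x A feature matrix or `quantized_feature`.
#' @param path Output file.
#' @return `path` invisibly; the file size is the payload size.
#' @export
write_feature_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(x, "quantized_feature")) {
    writeBin(as.raw(bitwAnd(as.integer(x$values) + 256L, 255L)), con)
  } else {
    writeBin(as.double(x), con, size = 4L)
  }
  invisible(path)
}

#' @rdname write_feature_bin
#' @return `feature_payload_bytes()`: payload size in bytes.
#' @export
feature_payload_bytes <- function(x) {
  if (inherits(x, "quantized_feature")) {
    length(x$values) * 1L
  } else {
    length(x) * 4L
  }
}

#' Plot a log-Mel feature
#'
#' @param x 48 x 32 log-Mel matrix.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_mel <- function(x, title = "log-Mel feature") {
  df <- tidyr::expand_grid(
    mel = seq_len(nrow(x)),
    frame = seq_len(ncol(x))
  )
  df$value <- as.vector(x[cbind(df$mel, df$frame)])
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$mel,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "frame (0.5 s hop)", y = "Mel band", title = title)
}
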