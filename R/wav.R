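#' Read and write 16-bit PCM mono 16 kHz WAV files
#'
#' The pipeline is pinned to a single WAV dialect (RIFF, PCM16, mono,
#' 16 kHz) so that the downstream feature geometry is fixed. Anything else is
#' rejected with a diagnostic rather than silently resampled or downmixed.
#' A write/read round trip preserves samples within one LSB of 16-bit
#' quantization (2^-15).
#'
#' @param path File path.
#' @return `read_wav()`: an [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz / 2, size = 2,
        signed = TRUE, endian = "little"
      )
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop("expected 16-bit PCM WAV, got format ", fmt$audio_format,
      " / ", fmt$bits, " bits",
      call. = FALSE
    )
  }
  if (fmt$channels != 1L) {
    stop("expected mono WAV, got ", fmt$channels, " channels", call. = FALSE)
  }
  if (fmt$rate != 16000L) {
    stop("expected 16000 Hz WAV, got ", fmt$rate, " Hz (no resampling)",
      call. = FALSE
    )
  }
  audio_clip(pmax(-1, pmin(1, samples / 32767)))
}

#' @param clip An [audio_clip()].
#' @rdname read_wav
#' @return `write_wav()`: `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(synth_clip("hitting", 0.5, seed = 3), f)
#' read_wav(f)
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  # symmetric PCM16 encoding; full-scale 1.0 maps to 32767 without overflow
  pcm <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32767))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
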