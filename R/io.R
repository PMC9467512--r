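## File I/O: WAV audio, plain-text beat annotations, and the array
## container (raw float64 binary + JSON sidecar) used to persist
## features, EEG datasets and fitted models.

#' Write a mono waveform to a WAV file
#'
#' Writes a canonical RIFF/WAVE file, either 16-bit PCM or IEEE float32.
#'
#' @param x numeric vector in [-1, 1] (clipped if outside).
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = 44100, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  assert_scalar_pos(fs, "fs")
  x <- pmin(1, pmax(-1, as.numeric(x)))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  bytes_per_sample <- bits %/% 8L
  data_bytes <- length(x) * bytes_per_sample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(bytes_per_sample, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Minimal RIFF parser supporting PCM16 and IEEE float32 mono files.
#'
#' @param path file path.
#' @return list with `x` (numeric waveform) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop_invalid("not a WAVE file: ", path)
  fs <- NULL; fmt_code <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (identical(id, "data")) {
      if (fmt_code == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      } else stop_invalid("unsupported WAV encoding")
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
    if (!is.null(x) && !is.null(fs)) break
  }
  list(x = as.numeric(x), fs = fs)
}

#' Write beat onset times as plain text
#'
#' One onset time in seconds per line.
#'
#' @param onsets_s numeric vector of onset times (seconds).
#' @param path output path.
#' @export
write_beats <- function(onsets_s, path) {
  writeLines(formatC(onsets_s, format = "fg", digits = 10), path)
  invisible(path)
}

#' Read beat onset times from plain text
#' @param path file path, one onset time in seconds per line.
#' @return numeric vector of onset times.
#' @export
read_beats <- function(path) {
  as.numeric(readLines(path, warn = FALSE))
}

#' Persist a numeric array to the package's array container
#'
#' The container is a raw little-endian float64 file plus a JSON sidecar
#' (`<path>.json`) recording the dimensions and arbitrary metadata, so
#' datasets and models survive a round trip without loss.
#'
#' @param x numeric vector, matrix or array.
#' @param path output path for the binary payload.
#' @param meta named list of metadata stored in the sidecar.
#' @export
write_array <- function(x, path, meta = list()) {
  dims <- dim(x) %||% length(x)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  sidecar <- c(list(dim = as.integer(dims)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an array written by [write_array()]
#' @param path path of the binary payload.
#' @return numeric array with attribute `meta` (the sidecar contents).
#' @export
read_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dim)
  n <- prod(dims)
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(dims) > 1L) dim(x) <- dims
  attr(x, "meta") <- meta[setdiff(names(meta), "dim")]
  x
}
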