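#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed 16-bit mono files the
#' recording rig and the synthetic generator produce. Samples are returned
#' rescaled to \code{[-1, 1]}.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \code{[-1, 1]}) and
#'   `sample_rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data chunk before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM supported, got ", bits, "-bit")
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!is.null(channels) && channels != 1L)
    stop("only mono WAV supported, got ", channels, " channels")
  list(samples = samples / 32767, sample_rate = sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Writes a numeric vector (values clipped to \code{[-1, 1]}) as 16-bit mono
#' PCM.
#'
#' @param samples Numeric amplitude series in \code{[-1, 1]}.
#' @param sample_rate Sampling rate, Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")       # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")      # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
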