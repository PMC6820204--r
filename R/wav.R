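# Minimal RIFF/WAVE I/O (16-bit PCM and 32-bit IEEE float, mono or
# multichannel). Written in-package because no WAV-capable package is among
# the declared dependencies; covers exactly what the stimulus module needs.

#' Write a waveform to a WAV file
#'
#' @param samples numeric vector (mono) or channels-by-samples matrix, in
#'   \[-1, 1\] for PCM output.
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bit_depth = 16) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(bit_depth %in% c(16L, 32L), sample_rate > 0)
  n_chan <- nrow(samples)
  n_samp <- ncol(samples)
  interleaved <- as.vector(samples)  # column-major = frame-interleaved
  bytes_per <- bit_depth / 8L
  data_size <- n_samp * n_chan * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_u32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_u32(16)
  w_u16(fmt_code)
  w_u16(n_chan)
  w_u32(sample_rate)
  w_u32(sample_rate * n_chan * bytes_per)
  w_u16(n_chan * bytes_per)
  w_u16(bit_depth)
  writeChar("data", con, eos = NULL)
  w_u32(data_size)
  if (bit_depth == 16) {
    x <- pmax(-1, pmin(1, interleaved))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports 16-bit PCM and 32-bit float chunks as written by [write_wav()].
#'
#' @param path input file path.
#' @return A list with `samples` (channels x samples matrix, scaled to
#'   \[-1, 1\] for PCM) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2, endian = "little",
                              signed = FALSE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  r_u32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- r_u32()
    if (id == "fmt ") {
      fmt <- list(code = r_u16(), n_chan = r_u16(), rate = r_u32(),
                  byte_rate = r_u32(), block = r_u16(), bits = r_u16())
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt in ", path)
      n_vals <- size / (fmt$bits / 8)
      x <- if (fmt$bits == 16) {
        readBin(con, "integer", n = n_vals, size = 2,
                endian = "little") / 32767
      } else if (fmt$bits == 32 && fmt$code == 3) {
        readBin(con, "double", n = n_vals, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (bits=", fmt$bits, ")")
      }
      return(list(samples = matrix(x, nrow = fmt$n_chan),
                  sample_rate = fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2)  # skip, chunks are word-aligned
    }
  }
}
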