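# Minimal RIFF/WAVE codec: mono or multichannel, PCM 16-bit or IEEE float32.
# Enough to round-trip synthesized stimuli and vocal recordings.

#' Write a waveform to a WAV file
#'
#' @param x Numeric vector (mono) or matrix (samples x channels) in [-1, 1].
#' @param sample_rate Sampling rate in Hz. Defaults to the `sample_rate`
#'   attribute of `x` if present.
#' @param path Output file path.
#' @param bit_depth 32 (IEEE float, default) or 16 (PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = attr(x, "sample_rate"),
                      bit_depth = 32) {
  if (is.null(sample_rate)) stop("sample_rate is required")
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32")
  x <- as.matrix(x)
  n_ch <- ncol(x)
  n <- nrow(x)
  bytes_per <- bit_depth / 8
  block_align <- n_ch * bytes_per
  data_size <- n * block_align
  fmt_code <- if (bit_depth == 32) 3L else 1L  # 3 = IEEE float, 1 = PCM
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  inter <- as.vector(t(x))  # interleave channels
  if (bit_depth == 32) {
    writeBin(as.numeric(inter), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, inter)) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE float32 data chunks.
#'
#' @param path Path to a WAV file.
#' @return Numeric vector (mono) or matrix (samples x channels) with
#'   attribute `sample_rate`. PCM data are rescaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- n_ch <- sample_rate <- bit_depth <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_ch <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bit_depth <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk")
      n_samp <- size / (bit_depth / 8)
      x <- if (fmt_code == 3 && bit_depth == 32) {
        readBin(con, "numeric", n = n_samp, size = 4, endian = "little")
      } else if (fmt_code == 1 && bit_depth == 16) {
        readBin(con, "integer", n = n_samp, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else stop("unsupported WAV encoding")
      out <- if (n_ch > 1) matrix(x, ncol = n_ch, byrow = TRUE) else x
      attr(out, "sample_rate") <- sample_rate
      return(out)
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
}
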