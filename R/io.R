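#' Read and write label masks and intensity channels as TIFF
#'
#' Label masks are stored as single-channel 16-bit TIFF (label 0 =
#' background); intensity channels as 32-bit float TIFF in \[0, 1\].
#' Matrices are written row = image row, matching the in-memory convention
#' (rows = RC axis, columns = ML axis).
#'
#' @param labels Integer label matrix (values 0..65535).
#' @param path Output file path.
#' @return `write_*` return the path invisibly; `read_*` return a matrix.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 labels: does not fit 16-bit")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname write_label_tiff
#' @param channel Numeric matrix in \[0, 1\].
#' @export
write_channel_tiff <- function(channel, path) {
  tiff::writeTIFF(channel, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_channel_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.numeric(m), nrow(m), ncol(m))
}
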