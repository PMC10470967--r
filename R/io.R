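#' Write / read a sinogram as CSV
#'
#' Plain-text exchange format: first column `angle` (degrees), remaining
#' columns the radial samples, with the offsets stored in the header as
#' `r_<offset>`.
#'
#' @param sino a [sinogram]
#' @param path file path
#' @return `read_sinogram_csv` returns a [sinogram];
#'   `write_sinogram_csv` returns `path` invisibly.
#' @export
write_sinogram_csv <- function(sino, path) {
  df <- data.frame(angle = sino$angles, sino$values)
  names(df) <- c("angle", sprintf("r_%.10g", sino$offsets))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram_csv
#' @export
read_sinogram_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  offsets <- as.numeric(sub("^r_", "", names(df)[-1]))
  sinogram(as.matrix(df[, -1, drop = FALSE]), df$angle, offsets)
}

#' Write / read an image matrix as CSV
#'
#' @param image numeric matrix
#' @param path file path
#' @return `read_image_csv` returns a matrix; `write_image_csv` returns
#'   `path` invisibly.
#' @export
write_image_csv <- function(image, path) {
  utils::write.csv(as.data.frame(as.matrix(image)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
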