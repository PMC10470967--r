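#' Affine rescale of an image to \[0, 255\]
#'
#' Maps `lo` to 0 and `hi` to 255. By default `lo`/`hi` are the image's own
#' range; pass a reference range to put several images on a common scale.
#'
#' @param image numeric matrix
#' @param lo,hi intensities mapped to 0 and 255
#' @return rescaled matrix (not clipped)
#' @export
rescale_255 <- function(image, lo = min(image), hi = max(image)) {
  if (hi <= lo) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) / (hi - lo) * 255
}

#' Mean squared error between two images
#'
#' @param reference,image same-size numeric matrices
#' @return mean over all pixels of the squared difference
#' @export
img_mse <- function(reference, image) {
  if (!all(dim(reference) == dim(image))) stop("image sizes differ")
  mean((reference - image)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(max_value^2 / MSE)` in dB; identical images give `Inf`.
#'
#' @inheritParams img_mse
#' @param max_value the peak intensity constant (255 for 8-bit-style scale)
#' @return PSNR in dB
#' @export
img_psnr <- function(reference, image, max_value = 255) {
  m <- img_mse(reference, image)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Shannon entropy of an image histogram
#'
#' The image is mapped to \[0, 255\] by its own range and binned into
#' `n_bins` levels; the entropy is `-sum p log2 p` (with `0 log 0 = 0`),
#' in bits. A constant image has entropy 0; 256 equiprobable levels give 8.
#'
#' @param image numeric matrix
#' @param n_bins histogram size
#' @return entropy in bits
#' @export
image_entropy <- function(image, n_bins = 256) {
  lo <- min(image); hi <- max(image)
  if (hi <= lo) return(0)
  lev <- pmin(floor((image - lo) / (hi - lo) * n_bins), n_bins - 1)
  p <- tabulate(lev + 1, nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Average gradient of an image
#'
#' Mean over the interior of `sqrt((dx^2 + dy^2) / 2)` with forward
#' differences: a sharpness measure that scales linearly with intensity.
#'
#' @param image numeric matrix with side >= 2
#' @return average gradient (intensity per pixel)
#' @export
average_gradient <- function(image) {
  n <- nrow(image); m <- ncol(image)
  if (n < 2 || m < 2) stop("image side must be >= 2")
  dx <- image[-n, -m] - image[-n, -1]   # column direction
  dy <- image[-n, -m] - image[-1, -m]   # row direction
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Full quality report of a reconstruction against a reference
#'
#' PSNR/MSE are computed after both images are put on the \[0, 255\] scale
#' defined by the reference's own min/max (`max_value` 255). Entropy and
#' average gradient are properties of the reconstructed image alone, on its
#' own \[0, 255\] scale.
#'
#' @param reference ground-truth matrix
#' @param image reconstructed matrix
#' @param method label recorded in the report
#' @return one-row tibble: `method, psnr, mse, entropy, avg_gradient,
#'   max_value`
#' @export
metrics_report <- function(reference, image, method = "image") {
  lo <- min(reference); hi <- max(reference)
  r255 <- rescale_255(reference, lo, hi)
  i255 <- rescale_255(image, lo, hi)
  i_own <- rescale_255(image)
  tibble::tibble(method = method,
                 psnr = img_psnr(r255, i255, 255),
                 mse = img_mse(r255, i255),
                 entropy = image_entropy(i_own),
                 avg_gradient = average_gradient(i_own),
                 max_value = 255)
}
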