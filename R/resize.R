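#' Separable Gaussian blur
#'
#' Convolution with a truncated Gaussian kernel (half-width
#' `ceiling(3 * sigma)`), applied separably along rows and columns with
#' symmetric-reflect border handling.
#'
#' @param image numeric matrix
#' @param sigma kernel standard deviation in pixels (> 0)
#' @return blurred matrix
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  image <- as.matrix(image)
  rad <- ceiling(3 * sigma)
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_mat <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- (i - rad):(i + rad)
      js <- ifelse(js < 1, 1 - js, js)
      js <- ifelse(js > n, 2 * n - js + 1, js)
      for (q in seq_along(js)) B[i, js[q]] <- B[i, js[q]] + k[q]
    }
    B
  }
  conv_mat(nrow(image)) %*% image %*% t(conv_mat(ncol(image)))
}

cubic_kernel <- function(t, a = -0.5) {
  # Keys cubic convolution kernel
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

resize_weights <- function(n_in, n_out, method) {
  # rows = output samples; pixel-center alignment, clamped (replicated) edges
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5 + 1  # 1-based
  W <- matrix(0, n_out, n_in)
  clamp <- function(j) pmin(pmax(j, 1), n_in)
  if (method == "nearest") {
    j <- clamp(round(src))
    W[cbind(seq_len(n_out), j)] <- 1
  } else if (method == "bilinear") {
    j0 <- floor(src); f <- src - j0
    for (d in 0:1) {
      w <- if (d == 0) 1 - f else f
      jj <- clamp(j0 + d)
      for (i in seq_len(n_out)) W[i, jj[i]] <- W[i, jj[i]] + w[i]
    }
  } else if (method == "bicubic") {
    j0 <- floor(src)
    for (d in -1:2) {
      w <- cubic_kernel(src - (j0 + d))
      jj <- clamp(j0 + d)
      for (i in seq_len(n_out)) W[i, jj[i]] <- W[i, jj[i]] + w[i]
    }
  } else stop(sprintf("unknown interpolation method '%s'", method))
  W
}

#' Resize an image by interpolation
#'
#' Supported methods: `"nearest"` (pixel replication), `"bilinear"`,
#' `"bicubic"` (Keys cubic convolution, a = -0.5), and `"spline"` (natural
#' interpolating cubic spline through all samples, applied separably).
#' Output/input grids are aligned by pixel centers; edges replicate.
#'
#' @param image numeric matrix
#' @param out_rows,out_cols output dimensions; `out_cols` defaults to
#'   `out_rows` scaled by the aspect ratio
#' @param method interpolation rule
#' @return resized matrix
#' @export
interp_resize <- function(image, out_rows, out_cols = NULL,
                          method = c("bicubic", "nearest", "bilinear", "spline")) {
  method <- match.arg(method)
  image <- as.matrix(image)
  if (is.null(out_cols))
    out_cols <- round(out_rows * ncol(image) / nrow(image))
  if (method == "spline") {
    src_r <- (seq_len(out_rows) - 0.5) * nrow(image) / out_rows - 0.5 + 1
    src_c <- (seq_len(out_cols) - 0.5) * ncol(image) / out_cols - 0.5 + 1
    src_r <- pmin(pmax(src_r, 1), nrow(image))
    src_c <- pmin(pmax(src_c, 1), ncol(image))
    tmp <- apply(image, 2, function(col)
      stats::spline(seq_along(col), col, xout = src_r, method = "natural")$y)
    tmp <- matrix(tmp, out_rows, ncol(image))
    out <- t(apply(tmp, 1, function(row)
      stats::spline(seq_along(row), row, xout = src_c, method = "natural")$y))
    return(matrix(out, out_rows, out_cols))
  }
  Wr <- resize_weights(nrow(image), out_rows, method)
  Wc <- resize_weights(ncol(image), out_cols, method)
  Wr %*% image %*% t(Wc)
}

#' Pad an image to even side lengths by edge replication
#'
#' @param image numeric matrix
#' @return matrix with even dimensions; attribute `"orig_dim"` records the
#'   input size so the padding can be cropped off later.
#' @keywords internal
pad_to_even <- function(image) {
  d <- dim(image)
  out <- image
  if (d[1] %% 2 == 1) out <- rbind(out, out[d[1], , drop = FALSE])
  if (d[2] %% 2 == 1) out <- cbind(out, out[, ncol(out), drop = FALSE])
  attr(out, "orig_dim") <- d
  out
}
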