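#' Construct a parallel-beam sinogram object
#'
#' A sinogram stores line integrals `g(theta, r)` with rows indexed by
#' projection angle and columns by radial offset. Radial samples are
#' equispaced and symmetric about `r = 0` in phantom-frame units.
#'
#' @param values matrix, rows = angles, cols = radial samples
#' @param angles projection angles in degrees
#' @param offsets radial sample positions (frame units)
#' @return object of class `sinogram`
#' @export
sinogram <- function(values, angles, offsets) {
  values <- as.matrix(values)
  if (nrow(values) != length(angles))
    stop("rows(values) must equal length(angles)")
  if (ncol(values) != length(offsets))
    stop("cols(values) must equal length(offsets)")
  structure(list(values = values, angles = as.numeric(angles),
                 offsets = as.numeric(offsets),
                 dr = if (length(offsets) > 1) offsets[2] - offsets[1] else NA_real_),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d radial samples, dr = %.4g\n",
              nrow(x$values), ncol(x$values), x$dr))
  cat(sprintf("  angles [%.2f, %.2f] deg, offsets [%.3f, %.3f]\n",
              min(x$angles), max(x$angles), min(x$offsets), max(x$offsets)))
  invisible(x)
}

default_n_radial <- function(size) {
  nr <- ceiling(sqrt(2) * size)
  if (nr %% 2 == 0) nr + 1 else nr
}

radial_offsets <- function(size, n_radial) {
  h <- 2 / (size - 1)
  (seq_len(n_radial) - (n_radial + 1) / 2) * h
}

#' Forward Radon projection of an image
#'
#' Approximates the line integral of the image along each ray
#' `x cos(theta) + y sin(theta) = r` by discrete line integration with
#' bilinear sampling (step = half a pixel). The transform is linear in the
#' image and conserves mass: `sum_r g(theta, r) * dr` equals the image
#' integral for every angle.
#'
#' @param image square numeric matrix in the `[-1, 1]^2` frame
#' @param angles projection angles in degrees, within `[0, 180)`
#' @param n_radial number of radial samples; default
#'   `ceiling(sqrt(2) * size)` rounded up to odd so the corners are covered
#' @return a [sinogram]
#' @export
radon_forward <- function(image, angles, n_radial = NULL) {
  image <- as.matrix(image)
  n <- nrow(image)
  if (ncol(image) != n) stop("'image' must be square")
  if (length(angles) == 0) stop("'angles' must be nonempty")
  if (any(angles < 0 | angles >= 180)) stop("'angles' must lie in [0, 180)")
  if (is.null(n_radial)) n_radial <- default_n_radial(n)
  if (n_radial < 2) stop("'n_radial' must be >= 2")
  offsets <- radial_offsets(n, n_radial)
  h <- 2 / (n - 1)
  th <- angles * pi / 180
  grid <- expand.grid(r = offsets, theta = th)
  vals <- cpp_line_integrals(image, grid$theta, grid$r, h / 2, sqrt(2) + h)
  sinogram(matrix(vals, nrow = length(angles), byrow = TRUE), angles, offsets)
}

#' Ramp-filter sinogram rows in the radial frequency domain
#'
#' Each projection row is zero-padded to a power of two, multiplied in the
#' frequency domain by `|omega|` (optionally apodized by a Hann window), and
#' transformed back. The zero-frequency component is suppressed by the
#' filter itself.
#'
#' @param sino a [sinogram]
#' @param window `"ramp"` (pure `|omega|`) or `"hann"`
#' @return filtered [sinogram]
#' @export
ramp_filter_projections <- function(sino, window = c("ramp", "hann")) {
  window <- match.arg(window)
  v <- sino$values
  if (length(v) == 0) stop("sinogram is empty")
  n <- ncol(v)
  m <- 2^ceiling(log2(max(2 * n, 8)))
  freq <- c(seq(0, m / 2), seq(-m / 2 + 1, -1)) / (m * sino$dr)
  resp <- abs(freq)
  if (window == "hann") {
    hn <- 0.5 * (1 + cos(pi * freq / max(abs(freq))))
    resp <- resp * hn
  }
  out <- matrix(0, nrow(v), n)
  for (k in seq_len(nrow(v))) {
    row <- c(v[k, ], rep(0, m - n))
    fr <- stats::fft(row) * resp
    out[k, ] <- Re(stats::fft(fr, inverse = TRUE) / m)[seq_len(n)]
  }
  sinogram(out, sino$angles, sino$offsets)
}

#' Filtered back projection reconstruction
#'
#' Ramp-filters the projections, then back-projects with linear
#' interpolation at `r = x cos(theta) + y sin(theta)`, scaled by
#' `pi / n_angles`.
#'
#' @param sino a [sinogram] with at least two angles
#' @param size output side length in pixels
#' @param window passed to [ramp_filter_projections()]
#' @return `size` x `size` reconstruction matrix
#' @export
fbp_reconstruct <- function(sino, size, window = "ramp") {
  if (nrow(sino$values) < 2) stop("FBP needs at least two angles")
  h <- 2 / (size - 1)
  # rays may cover only an interior disk (e.g. a ring aperture), but a
  # sinogram covering less than half the grid is a size mismatch
  if (max(abs(sino$offsets)) < 0.5 * (1 - h))
    stop("radial extent of the sinogram does not cover the requested grid")
  q <- ramp_filter_projections(sino, window)
  cpp_backproject(q$values, sino$angles * pi / 180,
                  sino$offsets[1], sino$dr, as.integer(size))
}

#' SART iterative reconstruction
#'
#' Simultaneous algebraic reconstruction: per projection angle, every pixel
#' is corrected by the ray residuals `(lambda * p_i - sum_j a_ij f_j)`
#' normalized by `sum_j a_ij^2` and weighted by `a_ij`, with a final
#' per-pixel normalization by `sum_i a_ij` over the rays of that angle. The
#' intersection lengths `a_ij` are exact ray-pixel lengths from a Siddon
#' traversal, in pixel units; one iteration sweeps all angles in sequence.
#'
#' @param sino a [sinogram]
#' @param size output side length
#' @param lambda relaxation factor in (0, 2)
#' @param iterations number of full sweeps (>= 1)
#' @param init starting image (matrix) or `NULL` for zeros
#' @return matrix with attribute `"residuals"` holding the projection
#'   residual norm after each sweep
#' @export
sart_reconstruct <- function(sino, size, lambda = 1.0, iterations = 20,
                             init = NULL) {
  if (!(lambda > 0 && lambda < 2)) stop("'lambda' must be in (0, 2)")
  if (iterations < 1) stop("'iterations' must be >= 1")
  h <- 2 / (size - 1)
  f0 <- if (is.null(init)) matrix(0, size, size) else as.matrix(init)
  res <- cpp_sart(sino$values / h, sino$angles * pi / 180, sino$offsets,
                  as.integer(size), lambda, as.integer(iterations), f0)
  if (res$skipped > 0)
    warning(sprintf("%d rays with all-zero intersection skipped", res$skipped))
  structure(res$image, residuals = res$residuals)
}

#' Add seeded Gaussian noise to a sinogram
#'
#' Emulates measurement noise on projection data: additive Gaussian noise
#' with standard deviation `sigma_frac` times the maximum projection value.
#'
#' @param sino a [sinogram]
#' @param sigma_frac noise level as a fraction of `max(values)`
#' @param seed integer RNG seed
#' @return noisy [sinogram]
#' @export
add_sinogram_noise <- function(sino, sigma_frac = 0.01, seed = 1L) {
  sig <- sigma_frac * max(sino$values)
  v <- sino$values
  if (sig > 0) {
    set.seed(seed)
    v <- v + matrix(stats::rnorm(length(v), 0, sig), nrow(v), ncol(v))
  }
  sinogram(v, sino$angles, sino$offsets)
}
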