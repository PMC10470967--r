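#' Construct a ring-array acquisition object
#'
#' A circular array of `N` equispaced transducers surrounds the object; for
#' each transmitter `i` every other element `j` records the peak received
#' pressure amplitude, giving an `N x N` amplitude matrix whose diagonal
#' (self-pairs) is ignored. There are `N (N - 1) / 2` informative pairs.
#'
#' @param amplitudes `N x N` matrix, entry (i, j) = amplitude for
#'   transmitter i / receiver j
#' @param ring_radius ring radius in phantom-frame units
#' @return object of class `ring_acquisition`
#' @export
ring_acquisition <- function(amplitudes, ring_radius = 0.95) {
  amplitudes <- as.matrix(amplitudes)
  n <- nrow(amplitudes)
  if (ncol(amplitudes) != n) stop("'amplitudes' must be square")
  if (n %% 2 != 0) stop("number of transducers must be even")
  structure(list(amplitudes = amplitudes, n_transducers = n,
                 ring_radius = ring_radius),
            class = "ring_acquisition")
}

#' @export
print.ring_acquisition <- function(x, ...) {
  cat(sprintf("<ring_acquisition> %d transducers (%d pairs), radius %.3f\n",
              x$n_transducers, x$n_transducers * (x$n_transducers - 1) / 2,
              x$ring_radius))
  invisible(x)
}

ring_pair_geometry <- function(n, ring_radius) {
  # all ordered pairs (i, j), i != j, with chord normal angle in [0, pi)
  # and signed offset of the chord from the center
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, ]
  alpha <- 2 * pi * (seq_len(n) - 1) / n
  pix <- ring_radius * cos(alpha[ij$i]); piy <- ring_radius * sin(alpha[ij$i])
  pjx <- ring_radius * cos(alpha[ij$j]); pjy <- ring_radius * sin(alpha[ij$j])
  tx <- pjx - pix; ty <- pjy - piy           # chord direction
  nx <- ty; ny <- -tx                        # chord normal
  nn <- sqrt(nx^2 + ny^2)
  nx <- nx / nn; ny <- ny / nn
  # reduce the normal angle to [0, pi), flipping the offset sign with it
  theta_raw <- atan2(ny, nx) %% (2 * pi)
  theta <- theta_raw %% pi
  r <- pix * nx + piy * ny
  r[theta_raw >= pi] <- -r[theta_raw >= pi]
  data.frame(i = ij$i, j = ij$j, theta = theta, r = r,
             chord = sqrt((pjx - pix)^2 + (pjy - piy)^2))
}

#' Synthesize a ring acquisition from an attenuation image
#'
#' Models amplitude attenuation along each transducer-pair chord by the
#' Beer-Lambert law: `A(i, j) = exp(-integral of alpha along the chord)`,
#' with the line integral computed by discrete ray integration over the
#' attenuation image. The k-space acoustic propagation of a physical system
#' is deliberately not modelled; this is the projection-domain surrogate.
#'
#' @param image square attenuation matrix in the `[-1, 1]^2` frame
#' @param n_transducers number of ring elements (even)
#' @param ring_radius ring radius in frame units
#' @return a [ring_acquisition]
#' @export
simulate_ring_acquisition <- function(image, n_transducers = 256,
                                      ring_radius = 0.95) {
  image <- as.matrix(image)
  n <- nrow(image)
  if (n_transducers %% 2 != 0) stop("'n_transducers' must be even")
  g <- ring_pair_geometry(n_transducers, ring_radius)
  h <- 2 / (n - 1)
  li <- cpp_line_integrals(image, g$theta, g$r, h / 2, sqrt(2) + h)
  amp <- matrix(1, n_transducers, n_transducers)
  amp[cbind(g$i, g$j)] <- exp(-li)
  diag(amp) <- 0
  ring_acquisition(amp, ring_radius)
}

#' Convert received amplitudes to path-integrated attenuation
#'
#' Entrywise `-log(amplitude / reference)` against a water-only reference
#' acquisition with identical geometry, yielding line integrals of the
#' attenuation contrast (tissue minus water) suitable as projection data.
#'
#' @param acq measured [ring_acquisition]
#' @param reference water-only [ring_acquisition], same geometry
#' @return a [ring_acquisition] whose `amplitudes` hold attenuation line
#'   integrals
#' @export
amplitude_to_attenuation <- function(acq, reference) {
  if (acq$n_transducers != reference$n_transducers)
    stop("acquisition and reference geometries differ")
  off <- row(acq$amplitudes) != col(acq$amplitudes)
  if (any(reference$amplitudes[off] <= 0))
    stop("reference contains non-positive amplitudes")
  v <- matrix(0, acq$n_transducers, acq$n_transducers)
  v[off] <- -log(acq$amplitudes[off] / reference$amplitudes[off])
  ring_acquisition(v, acq$ring_radius)
}

#' Rearrange ring-array pair data into a parallel-beam sinogram
#'
#' Groups the `N (N - 1)` ordered transducer pairs by common-midpoint
#' geometry into `N / 2` views of up to `2 N` samples (the intermediate
#' rearranged matrix), resamples each view's irregular chord offsets onto an
#' equispaced radial grid with cubic-spline interpolation, and keeps
#' `N / 2` equal-interval samples, giving an `(N/2) x (N/2)` sinogram.
#' The view of a pair `(i, j)` is `floor(((i + j) mod N) / 2)`; its signed
#' ray offset is the distance from the chord to the ring center.
#'
#' @param acq a [ring_acquisition] whose `amplitudes` hold projection values
#'   (e.g. the output of [amplitude_to_attenuation()])
#' @return a [sinogram] with attribute `"intermediate"` holding the
#'   `(N/2) x 2N` rearranged matrix (`NA` where no pair maps)
#' @export
rearrange_ring_data <- function(acq) {
  n <- acq$n_transducers
  if (n %% 2 != 0) stop("number of transducers must be even")
  R <- acq$ring_radius
  g <- ring_pair_geometry(n, R)
  g$view <- ((g$i + g$j) %% n) %/% 2 + 1
  g$value <- acq$amplitudes[cbind(g$i, g$j)]

  nview <- n %/% 2
  inter <- matrix(NA_real_, nview, 2 * n)
  r_lim <- R * cos(pi / n)
  offsets <- seq(-r_lim, r_lim, length.out = nview)
  values <- matrix(0, nview, nview)
  angles <- numeric(nview)
  for (v in seq_len(nview)) {
    gv <- g[g$view == v, ]
    ord <- order(gv$r)
    gv <- gv[ord, ]
    inter[v, seq_len(nrow(gv))] <- gv$value
    # average duplicate offsets (the two members of a reciprocal pair)
    agg <- stats::aggregate(gv$value, list(r = round(gv$r, 12)), mean)
    sp <- stats::spline(agg$r, agg$x, xout = offsets, method = "natural")
    values[v, ] <- sp$y
    # circular mean of the two midpoint-class angles in this view
    angles[v] <- atan2(mean(sin(2 * gv$theta)), mean(cos(2 * gv$theta))) / 2
  }
  angles <- (angles %% pi) * 180 / pi
  ord <- order(angles)
  out <- sinogram(values[ord, , drop = FALSE], angles[ord], offsets)
  attr(out, "intermediate") <- inter[ord, , drop = FALSE]
  out
}
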