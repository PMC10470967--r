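#' Bilateral filter
#'
#' Edge-preserving, noise-reducing smoothing: each output pixel is a
#' Gaussian-weighted mean whose weights combine spatial distance
#' (`sigma_spatial`, pixels) and intensity difference (`sigma_range`,
#' intensity units). With a very large `sigma_range` it reduces to a plain
#' Gaussian blur; borders are handled by symmetric reflection.
#'
#' @param image numeric matrix
#' @param sigma_spatial spatial kernel standard deviation in pixels (> 0)
#' @param sigma_range range kernel standard deviation in intensity units
#'   (> 0); default 10% of the image's intensity range
#' @param radius window half-width; default `ceiling(3 * sigma_spatial)`
#' @return filtered matrix (values stay within the input range)
#' @export
bilateral_filter <- function(image, sigma_spatial = 3,
                             sigma_range = NULL, radius = NULL) {
  image <- as.matrix(image)
  if (is.null(sigma_range)) {
    rg <- diff(range(image))
    sigma_range <- if (rg > 0) 0.1 * rg else 1
  }
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("'sigma_spatial' and 'sigma_range' must be positive")
  if (is.null(radius)) radius <- ceiling(3 * sigma_spatial)
  cpp_bilateral(image, sigma_spatial, sigma_range, as.integer(radius))
}

#' Brightness-preserving dynamic histogram equalization
#'
#' Contrast enhancement in five steps: (1) smooth the 256-bin histogram with
#' a Gaussian kernel, (2) partition the gray levels at the local minima
#' between successive local maxima of the smoothed histogram, (3) assign
#' each partition an output sub-range proportional to its input dynamic
#' range, (4) equalize classically within each sub-range, (5) rescale the
#' output so its mean brightness equals the input mean. A constant image is
#' returned unchanged.
#'
#' @param image numeric matrix (grayscale)
#' @param smooth_sigma standard deviation of the histogram smoothing kernel
#'   in bins
#' @return enhanced matrix in the same intensity range as the input
#' @export
bpdhe <- function(image, smooth_sigma = 1) {
  image <- as.matrix(image)
  lo <- min(image); hi <- max(image)
  if (hi <= lo) return(image)
  lev <- round((image - lo) / (hi - lo) * 255)
  h <- tabulate(lev + 1, nbins = 256)

  # gaussian smoothing of the histogram
  rad <- ceiling(3 * smooth_sigma)
  ker <- exp(-(-rad:rad)^2 / (2 * smooth_sigma^2))
  ker <- ker / sum(ker)
  hp <- c(rep(h[1], rad), h, rep(h[256], rad))
  hs <- stats::filter(hp, ker, sides = 2)[(rad + 1):(rad + 256)]

  # local maxima of the smoothed histogram
  d <- diff(hs)
  maxima <- which(c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE))
  if (hs[1] > hs[2]) maxima <- c(1, maxima)
  if (hs[256] > hs[255]) maxima <- c(maxima, 256)
  occupied <- range(which(h > 0))
  if (length(maxima) < 2) {
    bounds <- occupied  # single mode: one partition over the occupied range
  } else {
    mins <- vapply(seq_len(length(maxima) - 1), function(k) {
      a <- maxima[k]; b <- maxima[k + 1]
      as.integer(a + which.min(hs[a:b]) - 1)
    }, integer(1))
    bounds <- unique(c(occupied[1], mins[mins > occupied[1] & mins < occupied[2]],
                       occupied[2]))
  }

  # allocate output sub-ranges proportional to input dynamic ranges
  np <- length(bounds) - 1
  if (np < 1) { lo_p <- occupied[1]; bounds <- c(lo_p, occupied[2]); np <- 1 }
  spans <- diff(bounds)
  spans[spans <= 0] <- 1e-9
  out_edges <- c(0, cumsum(spans)) / sum(spans) * 255
  map <- numeric(256)
  for (p in seq_len(np)) {
    li <- bounds[p] + (p > 1)          # avoid double-assigning the boundary
    ui <- bounds[p + 1]
    if (li > ui) next
    hh <- h[li:ui]
    cdf <- cumsum(hh)
    if (cdf[length(cdf)] == 0) {
      map[li:ui] <- out_edges[p]
    } else {
      cdf <- cdf / cdf[length(cdf)]
      map[li:ui] <- out_edges[p] + cdf * (out_edges[p + 1] - out_edges[p])
    }
  }
  out <- matrix(map[lev + 1], nrow(image), ncol(image))

  # brightness normalization back to the input mean (on the 0..255 scale)
  mo <- mean(out)
  if (mo > 0) out <- out * mean(lev) / mo
  out / 255 * (hi - lo) + lo
}

#' Singular value equalization
#'
#' Scales all singular values of the image by
#' `xi = max(sv(reference)) / max(sv(image))`, where the reference is a
#' same-size matrix whose entries follow a uniform histogram over the full
#' intensity range (`range`), laid out deterministically in raster order.
#' An all-zero image is returned unchanged (`xi` undefined).
#'
#' @param image numeric matrix
#' @param range the full intensity range the reference is built on
#' @param clip if `TRUE`, clamp the output to `range`
#' @return equalized matrix
#' @export
sve <- function(image, range = c(0, 255), clip = TRUE) {
  image <- as.matrix(image)
  if (all(image == 0)) return(image)
  s <- svd(image)
  ref <- matrix(seq(range[1], range[2], length.out = length(image)),
                nrow(image), ncol(image), byrow = TRUE)
  smax_ref <- svd(ref, nu = 0, nv = 0)$d[1]
  xi <- smax_ref / s$d[1]
  out <- s$u %*% (xi * diag(s$d, length(s$d))) %*% t(s$v)
  if (clip) out <- pmin(pmax(out, range[1]), range[2])
  out
}

box_mean <- function(x, radius) {
  # box filter with symmetric-reflect padding, via a banded row operator
  n <- nrow(x); m <- ncol(x)
  bm <- function(k) {
    B <- matrix(0, k, k)
    for (i in seq_len(k)) {
      js <- (i - radius):(i + radius)
      js <- ifelse(js < 1, 1 - js, js)
      js <- ifelse(js > k, 2 * k - js + 1, js)
      for (j in js) B[i, j] <- B[i, j] + 1
    }
    B / (2 * radius + 1)
  }
  bm(n) %*% x %*% t(bm(m))
}

#' Guided filter
#'
#' Edge-preserving filter expressing the output as a local linear function
#' of a guide image: per window `w`,
#' `a_w = cov(guide, input) / (var(guide) + eps)` and
#' `b_w = mean(input) - a_w * mean(guide)`; the output averages
#' `a_w * guide + b_w` over all windows containing each pixel. Means are box
#' filters of half-width `radius` with reflect padding.
#'
#' @param guide guide image (matrix)
#' @param input image to be filtered, same size as `guide`
#' @param radius window half-width in pixels (>= 1)
#' @param eps regularizer added to the guide variance (>= 0), in squared
#'   intensity units of the guide
#' @return filtered matrix, linear in `input` for a fixed guide
#' @export
guided_filter <- function(guide, input, radius = 8, eps = 1e-4) {
  guide <- as.matrix(guide); input <- as.matrix(input)
  if (!all(dim(guide) == dim(input))) stop("'guide' and 'input' sizes differ")
  if (radius < 1) stop("'radius' must be >= 1")
  if (eps < 0) stop("'eps' must be >= 0")
  mg <- box_mean(guide, radius)
  mi <- box_mean(input, radius)
  vg <- box_mean(guide * guide, radius) - mg * mg
  cv <- box_mean(guide * input, radius) - mg * mi
  a <- cv / (vg + eps)
  if (eps == 0) a[abs(vg) < 1e-12] <- 0  # constant windows: fall back to mean
  b <- mi - a * mg
  box_mean(a, radius) * guide + box_mean(b, radius)
}
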