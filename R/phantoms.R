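#' Ellipse parameters of the standard ten-ellipse head phantom
#'
#' Each row defines one ellipse in the phantom frame `[-1, 1]^2` (y up):
#' center `(x0, y0)`, semi-axes `a` (horizontal) and `b` (vertical), rotation
#' `phi` in degrees counter-clockwise, and additive density `rho`. Densities
#' of overlapping ellipses add, which is how the low-density "brain" interior
#' arises from the two outermost ellipses (1.0 - 0.8 = 0.2).
#'
#' @return A tibble with columns `n0, x0, y0, a, b, phi, rho` and ten rows.
#' @export
#' @examples
#' ph <- rasterize_ellipses(shepp_logan_ellipses(), 128)
shepp_logan_ellipses <- function() {
  tibble::tibble(
    n0  = 1:10,
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.10, -0.10, -0.605, -0.605, -0.605),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    rho = c(1.0, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
}

#' Modified ellipse parameters used as the held-out test phantom
#'
#' A variant of [shepp_logan_ellipses()] in which the inner-ellipse rotations
#' and two semi-axes are changed, so that the dictionary learned on the
#' default phantom is evaluated on a genuinely different image.
#'
#' @return A tibble with the same columns as [shepp_logan_ellipses()].
#' @export
modified_shepp_logan_ellipses <- function() {
  tibble::tibble(
    n0  = 1:10,
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.10, -0.10, -0.605, -0.605, -0.605),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.45, 0.046, 0.046, 0.023, 0.013, 0.046),
    phi = c(0, 0, 18, -18, 0, 20, -10, 90, -15, 15),
    rho = c(1.0, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
}

#' Pixel-center coordinates of the phantom frame
#'
#' @param size side length in pixels (>= 2)
#' @return list with vectors `x` (by column, left to right) and `y`
#'   (by row, top to bottom), spanning `[-1, 1]` inclusive.
#' @export
frame_coords <- function(size) {
  if (length(size) != 1 || is.na(size) || size < 2)
    stop("'size' must be a single integer >= 2")
  s <- seq(-1, 1, length.out = size)
  list(x = s, y = rev(s))
}

#' Rasterize an additive ellipse phantom
#'
#' Pixel values are the sum of `rho` over all ellipses whose interior
#' (after rotating the query point by `-phi` about the ellipse center)
#' contains the pixel-center coordinate. Pixel centers sample the continuous
#' phantom directly; no area-weighted anti-aliasing is applied. Values are
#' the raw additive sums; clip negative densities separately if needed.
#'
#' @param specs data frame with columns `x0, y0, a, b, phi, rho`
#' @param size output side length in pixels (>= 2)
#' @param clip if `TRUE`, clamp the result at zero
#' @return `size` x `size` numeric matrix (row 1 = top of the frame)
#' @export
rasterize_ellipses <- function(specs, size, clip = FALSE) {
  if (is.null(specs) || nrow(specs) == 0) stop("'specs' must be nonempty")
  stopifnot(all(specs$a > 0), all(specs$b > 0))
  fc <- frame_coords(size)
  X <- matrix(fc$x, size, size, byrow = TRUE)
  Y <- matrix(fc$y, size, size)
  img <- matrix(0, size, size)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    phi <- s$phi * pi / 180
    dx <- X - s$x0
    dy <- Y - s$y0
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    inside <- (u / s$a)^2 + (v / s$b)^2 <= 1
    img <- img + s$rho * inside
  }
  if (clip) img[img < 0] <- 0
  img
}

#' Tissue property table for the numerical breast phantom
#'
#' Acoustic properties of the four tissue classes (density `rho` in kg/m^3,
#' sound speed `c` in m/s, attenuation `alpha0` in dB/MHz^y/cm) together
#' with a default circular geometry in the phantom frame: a water disk
#' (the coupling bath, radius 0.95), a fat disk representing the breast,
#' and two inclusions (fibroadenoma, cancer). The table lists tissues in
#' paint order; later rows overwrite earlier ones where regions overlap.
#' The attenuation column is what the ring-array acquisition images.
#'
#' @return tibble with columns `tissue, rho, c, alpha0, cx, cy, radius`.
#' @export
breast_tissues <- function() {
  tibble::tibble(
    tissue = c("water", "fat", "fibroadenoma", "cancer"),
    rho    = c(1000, 950, 1040, 1070),
    c      = c(1500, 1470, 1515, 1560),
    alpha0 = c(1, 1.2, 0.7, 1),
    cx     = c(0, 0, -0.18, 0.22),
    cy     = c(0, 0, 0.12, -0.18),
    radius = c(0.95, 0.60, 0.18, 0.13)
  )
}

#' Rasterize the breast attenuation phantom
#'
#' Pixel value is the attenuation `alpha0` of the last-listed tissue whose
#' circular region contains the pixel center; pixels outside every region
#' (outside the water bath) are zero.
#'
#' @param tissues data frame as returned by [breast_tissues()]
#' @param size side length in pixels (>= 2)
#' @return `size` x `size` attenuation matrix
#' @export
breast_phantom <- function(tissues = breast_tissues(), size = 128) {
  if (is.null(tissues) || nrow(tissues) == 0) stop("'tissues' must be nonempty")
  if (length(size) != 1 || is.na(size) || size < 2)
    stop("'size' must be a single integer >= 2")
  fc <- frame_coords(size)
  X <- matrix(fc$x, size, size, byrow = TRUE)
  Y <- matrix(fc$y, size, size)
  img <- matrix(0, size, size)
  for (i in seq_len(nrow(tissues))) {
    t <- tissues[i, ]
    inside <- (X - t$cx)^2 + (Y - t$cy)^2 <= t$radius^2
    img[inside] <- t$alpha0
  }
  img
}

#' Write / read an ellipse parameter table as CSV
#'
#' The CSV uses the header `N0,x0,y0,a,b,phi,rho`.
#'
#' @param specs data frame of ellipse parameters
#' @param path file path
#' @return `read_ellipses_csv` returns the tibble; `write_ellipses_csv`
#'   returns `path` invisibly.
#' @export
write_ellipses_csv <- function(specs, path) {
  df <- data.frame(N0 = specs$n0, x0 = specs$x0, y0 = specs$y0,
                   a = specs$a, b = specs$b, phi = specs$phi, rho = specs$rho)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ellipses_csv
#' @export
read_ellipses_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::tibble(n0 = df$N0, x0 = df$x0, y0 = df$y0, a = df$a, b = df$b,
                 phi = df$phi, rho = df$rho)
}
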