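test_that("the forward projection is linear and vanishes on zero images", {
  zero <- matrix(0, 64, 64)
  s <- radon_forward(zero, c(0, 30, 90))
  expect_true(all(s$values == 0))

  set.seed(4)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  sa <- radon_forward(a, c(10, 75))$values
  sb <- radon_forward(b, c(10, 75))$values
  sab <- radon_forward(2 * a - 3 * b, c(10, 75))$values
  expect_equal(sab, 2 * sa - 3 * sb, tolerance = 1e-12)

  expect_error(radon_forward(a, numeric(0)), "nonempty")
  expect_error(radon_forward(a, c(0, 181)), "180")
  expect_error(radon_forward(a, 10, n_radial = 1), "n_radial")
})

test_that("projections of a disk match the analytic chord lengths", {
  disk <- disk_image(256, radius = 0.5)
  s <- radon_forward(disk, c(0, 45, 90, 137), 363)
  i0 <- which.min(abs(s$offsets))
  # central chord = diameter = 1 for every angle
  expect_equal(unname(s$values[, i0]), rep(1, 4), tolerance = 0.02)
  # interior profile 2 sqrt(R^2 - r^2)
  sel <- abs(s$offsets) < 0.4
  chord <- 2 * sqrt(pmax(0.25 - s$offsets[sel]^2, 0))
  for (k in 1:4)
    expect_equal(unname(s$values[k, sel]), chord, tolerance = 0.02)
  # rotational symmetry: all rows agree
  expect_lt(max(abs(s$values[1, ] - s$values[3, ])), 0.01 * max(s$values))
})

test_that("the projection conserves mass at every angle", {
  ph <- rasterize_ellipses(shepp_logan_ellipses(), 128)
  s <- radon_forward(ph, c(0, 20, 65, 90, 150))
  mass <- rowSums(s$values) * s$dr
  h <- 2 / 127
  expect_equal(unname(mass), rep(sum(ph) * h^2, 5), tolerance = 0.01)
})

test_that("the ramp filter kills DC and scales sinusoids by |frequency|", {
  z <- sinogram(matrix(0, 3, 64), c(0, 60, 120), radial_offsets(64, 64))
  expect_true(all(ramp_filter_projections(z)$values == 0))

  offsets <- radial_offsets(128, 128)
  const <- sinogram(matrix(1, 1, 128), 0, offsets)
  fc <- ramp_filter_projections(const)$values[1, ]
  expect_lt(max(abs(fc[32:96])), 0.05 * max(abs(fc)))

  # a sampled cosine is an eigenfunction of the |omega| filter
  dr <- offsets[2] - offsets[1]
  for (cycles in c(8, 16)) {
    nu <- cycles / (128 * dr)           # cycles per frame unit
    row <- cos(2 * pi * nu * offsets)
    s <- sinogram(matrix(row, 1), 0, offsets)
    f <- ramp_filter_projections(s)$values[1, ]
    interior <- 33:96
    expect_equal(f[interior], nu * row[interior], tolerance = 0.05)
  }
  expect_error(ramp_filter_projections(const, "hamming"))
})

test_that("FBP inverts the projection increasingly well with more angles", {
  disk <- disk_image(128, radius = 0.5)
  expect_true(all(fbp_reconstruct(
    sinogram(matrix(0, 4, 183), test_angles(4), radial_offsets(128, 183)),
    128) == 0))

  psnrs <- sapply(c(45, 90, 180), function(na) {
    s <- radon_forward(disk, test_angles(na))
    psnr_ref(disk, fbp_reconstruct(s, 128))
  })
  expect_true(all(diff(psnrs) >= 0))
  # density recovery inside the disk
  s <- radon_forward(disk, test_angles(180))
  fb <- fbp_reconstruct(s, 128)
  expect_equal(mean(fb[disk > 0]), 1, tolerance = 0.05)
})

test_that("FBP round trip of the head phantom reaches 25 dB", {
  ph <- rasterize_ellipses(shepp_logan_ellipses(), 256)
  s <- radon_forward(ph, test_angles(180), 363)
  fb <- fbp_reconstruct(s, 256)
  expect_gte(psnr_ref(ph, fb), 25)
})

test_that("the SART update matches the per-angle normal form by hand", {
  # one pixel, one ray, a = 1, p = 5, f0 = 0, lambda = 1 -> f1 = 5
  f1 <- sart_sweep_dense(0, matrix(1, 1, 1), 5, angle_of = 1)
  expect_equal(as.numeric(f1), 5)
  # two rays of one angle through one pixel, a = (1, 1), p = (4, 6):
  # correction = [(4 - 0)/1 + (6 - 0)/1] / (1 + 1) = 5
  f1 <- sart_sweep_dense(0, matrix(c(1, 1), 2, 1), c(4, 6), angle_of = c(1, 1))
  expect_equal(as.numeric(f1), 5)
})

test_that("the compiled SART agrees with a dense per-angle evaluation", {
  size <- 8
  angles <- c(0, 36, 77, 101, 145)
  offsets <- radial_offsets(size, 11)
  A <- ray_matrix(size, angles, offsets)
  set.seed(9)
  img <- matrix(runif(size * size), size)
  p <- as.numeric(A %*% as.vector(img))      # consistent data, pixel units
  angle_of <- rep(seq_along(angles), each = length(offsets))

  f_dense <- sart_sweep_dense(rep(0, size^2), A, p, angle_of, lambda = 0.8)
  h <- 2 / (size - 1)
  sino <- sinogram(matrix(p * h, length(angles), byrow = TRUE,
                          ncol = length(offsets)), angles, offsets)
  f_cpp <- sart_reconstruct(sino, size, lambda = 0.8, iterations = 1)
  expect_equal(as.vector(f_cpp), f_dense, tolerance = 1e-10)

  # consistent data are a fixed point
  f_fix <- sart_reconstruct(sino, size, lambda = 1, iterations = 1,
                            init = img)
  expect_equal(as.vector(f_fix), as.vector(img), tolerance = 1e-10)
})

test_that("SART projection residuals are non-increasing over sweeps", {
  ph <- rasterize_ellipses(shepp_logan_ellipses(), 64)
  s <- radon_forward(ph, test_angles(128))
  f <- sart_reconstruct(s, 64, lambda = 1, iterations = 10)
  r <- attr(f, "residuals")
  expect_length(r, 10)
  expect_true(all(diff(r) <= 1e-9 * r[1]))
  expect_error(sart_reconstruct(s, 64, lambda = 2.5), "lambda")
  expect_error(sart_reconstruct(s, 64, iterations = 0), "iterations")
})

test_that("sinogram noise is seeded and scaled to the projection maximum", {
  ph <- disk_image(64)
  s <- radon_forward(ph, test_angles(16))
  n1 <- add_sinogram_noise(s, 0.05, seed = 7)
  n2 <- add_sinogram_noise(s, 0.05, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_equal(sd(n1$values - s$values), 0.05 * max(s$values),
               tolerance = 0.05)
})

test_that("sinograms survive a CSV round trip", {
  s <- radon_forward(disk_image(32), c(0, 45, 90))
  p <- withr::local_tempfile(fileext = ".csv")
  write_sinogram_csv(s, p)
  s2 <- read_sinogram_csv(p)
  expect_equal(s2$values, s$values, ignore_attr = TRUE)
  expect_equal(s2$angles, s$angles)
  expect_equal(s2$offsets, s$offsets)
})
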