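test_that("bilateral filtering reduces to known limits", {
  cc <- matrix(5, 12, 12)
  expect_equal(bilateral_filter(cc, 2, 10), cc, tolerance = 1e-12)

  set.seed(21)
  img <- matrix(runif(40 * 40) * 255, 40)
  # infinite range sigma -> plain Gaussian blur with the same kernel
  expect_equal(bilateral_filter(img, 2, 1e12), gaussian_blur(img, 2),
               tolerance = 1e-6)
  expect_error(bilateral_filter(img, -1, 10), "positive")
  expect_error(bilateral_filter(img, 2, 0), "positive")
})

test_that("bilateral filtering preserves a strong step edge", {
  step <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))
  out <- bilateral_filter(step, 2, sigma_range = 5)
  # no pixel crosses the midpoint of the step
  expect_true(all((out > 50) == (step > 50)))
  # adding a constant commutes exactly
  expect_equal(bilateral_filter(step + 7, 2, 5),
               bilateral_filter(step, 2, 5) + 7, tolerance = 1e-9)
  # output range within the input range
  expect_gte(min(out), 0)
  expect_lte(max(out), 100 + 1e-9)
})

test_that("BPDHE preserves brightness and degenerate structure", {
  cc <- matrix(3.5, 9, 9)
  expect_identical(bpdhe(cc), cc)

  set.seed(5)
  img <- matrix(runif(64 * 64) * 200 + 20, 64)
  out <- bpdhe(img)
  # mean brightness preserved to half a gray level
  rng <- diff(range(img))
  expect_lte(abs(mean(out) - mean(img)), 0.5 / 255 * rng)
  # output stays within the input intensity range
  expect_gte(min(out), min(img) - 1e-9)
  expect_lte(max(out), max(img) + 1e-9)

  # a balanced two-level image stays two-level with preserved ordering
  two <- matrix(c(10, 200), 32, 32)
  bt <- bpdhe(two)
  expect_equal(length(unique(round(as.vector(bt), 9))), 2)
  expect_true(all((bt[two == 200] > bt[two == 10][1])))
})

test_that("SVE scales singular values toward the uniform reference", {
  # the reference matrix itself is a fixed point (xi = 1)
  ref <- matrix(seq(0, 255, length.out = 32 * 32), 32, 32, byrow = TRUE)
  expect_equal(sve(ref), ref, tolerance = 1e-9)

  set.seed(8)
  img <- matrix(runif(30 * 30) * 255, 30)
  # xi is homogeneous of degree -1: scaling the input leaves the
  # (unclipped) output invariant
  expect_equal(sve(img, clip = FALSE), sve(img * 0.25, clip = FALSE),
               tolerance = 1e-9)
  # rank is preserved by a positive singular-value scaling
  low <- matrix(rnorm(20 * 3), 20) %*% matrix(rnorm(3 * 20), 3)
  expect_equal(qr(sve(low, range = range(low), clip = FALSE))$rank,
               qr(low)$rank)
  # all-zero input is returned unchanged
  expect_identical(sve(matrix(0, 5, 5)), matrix(0, 5, 5))
  # clipping keeps the output inside the stated range
  out <- sve(img)
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("the guided filter follows its local linear model", {
  set.seed(13)
  img <- matrix(runif(16 * 16), 16)
  # constant guide: a = 0, output is the box mean of the window means
  gd <- guided_filter(matrix(3, 16, 16), img, radius = 3, eps = 1e-4)
  expect_equal(gd, naive_box_mean(naive_box_mean(img, 3), 3),
               tolerance = 1e-10)

  # self-guidance with eps = 0 reproduces a piecewise-constant image away
  # from window-straddling boundaries
  pc <- cbind(matrix(1, 20, 10), matrix(4, 20, 10))
  out <- guided_filter(pc, pc, radius = 2, eps = 0)
  interior <- cbind(out[, 1:5], out[, 16:20])
  expect_equal(interior, cbind(pc[, 1:5], pc[, 16:20]), tolerance = 1e-9)

  # linear in the input for a fixed guide
  g <- matrix(runif(16 * 16), 16)
  p1 <- matrix(runif(16 * 16), 16)
  p2 <- matrix(runif(16 * 16), 16)
  expect_equal(guided_filter(g, 2 * p1 - 5 * p2, 3, 1e-3),
               2 * guided_filter(g, p1, 3, 1e-3) -
                 5 * guided_filter(g, p2, 3, 1e-3),
               tolerance = 1e-9)
  # adding a constant to the input shifts the output by that constant
  expect_equal(guided_filter(g, p1 + 2, 3, 1e-3),
               guided_filter(g, p1, 3, 1e-3) + 2, tolerance = 1e-9)
  expect_error(guided_filter(g, p1[1:10, ], 3, 1e-3), "size")
  expect_error(guided_filter(g, p1, 0), "radius")
})
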