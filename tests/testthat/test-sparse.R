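test_that("the degradation model blurs, decimates, and adds seeded noise", {
  set.seed(31)
  img <- matrix(runif(64 * 64), 64)
  # identity settings
  id <- degradation_spec(scale = 1L, blur_sigma = 0, noise_sigma = 0)
  expect_equal(degrade(img, id), img)
  # factor-2 decimation halves the side
  d2 <- degradation_spec(scale = 2L, blur_sigma = 1)
  expect_equal(dim(degrade(img, d2)), c(32, 32))
  expect_error(degrade(img[1:63, ], d2), "divisible")
  expect_error(degradation_spec(scale = 1.5), "integer")

  # the noise term has the half-normal mean sigma * sqrt(2/pi)
  dn <- degradation_spec(scale = 1L, blur_sigma = 0, noise_sigma = 0.1)
  z <- degrade(img, dn, seed = 5)
  expect_equal(mean(abs(z - img)), 0.1 * sqrt(2 / pi), tolerance = 0.05)
  expect_identical(z, degrade(img, dn, seed = 5))
})

test_that("upscaling recovers the grid and bounds smooth-image error", {
  cc <- matrix(4, 16, 16)
  spec <- degradation_spec(scale = 2L, blur_sigma = 0)
  up <- upscale(cc, spec)
  expect_equal(dim(up), c(32, 32))
  expect_true(all(abs(up - 4) < 1e-9))
  # round trip on a smooth ramp: bicubic reproduces linear surfaces in
  # the interior
  ramp <- outer(seq_len(64), seq_len(64), function(i, j) i + 0.5 * j) / 64
  z <- degrade(ramp, spec)
  back <- upscale(z, spec)
  expect_lt(max(abs(back - ramp)[8:56, 8:56]), 0.02)
})

test_that("the four high-pass filters respond as derivative operators", {
  flt <- highpass_filters()
  expect_length(flt, 4)
  cc <- matrix(5, 16, 16)
  expect_true(all(sapply(extract_lr_features(cc), function(f) max(abs(f)))
                  < 1e-12))

  # linear ramp along x: convolution with [1,0,-1] responds with
  # 2*slope (the kernel value at offset -1 is 1), second differences
  # vanish
  ramp <- matrix(rep(seq_len(16), each = 16), 16)   # varies along columns
  fx <- extract_lr_features(ramp)
  interior <- fx$dx[4:13, 4:13]
  expect_equal(as.vector(interior), rep(2, 100), tolerance = 1e-12)
  expect_lt(max(abs(fx$dxx[4:13, 4:13])), 1e-12)
  expect_lt(max(abs(fx$dy[4:13, 4:13])), 1e-12)

  # impulse response equals the flipped kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  r <- mesr:::conv2_reflect(imp, flt$dx)
  expect_equal(r[5, 4:6], c(1, 0, -1))  # flipped kernel
})

test_that("patch extraction and overlap averaging are mutually inverse", {
  img9 <- matrix(runif(81), 9)
  p <- extract_patches(img9, 9)
  expect_equal(ncol(p$patches), 1)
  img11 <- matrix(runif(121), 11)
  p11 <- extract_patches(img11, 9)
  expect_equal(ncol(p11$patches), 9)
  expect_error(extract_patches(img9, 10), "block")
  expect_error(extract_patches(img9, 3, stride = 0), "stride")

  set.seed(41)
  img <- matrix(runif(30 * 30), 30)
  g <- extract_patches(img, 7, stride = 1)
  expect_equal(reassemble_patches(g$patches, g), img)
})

test_that("PCA retains the smallest dimension reaching the variance target", {
  set.seed(51)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
  X <- basis %*% matrix(rnorm(3 * 200), 3)
  pca <- fit_pca_projection(X, 0.999)
  expect_equal(pca$dim, 3)
  expect_equal(tcrossprod(pca$rotation), diag(3), tolerance = 1e-9)

  Xn <- X + matrix(rnorm(20 * 200, 0, 0.01), 20)
  full <- fit_pca_projection(Xn, 1.0)
  expect_equal(full$dim, qr(Xn - rowMeans(Xn))$rank)

  # projecting then back-projecting loses at most the discarded variance
  rv <- 0.9
  pc <- fit_pca_projection(Xn, rv)
  Xc <- Xn - rowMeans(Xn)
  back <- t(pc$rotation) %*% pca_project(pc, Xn)
  lost <- sum((Xc - back)^2) / sum(Xc^2)
  expect_lte(lost, 1 - rv + 1e-9)

  expect_warning(fit_pca_projection(matrix(1, 5, 10)), "variance")
})

test_that("OMP recovers exact sparse representations", {
  set.seed(61)
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  # a scaled atom is recovered exactly
  r <- omp_code(Q, 2 * Q[, 3], sparsity = 3)
  expect_equal(r$support, 3L)
  expect_equal(r$coefficients[3], 2)
  expect_equal(r$residual_norm, 0, tolerance = 1e-12)
  # zero vector -> empty support
  z <- omp_code(Q, rep(0, 10))
  expect_length(z$support, 0)
  expect_equal(z$coefficients, rep(0, 10))

  # orthonormal dictionary: coefficients are inner products, selected in
  # decreasing magnitude
  x <- rnorm(10)
  enc <- omp_encode(Q, x, sparsity = 4)
  ip <- as.numeric(crossprod(Q, x))
  ord <- order(abs(ip), decreasing = TRUE)[1:4]
  expect_equal(enc$support[, 1], ord)
  expect_equal(enc$coef[, 1], ip[ord], tolerance = 1e-10)
})

test_that("OMP meets its least-squares and exhaustive-search oracles", {
  set.seed(62)
  A <- matrix(rnorm(8 * 12), 8)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  for (k in 1:10) {
    x <- rnorm(8)
    # full sparsity on a full-rank dictionary = unconstrained least squares
    full <- omp_code(A, x, sparsity = 8)
    expect_equal(full$residual_norm,
                 sqrt(sum(stats::lm.fit(A[, full$support], x)$residuals^2)),
                 tolerance = 1e-6)
    # sparsity 1 = exhaustive best single atom
    one <- omp_code(A, x, sparsity = 1)
    res1 <- sapply(seq_len(12), function(j)
      sqrt(sum((x - A[, j] * sum(A[, j] * x))^2)))
    expect_equal(one$residual_norm, min(res1), tolerance = 1e-10)
  }
})

test_that("K-SVD decreases the training error and recovers planted atoms", {
  rec <- ksvd_recovery(seed_data = 1, seed_ksvd = 101)
  expect_true(all(diff(rec$error) <= 1e-12))
  expect_gte(rec$recovery, 0.9)
  expect_equal(unname(colSums(rec$dictionary^2)), rep(1, 50),
               tolerance = 1e-9)
})

test_that("K-SVD initialization is seeded data atoms", {
  set.seed(71)
  X <- matrix(rnorm(10 * 40), 10)
  k0a <- ksvd_train(X, 8, 2, iterations = 0, seed = 3)
  k0b <- ksvd_train(X, 8, 2, iterations = 0, seed = 3)
  expect_identical(k0a$dictionary, k0b$dictionary)
  expect_length(k0a$error, 0)
  # every atom is a normalized training vector
  nX <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  match_best <- apply(abs(crossprod(k0a$dictionary, nX)), 1, max)
  expect_equal(unname(match_best), rep(1, 8), tolerance = 1e-12)
  expect_error(ksvd_train(X, 50, 2), "exceed")
})

test_that("the HR dictionary solve equals the normal-equation oracle", {
  set.seed(81)
  A <- matrix(rnorm(20 * 30), 20)
  Q <- matrix(0, 30, 200)
  for (j in 1:200) Q[sample(30, 3), j] <- rnorm(3)
  P <- A %*% Q
  expect_equal(solve_hr_dictionary(P, Q), A, tolerance = 1e-8)

  # noisy case: matches qr.solve and leaves a residual orthogonal to Q
  Pn <- P + matrix(rnorm(20 * 200, 0, 0.1), 20)
  Ah <- solve_hr_dictionary(Pn, Q)
  oracle <- t(qr.solve(tcrossprod(Q), Q %*% t(Pn)))
  expect_equal(Ah, oracle, tolerance = 1e-8)
  R <- Pn - Ah %*% Q
  expect_lt(max(abs(R %*% t(Q))), 1e-8)

  # rank-deficient codes are ridged with a warning
  Qd <- Q; Qd[30, ] <- 0
  expect_warning(solve_hr_dictionary(Pn, Qd), "ridge")
})
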