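test_that("the detail chain propagates zero detail and composes operators", {
  cc <- matrix(0.5, 32, 32)
  d <- build_mesr_detail_image(cc, cc)
  expect_true(all(abs(d$E_h_ppp) < 1e-9))
  expect_true(all(abs(d$E_h) < 1e-9))

  set.seed(91)
  y_l <- gaussian_blur(matrix(runif(48 * 48), 48), 2)
  y_h <- y_l + matrix(rnorm(48 * 48, 0, 0.05), 48)
  d <- build_mesr_detail_image(y_h, y_l)
  # stages compose the exported operators
  expect_equal(d$E_h, y_h - y_l)
  expect_equal(d$y_h_prime, bpdhe(bilateral_filter(y_h, 3)))
  expect_equal(d$E_h_p, d$y_h_prime - y_l)
  expect_true(all(dim(d$E_h_ppp) == dim(y_h)))
  expect_error(build_mesr_detail_image(y_h, y_l[1:10, ]), "size")
})

test_that("the detail chain keeps edges in place", {
  # vertical step edge; the enhanced detail must change sign at the same
  # column as the raw detail (no spatial shift)
  step <- cbind(matrix(0.1, 40, 20), matrix(0.9, 40, 20))
  spec <- degradation_spec(scale = 2L, blur_sigma = 1)
  y_l <- upscale(degrade(step, spec), spec)
  d <- build_mesr_detail_image(step, y_l)
  raw_profile <- colMeans(d$E_h)[17:24]
  enh_profile <- colMeans(d$E_h_ppp)[17:24]
  expect_equal(which.max(abs(diff(raw_profile))),
               which.max(abs(diff(enh_profile))))
})

test_that("training returns a coupled pair with the requested geometry", {
  set.seed(92)
  y_h <- gaussian_blur(matrix(runif(64 * 64), 64), 1.5)
  spec <- degradation_spec(scale = 2L, blur_sigma = 1)
  z_l <- degrade(y_h, spec)
  pair <- mesr_train(y_h, z_l, m = 40L, block = 7L, ksvd_iterations = 3L,
                     max_train_patches = 2000L, seed = 2)
  expect_s3_class(pair, "mesr_dictionary")
  expect_equal(ncol(pair$A_l), 40)
  expect_equal(ncol(pair$A_h), 40)
  expect_equal(nrow(pair$A_h), 49)
  expect_equal(unname(colSums(pair$A_l^2)), rep(1, 40), tolerance = 1e-9)
  # deterministic for a fixed seed
  pair2 <- mesr_train(y_h, z_l, m = 40L, block = 7L, ksvd_iterations = 3L,
                      max_train_patches = 2000L, seed = 2)
  expect_identical(pair$A_l, pair2$A_l)
  expect_identical(pair$A_h, pair2$A_h)
  # the experiment runners request the published dictionary sizes
  expect_equal(formals(run_shepp_logan_experiment)$dict_size, 1000L)
  expect_equal(formals(run_breast_experiment)$dict_size, 120L)
})

test_that("all-zero detail dictionaries reproduce the upscaled input", {
  set.seed(93)
  y_h <- gaussian_blur(matrix(runif(64 * 64), 64), 1.5)
  spec <- degradation_spec(scale = 2L, blur_sigma = 1)
  z_l <- degrade(y_h, spec)
  pair <- mesr_train(y_h, z_l, m = 30L, block = 7L, ksvd_iterations = 2L,
                     max_train_patches = 1500L, seed = 3)
  pair$A_h[] <- 0
  out <- sr_reconstruct(z_l, pair)
  expect_equal(out, upscale(z_l, spec), tolerance = 1e-12)
})

test_that("self-reconstruction beats plain interpolation", {
  set.seed(94)
  y_h <- gaussian_blur(matrix(runif(96 * 96), 96), 1)
  spec <- degradation_spec(scale = 2L, blur_sigma = 1)
  z_l <- degrade(y_h, spec)
  pair <- mesr_train(y_h, z_l, m = 60L, block = 7L, ksvd_iterations = 5L,
                     max_train_patches = 4000L, detail_chain = FALSE,
                     seed = 4)
  sr <- sr_reconstruct(z_l, pair)
  expect_gt(psnr_ref(y_h, sr), psnr_ref(y_h, upscale(z_l, spec)))
})

test_that("odd test sides are padded and cropped to side * scale", {
  set.seed(95)
  y_h <- gaussian_blur(matrix(runif(64 * 64), 64), 1.5)
  spec <- degradation_spec(scale = 2L, blur_sigma = 1)
  pair <- mesr_train(y_h, degrade(y_h, spec), m = 30L, block = 7L,
                     ksvd_iterations = 2L, max_train_patches = 1500L,
                     seed = 5)
  odd <- matrix(runif(63 * 63), 63)
  out <- sr_reconstruct(odd, pair)
  expect_equal(dim(out), c(126, 126))
})
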