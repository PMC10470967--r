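#' Pure interpolation super-resolution baseline
#'
#' @param z_l low-resolution matrix
#' @param method `"nearest"`, `"spline"`, or `"bicubic"`
#' @param scale integer upscaling factor
#' @return interpolated matrix of side `scale * side(z_l)`
#' @export
baseline_interpolate <- function(z_l, method = c("nearest", "spline", "bicubic"),
                                 scale = 2L) {
  method <- match.arg(method)
  z_l <- as.matrix(z_l)
  interp_resize(z_l, nrow(z_l) * scale, ncol(z_l) * scale, method = method)
}

experiment_angles <- function(n_angles) {
  seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
}

crop_to <- function(image, size) image[seq_len(size), seq_len(size), drop = FALSE]

#' Clamp and quantize a reconstruction to the 8-bit display convention
#'
#' Tomographic reconstructions of a density phantom are interpreted as
#' 8-bit grayscale images: values are clipped to the physical density range
#' `[lo, hi]` (negative streaks and overshoots are not representable) and
#' rounded to 256 levels.
#'
#' @param image numeric matrix
#' @param lo,hi representable density range
#' @return matrix with values on the 256-level grid within `[lo, hi]`
#' @export
as_display_image <- function(image, lo = 0, hi = 1) {
  round(pmin(pmax((image - lo) / (hi - lo), 0), 1) * 255) / 255 * (hi - lo) + lo
}

#' Reproduce the ellipse-phantom super-resolution comparison
#'
#' Full pipeline: (a) project the default ten-ellipse phantom, add seeded
#' Gaussian noise to the sinogram, and reconstruct a noisy SART training
#' image; (b) degrade it (blur + factor-`scale` decimation); (c) train the
#' dictionary pair, once with the enhancement chain (full method) and once
#' with the raw detail image (plain sparse-coding baseline); (d) project the
#' modified phantom, reconstruct the low-precision FBP image at the fine
#' grid (`scale * test_size`, clipped and quantized to the 8-bit density
#' range), and blur + downsample it to the `test_size` test image; (e)
#' super-resolve the test image by factor `scale` with nearest-neighbor
#' interpolation, spline interpolation, the sparse-coding baseline, and the
#' full method; (f) score every reconstruction against the modified phantom
#' rasterized at the fine grid.
#'
#' @param seed RNG seed controlling sinogram noise, patch subsampling and
#'   dictionary initialization
#' @param dict_size,block,scale,sparsity dictionary-pair hyperparameters
#' @param n_angles projection angles for both phantoms
#' @param train_size,test_size training / test image sides in pixels
#' @param sart_iterations,sart_lambda SART settings for the training image
#' @param sino_noise_frac sinogram noise level (fraction of max projection)
#' @param ksvd_iterations,retained_variance,max_train_patches training
#'   settings
#' @param out_dir optional output directory (metrics CSV, manifest, PNGs
#'   when the png package is available)
#' @return object of class `mesr_experiment`: `report` (tibble, one row per
#'   method in the order nearest, spline, sparse_baseline, mesr), `images`,
#'   `config`, `not_implemented` (deep-learning columns not reproduced)
#' @export
run_shepp_logan_experiment <- function(seed = 1L, dict_size = 1000L,
                                       block = 9L, scale = 2L,
                                       n_angles = 180L, train_size = 510L,
                                       test_size = 255L,
                                       sart_iterations = 20L,
                                       sart_lambda = 1.0,
                                       sino_noise_frac = 0.01,
                                       ksvd_iterations = 15L,
                                       retained_variance = 0.999,
                                       max_train_patches = 30000L,
                                       sparsity = 3L, out_dir = NULL) {
  angles <- experiment_angles(n_angles)
  dspec <- degradation_spec(scale = scale, blur_sigma = 1.0)

  # (a) noisy SART training image of the default phantom
  ph_train <- rasterize_ellipses(shepp_logan_ellipses(), train_size)
  dens_hi <- max(ph_train)
  sino_tr <- radon_forward(ph_train, angles)
  sino_tr <- add_sinogram_noise(sino_tr, sino_noise_frac, seed)
  y_h <- sart_reconstruct(sino_tr, train_size, sart_lambda, sart_iterations)
  y_h <- as_display_image(y_h, 0, dens_hi)

  # (b) degraded training input
  z_l <- degrade(y_h, dspec, seed)

  # (c) dictionary pairs: full method and raw-detail ablation; the LR
  # dictionary and codes depend only on y_l, so both targets share them
  y_l <- upscale(z_l, dspec)
  details <- build_mesr_detail_image(y_h, y_l)
  pairs <- train_pair_set(y_l,
                          list(base = y_h - y_l, mesr = details$E_h_ppp),
                          m = dict_size, block = block, sparsity = sparsity,
                          scale = scale, ksvd_iterations = ksvd_iterations,
                          retained_variance = retained_variance,
                          max_train_patches = max_train_patches,
                          upscaler = dspec$upscaler, seed = seed)
  pairs$base$detail_chain <- FALSE
  pairs$mesr$detail_chain <- TRUE

  # (d) low-precision FBP reconstruction of the modified phantom at the
  # fine grid, then blurred and downsampled to the test image: the
  # degraded FBP is the image the methods must super-resolve
  hr_size <- scale * test_size
  ph_ref <- rasterize_ellipses(modified_shepp_logan_ellipses(), hr_size)
  sino_te <- radon_forward(ph_ref, angles)
  fbp_img <- as_display_image(fbp_reconstruct(sino_te, hr_size), 0, dens_hi)
  z_t <- degrade(fbp_img, dspec, seed)

  # (e) super-resolve by `scale`
  sr <- sr_apply(z_t, pairs)
  recons <- list(
    nearest = interp_resize(z_t, hr_size, hr_size, method = "nearest"),
    spline = interp_resize(z_t, hr_size, hr_size, method = "spline"),
    sparse_baseline = sr[[1]],
    mesr = sr[[2]])
  recons <- lapply(recons, as_display_image, lo = 0, hi = dens_hi)

  # (f) metrics against the modified phantom at the fine grid
  report <- do.call(rbind, lapply(names(recons), function(m)
    metrics_report(ph_ref, recons[[m]], m)))

  res <- structure(
    list(report = report,
         images = c(list(reference = ph_ref, fbp = fbp_img, test_lr = z_t,
                         y_h = y_h), recons),
         config = list(seed = seed, dict_size = dict_size, block = block,
                       scale = scale, n_angles = n_angles,
                       train_size = train_size, test_size = test_size,
                       sart_iterations = sart_iterations,
                       sart_lambda = sart_lambda,
                       sino_noise_frac = sino_noise_frac,
                       ksvd_iterations = ksvd_iterations,
                       retained_variance = retained_variance,
                       max_train_patches = max_train_patches,
                       sparsity = sparsity),
         not_implemented = c("srcnn", "deeba")),
    class = "mesr_experiment")
  if (!is.null(out_dir)) save_experiment(res, out_dir, "shepp")
  res
}

#' Reproduce the ring-array breast imaging experiment
#'
#' Synthesizes a ring acquisition of the breast attenuation phantom,
#' converts amplitudes to attenuation line integrals against a water-only
#' reference, rearranges the pair data into a parallel-beam sinogram,
#' reconstructs a SART training image and an FBP test image, trains the
#' dictionary pair on the SART image, and super-resolves the FBP image.
#' Reconstructions are scored against the attenuation-contrast map (tissue
#' minus water), which is what the amplitude ratios project.
#'
#' @param seed RNG seed (patch subsampling, dictionary initialization)
#' @param dict_size,block,scale dictionary hyperparameters
#' @param n_transducers ring elements (even); the sinogram is
#'   `(N/2) x (N/2)`
#' @param size reconstruction side in pixels
#' @param sart_iterations,sart_lambda,ksvd_iterations,sparsity,
#'   max_train_patches training settings
#' @param amp_noise_frac fractional (log-normal) amplitude noise on the
#'   measured acquisition, seeded; 0 disables
#' @param out_dir optional output directory
#' @return object of class `mesr_experiment` with `report` rows `sart`,
#'   `fbp`, `mesr`, plus `images` and the rearranged `sinogram`
#' @export
run_breast_experiment <- function(seed = 1L, dict_size = 120L, block = 9L,
                                  scale = 2L, n_transducers = 256L,
                                  size = 128L, sart_iterations = 20L,
                                  sart_lambda = 1.0, ksvd_iterations = 15L,
                                  sparsity = 3L, max_train_patches = 30000L,
                                  amp_noise_frac = 0.01, out_dir = NULL) {
  tissues <- breast_tissues()
  phantom <- breast_phantom(tissues, size)
  water <- breast_phantom(tissues[tissues$tissue == "water", ], size)
  ref_rel <- phantom - water  # attenuation contrast actually projected

  acq <- simulate_ring_acquisition(phantom, n_transducers)
  if (amp_noise_frac > 0) {
    # multiplicative (log-normal) amplitude noise: measured peak pressures
    # carry a fractional error, which becomes additive Gaussian noise on
    # the log-ratio attenuation line integrals
    set.seed(seed)
    nz <- exp(matrix(stats::rnorm(length(acq$amplitudes), 0, amp_noise_frac),
                     n_transducers, n_transducers))
    acq <- ring_acquisition(acq$amplitudes * nz, acq$ring_radius)
  }
  ref_acq <- simulate_ring_acquisition(water, n_transducers)
  att <- amplitude_to_attenuation(acq, ref_acq)
  sino <- rearrange_ring_data(att)

  y_h <- sart_reconstruct(sino, size, sart_lambda, sart_iterations)
  fbp_img <- fbp_reconstruct(sino, size)

  dspec <- degradation_spec(scale = scale, blur_sigma = 1.0)
  z_l <- degrade(y_h, dspec, seed)
  pair <- mesr_train(y_h, z_l, m = dict_size, block = block,
                     sparsity = sparsity, scale = scale,
                     ksvd_iterations = ksvd_iterations,
                     max_train_patches = max_train_patches,
                     detail_chain = TRUE, degradation = dspec, seed = seed)
  sr <- sr_reconstruct(fbp_img, pair)
  ref_hr <- interp_resize(ref_rel, size * scale, method = "spline")

  report <- rbind(metrics_report(ref_rel, y_h, "sart"),
                  metrics_report(ref_rel, fbp_img, "fbp"),
                  metrics_report(ref_hr, sr, "mesr"))
  res <- structure(
    list(report = report, sinogram = sino,
         images = list(phantom = phantom, reference = ref_rel, sart = y_h,
                       fbp = fbp_img, mesr = sr),
         config = list(seed = seed, dict_size = dict_size, block = block,
                       scale = scale, n_transducers = n_transducers,
                       size = size, sart_iterations = sart_iterations,
                       sart_lambda = sart_lambda,
                       ksvd_iterations = ksvd_iterations,
                       sparsity = sparsity,
                       max_train_patches = max_train_patches),
         not_implemented = c("srcnn", "deeba")),
    class = "mesr_experiment")
  if (!is.null(out_dir)) save_experiment(res, out_dir, "breast")
  res
}

#' @export
print.mesr_experiment <- function(x, ...) {
  cat("<mesr_experiment>\n")
  print(x$report)
  invisible(x)
}

#' Metrics table of an experiment
#'
#' @param x a `mesr_experiment`
#' @return the metrics tibble (one row per reconstruction method)
#' @export
experiment_report <- function(x) x$report

save_experiment <- function(res, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep_out <- res$report
  for (m in res$not_implemented)
    rep_out <- rbind(rep_out,
                     tibble::tibble(method = paste0(m, " (not implemented)"),
                                    psnr = NA_real_, mse = NA_real_,
                                    entropy = NA_real_,
                                    avg_gradient = NA_real_,
                                    max_value = NA_real_))
  metrics_path <- file.path(out_dir, paste0(name, "_metrics.csv"))
  utils::write.csv(rep_out, metrics_path, row.names = FALSE)
  files <- metrics_path
  if (requireNamespace("png", quietly = TRUE)) {
    for (nm in names(res$images)) {
      img <- res$images[[nm]]
      p <- file.path(out_dir, paste0(name, "_", nm, ".png"))
      png::writePNG(rescale_255(img) / 255, p)
      files <- c(files, p)
    }
  }
  write_manifest(out_dir, res$config, files, name)
  invisible(res)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, package and R versions, and md5 hashes of the
#' produced files, so a run can be checked for bit-identical reproduction.
#'
#' @param out_dir output directory
#' @param config named list of run parameters (including the seed)
#' @param files files to hash
#' @param name run label
#' @return path of the manifest (invisibly)
#' @export
write_manifest <- function(out_dir, config, files, name = "run") {
  man <- list(name = name, config = config,
              r_version = R.version.string,
              package_version = as.character(utils::packageVersion("mesr")),
              files = as.list(tools::md5sum(files)))
  path <- file.path(out_dir, paste0(name, "_manifest.json"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(man, file = path)
  }
  invisible(path)
}

#' Write deterministic test fixtures
#'
#' Generates small plain-text fixtures: `disk` (uniform disk image),
#' `shepp` (ten-ellipse parameter table and raster), `breast` (tissue table
#' and attenuation raster), or `ring` (pair-amplitude matrix of a disk
#' phantom at `size` transducers). All outputs are CSV and byte-identical
#' across runs for a fixed seed.
#'
#' @param kind fixture family
#' @param seed RNG seed (recorded; the fixtures themselves are
#'   deterministic)
#' @param size image side or transducer count, depending on `kind`
#' @param dir output directory
#' @return character vector of file paths
#' @export
make_fixture <- function(kind = c("disk", "shepp", "breast", "ring"),
                         seed = 1L, size = 64L, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) {
    p <- file.path(dir, nm)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    p
  }
  set.seed(seed)
  if (kind == "disk") {
    img <- rasterize_ellipses(
      tibble::tibble(n0 = 1, x0 = 0, y0 = 0, a = 0.5, b = 0.5, phi = 0, rho = 1),
      size)
    return(wr(img, sprintf("disk_%d.csv", size)))
  }
  if (kind == "shepp") {
    p1 <- file.path(dir, "shepp_ellipses.csv")
    write_ellipses_csv(shepp_logan_ellipses(), p1)
    p2 <- wr(rasterize_ellipses(shepp_logan_ellipses(), size),
             sprintf("shepp_%d.csv", size))
    return(c(p1, p2))
  }
  if (kind == "breast") {
    p1 <- wr(breast_tissues(), "breast_tissues.csv")
    p2 <- wr(breast_phantom(breast_tissues(), size),
             sprintf("breast_%d.csv", size))
    return(c(p1, p2))
  }
  # ring: amplitudes of a uniform disk at `size` transducers
  img <- rasterize_ellipses(
    tibble::tibble(n0 = 1, x0 = 0, y0 = 0, a = 0.5, b = 0.5, phi = 0, rho = 1),
    64)
  acq <- simulate_ring_acquisition(img, size)
  wr(acq$amplitudes, sprintf("ring_%d.csv", size))
}
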