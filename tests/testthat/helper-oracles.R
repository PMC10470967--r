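# Shared fixtures and independent oracles used across the test files.

psnr_ref <- function(ref, img) {
  lo <- min(ref); hi <- max(ref)
  img_psnr(rescale_255(ref, lo, hi), rescale_255(img, lo, hi))
}

disk_spec <- function(radius = 0.5, rho = 1) {
  data.frame(n0 = 1, x0 = 0, y0 = 0, a = radius, b = radius, phi = 0,
             rho = rho)
}

disk_image <- function(size = 128, radius = 0.5, rho = 1) {
  rasterize_ellipses(disk_spec(radius, rho), size)
}

test_angles <- function(n) seq(0, 180, length.out = n + 1)[seq_len(n)]

# One full Eq-style SART sweep computed densely in R, updating per
# projection angle; `A` is the (rays x pixels) intersection-length matrix
# in pixel units, `angle_of` maps each ray to its angle group.
sart_sweep_dense <- function(f, A, p, angle_of, lambda = 1) {
  for (ang in unique(angle_of)) {
    rows <- which(angle_of == ang)
    Aa <- A[rows, , drop = FALSE]
    pa <- p[rows]
    Af <- as.numeric(Aa %*% f)
    s2 <- rowSums(Aa^2)
    ok <- s2 > 0
    num <- as.numeric(t(Aa[ok, , drop = FALSE]) %*%
                        ((lambda * pa[ok] - Af[ok]) / s2[ok]))
    den <- colSums(Aa[ok, , drop = FALSE])
    upd <- ifelse(den > 0, num / den, 0)
    f <- f + upd
  }
  f
}

# Intersection-length matrix recovered by projecting unit basis images
# with the package's ray model (tests the update rule independently of
# the traversal).
ray_matrix <- function(size, angles_deg, offsets) {
  th <- angles_deg * pi / 180
  A <- matrix(0, length(angles_deg) * length(offsets), size * size)
  for (j in seq_len(size * size)) {
    e <- matrix(0, size, size)
    e[j] <- 1
    A[, j] <- as.vector(t(mesr:::cpp_siddon_project(e, th, offsets)))
  }
  A
}

# naive windowed box mean with symmetric-reflect borders (guided-filter
# oracle)
naive_box_mean <- function(x, radius) {
  n <- nrow(x); m <- ncol(x)
  refl <- function(i, k) ifelse(i < 1, 1 - i, ifelse(i > k, 2 * k - i + 1, i))
  out <- matrix(0, n, m)
  for (r in seq_len(n))
    for (c in seq_len(m)) {
      rs <- refl((r - radius):(r + radius), n)
      cs <- refl((c - radius):(c + radius), m)
      out[r, c] <- mean(x[rs, cs])
    }
  out
}

# seeded 3-sparse synthetic dictionary-recovery experiment
ksvd_recovery <- function(seed_data = 1, seed_ksvd = 101, d = 20, m = 50,
                          N = 2000, iters = 80) {
  set.seed(seed_data)
  A0 <- matrix(rnorm(d * m), d, m)
  A0 <- sweep(A0, 2, sqrt(colSums(A0^2)), "/")
  S <- replicate(N, sample(m, 3))
  X <- sapply(seq_len(N), function(i) A0[, S[, i]] %*% rnorm(3))
  ks <- ksvd_train(X, m, 3, iters, seed_ksvd)
  M <- abs(crossprod(ks$dictionary, A0))
  list(recovery = mean(apply(M, 2, max) > 0.99), error = ks$error,
       dictionary = ks$dictionary)
}

# cache for the expensive full-protocol experiment runs shared between
# the acceptance criteria
.mesr_test_cache <- new.env(parent = emptyenv())

shepp_run <- function(seed) {
  key <- paste0("shepp_", seed)
  if (is.null(.mesr_test_cache[[key]]))
    .mesr_test_cache[[key]] <- run_shepp_logan_experiment(seed = seed)
  .mesr_test_cache[[key]]
}
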