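#' Degradation model specification
#'
#' The observation model producing a low-resolution image from a
#' high-resolution one: Gaussian blur (`blur_sigma`), decimation by an
#' integer `scale`, and optional additive Gaussian noise (`noise_sigma`).
#' The matching `upscaler` interpolation recovers the original grid size.
#'
#' @param scale integer upscaling factor (>= 1)
#' @param blur_sigma blur kernel standard deviation in pixels; 0 disables
#' @param noise_sigma standard deviation of additive Gaussian noise
#' @param upscaler interpolation used by [upscale()]
#' @return object of class `degradation_spec`
#' @export
degradation_spec <- function(scale = 2L, blur_sigma = 1.0, noise_sigma = 0,
                             upscaler = "bicubic") {
  if (scale < 1 || scale != round(scale)) stop("'scale' must be integer >= 1")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(scale = as.integer(scale), blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, upscaler = upscaler),
            class = "degradation_spec")
}

#' Degrade a high-resolution image
#'
#' Applies the observation model `z = D V y + v`: blur `V`, decimation `D`
#' (every `scale`-th pixel), and seeded additive Gaussian noise `v`.
#'
#' @param y_h high-resolution matrix, sides divisible by `spec$scale`
#' @param spec a [degradation_spec()]
#' @param seed RNG seed for the noise term
#' @return low-resolution matrix of side `side / scale`
#' @export
degrade <- function(y_h, spec = degradation_spec(), seed = 1L) {
  y_h <- as.matrix(y_h)
  if (any(dim(y_h) %% spec$scale != 0))
    stop("image sides must be divisible by the scale factor")
  z <- if (spec$blur_sigma > 0) gaussian_blur(y_h, spec$blur_sigma) else y_h
  z <- z[seq(1, nrow(z), by = spec$scale), seq(1, ncol(z), by = spec$scale),
         drop = FALSE]
  if (spec$noise_sigma > 0) {
    set.seed(seed)
    z <- z + matrix(stats::rnorm(length(z), 0, spec$noise_sigma),
                    nrow(z), ncol(z))
  }
  z
}

#' Upscale a low-resolution image back to the high-resolution grid
#'
#' @param z_l low-resolution matrix
#' @param spec a [degradation_spec()]; the interpolation rule and scale are
#'   taken from it
#' @return matrix of side `side * scale`
#' @export
upscale <- function(z_l, spec = degradation_spec()) {
  z_l <- as.matrix(z_l)
  interp_resize(z_l, nrow(z_l) * spec$scale, ncol(z_l) * spec$scale,
                method = spec$upscaler)
}

#' The four high-pass feature filters
#'
#' First derivatives `[1, 0, -1]` (horizontal and vertical) and second
#' derivatives `[1, 0, -2, 0, 1]` (horizontal and vertical), the standard
#' gradient/Laplacian feature set for sparse-coding super-resolution.
#'
#' @return list of four kernels (numeric matrices)
#' @export
highpass_filters <- function() {
  d1 <- matrix(c(1, 0, -1), 1, 3)
  d2 <- matrix(c(1, 0, -2, 0, 1), 1, 5)
  list(dx = d1, dy = t(d1), dxx = d2, dyy = t(d2))
}

conv2_reflect <- function(image, kernel) {
  # 2-D convolution, "same" size, symmetric-reflect borders
  kr <- nrow(kernel); kc <- ncol(kernel)
  rr <- (kr - 1) %/% 2; rc <- (kc - 1) %/% 2
  n <- nrow(image); m <- ncol(image)
  refl <- function(i, k) ifelse(i < 1, 1 - i, ifelse(i > k, 2 * k - i + 1, i))
  out <- matrix(0, n, m)
  for (a in seq_len(kr))
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      # convolution: output(i) += k(a) * image(i - (a - 1 - rr))
      ri <- refl(seq_len(n) - (a - 1 - rr), n)
      ci <- refl(seq_len(m) - (b - 1 - rc), m)
      out <- out + w * image[ri, ci, drop = FALSE]
    }
  out
}

#' High-pass feature maps of an upscaled low-resolution image
#'
#' Convolves the image with the four [highpass_filters()] (reflect
#' borders); the per-patch feature vector downstream concatenates the same
#' patch from all four maps.
#'
#' @param y_l matrix (the interpolated low-resolution image)
#' @return list of four filtered matrices
#' @export
extract_lr_features <- function(y_l) {
  lapply(highpass_filters(), function(k) conv2_reflect(as.matrix(y_l), k))
}

#' Extract vectorized patches on a stride grid
#'
#' @param image numeric matrix
#' @param block patch side length (pixels)
#' @param stride sampling step (>= 1)
#' @return list with `patches` (block^2 x n matrix, column-major pixel
#'   order), and `rows`, `cols` (top-left corners, 1-based)
#' @export
extract_patches <- function(image, block, stride = 1L) {
  image <- as.matrix(image)
  if (block > min(dim(image))) stop("'block' exceeds the image size")
  if (stride < 1) stop("'stride' must be >= 1")
  rs <- seq(1, nrow(image) - block + 1, by = stride)
  cs <- seq(1, ncol(image) - block + 1, by = stride)
  within <- as.vector(outer(0:(block - 1), 0:(block - 1),
                            function(dr, dc) dr + dc * nrow(image)))
  corners <- as.vector(outer(rs, (cs - 1) * nrow(image), `+`))
  P <- matrix(image[outer(within, corners, `+`)], nrow = block^2)
  list(patches = P,
       rows = rep(rs, times = length(cs)),
       cols = rep(cs, each = length(rs)),
       block = block, dim = dim(image))
}

#' Reassemble patches into an image by overlap averaging
#'
#' Inverse of [extract_patches()]: each patch is added back at its
#' location and every pixel is divided by the number of patches covering
#' it. At stride 1 with unmodified patches this reproduces the image
#' exactly.
#'
#' @param patches `block^2 x n` matrix of (possibly modified) patches
#' @param geom the list returned by [extract_patches()] (locations, block,
#'   image size)
#' @return reconstructed matrix; uncovered pixels are 0
#' @export
reassemble_patches <- function(patches, geom) {
  acc <- matrix(0, geom$dim[1], geom$dim[2])
  cnt <- matrix(0, geom$dim[1], geom$dim[2])
  b <- geom$block
  corners <- geom$rows + (geom$cols - 1) * geom$dim[1]
  within <- as.vector(outer(0:(b - 1), 0:(b - 1),
                            function(dr, dc) dr + dc * geom$dim[1]))
  for (d in seq_len(b^2)) {
    ii <- corners + within[d]
    acc[ii] <- acc[ii] + patches[d, ]
    cnt[ii] <- cnt[ii] + 1
  }
  acc[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  acc
}

#' Fit a PCA projection retaining a variance fraction
#'
#' Centers the feature vectors and keeps the smallest number of principal
#' directions whose cumulative variance reaches `retained_variance`. The
#' returned projector has orthonormal rows.
#'
#' @param X feature matrix, columns = observations
#' @param retained_variance fraction of total variance to keep (0, 1]
#' @return list with `rotation` (dim x d_in, orthonormal rows), `center`,
#'   and `dim` (retained dimension); class `pca_projection`
#' @export
fit_pca_projection <- function(X, retained_variance = 0.999) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two observations")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  # eigen-decomposition of the (small) feature covariance
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (sum(ev) <= 0) {
    warning("zero-variance features; returning identity projection")
    return(structure(list(rotation = diag(nrow(X)), center = ctr,
                          dim = nrow(X)), class = "pca_projection"))
  }
  cum <- cumsum(ev) / sum(ev)
  d <- which(cum >= retained_variance - 1e-12)[1]
  if (is.na(d)) d <- length(ev)
  structure(list(rotation = t(eg$vectors[, seq_len(d), drop = FALSE]),
                 center = ctr, dim = d), class = "pca_projection")
}

#' Apply a PCA projection to feature vectors
#'
#' @param pca a `pca_projection` from [fit_pca_projection()]
#' @param X feature matrix, columns = observations
#' @return projected matrix (`pca$dim` x n)
#' @export
pca_project <- function(pca, X) {
  pca$rotation %*% (as.matrix(X) - pca$center)
}

#' Sparse-code vectors with orthogonal matching pursuit
#'
#' Greedy sparse coding against a dictionary with unit-norm atoms: at each
#' step the atom with maximal absolute residual correlation is added and
#' the coefficients are refit by least squares on the selected support.
#' Stops at `sparsity` atoms or when the residual norm drops to `epsilon`.
#'
#' @param A dictionary, d x m, unit-norm columns
#' @param X matrix of vectors to code (d x n), or a single vector
#' @param sparsity maximum number of atoms per code
#' @param epsilon residual-norm stopping tolerance (default 0: code to the
#'   sparsity limit)
#' @return list with `support` (sparsity x n, 1-based atom indices, 0 =
#'   unused), `coef` (matching coefficients), `residual_norm` (length n)
#' @export
omp_encode <- function(A, X, sparsity = 3L, epsilon = 0) {
  X <- as.matrix(X)
  res <- cpp_omp(A, X, as.integer(sparsity), epsilon)
  res$support <- matrix(as.integer(res$support), nrow = sparsity)
  res
}

#' Sparse code of a single vector
#'
#' Convenience wrapper around [omp_encode()] returning a dense coefficient
#' vector of length `m` plus the support and residual.
#'
#' @inheritParams omp_encode
#' @param x vector to code
#' @return list with `coefficients` (length m), `support` (nonzero atom
#'   indices), `residual_norm`
#' @export
omp_code <- function(A, x, sparsity = 3L, epsilon = 0) {
  r <- omp_encode(A, matrix(x, ncol = 1), sparsity, epsilon)
  q <- numeric(ncol(A))
  sel <- r$support[, 1] > 0
  q[r$support[sel, 1]] <- r$coef[sel, 1]
  list(coefficients = q, support = r$support[sel, 1],
       residual_norm = r$residual_norm[1])
}

codes_to_sparse <- function(enc, m, n) {
  sel <- enc$support > 0
  Matrix::sparseMatrix(i = enc$support[sel],
                       j = rep(seq_len(n), each = nrow(enc$support))[sel],
                       x = enc$coef[sel], dims = c(m, n))
}

#' K-SVD dictionary learning
#'
#' Alternates OMP sparse coding of all training vectors with sequential
#' per-atom updates: for each atom, the restricted residual of the signals
#' using it is approximated by its leading singular pair (atom = left
#' singular vector, coefficients = scaled right singular vector). Unused or
#' near-duplicate atoms are replaced by the currently worst-represented
#' signals. Initialization is a seeded random subset of the training
#' vectors, normalized.
#'
#' @param X training matrix, columns = vectors (n >= m)
#' @param m dictionary size (number of atoms)
#' @param sparsity atoms per code during training
#' @param iterations number of coding/update rounds; 0 returns the
#'   initialization
#' @param seed RNG seed (initialization and replacements)
#' @return list with `dictionary` (unit-norm columns), `codes` (sparse
#'   m x n Matrix from the final coding pass), `error` (per-iteration mean
#'   squared representation error, non-increasing)
#' @export
ksvd_train <- function(X, m, sparsity = 3L, iterations = 15L, seed = 1L) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (m > n) stop("'m' must not exceed the number of training vectors")
  set.seed(seed)
  # seed atoms with distinct, non-degenerate training vectors
  nrm <- sqrt(colSums(X^2))
  cand <- sample(which(nrm > 1e-10))
  A <- X[, cand[seq_len(m)], drop = FALSE]
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  errs <- numeric(0)
  s_rows <- as.integer(sparsity)
  # triplet code store and residual matrix, maintained across iterations so
  # the coding stage can be safeguarded (a fresh OMP code is accepted only
  # where it improves that signal's residual; together with the SVD atom
  # update this makes the training error non-increasing by construction)
  Smat <- matrix(0L, s_rows, n)
  Cmat <- matrix(0, s_rows, n)
  R <- X
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      enc <- omp_encode(A, X, sparsity)
      acc <- enc$residual_norm^2 < colSums(R^2) - 1e-12
      if (any(acc)) {
        Smat[, acc] <- enc$support[, acc]
        Cmat[, acc] <- enc$coef[, acc]
        Qa <- codes_to_sparse(list(support = enc$support[, acc, drop = FALSE],
                                   coef = enc$coef[, acc, drop = FALSE]),
                              m, sum(acc))
        R[, acc] <- X[, acc, drop = FALSE] - as.matrix(A %*% Qa)
      }
      # entry indices of each atom in the triplet store
      ent <- split(seq_along(Smat), factor(Smat, levels = seq_len(m)))
      for (j in seq_len(m)) {
        e <- ent[[j]]
        if (length(e) == 0) next
        users <- (e - 1L) %/% s_rows + 1L
        qj <- Cmat[e]
        Ej <- R[, users, drop = FALSE] + outer(A[, j], qj)
        sv <- svd(Ej, nu = 1, nv = 1)
        a_new <- sv$u[, 1]
        q_new <- sv$d[1] * sv$v[, 1]
        A[, j] <- a_new
        Cmat[e] <- q_new
        R[, users] <- Ej - outer(a_new, q_new)
      }
      errs <- c(errs, mean(R^2))
      # replace unused and near-duplicate atoms by worst-represented
      # signals; a replacement whose re-coding would raise the residual is
      # reverted, so the logged error stays non-increasing by construction
      use_cnt <- tabulate(Smat[Smat > 0], nbins = m)
      G <- abs(crossprod(A)); diag(G) <- 0
      bad <- which(use_cnt < 4 | apply(G, 2, max) > 0.99)
      if (length(bad) > 0) {
        worst <- order(colSums(R^2), decreasing = TRUE)
        for (k in seq_along(bad)) {
          v <- X[, worst[k]]
          if (sqrt(sum(v^2)) <= 1e-10) next
          j <- bad[k]
          e <- ent[[j]]
          if (length(e) == 0) {           # unused atom: residual-neutral swap
            A[, j] <- v / sqrt(sum(v^2))
            next
          }
          # affected signals plus the donor (which the new atom represents)
          users <- unique(c((e - 1L) %/% s_rows + 1L, worst[k]))
          old <- list(a = A[, j], S = Smat[, users, drop = FALSE],
                      C = Cmat[, users, drop = FALSE],
                      R = R[, users, drop = FALSE])
          r2_old <- sum(old$R^2)
          drop_e <- e
          R[, (drop_e - 1L) %/% s_rows + 1L] <-
            R[, (drop_e - 1L) %/% s_rows + 1L, drop = FALSE] +
            outer(A[, j], Cmat[drop_e])
          Cmat[drop_e] <- 0
          Smat[drop_e] <- 0L
          A[, j] <- v / sqrt(sum(v^2))
          enc2 <- omp_encode(A, X[, users, drop = FALSE], sparsity)
          if (sum(enc2$residual_norm^2) <= r2_old + 1e-12) {
            Smat[, users] <- enc2$support
            Cmat[, users] <- enc2$coef
            Q2 <- codes_to_sparse(enc2, m, length(users))
            R[, users] <- X[, users, drop = FALSE] - as.matrix(A %*% Q2)
          } else {                        # revert: keep the old atom/codes
            A[, j] <- old$a
            Smat[, users] <- old$S
            Cmat[, users] <- old$C
            R[, users] <- old$R
          }
        }
      }
    }
  }
  enc <- omp_encode(A, X, sparsity)
  list(dictionary = A, codes = codes_to_sparse(enc, m, n), error = errs)
}

#' Solve the high-resolution dictionary by least squares
#'
#' Given high-resolution patches `P_h` and their sparse codes `Q` (from the
#' low-resolution dictionary), the high-resolution dictionary minimizing
#' `sum_k ||p_k - A q_k||^2` is the normal-equation solution
#' `A_h = P_h Q' (Q Q')^{-1}`. A rank-deficient Gram matrix is ridged by
#' `1e-8 * trace / m` with a warning.
#'
#' @param P_h patch matrix (n x N)
#' @param Q code matrix (m x N), dense or sparse
#' @return `A_h` (n x m)
#' @export
solve_hr_dictionary <- function(P_h, Q) {
  Q <- methods::as(Q, "CsparseMatrix")
  G <- as.matrix(Matrix::tcrossprod(Q))          # Q Q'
  B <- as.matrix(Matrix::tcrossprod(P_h, Q))     # P Q'
  ok <- tryCatch({ch <- chol(G); TRUE}, error = function(e) FALSE)
  if (!ok) {
    warning("rank-deficient code Gram matrix; adding ridge")
    G <- G + diag(1e-8 * sum(diag(G)) / nrow(G), nrow(G))
  }
  t(solve(G, t(B)))
}
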