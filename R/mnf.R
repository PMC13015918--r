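#' Noise whitening
#'
#' Projects the data onto the noise eigenbasis and rescales each direction
#' by the inverse square root of its noise variance, `W = X V L^(-1/2)`,
#' so the transformed noise has unit variance in every band and is
#' decorrelated. For a diagonal noise model this reduces to column-wise
#' division by the per-band noise standard deviation.
#'
#' @param cube a [spectral_cube()].
#' @param noise a [noise_covariance()] of matching dimension; all noise
#'   variances must be positive (dense: positive definite).
#' @return `m x v` whitened matrix.
#' @export
whiten <- function(cube, noise) {
  ws <- whitening_system(noise, v = ncol(cube$spectra))
  cube$spectra %*% ws$A
}

## Whitening system: A = V L^(-1/2) (maps data to whitened space) and its
## inverse Ainv = L^(1/2) V^T, plus the noise eigensystem. With
## reduce = TRUE a rank-deficient dense covariance is whitened into its
## rank-r noise subspace (A is v x r) with a warning, the SVD
## dimensionality-reduction treatment standard in fast-MNF
## implementations; with reduce = FALSE singularity is an error.
whitening_system <- function(noise, v, reduce = FALSE) {
  if (noise_dim(noise) != v)
    stop("noise covariance dimension (", noise_dim(noise),
         ") does not match cube bands (", v, ")")
  if (noise$kind == "diagonal") {
    p <- noise$profile
    bad <- which(!is.finite(p) | p <= 0)
    if (length(bad))
      stop("noise variance is not positive at band index ", bad[1])
    s <- sqrt(p)
    list(A = diag(1 / s, v), Ainv = diag(s, v),
         eigvecs = diag(v), eigvals = p)
  } else {
    S <- noise$matrix
    e <- eigen(S, symmetric = TRUE)
    lam <- e$values
    tol <- max(abs(lam)) * 1e-12
    keep <- lam > tol
    if (!all(keep)) {
      bad <- which(!keep)[1]
      if (!reduce)
        stop("noise covariance is singular or not positive definite ",
             "(eigenvalue index ", bad, " of ", v, " is ",
             format(lam[bad]), "); regularise or use a diagonal model")
      warning("noise covariance is rank-deficient (rank ", sum(keep),
              " of ", v, "); whitening into the reduced noise subspace")
      lam <- lam[keep]
    }
    V <- e$vectors[, keep, drop = FALSE]
    A <- sweep(V, 2, sqrt(lam), "/")
    Ainv <- t(sweep(V, 2, sqrt(lam), "*"))
    list(A = A, Ainv = Ainv, eigvecs = V, eigvals = lam)
  }
}

## deterministic eigenvector sign convention: flip each column so its
## largest-magnitude entry is positive
fix_signs <- function(G) {
  flip <- apply(G, 2, function(g) {
    j <- which.max(abs(g))
    if (g[j] < 0) -1 else 1
  })
  sweep(G, 2, flip, "*")
}

#' Fit a minimum noise fraction model
#'
#' The MNF transform whitens the data against a noise covariance, finds
#' the variance-maximising orthogonal components of the whitened data
#' (equivalently, components ordered by signal-to-noise ratio, since the
#' whitened noise has unit variance), and keeps the top `k` for
#' reconstruction. The second decomposition is computed through the SVD
#' of the whitened matrix `W` rather than an explicit eigendecomposition
#' of `W'W`, for numerical stability; both give the eigensystem of `W'W`.
#' Neither decomposition mean-centres the data: raw cross-products are
#' used throughout, matching the fast-MNF lineage this transform follows.
#' A rank-deficient dense noise covariance (fewer difference spectra than
#' bands, or collinear noise) is whitened into its rank-`r` subspace with
#' a warning, in which case `k` must not exceed `r`.
#'
#' Denoise data with [predict.mnf()]; the fitted (denoised) training cube
#' is available via [fitted.mnf()].
#'
#' @param cube a [spectral_cube()] with at least 2 spectra.
#' @param noise a [noise_covariance()]; defaults to the spatially
#'   invariant estimate [estimate_noise_imnf()] on `cube`.
#' @param k number of MNF bands kept for reconstruction (default 30, the
#'   value established in spectral-pathology practice).
#' @return object of class `"mnf"`: list with `noise_eigvecs`,
#'   `noise_eigvals`, `signal_eigvecs` (`G`), `signal_eigvals`
#'   (nonincreasing), `k`, `forward` (`v x k`, maps spectra to scores),
#'   `reconstruction` (`k x v`), `noise`, `axis`, `m`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(16, 16)))
#' ph <- add_noise(ph, sigma_t = 0.005, seed = 1)
#' fit <- mnf(ph$noisy, k = 10)
#' fit
#' den <- predict(fit, ph$noisy)
#' @export
mnf <- function(cube, noise = estimate_noise_imnf(cube), k = 30L) {
  X <- cube$spectra
  v <- ncol(X)
  if (nrow(X) < 2) stop("MNF needs at least 2 spectra")
  k <- as.integer(k)
  if (k < 1 || k > v) stop("k must be between 1 and v = ", v)
  ws <- whitening_system(noise, v, reduce = TRUE)
  r <- ncol(ws$A)
  if (k > r)
    stop("k = ", k, " exceeds the usable rank r = ", r,
         " of the noise covariance")
  W <- X %*% ws$A
  sv <- svd(W, nu = 0)
  G <- fix_signs(sv$v)
  lam <- sv$d^2                       # eigenvalues of W'W, nonincreasing
  Gk <- G[, seq_len(k), drop = FALSE]
  forward <- ws$A %*% Gk              # X %*% forward = scores
  reconstruction <- t(Gk) %*% ws$Ainv # scores %*% reconstruction = denoised
  structure(list(noise_eigvecs = ws$eigvecs, noise_eigvals = ws$eigvals,
                 signal_eigvecs = G, signal_eigvals = lam, k = k,
                 forward = forward, reconstruction = reconstruction,
                 noise = noise, axis = cube$axis, m = nrow(X)),
            class = "mnf")
}

#' @export
print.mnf <- function(x, ...) {
  cat("Minimum noise fraction model\n")
  cat("  fitted on ", x$m, " spectra x ", length(x$axis), " bands; ",
      x$k, " bands retained\n", sep = "")
  cat("  noise model: ", x$noise$kind, " (", x$noise$provenance, ")\n", sep = "")
  top <- utils::head(x$signal_eigvals, 3)
  cat("  leading SNR eigenvalues: ", paste(format(top, digits = 4),
                                           collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' @export
summary.mnf <- function(object, ...) {
  lam <- object$signal_eigvals
  out <- list(k = object$k, v = length(object$axis), m = object$m,
              noise = object$noise,
              eigvals = lam,
              retained_fraction = sum(lam[seq_len(object$k)]) / sum(lam))
  class(out) <- "summary.mnf"
  out
}

#' @export
print.summary.mnf <- function(x, ...) {
  cat("MNF model: ", x$m, " spectra, ", x$v, " bands, k = ", x$k, "\n", sep = "")
  cat("  noise model: ", x$noise$kind, " (", x$noise$provenance, ")\n", sep = "")
  cat("  whitened-variance fraction retained: ",
      format(100 * x$retained_fraction, digits = 4), "%\n", sep = "")
  cat("  eigenvalue quartiles:\n")
  print(stats::quantile(x$eigvals))
  invisible(x)
}

#' @export
coef.mnf <- function(object, ...) object$forward

#' Denoise spectra with a fitted MNF model
#'
#' Projects the data into the truncated MNF component space and back:
#' `D = (X Phi_K) R_K`. Each output row depends only on the corresponding
#' input row, so a fixed model can be applied patch-by-patch, in any
#' order, with results identical to a whole-image pass.
#'
#' @param object a fitted [mnf()] model.
#' @param newdata a [spectral_cube()] (or bare matrix) with the same band
#'   count the model was fitted on.
#' @param type `"denoised"` for the reconstructed cube, `"scores"` for the
#'   `m x k` MNF component scores.
#' @param ... unused.
#' @return a [spectral_cube()] of denoised spectra (same axis/shape as the
#'   input), or a score matrix for `type = "scores"`.
#' @export
predict.mnf <- function(object, newdata, type = c("denoised", "scores"), ...) {
  type <- match.arg(type)
  is_cube <- inherits(newdata, "spectral_cube")
  X <- if (is_cube) newdata$spectra else as.matrix(newdata)
  if (ncol(X) != nrow(object$forward))
    stop("model expects ", nrow(object$forward), " bands, data has ", ncol(X))
  if (type == "scores") return(X %*% object$forward)
  D <- project_spectra(X, object$forward, object$reconstruction)
  if (is_cube) cube_with(newdata, D) else D
}

## Row-deterministic projection kernel: each output row is computed with
## arithmetic that depends only on that input row, never on how many rows
## accompany it in the batch. (Optimised BLAS gemm picks kernels by matrix
## shape, so per-patch gemm is not bitwise-reproducible against a
## whole-image pass; this kernel is, which makes the patch-wise and
## streaming guarantees exact rather than approximate.)
project_spectra <- function(X, forward, reconstruction) {
  m <- nrow(X)
  D <- matrix(0, m, ncol(reconstruction))
  vk <- nrow(forward); k <- ncol(forward); vr <- ncol(reconstruction)
  for (i in seq_len(m)) {
    s <- .colSums(forward * X[i, ], vk, k)
    D[i, ] <- .colSums(reconstruction * s, k, vr)
  }
  D
}

#' @rdname predict.mnf
#' @param cube a [spectral_cube()] to denoise.
#' @param model a fitted [mnf()] model.
#' @export
denoise <- function(cube, model) predict(model, cube)

#' Residual (removed-noise) spectra
#'
#' The training cube is not stored in the model (row locality makes a
#' fresh `predict()` exact), so the cube must be supplied.
#'
#' @param object a fitted [mnf()] model.
#' @param cube the [spectral_cube()] to compare against its denoised version.
#' @param ... unused.
#' @return `m x v` matrix `X - D` of removed noise.
#' @export
residuals.mnf <- function(object, cube, ...) {
  if (missing(cube))
    stop("supply the cube: the model does not store its training data")
  cube$spectra - predict(object, cube)$spectra
}

#' Scree plot of MNF signal eigenvalues
#'
#' @param x a fitted [mnf()] model.
#' @param n number of leading eigenvalues to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mnf <- function(x, n = min(60L, length(x$signal_eigvals)), ...) {
  lam <- x$signal_eigvals[seq_len(n)]
  graphics::plot(seq_along(lam), lam, log = "y", type = "b", pch = 20,
                 xlab = "MNF component", ylab = "eigenvalue (SNR ordering)", ...)
  graphics::abline(v = x$k + 0.5, lty = 2)
  invisible(x)
}

#' PCA (uncentred truncated-SVD) denoising
#'
#' Reconstructs the cube from its top `k` singular vectors without
#' centring, matching the MNF formulation here. With a uniform (white)
#' noise model MNF reduces exactly to this, so it doubles as the
#' white-noise cross-check for [mnf()].
#'
#' @param cube a [spectral_cube()].
#' @param k number of components, `1 <= k <= v`.
#' @return a [spectral_cube()] of reconstructed spectra.
#' @export
pca_denoise <- function(cube, k) {
  X <- cube$spectra
  v <- ncol(X)
  k <- as.integer(k)
  if (k < 1 || k > v) stop("k must be between 1 and v = ", v)
  sv <- svd(X, nu = 0)
  Vk <- sv$v[, seq_len(k), drop = FALSE]
  cube_with(cube, X %*% Vk %*% t(Vk))
}

#' Extract MNF factor images
#'
#' Reshapes selected MNF score columns back to the 2-D image grid. Early
#' factors carry the bulk of coherent signal, so well-delineated tissue
#' morphology in the first factor images is a quick visual check that the
#' noise model is sound.
#'
#' @param model a fitted [mnf()] model.
#' @param cube the [spectral_cube()] to score; must have `shape2d`.
#' @param indices 1-based component indices, all `<= k`.
#' @return named list of `y x x` matrices, one per requested component.
#' @export
factor_images <- function(model, cube, indices = seq_len(min(4L, model$k))) {
  if (is.null(cube$shape2d))
    stop("factor images need a cube with 2-D shape information")
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > model$k))
    stop("factor indices must lie in 1..k = ", model$k)
  sc <- predict(model, cube, type = "scores")
  y <- cube$shape2d[1]; x <- cube$shape2d[2]
  out <- lapply(indices, function(j) matrix(sc[, j], nrow = y, ncol = x,
                                            byrow = TRUE))
  names(out) <- paste0("factor", indices)
  out
}
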