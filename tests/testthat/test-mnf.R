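test_that("whitening handles identity, scalar and dense covariances", {
  X <- matrix(rnorm(40), 8, 5)
  cube <- spectral_cube(X, axis = 1:5)
  # identity noise: whitening is a no-op
  expect_equal(whiten(cube, uniform_noise(5, 1)), X)
  # uniform variance 4: every entry divided by 2
  ones <- spectral_cube(matrix(1, 3, 5), axis = 1:5)
  expect_equal(whiten(ones, uniform_noise(5, 4)),
               matrix(0.5, 3, 5))
  # dense covariance from a toy noise matrix: whitened noise must have
  # unit variance and no correlation (the defining contract, checked on
  # the noise itself)
  set.seed(4)
  N <- matrix(rnorm(200), 50, 4)
  S <- crossprod(N) / nrow(N)
  noise <- noise_covariance(matrix = S)
  ncube <- spectral_cube(N / sqrt(nrow(N)), axis = 1:4)
  Wn <- whiten(ncube, noise)
  expect_equal(crossprod(Wn), diag(4), tolerance = 1e-10)
})

test_that("whitening rejects mismatched or degenerate noise", {
  cube <- spectral_cube(matrix(rnorm(20), 4, 5), axis = 1:5)
  expect_error(whiten(cube, uniform_noise(4, 1)), "dimension")
  bad <- noise_covariance(profile = rep(1, 5))
  bad$profile[3] <- 0  # bypass constructor to hit whiten's own check
  expect_error(whiten(cube, bad), "band index 3")
  sing <- noise_covariance(matrix = diag(c(1, 1, 1, 1, 0)))
  expect_error(whiten(cube, sing), "singular|positive definite")
})

test_that("rank-1 data with k = 1 is reconstructed exactly", {
  set.seed(7)
  u <- rnorm(30); w <- rnorm(6)
  X <- outer(u, w)                       # exactly rank 1, no noise
  cube <- spectral_cube(X, axis = 1:6)
  fit <- mnf(cube, uniform_noise(6), k = 1)
  expect_gt(fit$signal_eigvals[1] / (fit$signal_eigvals[2] + 1e-30), 1e10)
  expect_lt(max(abs(predict(fit, cube)$spectra - X)), 1e-8)
})

test_that("k = v reconstruction is the identity for any noise model", {
  ph <- small_phantom(shape = c(24L, 24L))  # enough pixels for a full-rank
                                            # adjacent-difference covariance
  v <- ncol(ph$noisy$spectra)
  for (noise in list(uniform_noise(v, 0.3),
                     estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy)),
                     estimate_noise_adjacent(ph$noisy))) {
    fit <- mnf(ph$noisy, noise, k = v)
    expect_lt(max(abs(fit$forward %*% fit$reconstruction - diag(v))), 1e-7)
    expect_lt(max(abs(predict(fit, ph$noisy)$spectra - ph$noisy$spectra)),
              1e-8)
  }
})

test_that("MNF under uniform noise equals uncentred truncated-SVD denoising", {
  ph <- small_phantom(shape = c(8L, 8L))
  v <- ncol(ph$noisy$spectra)
  for (k in c(1L, 3L, 10L)) {
    for (c0 in c(1, 0.25)) {             # any uniform variance, same answer
      fit <- mnf(ph$noisy, uniform_noise(v, c0), k = k)
      expect_lt(max(abs(predict(fit, ph$noisy)$spectra -
                        pca_denoise(ph$noisy, k)$spectra)), 1e-6)
    }
  }
})

test_that("pca_denoise reconstructs low-rank data exactly", {
  set.seed(8)
  X <- outer(rnorm(20), rnorm(7)) + outer(rnorm(20), rnorm(7))  # rank 2
  cube <- spectral_cube(X, axis = 1:7)
  expect_lt(max(abs(pca_denoise(cube, 2)$spectra - X)), 1e-8)
  expect_equal(pca_denoise(cube, 7)$spectra, X, tolerance = 1e-10)
  expect_error(pca_denoise(cube, 8), "between 1 and v")
})

test_that("scaling all noise variances leaves the denoised output unchanged", {
  ph <- small_phantom(shape = c(8L, 8L))
  noise <- estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy))
  fit1 <- mnf(ph$noisy, noise, k = 12)
  for (c0 in c(17, 1e-4)) {
    noise2 <- noise_covariance(profile = noise$profile * c0)
    fit2 <- mnf(ph$noisy, noise2, k = 12)
    expect_lt(max(abs(predict(fit1, ph$noisy)$spectra -
                      predict(fit2, ph$noisy)$spectra)), 1e-6)
    # eigenvalues scale by 1/c0, eigenvectors are preserved
    expect_equal(fit2$signal_eigvals, fit1$signal_eigvals / c0,
                 tolerance = 1e-8)
  }
})

test_that("denoising is row-local: permuting rows commutes bitwise", {
  ph <- small_phantom()
  fit <- mnf(ph$noisy, estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy)),
             k = 15)
  D <- predict(fit, ph$noisy)$spectra
  sh <- shuffle_cube(ph$noisy, seed = 5)
  Dsh <- predict(fit, sh$cube)$spectra
  expect_identical(Dsh[order(sh$perm), , drop = FALSE], D)
})

test_that("denoising with the same model is an idempotent projection", {
  ph <- small_phantom(shape = c(8L, 8L))
  fit <- mnf(ph$noisy, estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy)),
             k = 8)
  # explicit projector oracle: P = forward %*% reconstruction must satisfy
  # P %*% P = P, hence denoise(denoise(X)) = denoise(X)
  P <- fit$forward %*% fit$reconstruction
  expect_lt(max(abs(P %*% P - P)), 1e-8)
  D1 <- predict(fit, ph$noisy)
  D2 <- predict(fit, D1)
  expect_lt(max(abs(D2$spectra - D1$spectra)), 1e-8)
})

test_that("signal eigenvalues are nonincreasing for every fit", {
  ph <- small_phantom(shape = c(8L, 8L))
  for (noise in list(uniform_noise(ncol(ph$noisy$spectra)),
                     estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy)),
                     estimate_noise_adjacent(ph$noisy))) {
    # 64 pixels give a rank-deficient adjacent covariance: the fit
    # reduces to the noise subspace (with a warning) and must still be
    # SNR-ordered
    fit <- suppressWarnings(mnf(ph$noisy, noise, k = 5))
    expect_true(all(diff(fit$signal_eigvals) <= 1e-9))
  }
})

test_that("denoising reduces silent-region variance on a noisy phantom", {
  ph <- small_phantom()
  reg <- qcl_silent(ph$noisy)
  fit <- mnf(ph$noisy, estimate_noise_imnf(ph$noisy, reg), k = 10)
  den <- predict(fit, ph$noisy)
  expect_lt(silent_variance(den, reg), silent_variance(ph$noisy, reg))
})

test_that("factor images have image shape and track the class map", {
  ph <- small_phantom()
  fit <- mnf(ph$noisy, estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy)),
             k = 3)
  imgs <- factor_images(fit, ph$noisy, 1:3)
  expect_length(imgs, 3)
  expect_identical(dim(imgs[[1]]), as.integer(ph$spec$shape))
  # an early factor must correlate with spatial class structure
  r <- max(abs(vapply(imgs, function(im)
    stats::cor(as.vector(im), as.vector(ph$labels)), 0)))
  expect_gt(r, 0.5)
  expect_error(factor_images(fit, ph$noisy, 4), "1..k")
  nocube <- spectral_cube(ph$noisy$spectra, ph$noisy$axis)
  expect_error(factor_images(fit, nocube), "shape")
})

test_that("model accessors and guards behave", {
  ph <- small_phantom(shape = c(8L, 8L))
  noise <- estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy))
  expect_error(mnf(ph$noisy, noise, k = 0), "between 1 and v")
  expect_error(mnf(ph$noisy, noise, k = 1000), "between 1 and v")
  one <- spectral_cube(ph$noisy$spectra[1, , drop = FALSE], ph$noisy$axis)
  expect_error(mnf(one, noise), "at least 2")
  fit <- mnf(ph$noisy, noise, k = 6)
  expect_identical(dim(coef(fit)), c(425L, 6L))
  expect_identical(dim(predict(fit, ph$noisy, type = "scores")), c(64L, 6L))
  res <- residuals(fit, ph$noisy)
  expect_equal(res, ph$noisy$spectra - predict(fit, ph$noisy)$spectra)
  expect_output(print(fit), "bands retained")
  expect_output(print(summary(fit)), "fraction retained")
})
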