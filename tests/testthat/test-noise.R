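test_that("adjacent differencing matches the hand-computed cross-product", {
  # X = [[0,0],[1,2]] -> N = [[-1,-2]], NtN = [[1,2],[2,4]]
  cube <- spectral_cube(rbind(c(0, 0), c(1, 2)), axis = 1:2)
  S <- estimate_noise_adjacent(cube)
  expect_equal(S$matrix, rbind(c(1, 2), c(2, 4)))
  expect_identical(S$kind, "dense")
  # identical spectra difference to zero
  same <- spectral_cube(rbind(c(3, 1), c(3, 1)), axis = 1:2)
  expect_equal(estimate_noise_adjacent(same)$matrix, matrix(0, 2, 2))
  expect_error(estimate_noise_adjacent(spectral_cube(matrix(1, 1, 2), 1:2)),
               "at least 2")
})

test_that("adjacent covariance is order-dependent, the iMNF profile is not", {
  ph <- small_phantom()
  sh <- shuffle_cube(ph$noisy, seed = 21)
  Sa <- estimate_noise_adjacent(ph$noisy)$matrix
  Sb <- estimate_noise_adjacent(sh$cube)$matrix
  expect_gt(max(abs(Sa - Sb)), 1e-6 * max(abs(Sa)))
  reg <- qcl_silent(ph$noisy)
  p1 <- estimate_noise_imnf(ph$noisy, reg)$profile
  p2 <- estimate_noise_imnf(sh$cube, qcl_silent(sh$cube))$profile
  expect_lt(max(abs(p1 - p2) / p1), 1e-10)
})

test_that("dropping row-boundary pairs removes exactly height-1 differences", {
  ph <- small_phantom(shape = c(8L, 8L))
  keep <- estimate_noise_adjacent(ph$noisy)
  drop_ <- estimate_noise_adjacent(ph$noisy, drop_edge_pairs = TRUE)
  # oracle: recompute from the definition over within-row pairs only
  X <- ph$noisy$spectra
  N <- X[-64, ] - X[-1, ]
  inrow <- seq_len(63) %% 8 != 0
  expect_equal(drop_$matrix, crossprod(N[inrow, ]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(keep$matrix, drop_$matrix)))
})

test_that("SG base variance matches its closed-form filter oracle", {
  # constant spectra -> zero
  reg_axis <- 1:30
  const <- spectral_cube(matrix(5, 20, 30), axis = reg_axis)
  regc <- silent_region(reg_axis, 1, 30)
  expect_equal(sg_base_variance(const, regc), 0)
  # linear ramp -> first derivative constant -> variance 0
  ramp <- spectral_cube(matrix(rep(2 * reg_axis, each = 20), 20, 30),
                        axis = reg_axis)
  expect_lt(sg_base_variance(ramp, regc), 1e-12)
  # iid N(0, s2) noise, window 5 / order 2, unit spacing:
  # derivative = sum c_i x_i with c = (-2,-1,0,1,2)/10, so the derivative
  # variance is s2 * sum(c^2) = 0.1 * s2
  s2 <- 0.49
  wc <- white_cube(10000, 30, sd = sqrt(s2), seed = 12)
  got <- sg_base_variance(wc, regc, window = 5, polyorder = 2)
  expect_equal(got, 0.1 * s2, tolerance = 0.05)
})

test_that("SG base variance validates its parameters", {
  wc <- white_cube(10, 30, seed = 1)
  reg <- silent_region(wc$axis, 1, 30)
  expect_error(sg_base_variance(wc, reg, window = 4), "odd")
  expect_error(sg_base_variance(wc, reg, window = 5, polyorder = 4),
               "polyorder")
  short <- silent_region(wc$axis, 1, 4)
  expect_error(sg_base_variance(wc, short, window = 5), "longer")
})

test_that("transmittance conversion follows base-10 Beer-Lambert with clamp", {
  expect_equal(to_transmittance(0), 1)
  expect_equal(to_transmittance(1), 0.1)
  expect_equal(to_transmittance(c(0, 2)), c(1, 0.01))
  # A = 9 would give 1e-9; clamped at 1e-6
  expect_equal(to_transmittance(9), 1e-6)
  expect_error(to_transmittance(c(1, NA)), "non-finite")
})

test_that("reference transmittance is the region mean", {
  axis <- seq(1700, 1800, by = 10)
  tbar <- rep(1, 11)
  reg <- silent_region(axis, 1700, 1800)
  expect_equal(reference_transmittance(tbar, reg), 1)
  tbar2 <- c(rep(0.5, 9), 0.8, 1.0)
  reg2 <- silent_region(axis, 1790, 1800)
  expect_equal(reference_transmittance(tbar2, reg2), 0.9)
  expect_equal(reference_transmittance(tbar2, reg), mean(tbar2))
})

test_that("the noise profile follows the inverse-square transmittance law", {
  # T = T_ref everywhere: uniform profile at the base variance
  expect_equal(noise_profile(2, rep(0.7, 4), 0.7), rep(2, 4))
  # a band at T = 0.1 with T_ref = 1 is amplified 100-fold
  prof <- noise_profile(3, c(1, 0.1, 1), 1)
  expect_equal(prof[2] / prof[1], 100)
  # linear in the base variance
  expect_equal(noise_profile(2, c(1, 0.5), 1), 2 * noise_profile(1, c(1, 0.5), 1))
  # floor keeps the covariance invertible even at zero base variance
  expect_true(all(noise_profile(0, c(1, 0.5), 1) >= 1e-12))
  expect_error(noise_profile(1, c(1, -0.2), 1), "positive")
})

test_that("the composed iMNF estimate is maximal at strong absorbance bands", {
  ph <- small_phantom()
  noise <- estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy))
  # Amide I (~1656) has the lowest transmittance, hence the largest
  # modelled noise variance
  j <- nearest_band(ph$noisy, 1656)
  expect_identical(which.max(noise$profile), j)
  # flat zero-absorbance cube with white noise: scaling ~ 1, uniform profile
  flat <- white_cube(4000, 60, sd = 0.002, seed = 5, axis = seq(1700, 1818, 2))
  nf <- estimate_noise_imnf(flat, silent_region(flat$axis, 1750, 1800))
  expect_lt(diff(range(nf$profile)) / mean(nf$profile), 0.1)
})

test_that("calibrated iMNF recovers the delta-method noise variance on phantoms", {
  # transmittance-domain noise sd sigma_t: absorbance-noise variance per
  # band is (sigma_t / (Tbar * ln 10))^2 by the delta method
  ph <- small_phantom(shape = c(100L, 100L), sigma_t = 0.003, seed = 6)
  noise <- estimate_noise_imnf(ph$noisy, qcl_silent(ph$noisy))
  tbar <- to_transmittance(colMeans(ph$clean$spectra))
  predicted <- (ph$spec$sigma_t / (tbar * log(10)))^2
  ratio <- noise$profile / predicted
  expect_lt(max(abs(ratio - 1)), 0.2)
})

test_that("automatic window selection finds the globally flattest window", {
  ph <- small_phantom()
  # brute-force oracle over every window position in the candidate range
  cand <- c(1700, 1800); width <- 30
  reg <- select_silent_window(ph$noisy, cand[1], cand[2], width = width)
  idx <- band_indices(ph$noisy$axis, cand[1], cand[2])
  nb <- round(width / 2) + 1
  cc <- c(-2, -1, 0, 1, 2) / (10 * 2)   # w5/p2 derivative at 2 cm^-1 spacing
  oracle <- sapply(seq_len(length(idx) - nb + 1), function(s) {
    Xs <- ph$noisy$spectra[, idx[s:(s + nb - 1)]]
    vars <- sapply(seq_len(nb - 4), function(j) {
      d <- Xs[, j:(j + 4)] %*% cc
      mean(d^2) - mean(d)^2
    })
    mean(vars)
  })
  expect_equal(reg$criterion, min(oracle), tolerance = 1e-10)
  expect_true(reg$auto_selected)
  # window covering the whole candidate interval returns it unchanged
  whole <- select_silent_window(ph$noisy, 1750, 1800, width = 50)
  expect_equal(c(whole$lo, whole$hi), c(1750, 1800))
})

test_that("window selection avoids a contaminated sub-interval", {
  # flat candidate range with a noisy contaminated stretch at its centre
  set.seed(9)
  axis <- seq(1700, 1800, by = 2)
  X <- matrix(rnorm(200 * 51, sd = 0.001), 200, 51)
  bad <- band_indices(axis, 1740, 1770)
  X[, bad] <- X[, bad] + matrix(rnorm(200 * length(bad), sd = 0.05),
                                200, length(bad))
  cube <- spectral_cube(X, axis)
  reg <- select_silent_window(cube, 1700, 1800, width = 20)
  expect_true(reg$hi <= 1740 || reg$lo >= 1770)
})

test_that("spike QC flags narrow-band contaminants and nothing else", {
  set.seed(10)
  axis <- seq(1740, 1810, by = 2)
  X <- matrix(rnorm(500 * 36, sd = 0.01), 500, 36)
  cube <- spectral_cube(X, axis)
  reg <- silent_region(axis, 1740, 1810)
  clean_qc <- qc_spike_check(cube, reg, factor = 5)
  expect_length(clean_qc$flagged_wavenumbers, 0)
  # inject a single-band sinusoidal contaminant at 10x the noise
  # amplitude; the first-derivative response of a single-band spike
  # lands on the bands inside the filter window (the centre coefficient
  # of the w5/p2 derivative is zero), so the flags sit within one window
  # of the contaminated band
  j <- nearest_band(cube, 1776)
  X2 <- X; X2[, j] <- X2[, j] + 0.1 * sin(seq_len(500))
  qc <- qc_spike_check(spectral_cube(X2, axis), reg, factor = 5)
  expect_gt(length(qc$flagged_wavenumbers), 0)
  expect_true(all(abs(qc$flagged_wavenumbers - 1776) <= 4))
})

test_that("off-diagonal correlation summarises dense noise structure", {
  expect_equal(offdiag_noise_correlation(noise_covariance(matrix = diag(3))), 0)
  S <- rbind(c(1, 0.5), c(0.5, 1))
  expect_equal(offdiag_noise_correlation(noise_covariance(matrix = S)), 0.5)
  # perfectly correlated rank-1 noise across 3 bands
  v <- c(1, 2, 3)
  S1 <- outer(v, v)
  expect_equal(offdiag_noise_correlation(noise_covariance(matrix = S1)), 1)
  expect_warning(
    r <- offdiag_noise_correlation(noise_covariance(profile = c(1, 1))),
    "diagonal")
  expect_identical(r, 0)
})
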