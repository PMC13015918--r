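#' Cosine similarity of adjacent spectra
#'
#' Cosine similarity of each consecutive row pair in the unrolled pixel
#' order — the diagnostic for how well the "adjacent pixels are similar"
#' assumption of the standard MNF noise estimate holds. Ordered images
#' give values near 1; sampled or shuffled data do not.
#'
#' @param cube a [spectral_cube()] with at least 2 spectra and no
#'   zero-norm spectrum.
#' @return numeric vector of length `m - 1`, values in `[-1, 1]`.
#' @export
adjacent_cosine <- function(cube) {
  X <- cube$spectra
  m <- nrow(X)
  if (m < 2) stop("need at least 2 spectra")
  n <- sqrt(rowSums(X^2))
  if (any(n == 0)) stop("zero-norm spectrum at pixel ", which(n == 0)[1])
  num <- rowSums(X[-m, , drop = FALSE] * X[-1, , drop = FALSE])
  pmin(1, pmax(-1, num / (n[-m] * n[-1])))
}

#' Percentage of similarities below a threshold
#'
#' @param similarities vector of cosine similarities.
#' @param threshold cutoff in `[-1, 1]` (conventionally 0.99 or 0.95).
#' @return percentage (0-100) of values strictly below the threshold.
#' @export
fraction_below <- function(similarities, threshold = 0.99) {
  if (length(similarities) == 0) stop("empty similarity vector")
  if (threshold < -1 || threshold > 1) stop("threshold must be in [-1, 1]")
  100 * mean(similarities < threshold)
}

#' Mean silent-region variance
#'
#' Mean over the region's bands of the per-band variance across pixels —
#' the residual-noise proxy: on denoised data it should fall well below
#' the raw value.
#'
#' @param cube a [spectral_cube()].
#' @param region a [silent_region()].
#' @return scalar mean variance.
#' @export
silent_variance <- function(cube, region) {
  if (length(region$indices) == 0) stop("empty silent region")
  mean(apply(cube$spectra[, region$indices, drop = FALSE], 2, stats::var))
}

#' Amide I / Amide II absorbance ratio per pixel
#'
#' Ratio of the absorbance at the band nearest `num_wn` (Amide I,
#' ~1656 cm^-1) to that nearest `den_wn` (Amide II, ~1546 cm^-1) — a
#' biochemical-preservation readout. Pixels whose denominator absorbance
#' is not positive are returned as `NA` and counted in
#' `attr(, "n_flagged")`.
#'
#' @param cube a [spectral_cube()] whose axis covers both wavenumbers.
#' @param num_wn,den_wn numerator / denominator query wavenumbers.
#' @return numeric vector of length `m` (with `NA` at flagged pixels).
#' @export
amide_ratio <- function(cube, num_wn = 1656, den_wn = 1546) {
  rng <- range(cube$axis)
  if (num_wn < rng[1] || num_wn > rng[2] || den_wn < rng[1] || den_wn > rng[2])
    stop("axis does not cover the queried wavenumbers")
  a1 <- cube$spectra[, nearest_band(cube, num_wn)]
  a2 <- cube$spectra[, nearest_band(cube, den_wn)]
  bad <- a2 <= 0
  r <- a1 / a2
  r[bad] <- NA_real_
  attr(r, "n_flagged") <- sum(bad)
  r
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' `R^2` between an estimate and a reference, computed as the squared
#' Pearson correlation — scale-insensitive, so it measures preservation
#' of relative structure rather than agreement with the identity line.
#' Set `identity_line = TRUE` for the fit-to-identity definition
#' `1 - SS_res / SS_tot`.
#'
#' @param reference,estimate numeric vectors of equal length (>= 2);
#'   `NA`s are dropped pairwise.
#' @param identity_line use the identity-line definition instead.
#' @return scalar; in `[0, 1]` for the correlation definition.
#' @export
r_squared <- function(reference, estimate, identity_line = FALSE) {
  if (length(reference) != length(estimate)) stop("length mismatch")
  ok <- is.finite(reference) & is.finite(estimate)
  reference <- reference[ok]; estimate <- estimate[ok]
  if (length(reference) < 2) stop("need at least 2 finite pairs")
  if (stats::var(reference) == 0 || stats::var(estimate) == 0)
    stop("zero-variance input")
  if (identity_line)
    return(1 - sum((estimate - reference)^2) /
             sum((reference - mean(reference))^2))
  stats::cor(reference, estimate)^2
}

#' Pixel-wise absolute difference map at one wavenumber
#'
#' `|a - b|` at the band nearest the query wavenumber, reshaped to the
#' image grid — the order-dependence diagnostic: for a spatially
#' invariant denoiser the ordered-vs-shuffled difference map is zero.
#'
#' @param a,b [spectral_cube()]s with identical axes and shapes (`a`
#'   must carry `shape2d`).
#' @param wavenumber query position in cm^-1.
#' @return `y x x` matrix of absolute differences, with attributes
#'   `max` and `mean`.
#' @export
difference_map <- function(a, b, wavenumber = 1656) {
  if (!identical(dim(a$spectra), dim(b$spectra)) ||
      max(abs(a$axis - b$axis)) > 0)
    stop("cubes must share shape and axis")
  if (is.null(a$shape2d)) stop("difference map needs 2-D shape information")
  j <- nearest_band(a, wavenumber)
  d <- abs(a$spectra[, j] - b$spectra[, j])
  img <- matrix(d, nrow = a$shape2d[1], ncol = a$shape2d[2], byrow = TRUE)
  attr(img, "max") <- max(d)
  attr(img, "mean") <- mean(d)
  img
}

#' Edge transitions of row-major unrolling
#'
#' When a `height x width` image is unrolled row-major, consecutive
#' spectra are horizontally adjacent pixels except where a row ends:
#' those `height - 1` "edge transitions" pair pixels that are not
#' neighbours. Out of `height * width - 1` consecutive pairs they are a
#' negligible fraction for large images (511 of 262143, under 0.2%, at
#' 512 x 512).
#'
#' @param height,width image dimensions (>= 1).
#' @return list with `count` (edge transitions), `total_pairs`, and
#'   `fraction_pct` (their percentage).
#' @export
edge_transitions <- function(height, width) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1 || width < 1) stop("dimensions must be >= 1")
  total <- height * width - 1L
  count <- if (total == 0L) 0L else height - 1L
  list(count = count, total_pairs = total,
       fraction_pct = if (total == 0L) 0 else 100 * count / total)
}

#' Summary evaluation report for a denoising run
#'
#' Convenience wrapper computing the package's evaluation metrics of a
#' denoised cube against its raw input: adjacent cosine similarity
#' summaries, silent-region variances, and amide-ratio preservation.
#'
#' @param raw,denoised [spectral_cube()]s on the same axis.
#' @param region a [silent_region()] for the variance metric, or `NULL`.
#' @return named list of metrics (finite scalars) plus the per-pixel
#'   ratio vectors.
#' @export
evaluation_report <- function(raw, denoised, region = NULL) {
  out <- list()
  cs <- adjacent_cosine(denoised)
  out$mean_adjacent_cosine <- mean(cs)
  out$pct_below_0.99 <- fraction_below(cs, 0.99)
  out$pct_below_0.95 <- fraction_below(cs, 0.95)
  if (!is.null(region)) {
    out$silent_variance_raw <- silent_variance(raw, region)
    out$silent_variance_denoised <- silent_variance(denoised, region)
  }
  rng <- range(raw$axis)
  if (rng[1] <= 1546 && rng[2] >= 1656) {
    rr <- amide_ratio(raw); rd <- amide_ratio(denoised)
    out$amide_ratio_r2 <- r_squared(rr, rd)
    out$amide_ratio_raw <- rr
    out$amide_ratio_denoised <- rd
  }
  out
}
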