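#' Noise covariance objects
#'
#' A noise covariance is either *dense* (a full `v x v` matrix, as produced
#' by adjacent-pixel differencing) or *diagonal* (a `v`-long variance
#' profile, as produced by the spatially invariant silent-region model).
#'
#' @param matrix dense `v x v` covariance (dense kind).
#' @param profile vector of `v` per-band noise variances (diagonal kind).
#' @param base_variance scalar base noise variance the profile was scaled
#'   from, if applicable.
#' @param provenance one of `"adjacent"`, `"imnf"`, `"user"`.
#' @param region optional [silent_region()] the estimate used.
#' @return object of class `"noise_covariance"`.
#' @export
noise_covariance <- function(matrix = NULL, profile = NULL,
                             base_variance = NA_real_,
                             provenance = "user", region = NULL) {
  if (is.null(matrix) == is.null(profile))
    stop("supply exactly one of `matrix` (dense) or `profile` (diagonal)")
  if (!is.null(matrix)) {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) != ncol(matrix)) stop("dense covariance must be square")
    if (max(abs(matrix - t(matrix))) > 1e-10 * max(1, max(abs(matrix))))
      stop("dense covariance must be symmetric within 1e-10")
    kind <- "dense"
  } else {
    profile <- as.numeric(profile)
    if (any(!is.finite(profile)) || any(profile <= 0))
      stop("diagonal noise profile entries must be finite and > 0 (band ",
           which(!is.finite(profile) | profile <= 0)[1], ")")
    kind <- "diagonal"
  }
  structure(list(kind = kind, matrix = matrix, profile = profile,
                 base_variance = base_variance, provenance = provenance,
                 region = region),
            class = "noise_covariance")
}

noise_dim <- function(noise) {
  if (noise$kind == "dense") nrow(noise$matrix) else length(noise$profile)
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat("Noise covariance (", x$kind, ", provenance: ", x$provenance, ")\n",
      sep = "")
  cat("  bands: ", noise_dim(x), "\n", sep = "")
  if (!is.na(x$base_variance))
    cat("  base variance: ", format(x$base_variance, digits = 4), "\n", sep = "")
  if (!is.null(x$region))
    cat("  silent region: ", x$region$lo, "-", x$region$hi, " cm^-1",
        if (isTRUE(x$region$auto_selected)) " (auto-selected)", "\n", sep = "")
  invisible(x)
}

#' Adjacent-pixel noise covariance (standard MNF estimate)
#'
#' Estimates the noise matrix as differences of consecutive spectra in the
#' row-major unrolled pixel order, `N_i = X_i - X_{i+1}`, and returns the
#' dense cross-product covariance `NtN`. This estimate is deliberately
#' order-DEPENDENT: it is the standard method that the spatially invariant
#' model is contrasted against, and shuffling pixel order changes it.
#' Row-boundary pairs (last pixel of one image row against first of the
#' next) are included by default; for large images they are a negligible
#' fraction of all pairs (see [edge_transitions()]).
#'
#' @param cube a [spectral_cube()] with at least two spectra.
#' @param drop_edge_pairs if `TRUE` and the cube has `shape2d`, differences
#'   that straddle image-row boundaries are excluded.
#' @return dense [noise_covariance()].
#' @export
estimate_noise_adjacent <- function(cube, drop_edge_pairs = FALSE) {
  X <- cube$spectra
  m <- nrow(X)
  if (m < 2) stop("adjacent-difference noise estimation needs at least 2 spectra")
  N <- X[-m, , drop = FALSE] - X[-1, , drop = FALSE]
  if (drop_edge_pairs && !is.null(cube$shape2d)) {
    w <- cube$shape2d[2]
    edge <- seq_len(m - 1) %% w == 0
    N <- N[!edge, , drop = FALSE]
  }
  S <- crossprod(N)
  S <- (S + t(S)) / 2  # enforce exact symmetry against fp asymmetry
  noise_covariance(matrix = S, provenance = "adjacent")
}

#' Define a silent spectral region
#'
#' A contiguous wavenumber interval expected to carry no biological
#' absorbance (about 1750-1800 cm^-1 for QCL data, 1750-2200 cm^-1 for
#' FTIR), used to estimate pure noise.
#'
#' @param axis wavenumber axis the region indexes into.
#' @param lo,hi interval bounds in cm^-1 (inclusive).
#' @param auto_selected whether the window came from [select_silent_window()].
#' @param qc optional QC report from [qc_spike_check()].
#' @return object of class `"silent_region"` with fields `lo`, `hi`,
#'   `indices`, `qc`, `auto_selected`.
#' @export
silent_region <- function(axis, lo, hi, auto_selected = FALSE, qc = NULL) {
  if (lo >= hi) stop("silent region needs lo < hi")
  idx <- band_indices(axis, lo, hi)
  if (length(idx) == 0)
    stop("silent region ", lo, "-", hi, " cm^-1 contains no bands of the axis")
  structure(list(lo = lo, hi = hi, indices = idx, qc = qc,
                 auto_selected = auto_selected),
            class = "silent_region")
}

#' @export
print.silent_region <- function(x, ...) {
  cat("Silent region ", x$lo, "-", x$hi, " cm^-1 (", length(x$indices),
      " bands", if (isTRUE(x$auto_selected)) ", auto-selected", ")\n", sep = "")
  if (!is.null(x$qc) && length(x$qc$flagged_wavenumbers))
    cat("  QC: flagged bands at ",
        paste(x$qc$flagged_wavenumbers, collapse = ", "), " cm^-1\n", sep = "")
  invisible(x)
}

## Savitzky-Golay first-derivative values of the region columns,
## interior positions only (edges are dropped so padded values never
## enter the variance estimate). Returns an m x (n_region - window + 1)
## matrix of derivative values.
sg_region_derivative <- function(cube, indices, window, polyorder) {
  if (window %% 2 != 1) stop("SG window length must be odd")
  if (window < polyorder + 2)
    stop("SG window (", window, ") must be at least polyorder + 2 (",
         polyorder + 2, ")")
  if (length(indices) <= window)
    stop("silent region (", length(indices),
         " bands) must be longer than the SG window (", window, ")")
  ts <- abs(stats::median(diff(cube$axis[indices])))
  co <- signal::sgolay(p = polyorder, n = window, m = 1, ts = ts)
  cc <- co[(window + 1) / 2, ]                 # central (interior) filter row
  Xdz <- cube$spectra[, indices, drop = FALSE]
  nr <- length(indices)
  ni <- nr - window + 1                         # interior output positions
  C <- matrix(0, nr, ni)
  for (j in seq_len(ni)) C[j:(j + window - 1), j] <- cc
  list(deriv = Xdz %*% C, coef = cc)
}

#' Base noise variance from silent-region derivative
#'
#' Applies a Savitzky-Golay first-derivative filter to the silent-region
#' columns of the cube and returns the mean of the per-column population
#' variances. The derivative acts as a high-pass filter: slowly varying
#' chemical baseline is suppressed and the remaining variance is
#' attributable to high-frequency noise. Only interior filter outputs are
#' used (no edge padding enters the estimate).
#'
#' For iid white noise of variance `s2` and unit band spacing, the window-5 /
#' order-2 first-derivative coefficients are `c(-2,-1,0,1,2)/10`, so the
#' returned value converges to `0.1 * s2`; the scalar factor is determined by
#' the filter coefficients and the band spacing (see
#' [estimate_noise_imnf()]'s `calibrate` argument).
#'
#' @param cube a [spectral_cube()].
#' @param region a [silent_region()], longer than `window`.
#' @param window odd SG window length (points), at least `polyorder + 2`.
#' @param polyorder SG polynomial order.
#' @return scalar base variance (>= 0), in derivative-variance units.
#' @export
sg_base_variance <- function(cube, region, window = 5L, polyorder = 2L) {
  d <- sg_region_derivative(cube, region$indices, window, polyorder)
  mean(col_pop_var(d$deriv))
}

#' Convert mean absorbance to mean transmittance
#'
#' Beer-Lambert base-10 convention: `T = 10^(-A)`, clamped below at 1e-6
#' so saturated bands cannot produce a degenerate scaling.
#'
#' @param mean_absorbance numeric vector of mean absorbances.
#' @return transmittance vector in (0, 10^max(-A)], floored at 1e-6.
#' @export
to_transmittance <- function(mean_absorbance) {
  if (any(!is.finite(mean_absorbance)))
    stop("mean absorbance contains non-finite values")
  pmax(10^(-mean_absorbance), 1e-6)
}

#' Reference transmittance over a silent region
#'
#' @param transmittance mean transmittance vector (length v).
#' @param region a [silent_region()].
#' @return scalar arithmetic mean of the transmittance over the region bands.
#' @export
reference_transmittance <- function(transmittance, region) {
  if (length(region$indices) == 0) stop("empty silent region")
  mean(transmittance[region$indices])
}

#' Transmittance-scaled noise variance profile
#'
#' Noise variance in absorbance units is inversely proportional to the
#' square of transmittance, so the base variance measured in the silent
#' region (where transmittance is `t_ref`) is scaled per band by
#' `S_v = (t_ref / T_v)^2`. The profile is floored at 1e-12 to keep the
#' diagonal covariance invertible.
#'
#' @param base_variance scalar base noise variance (>= 0).
#' @param transmittance per-band mean transmittance, all > 0.
#' @param t_ref reference transmittance (scalar).
#' @return vector of per-band noise variances `base_variance * S`.
#' @export
noise_profile <- function(base_variance, transmittance, t_ref) {
  if (base_variance < 0) stop("base variance must be >= 0")
  if (any(transmittance <= 0)) stop("transmittance must be positive")
  s <- (t_ref / transmittance)^2
  pmax(base_variance * s, 1e-12)
}

#' Spatially invariant (iMNF) noise covariance
#'
#' Composes the silent-region derivative variance, the mean-spectrum
#' transmittance conversion, the reference transmittance and the
#' inverse-square transmittance scaling into a diagonal noise covariance.
#' The estimate depends only on column-wise means and variances of the
#' cube, so it is invariant to any pixel reordering (up to floating-point
#' summation order) — the property that makes patch-wise and masked
#' workflows safe.
#'
#' @param cube a [spectral_cube()].
#' @param region a [silent_region()], or `"auto"` to run
#'   [select_silent_window()] over `auto_candidate`.
#' @param window,polyorder SG derivative parameters (see [sg_base_variance()]).
#' @param calibrate if `TRUE` (default) the derivative variance is divided
#'   by the sum of squared (band-spacing-scaled) filter coefficients so
#'   `base_variance` is expressed in absorbance-variance units; the choice
#'   is a global scalar and does not affect the MNF transform.
#' @param auto_candidate candidate interval `c(lo, hi)` for automatic window
#'   selection (default the QCL silent region 1750-1800 cm^-1).
#' @param auto_width window width in cm^-1 for automatic selection.
#' @param qc_factor spike-QC threshold factor (see [qc_spike_check()]).
#' @return diagonal [noise_covariance()] with provenance `"imnf"`.
#' @export
estimate_noise_imnf <- function(cube, region = NULL, window = 5L,
                                polyorder = 2L, calibrate = TRUE,
                                auto_candidate = c(1750, 1800),
                                auto_width = 50, qc_factor = 5) {
  if (is.null(region) || identical(region, "auto"))
    region <- select_silent_window(cube, auto_candidate[1], auto_candidate[2],
                                   width = auto_width,
                                   window = window, polyorder = polyorder)
  region$qc <- qc_spike_check(cube, region, factor = qc_factor,
                              window = window, polyorder = polyorder)
  d <- sg_region_derivative(cube, region$indices, window, polyorder)
  base <- mean(col_pop_var(d$deriv))
  if (calibrate) base <- base / sum(d$coef^2)
  tbar <- to_transmittance(colMeans(cube$spectra))
  tref <- reference_transmittance(tbar, region)
  prof <- noise_profile(base, tbar, tref)
  noise_covariance(profile = prof, base_variance = base,
                   provenance = "imnf", region = region)
}

#' Automatic silent-window selection
#'
#' Slides a window of fixed wavenumber width across a candidate interval
#' (stride one band) and returns the window whose mean per-band
#' first-derivative variance is lowest — the flattest, least contaminated
#' stretch of the candidate region.
#'
#' @param cube a [spectral_cube()].
#' @param candidate_lo,candidate_hi candidate interval bounds (cm^-1),
#'   within the axis.
#' @param width window width in cm^-1 (at most the candidate length).
#' @param window,polyorder SG derivative parameters.
#' @return a [silent_region()] with `auto_selected = TRUE` and the winning
#'   mean derivative variance in `$criterion`.
#' @export
select_silent_window <- function(cube, candidate_lo, candidate_hi, width = 50,
                                 window = 5L, polyorder = 2L) {
  idx <- band_indices(cube$axis, candidate_lo, candidate_hi)
  if (length(idx) == 0) stop("candidate interval lies outside the axis")
  ax <- cube$axis[idx]
  step <- abs(stats::median(diff(ax)))
  nb <- min(length(idx), max(window + 1L, round(width / step) + 1L))
  starts <- seq_len(length(idx) - nb + 1L)
  best <- NULL; best_val <- Inf
  for (s in starts) {
    sub <- idx[s:(s + nb - 1L)]
    d <- sg_region_derivative(cube, sub, window, polyorder)
    val <- mean(col_pop_var(d$deriv))
    if (val < best_val) { best_val <- val; best <- sub }
  }
  reg <- silent_region(cube$axis, min(cube$axis[best]), max(cube$axis[best]),
                       auto_selected = TRUE)
  reg$criterion <- best_val
  reg
}

#' Quality-control spike check on a silent region
#'
#' Flags bands whose first-derivative variance exceeds `factor` times the
#' median derivative variance of the region — narrow-band contaminants
#' (atypical chemistry, laser artefacts) that would bias the base noise
#' estimate. Report-only: estimation proceeds either way.
#'
#' @param cube a [spectral_cube()].
#' @param region a [silent_region()].
#' @param factor spike threshold as a multiple of the median band variance.
#' @param window,polyorder SG derivative parameters.
#' @return list with `band_variances` (named by wavenumber, interior bands),
#'   `flagged_wavenumbers`, `flagged_indices` (into the axis), `factor`.
#' @export
qc_spike_check <- function(cube, region, factor = 5, window = 5L,
                           polyorder = 2L) {
  d <- sg_region_derivative(cube, region$indices, window, polyorder)
  v <- col_pop_var(d$deriv)
  h <- (window - 1L) %/% 2L
  interior <- region$indices[(h + 1L):(length(region$indices) - h)]
  names(v) <- cube$axis[interior]
  bad <- v > factor * stats::median(v)
  list(band_variances = v,
       flagged_wavenumbers = as.numeric(names(v)[bad]),
       flagged_indices = interior[bad],
       factor = factor)
}

#' Mean absolute off-diagonal noise correlation
#'
#' Converts a dense noise covariance to a correlation matrix and returns
#' the mean absolute off-diagonal entry — a summary of how strongly noise
#' is correlated across wavenumbers (values near 1 indicate the highly
#' structured detector noise that a diagonal model cannot whiten).
#'
#' @param noise a dense [noise_covariance()]. A diagonal covariance has no
#'   off-diagonal structure by construction; 0 is returned with a warning.
#' @return scalar in `[0, 1]`.
#' @export
offdiag_noise_correlation <- function(noise) {
  if (noise$kind != "dense") {
    warning("off-diagonal correlation of a diagonal noise model is 0 by construction")
    return(0)
  }
  S <- noise$matrix
  d <- sqrt(diag(S))
  if (any(d <= 0)) stop("covariance has non-positive diagonal entries")
  R <- S / tcrossprod(d)
  v <- nrow(R)
  if (v < 2) return(0)
  mean(abs(R[upper.tri(R)]))
}
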