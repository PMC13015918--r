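#' Savitzky-Golay filtering of a cube
#'
#' Per-spectrum SG convolution along the wavenumber axis. `deriv = 0`
#' smooths; `deriv = 1` or `2` differentiates, with derivative scaling
#' taken from the axis band spacing. Edges use the one-sided SG fits
#' (the standard full least-squares edge treatment), interior points the
#' central filter row; the whole cube is filtered with a single matrix
#' product.
#'
#' @param cube a [spectral_cube()].
#' @param window odd filter window length (points), `> polyorder`.
#' @param polyorder polynomial order.
#' @param deriv derivative order, `<= polyorder`.
#' @return a [spectral_cube()] of filtered spectra (same axis).
#' @export
sg_filter <- function(cube, window = 5L, polyorder = 2L, deriv = 0L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2 != 1) stop("SG window length must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  v <- ncol(cube$spectra)
  if (v < window) stop("cube has fewer bands (", v, ") than the window")
  ts <- abs(stats::median(diff(cube$axis)))
  Fm <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = ts)
  h <- (window - 1L) %/% 2L
  cc <- Fm[h + 1L, ]
  Op <- matrix(0, v, v)
  for (j in (h + 1L):(v - h)) Op[(j - h):(j + h), j] <- cc
  for (j in seq_len(h)) {                   # leading edge: one-sided fits
    Op[1:window, j] <- Fm[j, ]
    Op[(v - window + 1L):v, v - j + 1L] <- Fm[window - j + 1L, ]
  }
  cube_with(cube, cube$spectra %*% Op)
}

#' Linear baseline subtraction
#'
#' Subtracts, per spectrum, the straight line through its first and last
#' band, so both endpoints map exactly to zero. (Endpoint anchoring is
#' the minimal reading of a linear baseline; a least-squares line is
#' available with `method = "lsq"`.)
#'
#' @param cube a [spectral_cube()] with at least 2 bands.
#' @param method `"endpoints"` (default) or `"lsq"` for an ordinary
#'   least-squares line per spectrum.
#' @return baseline-corrected [spectral_cube()].
#' @export
baseline_linear <- function(cube, method = c("endpoints", "lsq")) {
  method <- match.arg(method)
  X <- cube$spectra
  v <- ncol(X)
  if (v < 2) stop("baseline subtraction needs at least 2 bands")
  ax <- cube$axis
  if (method == "endpoints") {
    slope <- (X[, v] - X[, 1]) / (ax[v] - ax[1])
    base <- outer(slope, ax - ax[1]) + X[, 1]
  } else {
    axc <- ax - mean(ax)
    slope <- (X %*% axc) / sum(axc^2)
    base <- outer(drop(slope), axc) + rowMeans(X)
  }
  cube_with(cube, X - base)
}

#' Truncate a cube to a wavenumber interval
#'
#' Keeps bands with `lo <= wavenumber <= hi` (closed interval on both
#' ends, the spectroscopic convention) and updates the axis accordingly.
#'
#' @param cube a [spectral_cube()].
#' @param lo,hi interval bounds in cm^-1.
#' @return truncated [spectral_cube()].
#' @export
truncate_cube <- function(cube, lo, hi) {
  keep <- band_indices(cube$axis, lo, hi)
  if (length(keep) == 0)
    stop("truncation interval ", lo, "-", hi,
         " cm^-1 contains no bands of the axis")
  spectral_cube(cube$spectra[, keep, drop = FALSE], cube$axis[keep],
                shape2d = cube$shape2d, mask = cube$mask)
}

#' Remove a wavenumber band from a cube
#'
#' Drops bands inside `[lo, hi]` inclusive — typically the paraffin wax
#' interval 1360-1490 cm^-1. An interval outside the axis is a no-op.
#'
#' @param cube a [spectral_cube()].
#' @param lo,hi interval bounds in cm^-1 (default the wax region).
#' @return [spectral_cube()] without the interval's bands.
#' @export
remove_band <- function(cube, lo = 1360, hi = 1490) {
  drop_ <- band_indices(cube$axis, lo, hi)
  if (length(drop_) == 0) return(cube)
  keep <- setdiff(seq_along(cube$axis), drop_)
  if (length(keep) == 0) stop("band removal would empty the axis")
  spectral_cube(cube$spectra[, keep, drop = FALSE], cube$axis[keep],
                shape2d = cube$shape2d, mask = cube$mask)
}

#' Vector normalisation
#'
#' Scales each spectrum to unit Euclidean norm.
#'
#' @param cube a [spectral_cube()] with no all-zero spectra.
#' @return normalised [spectral_cube()].
#' @export
vector_normalise <- function(cube) {
  n <- sqrt(rowSums(cube$spectra^2))
  if (any(n == 0))
    stop("cannot normalise zero spectrum at pixel ", which(n == 0)[1])
  cube_with(cube, cube$spectra / n)
}

#' Apply a declarative preprocessing pipeline
#'
#' Runs an ordered list of preprocessing steps. Each step is a list with
#' element `step` (one of `"baseline"`, `"truncate"`, `"remove_band"`,
#' `"vector_normalise"`, `"sg_filter"`) and that step's parameters, e.g.
#' `list(step = "truncate", lo = 1000, hi = 1800)`. This is the
#' programmatic mirror of the CLI `preprocess` subcommand.
#'
#' @param cube a [spectral_cube()].
#' @param steps list of step descriptions.
#' @return processed [spectral_cube()] with the applied steps recorded in
#'   `attr(, "pipeline")`.
#' @export
apply_pipeline <- function(cube, steps) {
  for (s in steps) {
    cube <- switch(s$step,
      baseline = baseline_linear(cube,
        method = if (is.null(s$method)) "endpoints" else s$method),
      truncate = truncate_cube(cube, s$lo, s$hi),
      remove_band = remove_band(cube,
        lo = if (is.null(s$lo)) 1360 else s$lo,
        hi = if (is.null(s$hi)) 1490 else s$hi),
      vector_normalise = vector_normalise(cube),
      sg_filter = sg_filter(cube,
        window = if (is.null(s$window)) 19L else s$window,
        polyorder = if (is.null(s$polyorder)) 4L else s$polyorder,
        deriv = if (is.null(s$deriv)) 2L else s$deriv),
      stop("unknown preprocessing step: ", s$step))
  }
  attr(cube, "pipeline") <- steps
  cube
}
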