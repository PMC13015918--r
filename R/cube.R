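#' Construct a spectral cube
#'
#' A spectral cube holds `m` pixel spectra as rows of an `m x v` matrix
#' together with the `v`-long wavenumber axis, and optionally the 2-D
#' image shape `(y, x)` the pixels were unrolled from (row-major) and a
#' per-pixel logical mask.
#'
#' @param spectra numeric matrix, one spectrum per row (absorbance units).
#' @param axis numeric vector of wavenumbers (cm^-1), strictly monotone,
#'   one per column of `spectra`.
#' @param shape2d optional integer vector `c(y, x)` with `y * x == nrow(spectra)`;
#'   rows are assumed unrolled row-major (pixel `(i, j)` at row `(i-1) * x + j`).
#' @param mask optional logical vector of length `nrow(spectra)`.
#' @return An object of class `"spectral_cube"`: a list with elements
#'   `spectra`, `axis`, `shape2d`, `mask`.
#' @examples
#' cube <- spectral_cube(matrix(rnorm(20), 4, 5), axis = seq(1000, 1008, by = 2))
#' dim(cube)
#' @export
spectral_cube <- function(spectra, axis, shape2d = NULL, mask = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  axis <- as.numeric(axis)
  if (ncol(spectra) != length(axis))
    stop("column count of `spectra` (", ncol(spectra),
         ") must equal length of `axis` (", length(axis), ")")
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0)))
    stop("`axis` must be strictly monotone")
  if (!is.null(shape2d)) {
    shape2d <- as.integer(shape2d)
    if (length(shape2d) != 2L || any(shape2d < 1L))
      stop("`shape2d` must be two positive integers c(y, x)")
    if (prod(shape2d) != nrow(spectra))
      stop("shape2d y*x = ", prod(shape2d), " does not match m = ", nrow(spectra))
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != nrow(spectra))
      stop("`mask` must have one entry per spectrum")
  }
  structure(list(spectra = spectra, axis = axis, shape2d = shape2d, mask = mask),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$spectra)

#' @export
as.matrix.spectral_cube <- function(x, ...) x$spectra

#' @export
print.spectral_cube <- function(x, ...) {
  cat("Spectral cube: ", nrow(x$spectra), " spectra x ", ncol(x$spectra),
      " bands\n", sep = "")
  cat("  axis: ", format(min(x$axis)), "-", format(max(x$axis)),
      " cm^-1 (step ", format(stats::median(abs(diff(x$axis)))), ")\n", sep = "")
  if (!is.null(x$shape2d))
    cat("  image: ", x$shape2d[1], " x ", x$shape2d[2], " pixels\n", sep = "")
  if (!is.null(x$mask))
    cat("  mask: ", sum(x$mask), " of ", length(x$mask), " pixels kept\n", sep = "")
  invisible(x)
}

## replace the spectra matrix, keeping axis/shape metadata consistent
cube_with <- function(cube, spectra, axis = cube$axis) {
  spectral_cube(spectra, axis, shape2d = cube$shape2d, mask = cube$mask)
}

#' Find the band index nearest a wavenumber
#'
#' @param cube a [spectral_cube()].
#' @param wavenumber query position in cm^-1.
#' @return integer column index of the nearest axis value (no interpolation,
#'   matching discrete instrument sampling).
#' @export
nearest_band <- function(cube, wavenumber) {
  which.min(abs(cube$axis - wavenumber))
}

#' Indices of bands inside a wavenumber interval
#'
#' Both endpoints are included: interval conventions are closed in
#' wavenumber space throughout the package.
#'
#' @param axis numeric wavenumber vector.
#' @param lo,hi interval bounds in cm^-1 (order-insensitive).
#' @return integer vector of indices with `lo <= axis <= hi`.
#' @export
band_indices <- function(axis, lo, hi) {
  b <- sort(c(lo, hi))
  which(axis >= b[1] & axis <= b[2])
}

#' Shuffle the pixel order of a cube
#'
#' Returns the shuffled cube together with the permutation used, so
#' spatial-invariance checks can un-permute the result
#' (`denoised$spectra[order(perm), ]`).
#'
#' @param cube a [spectral_cube()].
#' @param seed integer seed for the permutation.
#' @return list with elements `cube` (shuffled; `shape2d` dropped) and
#'   `perm` (the permutation applied, i.e. `shuffled$spectra == cube$spectra[perm, ]`).
#' @export
shuffle_cube <- function(cube, seed = 1L) {
  perm <- withr_seed(seed, sample.int(nrow(cube$spectra)))
  shuf <- spectral_cube(cube$spectra[perm, , drop = FALSE], cube$axis,
                        shape2d = NULL,
                        mask = if (!is.null(cube$mask)) cube$mask[perm])
  list(cube = shuf, perm = perm)
}

## evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## population (denominator n) column variances
col_pop_var <- function(x) {
  m <- nrow(x)
  mu <- colMeans(x)
  colMeans(x * x) - mu * mu
}
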