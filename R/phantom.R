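#' Specify a synthetic tissue phantom
#'
#' Describes a hyperspectral phantom: image shape, wavenumber axis,
#' spatial class layout, per-class Gaussian absorbance bands, the silent
#' interval that must stay chemically empty, and the transmittance-domain
#' noise level. Defaults emulate a QCL-style acquisition of heterogeneous
#' prostate-like tissue: axis 952-1800 cm^-1 at 2 cm^-1 step (425 bands),
#' four classes (stroma-like, epithelium-like, blood-like, background)
#' with distinct Amide I (~1656 cm^-1) / Amide II (~1546 cm^-1) ratios,
#' and a silent interval at 1750-1800 cm^-1.
#'
#' @param shape image shape `c(y, x)`.
#' @param axis_lo,axis_hi,axis_step wavenumber axis specification (cm^-1);
#'   `axis_step` must divide `axis_hi - axis_lo`.
#' @param layout spatial class layout: `"stripes"` (vertical bands),
#'   `"blobs"` (seeded nearest-centre regions), or `"cores"` (concentric
#'   tissue-core rings over background).
#' @param classes list of class descriptions, each a list with `name` and
#'   `bands`, a data frame / list of `centre` (cm^-1), `width` (cm^-1,
#'   Gaussian sd), `peak` (absorbance). Defaults give four tissue-like
#'   classes.
#' @param silent interval `c(lo, hi)` kept free of absorbance: every band
#'   centre must be at least 3 widths away.
#' @param sigma_t transmittance-domain noise standard deviation used by
#'   [add_noise()] (default 0.005; silent-region SNR of order 10-50).
#' @param correlated optional correlated-noise spec:
#'   `list(baseline_amp =, fringe_period =, fringe_amp =)`.
#' @param seed integer seed controlling layout and noise.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         axis_lo = 952, axis_hi = 1800, axis_step = 2,
                         layout = c("stripes", "blobs", "cores"),
                         classes = default_phantom_classes(),
                         silent = c(1750, 1800),
                         sigma_t = 0.005,
                         correlated = NULL,
                         seed = 1L) {
  layout <- match.arg(layout)
  if ((axis_hi - axis_lo) %% axis_step != 0)
    stop("axis_step must divide axis_hi - axis_lo")
  for (cl in classes) {
    b <- cl$bands
    for (i in seq_along(b$centre)) {
      lo3 <- b$centre[i] - 3 * b$width[i]
      hi3 <- b$centre[i] + 3 * b$width[i]
      if (hi3 >= silent[1] && lo3 <= silent[2])
        stop("class '", cl$name, "' band at ", b$centre[i],
             " cm^-1 encroaches (within 3 widths) on the silent interval")
    }
  }
  structure(list(shape = as.integer(shape), axis_lo = axis_lo,
                 axis_hi = axis_hi, axis_step = axis_step, layout = layout,
                 classes = classes, silent = silent, sigma_t = sigma_t,
                 correlated = correlated, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom tissue classes
#'
#' Four classes with tissue-like fingerprint bands. Amide I / Amide II
#' peak ratios differ by class (about 1.25, 1.67, 2.2 and a weak
#' background) so ratio-preservation evaluations have spread.
#'
#' @return list of class descriptions for [phantom_spec()].
#' @export
default_phantom_classes <- function() {
  band <- function(centre, width, peak)
    list(centre = centre, width = width, peak = peak)
  bands <- function(...) {
    b <- list(...)
    list(centre = vapply(b, `[[`, 0, "centre"),
         width = vapply(b, `[[`, 0, "width"),
         peak = vapply(b, `[[`, 0, "peak"))
  }
  list(
    list(name = "stroma", bands = bands(
      band(1656, 12, 1.00), band(1546, 10, 0.80), band(1236, 14, 0.25),
      band(1080, 14, 0.20), band(1452, 10, 0.22))),
    list(name = "epithelium", bands = bands(
      band(1656, 12, 1.15), band(1546, 10, 0.69), band(1236, 14, 0.35),
      band(1030, 16, 0.30), band(1452, 10, 0.18))),
    list(name = "blood", bands = bands(
      band(1656, 11, 1.20), band(1546, 10, 0.55), band(1392, 10, 0.20),
      band(1120, 14, 0.12))),
    list(name = "background", bands = bands(
      band(1656, 12, 0.08), band(1546, 10, 0.06)))
  )
}

#' Generate the clean phantom
#'
#' Builds the class-label image for the requested layout and the noise-free
#' absorbance cube: each class's spectrum is a sum of Gaussian bands in
#' absorbance. Deterministic given the spec's seed. The `noisy` slot is
#' filled by [add_noise()] / [add_correlated_noise()].
#'
#' @param spec a [phantom_spec()].
#' @return object of class `"phantom"`: list with `clean`
#'   (a [spectral_cube()]), `noisy` (`NULL` until noise is added),
#'   `labels` (`y x x` integer class image), `class_names`, `spec`.
#' @export
make_phantom <- function(spec) {
  y <- spec$shape[1]; x <- spec$shape[2]
  axis <- seq(spec$axis_lo, spec$axis_hi, by = spec$axis_step)
  ncl <- length(spec$classes)
  labels <- withr_seed(spec$seed, phantom_labels(y, x, ncl, spec$layout))
  profiles <- t(vapply(spec$classes, function(cl) {
    a <- numeric(length(axis))
    b <- cl$bands
    for (i in seq_along(b$centre))
      a <- a + b$peak[i] * exp(-0.5 * ((axis - b$centre[i]) / b$width[i])^2)
    a
  }, numeric(length(axis))))
  lab_vec <- as.integer(t(labels))          # row-major unroll
  X <- profiles[lab_vec, , drop = FALSE]
  clean <- spectral_cube(X, axis, shape2d = c(y, x))
  structure(list(clean = clean, noisy = NULL, labels = labels,
                 class_names = vapply(spec$classes, `[[`, "", "name"),
                 spec = spec),
            class = "phantom")
}

## spatial class layouts (called under the spec seed)
phantom_labels <- function(y, x, ncl, layout) {
  if (layout == "stripes") {
    # contiguous vertical stripes, one block per class
    col_class <- pmin(ceiling(seq_len(x) / ceiling(x / ncl)), ncl)
    matrix(rep(col_class, each = y), nrow = y, byrow = FALSE)
  } else if (layout == "blobs") {
    ncent <- max(ncl * 3L, 8L)
    cy <- stats::runif(ncent, 1, y); cx <- stats::runif(ncent, 1, x)
    cl <- rep(seq_len(ncl), length.out = ncent)
    lab <- matrix(0L, y, x)
    for (i in seq_len(y)) {
      dd <- sapply(seq_len(ncent), function(k) (i - cy[k])^2 + (seq_len(x) - cx[k])^2)
      lab[i, ] <- cl[max.col(-dd)]
    }
    lab
  } else { # cores: concentric rings over background (last class)
    cy <- (y + 1) / 2; cx <- (x + 1) / 2
    r <- sqrt(outer((seq_len(y) - cy)^2, (seq_len(x) - cx)^2, "+"))
    rmax <- min(y, x) / 2
    lab <- matrix(ncl, y, x)                 # background
    rings <- seq(0, 0.9 * rmax, length.out = ncl)
    for (k in rev(seq_len(ncl - 1L))) lab[r <= rings[k + 1L]] <- k
    lab
  }
}

#' @export
print.phantom <- function(x, ...) {
  cat("Phantom: ", x$spec$shape[1], " x ", x$spec$shape[2], " pixels, ",
      length(x$clean$axis), " bands (", x$spec$layout, " layout)\n", sep = "")
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  cat("  silent interval: ", x$spec$silent[1], "-", x$spec$silent[2],
      " cm^-1\n", sep = "")
  cat("  noise: ", if (is.null(x$noisy)) "none added yet"
      else paste0("sigma_T = ", x$spec$sigma_t), "\n", sep = "")
  invisible(x)
}

#' Add transmittance-domain noise to a phantom
#'
#' Noise is injected in the transmittance domain — `T = 10^(-A)`,
#' `T' = T + e` with `e ~ N(0, sigma_t^2)` iid, `A' = -log10(max(T', 1e-6))`
#' — so the absorbance-domain noise variance follows the inverse-square
#' transmittance law by physics rather than by construction in absorbance.
#' By the delta method the absorbance-noise variance at mean transmittance
#' `T` is approximately `(sigma_t / (T ln 10))^2`.
#'
#' @param phantom a [make_phantom()] result.
#' @param sigma_t transmittance noise sd (default the spec's value);
#'   `sigma_t = 0` returns the clean cube as `noisy`.
#' @param seed RNG seed (default the spec's seed).
#' @return the phantom with its `noisy` cube filled.
#' @export
add_noise <- function(phantom, sigma_t = phantom$spec$sigma_t,
                      seed = phantom$spec$seed) {
  if (sigma_t < 0) stop("sigma_t must be >= 0")
  A <- phantom$clean$spectra
  if (sigma_t == 0) {
    phantom$noisy <- phantom$clean
    return(phantom)
  }
  Tm <- 10^(-A)
  eps <- withr_seed(seed, matrix(stats::rnorm(length(Tm), sd = sigma_t),
                                 nrow(Tm), ncol(Tm)))
  An <- -log10(pmax(Tm + eps, 1e-6))
  phantom$noisy <- cube_with(phantom$clean, An)
  phantom$spec$sigma_t <- sigma_t
  phantom
}

#' Add spectrally correlated noise (baseline drift and fringing)
#'
#' Adds, per pixel, a random-slope linear baseline and a sinusoidal
#' fringe (random phase per pixel) across the axis — the highly
#' correlated noise structures a diagonal noise model deliberately
#' ignores. Used to exercise that documented failure mode.
#'
#' @param phantom a phantom whose `noisy` cube exists (run [add_noise()]
#'   first; use `sigma_t = 0` for correlated-only noise).
#' @param baseline_amp maximum absolute baseline offset at the axis ends
#'   (absorbance units).
#' @param fringe_period fringe period in cm^-1.
#' @param fringe_amp fringe amplitude (absorbance units).
#' @param seed RNG seed.
#' @return the phantom with correlated noise added to `noisy`.
#' @export
add_correlated_noise <- function(phantom, baseline_amp = 0,
                                 fringe_period = 100, fringe_amp = 0,
                                 seed = phantom$spec$seed + 1L) {
  if (baseline_amp < 0 || fringe_amp < 0) stop("amplitudes must be >= 0")
  if (is.null(phantom$noisy))
    stop("add_noise() first (sigma_t = 0 gives a clean starting point)")
  if (baseline_amp == 0 && fringe_amp == 0) return(phantom)
  X <- phantom$noisy$spectra
  m <- nrow(X)
  ax <- phantom$noisy$axis
  u <- (ax - min(ax)) / diff(range(ax)) * 2 - 1     # [-1, 1] across axis
  noise <- withr_seed(seed, {
    slope <- stats::runif(m, -baseline_amp, baseline_amp)
    phase <- stats::runif(m, 0, 2 * pi)
    outer(slope, u) + fringe_amp * sin(outer(phase, rep(1, length(ax))) +
                                       2 * pi * outer(rep(1, m), ax) / fringe_period)
  })
  phantom$noisy <- cube_with(phantom$noisy, X + noise)
  phantom$spec$correlated <- list(baseline_amp = baseline_amp,
                                  fringe_period = fringe_period,
                                  fringe_amp = fringe_amp)
  phantom
}
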