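# Shared fixtures: small phantoms and toy cubes built in code.

qcl_axis <- function() seq(952, 1800, by = 2)

# small noisy QCL-style phantom; memoised per (shape, sigma_t, seed)
.fixture_env <- new.env(parent = emptyenv())
small_phantom <- function(shape = c(16L, 16L), sigma_t = 0.005, seed = 3L,
                          layout = "stripes") {
  key <- paste(c(shape, sigma_t, seed, layout), collapse = "_")
  if (is.null(.fixture_env[[key]])) {
    ph <- make_phantom(phantom_spec(shape = shape, layout = layout,
                                    sigma_t = sigma_t, seed = seed))
    .fixture_env[[key]] <- add_noise(ph)
  }
  .fixture_env[[key]]
}

qcl_silent <- function(cube) silent_region(cube$axis, 1750, 1800)

# iid-noise cube on an arbitrary unit-spacing axis
white_cube <- function(m, v, sd = 1, seed = 1L, axis = seq_len(v)) {
  set.seed(seed)
  spectral_cube(matrix(rnorm(m * v, sd = sd), m, v), axis)
}

uniform_noise <- function(v, var = 1)
  noise_covariance(profile = rep(var, v), provenance = "user")
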