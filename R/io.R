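## ENVI data type codes used here: 4 = float32, 5 = float64
envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(size = 4L, what = "numeric"),
         "5" = list(size = 8L, what = "numeric"),
         stop("unsupported ENVI data type code: ", code,
              " (only 4 = float32 and 5 = float64 are supported)"))
}

parse_envi_header <- function(header_path) {
  if (!file.exists(header_path)) stop("missing ENVI header: ", header_path)
  txt <- readLines(header_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(joined, regexpr(paste0("(?mi)^", key, "\\s*=\\s*([^\\n{]+)"),
                                    joined, perl = TRUE))
    if (length(m) == 0) return(NULL)
    trimws(sub(paste0("(?i)^", key, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  get_block <- function(key) {
    m <- regmatches(joined,
                    regexpr(paste0("(?msi)^", key, "\\s*=\\s*\\{([^}]*)\\}"),
                            joined, perl = TRUE))
    if (length(m) == 0) return(NULL)
    body <- sub(paste0("(?msi)^", key, "\\s*=\\s*\\{"), "", m, perl = TRUE)
    body <- sub("\\}\\s*$", "", body)
    as.numeric(strsplit(body, "[,\\n]")[[1]][nzchar(trimws(strsplit(body, "[,\\n]")[[1]]))])
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       byte_order = as.integer(get_scalar("byte order")),
       wavelength = get_block("wavelength"))
}

#' Read an ENVI header/binary cube
#'
#' Supports BSQ, BIL and BIP interleaves, float32/float64 (data type
#' codes 4 and 5) and both byte orders. The wavenumber axis is taken from
#' the header's `wavelength` block; image lines become the unrolled
#' row-major pixel order.
#'
#' @param header_path path to the `.hdr` text header; the binary is the
#'   same path without the `.hdr` extension (or with `.dat`).
#' @return a [spectral_cube()] with `shape2d = c(lines, samples)`.
#' @export
read_envi <- function(header_path) {
  h <- parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "data_type"))
    if (is.null(h[[f]]) || is.na(h[[f]]))
      stop("ENVI header missing field: ", gsub("_", " ", f))
  if (is.null(h$wavelength))
    stop("ENVI header has no wavelength block")
  if (length(h$wavelength) != h$bands)
    stop("ENVI header: bands = ", h$bands, " but wavelength list has ",
         length(h$wavelength), " entries")
  bin <- envi_binary_path(header_path)
  if (!file.exists(bin)) stop("missing ENVI binary for header: ", header_path)
  dt <- envi_dtype(h$data_type)
  n <- h$samples * h$lines * h$bands
  endian <- if (identical(h$byte_order, 1L)) "big" else "little"
  con <- file(bin, "rb"); on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = n, size = dt$size, endian = endian)
  if (length(vals) != n)
    stop("ENVI binary holds ", length(vals), " values, expected ", n)
  m <- h$samples * h$lines
  il <- if (is.null(h$interleave)) "bsq" else h$interleave
  X <- switch(il,
    bip = matrix(vals, nrow = m, ncol = h$bands, byrow = TRUE),
    bil = {  # per line: bands x samples
      a <- array(vals, dim = c(h$samples, h$bands, h$lines))
      X <- matrix(0, m, h$bands)
      for (l in seq_len(h$lines))
        X[((l - 1) * h$samples + 1):(l * h$samples), ] <- a[, , l]
      X
    },
    bsq = matrix(vals, nrow = m, ncol = h$bands),
    stop("unsupported interleave: ", il))
  spectral_cube(X, h$wavelength, shape2d = c(h$lines, h$samples))
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (cand in c(base, paste0(base, ".dat"), paste0(base, ".img")))
    if (file.exists(cand)) return(cand)
  base
}

#' Write a cube as an ENVI header/binary pair
#'
#' @param cube a [spectral_cube()] with `shape2d` (a cube without one is
#'   written as a single-line image of `m` samples).
#' @param header_path output `.hdr` path; the binary goes to the same
#'   path without `.hdr`.
#' @param interleave `"bip"`, `"bil"` or `"bsq"`.
#' @param float32 store as float32 (data type 4) instead of float64 (5).
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bip", "bil", "bsq"),
                       float32 = FALSE) {
  interleave <- match.arg(interleave)
  shape <- if (is.null(cube$shape2d)) c(1L, nrow(cube$spectra)) else cube$shape2d
  v <- ncol(cube$spectra)
  hdr <- c("ENVI",
           "description = {imnf spectral cube}",
           paste0("samples = ", shape[2]),
           paste0("lines = ", shape[1]),
           paste0("bands = ", v),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", if (float32) 4L else 5L),
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Wavenumber",
           paste0("wavelength = {", paste(format(cube$axis, trim = TRUE,
                                                 digits = 12),
                                          collapse = ", "), "}"))
  writeLines(hdr, header_path)
  X <- cube$spectra
  vals <- switch(interleave,
    bip = as.vector(t(X)),
    bsq = as.vector(X),
    bil = {
      out <- numeric(length(X))
      s <- shape[2]
      for (l in seq_len(shape[1])) {
        block <- X[((l - 1) * s + 1):(l * s), , drop = FALSE]
        out[((l - 1) * s * v + 1):(l * s * v)] <- as.vector(block)
      }
      out
    })
  con <- file(envi_binary_out(header_path), "wb"); on.exit(close(con))
  writeBin(vals, con, size = if (float32) 4L else 8L, endian = "little")
  invisible(header_path)
}

envi_binary_out <- function(header_path) sub("\\.hdr$", "", header_path)

#' Read/write spectra as CSV
#'
#' The CSV carries one header row of wavenumbers followed by one row per
#' spectrum.
#'
#' @param path CSV file path.
#' @return [spectral_cube()] (reader) / `path` invisibly (writer).
#' @export
read_csv_spectra <- function(path) {
  d <- utils::read.csv(path, header = FALSE, colClasses = "numeric")
  d <- unname(as.matrix(d))
  if (nrow(d) < 2) stop("CSV must hold a wavenumber header row plus spectra")
  spectral_cube(d[-1, , drop = FALSE], d[1, ])
}

#' @rdname read_csv_spectra
#' @param cube a [spectral_cube()].
#' @param digits print precision for values.
#' @export
write_csv_spectra <- function(cube, path, digits = 12) {
  tab <- rbind(cube$axis, cube$spectra)
  utils::write.table(format(tab, trim = TRUE, digits = digits),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read/write a cube bundle
#'
#' The bundle is the package's on-disk container: a directory holding the
#' cube as an ENVI pair (`data.hdr` + `data`), optional `labels.csv` and
#' `mask.csv`, and `meta.json` with modality tag, seed and the provenance
#' log of every processing step applied.
#'
#' @param dir bundle directory.
#' @return list with `cube`, `labels` (matrix or `NULL`), `meta` (reader);
#'   `dir` invisibly (writer).
#' @export
read_bundle <- function(dir) {
  hdr <- file.path(dir, "data.hdr")
  cube <- read_envi(hdr)
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list()
  lab_path <- file.path(dir, "labels.csv")
  labels <- if (file.exists(lab_path))
    as.matrix(utils::read.csv(lab_path, header = FALSE)) else NULL
  mask_path <- file.path(dir, "mask.csv")
  if (file.exists(mask_path))
    cube$mask <- as.logical(as.vector(t(as.matrix(
      utils::read.csv(mask_path, header = FALSE)))))
  list(cube = cube, labels = labels, meta = meta)
}

#' @rdname read_bundle
#' @param cube a [spectral_cube()].
#' @param labels optional integer label image.
#' @param meta named list of provenance metadata (modality, seed, steps).
#' @param float32 store the cube as float32.
#' @export
write_bundle <- function(cube, dir, labels = NULL, meta = list(),
                         float32 = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_envi(cube, file.path(dir, "data.hdr"), interleave = "bip",
             float32 = float32)
  if (!is.null(labels))
    utils::write.table(labels, file.path(dir, "labels.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(cube$mask))
    utils::write.table(matrix(as.integer(cube$mask),
                              nrow = if (is.null(cube$shape2d)) 1
                                     else cube$shape2d[1], byrow = TRUE),
                       file.path(dir, "mask.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  meta$float32 <- float32
  meta$written <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialise / restore an MNF model
#'
#' Stores the full eigensystems, truncation, forward/reconstruction
#' matrices and the noise model (with provenance and silent-region
#' metadata) as JSON, so a model fitted once can be applied unchanged to
#' later patches or datasets.
#'
#' @param model a fitted [mnf()] model.
#' @param path output JSON path.
#' @return `path` invisibly (writer) / an `"mnf"` object (reader).
#' @export
write_mnf_model <- function(model, path) {
  noise <- model$noise
  obj <- list(
    k = model$k, m = model$m, axis = model$axis,
    signal_eigvals = model$signal_eigvals,
    signal_eigvecs = model$signal_eigvecs,
    noise_eigvals = model$noise_eigvals,
    noise_eigvecs = model$noise_eigvecs,
    forward = model$forward,
    reconstruction = model$reconstruction,
    noise = list(kind = noise$kind, profile = noise$profile,
                 matrix = noise$matrix, base_variance = noise$base_variance,
                 provenance = noise$provenance,
                 region = if (is.null(noise$region)) NULL else
                   list(lo = noise$region$lo, hi = noise$region$hi,
                        auto_selected = noise$region$auto_selected)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mnf_model
#' @export
read_mnf_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise <- if (identical(o$noise$kind, "dense"))
    noise_covariance(matrix = o$noise$matrix,
                     base_variance = o$noise$base_variance,
                     provenance = o$noise$provenance)
  else
    noise_covariance(profile = o$noise$profile,
                     base_variance = o$noise$base_variance,
                     provenance = o$noise$provenance)
  if (length(o$noise$region$lo))
    noise$region <- silent_region(o$axis, o$noise$region$lo, o$noise$region$hi,
                                  auto_selected = isTRUE(o$noise$region$auto_selected))
  structure(list(noise_eigvecs = as.matrix(o$noise_eigvecs),
                 noise_eigvals = o$noise_eigvals,
                 signal_eigvecs = as.matrix(o$signal_eigvecs),
                 signal_eigvals = o$signal_eigvals,
                 k = as.integer(o$k),
                 forward = as.matrix(o$forward),
                 reconstruction = as.matrix(o$reconstruction),
                 noise = noise, axis = o$axis, m = as.integer(o$m)),
            class = "mnf")
}

#' Streaming patch reader/writer over a BIP ENVI pair
#'
#' With pixel-interleaved (BIP) storage each spectrum is contiguous on
#' disk, so a patch can be read or written one image-row segment at a
#' time via seeks — the cube never has to be resident. The writer
#' preallocates the binary and writes its header up front; patches may
#' then be written in any order.
#'
#' @param header_path path of the `.hdr` of a BIP float64 ENVI pair.
#' @return `envi_patch_reader`: function `(patch) -> matrix` for
#'   [stream_denoise()].
#' @export
envi_patch_reader <- function(header_path) {
  h <- parse_envi_header(header_path)
  if (!identical(h$interleave, "bip"))
    stop("streaming requires BIP interleave")
  dt <- envi_dtype(h$data_type)
  bin <- envi_binary_path(header_path)
  force(bin)
  function(patch) {
    v <- h$bands
    nr <- patch["row_hi"] - patch["row_lo"] + 1L
    nc <- patch["col_hi"] - patch["col_lo"] + 1L
    out <- matrix(0, nr * nc, v)
    con <- file(bin, "rb"); on.exit(close(con))
    ri <- 0L
    for (r in patch["row_lo"]:patch["row_hi"]) {
      off <- ((r - 1) * h$samples + (patch["col_lo"] - 1)) * v * dt$size
      seek(con, where = off, origin = "start")
      seg <- readBin(con, "numeric", n = nc * v, size = dt$size,
                     endian = "little")
      out[ri + seq_len(nc), ] <- matrix(seg, nc, v, byrow = TRUE)
      ri <- ri + nc
    }
    out
  }
}

#' @rdname envi_patch_reader
#' @param axis wavenumber axis of the cube being written.
#' @param shape2d image shape `c(y, x)` of the output.
#' @param float32 write float32 instead of float64.
#' @return `envi_patch_writer`: function `(patch, matrix)` for
#'   [stream_denoise()].
#' @export
envi_patch_writer <- function(header_path, axis, shape2d, float32 = FALSE) {
  cube0 <- spectral_cube(matrix(0, prod(shape2d), length(axis)), axis,
                         shape2d = shape2d)
  write_envi(cube0, header_path, interleave = "bip", float32 = float32)
  bin <- envi_binary_out(header_path)
  size <- if (float32) 4L else 8L
  v <- length(axis); samples <- shape2d[2]
  function(patch, D) {
    con <- file(bin, "r+b"); on.exit(close(con))
    nc <- patch["col_hi"] - patch["col_lo"] + 1L
    ri <- 0L
    for (r in patch["row_lo"]:patch["row_hi"]) {
      off <- ((r - 1) * samples + (patch["col_lo"] - 1)) * v * size
      seek(con, where = off, origin = "start", rw = "write")
      writeBin(as.vector(t(D[ri + seq_len(nc), , drop = FALSE])), con,
               size = size, endian = "little")
      ri <- ri + nc
    }
    invisible(NULL)
  }
}
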