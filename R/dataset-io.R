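# Directory format for pseudo-2D datasets:
#   meta.json — acquisition + sequence parameters, domain flag, shape
#   data.bin  — little-endian 64-bit floats, interleaved real/imaginary,
#               row-major [increments x points]
# The writer and reader round-trip bit-exactly.

#' Write a pseudo-2D dataset to a directory
#'
#' @param ds a `pseudo2d` object (from [simulate_dataset()]) or a
#'   `spectrum_matrix` (frequency-domain; see [apodize_and_transform()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pseudo2d"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- ds$meta
  meta$shape <- dim(ds$matrix)
  meta$params <- unclass(meta$params)
  meta$params <- meta$params[!vapply(meta$params, is.null, logical(1))]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "meta.json"))
  # row-major on disk, each complex value as re,im
  v <- as.vector(t(ds$matrix))
  inter <- as.vector(rbind(Re(v), Im(v)))
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 8, endian = "little")
  invisible(dir)
}

#' Write a processed spectrum matrix to a directory
#'
#' Same directory format as [write_dataset()] with domain flag
#' `"frequency"`; the ppm axis (uniform, descending) is stored as
#' first value + step, the mask as a list of ppm intervals, and the
#' processing log inside `meta.json`.
#'
#' @param sm a `spectrum_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spectrum_matrix <- function(sm, dir) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- sm$meta
  meta$domain <- "frequency"
  meta$shape <- dim(sm$signal)
  meta$params <- unclass(meta$params)
  meta$params <- meta$params[!vapply(meta$params, is.null, logical(1))]
  meta$ppm_first <- sm$ppm_axis[1]
  meta$ppm_step <- sm$ppm_axis[2] - sm$ppm_axis[1]
  meta$noise_sd <- sm$noise_sd
  meta$processing_log <- sm$processing_log
  # store the mask as closed ppm intervals (runs of TRUE)
  r <- rle(sm$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(sm$ppm_axis[starts[r$values]], sm$ppm_axis[ends[r$values]])
  meta$mask_regions <- if (nrow(iv)) unname(apply(iv, 1, sort, simplify = FALSE)) else list()
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "meta.json"))
  v <- as.vector(t(sm$signal))
  inter <- as.vector(rbind(Re(v), Im(v)))
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 8, endian = "little")
  invisible(dir)
}

#' Read a processed spectrum matrix from a directory
#'
#' @param dir directory written by [write_spectrum_matrix()].
#' @return a `spectrum_matrix`.
#' @export
read_spectrum_matrix <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyMatrix = FALSE)
  if (!identical(meta$domain, "frequency"))
    stop_invalid("'%s' is not a frequency-domain dataset", dir)
  shape <- as.integer(meta$shape)
  params <- structure(meta$params, class = "dosy_params")
  params$n_increments <- as.integer(params$n_increments)
  params$n_scans <- as.integer(params$n_scans)
  n <- 2L * shape[1] * shape[2]
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8, endian = "little")
  mat <- matrix(complex(real = raw[seq(1, n, by = 2)],
                        imaginary = raw[seq(2, n, by = 2)]),
                nrow = shape[1], ncol = shape[2], byrow = TRUE)
  ppm <- meta$ppm_first + (seq_len(shape[2]) - 1L) * meta$ppm_step
  mask <- rep(FALSE, shape[2])
  eps <- abs(meta$ppm_step) / 2     # guard endpoint rounding
  for (r in meta$mask_regions)
    mask[ppm >= min(unlist(r)) - eps & ppm <= max(unlist(r)) + eps] <- TRUE
  keep <- c("params", "sw_ppm", "sfo1_mhz", "carrier_ppm", "points",
            "temperature_k", "seed")
  m2 <- meta[intersect(keep, names(meta))]
  m2$params <- params
  m2$domain <- "frequency"
  new_spectrum_matrix(mat, ppm, m2, unlist(meta$processing_log) %||% character(),
                      meta$noise_sd %||% NA_real_, mask)
}

#' Read a pseudo-2D dataset from a directory
#'
#' @param dir directory holding `meta.json` and `data.bin`.
#' @return a `pseudo2d` object (without ground truth).
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  dpath <- file.path(dir, "data.bin")
  if (!file.exists(mpath) || !file.exists(dpath))
    stop_invalid("dataset directory '%s' must contain meta.json and data.bin",
                 dir)
  meta <- jsonlite::fromJSON(mpath)
  shape <- as.integer(meta$shape)
  meta$params <- structure(meta$params, class = "dosy_params")
  meta$params$n_increments <- as.integer(meta$params$n_increments)
  meta$params$n_scans <- as.integer(meta$params$n_scans)
  validate_dosy_params(meta$params)
  n <- 2L * shape[1] * shape[2]
  con <- file(dpath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8, endian = "little")
  re <- raw[seq(1, n, by = 2)]
  im <- raw[seq(2, n, by = 2)]
  mat <- matrix(complex(real = re, imaginary = im),
                nrow = shape[1], ncol = shape[2], byrow = TRUE)
  meta$shape <- NULL
  structure(list(meta = meta, matrix = mat, ground_truth = NULL),
            class = "pseudo2d")
}
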