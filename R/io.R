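## File I/O: lossless paths (RDS for complex arrays and k-space bundles,
## NIfTI with paired real/imaginary volumes) and a viewable path (8-bit PNG
## magnitudes). All writes go through a write-temp-then-rename step so a
## crashed run never leaves a truncated file behind.

atomic_write <- function(path, writer) {
  # keep the extension so format-sniffing writers behave identically
  tmp <- file.path(dirname(path), paste0(".tmp", Sys.getpid(), "-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Write / read a sampling mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG (kept = 255, dropped = 0) in the
#' unshifted layout; the round trip is exact.
#'
#' @param mask a `sampling_mask`.
#' @param path output file path.
#' @export
write_mask_png <- function(mask, path) {
  atomic_write(path, function(p) png::writePNG(matrix(as.numeric(mask), nrow(mask)), p))
}

#' @rdname write_mask_png
#' @return for `read_mask_png`, a `sampling_mask` (scheme `"file"`).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  keep <- m > 0.5
  structure(keep, class = "sampling_mask", scheme = "file", seed = NA_integer_,
            target_factor = NA_real_)
}

#' Write a magnitude image as 8- or 16-bit PNG
#'
#' The magnitude is scaled linearly from `[0, scale_max]` (default: the image
#' maximum) into the PNG range. A viewable, lossy path; use [saveRDS()] or
#' [write_image_nifti()] for lossless storage.
#'
#' @param u complex image matrix.
#' @param path output path.
#' @param bits 8 or 16.
#' @param scale_max magnitude mapped to white (default `max(Mod(u))`).
#' @export
write_magnitude_png <- function(u, path, bits = 8L, scale_max = NULL) {
  m <- Mod(u)
  if (is.null(scale_max)) scale_max <- max(m, 1e-300)
  m <- pmin(pmax(m / scale_max, 0), 1)
  atomic_write(path, function(p) png::writePNG(m, p, dpi = NULL))
  invisible(path)
}

#' Lossless complex image I/O via NIfTI
#'
#' The complex image is stored as an `n x n x 2` volume (real and imaginary
#' channels); the round trip is exact to double precision.
#'
#' @param u complex image matrix.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_image_nifti <- function(u, path) {
  arr <- array(0, dim = c(nrow(u), ncol(u), 2L))
  arr[, , 1] <- Re(u); arr[, , 2] <- Im(u)
  atomic_write(path, function(p) RNifti::writeNifti(RNifti::asNifti(arr), p))
  invisible(path)
}

#' @rdname write_image_nifti
#' @return for `read_image_nifti`, the complex image matrix.
#' @export
read_image_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L || dim(arr)[3] != 2L)
    stop("expected an n x n x 2 real/imaginary volume")
  matrix(complex(real = arr[, , 1], imaginary = arr[, , 2]), dim(arr)[1])
}

#' Save / load k-space measurements
#'
#' Bundles (values, mask, sigma) in an RDS file.
#'
#' @param b a `"kspace"` object.
#' @param path output `.rds` path.
#' @export
write_kspace <- function(b, path) {
  stopifnot(inherits(b, "kspace"))
  atomic_write(path, function(p) saveRDS(b, p))
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "kspace")) stop("file does not contain k-space data")
  b
}

#' Archive a run configuration as JSON
#'
#' Serialises the full parameter set next to a run's outputs so the run can
#' be reproduced exactly from the archive.
#'
#' @param config named list of parameters.
#' @param path output `.json` path.
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(p)
    jsonlite::write_json(config, p, auto_unbox = TRUE, digits = NA, null = "null"))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write an iteration log as CSV
#'
#' @param result a `"recon_result"`.
#' @param path output `.csv` path.
#' @export
write_iteration_log <- function(result, path) {
  atomic_write(path, function(p) utils::write.csv(result$log, p, row.names = FALSE))
  invisible(path)
}
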