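#' Microscope calibration specification
#'
#' Bundles the physical pixel pitch of the camera sensor with the visual
#' magnification of the objective. Together they determine the physical size
#' of one image pixel (microns per pixel). The defaults match a 6.5 um CCD
#' pitch, the sensor used to acquire 700x460 breast histopathology fields at
#' 40x/100x/200x/400x.
#'
#' @param pps physical sensor pixel size in micrometres (> 0).
#' @param magnification unitless visual magnification (> 0); conventionally
#'   one of 40, 100, 200, 400, but any positive value is accepted.
#' @return An object of class `calibration_spec`.
#' @examples
#' calibration_spec(6.5, 40)
#' @export
calibration_spec <- function(pps = 6.5, magnification = 40) {
  if (!is.numeric(pps) || length(pps) != 1L || !is.finite(pps) || pps <= 0)
    stop("`pps` must be a single positive number (micrometres)", call. = FALSE)
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      !is.finite(magnification) || magnification <= 0)
    stop("`magnification` must be a single positive number", call. = FALSE)
  structure(list(pps = pps, magnification = magnification),
            class = "calibration_spec")
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat(sprintf("<calibration_spec> pps = %g um, magnification = %gx, mpp = %g um/px\n",
              x$pps, x$magnification, microns_per_pixel(x)))
  invisible(x)
}

#' Microns per pixel from sensor pitch and magnification
#'
#' The physical size of one image pixel is the sensor pixel pitch divided by
#' the visual magnification: `mpp = pps / m`. At a 6.5 um pitch this gives
#' 0.1625, 0.065, 0.0325 and 0.01625 um/pixel at 40x, 100x, 200x and 400x.
#'
#' @param spec a [calibration_spec()], or a positive pixel pitch in
#'   micrometres if `magnification` is given.
#' @param magnification visual magnification, used when `spec` is numeric.
#' @return Micrometres per pixel (scalar).
#' @examples
#' microns_per_pixel(calibration_spec(6.5, 400))  # 0.01625
#' @export
microns_per_pixel <- function(spec, magnification = NULL) {
  if (!inherits(spec, "calibration_spec"))
    spec <- calibration_spec(spec, magnification)
  spec$pps / spec$magnification
}

#' Physical size of a patch in micrometres
#'
#' @param w_p,h_p patch width and height in pixels (>= 0).
#' @param mpp_x,mpp_y microns-per-pixel along x and y; `mpp_y` defaults to
#'   `mpp_x` (square sensor pixels).
#' @return Named numeric vector `c(w_x =, h_y =)` in micrometres.
#' @examples
#' patch_physical_size(224, 224, 0.1625)  # 36.4 x 36.4 um
#' @export
patch_physical_size <- function(w_p, h_p, mpp_x, mpp_y = mpp_x) {
  if (w_p < 0 || h_p < 0)
    stop("pixel dimensions must be non-negative", call. = FALSE)
  if (mpp_x <= 0 || mpp_y <= 0)
    stop("microns-per-pixel must be positive", call. = FALSE)
  c(w_x = w_p * mpp_x, h_y = h_p * mpp_y)
}

#' Patch area in square micrometres
#'
#' @param w_x,h_y physical width and height in micrometres (>= 0).
#' @return Area in um^2.
#' @export
patch_area <- function(w_x, h_y) {
  if (w_x < 0 || h_y < 0) stop("physical dimensions must be non-negative",
                               call. = FALSE)
  w_x * h_y
}

#' Convert an area from square micrometres to square millimetres
#'
#' One um^2 is 1e-6 mm^2, so `a_mms = a_n * 1e-6`. (A 224-pixel patch at 40x
#' is 1324.96 um^2 = 0.00132496 mm^2.)
#'
#' @param a_n area in square micrometres (>= 0).
#' @return Area in mm^2.
#' @export
area_to_mm2 <- function(a_n) {
  if (a_n < 0) stop("area must be non-negative", call. = FALSE)
  a_n * 1e-6
}

#' Nuclei density per square millimetre
#'
#' @param n nuclei count (non-negative).
#' @param a_mms patch area in mm^2 (> 0).
#' @return Density in nuclei per mm^2.
#' @export
nuclei_density <- function(n, a_mms) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (!is.finite(a_mms) || a_mms <= 0)
    stop("`a_mms` must be positive", call. = FALSE)
  n / a_mms
}

#' Full patch calibration for a magnification
#'
#' Convenience constructor chaining [microns_per_pixel()],
#' [patch_physical_size()], [patch_area()] and [area_to_mm2()] for a square
#' patch of `w_p` x `h_p` pixels.
#'
#' @inheritParams microns_per_pixel
#' @param w_p,h_p patch dimensions in pixels (default 224).
#' @return A list of class `patch_calibration` with fields `mpp_x`, `mpp_y`,
#'   `w_p`, `h_p`, `w_x`, `h_y`, `a_n` (um^2) and `a_mms` (mm^2).
#' @examples
#' patch_calibration(calibration_spec(6.5, 400))
#' @export
patch_calibration <- function(spec, w_p = 224, h_p = 224) {
  mpp <- microns_per_pixel(spec)
  sz <- patch_physical_size(w_p, h_p, mpp)
  a_n <- patch_area(sz[["w_x"]], sz[["h_y"]])
  structure(list(mpp_x = mpp, mpp_y = mpp, w_p = w_p, h_p = h_p,
                 w_x = sz[["w_x"]], h_y = sz[["h_y"]],
                 a_n = a_n, a_mms = area_to_mm2(a_n)),
            class = "patch_calibration")
}

#' @export
print.patch_calibration <- function(x, ...) {
  cat(sprintf("<patch_calibration> %dx%d px @ %g um/px -> %.4g x %.4g um, %.6g um^2 = %.6g mm^2\n",
              x$w_p, x$h_p, x$mpp_x, x$w_x, x$h_y, x$a_n, x$a_mms))
  invisible(x)
}

#' Build per-patch density records
#'
#' @param patch_id character vector of patch identifiers.
#' @param n integer vector of nuclei counts.
#' @param a_mms patch area(s) in mm^2 (recycled).
#' @return A data frame with columns `patch_id`, `n`, `a_mms`, `a_d` and
#'   `bin` (initially `"UNASSIGNED"`); see [assign_bins()].
#' @export
density_records <- function(patch_id, n, a_mms) {
  stopifnot(length(patch_id) == length(n))
  a_mms <- rep_len(a_mms, length(n))
  data.frame(patch_id = as.character(patch_id), n = as.integer(n),
             a_mms = a_mms,
             a_d = mapply(nuclei_density, n, a_mms),
             bin = "UNASSIGNED", stringsAsFactors = FALSE)
}

#' Write / read a density manifest CSV
#'
#' Columns: `patch_id`, `n`, `a_mms`, `a_d`, `bin`.
#' @param records data frame from [density_records()] / [assign_bins()].
#' @param path CSV path.
#' @return `path` (write) or the data frame (read), invisibly for write.
#' @export
write_density_manifest <- function(records, path) {
  utils::write.csv(records[, c("patch_id", "n", "a_mms", "a_d", "bin")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_manifest
#' @export
read_density_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
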