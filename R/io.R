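# Image IO. Internal convention: RGB images are numeric arrays H x W x C on
# the 0..255 intensity scale (row = image row); instance/label masks are
# integer H x W matrices (0 = background). PNG via the png package (which is
# H x W native); 16-bit label masks via EBImage (x-major, hence transposes).

#' Read an image as an H x W x C array on the 0..255 scale
#' @param path PNG/TIFF/JPEG file.
#' @return numeric array `H x W x C`.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    return(img * 255)
  }
  img <- EBImage::imageData(EBImage::readImage(path)) * 255
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  aperm(img, c(2, 1, 3))
}

#' Write an H x W x C array (0..255) as an 8-bit PNG
#' @param img numeric array `H x W x C` or `H x W` matrix, 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmax(pmin(img / 255, 1), 0)
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
  png::writePNG(img, path)
  invisible(path)
}

#' Read / write an instance label mask PNG
#'
#' Instance labels (16-bit range, 0 = background) are stored losslessly in a
#' standard 8-bit RGB PNG: the red channel carries the high byte
#' (`label %/% 256`), the green channel the low byte (`label %% 256`), and
#' the blue channel is zero.
#' @param mask integer `H x W` matrix of instance labels.
#' @param path PNG path.
#' @return The label matrix (read) or `path` invisibly (write).
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 instances", call. = FALSE)
  hi <- mask %/% 256L; lo <- mask %% 256L
  img <- array(0, c(dim(mask), 3L))
  img[, , 1] <- hi / 255; img[, , 2] <- lo / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)               # plain grey mask: direct labels
    return(matrix(as.integer(round(img * 255)), nrow(img)))
  hi <- round(img[, , 1] * 255); lo <- round(img[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), nrow = dim(img)[1])
}

# stack a list of H x W x C arrays into an (H, W, C, N) batch
.stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}
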