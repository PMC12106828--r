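#' Plan a deterministic patch grid over a whole image
#'
#' Two tilings of a `image_w` x `image_h` field into square `patch`-pixel
#' tiles are supported:
#'
#' * `"grid6"` (default): 3 columns x 2 rows, evenly spaced so the last
#'   column/row is flush with the image edge. On a 700x460 field with
#'   224-pixel patches this gives x offsets {0, 238, 476} and y offsets
#'   {0, 236} — six patches per image, the tiling consistent with the
#'   six-patches-per-image corpus counts. Duplicate offsets arising from
#'   degenerate geometry (patch as large as the image) are removed.
#' * `"cover"`: the minimal evenly-strided grid whose tile footprints cover
#'   every pixel (`ceil((W-P)/P)+1` columns, likewise rows); 4 x 3 = 12
#'   tiles for 700x460/224.
#'
#' Offsets are 0-based top-left corners with half-open footprints
#' `[x, x+patch) x [y, y+patch)`, sorted row-major (by y then x).
#'
#' @param image_w,image_h image dimensions in pixels.
#' @param patch tile side in pixels (default 224); must not exceed either
#'   image dimension.
#' @param mode `"grid6"` or `"cover"`.
#' @return An object of class `patch_grid`: list with `image_w`, `image_h`,
#'   `patch`, `mode` and `offsets` (data frame with 0-based `x`, `y`).
#' @examples
#' plan_grid(700, 460)                  # 6 offsets
#' plan_grid(700, 460, mode = "cover")  # 12 offsets, full coverage
#' @export
plan_grid <- function(image_w, image_h, patch = 224,
                      mode = c("grid6", "cover")) {
  mode <- match.arg(mode)
  if (patch <= 0) stop("`patch` must be positive", call. = FALSE)
  if (patch > min(image_w, image_h))
    stop("patch size exceeds image dimensions", call. = FALSE)
  even_offsets <- function(extent, n) {
    span <- extent - patch
    if (n == 1L) return(0L)
    unique(as.integer(round((0:(n - 1)) * span / (n - 1))))
  }
  if (mode == "grid6") {
    xs <- even_offsets(image_w, 3L)
    ys <- even_offsets(image_h, 2L)
  } else {
    nx <- as.integer(ceiling((image_w - patch) / patch)) + 1L
    ny <- as.integer(ceiling((image_h - patch) / patch)) + 1L
    xs <- even_offsets(image_w, nx)
    ys <- even_offsets(image_h, ny)
  }
  offsets <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  offsets <- offsets[order(offsets$y, offsets$x), , drop = FALSE]
  rownames(offsets) <- NULL
  structure(list(image_w = as.integer(image_w), image_h = as.integer(image_h),
                 patch = as.integer(patch), mode = mode, offsets = offsets),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %dx%d image, %d px tiles, mode %s, %d offsets\n",
              x$image_w, x$image_h, x$patch, x$mode, nrow(x$offsets)))
  invisible(x)
}

#' Extract patches from an image according to a grid
#'
#' Each patch is an exact pixel copy (no resampling) of the half-open
#' footprint `[x, x+P) x [y, y+P)`.
#'
#' @param image numeric array `H x W x C` (or `H x W` matrix) in row/column
#'   pixel coordinates; values are copied untouched.
#' @param grid a [plan_grid()] result whose dimensions match `image`.
#' @param source name recorded in each patch id (default `"image"`).
#' @param magnification,class_label provenance propagated to each record.
#' @return A list of patch records: each a list with `patch_id`, `source`,
#'   `magnification`, `class_label`, `x`, `y` and `pixels` (P x P x C array).
#' @export
extract_patches <- function(image, grid, source = "image",
                            magnification = NA, class_label = NA) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("`image` must be a matrix or array",
                                         call. = FALSE)
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  if (d[1] != grid$image_h || d[2] != grid$image_w)
    stop(sprintf("image is %dx%d but grid expects %dx%d (H x W)",
                 d[1], d[2], grid$image_h, grid$image_w), call. = FALSE)
  P <- grid$patch
  lapply(seq_len(nrow(grid$offsets)), function(i) {
    x <- grid$offsets$x[i]; y <- grid$offsets$y[i]
    list(patch_id = sprintf("%s_x%d_y%d", source, x, y),
         source = source, magnification = magnification,
         class_label = class_label, x = x, y = y,
         pixels = image[(y + 1):(y + P), (x + 1):(x + P), , drop = FALSE])
  })
}

# infer class / magnification from BreakHis-style path components
.infer_from_path <- function(path) {
  parts <- tolower(strsplit(path, "[/\\\\]")[[1]])
  cls <- if (any(parts == "malignant")) "malignant"
         else if (any(parts == "benign")) "benign" else NA_character_
  magp <- grep("^[0-9]+x$", parts, value = TRUE)
  mag <- if (length(magp)) as.numeric(sub("x$", "", magp[length(magp)])) else NA_real_
  list(class_label = cls, magnification = mag)
}

#' Build a patch manifest (and optionally patch files) for an image corpus
#'
#' Walks a BreakHis-style folder tree (`class/[subtype/]magnification/*.png`,
#' magnification folders named like `40X`; the synthetic generator emulates
#' this layout), plans one grid per image, and writes a CSV manifest with one
#' row per patch. Unreadable images are skipped with a warning and counted.
#'
#' @param input_folder corpus root.
#' @param mode patch grid mode, see [plan_grid()].
#' @param manifest_path output CSV path (columns `patch_id`, `source`,
#'   `class`, `magnification`, `x`, `y`).
#' @param patch tile side in pixels.
#' @param patches_dir if non-`NULL`, patch PNGs named `{stem}_x{X}_y{Y}.png`
#'   are written there.
#' @param pattern filename regexp for images (default PNG/TIFF/JPEG).
#' @return The manifest data frame, invisibly, with attribute `"skipped"`
#'   holding the number of unreadable images.
#' @export
patch_corpus <- function(input_folder, mode = c("grid6", "cover"),
                         manifest_path = NULL, patch = 224,
                         patches_dir = NULL,
                         pattern = "\\.(png|tif|tiff|jpg|jpeg)$") {
  mode <- match.arg(mode)
  files <- list.files(input_folder, pattern = pattern, recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[!grepl("(^|/)masks?(/|_)", files, ignore.case = TRUE)]
  rows <- list(); skipped <- 0L
  for (f in files) {
    img <- tryCatch(read_image(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", f, call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    grid <- plan_grid(dim(img)[2], dim(img)[1], patch, mode)
    meta <- .infer_from_path(f)
    stem <- sub("\\.[^.]+$", "", basename(f))
    recs <- extract_patches(img, grid, source = stem,
                            magnification = meta$magnification,
                            class_label = meta$class_label)
    if (!is.null(patches_dir)) {
      dir.create(patches_dir, recursive = TRUE, showWarnings = FALSE)
      for (r in recs)
        write_image(r$pixels, file.path(patches_dir, paste0(r$patch_id, ".png")))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patch_id = vapply(recs, `[[`, "", "patch_id"),
      source = f, class = meta$class_label,
      magnification = meta$magnification,
      x = vapply(recs, `[[`, 0L, "x"), y = vapply(recs, `[[`, 0L, "y"),
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = character(), source = character(),
               class = character(), magnification = numeric(),
               x = integer(), y = integer(), stringsAsFactors = FALSE)
  if (!is.null(manifest_path)) {
    dir.create(dirname(manifest_path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
  }
  attr(manifest, "skipped") <- skipped
  invisible(manifest)
}
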