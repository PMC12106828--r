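#' Label connected components of a binary mask
#'
#' Breadth-first labelling with 4- or 8-connectivity; components smaller
#' than `min_area` pixels are dropped and the remaining labels renumbered
#' 1..n in first-encounter order.
#'
#' @param mask logical/0-1 `H x W` matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area minimum component area in pixels (default 0 = keep all).
#' @return Integer `H x W` label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8, min_area = 0) {
  lab <- .cc_label(mask > 0, as.integer(connectivity))
  if (min_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_area)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

#' Count nuclei in a segmentation mask
#'
#' Number of connected components with area at least `min_area` pixels.
#'
#' @param mask a [seg_mask()], or a logical/0-1 `H x W` matrix.
#' @param min_area minimum nucleus area in pixels (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer count.
#' @export
count_nuclei <- function(mask, min_area = 10, connectivity = 8) {
  if (inherits(mask, "seg_mask")) mask <- mask$mask
  max(label_components(mask, connectivity = connectivity,
                       min_area = min_area))
}

#' Density thresholds from a ratio
#'
#' Splits the density axis into low/medium/high bins at the cumulative
#' ratio fractions. With the default 30:30:40 ratio and the
#' `"fraction_of_max"` basis, `t_low = 0.30 * max(densities)` and
#' `t_high = 0.60 * max(densities)`; the `"quantile"` basis places them at
#' the corresponding percentiles (type-7 quantiles) instead.
#'
#' @param densities non-empty vector of non-negative densities (per mm^2).
#' @param ratio positive length-3 ratio for LD:MD:HD (default `c(30, 30, 40)`).
#' @param basis `"fraction_of_max"` (default) or `"quantile"`.
#' @return Object of class `density_thresholds`: list with `t_low`,
#'   `t_high`, `ratio`, `basis`.
#' @export
compute_thresholds <- function(densities, ratio = c(30, 30, 40),
                               basis = c("fraction_of_max", "quantile")) {
  basis <- match.arg(basis)
  if (length(densities) == 0) stop("empty density list", call. = FALSE)
  if (any(densities < 0)) stop("densities must be non-negative", call. = FALSE)
  if (length(ratio) != 3L || any(ratio <= 0))
    stop("`ratio` must be three positive numbers", call. = FALSE)
  cum <- cumsum(ratio) / sum(ratio)
  if (basis == "fraction_of_max") {
    mx <- max(densities)
    t_low <- cum[1] * mx; t_high <- cum[2] * mx
  } else {
    qs <- stats::quantile(densities, probs = cum[1:2], type = 7, names = FALSE)
    t_low <- qs[1]; t_high <- qs[2]
  }
  structure(list(t_low = t_low, t_high = t_high, ratio = ratio,
                 basis = basis), class = "density_thresholds")
}

#' @export
print.density_thresholds <- function(x, ...) {
  cat(sprintf("<density_thresholds> t_low=%.4g t_high=%.4g (%s, %s)\n",
              x$t_low, x$t_high, paste(x$ratio, collapse = ":"), x$basis))
  invisible(x)
}

#' Assign density bins to patch records
#'
#' LD if `d <= t_low`, MD if `t_low < d <= t_high`, HD if `d > t_high`
#' (ties go to the lower bin).
#'
#' @param records data frame with an `a_d` density column (see
#'   [density_records()]).
#' @param thresholds a [compute_thresholds()] result.
#' @return `records` with the `bin` column filled in.
#' @export
assign_bins <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "density_thresholds"))
  d <- records$a_d
  records$bin <- ifelse(d <= thresholds$t_low, "LD",
                        ifelse(d <= thresholds$t_high, "MD", "HD"))
  records
}

#' Build the stratified LD/MD/HD folder layout
#'
#' Creates `output_root/{LD,MD,HD}/{benign,malignant}/`. Malignant patches
#' go to the folder of their bin; benign patches (which bypass density
#' computation) are replicated into all three bins. Patch files are copied
#' when a `path` column is present; otherwise only the manifest is built.
#'
#' @param manifest data frame with columns `patch_id`, `class`
#'   (benign/malignant), optionally `path`, and for malignant rows a
#'   `bin` column (from [assign_bins()]) and `a_d`.
#' @param output_root output directory, or `NULL` for a manifest-only run.
#' @return The stratified manifest data frame (columns `patch_id`, `class`,
#'   `density`, `bin`, `split` — split is `NA` until [split_dataset()]),
#'   with one row per benign patch per bin plus one per malignant patch.
#' @export
build_stratified_layout <- function(manifest, output_root = NULL) {
  ben <- manifest[manifest$class == "benign", , drop = FALSE]
  mal <- manifest[manifest$class == "malignant", , drop = FALSE]
  if (nrow(mal) && (is.null(mal$bin) || any(!mal$bin %in% c("LD", "MD", "HD"))))
    stop("malignant rows must carry assigned bins", call. = FALSE)
  rows <- list()
  for (b in c("LD", "MD", "HD")) {
    if (nrow(ben))
      rows[[length(rows) + 1L]] <- data.frame(
        patch_id = ben$patch_id, class = "benign", density = NA_real_,
        bin = b, split = NA_character_,
        path = if (!is.null(ben$path)) ben$path else NA_character_,
        stringsAsFactors = FALSE)
  }
  if (nrow(mal))
    rows[[length(rows) + 1L]] <- data.frame(
      patch_id = mal$patch_id, class = "malignant",
      density = if (!is.null(mal$a_d)) mal$a_d else NA_real_,
      bin = mal$bin, split = NA_character_,
      path = if (!is.null(mal$path)) mal$path else NA_character_,
      stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = character(), class = character(),
               density = numeric(), bin = character(), split = character(),
               path = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(output_root)) {
    for (b in c("LD", "MD", "HD")) for (cl in c("benign", "malignant"))
      dir.create(file.path(output_root, b, cl), recursive = TRUE,
                 showWarnings = FALSE)
    src_ok <- !is.na(out$path)
    for (i in which(src_ok)) {
      dst <- file.path(output_root, out$bin[i], out$class[i],
                       paste0(out$patch_id[i], ".png"))
      if (file.exists(dst))
        stop("output path collision: ", dst, call. = FALSE)
      file.copy(out$path[i], dst)
    }
    utils::write.csv(out[, c("patch_id", "class", "density", "bin", "split")],
                     file.path(output_root, "stratified_manifest.csv"),
                     row.names = FALSE)
  }
  out
}

#' Stratified 70/15/15 train/validation/test split
#'
#' Within every (bin, class) group, patches are shuffled with `seed` and
#' assigned `floor(n * fraction)` to validation and test; rounding residues
#' go to training. Deterministic given the seed.
#'
#' @param manifest stratified manifest (see [build_stratified_layout()]).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return `manifest` with the `split` column filled with
#'   `train`/`val`/`test` and an added `seed` column.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                          seed = 42) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must sum to 1", call. = FALSE)
  set.seed(seed)
  manifest$split <- NA_character_
  for (b in unique(manifest$bin)) for (cl in unique(manifest$class)) {
    idx <- which(manifest$bin == b & manifest$class == cl)
    n <- length(idx)
    if (!n) next
    idx <- idx[sample(n)]
    nv <- floor(fractions[2] * n); nt <- floor(fractions[3] * n)
    manifest$split[idx[seq_len(n - nv - nt)]] <- "train"
    if (nv) manifest$split[idx[n - nv - nt + seq_len(nv)]] <- "val"
    if (nt) manifest$split[idx[n - nt + seq_len(nt)]] <- "test"
  }
  manifest$seed <- seed
  manifest
}
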