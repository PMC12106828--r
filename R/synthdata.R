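#' Specification of a synthetic H&E scene
#'
#' Describes a field of nuclei rendered in the Beer-Lambert optical-density
#' model of the [he_stain_model()]: each nucleus is an elliptical blob with
#' low-order radial-harmonic boundary irregularity and its own hematoxylin
#' concentration; the background carries a smooth eosin texture; Gaussian
#' pixel noise is added last. Benign-like scenes default to fewer, rounder,
#' size-uniform nuclei; malignant-like scenes to denser, pleomorphic nuclei
#' (wider size range, higher eccentricity, more irregular boundaries).
#'
#' @param width,height scene size in pixels (default 700 x 460).
#' @param class_label `"benign_like"` or `"malignant_like"`.
#' @param n_nuclei count or `c(min, max)` range; `NULL` scales a per-class
#'   areal rate (60 per megapixel-fraction for benign-like, 250 for
#'   malignant-like) to the scene area.
#' @param radius_range nucleus base radius range, pixels.
#' @param ecc_range eccentricity (major/minor axis ratio) range.
#' @param irregularity amplitude of the radial boundary harmonics.
#' @param overlap_allowance fraction by which nucleus centre spacing may
#'   undercut the sum of radii (0 = pairwise disjoint); defaults to 0 for
#'   benign-like scenes and 0.3 for malignant-like ones, whose crowded,
#'   overlapping nuclei are the segmenter's documented hard case.
#' @param c_h_range,c_e_range hematoxylin / eosin concentration ranges (OD).
#' @param noise_sd additive Gaussian noise, intensity units (0..255 scale).
#' @param eosin_texture_scale correlation length of the background eosin
#'   texture, pixels.
#' @param count_tiers optional named list `list(LD =, MD =, HD =)` of
#'   count ranges; each scene samples one tier and records it as the
#'   intended density bin.
#' @param seed RNG seed; scenes are bit-reproducible given the spec + seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 700, height = 460,
                       class_label = c("benign_like", "malignant_like"),
                       n_nuclei = NULL, radius_range = NULL,
                       ecc_range = NULL, irregularity = NULL,
                       overlap_allowance = NULL,
                       c_h_range = c(0.55, 0.95), c_e_range = c(0.05, 0.25),
                       noise_sd = 2, eosin_texture_scale = 24,
                       count_tiers = NULL, seed = 1) {
  class_label <- match.arg(class_label)
  mal <- class_label == "malignant_like"
  if (is.null(radius_range)) radius_range <- if (mal) c(4, 9) else c(6, 9)
  if (is.null(ecc_range)) ecc_range <- if (mal) c(1.2, 2.2) else c(1.0, 1.2)
  if (is.null(irregularity)) irregularity <- if (mal) 0.15 else 0.03
  if (is.null(overlap_allowance)) overlap_allowance <- if (mal) 0.3 else 0
  if (is.null(n_nuclei)) {
    rate <- if (mal) 250 else 60            # nuclei per full 700x460 field
    n_nuclei <- max(1L, round(width * height * rate / (700 * 460)))
  }
  if (any(n_nuclei < 0)) stop("`n_nuclei` must be non-negative", call. = FALSE)
  if (overlap_allowance < 0 || overlap_allowance >= 1)
    stop("`overlap_allowance` must be in [0, 1)", call. = FALSE)
  if (max(radius_range) * 2 > min(width, height))
    stop("nuclei radius range exceeds scene size", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 class_label = class_label, n_nuclei = n_nuclei,
                 radius_range = radius_range, ecc_range = ecc_range,
                 irregularity = irregularity,
                 overlap_allowance = overlap_allowance,
                 c_h_range = c_h_range, c_e_range = c_e_range,
                 noise_sd = noise_sd,
                 eosin_texture_scale = eosin_texture_scale,
                 count_tiers = count_tiers, seed = seed),
            class = "scene_spec")
}

#' Generate one synthetic scene with ground truth
#'
#' Nuclei are placed by rejection sampling honouring the overlap allowance,
#' rasterised into an instance label mask, and rendered channel-wise as
#' `I_c = background * exp(-(c_H V_H + c_E V_E))` with the package's stain
#' vectors, plus Gaussian pixel noise. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param stain_model the [he_stain_model()] used for rendering.
#' @return A list of class `scene_truth`: `image` (`H x W x 3`, 0..255,
#'   unquantised), `labels` (integer instance mask), `n_nuclei` (realised),
#'   `nuclei` (per-nucleus data frame: `x`, `y`, `radius`, `ecc`, `area`,
#'   `c_h`), `conc` (rendered concentration array, for round-trip checks),
#'   `class_label`, `intended_bin`, `spec`.
#' @export
generate_scene <- function(spec, stain_model = he_stain_model()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  intended_bin <- NA_character_
  nr <- spec$n_nuclei
  if (!is.null(spec$count_tiers)) {
    tier <- sample(names(spec$count_tiers), 1L)
    intended_bin <- tier
    nr <- spec$count_tiers[[tier]]
  }
  n <- if (length(nr) == 2L) sample(nr[1]:nr[2], 1L) else as.integer(nr)

  radii <- if (n) stats::runif(n, spec$radius_range[1], spec$radius_range[2]) else numeric()
  eccs <- if (n) stats::runif(n, spec$ecc_range[1], spec$ecc_range[2]) else numeric()
  # rejection-sample centres
  xs <- numeric(n); ys <- numeric(n)
  margin <- radii * sqrt(eccs) * (1 + 3 * spec$irregularity) + 1
  if (n) {
    tries <- 0L; max_tries <- 400L * n
    placed <- 0L
    while (placed < n) {
      if (tries >= max_tries)
        stop(sprintf(paste0("could not place %d nuclei of radius %.3g-%.3g in a %dx%d ",
                            "scene at overlap allowance %.2g after %d tries"),
                     n, spec$radius_range[1], spec$radius_range[2], W, H,
                     spec$overlap_allowance, max_tries), call. = FALSE)
      tries <- tries + 1L
      i <- placed + 1L
      x <- stats::runif(1, margin[i], W - margin[i])
      y <- stats::runif(1, margin[i], H - margin[i])
      ok <- TRUE
      if (placed > 0L) {
        dmin <- (1 - spec$overlap_allowance) *
          (margin[seq_len(placed)] + margin[i])
        ok <- all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >=
                  dmin^2)
      }
      if (ok) { xs[i] <- x; ys[i] <- y; placed <- i }
    }
  }

  labels <- matrix(0L, H, W)
  c_h_vals <- if (n) stats::runif(n, spec$c_h_range[1], spec$c_h_range[2]) else numeric()
  for (i in seq_len(n)) {
    r0 <- radii[i]; e <- eccs[i]
    a <- r0 * sqrt(e); b <- r0 / sqrt(e)
    th <- stats::runif(1, 0, pi)
    nk <- 3L
    amp <- stats::rnorm(nk, 0, spec$irregularity)
    ph <- stats::runif(nk, 0, 2 * pi)
    R <- ceiling(max(a, b) * (1 + 3 * spec$irregularity)) + 1L
    cx <- xs[i]; cy <- ys[i]
    px <- max(1L, floor(cx - R)):min(W, ceiling(cx + R))
    py <- max(1L, floor(cy - R)):min(H, ceiling(cy + R))
    gx <- outer(rep(1, length(py)), px) - cx
    gy <- outer(py, rep(1, length(px))) - cy
    u <- gx * cos(th) + gy * sin(th)
    v <- -gx * sin(th) + gy * cos(th)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    phi <- atan2(v, u)
    bnd <- 1
    for (k in seq_len(nk)) bnd <- bnd + amp[k] * cos((k + 1) * phi + ph[k])
    inside <- rho <= bnd
    sub <- labels[py, px]
    write <- inside & sub == 0L
    sub[write] <- i
    labels[py, px] <- sub
  }
  # drop fully occluded nuclei and renumber so labels == realised count
  if (n) {
    present <- sort(unique(labels[labels > 0L]))
    if (length(present) < n) {
      remap <- integer(n); remap[present] <- seq_along(present)
      labels[labels > 0L] <- remap[labels[labels > 0L]]
      keep <- present
    } else keep <- seq_len(n)
    xs <- xs[keep]; ys <- ys[keep]; radii <- radii[keep]
    eccs <- eccs[keep]; c_h_vals <- c_h_vals[keep]
    n <- length(keep)
  }

  # concentration maps: nucleus hematoxylin + smooth eosin background
  c_h <- matrix(0, H, W)
  if (n) c_h[labels > 0L] <- c_h_vals[labels[labels > 0L]]
  coarse_h <- max(2L, ceiling(H / spec$eosin_texture_scale))
  coarse_w <- max(2L, ceiling(W / spec$eosin_texture_scale))
  tex <- matrix(stats::runif(coarse_h * coarse_w), coarse_h, coarse_w)
  tex <- tex[rep(seq_len(coarse_h), each = ceiling(H / coarse_h))[seq_len(H)],
             rep(seq_len(coarse_w), each = ceiling(W / coarse_w))[seq_len(W)]]
  tex <- gaussian_denoise(tex, sigma = spec$eosin_texture_scale / 3)
  tr <- range(tex)
  tex <- if (diff(tr) > 0) (tex - tr[1]) / diff(tr) else tex * 0
  c_e <- spec$c_e_range[1] + tex * diff(spec$c_e_range)

  conc <- array(0, c(H, W, 3))
  conc[, , 1] <- c_h; conc[, , 2] <- c_e
  img <- stain_render(conc, stain_model)
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- pmax(pmin(img, 255), 0)

  areas <- if (n) tabulate(labels[labels > 0L], nbins = n) else integer()
  structure(list(image = img, labels = labels, n_nuclei = n,
                 nuclei = data.frame(x = xs, y = ys, radius = radii,
                                     ecc = eccs, area = areas,
                                     c_h = c_h_vals),
                 conc = conc, class_label = spec$class_label,
                 intended_bin = intended_bin, spec = spec),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %dx%d %s, %d nuclei, intended bin %s\n",
              ncol(x$labels), nrow(x$labels), x$class_label, x$n_nuclei,
              x$intended_bin))
  invisible(x)
}

#' Generate a BreakHis-style synthetic corpus on disk
#'
#' Writes `output_root/{class}/{mag}X/{stem}.png` images (700x460 by
#' default, 8-bit PNG), a parallel `masks/` tree of 16-bit instance label
#' PNGs, and a `truth_manifest.csv` recording class, magnification,
#' realised nuclei count and intended density bin. Per-image seeds are
#' derived from `seed` so the corpus is reproducible as a whole.
#'
#' @param benign_spec,malignant_spec [scene_spec()]s used per class (their
#'   `seed` fields are overridden per image).
#' @param counts named vector, images per class per magnification
#'   (e.g. `c(benign = 5, malignant = 5)`).
#' @param magnifications magnification folder labels (default `c(40, 400)`).
#' @param output_root destination; must be empty or absent unless `force`.
#' @param seed base seed.
#' @param force overwrite a non-empty `output_root`?
#' @return The truth manifest data frame, invisibly; columns `path`,
#'   `mask_path`, `class`, `magnification`, `n_nuclei`, `intended_bin`,
#'   `seed`.
#' @export
generate_corpus <- function(benign_spec, malignant_spec,
                            counts = c(benign = 5, malignant = 5),
                            magnifications = c(40, 400),
                            output_root, seed = 1, force = FALSE) {
  if (dir.exists(output_root) &&
      length(list.files(output_root, recursive = TRUE)) && !force)
    stop("output_root is not empty (use force = TRUE to overwrite)",
         call. = FALSE)
  specs <- list(benign = benign_spec, malignant = malignant_spec)
  rows <- list(); img_i <- 0L
  for (cl in names(counts)) for (mag in magnifications) {
    dir_img <- file.path(output_root, cl, paste0(mag, "X"))
    dir_msk <- file.path(output_root, "masks", cl, paste0(mag, "X"))
    dir.create(dir_img, recursive = TRUE, showWarnings = FALSE)
    dir.create(dir_msk, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(counts[[cl]])) {
      img_i <- img_i + 1L
      sp <- specs[[cl]]
      sp$seed <- seed * 100000L + img_i
      scene <- generate_scene(sp)
      stem <- sprintf("%s_%dX_%03d", cl, mag, j)
      ip <- file.path(dir_img, paste0(stem, ".png"))
      mp <- file.path(dir_msk, paste0(stem, "_mask.png"))
      write_image(scene$image, ip)
      write_mask(scene$labels, mp)
      rows[[img_i]] <- data.frame(path = ip, mask_path = mp, class = cl,
                                  magnification = mag,
                                  n_nuclei = scene$n_nuclei,
                                  intended_bin = scene$intended_bin,
                                  seed = sp$seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(output_root, "truth_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Desk-scale reference datasets
#'
#' Small, seeded reference datasets used throughout the package's examples
#' and tests. `segmentation_demo_set()` produces "easy" nuclei patches
#' (sparse, well-separated, strongly stained round nuclei on a clean eosin
#' background) with paired ground-truth masks — the conditions under which
#' the width-scaled segmenter is expected to converge on a single CPU.
#' `classification_demo_corpus()` produces a separable benign-like versus
#' malignant-like scene corpus: benign-like scenes hold 1-3 large round
#' nuclei, malignant-like scenes 12-20 small, crowded, pleomorphic nuclei.
#' `stratification_demo_corpus()` produces malignant scenes whose nuclei
#' counts are drawn from three well-separated tiers (LD 4-7, MD 18-24,
#' HD 40-48 per scene) so the intended density bin is recoverable.
#'
#' @param n_patches,n_per_class,n_scenes dataset sizes.
#' @param size scene side in pixels.
#' @param seed base seed; scene `i` uses `seed * 1000 + i`.
#' @return `segmentation_demo_set`: list with `x` (list of `H x W x 3`
#'   images), `masks` (list of 0/1 matrices). `classification_demo_corpus`:
#'   list with `x` (`(H, W, 3, N)` array) and `labels`
#'   (benign/malignant). `stratification_demo_corpus`: list with `masks`
#'   (list of instance label matrices), `intended_bin`, `n_nuclei`.
#' @export
segmentation_demo_set <- function(n_patches = 64, size = 48, seed = 1) {
  xs <- vector("list", n_patches); ms <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    sp <- scene_spec(width = size, height = size,
                     class_label = "benign_like", n_nuclei = c(2, 5),
                     radius_range = c(3, 5), ecc_range = c(1, 1.3),
                     irregularity = 0.03, c_h_range = c(0.9, 1.2),
                     noise_sd = 1, seed = seed * 1000 + i)
    sc <- generate_scene(sp)
    xs[[i]] <- sc$image
    ms[[i]] <- (sc$labels > 0) + 0
  }
  list(x = xs, masks = ms)
}

#' @rdname segmentation_demo_set
#' @export
classification_demo_corpus <- function(n_per_class = 100, size = 48,
                                       seed = 1) {
  n <- 2L * n_per_class
  xs <- vector("list", n); y <- character(n)
  for (i in seq_len(n)) {
    cl <- if (i <= n_per_class) "benign" else "malignant"
    sp <- if (cl == "benign")
      scene_spec(width = size, height = size, class_label = "benign_like",
                 n_nuclei = c(1, 3), radius_range = c(4.5, 6),
                 seed = seed * 1000 + i)
    else
      scene_spec(width = size, height = size,
                 class_label = "malignant_like", n_nuclei = c(12, 20),
                 radius_range = c(2.2, 3.2), overlap_allowance = 0.5,
                 seed = seed * 1000 + i)
    xs[[i]] <- generate_scene(sp)$image
    y[i] <- cl
  }
  list(x = .stack_batch(xs), labels = y)
}

#' @rdname segmentation_demo_set
#' @export
stratification_demo_corpus <- function(n_scenes = 60, size = 160, seed = 1) {
  tiers <- list(LD = c(4, 7), MD = c(18, 24), HD = c(40, 48))
  ms <- vector("list", n_scenes)
  bin <- character(n_scenes); nn <- integer(n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- scene_spec(width = size, height = size,
                     class_label = "malignant_like",
                     radius_range = c(2.5, 3.5), ecc_range = c(1.1, 1.6),
                     irregularity = 0.08, overlap_allowance = 0,
                     count_tiers = tiers, seed = seed * 1000 + i)
    sc <- generate_scene(sp)
    ms[[i]] <- sc$labels
    bin[i] <- sc$intended_bin
    nn[i] <- sc$n_nuclei
  }
  list(masks = ms, intended_bin = bin, n_nuclei = nn)
}
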