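#' Gaussian denoising with reflective borders
#'
#' Channel-wise separable Gaussian convolution. The kernel is the discrete
#' Gaussian truncated at `4*sigma` and normalised to sum 1; borders are
#' handled by reflection (edge pixel not repeated), so constant images pass
#' through unchanged and the mean intensity is preserved up to border
#' effects. `sigma = 0` is the identity.
#'
#' @param image numeric `H x W x C` array (or `H x W` matrix).
#' @param sigma Gaussian standard deviation in pixels (>= 0; default 1).
#' @return Array of the same shape.
#' @export
gaussian_denoise <- function(image, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(image)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(image)
  two_d <- is.null(d) || length(d) == 2L
  if (two_d) { image <- array(image, c(dim(image), 1L)); d <- dim(image) }
  reflect_idx <- function(n) {
    # index vector of length n + 2r implementing mirror padding
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    pmin(pmax(idx, 1L), n)
  }
  ri <- reflect_idx(d[1]); ci <- reflect_idx(d[2])
  out <- image
  for (ch in seq_len(d[3])) {
    m <- image[, , ch]
    pad <- m[ri, ]                                  # rows
    m1 <- apply(pad, 2, function(v) as.vector(stats::filter(v, k, sides = 2)))[r + seq_len(d[1]), , drop = FALSE]
    pad <- m1[, ci, drop = FALSE]                   # columns
    m2 <- t(apply(pad, 1, function(v) as.vector(stats::filter(v, k, sides = 2))))[, r + seq_len(d[2]), drop = FALSE]
    out[, , ch] <- m2
  }
  if (two_d) dim(out) <- d[1:2]
  out
}

#' H&E stain model for optical-density colour deconvolution
#'
#' Stain mixing in brightfield microscopy is approximately linear in optical
#' density (Beer-Lambert): `OD_c = -log(I_c / I0_c)` for channel `c`. A stain
#' model holds unit-norm OD absorption vectors for hematoxylin and eosin plus
#' a residual vector orthogonal to both, forming an invertible 3x3 system.
#' Defaults are the canonical published H&E vectors.
#'
#' @param hematoxylin,eosin length-3 OD absorption vectors (RGB order); they
#'   are unit-normalised.
#' @param background_intensity per-channel white reference (default 255,
#'   recycled to length 3).
#' @return An object of class `stain_model` with fields `vectors` (3x3
#'   matrix, columns H, E, residual), `inverse`, `background`.
#' @examples
#' he_stain_model()
#' @export
he_stain_model <- function(hematoxylin = c(0.65, 0.70, 0.29),
                           eosin = c(0.07, 0.99, 0.11),
                           background_intensity = 255) {
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(hematoxylin); e <- unit(eosin)
  res <- c(h[2] * e[3] - h[3] * e[2],
           h[3] * e[1] - h[1] * e[3],
           h[1] * e[2] - h[2] * e[1])
  if (sqrt(sum(res^2)) < 1e-8)
    stop("hematoxylin and eosin vectors are collinear; stain matrix is singular",
         call. = FALSE)
  res <- unit(res)
  V <- cbind(hematoxylin = h, eosin = e, residual = res)
  if (abs(det(V)) < 1e-8)
    stop("stain matrix is singular", call. = FALSE)
  structure(list(vectors = V, inverse = solve(V),
                 background = rep_len(background_intensity, 3L)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model> OD vectors (columns H, E, residual):\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Separate an RGB image into stain concentration maps
#'
#' Converts each pixel to optical density `OD_c = -log((I_c + eps) / I0_c)`
#' and solves the 3x3 linear system of the stain model, giving per-pixel
#' hematoxylin, eosin and residual concentrations (clipped at 0). A pure
#' white pixel has zero OD and hence zero concentrations.
#'
#' @param image numeric `H x W x 3` array on the 0..background scale.
#' @param model a [he_stain_model()].
#' @param eps intensity offset guarding `log(0)` (default 1).
#' @return `H x W x 3` array; slices are the hematoxylin, eosin and residual
#'   concentration maps (OD units).
#' @export
stain_separate <- function(image, model = he_stain_model(), eps = 1) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("`image` must be H x W x 3", call. = FALSE)
  I <- matrix(image, ncol = 3L)
  od <- -log(sweep(I + eps, 2, model$background + eps, "/"))
  conc <- od %*% t(model$inverse)
  conc[conc < 0] <- 0
  array(conc, d, dimnames = list(NULL, NULL,
                                 c("hematoxylin", "eosin", "residual")))
}

#' Stain-removed structure image
#'
#' Reconstructs a grayscale image from the hematoxylin concentration alone:
#' `I = background * exp(-c_H)` broadcast to all channels. Nuclear structure
#' is retained; eosin-stained stroma renders as uniform background, white
#' stays white.
#'
#' @inheritParams stain_separate
#' @return `H x W x 3` grayscale array on the 0..background scale.
#' @export
remove_stain <- function(image, model = he_stain_model(), eps = 1) {
  conc <- stain_separate(image, model, eps)
  g <- mean(model$background) * exp(-conc[, , 1])
  array(rep(pmax(pmin(g, mean(model$background)), 0), 3L),
        c(dim(g), 3L))
}

#' Reconstruct an RGB image from stain concentrations (Beer-Lambert forward)
#'
#' Inverse of [stain_separate()] (up to clipping): per channel,
#' `I_c = I0_c * exp(-(c_H V_Hc + c_E V_Ec + c_R V_Rc))`.
#'
#' @param conc `H x W x 3` concentration array (H, E, residual).
#' @param model a [he_stain_model()].
#' @return `H x W x 3` intensity array on the 0..background scale.
#' @export
stain_render <- function(conc, model = he_stain_model()) {
  d <- dim(conc)
  od <- matrix(conc, ncol = 3L) %*% t(model$vectors)
  I <- sweep(exp(-od), 2, model$background, "*")
  array(I, d)
}

#' Deterministic patch augmentation
#'
#' Applies, in order: intensity rescale, horizontal/vertical flip, rotation,
#' zoom and shear. Flips and rotations that are exact multiples of 90 degrees
#' are index operations (lossless); any other rotation, and zoom/shear, use
#' bilinear resampling about the patch centre, keeping the output shape. When
#' `ranges` is supplied the concrete parameters are drawn uniformly from the
#' ranges using `seed`, so the same seed reproduces the same augmentation.
#'
#' @param patch numeric `H x W x C` array.
#' @param params list with any of `rescale` (intensity multiplier), `hflip`,
#'   `vflip` (logical), `rotation` (degrees, counter-clockwise), `zoom`
#'   (scale factor, 1 = none), `shear` (x-shear factor).
#' @param ranges optional list with `rotation` (max |degrees|), `zoom`
#'   (max fractional deviation), `shear` (max factor), `hflip`, `vflip`
#'   (logical: allowed), `rescale`; concrete params are sampled from these.
#' @param seed integer seed used when sampling from `ranges`.
#' @return Augmented patch, same shape as input.
#' @export
augment <- function(patch, params = list(), ranges = NULL, seed = NULL) {
  if (!is.null(ranges)) {
    if (!is.null(seed)) set.seed(seed)
    params <- list(
      rescale = if (is.null(ranges$rescale)) 1 else ranges$rescale,
      rotation = stats::runif(1, -1, 1) * (ranges$rotation %||% 0),
      zoom = 1 + stats::runif(1, -1, 1) * (ranges$zoom %||% 0),
      shear = stats::runif(1, -1, 1) * (ranges$shear %||% 0),
      hflip = isTRUE(ranges$hflip) && stats::runif(1) < 0.5,
      vflip = isTRUE(ranges$vflip) && stats::runif(1) < 0.5)
  }
  p <- patch
  d <- dim(p); if (length(d) == 2L) { dim(p) <- c(d, 1L); d <- dim(p) }
  if (!is.null(params$rescale) && params$rescale != 1) p <- p * params$rescale
  if (isTRUE(params$hflip)) p <- p[, d[2]:1, , drop = FALSE]
  if (isTRUE(params$vflip)) p <- p[d[1]:1, , , drop = FALSE]
  rot <- params$rotation %||% 0
  zoom <- params$zoom %||% 1
  shear <- params$shear %||% 0
  if (rot %% 360 != 0 && rot %% 90 == 0 && zoom == 1 && shear == 0 &&
      d[1] == d[2]) {
    for (i in seq_len((rot / 90) %% 4))   # 90 deg ccw: (h,w) <- (w, H+1-h)
      p <- aperm(p, c(2, 1, 3))[d[1]:1, , , drop = FALSE]
  } else if (rot != 0 || zoom != 1 || shear != 0) {
    p <- .warp_affine(p, rot, zoom, shear)
  }
  if (length(dim(patch)) == 2L) dim(p) <- d[1:2]
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bilinear affine warp about the centre (rotation ccw degrees, zoom, x-shear)
.warp_affine <- function(p, rot, zoom, shear) {
  d <- dim(p)
  th <- rot * pi / 180
  # inverse map: output (r, c) -> input coordinates
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2) %*%
       matrix(c(1, 0, shear, 1), 2) * zoom
  Ai <- solve(A)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  rc <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  u <- Ai %*% rbind(rc$c - cx, rc$r - cy)
  sc <- u[1, ] + cx; sr <- u[2, ] + cy
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  out <- p
  for (ch in seq_len(d[3])) {
    m <- p[, , ch]
    g <- function(rr, cc) m[cbind(cl(rr, d[1]), cl(cc, d[2]))]
    v <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
         fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
    inside <- sr >= 1 & sr <= d[1] & sc >= 1 & sc <= d[2]
    v[!inside] <- 0
    out[, , ch] <- matrix(v, d[1], d[2])
  }
  out
}
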