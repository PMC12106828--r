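#' Configuration for the attention-gated U-Net segmenter
#'
#' A five-stage encoder (two 3x3 stride-1 convolutions + ReLU per stage,
#' filter widths `encoder_filters`), four 3x3 stride-2 max-pools between
#' stages, and a mirrored decoder whose skip connections are gated by a
#' spatial attention mechanism; a 1x1 convolution with sigmoid head yields
#' the per-pixel nucleus probability. Training uses binary cross-entropy.
#' `width_scale` multiplies every filter width (rounded, minimum 1) so the
#' same architecture runs at desk scale on a single CPU.
#'
#' @param encoder_filters increasing integer vector of stage widths.
#' @param conv_kernel convolution kernel size (square).
#' @param conv_stride stride of the stage convolutions.
#' @param pool_size,pool_stride max-pool geometry ('same' padding).
#' @param decoder_attention gate skip connections with spatial attention?
#' @param learning_rate,epochs,batch_size,optimizer,loss training settings.
#' @param width_scale filter-width multiplier for reduced-scale runs.
#' @param in_channels input channels (3 for RGB, 1 for a stain channel).
#' @param input_size spatial input side used for the model description.
#' @param seed RNG seed governing weight init, shuffling and augmentation.
#' @return A list of class `unet_sam_config`.
#' @export
unet_sam_config <- function(encoder_filters = c(16, 32, 64, 128, 256),
                            conv_kernel = 3, conv_stride = 1,
                            pool_size = 3, pool_stride = 2,
                            decoder_attention = TRUE,
                            learning_rate = 1e-4, epochs = 50,
                            batch_size = 16,
                            optimizer = c("adam", "sgd", "rmsprop"),
                            loss = "binary_crossentropy",
                            width_scale = 1, in_channels = 3,
                            input_size = 224, seed = 42) {
  optimizer <- match.arg(optimizer)
  if (any(diff(encoder_filters) <= 0))
    stop("`encoder_filters` must be strictly increasing", call. = FALSE)
  if (width_scale <= 0) stop("`width_scale` must be positive", call. = FALSE)
  if (epochs < 0 || batch_size <= 0)
    stop("`epochs` must be >= 0 and `batch_size` positive", call. = FALSE)
  structure(list(encoder_filters = encoder_filters, conv_kernel = conv_kernel,
                 conv_stride = conv_stride, pool_size = pool_size,
                 pool_stride = pool_stride,
                 num_pool_layers = length(encoder_filters) - 1L,
                 decoder_attention = isTRUE(decoder_attention),
                 hidden_activation = "relu", head_activation = "sigmoid",
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, optimizer = optimizer, loss = loss,
                 width_scale = width_scale, in_channels = in_channels,
                 input_size = input_size, seed = seed),
            class = "unet_sam_config")
}

.scaled_filters <- function(filters, width_scale) {
  f <- pmax(1L, as.integer(round(filters * width_scale)))
  cummax(f)  # keep monotone after rounding at tiny scales
}

#' Build the attention-gated U-Net
#'
#' Weight initialisation is He-normal driven by `config$seed`, so two builds
#' from the same config are bit-identical. The returned model carries a
#' layer-by-layer description with tensor shapes (at `config$input_size`)
#' and the total parameter count.
#'
#' @param config a [unet_sam_config()].
#' @return An object of class `unet_sam`: list with `config`, `params`
#'   (named weight arrays), `filters` (scaled widths), `layers` (description
#'   data frame) and `n_params`.
#' @export
build_unet_sam <- function(config = unet_sam_config()) {
  stopifnot(inherits(config, "unet_sam_config"))
  fil <- .scaled_filters(config$encoder_filters, config$width_scale)
  L <- length(fil)
  k <- config$conv_kernel
  down <- config$pool_stride^(L - 1L)
  if (config$input_size %% down != 0)
    stop(sprintf("input size %d is not divisible by the total downsampling factor %d; pad the input",
                 config$input_size, down), call. = FALSE)
  set.seed(config$seed)
  params <- list()
  add_conv <- function(nm, kk, cin, cout) {
    p <- .conv_init(kk, cin, cout)
    params[[paste0(nm, "_w")]] <<- p$w
    params[[paste0(nm, "_b")]] <<- p$b
  }
  cin <- config$in_channels
  for (i in seq_len(L)) {
    add_conv(sprintf("enc%d_a", i), k, cin, fil[i])
    add_conv(sprintf("enc%d_b", i), k, fil[i], fil[i])
    cin <- fil[i]
  }
  for (i in rev(seq_len(L - 1L))) {
    if (config$decoder_attention) {
      fint <- max(1L, fil[i] %/% 2L)
      add_conv(sprintf("att%d_theta", i), 1L, fil[i], fint)
      add_conv(sprintf("att%d_phi", i), 1L, fil[i + 1L], fint)
      add_conv(sprintf("att%d_psi", i), 1L, fint, 1L)
    }
    add_conv(sprintf("dec%d_a", i), k, fil[i] + fil[i + 1L], fil[i])
    add_conv(sprintf("dec%d_b", i), k, fil[i], fil[i])
  }
  add_conv("head", 1L, fil[1L], 1L)

  # description at the nominal input size
  sz <- config$input_size
  rows <- list()
  desc <- function(name, type, size, ch, np)
    rows[[length(rows) + 1L]] <<- data.frame(layer = name, type = type,
      out_h = size, out_w = size, out_ch = ch, n_params = np)
  cin <- config$in_channels; s <- sz
  for (i in seq_len(L)) {
    desc(sprintf("enc%d_a", i), "conv3x3+relu", s, fil[i], k * k * cin * fil[i] + fil[i])
    desc(sprintf("enc%d_b", i), "conv3x3+relu", s, fil[i], k * k * fil[i] * fil[i] + fil[i])
    if (i < L) { s <- .same_out(s, config$pool_stride)
                 desc(sprintf("pool%d", i), "maxpool3x3/2", s, fil[i], 0L) }
    cin <- fil[i]
  }
  for (i in rev(seq_len(L - 1L))) {
    s <- s * 2L
    desc(sprintf("up%d", i), "upsample2x", s, fil[i + 1L], 0L)
    if (config$decoder_attention) {
      fint <- max(1L, fil[i] %/% 2L)
      desc(sprintf("att%d", i), "attention-gate", s, fil[i],
           fil[i] * fint + fint + fil[i + 1L] * fint + fint + fint + 1L)
    }
    desc(sprintf("dec%d_a", i), "conv3x3+relu", s, fil[i],
         k * k * (fil[i] + fil[i + 1L]) * fil[i] + fil[i])
    desc(sprintf("dec%d_b", i), "conv3x3+relu", s, fil[i],
         k * k * fil[i] * fil[i] + fil[i])
  }
  desc("head", "conv1x1+sigmoid", s, 1L, fil[1L] + 1L)
  layers <- do.call(rbind, rows)

  structure(list(config = config, params = params, filters = fil,
                 layers = layers, n_params = .count_params(params),
                 state = new.env(parent = emptyenv())),
            class = "unet_sam")
}

#' @export
print.unet_sam <- function(x, ...) {
  cat(sprintf("<unet_sam> %d stages (%s), attention %s, %d parameters\n",
              length(x$filters), paste(x$filters, collapse = "-"),
              if (x$config$decoder_attention) "on" else "off", x$n_params))
  invisible(x)
}

#' Spatial attention gate
#'
#' The standard additive attention gate: 1x1 projections of the encoder skip
#' features and the (upsampled) decoder gating signal are summed, rectified,
#' projected to one channel and squashed with a sigmoid; the resulting
#' attention map in \[0, 1\] multiplies the encoder features, broadcast over
#' channels.
#'
#' @param encoder_features,decoder_features `(H, W, C, N)` arrays (an
#'   `(H, W, C)` array is treated as batch size 1) with matching spatial
#'   size and batch.
#' @param weights list with `theta_w`, `theta_b`, `phi_w`, `phi_b`, `psi_w`,
#'   `psi_b` (1x1 convolution weights); freshly He-initialised from the
#'   current RNG state if `NULL`.
#' @param attention optional `(H, W, 1, N)` map overriding the computed
#'   attention (used to probe the gating identity).
#' @return List with `gated` (encoder features x attention) and `attention`.
#' @export
spatial_attention_gate <- function(encoder_features, decoder_features,
                                   weights = NULL, attention = NULL) {
  as4 <- function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x }
  e <- as4(encoder_features); g <- as4(decoder_features)
  de <- dim(e); dg <- dim(g)
  if (any(de[c(1, 2, 4)] != dg[c(1, 2, 4)]))
    stop("encoder and decoder features are not spatially aligned", call. = FALSE)
  if (is.null(attention)) {
    if (is.null(weights)) {
      fint <- max(1L, de[3] %/% 2L)
      weights <- list(theta = .conv_init(1L, de[3], fint),
                      phi = .conv_init(1L, dg[3], fint),
                      psi = .conv_init(1L, fint, 1L))
      weights <- list(theta_w = weights$theta$w, theta_b = weights$theta$b,
                      phi_w = weights$phi$w, phi_b = weights$phi$b,
                      psi_w = weights$psi$w, psi_b = weights$psi$b)
    }
    t_ <- .nn_conv2d_fwd(e, weights$theta_w, weights$theta_b, 1L)
    p_ <- .nn_conv2d_fwd(g, weights$phi_w, weights$phi_b, 1L)
    q <- .relu_fwd(t_ + p_)
    attention <- .sigmoid(.nn_conv2d_fwd(q, weights$psi_w, weights$psi_b, 1L))
  } else attention <- as4(attention)
  # broadcast H,W,1,N over channels: replicate attention across dim 3
  att_b <- array(0, de)
  for (ch in seq_len(de[3])) att_b[, , ch, ] <- attention[, , 1, ]
  gated <- e * att_b
  list(gated = gated, attention = attention)
}

# --- forward / backward ----------------------------------------------------

.unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; P <- model$params; fil <- model$filters
  L <- length(fil); ps <- cfg$pool_size; pstr <- cfg$pool_stride
  cstr <- cfg$conv_stride
  cache <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  h <- x
  for (i in seq_len(L)) {
    ei <- list(x_in = h)
    pa <- .nn_conv2d_fwd(h, P[[sprintf("enc%d_a_w", i)]],
                         P[[sprintf("enc%d_a_b", i)]], cstr)
    ei$pre_a <- pa; a <- .relu_fwd(pa)
    ei$a <- a
    pb <- .nn_conv2d_fwd(a, P[[sprintf("enc%d_b_w", i)]],
                         P[[sprintf("enc%d_b_b", i)]], cstr)
    ei$pre_b <- pb; s <- .relu_fwd(pb)
    ei$s <- s
    if (i < L) {
      mp <- .nn_maxpool_fwd(s, ps, pstr)
      ei$pool_idx <- mp$idx; ei$sdim <- dim(s)
      h <- mp$y
    }
    cache$enc[[i]] <- ei
  }
  d <- cache$enc[[L]]$s
  for (i in rev(seq_len(L - 1L))) {
    di <- list(d_in = d)
    u <- .nn_upsample2_fwd(d)
    di$u <- u
    s <- cache$enc[[i]]$s
    if (cfg$decoder_attention) {
      t_ <- .nn_conv2d_fwd(s, P[[sprintf("att%d_theta_w", i)]],
                           P[[sprintf("att%d_theta_b", i)]], 1L)
      p_ <- .nn_conv2d_fwd(u, P[[sprintf("att%d_phi_w", i)]],
                           P[[sprintf("att%d_phi_b", i)]], 1L)
      pre_q <- t_ + p_
      q <- .relu_fwd(pre_q)
      psi <- .nn_conv2d_fwd(q, P[[sprintf("att%d_psi_w", i)]],
                            P[[sprintf("att%d_psi_b", i)]], 1L)
      alpha <- .sigmoid(psi)
      di$pre_q <- pre_q; di$q <- q; di$alpha <- alpha
      de <- dim(s)
      att_b <- array(0, de)
      for (ch in seq_len(de[3])) att_b[, , ch, ] <- alpha[, , 1, ]
      di$att_b <- att_b
      gs <- s * att_b
    } else gs <- s
    cc <- .cat_ch(gs, u)
    di$cc <- cc
    pa <- .nn_conv2d_fwd(cc, P[[sprintf("dec%d_a_w", i)]],
                         P[[sprintf("dec%d_a_b", i)]], 1L)
    di$pre_a <- pa; da <- .relu_fwd(pa)
    di$da <- da
    pb <- .nn_conv2d_fwd(da, P[[sprintf("dec%d_b_w", i)]],
                         P[[sprintf("dec%d_b_b", i)]], 1L)
    di$pre_b <- pb; d <- .relu_fwd(pb)
    di$d <- d
    cache$dec[[i]] <- di
  }
  logits <- .nn_conv2d_fwd(d, P[["head_w"]], P[["head_b"]], 1L)
  list(logits = logits, cache = cache, d1 = d)
}

.unet_backward <- function(model, fwd, dlogits) {
  cfg <- model$config; P <- model$params; fil <- model$filters
  L <- length(fil); grads <- list()
  acc <- function(nm, g) grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g

  r <- .nn_conv2d_bwd(fwd$d1, P[["head_w"]], dlogits, 1L)
  acc("head_w", r$dw); acc("head_b", r$db)
  dd <- r$dx
  ds_dec <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    di <- fwd$cache$dec[[i]]
    dx <- .relu_bwd(di$pre_b, dd)
    r <- .nn_conv2d_bwd(di$da, P[[sprintf("dec%d_b_w", i)]], dx, 1L)
    acc(sprintf("dec%d_b_w", i), r$dw); acc(sprintf("dec%d_b_b", i), r$db)
    dx <- .relu_bwd(di$pre_a, r$dx)
    r <- .nn_conv2d_bwd(di$cc, P[[sprintf("dec%d_a_w", i)]], dx, 1L)
    acc(sprintf("dec%d_a_w", i), r$dw); acc(sprintf("dec%d_a_b", i), r$db)
    dcc <- r$dx
    ci <- fil[i]
    dgs <- dcc[, , seq_len(ci), , drop = FALSE]
    du <- dcc[, , ci + seq_len(dim(dcc)[3] - ci), , drop = FALSE]
    s <- fwd$cache$enc[[i]]$s
    if (cfg$decoder_attention) {
      ds <- dgs * di$att_b
      dalpha <- array(0, c(dim(s)[1], dim(s)[2], 1L, dim(s)[4]))
      dalpha[, , 1, ] <- apply(dgs * s, c(1, 2, 4), sum)
      dpsi <- dalpha * di$alpha * (1 - di$alpha)
      r <- .nn_conv2d_bwd(di$q, P[[sprintf("att%d_psi_w", i)]], dpsi, 1L)
      acc(sprintf("att%d_psi_w", i), r$dw); acc(sprintf("att%d_psi_b", i), r$db)
      dq <- .relu_bwd(di$pre_q, r$dx)
      r <- .nn_conv2d_bwd(s, P[[sprintf("att%d_theta_w", i)]], dq, 1L)
      acc(sprintf("att%d_theta_w", i), r$dw); acc(sprintf("att%d_theta_b", i), r$db)
      ds <- ds + r$dx
      r <- .nn_conv2d_bwd(di$u, P[[sprintf("att%d_phi_w", i)]], dq, 1L)
      acc(sprintf("att%d_phi_w", i), r$dw); acc(sprintf("att%d_phi_b", i), r$db)
      du <- du + r$dx
    } else ds <- dgs
    ds_dec[[i]] <- ds
    dd <- .nn_upsample2_bwd(du, dim(fwd$cache$dec[[i]]$d_in))
  }
  ds_dec[[L]] <- dd

  din_next <- NULL
  for (i in rev(seq_len(L))) {
    ei <- fwd$cache$enc[[i]]
    ds <- ds_dec[[i]]
    if (is.null(ds)) ds <- array(0, dim(ei$s))
    if (!is.null(din_next))   # din_next is the gradient w.r.t. pool(s_i)
      ds <- ds + .nn_maxpool_bwd(ei$pool_idx, din_next, dim(ei$s))
    dx <- .relu_bwd(ei$pre_b, ds)
    r <- .nn_conv2d_bwd(ei$a, P[[sprintf("enc%d_b_w", i)]], dx, model$config$conv_stride)
    acc(sprintf("enc%d_b_w", i), r$dw); acc(sprintf("enc%d_b_b", i), r$db)
    dx <- .relu_bwd(ei$pre_a, r$dx)
    r <- .nn_conv2d_bwd(ei$x_in, P[[sprintf("enc%d_a_w", i)]], dx, model$config$conv_stride)
    acc(sprintf("enc%d_a_w", i), r$dw); acc(sprintf("enc%d_a_b", i), r$db)
    din_next <- r$dx
  }
  grads
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are in perfect agreement and
#' score 1 (the 0/0 case is defined as 1 by convention).
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @examples
#' dice(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 0.5
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop("masks must have identical shape", call. = FALSE)
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1.0)
  2 * sum(a & b) / s
}

#' Train the U-Net segmenter
#'
#' Minimises pixel-wise binary cross-entropy with the configured optimiser.
#' One seed (`config$seed`) governs weight initialisation, shuffling and the
#' train/validation split. With `k_folds` set, performs k-fold
#' cross-validation instead, returning per-fold metrics.
#'
#' @param config a [unet_sam_config()].
#' @param patches `(H, W, C, N)` array (0..255 scale; internally divided by
#'   255) or list of `H x W x C` arrays.
#' @param masks `(H, W, N)` array or list of binary `H x W` matrices.
#' @param val_frac held-out fraction for validation (default 0.25).
#' @param k_folds if non-`NULL`, number of cross-validation folds.
#' @return For a plain run, a list of class `unet_fit` with `model` (trained
#'   [build_unet_sam()] object) and `history` (per-epoch data frame with
#'   `epoch`, `loss`, `val_loss`, `val_dice`, `val_accuracy`,
#'   `val_precision`, `val_recall`); for k-fold, a list with `folds`
#'   (per-fold metric rows) and `fold_models`.
#' @export
train_segmenter <- function(config, patches, masks, val_frac = 0.25,
                            k_folds = NULL) {
  if (is.list(patches)) patches <- .stack_batch(patches)
  if (is.list(masks)) {
    m <- array(0, c(dim(masks[[1]])[1:2], length(masks)))
    for (i in seq_along(masks)) m[, , i] <- (masks[[i]] > 0) + 0
    masks <- m
  }
  N <- dim(patches)[4]
  if (N == 0 || length(masks) == 0) stop("empty dataset", call. = FALSE)
  if (dim(masks)[3] != N) stop("patches and masks differ in count", call. = FALSE)
  x <- patches / 255
  y <- array((masks > 0) + 0, dim(masks))

  if (!is.null(k_folds)) {
    set.seed(config$seed)
    fold <- sample(rep(seq_len(k_folds), length.out = N))
    rows <- list(); models <- list()
    for (kf in seq_len(k_folds)) {
      te <- which(fold == kf); tr <- which(fold != kf)
      fit <- .train_unet(config, x[, , , tr, drop = FALSE], y[, , tr, drop = FALSE],
                         x[, , , te, drop = FALSE], y[, , te, drop = FALSE])
      h <- fit$history
      last <- if (nrow(h)) h[nrow(h), ] else
        data.frame(loss = NA, val_loss = NA, val_dice = NA,
                   val_accuracy = NA, val_precision = NA, val_recall = NA)
      rows[[kf]] <- data.frame(fold = kf, n_train = length(tr),
                               n_test = length(te),
                               dice = last$val_dice, loss = last$val_loss,
                               accuracy = last$val_accuracy,
                               precision = last$val_precision,
                               recall = last$val_recall)
      models[[kf]] <- fit$model
    }
    return(list(folds = do.call(rbind, rows), fold_models = models))
  }

  set.seed(config$seed)
  nval <- max(1L, round(val_frac * N))
  val_idx <- sample(N, nval)
  tr_idx <- setdiff(seq_len(N), val_idx)
  if (!length(tr_idx)) { tr_idx <- val_idx }  # degenerate tiny inputs
  .train_unet(config, x[, , , tr_idx, drop = FALSE], y[, , tr_idx, drop = FALSE],
              x[, , , val_idx, drop = FALSE], y[, , val_idx, drop = FALSE])
}

.seg_val_metrics <- function(model, xval, yval) {
  fwd <- .unet_forward(model, xval, training = FALSE)
  lr <- .bce_logits(fwd$logits, array(yval, dim(fwd$logits)))
  pred <- lr$p >= 0.5
  dim(pred) <- dim(yval)
  truth <- yval > 0
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  c(val_loss = lr$loss,
    val_dice = dice(array(pred, dim(yval)), truth),
    val_accuracy = (tp + tn) / length(truth),
    val_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    val_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

.train_unet <- function(config, xtr, ytr, xval, yval) {
  model <- build_unet_sam(config)   # seeds the RNG via config$seed
  step <- .opt_step(config$optimizer)
  opt <- .adam_new()
  ntr <- dim(xtr)[4]
  hist <- list()
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    ord <- sample(ntr)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, ntr, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, ntr)]
      xb <- xtr[, , , idx, drop = FALSE]
      yb <- ytr[, , idx, drop = FALSE]
      fwd <- .unet_forward(model, xb, training = TRUE)
      lr <- .bce_logits(fwd$logits, array(yb, dim(fwd$logits)))
      grads <- .unet_backward(model, fwd, lr$dlogits)
      model$params <- step(model$params, grads, opt, config$learning_rate)
      ep_loss <- ep_loss + lr$loss; nb <- nb + 1L
    }
    vm <- .seg_val_metrics(model, xval, yval)
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb, t(vm))
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), loss = numeric(), val_loss = numeric(),
               val_dice = numeric(), val_accuracy = numeric(),
               val_precision = numeric(), val_recall = numeric())
  structure(list(model = model, history = history, seed = config$seed),
            class = "unet_fit")
}

#' Segment a patch with a trained model
#'
#' Runs the forward pass, thresholds the probability map, and labels
#' instances by connected components.
#'
#' @param model a trained `unet_sam` (or the `model` element of a
#'   [train_segmenter()] fit).
#' @param patch `H x W x C` array on the 0..255 scale (as trained).
#' @param threshold probability cut (default 0.5); 0 selects everything,
#'   anything above 1 nothing.
#' @param min_area,connectivity instance filtering, see [count_nuclei()].
#' @return A `seg_mask`: list with `prob` (H x W probability map), `mask`
#'   (logical H x W), `labels` (integer instance labels) and `n_instances`.
#' @export
predict_mask <- function(model, patch, threshold = 0.5, min_area = 10,
                         connectivity = 8) {
  if (inherits(model, "unet_fit")) model <- model$model
  d <- dim(patch); if (length(d) == 2L) { dim(patch) <- c(d, 1L); d <- dim(patch) }
  x <- array(patch / 255, c(d, 1L))
  down <- model$config$pool_stride^(length(model$filters) - 1L)
  padh <- (down - d[1] %% down) %% down
  padw <- (down - d[2] %% down) %% down
  if (padh || padw) {   # replicate-pad to a valid size, crop after
    xp <- array(0, c(d[1] + padh, d[2] + padw, d[3], 1L))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
    if (padh) xp[d[1] + seq_len(padh), seq_len(d[2]), , ] <-
      x[rep(d[1], padh), , , , drop = FALSE]
    if (padw) xp[, d[2] + seq_len(padw), , ] <-
      xp[, rep(d[2], padw), , , drop = FALSE]
    x <- xp
  }
  prob <- .sigmoid(.unet_forward(model, x)$logits)[, , 1, 1]
  prob <- prob[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  seg_mask(prob >= threshold, prob, min_area = min_area,
           connectivity = connectivity)
}

#' Construct a segmentation mask object
#'
#' @param mask logical/0-1 `H x W` matrix.
#' @param prob optional probability map of the same shape.
#' @param min_area,connectivity instance filtering, see [count_nuclei()].
#' @return A `seg_mask` list: `mask`, `prob`, `labels`, `n_instances`.
#' @export
seg_mask <- function(mask, prob = NULL, min_area = 10, connectivity = 8) {
  mask <- mask > 0
  lab <- label_components(mask, connectivity = connectivity,
                          min_area = min_area)
  structure(list(mask = mask, prob = prob, labels = lab,
                 n_instances = max(lab)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %dx%d, %d foreground px, %d instances\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$n_instances))
  invisible(x)
}

#' Otsu baseline nuclei mask
#'
#' Global Otsu threshold on a hematoxylin concentration map (the ablation
#' baseline standing in for the learned segmenter). Nuclei carry high
#' hematoxylin concentration, so foreground is the above-threshold class;
#' pass `polarity = "dark"` for plain intensity images where nuclei are
#' dark.
#'
#' @param channel numeric `H x W` matrix (any scale; internally normalised).
#' @param min_area,connectivity instance filtering, see [count_nuclei()].
#' @param polarity `"bright"` (default; foreground above threshold) or
#'   `"dark"`.
#' @return A [seg_mask()] with attribute `"threshold"` on the input scale;
#'   a constant image yields an empty mask with a warning.
#' @export
otsu_nuclei_mask <- function(channel, min_area = 10, connectivity = 8,
                             polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  rng <- range(channel)
  if (diff(rng) == 0) {
    warning("constant image: no Otsu threshold exists; returning empty mask",
            call. = FALSE)
    out <- seg_mask(matrix(FALSE, nrow(channel), ncol(channel)))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  norm <- (channel - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1), levels = 256)
  mask <- if (polarity == "bright") norm > th else norm <= th
  out <- seg_mask(mask, min_area = min_area, connectivity = connectivity)
  attr(out, "threshold") <- th * diff(rng) + rng[1]
  out
}
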