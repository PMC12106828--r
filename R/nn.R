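# Training engine shared by the segmentation and classification networks.
# Tensors are (H, W, C, N) arrays; the compiled primitives live in src/.
# Weight layout: conv (k, k, Cin, Cout), depthwise conv (k, k, C),
# dense (out x in). Initialisation is He-normal, driven by R's RNG so a
# set.seed() call makes builds reproducible.

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

.conv_init <- function(k, cin, cout) {
  list(w = .he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

.relu_fwd <- function(x) { y <- x; y[y < 0] <- 0; y }
.relu_bwd <- function(x, dy) { dy[x <= 0] <- 0; dy }
.sigmoid <- function(x) 1 / (1 + exp(-x))

# channel concatenation along dim 3
.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# --- batch normalisation over (H, W, N) per channel ------------------------

.bn_fwd <- function(x, gamma, beta, state, name, training, momentum = 0.9,
                    eps = 1e-5) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(sweep(xp, 2, mu)^2)
    rk <- paste0(name, "_running")
    run <- state[[rk]] %||% list(mu = mu, v = v)
    state[[rk]] <- list(mu = momentum * run$mu + (1 - momentum) * mu,
                        v = momentum * run$v + (1 - momentum) * v)
  } else {
    run <- state[[paste0(name, "_running")]]
    if (is.null(run)) { mu <- colMeans(xp); v <- colMeans(sweep(xp, 2, mu)^2) }
    else { mu <- run$mu; v <- run$v }
  }
  xh <- sweep(sweep(xp, 2, mu), 2, sqrt(v + eps), "/")
  yp <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  dim(yp) <- c(d[1], d[2], d[4], d[3])
  list(y = aperm(yp, c(1, 2, 4, 3)), xh = xh, v = v, eps = eps)
}

.bn_bwd <- function(cache, gamma, dy) {
  d <- dim(dy)
  dyp <- aperm(dy, c(1, 2, 4, 3)); dim(dyp) <- c(d[1] * d[2] * d[4], d[3])
  m <- nrow(dyp)
  dgamma <- colSums(dyp * cache$xh)
  dbeta <- colSums(dyp)
  dxh <- sweep(dyp, 2, gamma, "*")
  # dx = (1/m) / sqrt(v+eps) * (m*dxh - sum(dxh) - xh * sum(dxh*xh))
  t1 <- m * dxh
  t2 <- matrix(colSums(dxh), m, ncol(dxh), byrow = TRUE)
  t3 <- cache$xh * matrix(colSums(dxh * cache$xh), m, ncol(dxh), byrow = TRUE)
  dxp <- sweep(t1 - t2 - t3, 2, m * sqrt(cache$v + cache$eps), "/")
  dim(dxp) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxp, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# --- Adam ------------------------------------------------------------------

.adam_new <- function() new.env(parent = emptyenv())

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.null(opt$t)) { opt$t <- 0L; opt$m <- list(); opt$v <- list() }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

# sgd / rmsprop alternatives (optimizer is configurable)
.sgd_step <- function(params, grads, opt, lr) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

.rmsprop_step <- function(params, grads, opt, lr, rho = 0.9, eps = 1e-8) {
  if (is.null(opt$v)) opt$v <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- opt$v[[nm]]; if (is.null(v)) v <- g * 0
    v <- rho * v + (1 - rho) * g^2
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  params
}

.opt_step <- function(optimizer) {
  switch(optimizer, adam = .adam_step, sgd = .sgd_step,
         rmsprop = .rmsprop_step,
         stop("unknown optimizer: ", optimizer, call. = FALSE))
}

# --- generic sequential network -------------------------------------------
# layers: list of descriptors (type + fields); params: flat named list.

.seq_init_params <- function(layers) {
  params <- list()
  for (L in layers) {
    nm <- L$name
    if (L$type == "conv") {
      p <- .conv_init(L$k, L$in_ch, L$out_ch)
      params[[paste0(nm, "_w")]] <- p$w; params[[paste0(nm, "_b")]] <- p$b
    } else if (L$type == "dwconv") {
      params[[paste0(nm, "_w")]] <- .he_init(c(L$k, L$k, L$ch), L$k * L$k)
      params[[paste0(nm, "_b")]] <- numeric(L$ch)
    } else if (L$type == "bn") {
      params[[paste0(nm, "_gamma")]] <- rep(1, L$ch)
      params[[paste0(nm, "_beta")]] <- rep(0, L$ch)
    } else if (L$type == "dense") {
      params[[paste0(nm, "_w")]] <-
        matrix(stats::rnorm(L$out * L$`in`, sd = sqrt(2 / L$`in`)), L$out, L$`in`)
      params[[paste0(nm, "_b")]] <- numeric(L$out)
    }
  }
  params
}

.seq_forward <- function(layers, params, state, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    L <- layers[[i]]; nm <- L$name
    cache <- list(type = L$type)
    if (L$type == "conv") {
      cache$x <- x
      x <- .nn_conv2d_fwd(x, params[[paste0(nm, "_w")]],
                          params[[paste0(nm, "_b")]], L$stride)
      if (identical(L$activation, "relu")) { cache$pre <- x; x <- .relu_fwd(x) }
    } else if (L$type == "dwconv") {
      cache$x <- x
      x <- .nn_dwconv2d_fwd(x, params[[paste0(nm, "_w")]],
                            params[[paste0(nm, "_b")]], L$stride)
      if (identical(L$activation, "relu")) { cache$pre <- x; x <- .relu_fwd(x) }
    } else if (L$type == "maxpool") {
      cache$xdim <- dim(x)
      r <- .nn_maxpool_fwd(x, L$k, L$stride)
      cache$idx <- r$idx; x <- r$y
    } else if (L$type == "bn") {
      r <- .bn_fwd(x, params[[paste0(nm, "_gamma")]],
                   params[[paste0(nm, "_beta")]], state, nm, training)
      cache$bn <- r[c("xh", "v", "eps")]
      x <- r$y
    } else if (L$type == "dropout") {
      if (training && L$rate > 0) {
        mask <- (stats::runif(length(x)) >= L$rate) / (1 - L$rate)
        cache$mask <- mask
        x <- x * mask
      }
    } else if (L$type == "relu") {
      cache$x <- x; x <- .relu_fwd(x)
    } else if (L$type == "flatten") {
      cache$xdim <- dim(x)
      x <- matrix(x, ncol = dim(x)[4])
    } else if (L$type == "dense") {
      cache$x <- x
      x <- params[[paste0(nm, "_w")]] %*% x + params[[paste0(nm, "_b")]]
      if (identical(L$activation, "relu")) { cache$pre <- x; x <- .relu_fwd(x) }
    } else if (L$type == "zeropad") {
      # spatial padding is folded into the following stride-2 convolution
    } else stop("unknown layer type: ", L$type, call. = FALSE)
    caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

.seq_backward <- function(layers, params, caches, dout) {
  grads <- list()
  dx <- dout
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]; nm <- L$name; cache <- caches[[i]]
    if (L$type == "conv") {
      if (identical(L$activation, "relu")) dx <- .relu_bwd(cache$pre, dx)
      r <- .nn_conv2d_bwd(cache$x, params[[paste0(nm, "_w")]], dx, L$stride)
      grads[[paste0(nm, "_w")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      dx <- r$dx
    } else if (L$type == "dwconv") {
      if (identical(L$activation, "relu")) dx <- .relu_bwd(cache$pre, dx)
      r <- .nn_dwconv2d_bwd(cache$x, params[[paste0(nm, "_w")]], dx, L$stride)
      grads[[paste0(nm, "_w")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      dx <- r$dx
    } else if (L$type == "maxpool") {
      dx <- .nn_maxpool_bwd(cache$idx, dx, cache$xdim)
    } else if (L$type == "bn") {
      r <- .bn_bwd(cache$bn, params[[paste0(nm, "_gamma")]], dx)
      grads[[paste0(nm, "_gamma")]] <- r$dgamma
      grads[[paste0(nm, "_beta")]] <- r$dbeta
      dx <- r$dx
    } else if (L$type == "dropout") {
      if (!is.null(cache$mask)) dx <- dx * cache$mask
    } else if (L$type == "relu") {
      dx <- .relu_bwd(cache$x, dx)
    } else if (L$type == "flatten") {
      dim(dx) <- cache$xdim
    } else if (L$type == "dense") {
      if (identical(L$activation, "relu")) dx <- .relu_bwd(cache$pre, dx)
      grads[[paste0(nm, "_w")]] <- dx %*% t(cache$x)
      grads[[paste0(nm, "_b")]] <- rowSums(dx)
      dx <- t(params[[paste0(nm, "_w")]]) %*% dx
    }
  }
  grads
}

# softmax cross-entropy; y one-hot (classes x N); returns loss and dlogits
.softmax_ce <- function(logits, y) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  p <- sweep(exp(z), 2, colSums(exp(z)), "/")
  n <- ncol(y)
  list(loss = -sum(y * log(p + 1e-12)) / n, p = p, dlogits = (p - y) / n)
}

# sigmoid binary cross-entropy on pixel logits; y in {0,1}, same shape
.bce_logits <- function(logits, y) {
  p <- .sigmoid(logits)
  n <- length(y)
  loss <- -sum(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)) / n
  list(loss = loss, p = p, dlogits = (p - y) / n)
}

# spatial output size bookkeeping for model descriptions ('same' padding)
.same_out <- function(n, stride) as.integer(ceiling(n / stride))

.count_params <- function(params) sum(vapply(params, length, 0L))
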