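#' Configuration for the compact convolutional classifier (SCNN)
#'
#' Six 3x3 convolutions (widths `conv_filters`, the sixth repeating 256 by
#' default), three 2x2 max-pools, two batch-normalisation layers, three
#' dropout layers at rate 0.30, then a flattened two-layer rectified dense
#' head and a 2-way softmax. Training uses Adam on categorical
#' cross-entropy with an exponentially decaying learning rate
#' (`initial_lr * decay^epoch`, floored at `lr_floor`) and early stopping
#' on validation loss.
#'
#' @param conv_filters six convolution widths.
#' @param dense_units widths of the two rectified dense layers.
#' @param dropout_rate dropout probability in (0, 1).
#' @param initial_lr,lr_floor,decay learning-rate schedule, see
#'   [lr_schedule()].
#' @param epochs,batch_size,optimizer training settings.
#' @param min_delta,patience early stopping: training stops once validation
#'   loss has failed to improve by more than `min_delta` for more than
#'   `patience` consecutive epochs.
#' @param width_scale multiplier on all widths for desk-scale runs.
#' @param in_channels,input_size input geometry.
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @return A list of class `scnn_config`.
#' @export
scnn_config <- function(conv_filters = c(16, 32, 64, 128, 256, 256),
                        dense_units = c(64, 32), dropout_rate = 0.30,
                        initial_lr = 1e-5, lr_floor = 1e-8, decay = 0.8,
                        epochs = 50, batch_size = 32,
                        optimizer = c("adam", "sgd", "rmsprop"),
                        min_delta = 0.01, patience = 5,
                        width_scale = 1, in_channels = 3, input_size = 224,
                        seed = 42) {
  optimizer <- match.arg(optimizer)
  if (dropout_rate <= 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in (0, 1)", call. = FALSE)
  if (lr_floor >= initial_lr)
    stop("`lr_floor` must be below `initial_lr`", call. = FALSE)
  if (width_scale <= 0) stop("`width_scale` must be positive", call. = FALSE)
  structure(list(conv_filters = conv_filters, conv_kernel = 3L,
                 dense_units = dense_units, dropout_rate = dropout_rate,
                 initial_lr = initial_lr, lr_floor = lr_floor, decay = decay,
                 epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, loss = "categorical_crossentropy",
                 min_delta = min_delta, patience = patience,
                 width_scale = width_scale, in_channels = in_channels,
                 input_size = input_size, seed = seed),
            class = c("scnn_config", "clf_config"))
}

#' Configuration for the depthwise-separable classifier (DCNN)
#'
#' A MobileNet-style stack: one 3x3 stride-2 stem convolution (width 32),
#' then 13 depthwise-separable blocks (3x3 depthwise + 1x1 pointwise, batch
#' norm and ReLU after each convolution — 26 batch norms, 27 ReLUs counting
#' the stem) with channel progression 32-64-128-256-512-1024 and stride-2
#' depthwise downsampling at the four standard stages (each preceded by a
#' zero-padding stage), flatten, 2-way softmax head. `pretrained_weights`
#' optionally names an RDS file of externally trained weights; nothing in
#' the package depends on it.
#'
#' @inheritParams scnn_config
#' @param pretrained_weights optional path to a saved weight list.
#' @return A list of class `dcnn_config`.
#' @export
dcnn_config <- function(initial_lr = 1e-4, lr_floor = 1e-8, decay = 0.8,
                        epochs = 50, batch_size = 32,
                        optimizer = c("adam", "sgd", "rmsprop"),
                        min_delta = 0.001, patience = 10,
                        width_scale = 1, in_channels = 3, input_size = 224,
                        pretrained_weights = NULL, seed = 42) {
  optimizer <- match.arg(optimizer)
  if (lr_floor >= initial_lr)
    stop("`lr_floor` must be below `initial_lr`", call. = FALSE)
  if (width_scale <= 0) stop("`width_scale` must be positive", call. = FALSE)
  structure(list(initial_lr = initial_lr, lr_floor = lr_floor, decay = decay,
                 epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, loss = "categorical_crossentropy",
                 min_delta = min_delta, patience = patience,
                 width_scale = width_scale, in_channels = in_channels,
                 input_size = input_size,
                 pretrained_weights = pretrained_weights, seed = seed),
            class = c("dcnn_config", "clf_config"))
}

.sw <- function(w, ws) max(1L, as.integer(round(w * ws)))

#' Build the SCNN classifier
#'
#' @param config an [scnn_config()].
#' @return A `conv_classifier` object: `config`, `layers` (descriptors),
#'   `params`, `state` (batch-norm running stats), `classes`
#'   (`benign`, `malignant`), `n_params`, and a `description` data frame
#'   with per-layer output shapes at `config$input_size`.
#' @export
build_scnn <- function(config = scnn_config()) {
  stopifnot(inherits(config, "scnn_config"))
  ws <- config$width_scale
  f <- vapply(config$conv_filters, .sw, 1L, ws)
  if (length(f) != 6L) stop("SCNN expects six convolution widths", call. = FALSE)
  du <- vapply(config$dense_units, .sw, 1L, ws)
  cin <- config$in_channels
  layers <- list()
  add <- function(...) layers[[length(layers) + 1L]] <<- list(...)
  add(type = "conv", name = "conv1", k = 3L, stride = 1L, in_ch = cin, out_ch = f[1], activation = "relu")
  add(type = "conv", name = "conv2", k = 3L, stride = 1L, in_ch = f[1], out_ch = f[2], activation = "relu")
  add(type = "maxpool", name = "pool1", k = 2L, stride = 2L)
  add(type = "bn", name = "bn1", ch = f[2])
  add(type = "dropout", name = "drop1", rate = config$dropout_rate)
  add(type = "conv", name = "conv3", k = 3L, stride = 1L, in_ch = f[2], out_ch = f[3], activation = "relu")
  add(type = "conv", name = "conv4", k = 3L, stride = 1L, in_ch = f[3], out_ch = f[4], activation = "relu")
  add(type = "maxpool", name = "pool2", k = 2L, stride = 2L)
  add(type = "bn", name = "bn2", ch = f[4])
  add(type = "dropout", name = "drop2", rate = config$dropout_rate)
  add(type = "conv", name = "conv5", k = 3L, stride = 1L, in_ch = f[4], out_ch = f[5], activation = "relu")
  add(type = "conv", name = "conv6", k = 3L, stride = 1L, in_ch = f[5], out_ch = f[6], activation = "relu")
  add(type = "maxpool", name = "pool3", k = 2L, stride = 2L)
  add(type = "dropout", name = "drop3", rate = config$dropout_rate)
  add(type = "flatten", name = "flatten")
  s <- config$input_size
  for (i in 1:3) s <- .same_out(s, 2L)
  nflat <- s * s * f[6]
  add(type = "dense", name = "fc1", `in` = nflat, out = du[1], activation = "relu")
  add(type = "dense", name = "fc2", `in` = du[1], out = du[2], activation = "relu")
  add(type = "dense", name = "head", `in` = du[2], out = 2L, activation = "linear")
  .finish_classifier(config, layers, "scnn")
}

#' Build the DCNN classifier
#'
#' @param config a [dcnn_config()].
#' @inherit build_scnn return
#' @export
build_dcnn <- function(config = dcnn_config()) {
  stopifnot(inherits(config, "dcnn_config"))
  ws <- config$width_scale
  # MobileNet v1 body: (pointwise width, depthwise stride) per block
  plan <- list(c(64, 1), c(128, 2), c(128, 1), c(256, 2), c(256, 1),
               c(512, 2), c(512, 1), c(512, 1), c(512, 1), c(512, 1),
               c(512, 1), c(1024, 2), c(1024, 1))
  layers <- list()
  add <- function(...) layers[[length(layers) + 1L]] <<- list(...)
  stem <- .sw(32L, ws)
  add(type = "conv", name = "stem", k = 3L, stride = 2L,
      in_ch = config$in_channels, out_ch = stem, activation = "relu")
  cin <- stem
  s <- .same_out(config$input_size, 2L)
  for (i in seq_along(plan)) {
    out <- .sw(plan[[i]][1], ws); stride <- plan[[i]][2]
    if (stride == 2L) add(type = "zeropad", name = sprintf("pad%d", i))
    add(type = "dwconv", name = sprintf("dw%d", i), k = 3L, stride = stride,
        ch = cin, activation = "linear")
    add(type = "bn", name = sprintf("dw%d_bn", i), ch = cin)
    add(type = "relu", name = sprintf("dw%d_relu", i))
    add(type = "conv", name = sprintf("pw%d", i), k = 1L, stride = 1L,
        in_ch = cin, out_ch = out, activation = "linear")
    add(type = "bn", name = sprintf("pw%d_bn", i), ch = out)
    add(type = "relu", name = sprintf("pw%d_relu", i))
    cin <- out
    s <- .same_out(s, stride)
  }
  add(type = "flatten", name = "flatten")
  add(type = "dense", name = "head", `in` = s * s * cin, out = 2L,
      activation = "linear")
  model <- .finish_classifier(config, layers, "dcnn")
  if (!is.null(config$pretrained_weights)) {
    w <- readRDS(config$pretrained_weights)
    common <- intersect(names(w), names(model$params))
    model$params[common] <- w[common]
  }
  model
}

.finish_classifier <- function(config, layers, kind) {
  set.seed(config$seed)
  params <- .seq_init_params(layers)
  # per-layer description with output shapes
  s <- config$input_size; ch <- config$in_channels
  rows <- list()
  for (L in layers) {
    np <- 0L
    if (L$type == "conv") { s <- .same_out(s, L$stride); ch <- L$out_ch
      np <- L$k * L$k * L$in_ch * L$out_ch + L$out_ch }
    else if (L$type == "dwconv") { s <- .same_out(s, L$stride)
      np <- L$k * L$k * L$ch + L$ch }
    else if (L$type == "maxpool") s <- .same_out(s, L$stride)
    else if (L$type == "bn") np <- 2L * L$ch
    else if (L$type == "flatten") { ch <- s * s * ch; s <- 1L }
    else if (L$type == "dense") { ch <- L$out; np <- L$out * L$`in` + L$out }
    rows[[length(rows) + 1L]] <- data.frame(layer = L$name, type = L$type,
      out_h = s, out_w = s, out_ch = ch, n_params = np)
  }
  structure(list(config = config, layers = layers, params = params,
                 state = new.env(parent = emptyenv()),
                 classes = c("benign", "malignant"), kind = kind,
                 description = do.call(rbind, rows),
                 n_params = .count_params(params)),
            class = "conv_classifier")
}

#' @export
print.conv_classifier <- function(x, ...) {
  cat(sprintf("<conv_classifier:%s> %d layers, %d parameters, classes %s\n",
              x$kind, length(x$layers), x$n_params,
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Exponentially decaying learning-rate schedule
#'
#' `lr(e) = max(initial_lr * decay^e, lr_floor)`; non-increasing in `e`.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param initial_lr starting rate.
#' @param decay multiplicative decay per epoch, in (0, 1).
#' @param lr_floor lower bound.
#' @return Learning rate(s).
#' @examples
#' lr_schedule(2, 1e-4, 0.8, 1e-8)  # 6.4e-05
#' @export
lr_schedule <- function(epoch, initial_lr, decay, lr_floor = 0) {
  if (decay <= 0 || decay >= 1)
    stop("`decay` must be in (0, 1)", call. = FALSE)
  pmax(initial_lr * decay^epoch, lr_floor)
}

# labels -> one-hot (2 x N) in class order benign, malignant
.one_hot <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("labels outside {", paste(classes, collapse = ", "),
                       "}", call. = FALSE)
  y <- matrix(0, length(classes), length(labels),
              dimnames = list(classes, NULL))
  y[cbind(idx, seq_along(labels))] <- 1
  y
}

#' Forward-pass class probabilities
#'
#' @param model a `conv_classifier`.
#' @param x `(H, W, C, N)` array on the 0..255 scale.
#' @return `N x 2` matrix of class probabilities (columns benign,
#'   malignant), rows summing to 1.
#' @export
predict_proba <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  out <- .seq_forward(model$layers, model$params, model$state, x / 255,
                      training = FALSE)$out
  z <- sweep(out, 2, apply(out, 2, max))
  p <- sweep(exp(z), 2, colSums(exp(z)), "/")
  pm <- t(p)
  colnames(pm) <- model$classes
  pm
}

#' Train a classifier on one density bin
#'
#' Minimises categorical cross-entropy with the configured optimiser and the
#' [lr_schedule()] of the model's config; stops early once validation loss
#' has failed to improve by more than `min_delta` for more than `patience`
#' consecutive epochs (patience 0 stops at the first non-improving epoch),
#' restoring the best weights. Deterministic given `config$seed`.
#'
#' @param model a [build_scnn()] / [build_dcnn()] result.
#' @param data list with `x_train`, `y_train` (labels in
#'   benign/malignant), and optionally `x_val`, `y_val` (defaults to a
#'   15% split of the training data).
#' @param epochs optional override of `config$epochs`.
#' @return List of class `clf_fit`: `model` (best weights), `history`
#'   (per-epoch `epoch`, `lr`, `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`), `stopped_epoch`.
#' @export
train_classifier <- function(model, data, epochs = NULL) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  x <- data$x_train; y <- data$y_train
  if (length(unique(as.character(y))) < 2L)
    stop("training set contains a single class", call. = FALSE)
  set.seed(cfg$seed)
  if (is.null(data$x_val)) {
    N <- dim(x)[4]
    vi <- sample(N, max(1L, round(0.15 * N)))
    data$x_val <- x[, , , vi, drop = FALSE]; data$y_val <- y[vi]
    x <- x[, , , -vi, drop = FALSE]; y <- y[-vi]
  }
  xt <- x / 255; yt <- .one_hot(y, model$classes)
  xv <- data$x_val / 255; yv <- .one_hot(data$y_val, model$classes)
  N <- dim(xt)[4]
  step <- .opt_step(cfg$optimizer)
  opt <- .adam_new()
  best <- list(loss = Inf, params = model$params, state_bak = NULL)
  wait <- 0L; hist <- list(); stopped <- NA_integer_
  if (epochs > 0) for (ep in seq_len(epochs)) {
    lr <- lr_schedule(ep - 1L, cfg$initial_lr, cfg$decay, cfg$lr_floor)
    ord <- sample(N)
    ep_loss <- 0; ep_hit <- 0; nb <- 0L
    for (b0 in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
      xb <- xt[, , , idx, drop = FALSE]; yb <- yt[, idx, drop = FALSE]
      fwd <- .seq_forward(model$layers, model$params, model$state, xb,
                          training = TRUE)
      lres <- .softmax_ce(fwd$out, yb)
      grads <- .seq_backward(model$layers, model$params, fwd$caches,
                             lres$dlogits)
      model$params <- step(model$params, grads, opt, lr)
      ep_loss <- ep_loss + lres$loss
      ep_hit <- ep_hit + sum(apply(lres$p, 2, which.max) ==
                             apply(yb, 2, which.max))
      nb <- nb + 1L
    }
    vf <- .seq_forward(model$layers, model$params, model$state, xv,
                       training = FALSE)
    vres <- .softmax_ce(vf$out, yv)
    vacc <- mean(apply(vres$p, 2, which.max) == apply(yv, 2, which.max))
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, loss = ep_loss / nb,
                             accuracy = ep_hit / N, val_loss = vres$loss,
                             val_accuracy = vacc)
    if (vres$loss < best$loss - cfg$min_delta) {
      best$loss <- vres$loss; best$params <- model$params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) { stopped <- ep; break }
    }
  }
  model$params <- best$params
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
               accuracy = numeric(), val_loss = numeric(),
               val_accuracy = numeric())
  structure(list(model = model, history = history,
                 stopped_epoch = stopped, seed = cfg$seed),
            class = "clf_fit")
}

#' Confusion matrix from labels
#'
#' @param truth,pred vectors of class labels.
#' @param positive label counted as positive (default `"malignant"`).
#' @return Object of class `confusion_matrix`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_matrix <- function(truth, pred, positive = "malignant") {
  truth <- as.character(truth) == positive
  pred <- as.character(pred) == positive
  structure(list(TP = sum(truth & pred), TN = sum(!truth & !pred),
                 FP = sum(!truth & pred), FN = sum(truth & !pred)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Metric suite from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean),
#' accuracy `(TP+TN)/total`, specificity `TN/(TN+FP)`, and the
#' balanced-accuracy AUC surrogate
#' `auc_balanced = (TP/(TP+FN) + TN/(TN+FP)) / 2`. A metric whose denominator is
#' zero is reported as `NA` and listed in the `"undefined"` attribute. With
#' `debug = TRUE` the report additionally carries `specificity_variant`
#' (`TP/(FP+FN)`), the as-printed — dimensionally spurious — specificity
#' variant, for cross-checking published tables only.
#'
#' @param cm a [confusion_matrix()] or list with `TP`, `TN`, `FP`, `FN`.
#' @param debug include the literal Eq.-14 value?
#' @return Named list of metrics with attribute `"undefined"` (character
#'   vector of metrics with zero denominators).
#' @examples
#' metrics_from_confusion(list(TP = 415, TN = 416, FP = 4, FN = 4))
#' @export
metrics_from_confusion <- function(cm, debug = FALSE) {
  undef <- character()
  rat <- function(num, den, nm) {
    if (den == 0) { undef <<- c(undef, nm); return(NA_real_) }
    num / den
  }
  precision <- rat(cm$TP, cm$TP + cm$FP, "precision")
  recall <- rat(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  accuracy <- rat(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN, "accuracy")
  specificity <- rat(cm$TN, cm$TN + cm$FP, "specificity")
  auc_balanced <- if (is.na(recall) || is.na(specificity)) {
    undef <- c(undef, "auc_balanced"); NA_real_
  } else (recall + specificity) / 2
  out <- list(precision = precision, recall = recall, f1 = f1,
              accuracy = accuracy, specificity = specificity,
              auc_balanced = auc_balanced)
  if (debug) out$specificity_variant <- rat(cm$TP, cm$FP + cm$FN, "specificity_variant")
  attr(out, "undefined") <- unique(undef)
  out
}

#' Threshold-free ROC AUC (Mann-Whitney)
#'
#' The probability that a uniformly drawn positive scores above a uniformly
#' drawn negative, ties counting one half; computed from midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels vector with exactly two classes.
#' @param positive label treated as positive (default `"malignant"`).
#' @return AUC in \[0, 1\]; `NA` (with a warning) if one class is absent.
#' @export
roc_auc <- function(scores, labels, positive = "malignant") {
  pos <- as.character(labels) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) {
    warning("roc_auc undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = "malignant") {
  pos <- as.character(labels) == positive
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(scores[!pos] >= t), 0),
             tpr = vapply(th, function(t) mean(scores[pos] >= t), 0))
}

#' Evaluate a classifier on a test split
#'
#' @param model a `conv_classifier` or `clf_fit`.
#' @param x `(H, W, C, N)` test images (0..255 scale).
#' @param labels true labels (benign/malignant).
#' @param bin,magnification provenance recorded in the report.
#' @return Object of class `eval_report`: confusion matrix, the
#'   [metrics_from_confusion()] suite, `roc_auc`, `scores`, `labels`,
#'   `n`, `bin`, `magnification`.
#' @export
evaluate <- function(model, x, labels, bin = NA, magnification = NA) {
  if (inherits(model, "clf_fit")) model <- model$model
  if (length(labels) == 0) stop("empty test split", call. = FALSE)
  p <- predict_proba(model, x)
  pred <- model$classes[max.col(p)]
  scores <- p[, "malignant"]
  cm <- confusion_matrix(labels, pred)
  structure(c(list(cm = cm), metrics_from_confusion(cm),
              list(roc_auc = roc_auc(scores, labels), scores = scores,
                   labels = as.character(labels), n = length(labels),
                   bin = bin, magnification = magnification)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d bin=%s mag=%s\n", x$n, x$bin,
              x$magnification))
  print(x$cm)
  cat(sprintf("  precision %.4f recall %.4f f1 %.4f accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  cat(sprintf("  specificity %.4f auc_balanced %.4f roc_auc %.4f\n",
              x$specificity, x$auc_balanced, x$roc_auc))
  invisible(x)
}

#' Write an evaluation report to CSV + JSON (confusion, metrics, ROC points)
#'
#' @param report an [evaluate()] result (or list of them).
#' @param dir output directory (created).
#' @param stem filename stem.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir, stem = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- if (inherits(report, "eval_report")) list(report) else report
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(bin = r$bin, magnification = r$magnification, n = r$n,
               TP = r$cm$TP, TN = r$cm$TN, FP = r$cm$FP, FN = r$cm$FN,
               precision = r$precision, recall = r$recall, f1 = r$f1,
               accuracy = r$accuracy, specificity = r$specificity,
               auc_balanced = r$auc_balanced, roc_auc = r$roc_auc)))
  csv <- file.path(dir, paste0(stem, "_metrics.csv"))
  utils::write.csv(rows, csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_metrics.json"))
  jsonlite::write_json(rows, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  rocs <- file.path(dir, paste0(stem, "_roc.csv"))
  roc <- do.call(rbind, lapply(reports, function(r) {
    pts <- roc_points(r$scores, r$labels)
    pts$bin <- r$bin; pts$magnification <- r$magnification; pts
  }))
  utils::write.csv(roc, rocs, row.names = FALSE)
  invisible(c(csv, js, rocs))
}
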