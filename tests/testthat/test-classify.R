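test_that("SCNN contract: softmax output, deterministic build, width scaling", {
  cfg <- scnn_config(width_scale = 0.1, input_size = 16, seed = 3)
  m <- build_scnn(cfg)
  p <- predict_proba(m, array(runif(16 * 16 * 3 * 4) * 255, c(16, 16, 3, 4)))
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(rowSums(p), rep(1, 4))
  expect_identical(build_scnn(cfg)$params, m$params)
  big <- build_scnn(scnn_config(input_size = 16))
  expect_lt(m$n_params, big$n_params)
  expect_equal(sum(m$description$n_params), m$n_params)
  # six convolutions, three pools, two batch norms, three dropouts
  types <- vapply(m$layers, `[[`, "", "type")
  expect_equal(sum(types == "conv"), 6L)
  expect_equal(sum(types == "maxpool"), 3L)
  expect_equal(sum(types == "bn"), 2L)
  expect_equal(sum(types == "dropout"), 3L)
  expect_error(scnn_config(initial_lr = 1e-9, lr_floor = 1e-8), "below")
  expect_error(scnn_config(dropout_rate = 1.2), "0, 1")
})

test_that("DCNN layer inventory matches the depthwise-separable design", {
  m <- build_dcnn(dcnn_config(width_scale = 0.25, input_size = 32))
  types <- vapply(m$layers, `[[`, "", "type")
  expect_equal(sum(types == "dwconv"), 13L)                 # 13 separable blocks
  expect_equal(sum(types == "conv" &
                   vapply(m$layers, function(l) isTRUE(l$k == 1), TRUE)), 13L)
  expect_equal(sum(types == "bn"), 26L)
  n_relu <- sum(types == "relu") +
    sum(vapply(m$layers, function(l) identical(l$activation, "relu"), TRUE))
  expect_equal(n_relu, 27L)
  expect_equal(sum(types == "zeropad"), 4L)
  full <- build_dcnn(dcnn_config(input_size = 32))
  expect_lt(m$n_params, full$n_params)
  p <- predict_proba(m, array(runif(32 * 32 * 3) * 255, c(32, 32, 3)))
  expect_equal(rowSums(p), 1)
})

test_that("learning-rate schedule decays exponentially to the floor", {
  expect_equal(lr_schedule(0, 1e-4, 0.8, 1e-8), 1e-4)
  expect_equal(lr_schedule(2, 1e-4, 0.8, 1e-8), 6.4e-5)
  expect_equal(lr_schedule(1000, 1e-4, 0.8, 1e-8), 1e-8)
  lr <- lr_schedule(0:100, 1e-4, 0.8, 1e-8)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr >= 1e-8))
  expect_error(lr_schedule(1, 1e-4, 1.2), "0, 1")
})

test_that("confusion-matrix metrics match hand evaluation and flag zero denominators", {
  m <- metrics_from_confusion(list(TP = 50, TN = 90, FP = 10, FN = 50))
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.625)
  expect_equal(m$accuracy, 140 / 200)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$auc_balanced, 0.7)

  perfect <- metrics_from_confusion(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))

  z <- metrics_from_confusion(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(z$precision) && is.na(z$recall))
  expect_true(all(c("precision", "recall") %in% attr(z, "undefined")))

  dbg <- metrics_from_confusion(list(TP = 50, TN = 90, FP = 10, FN = 50),
                                debug = TRUE)
  expect_equal(dbg$specificity_variant, 50 / 60)

  # F1 is the harmonic mean of reported precision/recall on random matrices
  set.seed(4)
  for (i in 1:25) {
    cm <- as.list(setNames(sample(0:50, 4, replace = TRUE) + 1,
                           c("TP", "TN", "FP", "FN")))
    mm <- metrics_from_confusion(cm)
    expect_equal(mm$f1,
                 2 / (1 / mm$precision + 1 / mm$recall), tolerance = 1e-12)
    # and agrees with direct set-based computation from a label vector
    truth <- c(rep("malignant", cm$TP + cm$FN), rep("benign", cm$TN + cm$FP))
    pred <- c(rep("malignant", cm$TP), rep("benign", cm$FN),
              rep("benign", cm$TN), rep("malignant", cm$FP))
    cm2 <- confusion_matrix(truth, pred)
    expect_equal(unclass(cm2)[c("TP", "TN", "FP", "FN")],
                 cm[c("TP", "TN", "FP", "FN")])
    expect_equal(mm$accuracy, mean(truth == pred))
  }
})

test_that("roc_auc equals pairwise enumeration, with tie and degenerate handling", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.85),
                       c("malignant", "malignant", "benign", "benign")), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("malignant", "malignant",
                                        "benign", "benign")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("malignant", "benign"), 3)), 0.5)
  expect_warning(a <- roc_auc(1:3, rep("benign", 3)), "one class")
  expect_true(is.na(a))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)   # ties likely
    lb <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_roc_auc(sc, lb))
  }
})

test_that("classifier training is deterministic, stops early, and rejects one-class data", {
  set.seed(6)
  x <- array(runif(16 * 16 * 3 * 20) * 255, c(16, 16, 3, 20))
  y <- rep(c("benign", "malignant"), 10)
  x[, , , y == "malignant"] <- x[, , , y == "malignant"] * 0.3   # separable-ish
  cfg <- scnn_config(width_scale = 0.1, input_size = 16, epochs = 3,
                     batch_size = 4, initial_lr = 1e-3, decay = 0.9,
                     patience = 5, seed = 31)
  f1 <- train_classifier(build_scnn(cfg), list(x_train = x, y_train = y))
  f2 <- train_classifier(build_scnn(cfg), list(x_train = x, y_train = y))
  expect_equal(f1$history, f2$history)
  expect_lte(nrow(f1$history), 3L)

  expect_error(train_classifier(build_scnn(cfg),
                                list(x_train = x, y_train = rep("benign", 20))),
               "single class")

  # patience 0: training halts at the first epoch that fails to improve
  # (epoch 1 always establishes the baseline, epoch 2 cannot beat a 0.5
  # min_delta at a negligible learning rate)
  cfg0 <- scnn_config(width_scale = 0.1, input_size = 16, epochs = 10,
                      batch_size = 4, initial_lr = 1e-6, min_delta = 0.5,
                      patience = 0, seed = 31)
  f0 <- train_classifier(build_scnn(cfg0), list(x_train = x, y_train = y))
  expect_equal(nrow(f0$history), 2L)
  expect_equal(f0$stopped_epoch, 2L)
})

test_that("evaluation reconciles totals and handles degenerate predictors", {
  set.seed(7)
  x <- array(runif(16 * 16 * 3 * 12) * 255, c(16, 16, 3, 12))
  y <- rep(c("benign", "malignant"), 6)
  m <- build_scnn(scnn_config(width_scale = 0.1, input_size = 16, seed = 3))
  ev <- evaluate(m, x, y, bin = "LD", magnification = 40)
  expect_equal(ev$n, 12L)
  expect_equal(ev$cm$TP + ev$cm$TN + ev$cm$FP + ev$cm$FN, 12L)
  expect_error(evaluate(m, x, character()), "empty")

  # a constant-positive predictor: recall 1, specificity 0
  cmc <- confusion_matrix(y, rep("malignant", 12))
  mc <- metrics_from_confusion(cmc)
  expect_equal(mc$recall, 1)
  expect_equal(mc$specificity, 0)

  d <- withr::local_tempdir()
  paths <- write_eval_report(ev, d, "unit")
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$TP, ev$cm$TP)
})
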