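small_cfg <- function(...) {
  unet_sam_config(encoder_filters = c(4, 8, 16), input_size = 16,
                  epochs = 1, batch_size = 2, ...)
}

test_that("building the U-Net is deterministic and respects the width scale", {
  m1 <- build_unet_sam(small_cfg(seed = 9))
  m2 <- build_unet_sam(small_cfg(seed = 9))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$n_params, m2$n_params)
  m3 <- build_unet_sam(small_cfg(seed = 10))
  expect_false(identical(m1$params, m3$params))

  full <- build_unet_sam(unet_sam_config(input_size = 224))
  quarter <- build_unet_sam(unet_sam_config(width_scale = 0.25,
                                            input_size = 224))
  expect_lt(quarter$n_params, full$n_params)
  # parameter count agrees with the layer description
  expect_equal(sum(full$layers$n_params), full$n_params)
})

test_that("the segmenter maps an input patch to a same-size probability map", {
  m <- build_unet_sam(small_cfg(seed = 1))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 2))
  prob <- 1 / (1 + exp(-histodens:::.unet_forward(m, x)$logits))
  expect_equal(dim(prob), c(16L, 16L, 1L, 2L))
  expect_true(all(prob >= 0 & prob <= 1))
  expect_error(build_unet_sam(unet_sam_config(input_size = 100)),
               "divisible")
  expect_error(unet_sam_config(encoder_filters = c(8, 8)), "increasing")
})

test_that("the attention gate is an elementwise gain in [0, 1] on encoder features", {
  set.seed(2)
  e <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  g <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  ones <- array(1, c(8, 8, 1, 2))
  expect_equal(spatial_attention_gate(e, g, attention = ones)$gated, e)
  expect_equal(spatial_attention_gate(e, g, attention = ones * 0)$gated,
               e * 0)
  r <- spatial_attention_gate(e, g)
  expect_true(all(r$attention >= 0 & r$attention <= 1))
  expect_true(all(abs(r$gated) <= abs(e) + 1e-12))
  expect_error(spatial_attention_gate(e, g[1:4, , , , drop = FALSE]),
               "aligned")
})

test_that("dice matches the pixel-set oracle and its edge conventions", {
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1.0)
  # |A| = |B| = 100, |A n B| = 50
  A <- matrix(0, 20, 20); A[1:100] <- 1
  B <- matrix(0, 20, 20); B[51:150] <- 1
  expect_equal(dice(A, B), 0.5)
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  set.seed(7)
  for (i in 1:30) {
    a <- matrix(rbinom(256, 1, runif(1)), 16)
    b <- matrix(rbinom(256, 1, runif(1)), 16)
    expect_equal(dice(a, b), oracle_dice(a, b))
    expect_equal(dice(a, b), dice(b, a))
  }
})

test_that("training bookkeeping: empty history at zero epochs, fold arithmetic, empty-set error", {
  d <- segmentation_demo_set(n_patches = 8, size = 48, seed = 3)
  cfg <- unet_sam_config(encoder_filters = c(4, 8, 16), input_size = 48,
                         epochs = 0, batch_size = 2, seed = 4)
  fit <- train_segmenter(cfg, d$x, d$masks)
  expect_equal(nrow(fit$history), 0L)
  expect_s3_class(fit$model, "unet_sam")

  cfg1 <- unet_sam_config(encoder_filters = c(4, 8, 16), input_size = 48,
                          epochs = 1, batch_size = 2, seed = 4)
  cv <- train_segmenter(cfg1, d$x[1:6], d$masks[1:6], k_folds = 3)
  expect_equal(nrow(cv$folds), 3L)
  expect_equal(cv$folds$n_train, rep(4L, 3))
  expect_equal(cv$folds$n_test, rep(2L, 3))

  expect_error(train_segmenter(cfg, list(), list()), "empty|subscript")
})

test_that("prediction thresholds behave at the extremes and instances are labelled", {
  m <- build_unet_sam(small_cfg(seed = 5))
  patch <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  sm0 <- predict_mask(m, patch, threshold = 0)
  expect_true(all(sm0$mask))
  sm1 <- predict_mask(m, patch, threshold = 1 + 1e-9)
  expect_false(any(sm1$mask))
  expect_equal(sm1$n_instances, 0L)
  # non-multiple-of-16 inputs are padded then cropped back
  p2 <- array(runif(20 * 25 * 3) * 255, c(20, 25, 3))
  sm <- predict_mask(m, p2)
  expect_equal(dim(sm$prob), c(20L, 25L))
})

test_that("otsu threshold agrees with the exhaustive-search variance minimiser", {
  set.seed(8)
  for (i in 1:5) {
    x <- matrix(c(rnorm(600, 0.25, 0.05), rnorm(400, 0.75, 0.05)), 40, 25)
    om <- otsu_nuclei_mask(x, min_area = 0)
    expect_lt(abs(attr(om, "threshold") - oracle_otsu(x)),
              (max(x) - min(x)) / 256 + 1e-12)
    expect_gt(attr(om, "threshold"), 0.35)
    expect_lt(attr(om, "threshold"), 0.65)
  }
  expect_warning(om <- otsu_nuclei_mask(matrix(1, 5, 5)), "constant")
  expect_false(any(om$mask))
})

test_that("otsu recovers the exact nucleus count on a synthetic scene", {
  sp <- scene_spec(width = 160, height = 160, class_label = "benign_like",
                   n_nuclei = 20, radius_range = c(3, 5), seed = 11)
  sc <- generate_scene(sp)
  hc <- stain_separate(sc$image)[, , 1]
  om <- otsu_nuclei_mask(hc, min_area = 10)
  expect_equal(om$n_instances, 20L)
})
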