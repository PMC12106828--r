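test_that("gaussian denoise preserves constants, is identity at sigma 0, and matches the discrete kernel on an impulse", {
  img <- array(123.4, c(20, 20, 3))
  expect_equal(gaussian_denoise(img, 2), img)
  x <- array(runif(20 * 20 * 3), c(20, 20, 3))
  expect_identical(gaussian_denoise(x, 0), x)
  expect_error(gaussian_denoise(x, -1), "non-negative")

  # unit impulse: centre value equals the peak of the normalised 2-d kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_denoise(imp, 1)
  r <- ceiling(4)
  k <- exp(-((-r):r)^2 / 2); k <- k / sum(k)
  expect_equal(sm[11, 11], max(k)^2, tolerance = 1e-12)

  # mean preservation on an interior-supported image
  x <- matrix(0, 32, 32)
  x[12:20, 12:20] <- runif(81)
  expect_equal(mean(gaussian_denoise(x, 1.5)), mean(x), tolerance = 1e-3)
})

test_that("gaussian denoise agrees with EBImage gblur away from borders", {
  set.seed(2)
  x <- matrix(runif(40 * 40), 40, 40)
  ours <- gaussian_denoise(x, 1.2)
  ebi <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(x)), sigma = 1.2)))
  # kernel truncation radii differ slightly between the implementations
  expect_lt(max(abs(ours[10:30, 10:30] - ebi[10:30, 10:30])), 1e-3)
})

test_that("stain separation inverts the Beer-Lambert forward render", {
  model <- he_stain_model()
  set.seed(3)
  conc <- array(0, c(8, 8, 3))
  conc[, , 1] <- runif(64, 0, 1.2)   # hematoxylin
  conc[, , 2] <- runif(64, 0, 0.8)   # eosin
  img <- stain_render(conc, model)
  rec <- stain_separate(img, model, eps = 0)
  expect_lt(max(abs(rec - conc)), 1e-6)

  # pure white has zero optical density
  white <- array(255, c(4, 4, 3))
  expect_equal(max(abs(stain_separate(white, model, eps = 0))), 0)

  # known single-stain pixel recovers its concentration, others ~ 0
  c1 <- array(0, c(1, 1, 3)); c1[1, 1, 1] <- 0.7
  img1 <- stain_render(c1, model)
  rec1 <- stain_separate(img1, model, eps = 0)
  expect_equal(as.numeric(rec1[1, 1, 1]), 0.7, tolerance = 1e-8)
  expect_lt(max(abs(rec1[1, 1, 2:3])), 1e-8)

  expect_error(he_stain_model(c(1, 0, 0), c(2, 0, 0)), "singular|collinear")
})

test_that("stain removal keeps nuclei and suppresses eosin", {
  model <- he_stain_model()
  conc <- array(0, c(6, 6, 3))
  conc[, , 2] <- 0.5                      # eosin-only field
  conc[2:3, 2:3, 1] <- 1.0                # hematoxylin blob
  img <- stain_render(conc, model)
  out <- remove_stain(img, model, eps = 0)
  expect_true(all(abs(out[5:6, 5:6, 1] - 255) < 1e-6))  # eosin region -> white-ish gray
  expect_true(all(out[2:3, 2:3, 1] < 120))              # blob stays dark
  white <- array(255, c(3, 3, 3))
  expect_equal(remove_stain(white, model, eps = 0), array(255, c(3, 3, 3)))
})

test_that("augmentation identities: no-op params, flip involution, exact 90-degree rotation", {
  set.seed(4)
  p <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  expect_identical(augment(p, list()), p)
  expect_identical(augment(augment(p, list(hflip = TRUE)), list(hflip = TRUE)), p)
  expect_identical(augment(augment(p, list(vflip = TRUE)), list(vflip = TRUE)), p)

  m <- array(0, c(8, 8, 1)); m[2, 5, 1] <- 1     # marker at row 2, col 5
  r <- augment(m, list(rotation = 90))
  # 90 deg ccw index map: (h, w) <- (w, H + 1 - h)
  expect_equal(which(r[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 8 + 1 - 5, col = 2))

  # sampled augmentation is reproducible under a seed
  rng <- list(rotation = 20, zoom = 0.1, shear = 0.1, hflip = TRUE)
  a1 <- augment(p, ranges = rng, seed = 11)
  a2 <- augment(p, ranges = rng, seed = 11)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(p))
})
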