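test_that("grid6 tiling of a 700x460 field gives the canonical six offsets", {
  g <- plan_grid(700, 460, 224, "grid6")
  expect_equal(nrow(g$offsets), 6L)
  expect_equal(sort(unique(g$offsets$x)), c(0L, 238L, 476L))
  expect_equal(sort(unique(g$offsets$y)), c(0L, 236L))
  # row-major ordering, flush with the far edges
  expect_equal(g$offsets$x[1:3], c(0L, 238L, 476L))
  expect_true(all(g$offsets$x + 224 <= 700) && all(g$offsets$y + 224 <= 460))
})

test_that("cover mode tiles 700x460 with 12 offsets and leaves no pixel uncovered", {
  g <- plan_grid(700, 460, 224, "cover")
  expect_equal(nrow(g$offsets), 12L)
  covered <- matrix(FALSE, 460, 700)
  for (i in seq_len(nrow(g$offsets)))
    covered[g$offsets$y[i] + 1:224, g$offsets$x[i] + 1:224] <- TRUE
  expect_true(all(covered))
})

test_that("cover mode covers every pixel for randomized geometries", {
  set.seed(42)
  for (i in 1:25) {
    P <- sample(8:40, 1)
    W <- sample(P:(3 * P), 1); H <- sample(P:(3 * P), 1)
    g <- plan_grid(W, H, P, "cover")
    covered <- matrix(FALSE, H, W)
    for (j in seq_len(nrow(g$offsets)))
      covered[g$offsets$y[j] + 1:P, g$offsets$x[j] + 1:P] <- TRUE
    expect_true(all(covered), info = sprintf("W=%d H=%d P=%d", W, H, P))
    expect_false(any(duplicated(g$offsets)))
  }
})

test_that("degenerate single-tile grid and domain errors", {
  g <- plan_grid(224, 224, 224, "grid6")
  expect_equal(nrow(g$offsets), 1L)
  expect_equal(unlist(g$offsets), c(x = 0L, y = 0L))
  expect_error(plan_grid(100, 100, 224), "exceeds")
})

test_that("extracted patches are exact pixel copies and marked pixels land in the right tiles", {
  img <- array(7, c(460, 700, 3))
  g <- plan_grid(700, 460, 224, "grid6")
  recs <- extract_patches(img, g)
  expect_length(recs, 6L)
  expect_true(all(vapply(recs, function(r) all(r$pixels == 7), TRUE)))
  expect_true(all(vapply(recs, function(r) all(dim(r$pixels) == c(224, 224, 3)), TRUE)))

  # single marked pixel at 0-based (x=239, y=0): in columns with x <= 239 < x+224
  img[1, 240, 1] <- 99
  recs <- extract_patches(img, g)
  hit <- vapply(recs, function(r) any(r$pixels == 99), TRUE)
  expected <- vapply(recs, function(r)
    r$x <= 239 && 239 < r$x + 224 && r$y <= 0, TRUE)
  expect_equal(hit, expected)
  expect_equal(sum(hit), 1L)  # only the x=238, y=0 tile contains column 239
  expect_error(extract_patches(array(0, c(100, 100, 3)), g), "grid expects")
})

test_that("patch_corpus walks a BreakHis-style tree and multiplies counts by the grid size", {
  root <- withr::local_tempdir()
  for (cl in c("benign", "malignant")) {
    dir.create(file.path(root, cl, "40X"), recursive = TRUE)
    for (j in 1:3)
      write_image(array(runif(48 * 64 * 3) * 255, c(48, 64, 3)),
                  file.path(root, cl, "40X", sprintf("img%d.png", j)))
  }
  man <- patch_corpus(root, mode = "cover", patch = 16,
                      manifest_path = file.path(root, "man.csv"))
  g <- plan_grid(64, 48, 16, "cover")
  expect_equal(nrow(man), 6L * nrow(g$offsets))
  expect_setequal(unique(man$class), c("benign", "malignant"))
  expect_equal(unique(man$magnification), 40)
  expect_equal(attr(man, "skipped"), 0L)
  expect_true(file.exists(file.path(root, "man.csv")))

  # empty folder -> empty manifest; unreadable image -> skipped and counted
  empty <- withr::local_tempdir()
  expect_equal(nrow(patch_corpus(empty)), 0L)
  writeLines("not a png", file.path(root, "benign", "40X", "broken.png"))
  expect_warning(man2 <- patch_corpus(root, mode = "cover", patch = 16),
                 "skipping")
  expect_equal(attr(man2, "skipped"), 1L)
  expect_equal(nrow(man2), nrow(man))
})
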