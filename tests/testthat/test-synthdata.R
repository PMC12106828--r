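test_that("scene generation is bit-reproducible and honours the count contract", {
  sp <- scene_spec(width = 96, height = 96, class_label = "malignant_like",
                   n_nuclei = 20, radius_range = c(2.5, 4),
                   overlap_allowance = 0, seed = 21)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s1$n_nuclei, 20L)
  expect_equal(length(setdiff(unique(as.vector(s1$labels)), 0L)), 20L)
  # overlap allowance 0: instances are pairwise disjoint by construction;
  # each label forms its own component
  expect_equal(count_nuclei(s1$labels > 0, min_area = 0), 20L)
})

test_that("empty scenes and infeasible placement behave as specified", {
  sp <- scene_spec(width = 48, height = 48, n_nuclei = 0, seed = 1)
  sc <- generate_scene(sp)
  expect_equal(sc$n_nuclei, 0L)
  expect_true(all(sc$labels == 0L))
  expect_true(all(sc$image >= 0 & sc$image <= 255))
  toomany <- scene_spec(width = 40, height = 40, n_nuclei = 60,
                        radius_range = c(5, 6), overlap_allowance = 0,
                        class_label = "malignant_like", seed = 2)
  expect_error(generate_scene(toomany), "could not place")
})

test_that("rendered scenes invert through stain separation at zero noise", {
  sp <- scene_spec(width = 64, height = 64, n_nuclei = 8, noise_sd = 0,
                   radius_range = c(3, 5), class_label = "benign_like",
                   seed = 5)
  sc <- generate_scene(sp)
  rec <- stain_separate(sc$image, eps = 0)
  expect_lt(max(abs(rec - sc$conc)), 1e-3)
})

test_that("benign-like scenes have rounder nuclei than malignant-like scenes", {
  eccs <- function(cl, seeds) {
    unlist(lapply(seeds, function(s) {
      sp <- scene_spec(width = 128, height = 128, class_label = cl,
                       n_nuclei = c(4, 8), radius_range = c(3, 5), seed = s)
      generate_scene(sp)$nuclei$ecc
    }))
  }
  expect_lt(mean(eccs("benign_like", 1:5)),
            mean(eccs("malignant_like", 1:5)))
})

test_that("corpus generation produces the BreakHis-style tree with matching truth", {
  root <- file.path(withr::local_tempdir(), "corpus")
  b <- scene_spec(width = 64, height = 64, class_label = "benign_like",
                  n_nuclei = c(2, 4), radius_range = c(3, 5))
  m <- scene_spec(width = 64, height = 64, class_label = "malignant_like",
                  n_nuclei = c(6, 9), radius_range = c(2.5, 4),
                  overlap_allowance = 0.3)
  man <- generate_corpus(b, m, counts = c(benign = 5, malignant = 5),
                         magnifications = c(40, 400), output_root = root,
                         seed = 9)
  expect_equal(nrow(man), 20L)
  imgs <- list.files(root, pattern = "\\.png$", recursive = TRUE)
  expect_equal(sum(!grepl("^masks/", imgs)), 20L)
  expect_equal(sum(grepl("^masks/", imgs)), 20L)
  expect_true(all(file.exists(man$path)) && all(file.exists(man$mask_path)))
  # masks on disk agree with realised counts
  for (i in c(1, 11)) {
    lab <- read_mask(man$mask_path[i])
    expect_equal(max(lab), man$n_nuclei[i])
  }
  # refuses to clobber existing output
  expect_error(generate_corpus(b, m, counts = c(benign = 1, malignant = 1),
                               output_root = root, seed = 9), "not empty")
})

test_that("truth features separate the classes with a simple logistic baseline", {
  feats <- function(cl, seeds) {
    t(vapply(seeds, function(s) {
      sp <- scene_spec(width = 128, height = 128, class_label = cl, seed = s)
      sc <- generate_scene(sp)
      c(n = sc$n_nuclei, ecc = mean(sc$nuclei$ecc),
        sdarea = stats::sd(sc$nuclei$area))
    }, c(n = 0, ecc = 0, sdarea = 0)))
  }
  xb <- feats("benign_like", 1:30); xm <- feats("malignant_like", 31:60)
  df <- data.frame(rbind(xb, xm),
                   y = rep(c(0, 1), each = 30))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  acc <- mean((stats::predict(fit, type = "response") > 0.5) == df$y)
  expect_gte(acc, 0.95)
})
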