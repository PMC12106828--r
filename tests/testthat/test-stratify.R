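test_that("component counting matches the flood-fill oracle for both connectivities", {
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.2, 0.6)), 32)
    for (conn in c(4, 8)) {
      expect_equal(count_nuclei(m, min_area = 0, connectivity = conn),
                   oracle_count_components(m, conn),
                   info = sprintf("i=%d conn=%d", i, conn))
    }
    # min-area filtering agrees too
    expect_equal(count_nuclei(m, min_area = 5, connectivity = 8),
                 oracle_count_components(m, 8, min_area = 5))
  }
  # 4-connectivity cross-check against EBImage's labelling
  m <- matrix(rbinom(400, 1, 0.4), 20)
  expect_equal(count_nuclei(m, min_area = 0, connectivity = 4),
               max(EBImage::bwlabel(EBImage::Image(t(m)))))
})

test_that("counting rules: squares, specks, empty masks", {
  expect_equal(count_nuclei(matrix(0, 10, 10)), 0L)
  m <- matrix(0, 20, 20)
  m[2:6, 2:6] <- 1; m[10:14, 10:14] <- 1; m[2:6, 14:18] <- 1
  expect_equal(count_nuclei(m, min_area = 10), 3L)
  speck <- matrix(0, 10, 10); speck[5, 5:6] <- 1
  expect_equal(count_nuclei(speck, min_area = 10), 0L)
  expect_equal(count_nuclei(speck, min_area = 1), 1L)
})

test_that("thresholds follow the 30:30:40 ratio on both bases", {
  th <- compute_thresholds(c(10, 400, 1000))
  expect_equal(th$t_low, 300)
  expect_equal(th$t_high, 600)
  thq <- compute_thresholds(1:100, basis = "quantile")
  expect_equal(thq$t_low, 30.7)
  expect_equal(thq$t_high, 60.4)
  expect_error(compute_thresholds(numeric()), "empty")
  expect_error(compute_thresholds(c(-1, 2)), "non-negative")
  expect_error(compute_thresholds(1:5, ratio = c(1, 2)), "three")
})

test_that("bin assignment uses closed-left ties and is monotone in density", {
  th <- compute_thresholds(c(0, 1000))
  rec <- data.frame(patch_id = letters[1:5], n = 1:5, a_mms = 1,
                    a_d = c(0, 300, 300.0001, 600, 600.1),
                    bin = "UNASSIGNED")
  out <- assign_bins(rec, th)
  expect_equal(out$bin, c("LD", "LD", "MD", "MD", "HD"))
  # monotone: higher density never yields a lower bin
  set.seed(2)
  d <- sort(runif(200, 0, 1000))
  b <- assign_bins(data.frame(a_d = d), th)$bin
  lev <- match(b, c("LD", "MD", "HD"))
  expect_true(all(diff(lev) >= 0))
  # all densities equal: everything lands in HD (d > t_high fails only at ties)
  the <- compute_thresholds(rep(500, 4))
  expect_equal(unique(assign_bins(data.frame(a_d = rep(500, 4)), the)$bin),
               "HD")
})

test_that("uniform densities give approximately 30/30/40 bin proportions", {
  set.seed(3)
  d <- runif(4000, 0, 1)
  th <- compute_thresholds(d)
  b <- assign_bins(data.frame(a_d = d), th)$bin
  p <- as.vector(table(factor(b, c("LD", "MD", "HD")))) / length(d)
  expect_equal(p, c(0.3, 0.3, 0.4), tolerance = 0.1)
})

test_that("stratified layout replicates benign into every bin and copies files", {
  root <- withr::local_tempdir()
  pdir <- file.path(root, "p"); dir.create(pdir)
  mk <- function(id) {
    f <- file.path(pdir, paste0(id, ".png"))
    write_image(matrix(runif(16) * 255, 4), f)
    f
  }
  man <- data.frame(
    patch_id = c(sprintf("b%02d", 1:10), sprintf("m%d", 1:9)),
    class = c(rep("benign", 10), rep("malignant", 9)),
    a_d = c(rep(NA, 10), 1:9),
    bin = c(rep(NA, 10), rep(c("LD", "MD", "HD"), each = 3)),
    stringsAsFactors = FALSE)
  man$path <- vapply(man$patch_id, mk, "")
  out <- file.path(root, "strat")
  strat <- build_stratified_layout(man, out)
  expect_equal(nrow(strat), 3 * 10 + 9)
  for (b in c("LD", "MD", "HD")) {
    expect_length(list.files(file.path(out, b, "benign")), 10L)
    expect_length(list.files(file.path(out, b, "malignant")), 3L)
  }
  # bins partition the malignant set
  malb <- strat$bin[strat$class == "malignant"]
  expect_equal(sort(as.vector(table(malb))), c(3L, 3L, 3L))
  # empty malignant set: bins hold only benign
  s2 <- build_stratified_layout(man[man$class == "benign", ])
  expect_equal(nrow(s2), 30L)
  expect_true(all(s2$class == "benign"))
  # missing bins on malignant rows error
  bad <- man; bad$bin <- NA
  expect_error(build_stratified_layout(bad), "bins")
})

test_that("70/15/15 split respects floors, residues-to-train, and the seed", {
  man <- data.frame(patch_id = sprintf("p%03d", 1:100), class = "malignant",
                    density = runif(100), bin = "LD",
                    split = NA_character_, stringsAsFactors = FALSE)
  s <- split_dataset(man, seed = 5)
  expect_equal(as.vector(table(factor(s$split, c("train", "val", "test")))),
               c(70L, 15L, 15L))
  s7 <- split_dataset(man[1:7, ], seed = 5)
  expect_equal(as.vector(table(factor(s7$split, c("train", "val", "test")))),
               c(5L, 1L, 1L))
  expect_identical(split_dataset(man, seed = 5)$split, s$split)
  expect_false(identical(split_dataset(man, seed = 6)$split, s$split))
  expect_error(split_dataset(man, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("stratification recovers the generator's intended bins from ground truth", {
  d <- stratification_demo_corpus(n_scenes = 45, seed = 13)
  counts <- vapply(d$masks, function(m)
    count_nuclei(m > 0, min_area = 10, connectivity = 8), 0L)
  area <- area_to_mm2(patch_area(160 * 0.1625, 160 * 0.1625))
  dens <- vapply(counts, nuclei_density, 0, a_mms = area)
  th <- compute_thresholds(dens)
  rec <- assign_bins(data.frame(a_d = dens), th)$bin
  expect_gte(mean(rec == d$intended_bin), 0.95)
})
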