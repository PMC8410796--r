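# Synthetic lesion dataset generator and binormal score generator.

test_that("generated datasets have exact counts, splits and artifacts", {
  cfg <- synth_config(n_pos = 20, n_neg = 80, image_height = 48,
                      image_width = 64, seed = 5)
  dir <- withr::local_tempdir()
  m <- generate_dataset(cfg, dir)
  expect_equal(nrow(m), 100L)
  expect_equal(sum(m$label == 1), 20L)
  expect_equal(sum(m$label == 0), 80L)
  # stratified 80/10/10 within rounding
  tab <- table(m$label, m$split)
  expect_equal(unname(tab["1", c("train", "val", "test")]), c(16, 2, 2))
  expect_equal(unname(tab["0", c("train", "val", "test")]), c(64, 8, 8))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "params.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(all(file.exists(file.path(dir, m$path))))
  img <- read_ppm(file.path(dir, m$path[1]))
  expect_equal(dim(img), c(48L, 64L, 3L))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("generation is deterministic in the seed", {
  cfg <- synth_config(n_pos = 3, n_neg = 7, image_height = 48,
                      image_width = 64, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_equal(m1$split, m2$split)
  expect_identical(read_ppm(file.path(d1, m1$path[1])),
                   read_ppm(file.path(d2, m2$path[1])))
  cfg2 <- synth_config(n_pos = 3, n_neg = 7, image_height = 48,
                       image_width = 64, seed = 12)
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(cfg2, d3)
  expect_false(identical(read_ppm(file.path(d1, m1$path[1])),
                         read_ppm(file.path(d3, m3$path[1]))))
})

test_that("separability controls the class signal in the drawn parameters", {
  dir0 <- withr::local_tempdir(); dir1 <- withr::local_tempdir()
  n <- 60
  generate_dataset(synth_config(n, n, 48, 64, separability = 0,
                                noise_level = 0.1, seed = 21), dir0)
  generate_dataset(synth_config(n, n, 48, 64, separability = 1,
                                noise_level = 0, seed = 21), dir1)
  read_pars <- function(d) {
    p <- readr::read_csv(file.path(d, "params.csv"), show_col_types = FALSE)
    m <- readr::read_csv(file.path(d, "manifest.csv"), show_col_types = FALSE)
    dplyr::left_join(m, p, by = "path")
  }
  p0 <- read_pars(dir0); p1 <- read_pars(dir1)
  feat_auc <- function(p, col) auc(plogis(p[[col]]), p$label)
  # identical class distributions at separability 0: chance-level feature AUC
  expect_lt(abs(feat_auc(p0, "irregularity") - 0.5), 0.12)
  expect_lt(abs(feat_auc(p0, "darkness") - 0.5), 0.12)
  # full separation: border irregularity alone is near-perfect
  expect_gt(feat_auc(p1, "irregularity"), 0.98)
  expect_gt(feat_auc(p1, "darkness"), 0.95)
  # and the rendered images carry the signal: mean darkness feature ordering
  m1 <- readr::read_csv(file.path(dir1, "manifest.csv"), show_col_types = FALSE)
  imgs <- load_images(m1, dir1)
  dark <- vapply(imgs, function(i) 1 - mean(i[, , 1]), 0)
  # diluted relative to the parameter-level signal by lesion size/position
  # variation, but clearly informative
  expect_gt(auc(plogis(10 * dark), m1$label), 0.75)
})

test_that("image-level class signal grows with separability", {
  aucs <- vapply(c(0, 0.5, 1), function(s) {
    d <- withr::local_tempdir()
    m <- generate_dataset(synth_config(30, 30, 48, 64, separability = s,
                                       noise_level = 0.1, seed = 33), d)
    imgs <- load_images(m, d)
    dark <- vapply(imgs, function(i) 1 - mean(i[, , 1]), 0)
    auc(plogis(10 * dark), m$label)
  }, 0)
  expect_true(all(diff(aucs) > -0.08))   # non-decreasing up to sampling noise
  expect_gt(aucs[3], aucs[1] + 0.2)
})

test_that("the benchmark fixture mirrors the 20/80 reader-study shape", {
  dir <- withr::local_tempdir()
  m <- generate_benchmark(dir, image_height = 48, image_width = 64)
  expect_equal(sum(m$label == 1), 20L)
  expect_equal(sum(m$label == 0), 80L)
  expect_true(all(m$split == "benchmark"))
})

test_that("binormal scores hit their target AUC", {
  # closed form: mu = sqrt(2) * qnorm(auc)
  expect_equal(sqrt(2) * qnorm(0.5), 0)
  d1 <- generate_scores(10, 10, 0.5, seed = 41)
  d2 <- generate_scores(10, 10, 0.5, seed = 41)
  expect_identical(d1, d2)
  big <- generate_scores(1e5, 1e5, 0.944, seed = 42)
  expect_lt(abs(auc(big$score, big$label) - 0.944), 0.01)
  expect_true(all(big$score > 0 & big$score < 1))
  expect_error(generate_scores(5, 5, 0.3), class = "melbalance_invalid_input")
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(0, 5), class = "melbalance_invalid_input")
  expect_error(synth_config(5, 5, separability = 2),
               class = "melbalance_invalid_input")
  cfg <- synth_config(2, 2, 48, 64, seed = 1)
  expect_error(generate_dataset(cfg, withr::local_tempdir(),
                                splits = c(train = 0.5)),
               class = "melbalance_invalid_input")
})
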