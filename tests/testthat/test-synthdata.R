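small_spec <- function(...) {
  args <- utils::modifyList(list(image_size = c(96L, 96L), seed = 11L),
                            list(...))
  do.call(scene_spec, args)
}

test_that("scene generation is deterministic and honestly labelled", {
  sp <- small_spec()
  s1 <- generate_scene(sp, 3L)
  s2 <- generate_scene(sp, 3L)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$boxes, s2$boxes)
  s3 <- generate_scene(sp, 4L)
  expect_false(identical(s1$image, s3$image))
  # labels inside the unit square with positive extent, valid class ids
  for (i in 1:6) {
    sc <- generate_scene(sp, i)
    b <- sc$boxes
    if (nrow(b)) {
      expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
      expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
      expect_true(all(b$w > 0 & b$h > 0))
      expect_true(all(b$class >= 0 & b$class < 4))
    }
    expect_true(all(sc$image >= 0L & sc$image <= 255L))
  }
})

test_that("an empty object range yields a background-only scene", {
  sp <- small_spec(n_objects = c(0L, 0L))
  sc <- generate_scene(sp, 1L)
  expect_identical(nrow(sc$boxes), 0L)
  expect_identical(dim(sc$image), c(96L, 96L, 3L))
})

test_that("long-run class frequencies follow the long-tailed simplex", {
  sp <- small_spec(image_size = c(64L, 64L), seed = 21L)
  counts <- numeric(4)
  for (i in 1:500) {
    b <- generate_scene(sp, i)$boxes
    if (nrow(b)) counts <- counts + tabulate(b$class + 1L, 4L)
  }
  freq <- counts / sum(counts)
  expect_true(all(abs(freq - sp$class_probs) < 0.02))
  # echinus dominates: the long tail the loss reweighting targets
  expect_identical(which.max(freq), 2L)
})

test_that("the red channel is attenuated relative to green and blue", {
  sp <- small_spec(seed = 31L, n_objects = c(0L, 0L))
  sc <- generate_scene(sp, 1L)
  expect_lt(mean(sc$image[, , 1]), 0.7 * mean(sc$image[, , 2]))
})

test_that("scene spec validates its fields", {
  expect_error(scene_spec(image_size = c(100L, 96L)), "32")
  expect_error(scene_spec(class_probs = c(0.5, 0.5, 0.2, 0.2)), "sum")
  expect_error(scene_spec(size_range = c(0.0001, 0.001)),
               "incompatible")
  expect_error(scene_spec(occlusion_prob = 1.5), "occlusion")
})

test_that("poisson noise scales inversely with the scale parameter", {
  img <- array(128L, c(16, 16, 3))
  set.seed(41)
  # huge scale: relative sd ~ 0, output ~ input
  out <- add_poisson_noise(img, 1e4)
  expect_lt(max(abs(out - img)), 3)
  # unbiasedness: mean over many replicates of one mid-gray pixel
  px <- array(128L, c(1, 1, 1))
  set.seed(42)
  draws <- replicate(1e4, as.numeric(add_poisson_noise(px, 1)))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 128), 3 * se + 0.5) # 0.5 for rounding
  # variance ordering: scale 0.1 is strictly noisier than 1.0
  set.seed(43)
  v_strong <- var(as.numeric(add_poisson_noise(img, 0.1)))
  v_weak <- var(as.numeric(add_poisson_noise(img, 1.0)))
  expect_gt(v_strong, v_weak)
  expect_error(add_poisson_noise(img, 0), "> 0")
})

test_that("gaussian noise has the stated sd and clips at the ceiling", {
  img <- array(128L, c(200, 250, 2))
  expect_identical(add_gaussian_noise(img, 0), img)
  set.seed(44)
  out <- add_gaussian_noise(img, 10)
  expect_lt(abs(sd(as.numeric(out)) - 10) / 10, 0.05)
  bright <- array(250L, c(100, 100, 1))
  set.seed(45)
  expect_lt(mean(add_gaussian_noise(bright, 20)), 250)
  expect_error(add_gaussian_noise(img, -1), ">= 0")
})

test_that("YOLO labels round-trip through the text format", {
  b <- data.frame(class = 1L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.1)
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(b, f)
  expect_identical(readLines(f), "1 0.500000 0.500000 0.200000 0.100000")
  b0 <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                   w = numeric(0), h = numeric(0))
  write_yolo_labels(b0, f)
  expect_identical(length(readLines(f)), 0L)
  set.seed(46)
  br <- data.frame(class = sample(0:3, 100, TRUE),
                   cx = runif(100), cy = runif(100),
                   w = runif(100), h = runif(100))
  write_yolo_labels(br, f)
  rb <- read_yolo_labels(f)
  expect_identical(rb$class, br$class)
  for (col in c("cx", "cy", "w", "h"))
    expect_lt(max(abs(rb[[col]] - br[[col]])), 1e-6)
  writeLines(c("0 0.1 0.1 0.2 0.2", "oops"), f)
  expect_error(read_yolo_labels(f), "line 2")
  unlink(f)
})

test_that("dataset splitting uses floor allocation and is seeded", {
  s10 <- split_dataset(10, seed = 1L)
  expect_identical(lengths(s10), c(train = 7L, val = 2L, test = 1L))
  s3 <- split_dataset(3, seed = 1L)
  expect_identical(lengths(s3), c(train = 2L, val = 0L, test = 1L))
  expect_identical(split_dataset(50, seed = 9L), split_dataset(50, seed = 9L))
  s <- split_dataset(23, seed = 2L)
  all_idx <- sort(c(s$train, s$val, s$test))
  expect_identical(all_idx, 1:23)
  expect_error(split_dataset(2), "at least 3")
})

test_that("dataset generation writes the YOLO directory layout", {
  sp <- small_spec(seed = 51L)
  dir <- tempfile("ds")
  generate_dataset(sp, 10, dir)
  expect_identical(length(list.files(file.path(dir, "images", "train"))), 7L)
  expect_identical(length(list.files(file.path(dir, "labels", "test"))), 1L)
  meta <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  expect_identical(meta$classes[2], "echinus")
  # images round-trip to the generated scenes
  f <- list.files(file.path(dir, "images", "val"), full.names = TRUE)[1]
  img <- png::readPNG(f)
  expect_identical(dim(img), c(96L, 96L, 3L))
  unlink(dir, recursive = TRUE)
})
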