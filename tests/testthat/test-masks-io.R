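test_that("label PNG round trip is exact, including large ids", {
  set.seed(11)
  lab <- random_label_map(20L)
  while (n_instances(lab) == 0L) lab <- random_label_map(20L)
  lab[lab > 0] <- lab[lab > 0] * 300L    # exceed 8-bit range
  f <- tempfile(fileext = ".png")
  write_label_png(lab, f)
  back <- read_label_png(f)
  # ids are compacted by first appearance but the partition is identical
  expect_equal(n_instances(back), n_instances(lab))
  expect_equal(symmetric_best_dice(back, lab), 1)
  expect_equal(back > 0, lab > 0)
})

test_that("image PNG round trip preserves values to 8-bit precision", {
  set.seed(12)
  img <- array(runif(16 * 16 * 3), c(16L, 16L, 3L))
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})

test_that("HDF5 labels are read through the python bridge", {
  m1 <- matrix(c(0L, 1L, 1L, 0L, 2L, 2L), 2, 3)
  m2 <- matrix(0:5, 3, 2)
  f <- tempfile(fileext = ".h5")
  write_h5_fixture(f, list(label = m1, extra = m2))
  got <- read_label_h5(f, "label")
  expect_equal(names(got), "label")
  expect_equal(unclass(got$label), m1, ignore_attr = TRUE)
  got2 <- read_label_h5(f, "extra")
  expect_true(all(got2$extra == m2))
  both <- read_label_h5(f)
  expect_equal(names(both), c("extra", "label"))  # lexicographic
  expect_error(read_label_h5(f, "nope"), "key")
})

test_that("polygon txt round trip is exact to 1e-6", {
  set.seed(13)
  recs <- lapply(1:3, function(i) {
    k <- sample(3:8, 1L)
    list(class_id = 0L, vertices = matrix(runif(2 * k), k, 2L))
  })
  ann <- polygon_annotation(recs, image_id = "t")
  f <- tempfile(fileext = ".txt")
  write_annotation_txt(ann, f)
  back <- read_annotation_txt(f)
  expect_equal(length(back$records), 3L)
  for (i in 1:3) {
    expect_equal(back$records[[i]]$class_id, recs[[i]]$class_id)
    expect_lt(max(abs(back$records[[i]]$vertices - recs[[i]]$vertices)), 1e-6)
  }
})

test_that("malformed annotation lines are rejected with line numbers", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("0 0.1 0.1 0.9 0.1 0.5 0.9", "0 0.1 0.2 0.3"), f)
  expect_error(read_annotation_txt(f), "line 2")
  writeLines("0 0.1 zap 0.9 0.1 0.5 0.9", f)
  expect_error(read_annotation_txt(f), "line 1")
})

test_that("mask -> polygon -> mask keeps per-instance Dice at 0.95+ on convex shapes", {
  # convex instances of radius >= 10 px on a 512 x 512 canvas
  set.seed(14)
  for (trial in 1:2) {
    lab <- convex_label_map()
    ann <- mask_to_polygons(lab)
    back <- polygons_to_mask(ann, nrow(lab), ncol(lab))
    for (i in instance_ids(lab))
      expect_gte(dice_score(back == i, lab == i), 0.95)
  }
})

test_that("split takes every fourth file after sorting", {
  files <- sprintf("img_%03d.png", 1:8)
  sp <- split_file_list(sample(files))
  expect_equal(sp$val, files[c(4L, 8L)])
  expect_equal(sp$train, files[-c(4L, 8L)])
  sp4 <- split_file_list(files[1:4])
  expect_equal(length(sp4$train), 3L)
  expect_equal(length(sp4$val), 1L)
  sp100 <- split_file_list(sprintf("f%03d", 1:100))
  expect_equal(length(sp100$train), 75L)
  expect_equal(length(sp100$val), 25L)
  expect_equal(split_file_list(character(0)),
               list(train = character(0), val = character(0)))
})

test_that("resize_pair keeps labels integral and image in range", {
  set.seed(15)
  sc <- generate_rosette(rosette_config(size = 64L, k_range = c(3L, 5L),
                                        blur_sigma = c(0, 0), seed = 99))
  rp <- resize_pair(sc$image, sc$labels, 32L)
  expect_equal(dim(rp$image), c(32L, 32L, 3L))
  expect_equal(dim(rp$labels), c(32L, 32L))
  expect_true(is.integer(unclass(rp$labels)[1, 1]) || all(rp$labels == round(rp$labels)))
  expect_true(all(rp$labels %in% c(0L, instance_ids(sc$labels))))
  expect_true(min(rp$image) >= 0 && max(rp$image) <= 1)
})
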