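sample_scene <- function(seed, size = 64L) {
  sc <- generate_rosette(rosette_config(size = size, k_range = c(3L, 6L),
                                        blur_sigma = c(0, 0), seed = seed))
  list(image = sc$image,
       ann = suppressWarnings(mask_to_polygons(sc$labels)),
       labels = sc$labels)
}

check_ann_invariants <- function(ann) {
  expect_s3_class(ann, "polygon_annotation")
  for (r in ann$records) {
    expect_true(is.matrix(r$vertices) && ncol(r$vertices) == 2L)
    expect_gte(nrow(r$vertices), 3L)
    expect_true(all(r$vertices >= -1e-9 & r$vertices <= 1 + 1e-9))
  }
}

test_that("augmentation invariants hold over 50 seeded samples", {
  base <- sample_scene(1001)
  pool <- lapply(2:5, function(i) {
    s <- sample_scene(1000 + i); list(image = s$image, ann = s$ann)
  })
  cfg <- augment_config()
  for (i in 1:50) {
    set.seed(5000 + i)
    out <- augment_sample(base$image, base$ann, cfg, pool = pool)
    # image stays the working size with values in range
    expect_equal(dim(out$image), dim(base$image))
    expect_true(min(out$image) >= 0 && max(out$image) <= 1)
    check_ann_invariants(out$ann)
    # no instance is created out of thin air beyond the mosaic source count
    max_src <- length(base$ann$records) +
      sum(vapply(pool, function(p) length(p$ann$records), 0L))
    expect_lte(length(out$ann$records), max_src)
  }
})

test_that("augmentation replays bit-identically under a fixed seed", {
  s <- sample_scene(1010)
  cfg <- augment_config()
  pool <- lapply(1:3, function(i) {
    p <- sample_scene(1020 + i); list(image = p$image, ann = p$ann)
  })
  set.seed(77)
  a <- augment_sample(s$image, s$ann, cfg, pool = pool)
  set.seed(77)
  b <- augment_sample(s$image, s$ann, cfg, pool = pool)
  expect_identical(a$image, b$image)
  expect_equal(length(a$ann$records), length(b$ann$records))
  for (i in seq_along(a$ann$records))
    expect_equal(a$ann$records[[i]]$vertices, b$ann$records[[i]]$vertices)
})

test_that("flips move polygon vertices coherently with the image", {
  s <- sample_scene(1030)
  set.seed(1)
  fl <- flip_sample(s$image, s$ann, "lr", p = 1)
  expect_equal(fl$image[, ncol(s$image):1, , drop = FALSE][, , ],
               s$image[, , ])
  v0 <- s$ann$records[[1L]]$vertices
  v1 <- fl$ann$records[[1L]]$vertices
  expect_equal(v1[, 1L], 1 - v0[, 1L])
  expect_equal(v1[, 2L], v0[, 2L])
  # rasterized flip equals flipped raster
  m0 <- suppressWarnings(polygons_to_mask(s$ann, 64L, 64L))
  m1 <- suppressWarnings(polygons_to_mask(fl$ann, 64L, 64L))
  expect_gt(symmetric_best_dice(m1, m0[, 64:1]), 0.95)
})

test_that("identity affine keeps image and annotation unchanged", {
  s <- sample_scene(1040)
  id <- list(angle = 0, tx = 0, ty = 0, s = 1)
  out <- affine_sample(s$image, s$ann, augment_config(), params = id)
  expect_equal(out$image, s$image, tolerance = 1e-8)
  expect_equal(length(out$ann$records), length(s$ann$records))
  for (i in seq_along(out$ann$records))
    expect_equal(out$ann$records[[i]]$vertices, s$ann$records[[i]]$vertices,
                 tolerance = 1e-8)
})

test_that("affine drops instances that leave the canvas", {
  s <- sample_scene(1050)
  far <- list(angle = 0, tx = 1000, ty = 1000, s = 1)
  out <- affine_sample(s$image, s$ann, augment_config(), params = far)
  expect_equal(length(out$ann$records), 0L)
})

test_that("hsv jitter stays in gamut and is value-only when disabled", {
  s <- sample_scene(1060)
  cfg0 <- augment_config(hsv_h = 0, hsv_s = 0, hsv_v = 0)
  set.seed(2)
  expect_equal(hsv_jitter(s$image, cfg0), s$image, tolerance = 1e-7)
  cfg1 <- augment_config()
  for (i in 1:5) {
    j <- hsv_jitter(s$image, cfg1)
    expect_true(min(j) >= 0 && max(j) <= 1)
  }
})

test_that("mosaic composes exactly four samples and renormalizes", {
  ss <- lapply(1:4, function(i) {
    s <- sample_scene(1070 + i); list(image = s$image, ann = s$ann)
  })
  set.seed(3)
  mo <- mosaic4(ss)
  expect_equal(dim(mo$image)[1:2], 2L * dim(ss[[1]]$image)[1:2])
  check_ann_invariants(mo$ann)
  expect_error(mosaic4(ss[1:3]), "4")
})

test_that("random erase fills a rectangle and leaves the rest untouched", {
  s <- sample_scene(1080)
  cfg <- augment_config(erasing = 1, use_erasing = TRUE)
  set.seed(4)
  out <- random_erase(s$image, cfg)
  diff <- which(apply(out != s$image, c(1, 2), any), arr.ind = TRUE)
  expect_gt(nrow(diff), 0L)
  # changed pixels form one axis-aligned rectangle
  expect_equal(sort(unique(diff[, 1L])),
               seq(min(diff[, 1L]), max(diff[, 1L])))
  expect_equal(sort(unique(diff[, 2L])),
               seq(min(diff[, 2L]), max(diff[, 2L])))
})
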