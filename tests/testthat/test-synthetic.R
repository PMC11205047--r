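test_that("rosette generation is deterministic under a seed", {
  cfg <- rosette_config(size = 64L, k_range = c(4L, 8L), seed = 31L)
  a <- generate_rosette(cfg)
  b <- generate_rosette(cfg)
  expect_identical(a$image, b$image)
  expect_identical(unclass(a$labels), unclass(b$labels))
  c <- generate_rosette(cfg, seed = 32L)
  expect_false(identical(unclass(a$labels), unclass(c$labels)))
})

test_that("labels are valid maps with ids 1..K and leaves overlap center", {
  for (s in c(51L, 52L, 53L)) {
    sc <- generate_rosette(rosette_config(size = 64L, seed = s,
                                          k_range = c(5L, 10L)))
    ids <- instance_ids(sc$labels)
    expect_equal(ids, seq_along(ids))
    expect_gte(length(ids), 1L)
    # every surviving leaf holds at least one pixel
    expect_true(all(tabulate(sc$labels[sc$labels > 0]) > 0))
    expect_true(min(sc$image) >= 0 && max(sc$image) <= 1)
  }
})

test_that("mean leaf count stays near the configured range midpoint", {
  cfg <- rosette_config(size = 96L, k_range = c(5L, 30L), seed = 61L)
  counts <- vapply(1:40, function(i)
    n_instances(generate_rosette(cfg, seed = 6100L + i)$labels), 0L)
  mid <- mean(c(5, 30))
  expect_gt(mean(counts), mid * 0.9)
  expect_lt(mean(counts), mid * 1.1)
  expect_true(all(counts >= 1L & counts <= 30L))
})

test_that("generated scenes score perfectly against themselves", {
  sc <- generate_rosette(rosette_config(size = 64L, seed = 71L))
  rep <- evaluate_dataset(list(list(ar = sc$labels, gt = sc$labels)))
  expect_equal(rep$aggregate[["SBD"]], 100)
  expect_equal(rep$aggregate[["FGBGDice"]], 100)
  expect_equal(rep$aggregate[["AbsDiffFG"]], 0)
})

test_that("generate_dataset writes a consistent, reloadable directory", {
  dir <- tempfile("ds")
  # wider leaves: sub-3-px-wide structures cannot survive the pixel-center
  # polygon representation, which is not what this test is about
  cfg <- rosette_config(size = 64L, k_range = c(3L, 6L),
                        leaf_len = c(0.25, 0.45) * 64,
                        leaf_width = c(0.08, 0.16) * 64,
                        blur_sigma = c(0, 0), seed = 81L)
  man <- generate_dataset(cfg, 3L, dir)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$image), file.exists(man$label),
                  file.exists(man$annotation)))
  lab <- read_label_png(man$label[2L])
  expect_equal(n_instances(lab), man$n_leaves[2L])
  # polygon files rasterize back close to the label maps
  ann <- read_annotation_txt(man$annotation[2L])
  back <- suppressWarnings(polygons_to_mask(ann, 64L, 64L))
  expect_gt(symmetric_best_dice(back, lab), 0.9)
  # regeneration with the same seed is identical
  dir2 <- tempfile("ds")
  generate_dataset(cfg, 3L, dir2)
  expect_identical(readBin(man$image[1L], "raw", 1e6),
                   readBin(file.path(dir2, basename(man$image[1L])), "raw", 1e6))
})
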