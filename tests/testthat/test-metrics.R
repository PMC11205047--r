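test_that("dice_score handles the empty-mask conventions", {
  e <- matrix(FALSE, 3, 3)
  f <- matrix(TRUE, 3, 3)
  expect_equal(dice_score(e, e), 1)
  expect_equal(dice_score(e, f), 0)
  expect_equal(dice_score(f, e), 0)
  expect_equal(dice_score(f, f), 1)
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
  expect_equal(dice_score(a, b), 0.5)
})

test_that("metrics match the brute-force oracle on random maps", {
  set.seed(101)
  for (i in 1:60) {
    ar <- random_label_map()
    g2 <- matrix(sample(0:5, length(ar), replace = TRUE),
                 nrow(ar), ncol(ar))
    expect_equal(best_dice(ar, g2), oracle_best_dice(ar, g2))
    expect_equal(symmetric_best_dice(ar, g2), oracle_sbd(ar, g2))
    expect_equal(fgbg_dice(ar, g2), oracle_fgbg(ar, g2))
  }
})

test_that("identity scoring and count metrics", {
  set.seed(7)
  gt <- random_label_map()
  while (n_instances(gt) < 2L) gt <- random_label_map()
  expect_equal(best_dice(gt, gt), 1)
  expect_equal(symmetric_best_dice(gt, gt), 1)
  expect_equal(fgbg_dice(gt, gt), 1)
  expect_equal(diff_fg(gt, gt), 0L)
  empty <- matrix(0L, nrow(gt), ncol(gt))
  expect_equal(diff_fg(empty, gt), -n_instances(gt))
  expect_equal(abs_diff_fg(empty, gt), n_instances(gt))
  expect_equal(best_dice(empty, gt), 0)
  expect_equal(symmetric_best_dice(empty, gt), 0)
})

test_that("SBD symmetry and label-permutation invariance", {
  set.seed(55)
  for (i in 1:10) {
    ar <- random_label_map(); gt <- random_label_map()
    g2 <- matrix(0L, nrow(ar), ncol(ar))
    s <- gt[seq_len(min(nrow(gt), nrow(ar))), seq_len(min(ncol(gt), ncol(ar))), drop = FALSE]
    g2[seq_len(nrow(s)), seq_len(ncol(s))] <- s
    expect_equal(symmetric_best_dice(ar, g2), symmetric_best_dice(g2, ar))
    # relabel ar ids by a random bijection
    ids <- instance_ids(ar)
    if (length(ids)) {
      newids <- sample(1000:2000, length(ids))
      ar2 <- ar
      for (k in seq_along(ids)) ar2[ar == ids[k]] <- newids[k]
      expect_equal(symmetric_best_dice(ar2, g2), symmetric_best_dice(ar, g2))
      expect_equal(best_dice(ar2, g2), best_dice(ar, g2))
    }
  }
})

test_that("the under-segmentation textbook case gives SBD 2/3", {
  gt <- matrix(0L, 4, 4); gt[, 1:2] <- 1L; gt[, 3:4] <- 2L
  ar <- matrix(1L, 4, 4)
  expect_equal(best_dice(ar, gt), 2 / 3)
  expect_equal(best_dice(gt, ar), 2 / 3)
  expect_equal(symmetric_best_dice(ar, gt), 2 / 3)
})

test_that("evaluate_dataset aggregates by unweighted mean and prints ALL row", {
  gt1 <- matrix(0L, 6, 6); gt1[2:3, 2:3] <- 1L
  gt2 <- matrix(0L, 6, 6); gt2[2:5, 2:5] <- 1L; gt2[1, 1] <- 2L
  rep <- evaluate_dataset(list(list(ar = gt1, gt = gt1),
                               list(ar = matrix(0L, 6, 6), gt = gt2)))
  expect_s3_class(rep, "metric_report")
  expect_equal(nrow(rep$per_image), 2L)
  expect_equal(rep$aggregate[["SBD"]],
               mean(c(100, 0)))
  expect_equal(rep$aggregate[["AbsDiffFG"]], mean(c(0, 2)))
  out <- capture.output(print(rep))
  expect_true(any(grepl("ALL", out)))
  frac <- evaluate_dataset(list(list(ar = gt1, gt = gt1)), scale = "fraction")
  expect_equal(frac$aggregate[["BD"]], 1)
})

test_that("shape mismatches are rejected", {
  expect_error(best_dice(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(dice_score(matrix(TRUE, 2, 2), matrix(TRUE, 2, 3)), "shape")
})
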