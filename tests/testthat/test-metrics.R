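test_that("confusion counts match trivial cases and a voxel-loop census", {
  pr <- random_grid_pair(1, 8)
  cc <- confusion(pr$a, pr$b)
  bf <- bf_confusion(pr$a, pr$b)
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), unname(bf))

  same <- confusion(pr$a, pr$a)
  expect_equal(same$FP, 0); expect_equal(same$FN, 0)

  compl <- pr$a
  compl$occupancy <- !pr$a$occupancy
  cc2 <- confusion(compl, pr$a)
  expect_equal(cc2$TP, 0); expect_equal(cc2$TN, 0)

  other <- random_grid_pair(2, 10)$a
  expect_error(confusion(pr$a, other), "frame")
})

test_that("overlap ratios follow their definitions", {
  cc <- structure(list(TP = 3, FP = 1, FN = 2, TN = 10),
                  class = "confusion_counts")
  expect_equal(jaccard(cc), 0.5)
  ssp <- sens_spec_prec(cc)
  expect_equal(unname(ssp["sensitivity"]), 0.6)
  expect_equal(unname(ssp["precision"]), 0.75)
  expect_equal(unname(ssp["specificity"]), 10 / 11)

  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = 16),
                     class = "confusion_counts")
  expect_true(is.na(jaccard(empty)))
  expect_true(is.na(sens_spec_prec(empty)["precision"]))
})

test_that("adjusted Rand matches pair counting and its known anchors", {
  pr <- random_grid_pair(3, 8)
  expect_equal(adjusted_rand(confusion(pr$a, pr$b)),
               bf_adjusted_rand(pr$a, pr$b), tolerance = 1e-12)
  expect_equal(adjusted_rand(confusion(pr$a, pr$a)), 1)

  big <- random_grid_pair(5, 32, p = 0.5)
  expect_lt(abs(adjusted_rand(confusion(big$a, big$b))), 0.01)

  full <- voxel_grid(pr$a$frame, array(TRUE, rep(8, 3)))
  expect_true(is.na(adjusted_rand(confusion(full, full))))
})

test_that("mutual information in bits follows the closed forms", {
  fr <- grid_frame(c(0, 0, 0), 1, 4)
  half1 <- array(rep(c(TRUE, FALSE), each = 32), rep(4, 3))
  a <- voxel_grid(fr, half1)
  expect_equal(mutual_information(confusion(a, a)), 1)  # (0.5, 0, 0, 0.5)

  quarter <- voxel_grid(fr, array(rep(c(TRUE, FALSE), 32), rep(4, 3)))
  expect_equal(mutual_information(confusion(a, quarter)), 0)  # independent

  pr <- random_grid_pair(6, 8)
  p <- mean(pr$a$occupancy)
  expect_equal(mutual_information(confusion(pr$a, pr$a)),
               -p * log2(p) - (1 - p) * log2(1 - p), tolerance = 1e-12)
  expect_equal(mutual_information(confusion(pr$a, pr$b)),
               bf_mutual_information(pr$a, pr$b), tolerance = 1e-12)
})

test_that("voxel Hausdorff equals all-pairs brute force and is a metric", {
  pr <- random_grid_pair(7, 16)
  expect_equal(hausdorff(pr$a, pr$b), bf_hausdorff(pr$a, pr$b), tolerance = 1e-9)
  expect_equal(hausdorff(pr$a, pr$a), 0)
  expect_equal(hausdorff(pr$a, pr$b), hausdorff(pr$b, pr$a))

  fr <- grid_frame(c(0, 0, 0), 1, 8)
  o1 <- array(FALSE, rep(8, 3)); o1[2, 4, 4] <- TRUE
  o2 <- array(FALSE, rep(8, 3)); o2[5, 4, 4] <- TRUE
  expect_equal(hausdorff(voxel_grid(fr, o1), voxel_grid(fr, o2)), 3)

  empty <- voxel_grid(fr, array(FALSE, rep(8, 3)))
  expect_error(hausdorff(voxel_grid(fr, o1), empty), "undefined")

  # triangle inequality over random triples
  for (s in 1:5) {
    g1 <- random_grid_pair(100 + s, 8)
    g2 <- random_grid_pair(200 + s, 8)$a
    d12 <- hausdorff(g1$a, g1$b)
    d13 <- hausdorff(g1$a, g2)
    d23 <- hausdorff(g1$b, g2)
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("vertexwise RMSE needs index correspondence", {
  blob <- random_blob(9)
  expect_equal(unname(rmse_vertices(blob, blob)["rmse"]), 0)
  moved <- blob
  moved$vertices <- moved$vertices + matrix(c(3, 4, 0), nrow(blob$vertices), 3,
                                            byrow = TRUE)
  r <- rmse_vertices(moved, blob)
  expect_equal(unname(r["rmse"]), 5)
  expect_equal(unname(r["mse"]), 25)
  expect_error(rmse_vertices(blob, icosphere(3)), "cannot be calculated")
})

test_that("set-algebra bounds hold on random grids", {
  for (s in 1:10) {
    pr <- random_grid_pair(300 + s, 8)
    cc <- confusion(pr$a, pr$b)
    j <- jaccard(cc)
    ssp <- sens_spec_prec(cc)
    expect_lte(j, ssp["sensitivity"] + 1e-12)
    expect_lte(j, ssp["precision"] + 1e-12)
    # symmetry of the symmetric metrics
    cc_r <- confusion(pr$b, pr$a)
    expect_equal(jaccard(cc_r), j)
    expect_equal(adjusted_rand(cc_r), adjusted_rand(cc))
    expect_equal(mutual_information(cc_r), mutual_information(cc))
  }
})

test_that("the metric report carries undefined markers, not zeros", {
  pr <- random_grid_pair(11, 8)
  mr <- metric_report(pr$a, pr$b)
  expect_true(is.finite(mr$hausdorff_vox))
  expect_true(is.na(mr$rmse_mm))   # no meshes supplied
  mr2 <- metric_report(pr$a, pr$b, test_mesh = random_blob(1),
                       ref_mesh = icosphere(3))
  expect_true(is.na(mr2$rmse_mm))
  expect_match(mr2$rmse_note, "correspondence")
})
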