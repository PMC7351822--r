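# Driver contract tests run on a small scene (coarse lattice, 64^3 grids)
# to stay fast; the study-scale runs live in the acceptance suite.

small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_indentation(make_phantom(seed = 21, n_cells = 5))
    cache
  }
})

test_that("the orientation driver emits the fixed row layout plus baseline", {
  sc <- small_scene()
  rep1 <- run_orientation(as_experiment_dataset(sc),
                          registration_params("insilico"), grid_n = 64)
  expect_equal(rep1$rows$label,
               c("Full", "XZ", "XZ-hemi", "YZ", "YZ-hemi", "XY", "XY-hemi",
                 "baseline"))
  reg_rows <- rep1$rows[1:7, ]
  base_hd <- rep1$rows$hausdorff_vox[8]
  expect_gte(sum(base_hd > reg_rows$hausdorff_vox), 6)
  expect_equal(rep1$rows$area_percent[1], 100)
  expect_true(all(reg_rows$area_percent[2:7] < 100))
  hemi <- reg_rows$area_percent[c(3, 5, 7)]
  plain <- reg_rows$area_percent[c(2, 4, 6)]
  expect_true(all(hemi < plain))
})

test_that("the mesh-quality driver orders areas none >= (a) >= (b)", {
  sc <- small_scene()
  view <- crop_partial_view(sc$deformed_surface, c(0, -1, 0), 0.45)
  corr <- corrupt_surface(view, noise_sigma = 0.3, n_duplicates = 10,
                          n_fins = 3, n_holes = 2, n_blisters = 2,
                          blister_offset = 10, n_ghosts = 2, seed = 21)
  rep2 <- run_mesh_quality(as_experiment_dataset(sc), corr,
                           registration_params("insilico"), grid_n = 64)
  expect_equal(rep2$rows$label, c("none", "a", "b"))
  a <- rep2$rows$area_percent
  expect_gte(a[1], a[2]); expect_gte(a[2], a[3])
  mb <- rep2$provenance$manifold$b
  expect_equal(mb$n_nonmanifold_edges, 0L)
  expect_equal(mb$n_nonmanifold_vertices, 0L)
})

test_that("the surface-size driver sweeps, skips and self-checks", {
  sc <- small_scene()
  view <- crop_partial_view(sc$deformed_surface, c(0, -1, 0), 0.45)
  repaired <- strategy_b(corrupt_surface(view, n_fins = 2, n_holes = 1,
                                         seed = 21), max_loop_edges = 32)
  rep3 <- run_surface_size(as_experiment_dataset(sc), repaired,
                           registration_params("insilico"), count = 6,
                           grid_n = 64)
  expect_equal(nrow(rep3$rows), 6)
  done <- !rep3$rows$skipped
  expect_true(all(diff(rep3$rows$area_percent) >= -1e-9))
  # last bisection is the whole repaired target: area fractions agree
  expect_equal(rep3$rows$area_percent[6],
               area_percent(repaired, sc$deformed_surface), tolerance = 1e-9)
  expect_true(is.finite(rep3$provenance$min_area_percent))
})

test_that("summary statistics follow the reporting conventions", {
  rows <- data.frame(label = rep(c("A", "B"), each = 3),
                     area_percent = c(10, 20, 30, 40, 50, 60),
                     hausdorff_vox = c(9, 8, 7, 4, 3, 2),
                     jaccard = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                     adjusted_rand = 0.5, mutual_information_bits = 0.5,
                     sensitivity = 0.5, specificity = 0.5, precision = 0.5)
  rep_ <- structure(list(rows = rows, dataset = "toy", params = NULL,
                         provenance = list()), class = "experiment_report")
  s <- summarize_experiments(rep_)
  expect_lt(s$anova_p, 0.05)
  jrow <- s$correlations[s$correlations$metric == "jaccard", ]
  expect_equal(jrow$r, 1, tolerance = 1e-12)   # perfectly linear in area
  expect_true(jrow$significant)

  const <- rows; const$hausdorff_vox <- 5
  rep_c <- structure(list(rows = const, dataset = "toy", params = NULL,
                          provenance = list()), class = "experiment_report")
  sc_ <- summarize_experiments(rep_c, t_mu = 5)
  expect_equal(sc_$t_test$p, 1)
  expect_false(sc_$t_test$significant)
})

test_that("repairing the corrupted view never hurts the registration", {
  # strategy (b) removes the misleading stitching defects; its row must
  # score at least the raw corrupted row's Jaccard on every seed
  for (seed in 1:3) {
    sc <- get_scene(seed)
    view <- crop_partial_view(sc$deformed_surface, c(0, -1, 0), 0.45)
    corr <- corrupt_default(view, seed = seed)
    rep2 <- run_mesh_quality(as_experiment_dataset(sc), corr,
                             registration_params("insilico"), grid_n = 128)
    r <- rep2$rows
    expect_gte(r$jaccard[r$label == "b"], r$jaccard[r$label == "none"])
    expect_gte(r$area_percent[1], r$area_percent[2])
    expect_gte(r$area_percent[2], r$area_percent[3])
  }
})

test_that("reports are reproducible bit for bit", {
  sc <- small_scene()
  ds <- as_experiment_dataset(sc)
  p <- registration_params("insilico", iterations = 10)
  r1 <- run_orientation(ds, p, grid_n = 48)
  r2 <- run_orientation(ds, p, grid_n = 48)
  expect_identical(r1$rows, r2$rows)
})
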