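test_that("surface area matches closed forms", {
  expect_equal(surface_area(unit_cube_mesh()), 6)
  sph <- icosphere(4)
  expect_lt(abs(surface_area(sph) - 4 * pi) / (4 * pi), 0.005)
  # degenerate face contributes zero
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), matrix(1:3, 1))
  expect_equal(surface_area(m), 0)
})

test_that("area percentage helper is relative to the reference mesh", {
  cube <- unit_cube_mesh()
  pos <- bisect_plane(cube, axis = "z", keep = "positive")
  neg <- bisect_plane(cube, axis = "z", keep = "negative")
  expect_equal(area_percent(cube, cube), 100)
  expect_equal(area_percent(pos, cube) + area_percent(neg, cube), 100,
               tolerance = 1e-9)
})

test_that("surface centroid is area-weighted, symmetric and equivariant", {
  cube <- unit_cube_mesh()
  cube$vertices <- cube$vertices - 0.5  # origin-centred
  expect_equal(surface_centroid(cube), c(0, 0, 0), tolerance = 1e-9)
  t <- c(3.2, -1.5, 7)
  shifted <- cube
  shifted$vertices <- shifted$vertices + matrix(t, nrow(cube$vertices), 3, byrow = TRUE)
  expect_equal(surface_centroid(shifted), t, tolerance = 1e-9)

  blob <- random_blob(11)
  mc <- mc_surface_centroid(blob)
  expect_true(all(abs(surface_centroid(blob) - mc$mean) < 3 * mc$se + 1e-9))

  empty <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), matrix(1:3, 1))
  expect_error(surface_centroid(empty), "degenerate")
})

test_that("bisection splits a symmetric mesh in half and conserves area", {
  sph <- icosphere(3)
  for (ax in c("x", "y", "z")) {
    half <- bisect_plane(sph, axis = ax, keep = "positive")
    expect_lt(abs(area_percent(half, sph) - 50), 0.5)
  }
  for (seed in 1:10) {
    blob <- random_blob(seed)
    pos <- bisect_plane(blob, axis = "y", keep = "positive")
    neg <- bisect_plane(blob, axis = "y", keep = "negative")
    expect_lt(abs(surface_area(pos) + surface_area(neg) - surface_area(blob)) /
                surface_area(blob), 1e-6)
  }
})

test_that("hemi bisection re-centres the cutting plane on the retained half", {
  blob <- random_blob(3)
  hemi <- bisect_plane(blob, axis = "y", keep = "positive", iterations = 2)
  plain <- bisect_plane(blob, axis = "y", keep = "positive")
  # second cut goes through the half's own centroid, not the original plane
  manual <- bisect_plane(plain, axis = "y", keep = "positive")
  expect_equal(surface_area(hemi), surface_area(manual), tolerance = 1e-12)
  expect_lt(surface_area(hemi), surface_area(plain))
})

test_that("keep = larger retains the bigger half", {
  blob <- random_blob(5)
  larger <- bisect_plane(blob, axis = "z", keep = "larger")
  pos <- bisect_plane(blob, axis = "z", keep = "positive")
  neg <- bisect_plane(blob, axis = "z", keep = "negative")
  expect_equal(surface_area(larger), max(surface_area(pos), surface_area(neg)),
               tolerance = 1e-12)
})

test_that("stepwise bisections grow monotonically and match a clip oracle", {
  cube <- unit_cube_mesh()
  cube$vertices <- cube$vertices * 10
  expect_warning(parts <- stepwise_bisections(cube, "y", step = 5, count = 2),
                 regexp = NA)
  areas <- vapply(parts, surface_area, numeric(1))
  expect_lt(areas[1], areas[2])
  expect_equal(areas[2], surface_area(cube))

  blob <- random_blob(7)
  bb <- range(blob$vertices[, 2])
  s <- diff(bb) / 6
  parts <- stepwise_bisections(blob, "y", step = s, count = 6)
  areas <- vapply(parts, surface_area, numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
  for (k in c(2, 4)) {
    oracle <- bf_clipped_area(blob, 2L, bb[1] + k * s)
    expect_lt(abs(areas[k] - oracle) / surface_area(blob), 1e-6)
  }
  # final cut beyond the box returns the input unchanged
  expect_identical(parts[[6]]$faces, blob$faces)
})

test_that("boundary extraction yields closed outward-oriented surfaces", {
  expect_equal(nrow(boundary_surface(single_tet())$faces), 4)
  expect_equal(nrow(boundary_surface(two_tets())$faces), 6)

  vol <- make_phantom(seed = 2, n_cells = 4)$initial_volume
  b <- boundary_surface(vol)
  ec <- table(apply(rbind(b$faces[, 1:2], b$faces[, 2:3], b$faces[, c(3, 1)]),
                    1, function(e) paste(sort(e), collapse = "_")))
  expect_true(all(ec == 2))  # closed 2-manifold: every edge on exactly 2 faces
  # outward orientation: signed volume from the divergence theorem is positive
  v <- b$vertices; f <- b$faces
  svol <- sum((v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3 *
                hepareg:::face_normals_raw(b)[, 1]) / 2
  expect_gt(svol, 0)
})

test_that("tetrahedra are re-oriented to positive volume on construction", {
  tm <- tet_mesh(single_tet()$nodes, matrix(c(1L, 2L, 4L, 3L), 1))
  expect_gt(sum(hepareg:::tet_signed_volumes(tm$nodes, tm$tets)), 0)
})
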