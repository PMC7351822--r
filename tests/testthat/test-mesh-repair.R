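test_that("a clean closed surface reports all-clear", {
  r <- manifold_report(icosphere(2))
  expect_equal(r$n_duplicate_vertices, 0L)
  expect_equal(r$n_nonmanifold_edges, 0L)
  expect_equal(r$n_nonmanifold_vertices, 0L)
  expect_equal(r$n_boundary_loops, 0L)
  expect_equal(r$n_components, 1L)
})

test_that("the defining non-manifold configurations are detected", {
  # three triangles sharing one edge
  fin <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                             c(0, 0, 1)),
                       rbind(c(1, 2, 3), c(1, 4, 2), c(1, 2, 5)))
  expect_equal(manifold_report(fin)$n_nonmanifold_edges, 1L)

  # two fans connected only by a vertex, not by an edge
  bowtie <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                c(-1, 0, 0), c(-1, -1, 0)),
                          rbind(c(1, 2, 3), c(1, 4, 5)))
  expect_equal(manifold_report(bowtie)$n_nonmanifold_vertices, 1L)

  # exact duplicate vertex records
  dup <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
                       matrix(1:3, 1))
  expect_equal(manifold_report(dup)$n_duplicate_vertices, 1L)
  expect_equal(manifold_report(dup)$n_isolated_vertices, 1L)
})

test_that("strategy (a) welds, drops junk, keeps the largest component", {
  sph <- icosphere(2)
  expect_identical(strategy_a(sph)$faces, sph$faces)  # fixpoint on clean input

  # cube plus a far-away floating triangle
  cube <- unit_cube_mesh()
  v <- rbind(cube$vertices, c(50, 50, 50), c(51, 50, 50), c(50, 51, 50))
  f <- rbind(cube$faces, c(9L, 10L, 11L))
  out <- strategy_a(triangle_mesh(v, f))
  expect_equal(nrow(out$faces), 12)
  expect_equal(nrow(out$vertices), 8)

  # duplicates injected by the corruption generator are welded away
  view <- icosphere(2)
  corr <- corrupt_surface(view, n_duplicates = 7, seed = 9)
  expect_equal(nrow(corr$vertices), nrow(view$vertices) + 7)
  expect_equal(nrow(strategy_a(corr)$vertices), nrow(view$vertices))
})

test_that("strategy (b) restores a closed 2-manifold", {
  sph <- icosphere(2)
  expect_identical(strategy_b(sph)$faces, sph$faces)

  # sphere with one face removed: hole filled, Euler characteristic 2
  holed <- triangle_mesh(sph$vertices, sph$faces[-17, , drop = FALSE])
  fixed <- strategy_b(holed)
  r <- manifold_report(fixed)
  expect_equal(r$n_boundary_loops, 0L)
  expect_equal(r$n_nonmanifold_edges, 0L)
  V <- nrow(fixed$vertices)
  E <- nrow(unique(hepareg:::undirected_edges(fixed$faces), MARGIN = 1))
  F_ <- nrow(fixed$faces)
  expect_equal(V - E + F_, 2)
})

test_that("both strategies are idempotent and never gain area beyond fills", {
  scene <- make_phantom(seed = 6, n_cells = 4)
  corr <- corrupt_default(boundary_surface(scene$initial_volume), seed = 6)
  a1 <- strategy_a(corr); a2 <- strategy_a(a1)
  expect_identical(a1$vertices, a2$vertices)
  expect_identical(a1$faces, a2$faces)
  b1 <- strategy_b(corr); b2 <- strategy_b(b1)
  expect_identical(b1$vertices, b2$vertices)
  expect_identical(b1$faces, b2$faces)
  expect_lte(surface_area(a1), surface_area(corr))
  expect_lte(surface_area(b1), surface_area(corr))
})

test_that("hole filling respects the loop-size threshold", {
  sph <- icosphere(2)
  # open one small hole (1 face, 3-edge loop) and one large hole (a vertex
  # star, ~6-edge loop)
  star_v <- 13L
  star <- which(rowSums(sph$faces == star_v) > 0)
  star_verts <- unique(as.integer(sph$faces[star, ]))
  small <- which(!apply(matrix(sph$faces %in% star_verts, nrow(sph$faces), 3),
                        1, any))[1]  # vertex-disjoint from the big hole
  holed <- triangle_mesh(sph$vertices, sph$faces[-c(star, small), , drop = FALSE])
  holed <- hepareg:::remove_unreferenced_vertices(holed)
  r0 <- manifold_report(holed)
  expect_equal(r0$n_boundary_loops, 2L)

  only_small <- fill_holes(holed, max_loop_edges = 4)
  expect_equal(manifold_report(only_small)$n_boundary_loops, 1L)

  all_filled <- fill_holes(holed)
  expect_equal(manifold_report(all_filled)$n_boundary_loops, 0L)
  # filled area exceeds the punctured area but stays within the loop disks
  expect_gt(surface_area(all_filled), surface_area(holed))
  expect_lt(surface_area(all_filled), surface_area(holed) + surface_area(sph))
})

test_that("welding supports an explicit epsilon", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(1e-7, 0, 0)), rbind(c(1, 2, 3), c(4, 2, 3)))
  expect_equal(nrow(weld_vertices(m, eps = 0)$vertices), 4)
  expect_equal(nrow(weld_vertices(m, eps = 1e-5)$vertices), 3)
})
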