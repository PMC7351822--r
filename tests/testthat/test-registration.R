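test_that("elasticity matrix matches the Lame closed forms", {
  D <- elasticity_matrix(1, 0)
  expect_equal(diag(D), c(1, 1, 1, 0.5, 0.5, 0.5))
  expect_equal(D[1, 2], 0)

  D2 <- elasticity_matrix(1e3, 0.4)
  lambda <- 1e3 * 0.4 / (1.4 * 0.2)
  mu <- 1e3 / 2.8
  expect_equal(D2[1, 2], lambda, tolerance = 1e-12)
  expect_equal(D2[1, 1], lambda + 2 * mu, tolerance = 1e-12)
  expect_equal(D2[4, 4], mu, tolerance = 1e-12)

  for (p in c(-0.5, 0, 0.2, 0.45)) for (y in c(1, 1e3)) {
    ev <- eigen(elasticity_matrix(y, p), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(elasticity_matrix(1, 0.5), "0.5")
})

test_that("stiffness assembly has the rigid-body null space", {
  vol <- make_phantom(seed = 1, n_cells = 2)$initial_volume
  K <- assemble_stiffness(vol, elasticity_matrix(1e3, 0.4))
  N <- nrow(vol$nodes)
  for (d in 1:3) {
    u <- matrix(0, N, 3); u[, d] <- 1
    expect_lt(max(abs(K %*% as.numeric(t(u)))) / max(abs(K)), 1e-10)
  }
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-6 * max(ev)), 6)  # 3 translations + 3 rotations
})

test_that("the element matrix matches a direct quadrature oracle", {
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 1.5, 0), c(0.3, 0.4, 1.2))
  D <- elasticity_matrix(1e3, 0.4)
  vol <- tet_mesh(X, matrix(1:4, 1))
  K <- as.matrix(assemble_stiffness(vol, D))
  Ke <- bf_element_stiffness(X, D)
  expect_lt(max(abs(K - Ke)) / max(abs(Ke)), 1e-6)
})

test_that("degenerate tetrahedra are refused with their index", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  vol <- structure(list(nodes = nodes, tets = matrix(1:4, 1), name = "flat"),
                   class = "tet_mesh")
  expect_error(assemble_stiffness(vol, elasticity_matrix(1, 0.3)), "index 1")
})

test_that("electrostatic forces are attractive and match brute force", {
  # single pair along +x
  d <- triangle_mesh(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1)), matrix(1:3, 1))
  t_ <- triangle_mesh(rbind(c(5, 0, 0), c(5, 1, 0), c(5, 0, 1)), matrix(1:3, 1))
  f <- electrostatic_forces(d, t_, c = 1, eps = 0.1)$forces
  expect_true(all(f[, 1] > 0))

  # coincident surfaces: total force cancels by symmetry
  sph <- icosphere(1)
  f0 <- electrostatic_forces(sph, sph, c = 2, eps = 0.05)$forces
  expect_lt(max(abs(colSums(f0))) / max(abs(f0)), 1e-8)

  # 50-vertex random pair vs the naive double loop
  set.seed(4)
  xd <- matrix(rnorm(150), 50)
  xt <- matrix(rnorm(150) + 1, 50)
  dm <- random_blob(1, subdiv = 0)
  dm$vertices <- xd[1:12, ]  # reuse icosahedron connectivity for area shares
  tm <- random_blob(2, subdiv = 0)
  tm$vertices <- xt[1:12, ]
  qd <- 3 * hepareg:::vertex_area_shares(dm)
  qt <- 3 * hepareg:::vertex_area_shares(tm)
  got <- electrostatic_forces(dm, tm, c = 3, eps = 0.2)$forces
  want <- bf_electrostatic(dm$vertices, tm$vertices, qd, qt, eps = 0.2)
  expect_lt(max(abs(got - want)), 1e-12 * max(1, max(abs(want))))
})

test_that("registration is the identity at zero charge", {
  sc <- make_phantom(seed = 4, n_cells = 4)
  reg <- register(sc$initial_volume, sc$initial_surface,
                  registration_params("insilico", charge = 0, iterations = 5))
  expect_equal(max(abs(reg$displacement)), 0)
})

test_that("a coincident target is (nearly) a fixed point", {
  sc <- make_phantom(seed = 4, n_cells = 4)
  reg <- register(sc$initial_volume, sc$initial_surface,
                  registration_params("insilico"))
  bb <- apply(sc$initial_volume$nodes, 2, range)
  diag_len <- sqrt(sum(diff(bb)^2))
  expect_lt(max(sqrt(rowSums(reg$displacement^2))), 0.01 * diag_len)
})

test_that("a rigid translation of the target is recovered", {
  sc <- make_phantom(seed = 4, n_cells = 4)
  tvec <- c(3, -2, 1.5)
  tgt <- sc$initial_surface
  tgt$vertices <- tgt$vertices + matrix(tvec, nrow(tgt$vertices), 3, byrow = TRUE)
  reg <- register(sc$initial_volume, tgt,
                  registration_params("insilico", iterations = 400))
  expect_lt(max(abs(colMeans(reg$displacement) - tvec)) / sqrt(sum(tvec^2)), 0.05)
})

test_that("elastic energy is non-negative and the trace decreases at small dt", {
  sc <- get_scene(1)
  reg <- register(sc$initial_volume, sc$deformed_surface,
                  registration_params("insilico", dt = 0.02, iterations = 30))
  expect_true(all(reg$energy$elastic >= 0))
  expect_true(all(diff(reg$energy$total) <= 1e-8 * abs(reg$energy$total[-1])))
})

test_that("presets carry the published parameter sets", {
  p1 <- registration_params("insilico")
  expect_equal(c(p1$dt, p1$iterations, p1$charge), c(0.5, 50, 10))
  p2 <- registration_params("phantom")
  expect_equal(c(p2$dt, p2$iterations, p2$charge), c(1, 200, 500))
  expect_equal(c(p1$poisson, p1$young), c(0.4, 1e3))
  expect_equal(c(p2$poisson, p2$young), c(0.4, 1e3))
})
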