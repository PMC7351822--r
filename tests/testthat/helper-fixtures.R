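# Geometry fixtures built in code.

# closed unit cube [0,1]^3 with welded vertices, outward-oriented
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces per cube side, split into two triangles, outward orientation
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z = 0, normal -z
    quad(5, 6, 8, 7),  # z = 1, normal +z
    quad(1, 2, 6, 5),  # y = 0, normal -y
    quad(3, 7, 8, 4),  # y = 1, normal +y
    quad(1, 5, 7, 3),  # x = 0, normal -x
    quad(2, 4, 8, 6))  # x = 1, normal +x
  triangle_mesh(v, f, "cube")
}

# icosphere: subdivided icosahedron projected onto a sphere
icosphere <- function(subdiv = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v); nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    mid_env <- new.env(parent = emptyenv())
    vlist <- list(v)
    next_id <- nv
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      next_id <<- next_id + 1L
      vlist[[length(vlist) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      mid_env[[key]] <- next_id
      next_id
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c_, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, c(list(v), vlist[-1L]))
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f, "icosphere")
}

single_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L), "tet")
}

two_tets <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
           rbind(1:4, c(2L, 3L, 4L, 5L)), "two_tets")
}

# random star-shaped closed mesh (perturbed icosphere), deterministic
random_blob <- function(seed, subdiv = 1, radius = 10) {
  set.seed(seed)
  m <- icosphere(subdiv, radius)
  r <- 1 + 0.3 * runif(3)
  d <- matrix(rnorm(9), 3)
  d <- d / sqrt(rowSums(d^2))
  scale <- 1 + 0.2 * rowSums((m$vertices %*% t(d))^2) / radius^2
  m$vertices <- m$vertices * scale
  m$vertices <- m$vertices + matrix(rnorm(3, sd = radius / 4), nrow(m$vertices), 3, byrow = TRUE)
  m
}

# deterministic per-session cache of indentation scenes (expensive)
.scene_cache <- new.env(parent = emptyenv())
get_scene <- function(seed) {
  key <- as.character(seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- simulate_indentation(make_phantom(seed = seed))
  .scene_cache[[key]]
}

# corruption regime used by the mesh-quality experiments
corrupt_default <- function(mesh, seed) {
  corrupt_surface(mesh, noise_sigma = 0.3, n_duplicates = 10, n_fins = 6,
                  n_holes = 4, n_blisters = 5, blister_offset = 12,
                  n_ghosts = 5, ghost_offset = 10, seed = seed)
}
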