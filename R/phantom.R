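# Synthetic deformable liver-like scene with known ground truth: a
# perturbed superellipsoid solid, tetrahedralized by radially mapping a
# Kuhn-subdivided cube lattice, deformed by a prescribed-displacement
# indentation solve. Ground truth and registration intentionally use
# different numerical paths (static prescribed-displacement solve vs
# force-driven pseudo-dynamics) so validation is not an inverse crime.

# evaluate expr with a local RNG stream; the global .Random.seed is
# untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

superellipsoid_radius <- function(u, semiaxes, exponent) {
  s <- abs(u[, 1L] / semiaxes[1])^exponent +
       abs(u[, 2L] / semiaxes[2])^exponent +
       abs(u[, 3L] / semiaxes[3])^exponent
  s^(-1 / exponent)
}

superellipsoid_volume <- function(semiaxes, exponent) {
  8 * prod(semiaxes) * gamma(1 + 1 / exponent)^3 / gamma(1 + 3 / exponent)
}

#' Generate the undeformed phantom geometry
#'
#' Builds a smooth closed organ-like solid: a superellipsoid with
#' liver-scale semi-axes, radially perturbed by a low-frequency random
#' field (deterministic per seed), tetrahedralized by mapping a cube
#' lattice (6 Kuhn tetrahedra per cell) radially onto the shape. The
#' boundary of the volume is a closed 2-manifold.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_cells lattice cells per axis (resolution; default 8, about 770
#'   boundary faces — fine enough that localized mesh defects stay local).
#' @param semiaxes superellipsoid semi-axes in mm (default liver-like
#'   `c(60, 45, 35)`).
#' @param exponent superellipsoid exponent (2 = ellipsoid; default 2.5,
#'   slightly boxy like a liver lobe).
#' @param perturb_amp relative amplitude of the low-frequency radial
#'   perturbation (default 0.08).
#' @return an object of class `phantom_scene` with `initial_volume`,
#'   `initial_surface`, shape metadata and `seed`; the deformation fields
#'   are added by [simulate_indentation()].
#' @export
make_phantom <- function(seed = 1L, n_cells = 8L,
                         semiaxes = c(60, 45, 35), exponent = 2.5,
                         perturb_amp = 0.08) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("n_cells must be >= 2")
  pert <- with_local_seed(seed, {
    dirs <- matrix(stats::rnorm(9L), 3L, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(dirs = dirs, w = stats::runif(3L, -1, 1))
  })
  radius_fun <- function(u) {
    base <- superellipsoid_radius(u, semiaxes, exponent)
    mod <- rep(1, nrow(u))
    for (k in 1:3) {
      proj <- u %*% pert$dirs[k, ]
      mod <- mod + perturb_amp * pert$w[k] * (as.numeric(proj)^2 - 1 / 3)
    }
    base * mod
  }

  # lattice nodes on [-1, 1]^3
  g <- seq(-1, 1, length.out = n_cells + 1L)
  nodes_cube <- as.matrix(expand.grid(x = g, y = g, z = g))
  # radial map: inf-norm shell t, direction u, mapped point = u * t * R(u)
  t_inf <- apply(abs(nodes_cube), 1L, max)
  len <- sqrt(rowSums(nodes_cube^2))
  u <- nodes_cube / ifelse(len > 0, len, 1)
  r <- numeric(nrow(u))
  nz <- len > 0
  r[nz] <- radius_fun(u[nz, , drop = FALSE])
  nodes <- u * (t_inf * r)

  # 6 Kuhn tetrahedra per cell, all sharing the cell's main diagonal:
  # conforming across cells because every cell uses the same diagonal
  np <- n_cells + 1L
  nid <- function(i, j, k) i + (j - 1L) * np + (k - 1L) * np * np
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  tets <- vector("list", n_cells^3 * 6L)
  ti <- 0L
  for (k in seq_len(n_cells)) for (j in seq_len(n_cells)) for (i in seq_len(n_cells)) {
    base <- c(i, j, k)
    for (p in perms) {
      steps <- diag(3L)[p, , drop = FALSE]
      c1 <- base + steps[1L, ]
      c2 <- c1 + steps[2L, ]
      c3 <- c2 + steps[3L, ]
      ti <- ti + 1L
      tets[[ti]] <- c(nid(base[1], base[2], base[3]), nid(c1[1], c1[2], c1[3]),
                      nid(c2[1], c2[2], c2[3]), nid(c3[1], c3[2], c3[3]))
    }
  }
  tets <- do.call(rbind, tets)
  vols <- tet_signed_volumes(nodes, tets)
  if (any(abs(vols) < 1e-9 * max(abs(vols))))
    stop("degenerate tetrahedra produced; use a coarser lattice or a ",
         "smaller perturbation amplitude")
  vol <- tet_mesh(nodes, tets, name = sprintf("phantom_seed%d", seed))
  structure(list(initial_volume = vol,
                 initial_surface = boundary_surface(vol),
                 deformed_volume = NULL, deformed_surface = NULL,
                 true_displacement = NULL, indentation = NULL,
                 semiaxes = semiaxes, exponent = exponent,
                 perturb_amp = perturb_amp, seed = as.integer(seed)),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene (seed %d): %d nodes, %d tets%s\n", x$seed,
              nrow(x$initial_volume$nodes), nrow(x$initial_volume$tets),
              if (is.null(x$deformed_volume)) ", undeformed"
              else sprintf(", indented depth %.3g mm", x$indentation$depth)))
  invisible(x)
}

#' Simulate a spherical indentation of the phantom
#'
#' Emulates pressing a rigid sphere into the organ along one axis: boundary
#' nodes inside the indenter footprint receive a prescribed smooth
#' paraboloid displacement (exactly `-depth` at the apex, zero at the rim)
#' along the indentation axis; the far third of the organ along that axis
#' is pinned; all remaining nodes follow from a static linear-elastic
#' solve. An optional rigid `translation` can offset the whole deformed
#' state on top of the elastic field. The total displacement field is
#' stored as ground truth.
#'
#' @param scene a [make_phantom()] scene.
#' @param center footprint center; `NULL` picks the boundary point with the
#'   largest coordinate along `axis`.
#' @param radius footprint radius in mm (default 30, about half the organ's
#'   lateral extent).
#' @param depth apex indentation depth in mm (default 18, about a fifth of
#'   the organ extent along the indentation axis — a deformation large
#'   enough that overlap metrics separate good from poor registrations).
#' @param axis indentation axis (default `"y"`, as in a bench indentation
#'   experiment).
#' @param young,poisson material used for the ground-truth solve.
#' @param translation optional rigid offset (mm) of the deformed state
#'   relative to the initial frame, emulating an additional pose mismatch
#'   between the pre- and intra-operative coordinate frames (default zero:
#'   the reference bench data provide both states in one frame, and the
#'   unregistered baseline distance is the deformation itself).
#' @return the completed `phantom_scene` with `deformed_volume`,
#'   `deformed_surface`, `true_displacement` and `indentation` filled in.
#' @export
simulate_indentation <- function(scene, center = NULL, radius = 30, depth = 18,
                                 axis = "y", young = 1e3, poisson = 0.4,
                                 translation = c(0, 0, 0)) {
  if (!(depth >= 0)) stop("depth must be >= 0")
  vol <- scene$initial_volume
  ai <- axis_index(axis)
  bsurf <- scene$initial_surface
  bidx <- attr(bsurf, "node_index")
  nodes <- vol$nodes
  N <- nrow(nodes)

  if (is.null(center)) {
    top <- bidx[which.max(nodes[bidx, ai])]
    center <- nodes[top, ]
  }
  lat <- nodes[, -ai, drop = FALSE] -
    matrix(center[-ai], N, 2L, byrow = TRUE)
  lat_d <- sqrt(rowSums(lat^2))
  foot <- intersect(bidx, which(lat_d <= radius & nodes[, ai] > center[ai] - radius))
  if (!length(foot)) stop("indenter does not touch the surface; move center or enlarge radius")
  ext <- range(nodes[, ai])
  pinned <- which(nodes[, ai] <= ext[1] + diff(ext) / 3)
  if (!length(pinned)) stop("nothing pinned: indentation system is singular")

  u <- matrix(0, N, 3L)
  if (depth > 0) {
    u[foot, ai] <- -depth * (1 - (lat_d[foot] / radius)^2)
    K <- assemble_stiffness(vol, elasticity_matrix(young, poisson))
    cons_nodes <- union(foot, pinned)
    cons_dof <- as.integer(rbind(3L * cons_nodes - 2L, 3L * cons_nodes - 1L,
                                 3L * cons_nodes))
    free_dof <- setdiff(seq_len(3L * N), cons_dof)
    uc <- as.numeric(t(u))[cons_dof]
    rhs <- -(K[free_dof, cons_dof, drop = FALSE] %*% uc)
    uf <- Matrix::solve(K[free_dof, free_dof], rhs)
    uu <- numeric(3L * N)
    uu[cons_dof] <- uc
    uu[free_dof] <- as.numeric(uf)
    u <- matrix(uu, N, 3L, byrow = TRUE)
  }
  u <- u + matrix(translation, N, 3L, byrow = TRUE)
  deformed <- tet_mesh(nodes + u, vol$tets, name = paste0(vol$name, "_deformed"))
  scene$deformed_volume <- deformed
  scene$deformed_surface <- boundary_surface(deformed)
  scene$true_displacement <- u
  scene$indentation <- list(center = center, radius = radius, depth = depth,
                            axis = c("x", "y", "z")[ai],
                            translation = translation)
  scene
}

#' Crop a partial view of a surface
#'
#' Emulates a partial intra-operative surface: keeps the faces visible from
#' `view_direction` (outward normal opposing the gaze), then trims by
#' sweeping a plane along the view direction until the retained area is
#' within one percentage point of the requested fraction of the full input
#' surface. When the request exceeds what visibility allows, the whole
#' visible set is returned (e.g. at most about half a convex shape is ever
#' visible).
#'
#' @param mesh a [triangle_mesh()].
#' @param view_direction gaze direction vector (from the camera toward the
#'   organ).
#' @param area_fraction requested fraction of the full surface area, in
#'   (0, 1].
#' @return the cropped `triangle_mesh`.
#' @export
crop_partial_view <- function(mesh, view_direction = c(0, -1, 0),
                              area_fraction = 0.2) {
  if (!(area_fraction > 0 && area_fraction <= 1))
    stop("area_fraction must lie in (0, 1]")
  v <- view_direction / sqrt(sum(view_direction^2))
  nrm <- face_normals_raw(mesh)
  visible <- as.numeric(nrm %*% v) < 0
  if (!any(visible)) stop("no face is visible from that direction")
  vis <- triangle_mesh(mesh$vertices, mesh$faces[visible, , drop = FALSE],
                       mesh$name)
  # a camera sees one connected patch: drop beyond-horizon islands
  vis <- keep_largest_component(vis)
  vis <- remove_unreferenced_vertices(vis)
  a_full <- surface_area(mesh)
  a_vis <- surface_area(vis)
  target <- area_fraction * a_full
  if (target >= a_vis) return(vis)

  # sweep plane along the view axis, keeping the near (t <= cut) portion
  tv <- as.numeric(vis$vertices %*% v)
  lo <- min(tv); hi <- max(tv)
  # weld the clip's duplicated cut vertices so the view is a clean open cap
  clean <- function(m)
    remove_unreferenced_vertices(keep_largest_component(weld_vertices(m)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    point <- mid * v
    part <- clip_mesh_plane(vis, point, v)$negative
    a <- surface_area(part)
    if (abs(a - target) <= 0.01 * a_full) return(clean(part))
    if (a > target) hi <- mid else lo <- mid
  }
  clean(part)
}

#' Corrupt a surface like a stitched intra-operative mesh
#'
#' Deterministically (per seed) applies: Gaussian vertex jitter, duplicated
#' (unreferenced) vertex records, non-manifold fins (extra triangles glued
#' onto existing interior edges, giving those edges three incident faces),
#' and holes (removal of pairwise non-adjacent faces, each opening one
#' 3-edge boundary loop). The injected corruption manifest is attached as
#' `attr(out, "manifest")` for oracle tests.
#'
#' @param mesh a [triangle_mesh()].
#' @param noise_sigma vertex jitter standard deviation in mm.
#' @param n_duplicates,n_fins,n_holes corruption counts (>= 0).
#' @param fin_scale fin apex offset as a multiple of the host edge length
#'   (default 1: fins protrude about one edge length).
#' @param n_blisters number of stitch blisters: misaligned duplicated
#'   patches (a copy of a vertex's incident-face star with the apex lifted
#'   by `blister_offset`, rim-stitched through exact-duplicate vertices),
#'   the signature defect of overlapping misregistered reconstructions.
#' @param blister_offset blister lift in mm (default 6).
#' @param n_ghosts number of stitching ghosts: fully detached misaligned
#'   copies of a surface patch (each face doubled in place, so the ghost is
#'   non-manifold throughout). Strategy (a) drops them as separate meshes;
#'   strategy (b) drops them as non-manifold geometry.
#' @param ghost_offset ghost displacement in mm (default 5).
#' @param seed integer seed.
#' @return the corrupted `triangle_mesh` with a `manifest` attribute.
#' @export
corrupt_surface <- function(mesh, noise_sigma = 0, n_duplicates = 0L,
                            n_fins = 0L, n_holes = 0L, fin_scale = 1,
                            n_blisters = 0L, blister_offset = 6,
                            n_ghosts = 0L, ghost_offset = 5,
                            seed = 1L) {
  if (n_holes > nrow(mesh$faces)) stop("more holes requested than faces exist")
  with_local_seed(seed + 7919L, {
    v <- mesh$vertices
    f <- mesh$faces
    manifest <- list(noise_sigma = noise_sigma, duplicates = integer(0),
                     fins = NULL, holes = integer(0), seed = seed)
    if (noise_sigma > 0)
      v <- v + matrix(stats::rnorm(length(v), sd = noise_sigma), nrow(v), 3L)
    if (n_duplicates > 0L) {
      src <- sample.int(nrow(v), n_duplicates, replace = FALSE)
      manifest$duplicates <- src
      v <- rbind(v, v[src, , drop = FALSE])
    }
    used_verts <- integer(0)  # keeps injected defects disjoint
    boundary_verts <- {
      ec0 <- edge_counts(mesh$faces)
      be <- ec0$edges[ec0$key %in% names(ec0$tab)[ec0$tab == 1L], , drop = FALSE]
      unique(as.integer(be))
    }
    # vertices at graph distance >= 3 from any boundary vertex
    interior_verts <- {
      ec0 <- edge_counts(mesh$faces)
      grow <- function(vs) unique(as.integer(
        ec0$edges[ec0$edges[, 1L] %in% vs | ec0$edges[, 2L] %in% vs, ]))
      setdiff(seq_len(nrow(mesh$vertices)), grow(grow(boundary_verts)))
    }
    if (n_fins > 0L) {
      ec <- edge_counts(f)
      inner <- unique(ec$key[ec$key %in% names(ec$tab)[ec$tab == 2L]])
      if (length(inner) < n_fins) stop("not enough interior edges for fins")
      pick <- character(0)
      for (key in sample(inner)) {
        ends <- as.integer(strsplit(key, " ")[[1]])
        if (any(ends %in% boundary_verts)) next
        # the fin's future excision hole spans the host faces: keep that
        # whole vertex set clear of every other defect
        host <- which(rowSums(matrix(mesh$faces %in% ends,
                                     nrow(mesh$faces), 3L)) == 2L)
        hostv <- unique(as.integer(mesh$faces[host, ]))
        if (any(hostv %in% used_verts)) next
        pick <- c(pick, key)
        used_verts <- c(used_verts, hostv)
        if (length(pick) == n_fins) break
      }
      if (length(pick) < n_fins) stop("not enough disjoint edges for fins")
      pe <- matrix(as.integer(do.call(rbind, strsplit(pick, " "))), ncol = 2L)
      manifest$fins <- pe
      for (r in seq_len(n_fins)) {
        a <- pe[r, 1L]; b <- pe[r, 2L]
        mid <- (v[a, ] + v[b, ]) / 2
        edge_v <- v[b, ] - v[a, ]
        ref <- if (abs(edge_v[1]) < 0.9 * sqrt(sum(edge_v^2))) c(1, 0, 0) else c(0, 1, 0)
        out_dir <- c(edge_v[2] * ref[3] - edge_v[3] * ref[2],
                     edge_v[3] * ref[1] - edge_v[1] * ref[3],
                     edge_v[1] * ref[2] - edge_v[2] * ref[1])
        out_dir <- out_dir / sqrt(sum(out_dir^2))
        apex <- mid + out_dir * fin_scale * sqrt(sum(edge_v^2))
        v <- rbind(v, apex)
        f <- rbind(f, c(a, b, nrow(v)))
      }
    }
    if (n_blisters > 0L) {
      # stitch blister: duplicate a vertex star, lift the copied apex along
      # the local outward normal, stitch the rim with exact-duplicate
      # vertex records (welding re-attaches it non-manifoldly)
      manifest$blisters <- integer(0)
      vnorm_raw <- face_normals_raw(mesh)
      cand <- setdiff(if (length(interior_verts)) interior_verts
                      else seq_len(nrow(mesh$vertices)), used_verts)
      placed <- 0L
      for (centre in sample(cand)) {
        if (placed == n_blisters) break
        star2 <- which(rowSums(mesh$faces == centre) > 0L)
        if (!length(star2)) next
        patch_v <- unique(as.integer(mesh$faces[star2, ]))
        ring2_f <- which(rowSums(matrix(mesh$faces %in% patch_v,
                                        nrow(mesh$faces), 3L)) > 0L)
        ring2_v <- unique(as.integer(mesh$faces[ring2_f, ]))
        if (any(ring2_v %in% used_verts)) next
        interior <- centre
        nrm <- colSums(vnorm_raw[star2, , drop = FALSE])
        nl <- sqrt(sum(nrm^2)); if (nl == 0) next
        nrm <- nrm / nl
        copy_idx <- stats::setNames(seq_along(patch_v) + nrow(v), patch_v)
        newv <- v[patch_v, , drop = FALSE]
        lift <- patch_v %in% interior
        newv[lift, ] <- newv[lift, ] +
          matrix(nrm * blister_offset, sum(lift), 3L, byrow = TRUE)
        v <- rbind(v, newv)
        f <- rbind(f, matrix(copy_idx[as.character(mesh$faces[star2, ])],
                             length(star2), 3L))
        manifest$blisters <- c(manifest$blisters, centre)
        manifest$blister_vertices <- union(manifest$blister_vertices, patch_v)
        used_verts <- c(used_verts, ring2_v)
        placed <- placed + 1L
      }
    }
    if (n_ghosts > 0L) {
      # stitching ghost: detached, offset copy of a 2-ring patch with every
      # face doubled in place — non-manifold throughout and a separate
      # component, emulating an overlapping misregistered reconstruction
      manifest$ghosts <- integer(0)
      vnorm_raw2 <- face_normals_raw(mesh)
      candg <- if (length(interior_verts)) interior_verts else seq_len(nrow(mesh$vertices))
      for (gh in seq_len(n_ghosts)) {
        centre <- candg[sample.int(length(candg), 1L)]
        star1 <- which(rowSums(mesh$faces == centre) > 0L)
        ring1 <- unique(as.integer(mesh$faces[star1, ]))
        patch_f <- which(rowSums(matrix(mesh$faces %in% ring1,
                                        nrow(mesh$faces), 3L)) > 0L)
        patch_v <- unique(as.integer(mesh$faces[patch_f, ]))
        nrm <- colSums(vnorm_raw2[patch_f, , drop = FALSE])
        nl <- sqrt(sum(nrm^2)); if (nl == 0) next
        nrm <- nrm / nl
        newv <- v[patch_v, , drop = FALSE] +
          matrix(nrm * ghost_offset, length(patch_v), 3L, byrow = TRUE)
        copy_idx <- stats::setNames(seq_along(patch_v) + nrow(v), patch_v)
        v <- rbind(v, newv)
        gf <- matrix(copy_idx[as.character(mesh$faces[patch_f, ])],
                     length(patch_f), 3L)
        f <- rbind(f, gf, gf)  # doubled faces: non-manifold throughout
        manifest$ghosts <- c(manifest$ghosts, centre)
        candg <- setdiff(candg, patch_v)
        if (!length(candg)) break
      }
    }
    if (n_holes > 0L) {
      # pick faces that share no vertex with each other or with fins, so
      # each removal opens exactly one clean 3-edge loop
      banned <- used_verts
      order_f <- sample.int(nrow(mesh$faces))
      chosen <- integer(0)
      used_v <- banned
      for (fi in order_f) {
        fv <- mesh$faces[fi, ]
        if (!any(fv %in% c(used_v, boundary_verts))) {
          chosen <- c(chosen, fi)
          used_v <- c(used_v, fv)
          if (length(chosen) == n_holes) break
        }
      }
      if (length(chosen) < n_holes)
        stop("could not place ", n_holes, " disjoint holes on this mesh")
      manifest$holes <- chosen
      f <- f[-chosen, , drop = FALSE]
    }
    out <- triangle_mesh(v, f, paste0(mesh$name, "_corrupted"))
    attr(out, "manifest") <- manifest
    out
  })
}

#' Enclosed volume of a closed surface's tetrahedral solid
#' @param vol a [tet_mesh()].
#' @return total volume in mm^3.
#' @export
enclosed_volume <- function(vol) sum(tet_signed_volumes(vol$nodes, vol$tets))
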