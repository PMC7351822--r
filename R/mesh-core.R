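#' Triangle surface mesh
#'
#' Container for an organ surface: a vertex matrix in millimetres and a face
#' matrix of 1-based vertex indices, three per face.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces integer matrix (m x 3) of vertex indices (1-based).
#' @param name optional label carried through the pipeline.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L) stop("faces must be triangles (3 indices each)")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range")
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh%s: %d vertices, %d faces, area %.4g mm^2\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

#' Tetrahedral volume mesh
#'
#' Container for a deformable organ volume: nodes in millimetres and
#' tetrahedra as quadruples of 1-based node indices. Tetrahedra are
#' re-oriented on construction so every signed volume is positive.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in mm.
#' @param tets integer matrix (m x 4) of node indices (1-based).
#' @param name optional label.
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, name = "") {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("tets must have 4 indices each")
  if (nrow(tets) > 0L && (min(tets) < 1L || max(tets) > nrow(nodes)))
    stop("tet index out of range")
  v <- tet_signed_volumes(nodes, tets)
  flip <- which(v < 0)
  if (length(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  structure(list(nodes = nodes, tets = tets, name = as.character(name)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh%s: %d nodes, %d tetrahedra, volume %.4g mm^3\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$nodes), nrow(x$tets),
              sum(tet_signed_volumes(x$nodes, x$tets))))
  invisible(x)
}

tet_signed_volumes <- function(nodes, tets) {
  if (nrow(tets) == 0L) return(numeric(0))
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c_ <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  # det [b; c; d] / 6 row-wise
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) -
    b[, 2L] * (c_[, 1L] * d[, 3L] - c_[, 3L] * d[, 1L]) +
    b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

face_normals_raw <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(matrix(numeric(0), 0L, 3L))
  v <- mesh$vertices
  row_cross(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
            v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE])
}

#' Per-face triangle areas
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of face areas in mm^2.
#' @export
face_areas <- function(mesh) {
  n <- face_normals_raw(mesh)
  if (nrow(n) == 0L) return(numeric(0))
  0.5 * sqrt(rowSums(n * n))
}

#' Total surface area
#'
#' Sum of triangle areas; degenerate faces contribute zero.
#'
#' @param mesh a `triangle_mesh`.
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Surface area as a percentage of a reference surface
#' @param mesh a `triangle_mesh`.
#' @param reference the full surface the percentage refers to.
#' @return `100 * area(mesh) / area(reference)`.
#' @export
area_percent <- function(mesh, reference) {
  100 * surface_area(mesh) / surface_area(reference)
}

#' Area-weighted surface centroid
#'
#' The centre of mass of the surface sheet itself (area-weighted mean of
#' triangle centroids), used as the bisection plane anchor. This is
#' tessellation-independent, unlike a plain vertex mean.
#'
#' @param mesh a `triangle_mesh` with positive total area.
#' @return length-3 numeric point.
#' @export
surface_centroid <- function(mesh) {
  a <- face_areas(mesh)
  tot <- sum(a)
  if (!(tot > 0)) stop("degenerate geometry: total surface area is zero")
  f <- mesh$faces
  v <- mesh$vertices
  cent <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
             v[f[, 3L], , drop = FALSE]) / 3
  as.numeric(colSums(cent * a) / tot)
}

mesh_bbox <- function(mesh) {
  v <- if (inherits(mesh, "tet_mesh")) mesh$nodes else mesh$vertices
  if (nrow(v) == 0L) stop("empty mesh has no bounding box")
  rbind(min = apply(v, 2L, min), max = apply(v, 2L, max))
}

axis_index <- function(axis) {
  i <- match(tolower(as.character(axis)), c("x", "y", "z"))
  if (is.na(i)) stop("axis must be one of 'x', 'y', 'z'")
  i
}

#' Bisection specification
#'
#' Describes how a partial target surface is cut out of a full surface:
#' the cutting-plane normal axis, which half to keep, and how many times
#' the cut is applied (`iterations = 2` gives the hemi surface, where the
#' second cut passes through the retained half's own centroid).
#'
#' @param axis plane normal, one of `"x"`, `"y"`, `"z"`.
#' @param keep `"positive"`, `"negative"`, or `"larger"` (by area).
#' @param iterations 1 (plain bisection) or 2 (hemi).
#' @param step stepwise increment `s` in local coordinate units (only used by
#'   [stepwise_bisections()]).
#' @return an object of class `bisection_spec`.
#' @export
bisection_spec <- function(axis = "y", keep = c("positive", "negative", "larger"),
                           iterations = 1L, step = NULL) {
  keep <- match.arg(keep)
  iterations <- as.integer(iterations)
  if (!iterations %in% c(1L, 2L)) stop("iterations must be 1 or 2")
  if (!is.null(step) && !(step > 0)) stop("step must be > 0")
  structure(list(axis = tolower(axis), keep = keep, iterations = iterations,
                 step = step), class = "bisection_spec")
}

# Split every triangle of `mesh` at the plane through `point` with `normal`.
# Triangles crossing the plane are cut exactly, so the two halves' areas sum
# to the input area. Vertices exactly on the plane belong to both halves.
clip_mesh_plane <- function(mesh, point, normal) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) {
    e <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3), mesh$name)
    return(list(positive = e, negative = e))
  }
  d <- as.numeric((v - matrix(point, nrow(v), 3L, byrow = TRUE)) %*% normal)
  side <- matrix(d[f], nrow(f), 3L)
  all_pos <- rowSums(side >= 0) == 3L
  all_neg <- rowSums(side <= 0) == 3L
  crossing <- which(!(all_pos | all_neg))

  pos_faces <- list(f[all_pos, , drop = FALSE])
  neg_faces <- list(f[all_neg, , drop = FALSE])
  new_v <- list()
  nv <- nrow(v)

  for (fi in crossing) {
    idx <- f[fi, ]
    dv <- d[idx]
    # rotate so that vertex 1 is alone on its side
    sgn <- dv > 0  # on-plane treated as negative-side here; crossing faces
                   # have at least one strictly positive and one strictly
                   # negative vertex unless a vertex sits on the plane
    pos_ct <- sum(dv > 0)
    if (pos_ct == 0L || sum(dv < 0) == 0L) {
      # one vertex exactly on the plane, others on one side: no split needed
      if (pos_ct > 0L) pos_faces[[length(pos_faces) + 1L]] <- matrix(idx, 1L)
      else neg_faces[[length(neg_faces) + 1L]] <- matrix(idx, 1L)
      next
    }
    lone_pos <- pos_ct == 1L
    lone <- if (lone_pos) which(dv > 0) else which(dv <= 0)
    if (length(lone) != 1L) lone <- lone[1L]
    ord <- ((lone - 1L) + 0:2) %% 3L + 1L  # lone vertex first, orientation kept
    i1 <- idx[ord[1L]]; i2 <- idx[ord[2L]]; i3 <- idx[ord[3L]]
    d1 <- d[i1]; d2 <- d[i2]; d3 <- d[i3]
    # intersections on edges (1,2) and (1,3); guard exact-on-plane neighbours
    p12 <- if (d1 != d2) v[i1, ] + (d1 / (d1 - d2)) * (v[i2, ] - v[i1, ]) else v[i2, ]
    p13 <- if (d1 != d3) v[i1, ] + (d1 / (d1 - d3)) * (v[i3, ] - v[i1, ]) else v[i3, ]
    new_v[[length(new_v) + 1L]] <- rbind(p12, p13)
    j12 <- nv + 2L * (length(new_v) - 1L) + 1L
    j13 <- j12 + 1L
    lone_tri <- matrix(c(i1, j12, j13), 1L)
    quad_tris <- rbind(c(j12, i2, i3), c(j12, i3, j13))
    if (lone_pos) {
      pos_faces[[length(pos_faces) + 1L]] <- lone_tri
      neg_faces[[length(neg_faces) + 1L]] <- quad_tris
    } else {
      neg_faces[[length(neg_faces) + 1L]] <- lone_tri
      pos_faces[[length(pos_faces) + 1L]] <- quad_tris
    }
  }

  verts <- if (length(new_v)) rbind(v, do.call(rbind, new_v)) else v
  build_half <- function(face_list) {
    ff <- do.call(rbind, face_list)
    if (is.null(ff) || nrow(ff) == 0L)
      return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                           mesh$name))
    keep_idx <- sort(unique(as.integer(ff)))
    remap <- integer(nrow(verts))
    remap[keep_idx] <- seq_along(keep_idx)
    triangle_mesh(verts[keep_idx, , drop = FALSE],
                  matrix(remap[ff], nrow(ff), 3L), mesh$name)
  }
  list(positive = build_half(pos_faces), negative = build_half(neg_faces))
}

#' Bisect a surface at its centre of mass
#'
#' Cuts the surface with an axis-normal plane through its area-weighted
#' centroid, splitting crossing triangles exactly at the plane so the two
#' halves' areas sum to the input area. With `iterations = 2` the retained
#' half is cut again through its own centroid with the same normal and keep
#' rule, producing the hemi surface.
#'
#' @param mesh a `triangle_mesh` with positive area.
#' @param spec a [bisection_spec()]; alternatively pass `axis`, `keep`,
#'   `iterations` directly.
#' @param axis,keep,iterations used when `spec` is missing.
#' @return the retained `triangle_mesh` half.
#' @export
bisect_plane <- function(mesh, spec = NULL, axis = "y", keep = "larger",
                         iterations = 1L) {
  if (is.null(spec)) spec <- bisection_spec(axis, keep, iterations)
  ai <- axis_index(spec$axis)
  normal <- c(0, 0, 0); normal[ai] <- 1
  out <- mesh
  for (it in seq_len(spec$iterations)) {
    halves <- clip_mesh_plane(out, surface_centroid(out), normal)
    out <- switch(spec$keep,
      positive = halves$positive,
      negative = halves$negative,
      larger = {
        ap <- surface_area(halves$positive); an <- surface_area(halves$negative)
        if (an > ap) halves$negative else {
          if (an == ap) message("bisect_plane: equal halves, tie broken toward positive side")
          halves$positive
        }
      })
  }
  out
}

#' Stepwise bisections along an axis
#'
#' Cuts the surface at planes `axis_min + k * s` for `k = 1..count`, keeping
#' for each `k` the portion whose coordinate along `axis` is at most the
#' plane, measured in the mesh's native (local) coordinate units. The
#' resulting areas are non-decreasing in `k`; the final output equals the
#' input once the cut plane passes the bounding box.
#'
#' @param mesh a `triangle_mesh`.
#' @param axis sweep axis (`"x"`, `"y"`, `"z"`).
#' @param step increment `s` (> 0) in local units.
#' @param count number of bisections.
#' @return list of `count` `triangle_mesh` objects (possibly empty meshes for
#'   early cuts).
#' @export
stepwise_bisections <- function(mesh, axis = "y", step, count) {
  if (!(step > 0)) stop("step must be > 0")
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  ai <- axis_index(axis)
  bb <- mesh_bbox(mesh)
  if (count * step < (bb["max", ai] - bb["min", ai]))
    warning("count * step does not span the mesh extent; outputs stay partial")
  normal <- c(0, 0, 0); normal[ai] <- 1
  lapply(seq_len(count), function(k) {
    cut <- bb["min", ai] + k * step
    if (cut >= bb["max", ai]) return(mesh)
    point <- c(0, 0, 0); point[ai] <- cut
    clip_mesh_plane(mesh, point, normal)$negative
  })
}

#' Boundary surface of a tetrahedral volume
#'
#' Extracts the faces incident to exactly one tetrahedron, consistently
#' outward-oriented. For a watertight tet complex the result is a closed
#' 2-manifold. The returned mesh carries an attribute `node_index` mapping
#' each surface vertex to its node index in the volume.
#'
#' @param vol a `tet_mesh`.
#' @return a `triangle_mesh`.
#' @export
boundary_surface <- function(vol) {
  tt <- vol$tets
  if (nrow(tt) == 0L)
    return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                         vol$name))
  # outward-oriented faces of a positively oriented tet (a, b, c, d)
  faces <- rbind(tt[, c(1L, 3L, 2L), drop = FALSE],
                 tt[, c(1L, 2L, 4L), drop = FALSE],
                 tt[, c(1L, 4L, 3L), drop = FALSE],
                 tt[, c(2L, 3L, 4L), drop = FALSE])
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  boundary <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  used <- sort(unique(as.integer(boundary)))
  remap <- integer(nrow(vol$nodes))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(vol$nodes[used, , drop = FALSE],
                       matrix(remap[boundary], nrow(boundary), 3L), vol$name)
  # slightly tangled elements (a radially mapped lattice can carry a few)
  # would leave isolated flipped faces: restore consistent outward
  # orientation combinatorially
  out <- orient_consistently(out)
  attr(out, "node_index") <- used
  out
}

# flood-fill a consistent face orientation (adjacent faces traverse their
# shared edge in opposite directions), then flip whole components so the
# divergence-theorem signed volume is positive (outward normals)
orient_consistently <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  if (m == 0L) return(mesh)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ekey(f[, 1L], f[, 2L]), ekey(f[, 2L], f[, 3L]), ekey(f[, 3L], f[, 1L]))
  face_of <- rep(seq_len(m), 3L)
  adj <- split(face_of, keys)
  flipped <- logical(m)
  seen <- logical(m)
  comp_id <- integer(m)
  ncomp <- 0L
  for (s in seq_len(m)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    comp_id[s] <- ncomp
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      fc <- f[cur, ]
      if (flipped[cur]) fc <- fc[c(1L, 3L, 2L)]
      dir_cur <- rbind(fc[1:2], fc[2:3], fc[c(3, 1)])
      for (r in 1:3) {
        k <- ekey(dir_cur[r, 1L], dir_cur[r, 2L])
        nbs <- setdiff(adj[[k]], cur)
        for (nb in nbs) {
          fn <- f[nb, ]
          if (flipped[nb]) fn <- fn[c(1L, 3L, 2L)]
          dir_nb <- rbind(fn[1:2], fn[2:3], fn[c(3, 1)])
          same <- any(dir_nb[, 1L] == dir_cur[r, 1L] & dir_nb[, 2L] == dir_cur[r, 2L])
          if (!seen[nb]) {
            flipped[nb] <- xor(flipped[nb], same)
            seen[nb] <- TRUE
            comp_id[nb] <- ncomp
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  out <- triangle_mesh(mesh$vertices, f, mesh$name)
  # outward: per component, positive enclosed volume
  nrm <- face_normals_raw(out)
  cx <- (out$vertices[f[, 1L], 1L] + out$vertices[f[, 2L], 1L] +
           out$vertices[f[, 3L], 1L]) / 3
  vc <- tapply(cx * nrm[, 1L] / 2, comp_id, sum)
  for (ci in which(vc < 0)) {
    sel <- comp_id == ci
    f[sel, ] <- f[sel, c(1L, 3L, 2L), drop = FALSE]
  }
  triangle_mesh(mesh$vertices, f, mesh$name)
}
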