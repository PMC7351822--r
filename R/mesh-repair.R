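# Manifoldness diagnostics and the two automatic repair strategies used to
# clean stitched intra-operative surfaces before registration.

vertex_key <- function(vertices, eps = 0) {
  if (eps > 0) {
    g <- round(sweep(vertices, 2L, eps, "/"))
    paste(g[, 1L], g[, 2L], g[, 3L])
  } else {
    paste(vertices[, 1L], vertices[, 2L], vertices[, 3L])
  }
}

undirected_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L), drop = FALSE],
             faces[, c(2L, 3L), drop = FALSE],
             faces[, c(3L, 1L), drop = FALSE])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

# number of faces incident to each undirected edge, keyed
edge_counts <- function(faces) {
  e <- undirected_edges(faces)
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  list(edges = e, key = key, tab = tab)
}

# connected components of faces under shared-edge adjacency
face_components <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  if (m == 0L) return(integer(0))
  ec <- edge_counts(f)
  face_of <- rep(seq_len(m), 3L)
  grp <- split(face_of, ec$key)
  # union-find over faces
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (g in grp) {
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) { rj <- find(j); if (rj != r) parent[rj] <- r }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Manifoldness diagnostics
#'
#' Counts the defects that make a mesh "geometry that cannot exist in the
#' real world": duplicate vertices, isolated (unreferenced) vertices,
#' edges incident to more than two faces, vertices whose incident-face star
#' is not a single edge-connected fan, boundary loops, connected components,
#' zero-area faces and zero-length edges. A clean closed 2-manifold single
#' component reports zeros everywhere except `n_components = 1`.
#'
#' Triangle meshes carry no standalone edge primitives, so
#' `n_isolated_edges` is structurally 0 here.
#'
#' @param mesh a [triangle_mesh()].
#' @param weld_eps duplicate-vertex tolerance in mm; 0 means exact
#'   coordinate equality.
#' @return an object of class `manifold_report` (a named list of counts).
#' @export
manifold_report <- function(mesh, weld_eps = 0) {
  v <- mesh$vertices; f <- mesh$faces
  n_dup <- nrow(v) - length(unique(vertex_key(v, weld_eps)))
  referenced <- seq_len(nrow(v)) %in% unique(as.integer(f))
  n_isolated <- sum(!referenced)

  n_nm_edges <- 0L; n_boundary_loops <- 0L; n_nm_vertices <- 0L
  n_zero_area <- 0L; n_zero_len <- 0L
  n_components <- 0L
  if (nrow(f) > 0L) {
    ec <- edge_counts(f)
    n_nm_edges <- sum(ec$tab > 2L)
    n_zero_area <- sum(face_areas(mesh) == 0)
    el <- sqrt(rowSums((v[ec$edges[, 1L], , drop = FALSE] -
                          v[ec$edges[, 2L], , drop = FALSE])^2))
    n_zero_len <- length(unique(ec$key[el == 0]))
    n_components <- length(unique(face_components(mesh)))

    # boundary loops: components of boundary edges in which every vertex has
    # degree exactly 2 (open chains are not loops)
    bkey <- names(ec$tab)[ec$tab == 1L]
    if (length(bkey)) {
      be <- do.call(rbind, strsplit(bkey, " "))
      be <- matrix(as.integer(be), ncol = 2L)
      n_boundary_loops <- count_closed_loops(be)
    }

    # non-manifold vertices: star splits into >1 edge-connected piece
    comp_cache <- new.env(parent = emptyenv())
    vstars <- split(rep(seq_len(nrow(f)), 3L), as.integer(f))
    for (vi in names(vstars)) {
      star <- unique(vstars[[vi]])
      if (length(star) <= 1L) next
      sub <- f[star, , drop = FALSE]
      # adjacency through edges that contain vertex vi
      vv <- as.integer(vi)
      other <- t(apply(sub, 1L, function(r) r[r != vv][1:2]))
      # faces are adjacent at vi when they share one of the two spoke edges
      spoke <- cbind(rep(seq_along(star), 2L), c(other[, 1L], other[, 2L]))
      parent <- seq_along(star)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (g in split(spoke[, 1L], spoke[, 2L])) {
        if (length(g) > 1L) {
          r <- find(g[1L])
          for (j in g[-1L]) { rj <- find(j); if (rj != r) parent[rj] <- r }
        }
      }
      if (length(unique(vapply(seq_along(star), find, integer(1)))) > 1L)
        n_nm_vertices <- n_nm_vertices + 1L
    }
  }
  structure(list(n_duplicate_vertices = as.integer(n_dup),
                 n_isolated_vertices = as.integer(n_isolated),
                 n_isolated_edges = 0L,
                 n_nonmanifold_edges = as.integer(n_nm_edges),
                 n_nonmanifold_vertices = as.integer(n_nm_vertices),
                 n_boundary_loops = as.integer(n_boundary_loops),
                 n_components = as.integer(n_components),
                 n_zero_area_faces = as.integer(n_zero_area),
                 n_zero_length_edges = as.integer(n_zero_len)),
            class = "manifold_report")
}

#' @export
print.manifold_report <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%s: %d\n", k, x[[k]]))
  invisible(x)
}

count_closed_loops <- function(boundary_edges) {
  verts <- unique(as.integer(boundary_edges))
  deg <- table(factor(as.integer(boundary_edges), levels = verts))
  # union-find over boundary vertices
  idx <- stats::setNames(seq_along(verts), verts)
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(boundary_edges))) {
    a <- idx[as.character(boundary_edges[r, 1L])]
    b <- idx[as.character(boundary_edges[r, 2L])]
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(verts), find, integer(1))
  # a component is a closed loop iff all its vertices have degree 2
  sum(vapply(split(as.integer(deg), comp), function(d) all(d == 2L), logical(1)))
}

#' Weld duplicate vertices
#'
#' Merges vertices with identical coordinates (or within `eps`, using a grid
#' snap) into one record, remapping faces. Face connectivity can become
#' degenerate (repeated indices) if welded vertices share a face; such faces
#' are kept — removing them is a separate repair step.
#'
#' @param mesh a [triangle_mesh()].
#' @param eps weld tolerance in mm (0 = exact bitwise equality).
#' @return a welded `triangle_mesh`.
#' @export
weld_vertices <- function(mesh, eps = 0) {
  key <- vertex_key(mesh$vertices, eps)
  first <- !duplicated(key)
  map <- match(key, key[first])
  triangle_mesh(mesh$vertices[first, , drop = FALSE],
                matrix(map[mesh$faces], nrow(mesh$faces), 3L), mesh$name)
}

remove_unreferenced_vertices <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces], nrow(mesh$faces), 3L), mesh$name)
}

keep_largest_component <- function(mesh) {
  comp <- face_components(mesh)
  if (length(unique(comp)) <= 1L) return(mesh)
  a <- face_areas(mesh)
  best <- names(which.max(tapply(a, comp, sum)))
  triangle_mesh(mesh$vertices, mesh$faces[comp == as.integer(best), , drop = FALSE],
                mesh$name)
}

#' Repair strategy (a): quick pass
#'
#' Three consecutive removal steps that clean a surface without drastically
#' changing its geometry: (1) weld duplicate vertices, (2) remove isolated
#' (disconnected) vertices and edges, (3) remove separate components,
#' keeping the single largest-area one. Never increases area or face count.
#'
#' @param mesh a [triangle_mesh()].
#' @param weld_eps weld tolerance in mm (default exact).
#' @return the repaired `triangle_mesh`.
#' @export
strategy_a <- function(mesh, weld_eps = 0) {
  out <- weld_vertices(mesh, weld_eps)
  out <- remove_unreferenced_vertices(out)
  out <- keep_largest_component(out)
  out <- remove_unreferenced_vertices(out)
  if (nrow(out$faces) == 0L)
    stop("degenerate geometry: repair removed every face")
  out
}

#' Repair strategy (b): full manifold repair
#'
#' Seven consecutive steps: (1) weld duplicate vertices; (2) delete zero-area
#' faces and zero-length edges; (3) make all faces convex (a no-op on
#' triangle-only meshes); (4) delete all non-manifold vertices and edges
#' together with their incident faces; (5) fill holes by triangulating each
#' closed boundary edge loop; (6) triangulate faces (fan filling already
#' emits triangles); (7) remove isolated vertices and edges. The output has
#' zero non-manifold edges and vertices.
#'
#' @param mesh a [triangle_mesh()].
#' @param weld_eps weld tolerance in mm (default exact).
#' @param max_loop_edges only boundary loops with at most this many edges are
#'   filled (default unlimited; large holes are geometrically unreliable and
#'   the cutoff is a user decision).
#' @return the repaired `triangle_mesh`.
#' @export
strategy_b <- function(mesh, weld_eps = 0, max_loop_edges = Inf) {
  out <- weld_vertices(mesh, weld_eps)                       # (1)
  keep <- face_areas(out) > 0 &
    out$faces[, 1L] != out$faces[, 2L] &
    out$faces[, 2L] != out$faces[, 3L] &
    out$faces[, 3L] != out$faces[, 1L]                       # (2)
  out <- triangle_mesh(out$vertices, out$faces[keep, , drop = FALSE], out$name)
  # (3) all faces are already triangles, hence convex
  # (4) + (5): excision can expose new split-star vertices, and filling a
  # pinched pair of holes can recreate one, so the two steps alternate
  # until a fixed point
  for (round in 1:5) {
    for (pass in 1:10) {                                     # (4)
      rep_ <- manifold_report(out)
      if (rep_$n_nonmanifold_edges == 0L && rep_$n_nonmanifold_vertices == 0L) break
      out <- excise_nonmanifold(out)
      if (nrow(out$faces) == 0L)
        stop("degenerate geometry: repair removed every face")
    }
    filled <- fill_holes(out, max_loop_edges)                # (5) + (6)
    rep_f <- manifold_report(filled)
    if (rep_f$n_nonmanifold_edges == 0L && rep_f$n_nonmanifold_vertices == 0L) {
      out <- filled
      break
    }
    out <- filled
  }
  out <- remove_unreferenced_vertices(out)                   # (7)
  if (nrow(out$faces) == 0L)
    stop("degenerate geometry: repair removed every face")
  out
}

# delete non-manifold configurations: every face incident to an edge with
# more than two faces is removed; a vertex whose star splits into several
# edge-connected fans keeps its largest fan and loses the others (minimal
# resolution — deleting the whole star cascades into ever-growing holes
# when two excision scars meet at a vertex)
excise_nonmanifold <- function(mesh) {
  f <- mesh$faces
  ec <- edge_counts(f)
  bad_edge_keys <- names(ec$tab)[ec$tab > 2L]
  face_of <- rep(seq_len(nrow(f)), 3L)
  bad_faces <- unique(face_of[ec$key %in% bad_edge_keys])

  vstars <- split(rep(seq_len(nrow(f)), 3L), as.integer(f))
  for (vi in names(vstars)) {
    star <- unique(vstars[[vi]])
    if (length(star) <= 1L) next
    sub <- f[star, , drop = FALSE]
    vv <- as.integer(vi)
    other <- t(apply(sub, 1L, function(r) r[r != vv][1:2]))
    spoke <- cbind(rep(seq_along(star), 2L), c(other[, 1L], other[, 2L]))
    parent <- seq_along(star)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (g in split(spoke[, 1L], spoke[, 2L])) {
      if (length(g) > 1L) {
        r <- find(g[1L])
        for (j in g[-1L]) { rj <- find(j); if (rj != r) parent[rj] <- r }
      }
    }
    comp <- vapply(seq_along(star), find, integer(1))
    if (length(unique(comp)) > 1L) {
      keep_comp <- names(which.max(table(comp)))
      bad_faces <- union(bad_faces, star[comp != as.integer(keep_comp)])
    }
  }
  if (!length(bad_faces)) return(mesh)
  triangle_mesh(mesh$vertices, f[-bad_faces, , drop = FALSE], mesh$name)
}

#' Fill holes bounded by closed boundary edge loops
#'
#' Each closed cycle of boundary edges (edges incident to exactly one face)
#' with at most `max_loop_edges` edges is triangulated by a fan around the
#' loop's vertex centroid, oriented consistently with the surrounding
#' surface. Open (non-cyclic) boundary chains are left untouched with a
#' warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param max_loop_edges maximum loop length to fill (default unlimited).
#' @return a `triangle_mesh` with the qualifying loops closed.
#' @export
fill_holes <- function(mesh, max_loop_edges = Inf) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(mesh)
  # directed boundary edges, as oriented inside their face
  dir_e <- rbind(f[, c(1L, 2L), drop = FALSE],
                 f[, c(2L, 3L), drop = FALSE],
                 f[, c(3L, 1L), drop = FALSE])
  key <- paste(pmin(dir_e[, 1L], dir_e[, 2L]), pmax(dir_e[, 1L], dir_e[, 2L]))
  tab <- table(key)
  bnd <- dir_e[key %in% names(tab)[tab == 1L], , drop = FALSE]
  if (nrow(bnd) == 0L) return(mesh)

  # decompose the directed boundary edges into edge-disjoint cycles
  # (Hierholzer-style); a pinch vertex shared by two holes is traversed
  # once per cycle. Vertices with unbalanced in/out degree belong to open
  # chains and are left untouched.
  out_deg <- table(bnd[, 1L])
  in_deg <- table(bnd[, 2L])
  verts <- union(names(out_deg), names(in_deg))
  bal <- sapply(verts, function(v) {
    o <- out_deg[v]; i <- in_deg[v]
    (if (is.na(o)) 0L else o) == (if (is.na(i)) 0L else i)
  })
  if (!all(bal))
    warning("open boundary chain left unfilled")
  good <- bnd[bnd[, 1L] %in% verts[bal] & bnd[, 2L] %in% verts[bal], ,
              drop = FALSE]
  edge_used <- rep(FALSE, nrow(good))
  out_of <- split(seq_len(nrow(good)), good[, 1L])
  loops <- list()
  for (e0 in seq_len(nrow(good))) {
    if (edge_used[e0]) next
    loop <- good[e0, 1L]
    edge_used[e0] <- TRUE
    cur <- good[e0, 2L]
    ok <- TRUE
    while (cur != loop[1L]) {
      cand <- out_of[[as.character(cur)]]
      cand <- cand[!edge_used[cand]]
      if (!length(cand)) { ok <- FALSE; break }
      e <- cand[1L]
      edge_used[e] <- TRUE
      loop <- c(loop, cur)
      cur <- good[e, 2L]
      if (length(loop) > nrow(good)) { ok <- FALSE; break }
    }
    if (ok && length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
    else if (!ok) warning("open boundary chain left unfilled")
  }
  if (!length(loops)) return(mesh)

  verts <- mesh$vertices
  new_faces <- list()
  for (loop in loops) {
    if (length(loop) > max_loop_edges) next
    centre <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, centre)
    ci <- nrow(verts)
    k <- length(loop)
    # boundary edges run a -> b along the hole rim; fill with (b, a, centre)
    # to mirror the orientation of the missing faces
    a <- loop
    b <- c(loop[-1L], loop[1L])
    new_faces[[length(new_faces) + 1L]] <- cbind(b, a, rep(ci, k))
  }
  if (!length(new_faces)) return(mesh)
  triangle_mesh(verts, rbind(f, do.call(rbind, new_faces)), mesh$name)
}
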