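# Solid voxelization of closed surfaces onto a shared uniform grid, so that
# differently meshed deformed geometries become directly comparable.

#' Uniform voxel grid frame
#'
#' @param origin corner of the grid box (mm); voxel `(i, j, k)` has its
#'   center at `origin + (c(i, j, k) - 0.5) * pitch`.
#' @param pitch isotropic voxel edge length (mm, > 0).
#' @param dims integer voxel counts per axis.
#' @return an object of class `grid_frame`.
#' @export
grid_frame <- function(origin, pitch, dims) {
  if (!(pitch > 0)) stop("pitch must be > 0")
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (any(dims < 1L)) stop("dims must be positive")
  structure(list(origin = as.numeric(origin), pitch = as.numeric(pitch),
                 dims = dims), class = "grid_frame")
}

#' Build one shared grid frame for a set of meshes
#'
#' Computes the joint axis-aligned bounding box of all meshes and centers it
#' in an `N^3` grid, leaving at least `pad` voxels of margin on each side.
#' Every grid entering one comparison must use the same frame object.
#'
#' @param meshes list of [triangle_mesh()] (tet meshes are accepted too).
#' @param n grid size per axis (default 1024; tests and desk-scale runs use
#'   128).
#' @param pad margin in voxels (`n > 2 * pad`).
#' @return a [grid_frame()].
#' @export
make_common_frame <- function(meshes, n = 1024L, pad = 2L) {
  if (inherits(meshes, "triangle_mesh") || inherits(meshes, "tet_mesh"))
    meshes <- list(meshes)
  if (!length(meshes)) stop("at least one mesh is required")
  n <- as.integer(n); pad <- as.integer(pad)
  if (n <= 2L * pad) stop("n must exceed 2 * pad")
  boxes <- lapply(meshes, mesh_bbox)
  lo <- do.call(pmin, lapply(boxes, function(b) b["min", ]))
  hi <- do.call(pmax, lapply(boxes, function(b) b["max", ]))
  pitch <- max(hi - lo) / (n - 2L * pad)
  centre <- (lo + hi) / 2
  grid_frame(origin = centre - n * pitch / 2, pitch = pitch, dims = rep(n, 3L))
}

#' Binary occupancy grid
#' @param frame a [grid_frame()].
#' @param occupancy logical array matching `frame$dims`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(frame, occupancy) {
  if (!inherits(frame, "grid_frame")) stop("frame must be a grid_frame")
  occupancy <- array(as.logical(occupancy), dim = frame$dims)
  structure(list(frame = frame, occupancy = occupancy), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s, pitch %.4g mm, %d occupied voxels\n",
              paste(x$frame$dims, collapse = "x"), x$frame$pitch,
              sum(x$occupancy)))
  invisible(x)
}

frames_equal <- function(a, b) {
  identical(a$dims, b$dims) && a$pitch == b$pitch && all(a$origin == b$origin)
}

voxel_centers_axis <- function(frame, axis) {
  frame$origin[axis] + (seq_len(frame$dims[axis]) - 0.5) * frame$pitch
}

#' Solid voxelization of a closed surface
#'
#' A voxel is occupied iff its center lies inside the surface, decided by
#' ray parity along +x. Columns whose ray grazes a triangle edge or vertex
#' are recomputed with the ray jittered by `pitch * 1e-6`, keeping the
#' result deterministic. Only closed surfaces are accepted: open meshes must
#' be repaired first (see [strategy_b()]).
#'
#' @param mesh a closed [triangle_mesh()] inside the frame box.
#' @param frame a [grid_frame()], shared across every grid of a comparison.
#' @param fill `"solid"` fills the interior; `"shell"` keeps only the
#'   surface voxels of the solid.
#' @return a [voxel_grid()].
#' @export
voxelize_solid <- function(mesh, frame, fill = c("solid", "shell")) {
  fill <- match.arg(fill)
  ec <- edge_counts(mesh$faces)
  if (any(ec$tab != 2L))
    stop("mesh is not closed (boundary or non-manifold edges present); ",
         "repair it first (strategy_b) - only closed deformed boundaries ",
         "are voxelized")
  dims <- frame$dims
  xs <- voxel_centers_axis(frame, 1L)
  ys <- voxel_centers_axis(frame, 2L)
  zs <- voxel_centers_axis(frame, 3L)

  res <- voxelize_columns(mesh, xs, ys, zs)
  todo <- res$suspect
  attempt <- 1L
  # grazing rays are re-cast with an asymmetric jitter (equal y/z offsets
  # would slide along diagonal edges); grow the jitter until no ray grazes
  while (length(todo) && attempt <= 8L) {
    jit <- frame$pitch * 1e-6 * attempt
    redo <- voxelize_columns(mesh, xs, ys + jit, zs + jit * (1 + sqrt(2)),
                             only_cols = todo)
    res$inside[, todo] <- redo$inside[, todo]
    todo <- intersect(todo, redo$suspect)
    attempt <- attempt + 1L
  }
  occ <- array(FALSE, dims)
  occ[] <- as.logical(res$inside)  # inside is nx x (ny*nz), column-major ok
  grid <- voxel_grid(frame, occ)
  if (fill == "shell") {
    sv <- surface_voxels(grid)
    occ2 <- array(FALSE, dims)
    occ2[sv] <- TRUE
    grid <- voxel_grid(frame, occ2)
  }
  grid
}

# parity fill per (y, z) column; returns inside matrix (nx rows, ny*nz cols)
# and the set of suspect columns that grazed a triangle boundary
voxelize_columns <- function(mesh, xs, ys, zs, only_cols = NULL) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  v <- mesh$vertices; f <- mesh$faces
  ncol_total <- ny * nz
  col_acc <- vector("list", nrow(f))
  x_acc <- vector("list", nrow(f))
  sus_acc <- vector("list", nrow(f))
  tol <- 1e-12

  col_mask <- if (is.null(only_cols)) NULL else {
    m <- logical(ncol_total); m[only_cols] <- TRUE; m
  }

  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1L], ]; p2 <- v[f[t, 2L], ]; p3 <- v[f[t, 3L], ]
    ymin <- min(p1[2], p2[2], p3[2]); ymax <- max(p1[2], p2[2], p3[2])
    zmin <- min(p1[3], p2[3], p3[3]); zmax <- max(p1[3], p2[3], p3[3])
    iy <- which(ys >= ymin - tol & ys <= ymax + tol)
    iz <- which(zs >= zmin - tol & zs <= zmax + tol)
    if (!length(iy) || !length(iz)) next
    # signed area of the yz-projection
    d <- (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p3[2] - p1[2]) * (p2[3] - p1[3])
    if (abs(d) < 1e-14) next  # triangle parallel to the ray
    yy <- rep(ys[iy], times = length(iz))
    zz <- rep(zs[iz], each = length(iy))
    l1 <- ((p2[2] - yy) * (p3[3] - zz) - (p3[2] - yy) * (p2[3] - zz)) / d
    l2 <- ((p3[2] - yy) * (p1[3] - zz) - (p1[2] - yy) * (p3[3] - zz)) / d
    l3 <- 1 - l1 - l2
    graze_tol <- 1e-9
    inside_tri <- l1 > graze_tol & l2 > graze_tol & l3 > graze_tol
    grazing <- (abs(l1) <= graze_tol | abs(l2) <= graze_tol | abs(l3) <= graze_tol) &
               l1 > -graze_tol & l2 > -graze_tol & l3 > -graze_tol
    cols <- rep(iy, times = length(iz)) + (rep(iz, each = length(iy)) - 1L) * ny
    if (!is.null(col_mask)) {
      keep <- col_mask[cols]
      inside_tri <- inside_tri & keep
      grazing <- grazing & keep
    }
    if (any(grazing)) sus_acc[[t]] <- cols[grazing]
    hit <- which(inside_tri)
    if (length(hit)) {
      col_acc[[t]] <- cols[hit]
      x_acc[[t]] <- l1[hit] * p1[1] + l2[hit] * p2[1] + l3[hit] * p3[1]
    }
  }
  col_ids <- unlist(col_acc)
  x_cross <- unlist(x_acc)
  suspect <- unlist(sus_acc)
  if (is.null(col_ids)) col_ids <- integer(0)
  if (is.null(suspect)) suspect <- integer(0)

  inside <- matrix(FALSE, nx, ncol_total)
  if (length(col_ids)) {
    sp <- split(x_cross, col_ids)
    for (cn in names(sp)) {
      cr <- sort(sp[[cn]])
      parity <- findInterval(xs, cr) %% 2L == 1L
      inside[, as.integer(cn)] <- parity
    }
  }
  list(inside = inside, suspect = unique(suspect))
}

#' Surface voxels of an occupancy grid
#'
#' Occupied voxels with at least one empty 6-neighbor; the grid boundary
#' counts as empty.
#'
#' @param grid a [voxel_grid()].
#' @return integer matrix of voxel indices (one row per surface voxel,
#'   columns i, j, k).
#' @export
surface_voxels <- function(grid) {
  occ <- grid$occupancy
  d <- dim(occ)
  interior <- array(TRUE, d)
  pad_shift <- function(ax, dir) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1L) }
    else { idx_dst[[ax]] <- 1:(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      occ[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  all_nb <- pad_shift(1L, 1L) & pad_shift(1L, -1L) &
            pad_shift(2L, 1L) & pad_shift(2L, -1L) &
            pad_shift(3L, 1L) & pad_shift(3L, -1L)
  surf <- occ & !all_nb
  which(surf, arr.ind = TRUE)
}

surface_mask <- function(grid) {
  sv <- surface_voxels(grid)
  m <- array(FALSE, dim(grid$occupancy))
  m[sv] <- TRUE
  m
}
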