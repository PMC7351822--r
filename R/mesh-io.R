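#' Read a triangle surface mesh
#'
#' Supported formats: STL (ASCII and binary), PLY (ASCII), OFF, and legacy
#' VTK polydata (ASCII). STL facets are read as-is: every facet contributes
#' three vertex records and no implicit welding is performed — welding is a
#' repair step ([strategy_a()]), not an I/O step.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"off"`, `"vtk"`; inferred from the
#'   file extension when missing.
#' @return a [triangle_mesh()].
#' @export
read_surface <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read surface file: ", path)
  format <- infer_format(path, format)
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         off = read_off(path),
         vtk = read_vtk_polydata(path),
         stop("unsupported surface format: ", format))
}

#' Write a triangle surface mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format one of `"stl"`, `"ply"`, `"off"`, `"vtk"`; inferred from the
#'   extension when missing. STL output stores per-facet vertices (ASCII).
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- infer_format(path, format)
  switch(format,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         vtk = write_vtk_polydata(mesh, path),
         stop("unsupported surface format: ", format))
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("stl", "ply", "off", "vtk"))
    stop("cannot infer mesh format from extension: ", ext)
  ext
}

is_binary_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) return(FALSE)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) == 0L) return(FALSE)
  file.size(path) == 84 + 50 * as.numeric(n)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
  coords <- t(vapply(strsplit(trimws(vx), "\\s+"),
                     function(x) as.numeric(x[2:4]), numeric(3)))
  n_f <- nrow(coords) / 3L
  triangle_mesh(coords, matrix(seq_len(3L * n_f), n_f, 3L, byrow = TRUE),
                name = sub("\\.[^.]*$", "", basename(path)))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", 50L * n)
  m <- matrix(rec, nrow = 50L)
  fl <- matrix(NA_real_, n, 12L)
  for (j in 1:12) {
    bytes <- m[(4L * j - 3L):(4L * j), , drop = FALSE]
    fl[, j] <- readBin(as.raw(bytes), "double", n, size = 4L, endian = "little")
  }
  verts <- matrix(t(fl[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, matrix(seq_len(3L * n), n, 3L, byrow = TRUE),
                name = sub("\\.[^.]*$", "", basename(path)))
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals_raw(mesh)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals_raw(mesh)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(c(nrm[i, ], t(v[f[i, ], ])), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  hdr_end <- grep("^end_header", lines)[1]
  hdr <- lines[1:hdr_end]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                 function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    rec <- as.integer(fl[[i]])
    if (rec[1] != 3L) stop("non-triangular face in PLY at face index ", i)
    faces[i, ] <- rec[2:4] + 1L
  }
  triangle_mesh(vt, faces, name = sub("\\.[^.]*$", "", basename(path)))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(apply(mesh$faces - 1L, 1L, function(f) sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (!grepl("^OFF", trimws(lines[1]))) stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vt <- t(vapply(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"),
                 function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    rec <- as.integer(strsplit(trimws(lines[2 + nv + i]), "\\s+")[[1]])
    if (rec[1] != 3L) stop("non-triangular face in OFF at face index ", i)
    faces[i, ] <- rec[2:4] + 1L
  }
  triangle_mesh(vt, faces, name = sub("\\.[^.]*$", "", basename(path)))
}

write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(apply(mesh$faces - 1L, 1L, function(f) sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pts_i <- grep("^POINTS", lines)[1]
  if (is.na(pts_i)) stop("no POINTS section in VTK file: ", path)
  nv <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  nums <- scan_numbers_after(lines, pts_i, 3L * nv)
  vt <- matrix(nums, nv, 3L, byrow = TRUE)
  poly_i <- grep("^POLYGONS", lines)[1]
  if (is.na(poly_i)) stop("no POLYGONS section in VTK file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[poly_i]), "\\s+")[[1]][2:3])
  nf <- hdr[1]
  recs <- scan_numbers_after(lines, poly_i, hdr[2])
  faces <- matrix(NA_integer_, nf, 3L)
  pos <- 1L
  for (i in seq_len(nf)) {
    k <- as.integer(recs[pos])
    if (k != 3L) stop("non-triangular face in VTK polydata at face index ", i)
    faces[i, ] <- as.integer(recs[pos + 1:3]) + 1L
    pos <- pos + k + 1L
  }
  triangle_mesh(vt, faces, name = sub("\\.[^.]*$", "", basename(path)))
}

scan_numbers_after <- function(lines, header_idx, n_needed) {
  out <- numeric(0)
  i <- header_idx + 1L
  while (length(out) < n_needed && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    out <- c(out, as.numeric(tok))
    i <- i + 1L
  }
  if (length(out) < n_needed) stop("truncated VTK section")
  out[seq_len(n_needed)]
}

write_vtk_polydata <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", mesh$name, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mesh$vertices))), con)
  writeLines(apply(mesh$vertices, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(mesh$faces), 4L * nrow(mesh$faces)), con)
  writeLines(apply(mesh$faces - 1L, 1L, function(f) sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

#' Read a tetrahedral volume (legacy VTK unstructured grid)
#'
#' Only tetrahedral cells (VTK cell type 10) are accepted; any other cell
#' type is a format error. Node order is preserved.
#'
#' @param path file path to an ASCII legacy VTK unstructured grid.
#' @param format only `"vtk"` is supported.
#' @return a [tet_mesh()].
#' @export
read_volume <- function(path, format = "vtk") {
  if (!file.exists(path)) stop("cannot read volume file: ", path)
  lines <- readLines(path, warn = FALSE)
  pts_i <- grep("^POINTS", lines)[1]
  if (is.na(pts_i)) stop("no POINTS section in VTK file: ", path)
  nv <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  nodes <- matrix(scan_numbers_after(lines, pts_i, 3L * nv), nv, 3L, byrow = TRUE)
  cells_i <- grep("^CELLS", lines)[1]
  hdr <- as.integer(strsplit(trimws(lines[cells_i]), "\\s+")[[1]][2:3])
  nc <- hdr[1]
  recs <- scan_numbers_after(lines, cells_i, hdr[2])
  types_i <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(scan_numbers_after(lines, types_i, nc))
  bad <- which(types != 10L)
  if (length(bad))
    stop("non-tetrahedral cell type ", types[bad[1]], " at cell ", bad[1],
         "; only tetrahedra (VTK type 10) are supported")
  tets <- matrix(NA_integer_, nc, 4L)
  pos <- 1L
  for (i in seq_len(nc)) {
    k <- as.integer(recs[pos])
    if (k != 4L) stop("cell ", i, " has ", k, " nodes; expected 4")
    tets[i, ] <- as.integer(recs[pos + 1:4]) + 1L
    pos <- pos + k + 1L
  }
  tet_mesh(nodes, tets, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a tetrahedral volume (legacy VTK unstructured grid)
#'
#' @param vol a [tet_mesh()].
#' @param path output path.
#' @param point_vectors optional n x 3 matrix written as a `VECTORS` point
#'   data field (e.g. a displacement field).
#' @param vectors_name name of the point data field.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, point_vectors = NULL,
                         vectors_name = "displacement") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", vol$name, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(vol$nodes))), con)
  writeLines(apply(vol$nodes, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  nt <- nrow(vol$tets)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(apply(vol$tets - 1L, 1L,
                   function(t) sprintf("4 %d %d %d %d", t[1], t[2], t[3], t[4])), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  if (!is.null(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", nrow(vol$nodes)), con)
    writeLines(sprintf("VECTORS %s float", vectors_name), con)
    writeLines(apply(point_vectors, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  }
  invisible(path)
}
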