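# Independent brute-force oracles used to freeze expected values.

random_grid_pair <- function(seed, n, p = 0.35) {
  set.seed(seed)
  frame <- grid_frame(origin = c(0, 0, 0), pitch = 1, dims = rep(n, 3L))
  a <- voxel_grid(frame, array(runif(n^3) < p, rep(n, 3L)))
  b <- voxel_grid(frame, array(runif(n^3) < p, rep(n, 3L)))
  list(a = a, b = b)
}

# per-voxel loop confusion census
bf_confusion <- function(test, ref) {
  a <- as.logical(test$occupancy); b <- as.logical(ref$occupancy)
  counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(a)) {
    if (a[i] && b[i]) counts["TP"] <- counts["TP"] + 1
    else if (a[i] && !b[i]) counts["FP"] <- counts["FP"] + 1
    else if (!a[i] && b[i]) counts["FN"] <- counts["FN"] + 1
    else counts["TN"] <- counts["TN"] + 1
  }
  counts
}

# O(n^2) pair-counting adjusted Rand over all voxel pairs
bf_adjusted_rand <- function(test, ref) {
  x <- as.integer(test$occupancy)
  y <- as.integer(ref$occupancy)
  n <- length(x)
  s_both <- 0; s_x <- 0; s_y <- 0
  for (i in 1:(n - 1)) {
    same_x <- x[(i + 1):n] == x[i]
    same_y <- y[(i + 1):n] == y[i]
    s_x <- s_x + sum(same_x)
    s_y <- s_y + sum(same_y)
    s_both <- s_both + sum(same_x & same_y)
  }
  total <- n * (n - 1) / 2
  expected <- s_x * s_y / total
  maxi <- (s_x + s_y) / 2
  if (maxi == expected) return(NA_real_)
  (s_both - expected) / (maxi - expected)
}

bf_mutual_information <- function(test, ref) {
  a <- as.logical(test$occupancy); b <- as.logical(ref$occupancy)
  n <- length(a)
  mi <- 0
  for (va in c(TRUE, FALSE)) for (vb in c(TRUE, FALSE)) {
    pj <- sum(a == va & b == vb) / n
    if (pj > 0) mi <- mi + pj * log2(pj / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  mi
}

# all-pairs symmetric Hausdorff over surface voxel center coordinates
bf_hausdorff <- function(test, ref) {
  sa <- surface_voxels(test)
  sb <- surface_voxels(ref)
  d2 <- outer(sa[, 1], sb[, 1], "-")^2 + outer(sa[, 2], sb[, 2], "-")^2 +
    outer(sa[, 3], sb[, 3], "-")^2
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

# Sutherland-Hodgman halfspace clip of each triangle, fan-triangulated;
# independent of the package's edge-split construction
bf_clipped_area <- function(mesh, axis, cut) {
  total <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    poly <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    out <- list()
    np <- nrow(poly)
    for (k in seq_len(np)) {
      p <- poly[k, ]; q <- poly[if (k == np) 1L else k + 1L, ]
      pin <- p[axis] <= cut; qin <- q[axis] <= cut
      if (pin) out[[length(out) + 1L]] <- p
      if (pin != qin) {
        t <- (cut - p[axis]) / (q[axis] - p[axis])
        out[[length(out) + 1L]] <- p + t * (q - p)
      }
    }
    if (length(out) >= 3L) {
      pv <- do.call(rbind, out)
      for (k in 2:(nrow(pv) - 1L)) {
        u <- pv[k, ] - pv[1, ]; w <- pv[k + 1L, ] - pv[1, ]
        cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
                u[1] * w[2] - u[2] * w[1])
        total <- total + 0.5 * sqrt(sum(cr^2))
      }
    }
  }
  total
}

# Monte-Carlo area-weighted surface centroid (rejection-free: sample faces
# by area, uniform barycentric points)
mc_surface_centroid <- function(mesh, n = 20000, seed = 42) {
  set.seed(seed)
  a <- face_areas(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = a)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  pts <- w1 * mesh$vertices[mesh$faces[fi, 1L], , drop = FALSE] +
    w2 * mesh$vertices[mesh$faces[fi, 2L], , drop = FALSE] +
    w3 * mesh$vertices[mesh$faces[fi, 3L], , drop = FALSE]
  list(mean = colMeans(pts), se = apply(pts, 2, sd) / sqrt(n))
}

# direct quadrature oracle for one linear tet element stiffness matrix:
# shape gradients via central finite differences of barycentric coordinates
bf_element_stiffness <- function(X, D) {
  bary <- function(p) {
    # barycentric coordinates of p in tet X by solving the linear system
    A <- cbind(1, X)
    as.numeric(solve(t(A), c(1, p)))
  }
  h <- 1e-5
  g <- matrix(0, 4, 3)
  centre <- colMeans(X)
  for (d in 1:3) {
    e <- c(0, 0, 0); e[d] <- h
    g[, d] <- (bary(centre + e) - bary(centre - e)) / (2 * h)
  }
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[a, 1]; B[2, c0 + 2] <- g[a, 2]; B[3, c0 + 3] <- g[a, 3]
    B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
    B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
    B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
  }
  vol <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
  vol * t(B) %*% D %*% B
}

# naive double-loop electrostatic force sum
bf_electrostatic <- function(xd, xt, qd, qt, eps) {
  f <- matrix(0, nrow(xd), 3)
  for (i in seq_len(nrow(xd))) for (t in seq_len(nrow(xt))) {
    d <- xt[t, ] - xd[i, ]
    r2 <- sum(d * d) + eps^2
    f[i, ] <- f[i, ] + qd[i] * qt[t] * d / r2^1.5
  }
  f
}
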