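# Linear-elastic FEM on first-order tetrahedra: constitutive matrix and
# sparse stiffness assembly. These are the building blocks of both the
# registration dynamics and the phantom's ground-truth indentation solve.

#' Isotropic linear-elastic material matrix
#'
#' The 6x6 constitutive matrix in Voigt notation (engineering shear
#' strains), built from the Lame constants
#' `lambda = y p / ((1 + p)(1 - 2p))` and `mu = y / (2 (1 + p))`.
#'
#' @param young Young modulus `y` (stiffness scale).
#' @param poisson Poisson ratio `p`, strictly below 0.5 (the incompressible
#'   limit is singular) and above -1.
#' @return a symmetric positive-definite 6x6 matrix.
#' @export
elasticity_matrix <- function(young, poisson) {
  if (!(poisson > -1 && poisson < 0.5))
    stop("poisson ratio must lie in (-1, 0.5); p = 0.5 is singular")
  lambda <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- young / (2 * (1 + poisson))
  D <- matrix(0, 6L, 6L)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 12) for one linear tet, from the shape
# function gradients g (4 x 3)
tet_B_matrix <- function(g) {
  B <- matrix(0, 6L, 12L)
  for (a in 1:4) {
    c0 <- 3L * (a - 1L)
    B[1L, c0 + 1L] <- g[a, 1L]
    B[2L, c0 + 2L] <- g[a, 2L]
    B[3L, c0 + 3L] <- g[a, 3L]
    B[4L, c0 + 1L] <- g[a, 2L]; B[4L, c0 + 2L] <- g[a, 1L]
    B[5L, c0 + 2L] <- g[a, 3L]; B[5L, c0 + 3L] <- g[a, 2L]
    B[6L, c0 + 1L] <- g[a, 3L]; B[6L, c0 + 3L] <- g[a, 1L]
  }
  B
}

#' Assemble the global stiffness operator
#'
#' First-order tetrahedral FEM assembly of the elastic stiffness. The
#' operator is symmetric and, for a connected free-floating mesh, its null
#' space spans exactly the six rigid-body modes.
#'
#' @param vol a [tet_mesh()] with non-degenerate tetrahedra.
#' @param mat a 6x6 material matrix from [elasticity_matrix()].
#' @return a sparse symmetric `3N x 3N` `Matrix::dgCMatrix`, dof ordered as
#'   `(x1, y1, z1, x2, ...)`.
#' @export
assemble_stiffness <- function(vol, mat) {
  nodes <- vol$nodes
  tets <- vol$tets
  nt <- nrow(tets)
  vols <- tet_signed_volumes(nodes, tets)
  bad <- which(vols <= 0)
  if (length(bad))
    stop("degenerate (zero or inverted) tetrahedron at index ", bad[1])
  ii <- vector("list", nt); jj <- vector("list", nt); xx <- vector("list", nt)
  for (t in seq_len(nt)) {
    idx <- tets[t, ]
    X <- nodes[idx, , drop = FALSE]
    # gradients of barycentric shape functions: rows of solve([1 X])
    A <- cbind(1, X)
    G <- solve(A)            # 4x4; gradients are rows 2:4 transposed
    g <- t(G[2:4, , drop = FALSE])  # 4 x 3
    B <- tet_B_matrix(g)
    Ke <- vols[t] * crossprod(B, mat %*% B)
    dof <- as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
    ii[[t]] <- rep(dof, times = 12L)
    jj[[t]] <- rep(dof, each = 12L)
    xx[[t]] <- as.numeric(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3L * nrow(nodes), 3L * nrow(nodes)))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}
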