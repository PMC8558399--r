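# Diffusion-approximation FEM forward model.
#
# Photon transport in strongly scattering tissue is modeled by the
# steady-state diffusion equation
#     -div(D grad(phi)) + mua * phi = S,   D = 1/(3 (mua + musp)),
# with the Robin (partial-current) boundary condition
#     phi + 2 A D dphi/dn = 0,
# discretized with linear tetrahedral finite elements. The assembled
# operator K = stiffness + absorption mass + (1/2A) boundary mass is sparse,
# symmetric positive definite; one Cholesky factorization is reused across
# all right-hand sides of a dataset sweep.

#' Region-wise optical properties
#'
#' @param mua Named numeric vector of absorption coefficients (mm^-1), one
#'   entry per mesh region name.
#' @param musp Named numeric vector of reduced scattering coefficients
#'   (mm^-1), same names.
#' @param n Tissue refractive index (default 1.37), used to derive the
#'   internal-reflection boundary parameter `A` when not given.
#' @param A Optional override of the boundary reflection parameter.
#' @return An object of class `blt_optics`.
#' @details With refractive-index mismatch at the tissue--air interface,
#'   `A = (1 + R_eff) / (1 - R_eff)` where `R_eff` is an empirical
#'   polynomial fit in `1/n` (Schweiger-style approximation). `A = 1`
#'   corresponds to a matched boundary.
#' @examples
#' default_optics()
#' @export
optical_properties <- function(mua, musp, n = 1.37, A = NULL) {
  if (is.null(names(mua)) || is.null(names(musp)) ||
      !setequal(names(mua), names(musp))) {
    stop("mua and musp must be named vectors over the same region names")
  }
  musp <- musp[names(mua)]
  if (any(mua <= 0) || any(musp <= 0)) {
    stop("all optical coefficients must be positive")
  }
  if (n < 1) stop("refractive index must be >= 1")
  if (is.null(A)) {
    reff <- -1.4399 / n^2 + 0.7099 / n + 0.6681 + 0.0636 * n
    A <- (1 + reff) / (1 - reff)
  }
  structure(list(mua = mua, musp = musp, n = n, A = A), class = "blt_optics")
}

#' Default head-tissue optical properties at the firefly-luciferase
#' emission band
#'
#' Absorption and reduced scattering coefficients (mm^-1) for brain, skull
#' and muscle used throughout the simulations.
#' @param n Tissue refractive index.
#' @return A `blt_optics` object.
#' @export
default_optics <- function(n = 1.37) {
  optical_properties(
    mua  = c(brain = 0.0389, skull = 0.0804, muscle = 0.1154),
    musp = c(brain = 1.7134, skull = 2.0690, muscle = 0.4674),
    n = n)
}

#' Diffusion coefficient for one region
#' @param mua,musp Absorption and reduced scattering coefficients (mm^-1).
#' @return `1 / (3 (mua + musp))` in mm.
#' @export
diffusion_coefficient <- function(mua, musp) 1 / (3 * (mua + musp))

#' Assemble the diffusion FEM system for a mesh and optics
#'
#' @param mesh A `blt_tetmesh`.
#' @param optics A `blt_optics` with entries for every region in the mesh.
#' @return A `blt_forward_system`: the sparse SPD operator `K`, its Cholesky
#'   factorization, the plain (unit-coefficient) mass matrix `M0` used to
#'   form volume-source loads, and the mesh.
#' @export
assemble_system <- function(mesh, optics) {
  stopifnot(inherits(mesh, "blt_tetmesh"), inherits(optics, "blt_optics"))
  regions_present <- mesh$region_names[sort(unique(mesh$region))]
  missing <- setdiff(regions_present, names(optics$mua))
  if (length(missing)) {
    stop("no optical properties for region(s): ",
         paste(missing, collapse = ", "))
  }
  nn <- nrow(mesh$nodes)
  tets <- mesh$tets
  nt <- nrow(tets)
  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  a <- mesh$nodes[tets[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[tets[, 3], , drop = FALSE] - p1
  cc <- mesh$nodes[tets[, 4], , drop = FALSE] - p1
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  bxc <- cross3(b, cc)
  det6 <- rowSums(a * bxc)          # 6 * signed volume, > 0 by orientation
  vol <- det6 / 6
  g2 <- bxc / det6                  # grad of barycentric coords 2..4
  g3 <- cross3(cc, a) / det6
  g4 <- cross3(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)
  rname <- mesh$region_names[mesh$region]
  Dt <- diffusion_coefficient(optics$mua[rname], optics$musp[rname])
  mua_t <- optics$mua[rname]

  ii <- integer(0); jj <- integer(0)
  xk <- numeric(0); xm <- numeric(0)   # K-values and plain-mass values
  idx <- vector("list", 16)
  k <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      k <- k + 1
      stiff <- Dt * vol * rowSums(grads[[i]] * grads[[j]])
      mass0 <- vol / 20 * (1 + (i == j))
      idx[[k]] <- list(i = tets[, i], j = tets[, j],
                       xk = stiff + mua_t * mass0, xm = mass0)
    }
  }
  ii <- unlist(lapply(idx, `[[`, "i"), use.names = FALSE)
  jj <- unlist(lapply(idx, `[[`, "j"), use.names = FALSE)
  xk <- unlist(lapply(idx, `[[`, "xk"), use.names = FALSE)
  xm <- unlist(lapply(idx, `[[`, "xm"), use.names = FALSE)

  # Robin boundary mass: (1/(2A)) * int_{dOmega} u v dA on linear triangles
  f <- mesh$boundary_faces
  fa <- mesh$nodes[f[, 1], , drop = FALSE]
  e1 <- mesh$nodes[f[, 2], , drop = FALSE] - fa
  e2 <- mesh$nodes[f[, 3], , drop = FALSE] - fa
  area <- sqrt(rowSums(cross3(e1, e2)^2)) / 2
  bscale <- 1 / (2 * optics$A)
  bi <- integer(0); bj <- integer(0); bx <- numeric(0)
  for (i in 1:3) {
    for (j in 1:3) {
      bi <- c(bi, f[, i]); bj <- c(bj, f[, j])
      bx <- c(bx, bscale * area / 12 * (1 + (i == j)))
    }
  }
  K <- Matrix::sparseMatrix(i = c(ii, bi), j = c(jj, bj), x = c(xk, bx),
                            dims = c(nn, nn), symmetric = FALSE)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  M0 <- Matrix::sparseMatrix(i = ii, j = jj, x = xm, dims = c(nn, nn))
  M0 <- Matrix::forceSymmetric((M0 + Matrix::t(M0)) / 2)
  chol <- tryCatch(Matrix::Cholesky(K, LDL = FALSE),
                   error = function(e) {
                     stop("assembled operator is not positive definite: ",
                          conditionMessage(e))
                   })
  structure(list(K = K, M0 = M0, chol = chol, mesh = mesh, optics = optics),
            class = "blt_forward_system")
}

#' Solve the forward problem for one or more source distributions
#'
#' The source is a nodal density (photons per mm^3 per s, arbitrary
#' consistent units); the load vector is the mass-matrix-weighted source so
#' that total emitted power scales with source volume. Columns are solved
#' simultaneously against the cached factorization.
#'
#' @param system A `blt_forward_system`.
#' @param source Numeric vector of length `n_nodes`, or a matrix with one
#'   source per column. Set `point_load = TRUE` to interpret `source`
#'   directly as a nodal load (used e.g. for reciprocity checks).
#' @param point_load Skip the mass-matrix weighting.
#' @return Nodal fluence, same shape as `source`.
#' @export
solve_forward <- function(system, source, point_load = FALSE) {
  stopifnot(inherits(system, "blt_forward_system"))
  v <- is.null(dim(source))
  src <- if (v) matrix(source, ncol = 1) else as.matrix(source)
  if (nrow(src) != nrow(system$K)) {
    stop("source length ", nrow(src), " does not match node count ",
         nrow(system$K))
  }
  if (any(!is.finite(src))) stop("source contains non-finite values")
  rhs <- if (point_load) src else as.matrix(system$M0 %*% src)
  x <- as.matrix(Matrix::solve(system$chol, rhs, system = "A"))
  res <- as.matrix(system$K %*% x) - rhs
  rel <- sqrt(colSums(res^2)) / pmax(sqrt(colSums(rhs^2)), .Machine$double.xmin)
  if (any(rel > 1e-8 & colSums(rhs^2) > 0)) {
    stop("forward solve residual exceeds tolerance: max relative residual ",
         format(max(rel), digits = 3))
  }
  if (v) drop(x) else x
}

#' Restrict nodal fluence to the surface measurement vector
#'
#' Returns the fluence at the mesh's persisted surface-node order; tiny
#' negative values from non-acute elements (magnitude below `1e-12 * max`)
#' are clamped to zero.
#'
#' @param fluence Length `n_nodes` vector (or matrix, one field per column).
#' @param mesh A `blt_tetmesh`.
#' @return Length-N surface flux vector (or N x k matrix).
#' @export
surface_flux <- function(fluence, mesh) {
  v <- is.null(dim(fluence))
  fl <- if (v) matrix(fluence, ncol = 1) else fluence
  if (nrow(fl) != nrow(mesh$nodes)) {
    stop("fluence length ", nrow(fl), " does not match node count ",
         nrow(mesh$nodes))
  }
  phi <- fl[mesh$surface_nodes, , drop = FALSE]
  thr <- -1e-12 * max(abs(phi))
  phi[phi < 0 & phi >= thr] <- 0
  if (v) drop(phi) else phi
}
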