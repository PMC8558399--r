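test_that("optical properties validate and derive the boundary parameter", {
  opt <- default_optics()
  expect_equal(unname(opt$mua["brain"]), 0.0389)
  expect_equal(unname(opt$musp["skull"]), 2.0690)
  expect_gt(opt$A, 1)  # mismatched boundary reflects more than matched
  expect_equal(optical_properties(c(a = 1), c(a = 1), A = 2)$A, 2)
  expect_error(optical_properties(c(a = -1), c(a = 1)), "positive")
  expect_error(optical_properties(c(a = 1), c(b = 1)), "same region names")
  # diffusion coefficient from the stated formula, brain tissue
  expect_equal(diffusion_coefficient(0.0389, 1.7134),
               1 / (3 * (0.0389 + 1.7134)), tolerance = 1e-12)
  expect_equal(diffusion_coefficient(0.0389, 1.7134), 0.19023,
               tolerance = 1e-4)
})

test_that("assembly yields a symmetric positive-definite operator", {
  one <- single_tet_mesh()
  sys1 <- assemble_system(one, optical_properties(c(brain = 0.01),
                                                  c(brain = 1)))
  expect_equal(dim(sys1$K), c(4, 4))
  expect_equal(max(abs(sys1$K - Matrix::t(sys1$K))), 0)
  expect_true(all(eigen(as.matrix(sys1$K))$values > 0))
  expect_error(assemble_system(one, optical_properties(c(liver = 1),
                                                       c(liver = 1))),
               "no optical properties")
})

test_that("stronger absorption decreases fluence pointwise", {
  mesh <- small_mesh()
  opt1 <- default_optics()
  opt2 <- optical_properties(mua = opt1$mua * 2, musp = opt1$musp,
                             n = opt1$n)
  ctr <- which.min(rowSums(mesh$nodes^2))
  src <- numeric(nrow(mesh$nodes))
  src[ctr] <- 1
  x1 <- solve_forward(assemble_system(mesh, opt1), src)
  x2 <- solve_forward(assemble_system(mesh, opt2), src)
  expect_true(all(x2 < x1))
})

test_that("forward solve is linear and exact for degenerate inputs", {
  mesh <- small_mesh()
  sys <- small_system()
  n <- nrow(mesh$nodes)
  expect_equal(solve_forward(sys, numeric(n)), numeric(n))
  set.seed(4)
  s1 <- runif(n)
  s2 <- runif(n)
  x12 <- solve_forward(sys, 2 * s1 + 3 * s2)
  xs <- solve_forward(sys, cbind(s1, s2))
  expect_lt(max(abs(x12 - (2 * xs[, 1] + 3 * xs[, 2]))) / max(abs(x12)),
            1e-10)
  expect_error(solve_forward(sys, numeric(3)), "does not match")
  expect_error(solve_forward(sys, c(NA, numeric(n - 1))), "non-finite")
})

test_that("reciprocity holds to solver tolerance", {
  mesh <- small_mesh()
  sys <- small_system()
  n <- nrow(mesh$nodes)
  i <- which.min(rowSums(mesh$nodes^2))
  j <- mesh$surface_nodes[7]
  ei <- numeric(n); ei[i] <- 1
  ej <- numeric(n); ej[j] <- 1
  xi <- solve_forward(sys, ei, point_load = TRUE)
  xj <- solve_forward(sys, ej, point_load = TRUE)
  expect_lt(abs(xi[j] - xj[i]) / abs(xi[j]), 1e-10)
})

test_that("surface restriction follows the persisted order", {
  mesh <- small_mesh()
  n <- nrow(mesh$nodes)
  phi <- surface_flux(rep(1, n), mesh)
  expect_length(phi, length(mesh$surface_nodes))
  expect_true(all(phi == 1))
  # restriction picks exactly the surface nodes in persisted order
  fl <- seq_len(n) * 1.0
  expect_equal(surface_flux(fl, mesh), fl[mesh$surface_nodes])
  # tiny negatives are clamped, larger values untouched
  fl2 <- rep(1, n)
  fl2[mesh$surface_nodes[1]] <- -1e-15
  expect_equal(surface_flux(fl2, mesh)[1], 0)
})

test_that("a centered source respects the lattice symmetry of the phantom", {
  mesh <- small_mesh()
  sys <- small_system()
  ctr <- which.min(rowSums(mesh$nodes^2))
  src <- numeric(nrow(mesh$nodes))
  src[ctr] <- 1
  phi <- surface_flux(solve_forward(sys, src), mesh)
  # the lattice triangulation is symmetric under coordinate permutations
  # and point inversion (not the full octahedral group: the cube diagonal
  # picks a direction); flux must agree exactly within those orbits
  orb <- apply(mesh$nodes[mesh$surface_nodes, ], 1, function(p) {
    min(paste(sort(p), collapse = ","), paste(sort(-p), collapse = ","))
  })
  spread <- tapply(phi, orb, function(v) diff(range(v)) / max(v))
  expect_lt(max(spread), 1e-10)
})

test_that("deeper sources produce dimmer surface maxima", {
  mesh <- fixture("mesh678", function() {
    generate_layered_phantom(phantom_spec(radii = c(6, 7, 8), edge = 1))
  })
  sys <- fixture("sys678u", function() {
    assemble_system(mesh, optical_properties(
      mua = c(brain = 0.0389, skull = 0.0389, muscle = 0.0389),
      musp = c(brain = 1.7134, skull = 1.7134, muscle = 1.7134)))
  })
  n <- nrow(mesh$nodes)
  shallow <- which.min(rowSums(sweep(mesh$nodes, 2, c(0, 0, 5))^2))
  deep <- which.min(rowSums(mesh$nodes^2))
  mk <- function(ctr) {
    inc <- which(rowSums(matrix(mesh$tets %in% ctr, ncol = 4)) > 0)
    ns <- unique(as.vector(mesh$tets[inc, ]))
    s <- numeric(n); s[ns] <- 1
    s
  }
  phi_sh <- surface_flux(solve_forward(sys, mk(shallow)), mesh)
  phi_dp <- surface_flux(solve_forward(sys, mk(deep)), mesh)
  expect_gt(max(phi_sh), max(phi_dp))
})

test_that("FEM fluence matches the infinite-medium Green's function in the
           interior regime", {
  mesh <- fixture("mesh678", function() {
    generate_layered_phantom(phantom_spec(radii = c(6, 7, 8), edge = 1))
  })
  sys <- fixture("sys678u", function() {
    assemble_system(mesh, optical_properties(
      mua = c(brain = 0.0389, skull = 0.0389, muscle = 0.0389),
      musp = c(brain = 1.7134, skull = 1.7134, muscle = 1.7134)))
  })
  n <- nrow(mesh$nodes)
  ctr <- which.min(rowSums(mesh$nodes^2))
  inc <- which(rowSums(matrix(mesh$tets %in% ctr, ncol = 4)) > 0)
  node_set <- sort(unique(as.vector(mesh$tets[inc, ])))
  src <- numeric(n); src[node_set] <- 1
  x <- solve_forward(sys, src)
  D <- diffusion_coefficient(0.0389, 1.7134)
  mueff <- sqrt(0.0389 / D)
  tc <- bltrecon:::tet_centroids(mesh$nodes, mesh$tets)
  tv <- tet_volumes(mesh)
  frac <- rowSums(matrix(mesh$tets %in% node_set, ncol = 4)) / 4
  touch <- which(frac > 0)
  # probes >= 2 transport mean free paths from the source region and
  # >= 3 from the boundary (mfp ~ 0.57 mm here)
  r <- sqrt(rowSums(mesh$nodes^2))
  probe <- which(r >= 3 & r <= 5.5)
  G <- function(d) exp(-mueff * d) / (4 * pi * D * pmax(d, 1e-9))
  pred <- vapply(probe, function(i) {
    d <- sqrt(rowSums((tc[touch, , drop = FALSE] -
                         matrix(mesh$nodes[i, ], length(touch), 3,
                                byrow = TRUE))^2))
    sum(tv[touch] * frac[touch] * G(d))
  }, numeric(1))
  rel <- abs(x[probe] - pred) / pred
  expect_lt(max(rel), 0.15)
})

test_that("interior fluence converges under mesh refinement", {
  probe_pt <- c(0, 0, 2)
  vals <- vapply(c(2, 1, 0.5), function(h) {
    mesh <- generate_layered_phantom(phantom_spec(radii = c(3, 3.5, 4),
                                                  edge = h))
    sys <- assemble_system(mesh, default_optics())
    # geometric source: unit density on tets with centroid within 1 mm of
    # the center, comparable across resolutions
    tc <- bltrecon:::tet_centroids(mesh$nodes, mesh$tets)
    st <- which(rowSums(tc^2) <= 1)
    src_nodes <- unique(as.vector(mesh$tets[st, ]))
    s <- numeric(nrow(mesh$nodes)); s[src_nodes] <- 1
    x <- solve_forward(sys, s)
    x[which.min(rowSums(sweep(mesh$nodes, 2, probe_pt)^2))]
  }, numeric(1))
  expect_lt(abs(vals[3] - vals[2]), abs(vals[2] - vals[1]))
})
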