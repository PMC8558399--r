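# Labeled tetrahedral phantoms: generation, surface extraction, geometry queries.

#' Specification of a layered spherical phantom
#'
#' Describes a nested three-region phantom (by default brain core, skull
#' shell, muscle shell) used as a reproducible stand-in for a small-animal
#' head geometry. All lengths are millimetres.
#'
#' @param radii Strictly increasing numeric vector of layer radii (mm),
#'   innermost region first. The last entry is the outer surface radius.
#' @param edge Target edge length (mm) of the tetrahedral mesh; the phantom
#'   is built on a regular lattice with this spacing.
#' @param regions Character vector of region names, one per radius,
#'   innermost first.
#' @return An object of class `blt_phantom_spec`.
#' @examples
#' spec <- phantom_spec(radii = c(6, 7, 8), edge = 1.5)
#' @export
phantom_spec <- function(radii = c(4, 6, 8), edge = 1,
                         regions = c("brain", "skull", "muscle")) {
  radii <- as.numeric(radii)
  if (length(radii) < 1 || any(!is.finite(radii)) || any(diff(radii) <= 0) ||
      radii[1] <= 0) {
    stop("phantom radii must be positive and strictly increasing, got: ",
         paste(radii, collapse = ", "))
  }
  if (!is.numeric(edge) || length(edge) != 1 || edge <= 0) {
    stop("target edge length must be a single positive number, got: ", edge)
  }
  if (length(regions) != length(radii)) {
    stop("need one region name per radius (", length(radii), "), got ",
         length(regions))
  }
  if (edge > radii[1]) {
    stop("edge length ", edge, " mm exceeds the innermost radius ", radii[1],
         " mm; the inner region would contain no elements")
  }
  structure(list(radii = radii, edge = edge, regions = as.character(regions)),
            class = "blt_phantom_spec")
}

# Kuhn/Freudenthal subdivision of the unit cube into 6 tetrahedra sharing the
# main diagonal. Using the same subdivision in every lattice cell yields a
# face-to-face conforming tetrahedralization.
.kuhn_tets <- local({
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  idx <- function(x, y, z) which(corners[, 1] == x & corners[, 2] == y &
                                   corners[, 3] == z)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tets <- t(vapply(perms, function(p) {
    v <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
    v[2, p[1]] <- 1
    v[3, p[1]] <- 1
    v[3, p[2]] <- 1
    vapply(seq_len(4), function(i) idx(v[i, 1], v[i, 2], v[i, 3]), integer(1))
  }, integer(4)))
  list(corners = corners, tets = tets)
})

#' Generate a layered spherical tetrahedral phantom
#'
#' Builds a conforming tetrahedral mesh of a ball of the outer radius on a
#' regular lattice (each lattice cell split into six tetrahedra), labels each
#' tetrahedron by the innermost layer containing its centroid, and extracts
#' the boundary surface. The surface-node order is persisted with the mesh
#' (ascending node index) so that surface flux vectors are reproducible.
#'
#' @param spec A [phantom_spec()].
#' @return A `blt_tetmesh`: list with `nodes` (n x 3 matrix, mm), `tets`
#'   (t x 4 integer matrix, 1-based), `region` (integer per tet),
#'   `region_names`, `boundary_faces` (f x 3 integer matrix) and
#'   `surface_nodes` (sorted integer vector).
#' @examples
#' mesh <- generate_layered_phantom(phantom_spec(radii = c(3, 3.5, 4)))
#' @export
generate_layered_phantom <- function(spec) {
  stopifnot(inherits(spec, "blt_phantom_spec"))
  h <- spec$edge
  R <- spec$radii[length(spec$radii)]
  n <- ceiling(R / h)
  # lattice cell lower corners; keep cells whose center lies inside the ball
  g <- seq(-n, n - 1)
  cells <- as.matrix(expand.grid(i = g, j = g, k = g))
  ctr <- (cells + 0.5) * h
  keep <- rowSums(ctr^2) <= R^2
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) {
    stop("no lattice cells inside radius ", R, " mm at edge length ", h,
         " mm; refine the edge length")
  }
  # enumerate nodes of kept cells
  corners <- .kuhn_tets$corners
  ncell <- nrow(cells)
  vi <- cells[rep(seq_len(ncell), each = 8), , drop = FALSE] +
    corners[rep(1:8, times = ncell), , drop = FALSE]
  side <- 2L * n + 2L
  key <- (vi[, 1] + n) * side * side + (vi[, 2] + n) * side + (vi[, 3] + n)
  ukey <- sort(unique(key))
  node_id <- match(key, ukey)
  un <- match(ukey, key)
  nodes <- vi[un, , drop = FALSE] * h
  colnames(nodes) <- c("x", "y", "z")
  # six tets per cell, corner ids mapped through node_id
  corner_ids <- matrix(node_id, nrow = 8)  # 8 x ncell
  kt <- .kuhn_tets$tets                    # 6 x 4
  tets <- matrix(0L, nrow = 6L * ncell, ncol = 4L)
  for (r in 1:6) {
    tets[seq.int(r, by = 6L, length.out = ncell), ] <- t(corner_ids[kt[r, ], ,
                                                                    drop = FALSE])
  }
  tets <- orient_tets(nodes, tets)
  cen <- tet_centroids(nodes, tets)
  rad <- sqrt(rowSums(cen^2))
  region <- findInterval(rad, spec$radii, left.open = TRUE) + 1L
  region[region > length(spec$radii)] <- length(spec$radii)
  surf <- extract_surface_raw(tets)
  mesh <- structure(list(
    nodes = nodes, tets = tets, region = region,
    region_names = spec$regions,
    boundary_faces = surf$boundary_faces,
    surface_nodes = surf$surface_nodes,
    spec = spec), class = "blt_tetmesh")
  if (!mesh_is_connected(mesh)) {
    stop("generated phantom is not connected (radii ",
         paste(spec$radii, collapse = "/"), " mm, edge ", h, " mm)")
  }
  mesh
}

#' @exportS3Method base::print
print.blt_tetmesh <- function(x, ...) {
  cat("blt_tetmesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      length(x$surface_nodes), "surface nodes\n")
  vols <- tapply(tet_volumes(x), x$region_names[x$region], sum)
  cat("  region volumes (mm^3):",
      paste(names(vols), round(vols, 1), collapse = ", "), "\n")
  invisible(x)
}

# Flip vertex pairs so every signed tet volume is positive.
orient_tets <- function(nodes, tets) {
  v <- signed_tet_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  if (any(abs(signed_tet_volumes(nodes, tets)) < .Machine$double.eps)) {
    stop("mesh contains degenerate (zero-volume) tetrahedra")
  }
  tets
}

signed_tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
     a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
     a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Per-tetrahedron volumes (mm^3)
#' @param mesh A `blt_tetmesh`.
#' @return Numeric vector, one volume per tetrahedron.
#' @export
tet_volumes <- function(mesh) {
  abs(signed_tet_volumes(mesh$nodes, mesh$tets))
}

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
     nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

# Encode sorted triangles as scalar keys (valid while n_nodes^3 < 2^53).
face_keys <- function(faces, n_nodes) {
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  (lo - 1) * n_nodes^2 + (mid - 1) * n_nodes + (hi - 1)
}

.face_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))

# Surface extraction on a raw connectivity matrix: a face is on the boundary
# iff it belongs to exactly one tetrahedron.
extract_surface_raw <- function(tets) {
  nn <- max(tets)
  faces <- do.call(rbind, lapply(1:4, function(r) tets[, .face_local[r, ]]))
  key <- face_keys(faces, nn)
  ord <- order(key)
  r <- rle(key[ord])
  if (any(r$lengths > 2)) {
    stop("non-manifold connectivity: ", sum(r$lengths > 2),
         " faces shared by more than two tetrahedra")
  }
  ends <- cumsum(r$lengths)
  bidx <- ord[ends[r$lengths == 1]]
  boundary_faces <- faces[bidx, , drop = FALSE]
  surface_nodes <- sort(unique(as.vector(boundary_faces)))
  list(boundary_faces = boundary_faces, surface_nodes = surface_nodes)
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' A triangular face is a boundary face iff it belongs to exactly one
#' tetrahedron. Surface nodes are returned in ascending node-index order;
#' this order is the canonical arrangement of surface flux vectors.
#'
#' @param mesh A `blt_tetmesh` (or any list with a `tets` matrix).
#' @return List with `boundary_faces` (f x 3 integer matrix) and
#'   `surface_nodes` (sorted integer vector).
#' @export
extract_surface <- function(mesh) {
  extract_surface_raw(mesh$tets)
}

mesh_is_connected <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$nodes) - igraph::vcount(g)))
  igraph::components(g)$no == 1
}

# Unique undirected node-adjacency edges (nodes sharing a tet edge).
mesh_edges <- function(mesh) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ed <- do.call(rbind, lapply(seq_len(6), function(r) {
    mesh$tets[, pairs[r, ], drop = FALSE]
  }))
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed[!duplicated(ed[, 1] * (nrow(mesh$nodes) + 1) + ed[, 2]), , drop = FALSE]
}

# Tets incident to each node, as a list indexed by node id.
node_tet_incidence <- function(mesh) {
  nt <- nrow(mesh$tets)
  split(rep(seq_len(nt), times = 4), as.vector(mesh$tets))
}

#' Geometry of a source node set
#'
#' Computes the volume, barycenter and depth of a candidate source. The
#' source region is the set of tetrahedra incident to `center_node` when one
#' is given (the construction used for single sources), otherwise all
#' tetrahedra whose four vertices lie in `node_set`. The barycenter is the
#' unweighted mean of the node coordinates; depth is the minimum Euclidean
#' distance from the barycenter to the boundary surface (point-to-triangle
#' distance over the boundary faces).
#'
#' @param mesh A `blt_tetmesh`.
#' @param node_set Integer vector of node indices defining the source.
#' @param center_node Optional center node whose incident tetrahedra define
#'   the source region.
#' @return List with `volume` (mm^3), `barycenter` (length-3, mm) and
#'   `depth` (mm).
#' @export
source_geometry <- function(mesh, node_set, center_node = NULL) {
  node_set <- as.integer(node_set)
  if (length(node_set) == 0) stop("source node set is empty")
  if (any(node_set < 1 | node_set > nrow(mesh$nodes))) {
    stop("source node set contains invalid node indices")
  }
  if (!is.null(center_node)) {
    inc <- which(rowSums(matrix(mesh$tets %in% as.integer(center_node),
                                ncol = 4)) > 0)
    src_tets <- inc
  } else {
    inset <- matrix(mesh$tets %in% node_set, ncol = 4)
    src_tets <- which(rowSums(inset) == 4)
  }
  vol <- sum(abs(signed_tet_volumes(mesh$nodes,
                                    mesh$tets[src_tets, , drop = FALSE])))
  bc <- colMeans(mesh$nodes[node_set, , drop = FALSE])
  depth <- min(point_triangle_distances(bc, mesh))
  list(volume = vol, barycenter = unname(bc), depth = depth,
       source_tets = src_tets)
}

# Distance from a point to each boundary triangle: closest point on the
# supporting plane if its barycentric coordinates are admissible, otherwise
# the nearest point on one of the three edges.
point_triangle_distances <- function(p, mesh) {
  f <- mesh$boundary_faces
  A <- mesh$nodes[f[, 1], , drop = FALSE]
  B <- mesh$nodes[f[, 2], , drop = FALSE]
  C <- mesh$nodes[f[, 3], , drop = FALSE]
  E0 <- B - A
  E1 <- C - A
  D <- sweep(A, 2, p)
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c2 <- rowSums(E1 * E1)
  d <- rowSums(E0 * D);  e <- rowSums(E1 * D)
  det <- pmax(a * c2 - b * b, .Machine$double.eps)
  s <- (b * e - c2 * d) / det
  t <- (b * d - a * e) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  cp <- A + s * E0 + t * E1
  d2 <- rowSums((cp - rep(p, each = nrow(A)))^2)
  out <- which(!inside)
  if (length(out)) {
    seg <- function(P, Q) {
      PQ <- Q - P
      tt <- rowSums(sweep(-P, 2, p, `+`) * PQ) /
        pmax(rowSums(PQ * PQ), .Machine$double.eps)
      tt <- pmin(pmax(tt, 0), 1)
      cps <- P + tt * PQ
      rowSums((cps - rep(p, each = nrow(P)))^2)
    }
    d2[out] <- pmin(seg(A[out, , drop = FALSE], B[out, , drop = FALSE]),
                    seg(A[out, , drop = FALSE], C[out, , drop = FALSE]),
                    seg(B[out, , drop = FALSE], C[out, , drop = FALSE]))
  }
  sqrt(d2)
}
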