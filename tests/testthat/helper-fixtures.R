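# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# ~300-node three-region phantom: fast enough for per-test solves
small_mesh <- function() {
  fixture("small_mesh", function() {
    generate_layered_phantom(phantom_spec(radii = c(3, 3.5, 4), edge = 1))
  })
}

small_system <- function() {
  fixture("small_system", function() {
    assemble_system(small_mesh(), default_optics())
  })
}

small_dataset <- function() {
  fixture("small_dataset", function() {
    build_dataset(small_mesh(), small_system(),
                  dataset_config(n_dual = 40, seed = 11))
  })
}

# memorization run on the tiny phantom: train and evaluate on the same
# singles (capacity/optimization sanity); shared between test files
memo_eval <- function() {
  fixture("memo_eval", function() {
    mesh <- small_mesh()
    ds <- build_dataset(mesh, small_system(),
                        dataset_config(n_dual = 30, seed = 2,
                                       split = c(train = 1, val = 0,
                                                 test = 0)))
    ds$splits$test <- ds$splits$train
    model <- build_1dcnn(ncol(ds$phi), nrow(mesh$nodes), seed = 1)
    tr <- train_model(model, ds, train_config(epochs = 200, seed = 1))
    evaluate_dataset(tr, ds, mesh, split = "test")
  })
}

# single regular-ish tetrahedron as a complete blt_tetmesh
single_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(nodes) <- c("x", "y", "z")
  tets <- matrix(c(1L, 2L, 3L, 4L), 1)
  tets <- bltrecon:::orient_tets(nodes, tets)
  surf <- extract_surface(list(tets = tets))
  structure(list(nodes = nodes, tets = tets, region = 1L,
                 region_names = "brain",
                 boundary_faces = surf$boundary_faces,
                 surface_nodes = surf$surface_nodes, spec = NULL),
            class = "blt_tetmesh")
}

# coordinate-only stub for barycenter/LE arithmetic
coord_mesh <- function(coords) {
  structure(list(nodes = coords), class = "blt_tetmesh")
}

# brute-force boundary-face count: a face is on the boundary iff its sorted
# vertex triple occurs in exactly one tet
brute_force_boundary_count <- function(tets) {
  keys <- character(0)
  for (t in seq_len(nrow(tets))) {
    for (f in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
      keys <- c(keys, paste(sort(tets[t, f]), collapse = "-"))
    }
  }
  sum(table(keys) == 1)
}

# brute-force connected components by flood fill over an edge list
brute_force_components <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)),
                          as.character(nodes))
  cid <- 0
  adj <- lapply(stats::setNames(nodes, as.character(nodes)), function(n) {
    c(edges[edges[, 1] == n, 2], edges[edges[, 2] == n, 1])
  })
  for (n in nodes) {
    if (!is.na(comp[as.character(n)])) next
    cid <- cid + 1
    queue <- n
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[as.character(cur)])) next
      comp[as.character(cur)] <- cid
      nb <- intersect(adj[[as.character(cur)]], nodes)
      queue <- c(queue, nb[is.na(comp[as.character(nb)])])
    }
  }
  split(nodes, comp)
}
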