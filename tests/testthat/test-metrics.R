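test_that("barycenter implements the intensity-weighted center", {
  stub <- coord_mesh(rbind(c(1, 0, 0), c(3, 0, 0)))
  expect_equal(barycenter(1:2, stub), c(2, 0, 0), ignore_attr = TRUE)
  stub2 <- coord_mesh(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(barycenter(1:2, stub2, c(1, 3)), c(2.25, 0, 0),
               ignore_attr = TRUE)
  expect_equal(barycenter(2, stub2), c(3, 0, 0), ignore_attr = TRUE)
  expect_error(barycenter(integer(0), stub), "empty")
  expect_error(barycenter(1:2, stub, c(0, 0)), "positive")
})

test_that("location error is a barycenter distance with the right
           invariances", {
  stub <- coord_mesh(rbind(c(2, 0, 0), c(2, 0, 1)))
  expect_equal(location_error(1, 1, stub), 0)
  expect_equal(location_error(1, 2, stub), 1)
  # invariant under uniform intensity scaling
  set.seed(9)
  coords <- matrix(runif(30), 10)
  stub3 <- coord_mesh(coords)
  w <- runif(4)
  expect_equal(location_error(1:4, 5:8, stub3, w),
               location_error(1:4, 5:8, stub3, 13 * w))
  # invariant under rigid translation of everything
  stub4 <- coord_mesh(sweep(coords, 2, c(5, -3, 2), `+`))
  expect_equal(location_error(1:4, 5:8, stub3, w),
               location_error(1:4, 5:8, stub4, w))
})

test_that("dice matches the set formula and brute force", {
  expect_equal(dice(1:10, 1:10), 1)
  expect_equal(dice(1:5, 6:10), 0)
  expect_equal(dice(1:10, 6:15), 0.5)
  expect_error(dice(integer(0), integer(0)), "empty")
  set.seed(21)
  for (i in 1:20) {
    s1 <- sample(50, sample(10, 1))
    s2 <- sample(50, sample(10, 1))
    brute <- 2 * sum(s1 %in% s2) / (length(s1) + length(s2))
    expect_equal(dice(s1, s2), brute)
    expect_equal(dice(s1, s2), dice(s2, s1))
    expect_gte(dice(s1, s2), 0)
    expect_lte(dice(s1, s2), 1)
  }
})

test_that("segmentation thresholds, splits components, drops artifacts", {
  mesh <- small_mesh()
  n <- nrow(mesh$nodes)
  sources <- enumerate_single_sources(mesh, "brain")
  # a binary true label is recovered exactly
  ns <- sources[[1]]$node_set
  pred <- numeric(n)
  pred[ns] <- 1
  seg <- segment_reconstruction(pred, mesh)
  expect_false(seg$failed)
  expect_setequal(unlist(seg$components), ns)
  # two well-separated blobs give exactly two components
  far <- which.max(vapply(sources, function(s) {
    sum((s$barycenter - sources[[1]]$barycenter)^2)
  }, numeric(1)))
  ns2 <- sources[[far]]$node_set
  pred2 <- numeric(n)
  pred2[ns] <- 1
  pred2[setdiff(ns2, ns)] <- 0.8
  seg2 <- segment_reconstruction(pred2, mesh)
  expect_length(seg2$components, 2)
  # a lone hot node is dropped by the min-size rule and flagged
  pred3 <- rep(0.1, n)
  pred3[ns[1]] <- 1
  seg3 <- segment_reconstruction(pred3, mesh)
  expect_true(seg3$failed)
  expect_length(seg3$components, 0)
})

test_that("segmentation components agree with brute-force flood fill", {
  mesh <- small_mesh()
  ed <- bltrecon:::mesh_edges(mesh)
  set.seed(31)
  for (rep in 1:5) {
    pred <- numeric(nrow(mesh$nodes))
    hot <- sample(nrow(mesh$nodes), 25)
    pred[hot] <- runif(25, 0.6, 1)
    seg <- segment_reconstruction(pred, mesh, min_size = 1)
    brute <- brute_force_components(sort(hot), ed)
    expect_equal(length(seg$components), length(brute))
    key <- function(comps) {
      unname(sort(vapply(comps, function(cn) {
        paste(sort(cn), collapse = "-")
      }, "")))
    }
    expect_equal(key(seg$components), key(brute))
  }
})

test_that("dual matching equals exhaustive pairing and scores correctly", {
  mesh <- small_mesh()
  n <- nrow(mesh$nodes)
  sources <- enumerate_single_sources(mesh, "brain")
  bc1 <- sources[[1]]$barycenter
  far <- which.max(vapply(sources, function(s) {
    sum((s$barycenter - bc1)^2)
  }, numeric(1)))
  truth <- list(sources[[1]]$node_set, sources[[far]]$node_set)
  pred <- numeric(n)
  pred[truth[[1]]] <- 1
  pred[truth[[2]]] <- 1
  seg <- segment_reconstruction(pred, mesh)
  sc <- match_and_score_dual(seg, truth, mesh)
  expect_equal(sc$le1, 0, tolerance = 1e-12)
  expect_equal(sc$le2, 0, tolerance = 1e-12)
  expect_equal(sc$dice, 1)
  expect_equal(sc$total_le, sc$le1 + sc$le2)
  # swapping the true-source order must not change the assignment quality
  sc_sw <- match_and_score_dual(seg, rev(truth), mesh)
  expect_equal(sc_sw$total_le, sc$total_le)
  # the chosen pairing beats the alternative pairing (exhaustive check)
  comps <- seg$components[1:2]
  cb <- lapply(comps, function(cn) barycenter(cn, mesh, pred[cn]))
  tb <- lapply(truth, barycenter, mesh = mesh)
  d <- function(a, b) sqrt(sum((a - b)^2))
  pairings <- c(d(cb[[1]], tb[[1]]) + d(cb[[2]], tb[[2]]),
                d(cb[[1]], tb[[2]]) + d(cb[[2]], tb[[1]]))
  expect_equal(sc$total_le, min(pairings))
  # a missed source yields NA location error and a failure flag
  pred1 <- numeric(n)
  pred1[truth[[1]]] <- 1
  sc1 <- match_and_score_dual(segment_reconstruction(pred1, mesh), truth,
                              mesh)
  expect_equal(sc1$missed, 1L)
  expect_true(is.na(sc1$total_le))
  expect_true(xor(is.na(sc1$le1), is.na(sc1$le2)))
})

test_that("perfect predictions evaluate to Dice 1 and LE 0 on every
           sample type", {
  mesh <- small_mesh()
  ds <- small_dataset()
  pred <- as.matrix(ds$X)[ds$splits$test, , drop = FALSE]
  for (k in seq_along(ds$splits$test)) {
    s <- ds$samples[[ds$splits$test[k]]]
    seg <- segment_reconstruction(pred[k, ], mesh)
    if (s$meta$n_sources == 1) {
      rec <- unique(unlist(seg$components))
      expect_equal(dice(rec, s$node_set), 1)
      expect_equal(location_error(rec, s$node_set, mesh,
                                  seg$intensities[rec]), 0,
                   tolerance = 1e-12)
    } else {
      sc <- match_and_score_dual(seg, s$meta$node_sets, mesh)
      expect_equal(sc$dice, 1)
      expect_equal(sc$total_le, 0, tolerance = 1e-12)
    }
  }
})
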