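# Sample synthesis: single sources by traversal of region nodes, dual
# sources by superposition of two singles, per-sample normalization, and
# seeded train/validation/test splitting.

#' Dataset generation configuration
#'
#' @param region Region name whose nodes seed single sources.
#' @param n_dual Number of dual-source samples to compose.
#' @param split Named fractions for `train`/`val`/`test`; must sum to 1.
#'   Splitting is stratified by sample type so the test set contains both
#'   singles and duals.
#' @param normalization `"max"` (each flux vector scaled to unit maximum,
#'   the default) or `"none"`.
#' @param noise Relative standard deviation of additive Gaussian measurement
#'   noise (fraction of each sample's maximum flux); 0 disables it.
#' @param seed Integer seed controlling pairing and splitting.
#' @return A `blt_dataset_config`.
#' @export
dataset_config <- function(region = "brain", n_dual = 1500,
                           split = c(train = 0.8, val = 0.1, test = 0.1),
                           normalization = c("max", "none"),
                           noise = 0, seed = 1) {
  normalization <- match.arg(normalization)
  if (!all(c("train", "val", "test") %in% names(split)) ||
      abs(sum(split) - 1) > 1e-9 || any(split < 0)) {
    stop("split must be named fractions train/val/test summing to 1")
  }
  if (n_dual < 0 || noise < 0) stop("n_dual and noise must be non-negative")
  structure(list(region = region, n_dual = as.integer(n_dual),
                 split = split[c("train", "val", "test")],
                 normalization = normalization, noise = noise,
                 seed = as.integer(seed)),
            class = "blt_dataset_config")
}

#' Enumerate single sources over a tissue region
#'
#' Every node belonging to the region (i.e. a vertex of at least one
#' element carrying the region label) defines one single source: the set of
#' tetrahedra incident to that center node. The source node set is the set
#' of vertices of those tetrahedra, and the label vector marks exactly
#' those nodes.
#'
#' @param mesh A `blt_tetmesh`.
#' @param region Region name (default `"brain"`).
#' @return List of sources, each with `center`, `node_set`, `source_tets`,
#'   `volume` (mm^3), `barycenter` (mm) and `depth` (mm).
#' @export
enumerate_single_sources <- function(mesh, region = "brain") {
  rid <- match(region, mesh$region_names)
  if (is.na(rid)) stop("unknown region: ", region)
  rtets <- mesh$tets[mesh$region == rid, , drop = FALSE]
  if (nrow(rtets) == 0) stop("region '", region, "' contains no elements")
  centers <- sort(unique(as.vector(rtets)))
  inc <- node_tet_incidence(mesh)
  tv <- tet_volumes(mesh)
  lapply(centers, function(ctr) {
    st <- inc[[as.character(ctr)]]
    ns <- sort(unique(as.vector(mesh$tets[st, , drop = FALSE])))
    bc <- colMeans(mesh$nodes[ns, , drop = FALSE])
    list(center = ctr, node_set = ns, source_tets = st,
         volume = sum(tv[st]), barycenter = unname(bc),
         depth = min(point_triangle_distances(bc, mesh)))
  })
}

# A single simulated sample: raw surface flux + binary node labels + meta.
make_sample <- function(phi_raw, node_sets, centers, barycenters, volumes,
                        depths) {
  gap <- if (length(node_sets) == 2) {
    sqrt(sum((barycenters[[1]] - barycenters[[2]])^2))
  } else NA_real_
  list(phi = phi_raw,
       node_set = sort(unique(unlist(node_sets))),
       meta = list(n_sources = length(node_sets), node_sets = node_sets,
                   centers = centers, barycenters = barycenters,
                   volumes = volumes, depths = depths, gap = gap))
}

#' Compose a dual-source sample by superposition
#'
#' Because the forward model is linear, the surface flux of a two-source
#' sample is the sum of the raw fluxes of its constituents and its label
#' vector is the union (disjoint sum) of their labels.
#'
#' @param s1,s2 Single-source samples as produced internally by
#'   [build_dataset()] (`phi` raw, `node_set`, `meta`).
#' @return A dual sample; errors if the node sets overlap.
#' @export
compose_dual <- function(s1, s2) {
  if (s1$meta$n_sources != 1 || s2$meta$n_sources != 1) {
    stop("compose_dual expects two single-source samples")
  }
  if (length(intersect(s1$node_set, s2$node_set)) > 0) {
    stop("source node sets overlap; redraw the pair")
  }
  if (length(s1$phi) != length(s2$phi)) stop("surface flux lengths differ")
  make_sample(s1$phi + s2$phi,
              node_sets = c(s1$meta$node_sets, s2$meta$node_sets),
              centers = c(s1$meta$centers, s2$meta$centers),
              barycenters = c(s1$meta$barycenters, s2$meta$barycenters),
              volumes = c(s1$meta$volumes, s2$meta$volumes),
              depths = c(s1$meta$depths, s2$meta$depths))
}

#' Normalize a surface flux vector (or matrix of row vectors)
#'
#' Default mode scales each flux vector to unit maximum, making the learned
#' inverse map invariant to absolute source power; mode `"none"` passes
#' through unchanged.
#'
#' @param phi Numeric vector, or matrix with one sample per row.
#' @param mode `"max"` or `"none"`.
#' @return Same shape as `phi`.
#' @export
normalize_flux <- function(phi, mode = c("max", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(phi)
  if (is.null(dim(phi))) {
    m <- max(phi)
    if (m <= 0) stop("cannot normalize an all-zero flux vector")
    return(phi / m)
  }
  m <- apply(phi, 1, max)
  if (any(m <= 0)) {
    stop("cannot normalize all-zero flux vectors (rows ",
         paste(utils::head(which(m <= 0), 5), collapse = ", "), ")")
  }
  phi / m
}

#' Build a complete single/dual-source dataset with splits
#'
#' Enumerates every single source in the configured region, solves the
#' forward model once per single source (one factorization, many right-hand
#' sides), composes the requested number of dual samples from seeded random
#' disjoint pairs, optionally adds measurement noise, normalizes, and
#' splits samples into train/validation/test sets stratified by sample
#' type.
#'
#' @param mesh A `blt_tetmesh`.
#' @param system The assembled `blt_forward_system` for this mesh.
#' @param config A [dataset_config()].
#' @return A `blt_dataset`: list with `phi` (n_samples x N normalized flux),
#'   `phi_raw`, `X` (sparse n_samples x M binary labels), `meta`
#'   (data.frame), `splits` (named index list), `sources`, `config` and
#'   `provenance`.
#' @export
build_dataset <- function(mesh, system, config = dataset_config()) {
  stopifnot(inherits(config, "blt_dataset_config"))
  sources <- enumerate_single_sources(mesh, config$region)
  ns <- length(sources)
  nn <- nrow(mesh$nodes)
  Xs <- matrix(0, nn, ns)
  for (i in seq_len(ns)) Xs[sources[[i]]$node_set, i] <- 1
  fl <- solve_forward(system, Xs)
  phi_s <- t(surface_flux(fl, mesh))          # ns x N
  singles <- lapply(seq_len(ns), function(i) {
    s <- sources[[i]]
    make_sample(phi_s[i, ], node_sets = list(s$node_set),
                centers = list(s$center), barycenters = list(s$barycenter),
                volumes = list(s$volume), depths = list(s$depth))
  })

  max_pairs <- ns * (ns - 1) / 2
  if (config$n_dual > max_pairs) {
    stop("requested ", config$n_dual, " dual samples but only ", max_pairs,
         " distinct pairs exist")
  }
  set.seed(derive_seed(config$seed, "dual-pairs"))
  chosen <- integer(0)
  attempts <- 0L
  max_attempts <- 100L * max(config$n_dual, 1L)
  while (length(chosen) < config$n_dual) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not draw ", config$n_dual,
           " disjoint dual pairs within ", max_attempts, " attempts")
    }
    ij <- sort(sample.int(ns, 2))
    key <- (ij[1] - 1) * ns + ij[2]
    if (key %in% chosen) next
    if (length(intersect(singles[[ij[1]]]$node_set,
                         singles[[ij[2]]]$node_set)) > 0) next
    chosen <- c(chosen, key)
  }
  duals <- lapply(chosen, function(key) {
    i <- (key - 1) %/% ns + 1
    j <- (key - 1) %% ns + 1
    compose_dual(singles[[i]], singles[[j]])
  })

  samples <- c(singles, duals)
  n <- length(samples)
  phi_raw <- do.call(rbind, lapply(samples, `[[`, "phi"))
  if (config$noise > 0) {
    set.seed(derive_seed(config$seed, "noise"))
    sdv <- config$noise * apply(phi_raw, 1, max)
    phi_noisy <- pmax(phi_raw +
                        matrix(stats::rnorm(length(phi_raw)), n) * sdv, 0)
  } else {
    phi_noisy <- phi_raw
  }
  phi <- normalize_flux(phi_noisy, config$normalization)
  ii <- unlist(lapply(seq_len(n), function(i) {
    rep(i, length(samples[[i]]$node_set))
  }))
  jj <- unlist(lapply(samples, `[[`, "node_set"))
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, nn))
  meta <- data.frame(
    id = seq_len(n),
    type = rep(c("single", "dual"), c(ns, length(duals))),
    center1 = vapply(samples, function(s) s$meta$centers[[1]], numeric(1)),
    center2 = vapply(samples, function(s) {
      if (s$meta$n_sources == 2) s$meta$centers[[2]] else NA_real_
    }, numeric(1)),
    volume = vapply(samples, function(s) {
      sum(unlist(s$meta$volumes))
    }, numeric(1)),
    depth = vapply(samples, function(s) {
      min(unlist(s$meta$depths))
    }, numeric(1)),
    gap = vapply(samples, function(s) s$meta$gap, numeric(1)))

  set.seed(derive_seed(config$seed, "split"))
  splits <- list(train = integer(0), val = integer(0), test = integer(0))
  for (ty in c("single", "dual")) {
    idx <- which(meta$type == ty)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    nv <- round(config$split[["val"]] * length(idx))
    nt <- round(config$split[["test"]] * length(idx))
    splits$val <- c(splits$val, idx[seq_len(nv)])
    splits$test <- c(splits$test, idx[nv + seq_len(nt)])
    splits$train <- c(splits$train,
                      if (nv + nt > 0) idx[-seq_len(nv + nt)] else idx)
  }
  splits <- lapply(splits, sort)

  structure(list(
    phi = phi, phi_raw = phi_raw, X = X, meta = meta, splits = splits,
    samples = samples, sources = sources, config = config,
    provenance = list(schema = "blt_dataset/1",
                      mesh_hash = hash_obj(mesh[c("nodes", "tets", "region")]),
                      config_hash = hash_obj(unclass(config)),
                      seed = config$seed,
                      n_surface = ncol(phi), n_nodes = nn)),
    class = "blt_dataset")
}

#' @exportS3Method base::print
print.blt_dataset <- function(x, ...) {
  cat("blt_dataset:", nrow(x$phi), "samples (",
      sum(x$meta$type == "single"), "single /",
      sum(x$meta$type == "dual"), "dual ),",
      ncol(x$phi), "surface nodes,", ncol(x$X), "mesh nodes\n")
  cat("  splits:", paste(names(x$splits), lengths(x$splits),
                         collapse = ", "), "\n")
  invisible(x)
}

write_num_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t")), con)
}

read_num_matrix <- function(path) {
  hdr <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  vals <- scan(path, what = numeric(), skip = 1, quiet = TRUE)
  if (length(vals) != hdr[1] * hdr[2]) {
    stop("matrix file ", path, " is truncated: expected ", hdr[1] * hdr[2],
         " values, found ", length(vals))
  }
  matrix(vals, nrow = hdr[1], byrow = TRUE)
}

#' Write / read a dataset as a plain-text directory container
#'
#' Layout: `phi.tsv` and `phi_raw.tsv` (dense matrices with a dimension
#' header), `X.tsv` (sparse triplets), `meta.tsv`, `splits.json`,
#' `provenance.json` (schema version, seed, hashes, config). Numeric values
#' are written with 17 significant digits so the round trip is exact.
#'
#' @param dataset A `blt_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
dataset_write <- function(dataset, dir) {
  stopifnot(inherits(dataset, "blt_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_matrix(dataset$phi, file.path(dir, "phi.tsv"))
  write_num_matrix(dataset$phi_raw, file.path(dir, "phi_raw.tsv"))
  Xt <- Matrix::summary(dataset$X)
  writeLines(c(sprintf("%d %d %d", nrow(dataset$X), ncol(dataset$X),
                       nrow(Xt)),
               sprintf("%d\t%d", Xt$i, Xt$j)),
             file.path(dir, "X.tsv"))
  utils::write.table(dataset$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dataset$splits, file.path(dir, "splits.json"))
  prov <- dataset$provenance
  prov$config <- unclass(dataset$config)
  prov$config$split <- as.list(prov$config$split)  # keep names in JSON
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  node_sets <- lapply(dataset$samples, function(s) s$meta$node_sets)
  jsonlite::write_json(node_sets, file.path(dir, "node_sets.json"))
  bc <- lapply(dataset$samples, function(s) s$meta$barycenters)
  jsonlite::write_json(bc, file.path(dir, "barycenters.json"), digits = NA)
  invisible(dir)
}

#' @rdname dataset_write
#' @param split Optional split name; when given, only samples of that split
#'   are returned (with the split index list reduced accordingly).
#' @export
dataset_read <- function(dir, split = NULL) {
  prov_path <- file.path(dir, "provenance.json")
  if (!file.exists(prov_path)) stop("not a dataset directory: ", dir)
  prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
  if (!identical(prov$schema, "blt_dataset/1")) {
    stop("unsupported dataset schema: ",
         if (is.null(prov$schema)) "<missing>" else prov$schema)
  }
  sp_path <- file.path(dir, "splits.json")
  if (!file.exists(sp_path)) stop("missing splits.json in ", dir)
  splits <- lapply(jsonlite::read_json(sp_path, simplifyVector = TRUE),
                   as.integer)
  phi <- read_num_matrix(file.path(dir, "phi.tsv"))
  phi_raw <- read_num_matrix(file.path(dir, "phi_raw.tsv"))
  xh <- scan(file.path(dir, "X.tsv"), what = integer(), nlines = 1,
             quiet = TRUE)
  xt <- matrix(scan(file.path(dir, "X.tsv"), what = integer(), skip = 1,
                    quiet = TRUE), ncol = 2, byrow = TRUE)
  X <- Matrix::sparseMatrix(i = xt[, 1], j = xt[, 2], x = 1,
                            dims = xh[1:2])
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  node_sets <- jsonlite::read_json(file.path(dir, "node_sets.json"),
                                   simplifyVector = TRUE)
  bcs <- jsonlite::read_json(file.path(dir, "barycenters.json"),
                             simplifyVector = TRUE)
  cfg <- prov$config
  config <- dataset_config(region = cfg$region, n_dual = cfg$n_dual,
                           split = unlist(cfg$split),
                           normalization = cfg$normalization,
                           noise = cfg$noise, seed = cfg$seed)
  samples <- lapply(seq_len(nrow(phi)), function(i) {
    nsets <- node_sets[[i]]
    if (!is.list(nsets)) nsets <- list(nsets)
    nsets <- lapply(nsets, as.integer)
    b <- bcs[[i]]
    if (!is.list(b)) b <- if (is.matrix(b)) lapply(seq_len(nrow(b)),
                                                   function(k) b[k, ])
    else list(b)
    make_sample(phi_raw[i, ], nsets,
                centers = as.list(c(meta$center1[i],
                                    meta$center2[i])[!is.na(
                                      c(meta$center1[i], meta$center2[i]))]),
                barycenters = b,
                volumes = list(meta$volume[i]),
                depths = list(meta$depth[i]))
  })
  ds <- structure(list(phi = phi, phi_raw = phi_raw, X = X, meta = meta,
                       splits = splits, samples = samples, sources = NULL,
                       config = config,
                       provenance = prov[setdiff(names(prov), "config")]),
                  class = "blt_dataset")
  if (!is.null(split)) {
    if (!split %in% names(ds$splits)) stop("unknown split: ", split)
    idx <- ds$splits[[split]]
    ds$phi <- ds$phi[idx, , drop = FALSE]
    ds$phi_raw <- ds$phi_raw[idx, , drop = FALSE]
    ds$X <- ds$X[idx, , drop = FALSE]
    ds$meta <- ds$meta[idx, , drop = FALSE]
    ds$samples <- ds$samples[idx]
    ds$splits <- stats::setNames(list(seq_along(idx)), split)
  }
  ds
}
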