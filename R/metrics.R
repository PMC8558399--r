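# Reconstruction evaluation: intensity-weighted barycenters, location error
# (LE), Dice on node sets, thresholded segmentation with connected
# components over mesh node adjacency, dual-source component matching, and
# stratified dataset-level reporting.

#' Intensity-weighted barycenter of a node set
#'
#' `SC = sum(P_i * x_i) / sum(x_i)` over the nodes of a source, where `P_i`
#' are node coordinates and `x_i` the retained intensities (unit weights
#' for binary true sources).
#'
#' @param node_ids Integer node indices.
#' @param mesh A `blt_tetmesh`.
#' @param intensities Optional weights; default 1 per node.
#' @return Length-3 coordinate (mm).
#' @export
barycenter <- function(node_ids, mesh, intensities = NULL) {
  if (length(node_ids) == 0) stop("cannot take barycenter of an empty set")
  if (is.null(intensities)) intensities <- rep(1, length(node_ids))
  if (length(intensities) != length(node_ids)) {
    stop("intensities length must match node_ids")
  }
  tot <- sum(intensities)
  if (tot <= 0) stop("total intensity must be positive")
  drop(crossprod(mesh$nodes[node_ids, , drop = FALSE], intensities)) / tot
}

#' Location error between reconstructed and true sources
#'
#' Euclidean distance between the intensity-weighted barycenter of the
#' reconstruction and the (unit-weighted) barycenter of the true node set.
#'
#' @param recon_ids,true_ids Node index vectors.
#' @param mesh A `blt_tetmesh`.
#' @param recon_intensities Weights for the reconstructed nodes.
#' @return Distance in mm.
#' @export
location_error <- function(recon_ids, true_ids, mesh,
                           recon_intensities = NULL) {
  sqrt(sum((barycenter(recon_ids, mesh, recon_intensities) -
              barycenter(true_ids, mesh))^2))
}

#' Dice similarity of two node sets
#'
#' `2 |S1 n S2| / (|S1| + |S2|)`.
#' @param s1,s2 Node index vectors (reconstructed, true).
#' @return Value in `[0, 1]`.
#' @export
dice <- function(s1, s2) {
  s1 <- unique(s1)
  s2 <- unique(s2)
  if (length(s1) + length(s2) == 0) {
    stop("Dice undefined for two empty sets")
  }
  2 * length(intersect(s1, s2)) / (length(s1) + length(s2))
}

#' Segment a continuous reconstruction into source components
#'
#' Retains nodes whose predicted intensity is at least
#' `threshold * max(prediction)`, groups them into connected components of
#' the mesh node-adjacency graph (nodes sharing a tetrahedron edge), and
#' drops components smaller than `min_size` nodes as artifacts. Components
#' are ordered by total retained intensity (mass), largest first.
#'
#' @param prediction Length-M vector in `[0, 1]`.
#' @param mesh A `blt_tetmesh`.
#' @param threshold Fraction of the prediction maximum (default 0.5).
#' @param min_size Minimum component size in nodes (default 2).
#' @param edges Optional precomputed [mesh_edges()] matrix.
#' @return A `blt_segmentation`: `components` (list of node-id vectors),
#'   `intensities` (the prediction), `retained`, `failed` (no component
#'   survived).
#' @export
segment_reconstruction <- function(prediction, mesh, threshold = 0.5,
                                   min_size = 2, edges = NULL) {
  if (length(prediction) != nrow(mesh$nodes)) {
    stop("prediction length does not match mesh node count")
  }
  mx <- max(prediction)
  retained <- which(prediction >= threshold * mx & prediction > 0)
  comps <- list()
  if (length(retained)) {
    if (is.null(edges)) edges <- mesh_edges(mesh)
    keep <- edges[, 1] %in% retained & edges[, 2] %in% retained
    sub <- edges[keep, , drop = FALSE]
    idx <- match(sub, retained)
    g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(retained) -
                                       igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    comps <- split(retained, memb)
    comps <- comps[lengths(comps) >= min_size]
    mass <- vapply(comps, function(cn) sum(prediction[cn]), numeric(1))
    comps <- comps[order(mass, decreasing = TRUE)]
    names(comps) <- NULL
  }
  structure(list(components = comps, intensities = prediction,
                 retained = retained, threshold = threshold,
                 min_size = min_size, failed = length(comps) == 0),
            class = "blt_segmentation")
}

#' Score a dual-source reconstruction
#'
#' The two largest components are assigned to the two true sources by
#' minimizing the total barycenter distance over both pairings (exhaustive
#' for the 2 x 2 case). `LE1`/`LE2` follow the true-source indexing; total
#' LE is their sum. Dice is computed between the union of all retained
#' component nodes and the union of the true node sets. A true source with
#' no assigned component gets `NA` location error and marks the
#' reconstruction as a partial failure.
#'
#' @param segmentation A `blt_segmentation`.
#' @param true_sets List of exactly two true node-id vectors.
#' @param mesh A `blt_tetmesh`.
#' @return List with `le1`, `le2`, `total_le`, `dice`, `n_components`,
#'   `missed` (number of unmatched true sources).
#' @export
match_and_score_dual <- function(segmentation, true_sets, mesh) {
  if (length(true_sets) != 2) stop("expected exactly two true sources")
  tb <- lapply(true_sets, barycenter, mesh = mesh)
  comps <- segmentation$components
  ncomp <- length(comps)
  d_union <- if (length(segmentation$retained) && ncomp > 0) {
    dice(unique(unlist(comps)), unique(unlist(true_sets)))
  } else 0
  if (ncomp == 0) {
    return(list(le1 = NA_real_, le2 = NA_real_, total_le = NA_real_,
                dice = 0, n_components = 0L, missed = 2L))
  }
  cb <- lapply(comps, function(cn) {
    barycenter(cn, mesh, segmentation$intensities[cn])
  })
  if (ncomp >= 2) {
    cb2 <- cb[1:2]   # two largest by mass; the rest are artifacts
    d <- function(a, b) sqrt(sum((a - b)^2))
    straight <- d(cb2[[1]], tb[[1]]) + d(cb2[[2]], tb[[2]])
    crossed <- d(cb2[[1]], tb[[2]]) + d(cb2[[2]], tb[[1]])
    if (straight <= crossed) {
      le1 <- d(cb2[[1]], tb[[1]]); le2 <- d(cb2[[2]], tb[[2]])
    } else {
      le1 <- d(cb2[[2]], tb[[1]]); le2 <- d(cb2[[1]], tb[[2]])
    }
    list(le1 = le1, le2 = le2, total_le = le1 + le2, dice = d_union,
         n_components = as.integer(ncomp), missed = 0L)
  } else {
    dd <- vapply(tb, function(b) sqrt(sum((b - cb[[1]])^2)), numeric(1))
    nearer <- which.min(dd)
    le <- c(NA_real_, NA_real_)
    le[nearer] <- dd[nearer]
    list(le1 = le[1], le2 = le[2], total_le = NA_real_, dice = d_union,
         n_components = 1L, missed = 1L)
  }
}

bin_label <- function(x, breaks) {
  as.character(cut(x, breaks = breaks, right = FALSE,
                   include.lowest = TRUE,
                   labels = sprintf("[%g,%g)", utils::head(breaks, -1),
                                    utils::tail(breaks, -1))))
}

#' Evaluate a trained model on a dataset split
#'
#' Runs the model on every sample of the split, segments each prediction,
#' scores singles with LE/Dice and duals with matched LE1/LE2/total
#' LE/Dice, and aggregates mean +/- sd overall and within depth bins
#' (singles) and barycenter-gap bins (duals). Failed reconstructions keep
#' Dice 0 and are excluded from LE means but tallied.
#'
#' @param trained A `blt_trained_model` (or bare `blt_model`).
#' @param dataset A `blt_dataset`.
#' @param mesh The `blt_tetmesh` the dataset was built on.
#' @param split Split name, default `"test"`.
#' @param depth_bins,gap_bins Bin edges (mm) for the stratified summaries.
#' @param threshold,min_size Segmentation parameters, see
#'   [segment_reconstruction()].
#' @return A `blt_eval_report`: `per_sample` data.frame, `summary`
#'   data.frame of aggregates, and the binning used.
#' @export
evaluate_dataset <- function(trained, dataset, mesh, split = "test",
                             depth_bins = c(0, 2, 4, 6, 8),
                             gap_bins = seq(2, 14, by = 4),
                             threshold = 0.5, min_size = 2) {
  idx <- dataset$splits[[split]]
  if (is.null(idx)) stop("unknown split: ", split)
  if (!length(idx)) stop("split '", split, "' is empty")
  edges <- mesh_edges(mesh)
  pred <- predict(trained, dataset$phi[idx, , drop = FALSE])
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    s <- dataset$samples[[i]]
    seg <- segment_reconstruction(pred[k, ], mesh, threshold = threshold,
                                  min_size = min_size, edges = edges)
    if (s$meta$n_sources == 1) {
      if (seg$failed) {
        data.frame(id = i, type = "single", depth = s$meta$depths[[1]],
                   gap = NA_real_, le = NA_real_, le1 = NA_real_,
                   le2 = NA_real_, dice = 0, failed = TRUE)
      } else {
        rec <- unique(unlist(seg$components))
        data.frame(id = i, type = "single", depth = s$meta$depths[[1]],
                   gap = NA_real_,
                   le = location_error(rec, s$node_set, mesh,
                                       seg$intensities[rec]),
                   le1 = NA_real_, le2 = NA_real_,
                   dice = dice(rec, s$node_set), failed = FALSE)
      }
    } else {
      sc <- match_and_score_dual(seg, s$meta$node_sets, mesh)
      data.frame(id = i, type = "dual", depth = min(unlist(s$meta$depths)),
                 gap = s$meta$gap, le = sc$total_le, le1 = sc$le1,
                 le2 = sc$le2, dice = sc$dice, failed = sc$missed > 0)
    }
  })
  per_sample <- do.call(rbind, rows)
  summ <- list()
  add_row <- function(group, subset_df, metric) {
    ms <- mean_sd(subset_df[[metric]])
    data.frame(group = group, metric = metric, mean = ms$mean, sd = ms$sd,
               n = ms$n, n_failed = sum(subset_df$failed))
  }
  sing <- per_sample[per_sample$type == "single", , drop = FALSE]
  dual <- per_sample[per_sample$type == "dual", , drop = FALSE]
  if (nrow(sing)) {
    summ <- c(summ, list(add_row("single", sing, "le"),
                         add_row("single", sing, "dice")))
    sing$bin <- bin_label(sing$depth, depth_bins)
    for (b in sprintf("[%g,%g)", utils::head(depth_bins, -1),
                      utils::tail(depth_bins, -1))) {
      sb <- sing[!is.na(sing$bin) & sing$bin == b, , drop = FALSE]
      if (nrow(sb)) {
        summ <- c(summ, list(add_row(paste0("single depth ", b), sb, "le"),
                             add_row(paste0("single depth ", b), sb,
                                     "dice")))
      }
    }
  }
  if (nrow(dual)) {
    summ <- c(summ, list(add_row("dual", dual, "le1"),
                         add_row("dual", dual, "le2"),
                         add_row("dual", dual, "le"),
                         add_row("dual", dual, "dice")))
    dual$bin <- bin_label(dual$gap, gap_bins)
    for (b in sprintf("[%g,%g)", utils::head(gap_bins, -1),
                      utils::tail(gap_bins, -1))) {
      db <- dual[!is.na(dual$bin) & dual$bin == b, , drop = FALSE]
      if (nrow(db)) {
        summ <- c(summ, list(add_row(paste0("dual gap ", b), db, "le"),
                             add_row(paste0("dual gap ", b), db, "dice")))
      }
    }
  }
  structure(list(per_sample = per_sample,
                 summary = do.call(rbind, summ),
                 split = split, depth_bins = depth_bins,
                 gap_bins = gap_bins, threshold = threshold,
                 min_size = min_size),
            class = "blt_eval_report")
}

#' @exportS3Method base::print
print.blt_eval_report <- function(x, ...) {
  cat("blt_eval_report on split '", x$split, "' (",
      nrow(x$per_sample), " samples)\n", sep = "")
  ov <- x$summary[x$summary$group %in% c("single", "dual"), ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-7s %-5s %.3f +/- %.3f (n=%d, failed=%d)\n",
                ov$group[i], ov$metric[i], ov$mean[i], ov$sd[i], ov$n[i],
                ov$n_failed[i]))
  }
  invisible(x)
}

#' Write an evaluation report as JSON and CSV
#' @param report A `blt_eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
report_write <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_sample, file.path(dir, "per_sample.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(split = report$split, depth_bins = report$depth_bins,
         gap_bins = report$gap_bins, threshold = report$threshold,
         summary = report$summary),
    file.path(dir, "report.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  invisible(dir)
}
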