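# TetGen-style .node/.ele serialization with a JSON sidecar carrying region
# names and the persisted surface-node order. Indices are 1-based on disk
# (TetGen's default numbering) and in memory.

#' Write a tetrahedral mesh to TetGen-style files
#'
#' Writes `<basepath>.node` (coordinates), `<basepath>.ele` (connectivity
#' with a region attribute column) and `<basepath>.json` (region-name map,
#' persisted surface-node order, schema version). Coordinates are written
#' with 17 significant digits so a read/write round trip is exact.
#'
#' @param mesh A `blt_tetmesh`.
#' @param basepath Path prefix; the three files get their extensions added.
#' @return `basepath`, invisibly.
#' @export
write_mesh <- function(mesh, basepath) {
  stopifnot(inherits(mesh, "blt_tetmesh"))
  n <- nrow(mesh$nodes)
  node_lines <- c(
    sprintf("%d 3 0 0", n),
    sprintf("%d %.17g %.17g %.17g", seq_len(n),
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  writeLines(node_lines, paste0(basepath, ".node"))
  t_ <- nrow(mesh$tets)
  ele_lines <- c(
    sprintf("%d 4 1", t_),
    sprintf("%d %d %d %d %d %d", seq_len(t_),
            mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3], mesh$tets[, 4],
            mesh$region))
  writeLines(ele_lines, paste0(basepath, ".ele"))
  sidecar <- list(
    schema = "blt_tetmesh/1",
    region_names = mesh$region_names,
    surface_nodes = mesh$surface_nodes,
    spec = if (!is.null(mesh$spec)) unclass(mesh$spec) else NULL)
  jsonlite::write_json(sidecar, paste0(basepath, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basepath)
}

parse_num_table <- function(path, ncol_expected, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 1) stop("empty ", what, " file: ", path)
  header <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]),
                                                 "\\s+")[[1]]))
  count <- header[1]
  if (is.na(count) || count < 1) {
    stop("malformed ", what, " header at line 1 of ", path, ": ", lines[1])
  }
  if (length(lines) - 1 < count) {
    stop("truncated ", what, " file ", path, ": header declares ", count,
         " rows but only ", length(lines) - 1, " present (last line ",
         length(lines), ")")
  }
  body <- lines[2:(count + 1)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) < ncol_expected)
  if (length(bad)) {
    stop("malformed ", what, " row at line ", bad[1] + 1, " of ", path,
         ": expected ", ncol_expected, " fields, got ",
         lengths(parts)[bad[1]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(parts, `[`, seq_len(ncol_expected))))),
    ncol = ncol_expected, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric field at line ", bad + 1, " of ", path)
  }
  m
}

#' Read a tetrahedral mesh written by [write_mesh()]
#'
#' @param basepath Path prefix used when writing.
#' @return A `blt_tetmesh`. The surface-node order stored in the sidecar is
#'   validated against a fresh surface extraction.
#' @export
read_mesh <- function(basepath) {
  nodes_m <- parse_num_table(paste0(basepath, ".node"), 4, ".node")
  ele_m <- parse_num_table(paste0(basepath, ".ele"), 6, ".ele")
  nodes <- nodes_m[, 2:4, drop = FALSE]
  colnames(nodes) <- c("x", "y", "z")
  tets <- matrix(as.integer(ele_m[, 2:5]), ncol = 4)
  region <- as.integer(ele_m[, 6])
  if (any(tets < 1 | tets > nrow(nodes))) {
    stop("element file references node indices outside 1..", nrow(nodes))
  }
  sidecar_path <- paste0(basepath, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar file: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$schema) || !identical(sc$schema, "blt_tetmesh/1")) {
    stop("unsupported mesh schema in ", sidecar_path, ": ",
         if (is.null(sc$schema)) "<missing>" else sc$schema)
  }
  surf <- extract_surface_raw(tets)
  persisted <- as.integer(sc$surface_nodes)
  if (!setequal(persisted, surf$surface_nodes)) {
    stop("sidecar surface-node set disagrees with mesh connectivity in ",
         sidecar_path)
  }
  spec <- NULL
  if (!is.null(sc$spec)) {
    spec <- structure(list(radii = as.numeric(sc$spec$radii),
                           edge = as.numeric(sc$spec$edge),
                           regions = as.character(sc$spec$regions)),
                      class = "blt_phantom_spec")
  }
  structure(list(nodes = nodes, tets = tets, region = region,
                 region_names = as.character(sc$region_names),
                 boundary_faces = surf$boundary_faces,
                 surface_nodes = persisted,
                 spec = spec), class = "blt_tetmesh")
}

#' Export a mesh (optionally with nodal data) as legacy ASCII VTK
#'
#' Intended for visual inspection of phantoms and fluence fields in
#' ParaView; not used by the reconstruction pipeline.
#'
#' @param mesh A `blt_tetmesh`.
#' @param path Output `.vtk` file.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes)
  t_ <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "blt_tetmesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", t_, 5 * t_), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1, mesh$tets[, 2] - 1,
                     mesh$tets[, 3] - 1, mesh$tets[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", t_), con)
  writeLines(rep("10", t_), con)
  writeLines(sprintf("CELL_DATA %d", t_), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$region), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}
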