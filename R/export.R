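# Scene assembly (grid + colors + external overlay), JSON/HTML export and
# the end-to-end pipeline.

OVERLAY_COLOR <- c(148L, 0L, 211L)  # "dark violet"
OVERLAY_LIMIT <- 1000L

#' Project external molecules into a fitted space
#'
#' Fingerprints, projects (with the stored PCA model, never refit) and bins
#' (with the stored grid range) externally supplied standardized molecules.
#' Coordinates outside the fitted range are clamped to the boundary cell.
#'
#' @param model the `pca_model` fitted on the library.
#' @param grid the `grid3d` built on the library coordinates.
#' @param externals list of `std_mol` (standardized with the same pipeline),
#'   at most 1000.
#' @param kind fingerprint kind used for the space.
#' @return data.frame with columns id, name, i, j, k (one row per external).
#' @export
overlay_external <- function(model, grid, externals,
                             kind = c("mqn", "smifp", "apfp", "xfp", "sfp")) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "pca_model"), inherits(grid, "grid3d"))
  if (length(externals) > OVERLAY_LIMIT)
    stop(sprintf("external overlay is limited to %d molecules (got %d)",
                 OVERLAY_LIMIT, length(externals)), call. = FALSE)
  if (!length(externals))
    return(data.frame(id = character(), name = character(),
                      i = integer(), j = integer(), k = integer(),
                      stringsAsFactors = FALSE))
  fps <- fingerprint_matrix(externals, kind)
  coords <- pca_project(model, fps, k = 3L)
  idx <- vapply(1:3, function(j)
    bin_axis(coords[, j], grid$pc_min, grid$bin_size, grid$n_bins),
    integer(nrow(coords)))
  if (nrow(coords) == 1) idx <- matrix(idx, nrow = 1)
  data.frame(
    id = vapply(externals, function(m) m$record$id, character(1)),
    name = vapply(externals, function(m) m$record$name, character(1)),
    i = idx[, 1], j = idx[, 2], k = idx[, 3], stringsAsFactors = FALSE)
}

#' Assemble a colored scene
#'
#' Combines the grid, per-cell colors and an optional external overlay into
#' a serializable scene. Each multi-member cell carries the full member id
#' list and, as its representative, the canonical SMILES of the member with
#' the smallest source index.
#'
#' @param grid a `grid3d`.
#' @param cells data.frame from [color_cells()].
#' @param mols the standardized library (list of `std_mol`) behind the grid.
#' @param kind fingerprint kind of the space.
#' @param descriptor descriptor name used for coloring.
#' @param overlay data.frame from [overlay_external()] (optional).
#' @return an object of class `scene`.
#' @export
make_scene <- function(grid, cells, mols, kind, descriptor, overlay = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  ids <- vapply(mols, function(m) m$record$id, character(1))
  srcidx <- vapply(mols, function(m) m$record$source_index, integer(1))
  smis <- vapply(mols, `[[`, character(1), "canonical_smiles")
  keys <- names(grid$cells)
  points <- lapply(seq_along(keys), function(ci) {
    members <- grid$cells[[ci]]
    rep_m <- members[which.min(srcidx[members])]
    list(cell = as.integer(c(cells$i[ci], cells$j[ci], cells$k[ci])),
         rgb = as.integer(c(cells$r[ci], cells$g[ci], cells$b[ci])),
         member_ids = ids[members],
         smiles = smis[rep_m])
  })
  overlay_points <- list()
  if (!is.null(overlay) && nrow(overlay)) {
    overlay_points <- lapply(seq_len(nrow(overlay)), function(r)
      list(cell = as.integer(c(overlay$i[r], overlay$j[r], overlay$k[r])),
           id = overlay$id[r], name = overlay$name[r]))
  }
  structure(list(
    fingerprint = kind, descriptor = descriptor,
    grid = list(n_bins = grid$n_bins, pc_min = grid$pc_min,
                pc_max = grid$pc_max, bin_size = grid$bin_size),
    overlay_color = OVERLAY_COLOR,
    points = points, overlay_points = overlay_points), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene: %s space, %d grid points, %d overlay points>\n",
              x$fingerprint, length(x$points), length(x$overlay_points)))
  invisible(x)
}

scene_to_list <- function(scene) {
  list(fingerprint = jsonlite::unbox(scene$fingerprint),
       descriptor = jsonlite::unbox(scene$descriptor),
       grid = lapply(scene$grid, jsonlite::unbox),
       overlay_color = scene$overlay_color,
       points = lapply(scene$points, function(p)
         list(cell = p$cell, rgb = p$rgb,
              member_ids = as.list(p$member_ids),
              smiles = jsonlite::unbox(p$smiles))),
       overlay_points = lapply(scene$overlay_points, function(p)
         list(cell = p$cell, id = jsonlite::unbox(p$id),
              name = jsonlite::unbox(p$name))))
}

#' Export a scene as JSON
#'
#' Round-trips losslessly through [load_scene_json()].
#'
#' @param scene a `scene`.
#' @param path output file.
#' @export
export_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  jsonlite::write_json(scene_to_list(scene), path, digits = NA)
  invisible(path)
}

#' Load a scene from JSON
#' @param path file written by [export_scene_json()].
#' @return a `scene`.
#' @export
load_scene_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    fingerprint = x$fingerprint, descriptor = x$descriptor,
    grid = list(n_bins = as.integer(x$grid$n_bins),
                pc_min = as.numeric(x$grid$pc_min),
                pc_max = as.numeric(x$grid$pc_max),
                bin_size = as.numeric(x$grid$bin_size)),
    overlay_color = as.integer(unlist(x$overlay_color)),
    points = lapply(x$points, function(p)
      list(cell = as.integer(unlist(p$cell)), rgb = as.integer(unlist(p$rgb)),
           member_ids = as.character(unlist(p$member_ids)),
           smiles = p$smiles)),
    overlay_points = lapply(x$overlay_points, function(p)
      list(cell = as.integer(unlist(p$cell)), id = p$id, name = p$name))),
    class = "scene")
}

#' Export a self-contained HTML viewer
#'
#' Embeds the scene JSON and a small dependency-free canvas point-cloud
#' viewer (drag to rotate, wheel to zoom, hover shows id and SMILES) into a
#' single HTML file; opening it requires no network access.
#'
#' @param scene a `scene`.
#' @param path output file.
#' @export
export_html <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  template <- system.file("templates", "viewer-template.txt",
                          package = "chemspace3d", mustWork = TRUE)
  html <- paste(readLines(template, warn = FALSE), collapse = "\n")
  js <- jsonlite::toJSON(scene_to_list(scene), digits = NA)
  out <- sub("__SCENE_JSON__", js, html, fixed = TRUE)
  writeLines(out, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' read -> standardize -> fingerprint -> PCA -> grid -> color -> export.
#' Writes model.json, coords.csv, grid.json, scene.json, diagnostics.json
#' (variance coverage per k up to `diag_max_k`, distance correlation at k =
#' 3, single-occupancy fractions) and rejections.tsv into `out_dir`.
#'
#' @param input path to the library (SMILES text or SDF).
#' @param out_dir output directory (created if missing).
#' @param format `"smiles"` or `"sdf"`.
#' @param kind fingerprint kind.
#' @param descriptor descriptor for coloring (see [compute_properties()]).
#' @param n_bins grid bins per axis.
#' @param max_hac heavy-atom cap for standardization.
#' @param overlay_file optional SMILES file of external molecules.
#' @param n_pairs pair-sample cap for the distance-correlation diagnostic.
#' @param seed seed for the pair sample.
#' @param diag_max_k highest k reported in the variance-coverage diagnostic.
#' @return invisibly, a list with the in-memory artifacts (mols, fps, model,
#'   coords, grid, cells, scene, diagnostics).
#' @export
run_pipeline <- function(input, out_dir, format = c("smiles", "sdf"),
                         kind = c("mqn", "smifp", "apfp", "xfp", "sfp"),
                         descriptor = "ringcount", n_bins = 300L,
                         max_hac = 50L, overlay_file = NULL, n_pairs = 1e6,
                         seed = 1L, diag_max_k = 10L) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!descriptor %in% c("ringcount", "aromatic_c", "rotatable",
                         "frac_aromatic", "hba_count", "hac", "ncc_count"))
    stop("config error: unknown descriptor '", descriptor, "'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  records <- stage("read", switch(format, smiles = read_smiles_file(input),
                                  sdf = read_sdf(input)))
  mols <- stage("standardize", standardize_library(records, max_hac = max_hac))
  if (!length(mols)) stop("[standardize] no molecules survived", call. = FALSE)
  fps <- stage("fingerprint", fingerprint_matrix(mols, kind))
  model <- stage("pca", fit_pca(fps))
  coords <- stage("project", pca_project(model, fps, k = 3L))
  grid <- stage("grid", build_grid(coords, n_bins = n_bins))
  props <- stage("properties", compute_properties(mols))
  cells <- stage("color", color_cells(grid, props, descriptor))

  overlay <- NULL
  if (!is.null(overlay_file)) {
    ext <- stage("overlay", standardize_library(
      read_smiles_file(overlay_file), max_hac = max_hac))
    overlay <- stage("overlay", overlay_external(model, grid, ext, kind))
  }
  scene <- stage("scene", make_scene(grid, cells, mols, kind, descriptor,
                                     overlay))

  kmax <- min(diag_max_k, model$dim)
  diagnostics <- list(
    n_input = length(records) + nrow(attr(records, "rejections")),
    n_standardized = length(mols),
    fingerprint = kind,
    variance_coverage = vapply(seq_len(kmax), function(k)
      variance_coverage(model, k), numeric(1)),
    distance_correlation_k3 = tryCatch(
      distance_correlation(coords, fps, n_pairs = n_pairs, seed = seed),
      error = function(e) NA_real_),
    unique_fp_fraction = unique_fp_fraction(fps),
    single_occupancy_3d = occupancy_stats(grid),
    single_occupancy_2d = pixel_stats_2d(coords[, 1:2, drop = FALSE],
                                         n_bins = n_bins))

  stage("export", {
    write_pca_model(model, file.path(out_dir, "model.json"))
    utils::write.csv(data.frame(id = rownames(fps), coords),
                     file.path(out_dir, "coords.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_bins = grid$n_bins, pc_min = grid$pc_min, pc_max = grid$pc_max,
           bin_size = grid$bin_size,
           cells = lapply(seq_along(grid$cells), function(ci)
             list(cell = as.integer(strsplit(names(grid$cells)[ci], ",")[[1]]),
                  members = grid$cells[[ci]]))),
      file.path(out_dir, "grid.json"), digits = NA, auto_unbox = TRUE)
    export_scene_json(scene, file.path(out_dir, "scene.json"))
    export_html(scene, file.path(out_dir, "scene.html"))
    jsonlite::write_json(diagnostics, file.path(out_dir, "diagnostics.json"),
                         digits = NA, auto_unbox = TRUE)
    write_rejections_tsv(attr(mols, "rejections"),
                         file.path(out_dir, "rejections.tsv"))
  })

  invisible(list(mols = mols, fps = fps, model = model, coords = coords,
                 grid = grid, props = props, cells = cells, scene = scene,
                 diagnostics = diagnostics))
}
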