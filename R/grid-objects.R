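#' Gridded containers used throughout the pipeline
#'
#' All spatial objects in rangegap live on a common regular grid of
#' `nrow x ncol` square cells, indexed `(row, col)` with row 1 at the top
#' (standard matrix orientation). Cell area is a scalar in km² shared by
#' every cell; the default of 25 km² mirrors the ~5 km cells of a
#' 2.5 arc-minute climate grid. Values are stored as plain R matrices so
#' raster algebra is ordinary matrix algebra.
#'
#' * `climate_stack`: one climate scenario — a named list of per-variable
#'   matrices plus a validity mask.
#' * `score_stack`: principal-component scores for one scenario.
#' * `landcover_grid`: a single integer-coded categorical layer with the
#'   set of codes treated as forest habitat.
#' * `binary_range`: a thresholded presence/absence range for one taxon
#'   and scenario, with its area.
#' * `richness_map`: a per-cell count of overlapping binary ranges.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param scenario_id scenario label, e.g. `"present"`.
#' @param cell_area area of one grid cell in km² (scalar, > 0).
#' @param valid_mask logical matrix marking cells that carry data; defaults
#'   to all cells valid.
#' @name grid-objects
NULL

new_climate_stack <- function(layers, scenario_id, cell_area = 25,
                              valid_mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L) {
    abort("All layers of a climate_stack must share the same grid shape.")
  }
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == "")) {
    names(layers) <- paste0("var", seq_along(layers))
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow = dims[[1]][1], ncol = dims[[1]][2])
  }
  stopifnot(identical(dim(valid_mask), dims[[1]]), cell_area > 0)
  for (nm in names(layers)) {
    if (anyNA(layers[[nm]][valid_mask])) {
      abort(paste0("Layer '", nm, "' has missing values inside valid_mask."))
    }
  }
  structure(
    list(
      layers = layers,
      scenario_id = scenario_id,
      cell_area = cell_area,
      valid_mask = valid_mask
    ),
    class = "climate_stack"
  )
}

new_score_stack <- function(scores, scenario_id, valid_mask, cell_area = 25) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  structure(
    list(
      scores = scores,
      scenario_id = scenario_id,
      cell_area = cell_area,
      valid_mask = valid_mask
    ),
    class = "score_stack"
  )
}

new_landcover_grid <- function(category, forest_codes, cell_area = 25) {
  stopifnot(is.matrix(category))
  structure(
    list(category = category, forest_codes = as.integer(forest_codes),
         cell_area = cell_area),
    class = "landcover_grid"
  )
}

new_binary_range <- function(cells, taxon_id, scenario_id, threshold_used,
                             cell_area = 25) {
  stopifnot(is.matrix(cells), is.logical(cells))
  structure(
    list(
      taxon_id = taxon_id,
      scenario_id = scenario_id,
      cells = cells,
      threshold_used = threshold_used,
      cell_area = cell_area,
      area_km2 = sum(cells) * cell_area
    ),
    class = "binary_range"
  )
}

new_richness_map <- function(richness, scenario_id, taxa_included,
                             cell_area = 25) {
  structure(
    list(richness = richness, scenario_id = scenario_id,
         taxa_included = taxa_included, cell_area = cell_area),
    class = "richness_map"
  )
}

#' @export
dim.climate_stack <- function(x) dim(x$layers[[1]])

#' @export
dim.score_stack <- function(x) dim(x$scores[[1]])

#' @export
dim.landcover_grid <- function(x) dim(x$category)

#' @export
dim.binary_range <- function(x) dim(x$cells)

#' @export
dim.richness_map <- function(x) dim(x$richness)

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x)
  cat("<climate_stack> scenario '", x$scenario_id, "': ",
      length(x$layers), " layers on a ", d[1], "x", d[2], " grid (",
      sum(x$valid_mask), " valid cells, ", x$cell_area, " km2/cell)\n",
      sep = "")
  invisible(x)
}

#' @export
print.score_stack <- function(x, ...) {
  d <- dim(x)
  cat("<score_stack> scenario '", x$scenario_id, "': ", length(x$scores),
      " axes on a ", d[1], "x", d[2], " grid\n", sep = "")
  invisible(x)
}

#' @export
print.binary_range <- function(x, ...) {
  cat("<binary_range> ", x$taxon_id, " / ", x$scenario_id, ": ",
      sum(x$cells), " cells, ", x$area_km2, " km2 (threshold ",
      signif(x$threshold_used, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
print.richness_map <- function(x, ...) {
  cat("<richness_map> scenario '", x$scenario_id, "': ",
      length(x$taxa_included), " taxa, richness 0-", max(x$richness),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.landcover_grid <- function(x, ...) {
  d <- dim(x)
  ff <- mean(x$category %in% x$forest_codes)
  cat("<landcover_grid> ", d[1], "x", d[2], " grid, ",
      length(unique(as.vector(x$category))), " classes, forest share ",
      round(100 * ff, 1), "%\n", sep = "")
  invisible(x)
}

# ---- tabular views --------------------------------------------------------

grid_tibble <- function(mat) {
  d <- dim(mat)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(mat)
  )
}

#' @method as_tibble climate_stack
#' @export
as_tibble.climate_stack <- function(x, ...) {
  out <- purrr::imap(x$layers, function(m, nm) {
    mutate(grid_tibble(m), variable = nm, .before = "value")
  })
  mutate(bind_rows(out), scenario_id = x$scenario_id)
}

#' @method as_tibble score_stack
#' @export
as_tibble.score_stack <- function(x, ...) {
  out <- purrr::imap(x$scores, function(m, nm) {
    mutate(grid_tibble(m), axis = nm, .before = "value")
  })
  mutate(bind_rows(out), scenario_id = x$scenario_id)
}

#' @method as_tibble binary_range
#' @export
as_tibble.binary_range <- function(x, ...) {
  idx <- which(x$cells, arr.ind = TRUE)
  tibble(
    taxon_id = x$taxon_id, scenario_id = x$scenario_id,
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2])
  )
}

#' @method as_tibble richness_map
#' @export
as_tibble.richness_map <- function(x, ...) {
  mutate(grid_tibble(x$richness), scenario_id = x$scenario_id) |>
    dplyr::rename(richness = "value")
}

# ---- cell-set helpers -----------------------------------------------------

# cells: integer matrix with columns row, col
as_cell_matrix <- function(cells) {
  if (is.data.frame(cells)) {
    cells <- cbind(row = cells$row, col = cells$col)
  }
  storage.mode(cells) <- "integer"
  colnames(cells) <- c("row", "col")
  cells
}

cells_in_mask <- function(cells, mask) {
  cells <- as_cell_matrix(cells)
  inb <- cells[, 1] >= 1L & cells[, 1] <= nrow(mask) &
    cells[, 2] >= 1L & cells[, 2] <= ncol(mask)
  ok <- logical(nrow(cells))
  ok[inb] <- mask[cells[inb, , drop = FALSE]]
  ok
}

mask_from_cells <- function(cells, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[as_cell_matrix(cells)] <- TRUE
  m
}

# Extract per-record axis-score features at a set of cells.
score_features <- function(scores, cells) {
  cells <- as_cell_matrix(cells)
  out <- vapply(scores$scores, function(m) m[cells], numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells),
                dimnames = list(NULL, names(scores$scores)))
  out
}
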