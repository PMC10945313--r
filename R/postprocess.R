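#' Jaccard-maximizing binarization threshold
#'
#' Scans every candidate threshold (the sorted unique suitability values at
#' the evaluation cells) and returns the one whose presence prediction
#' (`suitability >= t`) maximizes the Jaccard similarity with the observed
#' presences; ties are broken by the smallest such threshold. This is the
#' threshold used to turn continuous ensemble maps into binary ranges.
#'
#' @param suitability numeric matrix of ensemble suitability.
#' @param presence_cells,absence_cells evaluation cells as `(row, col)`
#'   tibbles or matrices (both non-empty).
#' @return The selected threshold (a suitability value).
#' @export
select_threshold <- function(suitability, presence_cells, absence_cells) {
  pres <- as_cell_matrix(presence_cells)
  absc <- as_cell_matrix(absence_cells)
  if (!nrow(pres) || !nrow(absc)) {
    abort("select_threshold needs non-empty presence and absence cells.")
  }
  scores <- c(suitability[pres], suitability[absc])
  labels <- rep(c(1L, 0L), c(nrow(pres), nrow(absc)))
  if (length(unique(scores)) == 1L) {
    warn("Suitability is constant at evaluation cells; returning that constant.")
    return(scores[1])
  }
  jaccard_threshold_search(scores, labels)$threshold
}

#' Binarize a suitability map
#'
#' A cell is inside the range iff its suitability is defined and at or
#' above the threshold (attaining the threshold counts as suitable). Area
#' is the cell count times the cell area.
#'
#' @param suitability numeric matrix (or an `ensemble_result`).
#' @param threshold cut in `[0, 1]`.
#' @param cell_area km² per cell.
#' @param taxon_id,scenario_id labels; taken from the ensemble when one is
#'   supplied.
#' @return A `binary_range`.
#' @export
binarize <- function(suitability, threshold, cell_area = 25,
                     taxon_id = NA_character_, scenario_id = NA_character_) {
  if (inherits(suitability, "ensemble_result")) {
    if (is.na(taxon_id)) taxon_id <- suitability$taxon_id
    if (is.na(scenario_id)) scenario_id <- suitability$scenario_id
    suitability <- suitability$suitability
  }
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1].")
  cells <- !is.na(suitability) & suitability >= threshold
  new_binary_range(cells, taxon_id, scenario_id, threshold, cell_area)
}

#' Mask a binary range to forest land cover
#'
#' Keeps only range cells whose land-cover code belongs to the grid's
#' forest (habitat) classes, restricting climate ranges to forested
#' vegetation the taxa depend on.
#'
#' @param range a `binary_range`.
#' @param lc a `landcover_grid` with matching dimensions.
#' @return A `binary_range` with the same threshold and updated area.
#' @export
apply_forest_mask <- function(range, lc) {
  stopifnot(inherits(range, "binary_range"), inherits(lc, "landcover_grid"))
  if (!identical(dim(range), dim(lc))) {
    abort("Land-cover grid and range have different dimensions.")
  }
  forest <- matrix(lc$category %in% lc$forest_codes, nrow(lc$category))
  new_binary_range(range$cells & forest, range$taxon_id, range$scenario_id,
                   range$threshold_used, range$cell_area)
}

#' Restrict a future range to the present one
#'
#' Cell-wise AND of the two ranges — applied to floodplain-restricted taxa
#' whose future distributions are limited by their present climatically
#' suitable areas.
#'
#' @param future,present `binary_range`s of the same taxon and grid.
#' @return The restricted future `binary_range`.
#' @export
restrict_future_to_present <- function(future, present) {
  stopifnot(inherits(future, "binary_range"), inherits(present, "binary_range"))
  if (!identical(dim(future), dim(present))) {
    abort("Ranges have different dimensions.")
  }
  new_binary_range(future$cells & present$cells, future$taxon_id,
                   future$scenario_id, future$threshold_used,
                   future$cell_area)
}

#' Percent change in suitable area between scenarios
#'
#' `100 * (future - present) / present` on the ranges' areas; losses are
#' negative, and a complete loss of suitable area reports -100. Taxa whose
#' loss exceeds 99% are flagged downstream as lacking climatically suitable
#' area in that future.
#'
#' @param present,future `binary_range`s (present area must be positive).
#' @return Percent change (scalar).
#' @export
area_change <- function(present, future) {
  stopifnot(inherits(present, "binary_range"), inherits(future, "binary_range"))
  if (present$area_km2 <= 0) {
    abort("Present area is zero; percent change is undefined.")
  }
  100 * (future$area_km2 - present$area_km2) / present$area_km2
}

#' Stack binary ranges into a richness map
#'
#' The stacked-SDM richness of a cell is the number of taxa whose binary
#' range covers it. All ranges must share the grid and scenario.
#'
#' @param ranges list of `binary_range`s for one scenario (may be empty if
#'   `dims` is given).
#' @param dims grid dimensions, required when `ranges` is empty.
#' @param scenario_id scenario label; defaults to the ranges' common label.
#' @return A `richness_map`.
#' @export
stack_richness <- function(ranges, dims = NULL, scenario_id = NULL) {
  if (!length(ranges)) {
    if (is.null(dims)) abort("Empty range list needs explicit dims.")
    return(new_richness_map(matrix(0L, dims[1], dims[2]),
                            scenario_id %||% NA_character_, character(0)))
  }
  scen <- unique(map_chr(ranges, "scenario_id"))
  if (length(scen) > 1L) {
    abort(paste0("Ranges mix scenarios: ", paste(scen, collapse = ", ")))
  }
  dd <- unique(lapply(ranges, dim))
  if (length(dd) != 1L) abort("Ranges are on different grids.")
  rich <- Reduce(`+`, purrr::map(ranges, function(r) r$cells * 1L))
  new_richness_map(matrix(as.integer(rich), dd[[1]][1], dd[[1]][2]),
                   scenario_id %||% scen,
                   map_chr(ranges, "taxon_id"),
                   cell_area = ranges[[1]]$cell_area)
}
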