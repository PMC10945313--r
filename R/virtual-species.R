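#' Create a virtual species with a known climate niche
#'
#' The species' suitability follows the standard virtual-species
#' convention: an independent Gaussian response curve per climate variable,
#' multiplied across variables and rescaled so the best cell scores 1. The
#' true range is the set of cells at or above `range_cut`; an endemism
#' region (the padded bounding box of the true range) plays the role of the
#' biogeographic calibration area.
#'
#' @param stack a `climate_stack`.
#' @param niche_params data frame with columns `var`, `optimum`, `breadth`
#'   (one row per climate variable used; `breadth` is the Gaussian sd).
#' @param range_cut suitability cut defining the true range, in `[0, 1]`.
#' @param taxon_id species label.
#' @param endemism_margin cells of padding around the true range's bounding
#'   box when defining the endemism region.
#' @return A `virtual_species` with fields `taxon_id`, `niche_params`,
#'   `true_suitability`, `true_range`, `endemism_region`.
#' @examples
#' land <- generate_landscape(1, c(30, 30), n_vars = 3)
#' np <- tibble::tibble(var = c("var1", "var2"), optimum = 0, breadth = 1)
#' sp <- generate_virtual_species(land, np, range_cut = 0.4)
#' @export
generate_virtual_species <- function(stack, niche_params, range_cut = 0.3,
                                     taxon_id = "vsp1", endemism_margin = 5) {
  stopifnot(inherits(stack, "climate_stack"))
  niche_params <- as_tibble(niche_params)
  missing_vars <- setdiff(niche_params$var, names(stack$layers))
  if (length(missing_vars)) {
    abort(paste0("niche_params reference unknown layers: ",
                 paste(missing_vars, collapse = ", ")))
  }
  stopifnot(all(niche_params$breadth > 0), range_cut >= 0, range_cut <= 1)
  dims <- dim(stack)
  log_suit <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(niche_params))) {
    x <- stack$layers[[niche_params$var[i]]]
    log_suit <- log_suit -
      (x - niche_params$optimum[i])^2 / (2 * niche_params$breadth[i]^2)
  }
  suit <- exp(log_suit)
  suit[!stack$valid_mask] <- NA_real_
  mx <- max(suit, na.rm = TRUE)
  if (mx > 0) suit <- suit / mx
  true_range <- !is.na(suit) & suit >= range_cut
  if (!any(true_range)) {
    warn(paste0("Virtual species '", taxon_id,
                "' has an empty true range at range_cut = ", range_cut, "."))
  }
  structure(
    list(
      taxon_id = taxon_id,
      niche_params = niche_params,
      true_suitability = suit,
      true_range = true_range,
      endemism_region = endemism_region(true_range, stack$valid_mask,
                                        endemism_margin),
      cell_area = stack$cell_area
    ),
    class = "virtual_species"
  )
}

endemism_region <- function(true_range, valid_mask, margin) {
  if (!any(true_range)) return(valid_mask)
  idx <- which(true_range, arr.ind = TRUE)
  r1 <- max(1L, min(idx[, 1]) - margin)
  r2 <- min(nrow(true_range), max(idx[, 1]) + margin)
  c1 <- max(1L, min(idx[, 2]) - margin)
  c2 <- min(ncol(true_range), max(idx[, 2]) + margin)
  reg <- matrix(FALSE, nrow(true_range), ncol(true_range))
  reg[r1:r2, c1:c2] <- TRUE
  reg & valid_mask
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("<virtual_species> ", x$taxon_id, ": true range ", sum(x$true_range),
      " cells, calibration region ", sum(x$endemism_region), " cells\n",
      sep = "")
  invisible(x)
}

#' Sample occurrence cells for a virtual species
#'
#' Draws `n` unique presence cells without replacement from the species'
#' true range, with inclusion probability proportional to true suitability —
#' detections concentrate where the species does. No survey-bias structure
#' is modelled.
#'
#' @param species a `virtual_species`.
#' @param n number of unique occurrence cells (`<=` size of the true range).
#' @param seed integer seed.
#' @return A tibble with columns `taxon_id`, `row`, `col` (one row per
#'   unique occurrence cell), sorted by cell.
#' @export
sample_occurrences <- function(species, n, seed) {
  stopifnot(inherits(species, "virtual_species"))
  idx <- which(species$true_range)
  if (n > length(idx)) {
    abort(paste0("Requested ", n, " occurrences but the true range has only ",
                 length(idx), " cells."))
  }
  w <- species$true_suitability[idx]
  pick <- with_seed(seed, sample(idx, size = n, replace = FALSE, prob = w))
  d <- dim(species$true_range)
  out <- tibble(
    taxon_id = species$taxon_id,
    row = as.integer((pick - 1L) %% d[1] + 1L),
    col = as.integer((pick - 1L) %/% d[1] + 1L)
  )
  arrange(out, .data$row, .data$col)
}

#' Generate a categorized set of protected areas
#'
#' Places `n_areas` contiguous blob-shaped footprints on the grid by seeded
#' random growth (each blob starts at a random cell and accretes random
#' neighbouring cells until it reaches its target size), assigning each a
#' protection category drawn by weight from strictly protected areas (SPA),
#' sustainable use areas (SUA) and indigenous territories (IT).
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param n_areas number of protected areas (the source study used 347).
#' @param size_range integer `c(min, max)` footprint size in cells.
#' @param category_weights named weights over `SPA`, `SUA`, `IT`.
#' @param seed integer seed.
#' @param valid_mask optional logical matrix; footprints stay inside it.
#' @return A `pa_set`: a tibble with columns `pa_id`, `category` and a
#'   list-column `footprint` of `(row, col)` cell matrices.
#' @export
generate_protected_areas <- function(grid_shape = c(50, 50), n_areas = 347,
                                     size_range = c(2, 40),
                                     category_weights = c(SPA = 1, SUA = 1, IT = 1),
                                     seed = 1, valid_mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(n_areas >= 1, length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2])
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, grid_shape[1], grid_shape[2])
  }
  cats <- names(category_weights)
  out <- with_seed(seed, {
    res <- vector("list", n_areas)
    for (i in seq_len(n_areas)) {
      size <- sample(size_range[1]:size_range[2], 1L)
      fp <- NULL
      for (attempt in 1:2) {
        fp <- grow_blob(grid_shape, size, valid_mask)
        if (!is.null(fp)) break
      }
      if (is.null(fp)) {
        warn(paste0("Protected area ", i, " of size ", size,
                    " could not be placed; skipped."))
        next
      }
      res[[i]] <- list(
        pa_id = sprintf("PA%03d", i),
        category = sample(cats, 1L, prob = category_weights),
        footprint = fp
      )
    }
    res[!vapply(res, is.null, logical(1))]
  })
  tb <- tibble(
    pa_id = map_chr(out, "pa_id"),
    category = map_chr(out, "category"),
    footprint = map(out, "footprint")
  )
  class(tb) <- c("pa_set", class(tb))
  tb
}

# Random connected blob of `size` cells inside valid_mask; NULL on failure.
grow_blob <- function(grid_shape, size, valid_mask) {
  valid_idx <- which(valid_mask)
  if (length(valid_idx) < size) return(NULL)
  start <- valid_idx[sample.int(length(valid_idx), 1L)]
  nr <- grid_shape[1]
  region <- start
  in_region <- logical(prod(grid_shape))
  in_region[start] <- TRUE
  while (length(region) < size) {
    cand <- unique(as.vector(vapply(region, function(ix) {
      r <- (ix - 1L) %% nr + 1L
      c(if (r > 1L) ix - 1L else NA_integer_,
        if (r < nr) ix + 1L else NA_integer_,
        ix - nr, ix + nr)
    }, integer(4))))
    cand <- cand[!is.na(cand) & cand >= 1L & cand <= prod(grid_shape)]
    cand <- cand[!in_region[cand] & valid_mask[cand]]
    if (!length(cand)) return(NULL)
    nxt <- cand[sample.int(length(cand), 1L)]
    region <- c(region, nxt)
    in_region[nxt] <- TRUE
  }
  cbind(row = as.integer((region - 1L) %% nr + 1L),
        col = as.integer((region - 1L) %/% nr + 1L))
}

#' @export
print.pa_set <- function(x, ...) {
  cat("<pa_set> ", nrow(x), " protected areas: ",
      paste(names(table(x$category)), table(x$category), sep = "=",
            collapse = ", "),
      "; footprint sizes ", min(map_int(x$footprint, nrow)), "-",
      max(map_int(x$footprint, nrow)), " cells\n", sep = "")
  NextMethod()
}

#' Union footprint mask of selected protected-area categories
#'
#' Cell-level OR over the footprints of all areas whose category is in
#' `categories`, so overlapping areas are never double-counted.
#'
#' @param pas a `pa_set`.
#' @param categories categories to include (default all present).
#' @param dims grid dimensions `c(rows, cols)`.
#' @return Logical matrix of protected cells.
#' @export
pa_union_mask <- function(pas, dims, categories = unique(pas$category)) {
  m <- matrix(FALSE, dims[1], dims[2])
  sel <- pas$footprint[pas$category %in% categories]
  for (fp in sel) m[fp] <- TRUE
  m
}
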