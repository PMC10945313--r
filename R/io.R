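#' Read and write single-layer grids as ESRI ASCII rasters
#'
#' Grids travel as the plain-text ESRI ASCII grid format (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values, top row first —
#' matching the package's row-1-at-top matrix orientation. `NA` cells are
#' written as the nodata value and read back as `NA`.
#'
#' @param mat numeric matrix (row 1 = top of the map).
#' @param path file path (`.asc`).
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize cell edge length (same units as `xll`/`yll`).
#' @param nodata value standing for missing cells in the file.
#' @return `read_ascii_grid()` returns a list with `values` (matrix),
#'   `xll`, `yll`, `cellsize`.
#' @export
write_ascii_grid <- function(mat, path, xll = 0, yll = 0, cellsize = 5,
                             nodata = -9999) {
  stopifnot(is.matrix(mat))
  vals <- mat
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(vals, 1, function(r) {
    paste(format(r, scientific = FALSE, trim = TRUE, digits = 15),
          collapse = " ")
  }), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    abort(paste0("'", path, "': expected ", hdr$nrows, " data rows, found ",
                 length(body), "."))
  }
  vals <- t(vapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }, numeric(hdr$ncols), USE.NAMES = FALSE))
  vals[vals == hdr$nodata_value] <- NA_real_
  list(values = matrix(vals, hdr$nrows, hdr$ncols),
       xll = hdr$xllcorner, yll = hdr$yllcorner, cellsize = hdr$cellsize)
}

grid_cellsize <- function(cell_area) sqrt(cell_area)

#' Write / read a climate stack as per-layer ASCII rasters with a sidecar
#'
#' Each layer goes to `<prefix>_<variable>.asc`; scenario id, cell area,
#' variable order and grid geometry go to `<prefix>_meta.json`. Reading
#' validates that every layer shares the recorded geometry and rejects
#' mismatched grids rather than resampling; cells that are nodata in any
#' layer are excluded from the validity mask.
#'
#' @param stack a `climate_stack`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the scenario id).
#' @param meta_path path to a `<prefix>_meta.json` written earlier.
#' @return `read_climate_stack()` returns a `climate_stack`.
#' @export
write_climate_stack <- function(stack, dir, prefix = stack$scenario_id) {
  stopifnot(inherits(stack, "climate_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- grid_cellsize(stack$cell_area)
  files <- purrr::imap_chr(stack$layers, function(m, nm) {
    f <- file.path(dir, paste0(prefix, "_", nm, ".asc"))
    m[!stack$valid_mask] <- NA_real_
    write_ascii_grid(m, f, cellsize = cs)
    basename(f)
  })
  meta <- list(
    scenario_id = stack$scenario_id,
    cell_area = stack$cell_area,
    variables = names(stack$layers),
    files = unname(files),
    nrows = nrow(stack$valid_mask),
    ncols = ncol(stack$valid_mask),
    cellsize = cs
  )
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_climate_stack
#' @export
read_climate_stack <- function(meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dir <- dirname(meta_path)
  layers <- list()
  geom <- NULL
  geom_file <- NULL
  for (i in seq_along(meta$variables)) {
    f <- file.path(dir, meta$files[i])
    g <- read_ascii_grid(f)
    this_geom <- c(nrow(g$values), ncol(g$values), g$xll, g$yll, g$cellsize)
    if (is.null(geom)) {
      geom <- this_geom
      geom_file <- f
    } else if (!isTRUE(all.equal(geom, this_geom))) {
      abort(paste0("Grid geometry mismatch between '", geom_file, "' (",
                   paste(geom, collapse = ", "), ") and '", f, "' (",
                   paste(this_geom, collapse = ", "), ")."))
    }
    layers[[meta$variables[i]]] <- g$values
  }
  valid <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  new_climate_stack(layers, scenario_id = meta$scenario_id,
                    cell_area = meta$cell_area, valid_mask = valid)
}

#' Write and read occurrence tables
#'
#' Occurrences travel as CSV with columns `taxon_id,x,y` in the raster's
#' coordinate system. On reading, points are snapped to the containing
#' cell using half-open cell intervals `[x0, x1) x [y0, y1)`; duplicate
#' points within a cell collapse to a single unique occurrence, points
#' falling off the grid are dropped with a message, and malformed rows
#' (unparseable coordinates) are skipped — an all-malformed or empty file
#' is an error.
#'
#' @param occ tibble with `taxon_id`, `row`, `col`.
#' @param path CSV path.
#' @param dims grid dimensions `c(rows, cols)`.
#' @param cellsize cell edge; defaults to `sqrt(25)` (25 km² cells).
#' @param xll,yll lower-left corner of the grid.
#' @return `read_occurrences()` returns a tibble `taxon_id`, `row`, `col`
#'   of unique in-grid occurrence cells.
#' @export
write_occurrences <- function(occ, path, dims, cellsize = sqrt(25),
                              xll = 0, yll = 0) {
  out <- tibble(
    taxon_id = occ$taxon_id,
    x = xll + (occ$col - 0.5) * cellsize,
    y = yll + (dims[1] - occ$row + 0.5) * cellsize
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path, dims, cellsize = sqrt(25),
                             xll = 0, yll = 0) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    taxon_id = readr::col_character(),
    x = readr::col_character(),
    y = readr::col_character()
  ))
  if (!nrow(raw)) abort(paste0("'", path, "' contains no occurrence rows."))
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- is.na(x) | is.na(y) | is.na(raw$taxon_id)
  if (all(bad)) abort(paste0("'", path, "': every row is malformed."))
  if (any(bad)) {
    inform(paste0("Skipped ", sum(bad), " malformed occurrence row(s)."))
  }
  col <- floor((x[!bad] - xll) / cellsize) + 1
  row <- dims[1] - floor((y[!bad] - yll) / cellsize)
  keep <- row >= 1 & row <= dims[1] & col >= 1 & col <= dims[2]
  if (any(!keep)) {
    inform(paste0("Dropped ", sum(!keep), " occurrence point(s) outside the grid."))
  }
  distinct(tibble(
    taxon_id = raw$taxon_id[!bad][keep],
    row = as.integer(row[keep]),
    col = as.integer(col[keep])
  ))
}

#' Write and read protected areas
#'
#' Two on-disk forms are supported. The GeoJSON writer emits each area as
#' a MultiPolygon of axis-aligned cell squares with properties `pa_id` and
#' `category`; the GeoJSON reader recovers footprint cells from those
#' grid-aligned squares (it reads this dialect, not arbitrary polygons).
#' The rasterized-mask CSV (`pa_id,category,row,col`, one row per
#' footprint cell) is the lossless round-trip form.
#'
#' @param pas a `pa_set`.
#' @param path output path.
#' @param dims grid dimensions `c(rows, cols)`.
#' @param cellsize,xll,yll grid geometry (as in [write_occurrences()]).
#' @return Readers return a `pa_set`.
#' @export
write_pa_geojson <- function(pas, path, dims, cellsize = sqrt(25),
                             xll = 0, yll = 0) {
  features <- purrr::pmap(
    list(pas$pa_id, pas$category, pas$footprint),
    function(id, cat, fp) {
      fp <- as_cell_matrix(fp)
      polys <- lapply(seq_len(nrow(fp)), function(i) {
        x0 <- xll + (fp[i, 2] - 1) * cellsize
        y0 <- yll + (dims[1] - fp[i, 1]) * cellsize
        list(list(
          list(x0, y0), list(x0 + cellsize, y0),
          list(x0 + cellsize, y0 + cellsize), list(x0, y0 + cellsize),
          list(x0, y0)
        ))
      })
      list(
        type = "Feature",
        properties = list(pa_id = id, category = cat),
        geometry = list(type = "MultiPolygon", coordinates = polys)
      )
    }
  )
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pa_geojson
#' @export
read_pa_geojson <- function(path, dims, cellsize = sqrt(25),
                            xll = 0, yll = 0) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(obj$features, function(ft) {
    cells <- purrr::map(ft$geometry$coordinates, function(poly) {
      ring <- poly[[1]]
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
      c(row = dims[1] - round((min(ys) - yll) / cellsize),
        col = round((min(xs) - xll) / cellsize) + 1)
    })
    fp <- do.call(rbind, cells)
    list(pa_id = ft$properties$pa_id, category = ft$properties$category,
         footprint = as_cell_matrix(fp))
  })
  tb <- tibble(
    pa_id = map_chr(rows, "pa_id"),
    category = map_chr(rows, "category"),
    footprint = map(rows, "footprint")
  )
  class(tb) <- c("pa_set", class(tb))
  tb
}

#' @rdname write_pa_geojson
#' @export
write_pa_mask_csv <- function(pas, path) {
  rows <- purrr::pmap(
    list(pas$pa_id, pas$category, pas$footprint),
    function(id, cat, fp) {
      fp <- as_cell_matrix(fp)
      tibble(pa_id = id, category = cat,
             row = fp[, 1], col = fp[, 2])
    }
  )
  readr::write_csv(bind_rows(rows), path)
  invisible(path)
}

#' @rdname write_pa_geojson
#' @export
read_pa_mask_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    pa_id = readr::col_character(), category = readr::col_character(),
    row = readr::col_integer(), col = readr::col_integer()
  ))
  tb <- raw |>
    group_by(.data$pa_id, .data$category) |>
    summarise(footprint = list(cbind(row = .data$row, col = .data$col)),
              .groups = "drop") |>
    arrange(.data$pa_id)
  tb$footprint <- purrr::map(tb$footprint, as_cell_matrix)
  class(tb) <- c("pa_set", class(tb))
  tb
}

#' Write a land-cover grid / binary range / richness map as ASCII rasters
#'
#' @param x the gridded object.
#' @param path `.asc` output path.
#' @return The path, invisibly.
#' @export
write_grid_asc <- function(x, path) {
  m <- if (inherits(x, "landcover_grid")) {
    matrix(as.numeric(x$category), nrow(x$category))
  } else if (inherits(x, "binary_range")) {
    matrix(as.numeric(x$cells), nrow(x$cells))
  } else if (inherits(x, "richness_map")) {
    matrix(as.numeric(x$richness), nrow(x$richness))
  } else if (is.matrix(x)) {
    x
  } else {
    abort("Unsupported object for write_grid_asc().")
  }
  area <- if (is.list(x) && !is.null(x$cell_area)) x$cell_area else 25
  cs <- grid_cellsize(area)
  write_ascii_grid(m, path, cellsize = cs)
}
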