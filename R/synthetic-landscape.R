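#' Generate a spatially autocorrelated synthetic climate landscape
#'
#' Builds one climate scenario as a set of independent spatially
#' autocorrelated fields: per variable, white Gaussian noise is smoothed
#' with an isotropic Gaussian kernel of standard deviation `autocorr_scale`
#' (cells; wrap-around convolution keeps the field stationary) and then
#' standardized to zero mean and unit variance over valid cells. The result
#' plays the role of a set of bioclimatic predictor layers.
#'
#' @param seed integer seed; the generator is a pure function of the seed
#'   and parameters.
#' @param grid_shape integer `c(rows, cols)`.
#' @param n_vars number of climate variables (layers), at least 2.
#' @param autocorr_scale Gaussian smoothing scale in cells (> 0). Larger
#'   scales give longer-range spatial autocorrelation.
#' @param cell_area cell area in km² (default 25, i.e. ~5 km cells).
#' @param scenario_id scenario label (default `"present"`).
#' @param valid_mask optional logical matrix of cells that carry data.
#' @return A `climate_stack`.
#' @examples
#' land <- generate_landscape(seed = 1, grid_shape = c(30, 30), n_vars = 4)
#' land
#' @export
generate_landscape <- function(seed, grid_shape = c(50, 50), n_vars = 6,
                               autocorr_scale = 5, cell_area = 25,
                               scenario_id = "present", valid_mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L)) {
    abort("grid_shape must be two positive integers c(rows, cols).")
  }
  if (n_vars < 2L) abort("n_vars must be at least 2.")
  if (autocorr_scale <= 0) abort("autocorr_scale must be positive.")
  if (is.null(valid_mask)) matrix(TRUE, grid_shape[1], grid_shape[2]) -> valid_mask
  layers <- with_seed(seed, {
    lapply(seq_len(n_vars), function(i) {
      f <- smooth_field(matrix(stats::rnorm(prod(grid_shape)),
                               grid_shape[1], grid_shape[2]),
                        autocorr_scale)
      standardize_field(f, valid_mask)
    })
  })
  names(layers) <- paste0("var", seq_len(n_vars))
  new_climate_stack(layers, scenario_id = scenario_id,
                    cell_area = cell_area, valid_mask = valid_mask)
}

# Gaussian-kernel smoothing with wrap-around edges (separable convolution).
smooth_field <- function(mat, scale) {
  if (scale <= 0) return(mat)
  kernel <- function(n) {
    # truncate at 3 sd but never longer than the series being filtered
    half <- min(max(1L, as.integer(ceiling(3 * scale))), (n - 1L) %/% 2L)
    k <- dnorm(seq(-half, half), sd = scale)
    k / sum(k)
  }
  k_col <- kernel(nrow(mat))
  k_row <- kernel(ncol(mat))
  sm_col <- apply(mat, 2, function(v) {
    as.numeric(stats::filter(v, k_col, method = "convolution", sides = 2,
                             circular = TRUE))
  })
  sm <- t(apply(sm_col, 1, function(v) {
    as.numeric(stats::filter(v, k_row, method = "convolution", sides = 2,
                             circular = TRUE))
  }))
  matrix(sm, nrow = nrow(mat), ncol = ncol(mat))
}

standardize_field <- function(mat, valid_mask) {
  v <- mat[valid_mask]
  s <- sd(v)
  if (s < 1e-12) s <- 1
  out <- (mat - mean(v)) / s
  out[!valid_mask] <- NA_real_
  out
}

#' Lag-1 spatial autocorrelation of a gridded field
#'
#' Mean correlation between the field and its one-cell shifts along rows and
#' columns — a quick Moran's-I-style summary used to compare smoothing
#' scales.
#'
#' @param mat numeric matrix.
#' @return Correlation in `[-1, 1]`.
#' @export
lag1_autocorrelation <- function(mat) {
  r <- stats::cor(as.vector(mat[-1, ]), as.vector(mat[-nrow(mat), ]),
                  use = "complete.obs")
  c <- stats::cor(as.vector(mat[, -1]), as.vector(mat[, -ncol(mat)]),
                  use = "complete.obs")
  mean(c(r, c))
}

#' Derive a future climate scenario from the present one
#'
#' A future scenario is the present layers plus a per-variable uniform
#' offset (the scenario's mean climate shift) plus optional spatially
#' autocorrelated noise of standard deviation `noise_sd`, emulating the
#' spatial heterogeneity of projected anomalies. Geometry, validity mask and
#' cell area are inherited from the present stack.
#'
#' @param present a `climate_stack`.
#' @param shift numeric offsets, one per layer (or a single value recycled).
#' @param noise_sd standard deviation of the added autocorrelated anomaly
#'   field (0 for a deterministic shift).
#' @param seed integer seed for the anomaly field.
#' @param autocorr_scale smoothing scale of the anomaly field, in cells.
#' @param scenario_id label for the new scenario.
#' @return A `climate_stack` with the same geometry as `present`.
#' @export
generate_future <- function(present, shift, noise_sd = 0, seed = 1,
                            autocorr_scale = 5, scenario_id = "future") {
  stopifnot(inherits(present, "climate_stack"))
  n <- length(present$layers)
  if (length(shift) == 1L) shift <- rep(shift, n)
  if (length(shift) != n) {
    abort(paste0("shift must have one entry per layer (", n, "), got ",
                 length(shift), "."))
  }
  dims <- dim(present)
  noise <- if (noise_sd > 0) {
    with_seed(seed, {
      lapply(seq_len(n), function(i) {
        f <- smooth_field(matrix(stats::rnorm(prod(dims)), dims[1], dims[2]),
                          autocorr_scale)
        noise_sd * standardize_field(f, present$valid_mask)
      })
    })
  } else {
    lapply(seq_len(n), function(i) 0)
  }
  layers <- purrr::map(seq_len(n), function(i) {
    present$layers[[i]] + shift[i] + noise[[i]]
  })
  names(layers) <- names(present$layers)
  new_climate_stack(layers, scenario_id = scenario_id,
                    cell_area = present$cell_area,
                    valid_mask = present$valid_mask)
}

#' Generate a clumped categorical land-cover grid
#'
#' Thresholds a smoothed random field so that the `forest_fraction` share of
#' cells with the highest field values become forest; forest is split into
#' two forest classes (codes 1-2, e.g. evergreen and deciduous broadleaf)
#' and the remainder into two non-forest classes (codes 3-4), all spatially
#' clumped. Codes 1 and 2 form `forest_codes`, the habitat classes retained
#' when masking ranges.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param forest_fraction target share of forest cells in `[0, 1]`.
#' @param autocorr_scale smoothing scale of the underlying field (cells).
#' @param seed integer seed.
#' @param cell_area cell area in km².
#' @return A `landcover_grid`.
#' @export
generate_landcover <- function(grid_shape = c(50, 50), forest_fraction = 0.7,
                               autocorr_scale = 5, seed = 1, cell_area = 25) {
  if (forest_fraction < 0 || forest_fraction > 1) {
    abort("forest_fraction must lie in [0, 1].")
  }
  grid_shape <- as.integer(grid_shape)
  ncell <- prod(grid_shape)
  field <- with_seed(seed, {
    smooth_field(matrix(stats::rnorm(ncell), grid_shape[1], grid_shape[2]),
                 autocorr_scale)
  })
  n_forest <- round(forest_fraction * ncell)
  ord <- order(field, decreasing = TRUE)
  category <- matrix(4L, grid_shape[1], grid_shape[2])
  if (n_forest > 0) {
    forest_idx <- ord[seq_len(n_forest)]
    # split forest into two classes by field value, non-forest likewise
    n1 <- ceiling(n_forest / 2)
    category[forest_idx[seq_len(n1)]] <- 1L
    if (n_forest > n1) category[forest_idx[(n1 + 1):n_forest]] <- 2L
  }
  if (n_forest < ncell) {
    rest <- ord[(n_forest + 1):ncell]
    n3 <- ceiling(length(rest) / 2)
    category[rest[seq_len(n3)]] <- 3L
  }
  new_landcover_grid(category, forest_codes = c(1L, 2L),
                     cell_area = cell_area)
}
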