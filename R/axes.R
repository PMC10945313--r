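#' Fit orthogonal climate axes on the present scenario
#'
#' Standardizes each climate variable over valid cells of the present
#' scenario and fits a principal component analysis, keeping the smallest
#' number of axes whose cumulative variance reaches `variance_target`
#' (default 0.95, i.e. axes explaining at least 95% of the original climate
#' variation). The standardization constants and loadings are stored so
#' every scenario — present and future — is projected with the same
#' present-fit coefficients, keeping the predictor space dimensionally
#' consistent across time.
#'
#' Constant layers (zero variance) cannot be standardized and are dropped
#' with a warning before fitting. For reproducibility across linear-algebra
#' backends, each loading column is oriented so its largest-magnitude entry
#' is positive.
#'
#' @param present a `climate_stack` for the baseline scenario.
#' @param variance_target fraction of variance the kept axes must explain.
#' @return An `axis_model` with fields `var_names`, `means`, `sds`,
#'   `loadings` (variables x kept axes, orthonormal columns),
#'   `variance_explained` (all axes), `n_axes_kept`, `variance_target`, and
#'   `fit_scores` (the present-scenario `score_stack`).
#' @seealso [project_scores()], [tidy.axis_model()]
#' @export
fit_axes <- function(present, variance_target = 0.95) {
  stopifnot(inherits(present, "climate_stack"))
  if (length(present$layers) < 2L) {
    abort("fit_axes needs at least two climate layers.")
  }
  valid <- present$valid_mask
  X <- vapply(present$layers, function(m) m[valid], numeric(sum(valid)))
  if (nrow(X) < ncol(X)) {
    abort("Fewer valid cells than variables; cannot fit axes.")
  }
  sds <- apply(X, 2, sd)
  constant <- sds < 1e-12
  if (any(constant)) {
    warn(paste0("Dropping constant layer(s) before fitting: ",
                paste(colnames(X)[constant], collapse = ", ")))
    X <- X[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  if (ncol(X) < 2L) abort("Fewer than two non-constant layers remain.")
  means <- colMeans(X)
  Z <- sweep(sweep(X, 2, means, "-"), 2, sds, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(ve)
  k <- if (variance_target >= 1) length(ve) else {
    which(cum >= variance_target - 1e-12)[1]
  }
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("PC", seq_len(k))
  model <- structure(
    list(
      var_names = colnames(X),
      means = means,
      sds = sds,
      loadings = loadings,
      variance_explained = unname(ve),
      n_axes_kept = k,
      variance_target = variance_target
    ),
    class = "axis_model"
  )
  model$fit_scores <- project_scores(present, model)
  model
}

#' Project a climate scenario onto fitted axes
#'
#' Applies the present-fit standardization and loadings to any scenario:
#' per cell, `scores = ((values - means) / sds) %*% loadings`. Future
#' scenarios are never re-standardized, so a uniform climate shift moves
#' axis scores by the corresponding loading-weighted amount. Projecting the
#' present stack through its own model reproduces the fitting-time scores.
#'
#' @param stack a `climate_stack` whose variables include the model's, in
#'   the same order (extra variables the model dropped are ignored).
#' @param model an `axis_model` from [fit_axes()].
#' @return A `score_stack` with `n_axes_kept` axes.
#' @export
project_scores <- function(stack, model) {
  stopifnot(inherits(stack, "climate_stack"), inherits(model, "axis_model"))
  missing_vars <- setdiff(model$var_names, names(stack$layers))
  if (length(missing_vars)) {
    abort(paste0("Stack is missing model variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  }
  present_order <- intersect(names(stack$layers), model$var_names)
  if (!identical(present_order, model$var_names)) {
    abort(paste0("Stack variables are not in the model's order; expected ",
                 paste(model$var_names, collapse = ", ")))
  }
  dims <- dim(stack)
  valid <- stack$valid_mask
  X <- vapply(model$var_names, function(nm) stack$layers[[nm]][valid],
              numeric(sum(valid)))
  Z <- sweep(sweep(X, 2, model$means, "-"), 2, model$sds, "/")
  S <- Z %*% model$loadings
  scores <- lapply(seq_len(ncol(S)), function(j) {
    m <- matrix(NA_real_, dims[1], dims[2])
    m[valid] <- S[, j]
    m
  })
  names(scores) <- colnames(model$loadings)
  new_score_stack(scores, scenario_id = stack$scenario_id,
                  valid_mask = valid, cell_area = stack$cell_area)
}

#' @export
print.axis_model <- function(x, ...) {
  cum <- sum(x$variance_explained[seq_len(x$n_axes_kept)])
  cat("<axis_model> ", length(x$var_names), " variables -> ", x$n_axes_kept,
      " axes (", round(100 * cum, 1), "% of variance; target ",
      100 * x$variance_target, "%)\n", sep = "")
  invisible(x)
}

#' Tidy an axis model
#'
#' @param x an `axis_model`.
#' @param ... unused.
#' @return `tidy()`: one row per variable x kept axis with the loading;
#'   `glance()`: a one-row summary.
#' @method tidy axis_model
#' @export
tidy.axis_model <- function(x, ...) {
  tibble(
    variable = rep(rownames(x$loadings), times = ncol(x$loadings)),
    axis = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' @rdname tidy.axis_model
#' @method glance axis_model
#' @export
glance.axis_model <- function(x, ...) {
  tibble(
    n_variables = length(x$var_names),
    n_axes_kept = x$n_axes_kept,
    variance_target = x$variance_target,
    cum_variance = sum(x$variance_explained[seq_len(x$n_axes_kept)])
  )
}

#' Serialize / restore an axis model as JSON
#'
#' Writes the standardization constants, loadings and variances to a plain
#' JSON sidecar so projections can be re-run bit-identically, and reads the
#' model back.
#'
#' @param model an `axis_model`.
#' @param path file path.
#' @return `read_axis_model()` returns an `axis_model` (without the cached
#'   fit-time scores).
#' @export
write_axis_model <- function(model, path) {
  obj <- list(
    var_names = model$var_names,
    means = unname(model$means),
    sds = unname(model$sds),
    loadings = lapply(seq_len(ncol(model$loadings)),
                      function(j) unname(model$loadings[, j])),
    variance_explained = model$variance_explained,
    n_axes_kept = model$n_axes_kept,
    variance_target = model$variance_target
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_axis_model
#' @export
read_axis_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # loadings are serialized as a list of per-axis columns; jsonlite
  # simplifies equal-length columns to an axes x variables matrix
  loadings <- if (is.matrix(obj$loadings)) {
    t(obj$loadings)
  } else {
    matrix(unlist(obj$loadings), ncol = obj$n_axes_kept)
  }
  rownames(loadings) <- obj$var_names
  colnames(loadings) <- paste0("PC", seq_len(obj$n_axes_kept))
  structure(
    list(
      var_names = obj$var_names,
      means = stats::setNames(obj$means, obj$var_names),
      sds = stats::setNames(obj$sds, obj$var_names),
      loadings = loadings,
      variance_explained = obj$variance_explained,
      n_axes_kept = obj$n_axes_kept,
      variance_target = obj$variance_target
    ),
    class = "axis_model"
  )
}
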