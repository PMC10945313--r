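#' Assemble a presence / pseudo-absence training set
#'
#' Pairs a taxon's unique presence cells with pseudo-absences drawn
#' uniformly at random from the calibration region (the taxon's endemism
#' area), excluding presence cells, at `round(pa_ratio * n_presences)`
#' background points — the common ensemble-modelling default is a 1:1
#' ratio. Per-record predictor features are the axis scores at each cell.
#'
#' @param occ tibble of presence cells with columns `row`, `col` (and
#'   optionally `taxon_id`); cells must be unique and inside the
#'   calibration region.
#' @param scores a `score_stack` for the fitting scenario.
#' @param calibration_mask logical matrix delimiting the calibration
#'   region; defaults to the score stack's valid mask.
#' @param pa_ratio pseudo-absences per presence (> 0).
#' @param seed integer seed for the background draw.
#' @return A `training_set`: records tibble (`row`, `col`, `label` 1/0),
#'   feature matrix aligned with records, the calibration mask, taxon id.
#' @export
build_training_set <- function(occ, scores, calibration_mask = NULL,
                               pa_ratio = 1, seed = 1) {
  stopifnot(inherits(scores, "score_stack"), pa_ratio > 0)
  occ <- as_tibble(occ)
  dims <- dim(scores)
  if (is.null(calibration_mask)) calibration_mask <- scores$valid_mask
  calib <- calibration_mask & scores$valid_mask
  pres <- distinct(occ, .data$row, .data$col)
  if (!all(cells_in_mask(pres, calib))) {
    abort("Some presence cells fall outside the calibration region.")
  }
  pres_mask <- mask_from_cells(pres, dims)
  cand <- which(calib & !pres_mask)
  n_abs <- round(pa_ratio * nrow(pres))
  if (length(cand) < n_abs || n_abs < 1L) {
    abort(paste0("Need ", n_abs, " pseudo-absence cells but only ",
                 length(cand), " candidate cells are available."))
  }
  abs_idx <- with_seed(seed, sample(cand, n_abs, replace = FALSE))
  records <- bind_rows(
    mutate(pres, label = 1L),
    tibble(
      row = as.integer((abs_idx - 1L) %% dims[1] + 1L),
      col = as.integer((abs_idx - 1L) %/% dims[1] + 1L),
      label = 0L
    )
  )
  structure(
    list(
      taxon_id = if ("taxon_id" %in% names(occ)) occ$taxon_id[1] else NA_character_,
      records = records,
      features = score_features(scores, records),
      calibration_mask = calib
    ),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> ", sum(x$records$label == 1L), " presences + ",
      sum(x$records$label == 0L), " pseudo-absences, ",
      ncol(x$features), " predictors\n", sep = "")
  invisible(x)
}

#' Partition training records for cross-validation
#'
#' Taxa with 15 or more unique occurrences get the geographically
#' structured two-fold checkerboard partition: cell `(r, c)` (1-based)
#' belongs to fold `(floor((r-1)/block) + floor((c-1)/block)) %% 2`, so
#' alternating spatial blocks are fitted and evaluated in both directions.
#' Taxa below 15 unique occurrences get random balanced k-fold assignment
#' (stratified by label) with `k = min(k, n_unique)`.
#'
#' If a checkerboard fold ends up with no presences the block size is
#' halved and the assignment retried; if that still fails at block size 1
#' the partition falls back to k-fold with a warning.
#'
#' @param ts a `training_set`.
#' @param n_unique number of unique occurrences, deciding the method
#'   (defaults to the presence count in `ts`).
#' @param seed integer seed (k-fold assignment only; checkerboard is a pure
#'   function of cell coordinates).
#' @param k maximum number of folds for k-fold (default 5).
#' @param block_size checkerboard block edge in cells; defaults to
#'   calibration-region width / 10, at least 2.
#' @return A `partition_scheme`: method, per-record fold ids (0-based),
#'   and the block size or k used.
#' @export
partition <- function(ts, n_unique = NULL, seed = 1, k = 5,
                      block_size = NULL) {
  stopifnot(inherits(ts, "training_set"))
  n_unique <- n_unique %||% sum(ts$records$label == 1L)
  if (n_unique < 3L) abort("Need at least 3 unique occurrences to partition.")
  if (n_unique >= 15L) {
    if (is.null(block_size)) {
      cols <- range(which(apply(ts$calibration_mask, 2, any)))
      block_size <- max(2L, as.integer(floor((cols[2] - cols[1] + 1) / 10)))
    }
    b <- as.integer(block_size)
    while (b >= 1L) {
      fold <- checkerboard_fold(ts$records$row, ts$records$col, b)
      pres_per_fold <- table(factor(fold[ts$records$label == 1L],
                                    levels = c(0L, 1L)))
      if (all(pres_per_fold > 0L)) {
        return(structure(
          list(method = "checkerboard", fold = fold, block_size = b,
               n_folds = 2L),
          class = "partition_scheme"
        ))
      }
      b <- b %/% 2L
    }
    warn("Checkerboard could not balance presences at any block size; falling back to k-fold.")
  }
  k_use <- min(k, n_unique)
  fold <- with_seed(seed, {
    f <- integer(nrow(ts$records))
    for (lab in c(1L, 0L)) {
      ix <- which(ts$records$label == lab)
      f[ix] <- (sample(rep_len(seq_len(k_use), length(ix))) - 1L)
    }
    f
  })
  structure(
    list(method = "kfold", fold = fold, k = k_use, n_folds = k_use),
    class = "partition_scheme"
  )
}

checkerboard_fold <- function(row, col, block) {
  as.integer((((row - 1L) %/% block) + ((col - 1L) %/% block)) %% 2L)
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("<partition_scheme> ", x$method, " with ", x$n_folds, " folds",
      if (x$method == "checkerboard") paste0(" (block ", x$block_size, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half — the Mann-Whitney formulation of AUC.
#'
#' @param pos_scores scores at positive (presence) records.
#' @param neg_scores scores at negative (absence) records.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8), c(0.3, 0.4)) # 1
#' auc(c(0.7, 0.2), c(0.5, 0.1)) # 0.75
#' @export
auc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores)) {
    abort("auc needs at least one positive and one negative score.")
  }
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Jaccard similarity between predicted and observed presence sets
#'
#' `TP / (TP + FP + FN)` over a common record universe; 1 when both sets
#' are empty.
#'
#' @param predicted,observed logical vectors of equal length.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  tp <- sum(predicted & observed)
  denom <- sum(predicted | observed)
  if (denom == 0) 1 else tp / denom
}

# Maximize Jaccard over candidate thresholds (the sorted unique scores).
# Ties broken by the smallest threshold. Returns list(threshold, jaccard).
jaccard_threshold_search <- function(scores, labels) {
  cand <- sort(unique(scores))
  jac <- vapply(cand, function(t) jaccard(scores >= t, labels == 1L),
                numeric(1))
  best <- which.max(jac) # which.max returns the first (smallest) maximizer
  list(threshold = cand[best], jaccard = jac[best])
}

#' Evaluate prediction scores on held-out records
#'
#' Computes the two evaluation metrics: AUC, and the maximum Jaccard
#' similarity over all candidate thresholds (the unique held-out scores).
#'
#' @param scores numeric prediction scores at test records.
#' @param labels 0/1 labels at test records (needs both classes).
#' @return One-row tibble with `auc` and `jaccard_max`.
#' @export
evaluate_predictions <- function(scores, labels) {
  if (!any(labels == 1L) || !any(labels == 0L)) {
    abort("Evaluation needs at least one presence and one absence.")
  }
  tibble(
    auc = auc(scores[labels == 1L], scores[labels == 0L]),
    jaccard_max = jaccard_threshold_search(scores, labels)$jaccard
  )
}

# ---- estimator registry ---------------------------------------------------

#' Shipped distribution-model estimators
#'
#' An estimator is a list with fields `id`, `fit(X, y) -> model` and
#' `predict(model, X) -> scores` (any monotone suitability scale; maps are
#' min-max rescaled downstream). Two concrete estimators ship:
#'
#' * `estimator_logistic()` — ridge-regularized logistic regression on
#'   linear plus quadratic axis terms (the GLM/Maxent family: linear and
#'   quadratic features with weight shrinkage).
#' * `estimator_gaussian()` — a Gaussian environmental-distance scorer:
#'   suitability declines as `exp(-d²/2)` with the Mahalanobis distance `d`
#'   to the presence centroid (the climate-envelope family; presence-only,
#'   shrunken covariance).
#'
#' Users can plug additional estimators into [fit_estimators()] by
#' supplying objects with the same three fields.
#'
#' @param lambda ridge penalty used for prediction.
#' @return An estimator object (`rg_estimator`).
#' @export
estimator_logistic <- function(lambda = 1e-3) {
  expand <- function(X) {
    Q <- cbind(X, X^2)
    colnames(Q) <- c(colnames(X), paste0(colnames(X), "_sq"))
    Q
  }
  structure(
    list(
      id = "ridge_logistic",
      fit = function(X, y) {
        glmnet::glmnet(expand(X), y, family = "binomial", alpha = 0,
                       lambda = c(1, 0.1, lambda), standardize = TRUE)
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, newx = expand(X), s = lambda,
                                  type = "response"))
      }
    ),
    class = "rg_estimator"
  )
}

#' @rdname estimator_logistic
#' @export
estimator_gaussian <- function() {
  structure(
    list(
      id = "gaussian_distance",
      fit = function(X, y) {
        P <- X[y == 1L, , drop = FALSE]
        mu <- colMeans(P)
        d <- ncol(X)
        S <- if (nrow(P) >= 2L) cov(P) else diag(1, d)
        # shrink toward a spherical target so tiny folds stay invertible
        S <- 0.9 * S + diag(0.1 * mean(diag(S)) + 1e-6, d)
        list(mu = mu, sigma = S)
      },
      predict = function(model, X) {
        exp(-0.5 * mahalanobis(X, model$mu, model$sigma))
      }
    ),
    class = "rg_estimator"
  )
}

#' @rdname estimator_logistic
#' @export
default_estimators <- function() {
  list(estimator_logistic(), estimator_gaussian())
}

# ---- fitting and ensembling ----------------------------------------------

#' Fit, cross-validate and map every registered estimator
#'
#' For each estimator: every fold is held out in turn (both directions for
#' the two checkerboard folds; leave-one-fold-out for k-fold), the model is
#' fitted on the remaining records and scored on the held-out ones with AUC
#' and maximum Jaccard; the per-algorithm performance is the mean of the
#' chosen metric across evaluated folds. The estimator is then refitted on
#' all records and its raw scores over the calibration region are min-max
#' rescaled to `[0, 1]` so algorithms with different output scales average
#' sensibly. Folds lacking either class are skipped with a warning; an
#' estimator whose fit fails is excluded with a warning rather than
#' aborting the taxon.
#'
#' @param ts a `training_set`.
#' @param scheme a `partition_scheme` for `ts`.
#' @param scores the `score_stack` the training features came from.
#' @param estimators list of estimator objects (default both shipped ones).
#' @param metric which metric ranks algorithms: `"jaccard"` (the
#'   threshold-based evaluation metric, default) or `"auc"`.
#' @return List of `estimator_result` objects: `algorithm_id`,
#'   `fold_metrics` tibble, `mean_metric`, calibration-wide `suitability`
#'   matrix in `[0, 1]`, plus the refitted model and its rescaling
#'   constants for projecting other scenarios.
#' @export
fit_estimators <- function(ts, scheme, scores,
                           estimators = default_estimators(),
                           metric = c("jaccard", "auc")) {
  stopifnot(inherits(ts, "training_set"), inherits(scheme, "partition_scheme"),
            length(estimators) >= 1L)
  metric <- match.arg(metric)
  labels <- ts$records$label
  folds <- sort(unique(scheme$fold))
  calib_idx <- which(ts$calibration_mask)
  dims <- dim(ts$calibration_mask)
  calib_cells <- cbind(
    row = as.integer((calib_idx - 1L) %% dims[1] + 1L),
    col = as.integer((calib_idx - 1L) %/% dims[1] + 1L)
  )
  calib_feats <- score_features(scores, calib_cells)
  out <- list()
  for (est in estimators) {
    res <- tryCatch({
      fm <- purrr::map(folds, function(f) {
        test <- scheme$fold == f
        train <- !test
        if (!any(labels[test] == 1L) || !any(labels[test] == 0L) ||
            !any(labels[train] == 1L) || !any(labels[train] == 0L)) {
          warn(paste0("Fold ", f, " lacks a class for ", est$id,
                      "; fold skipped."))
          return(NULL)
        }
        model <- est$fit(ts$features[train, , drop = FALSE], labels[train])
        sc <- est$predict(model, ts$features[test, , drop = FALSE])
        mutate(evaluate_predictions(sc, labels[test]), fold = f,
               .before = 1L)
      })
      fm <- bind_rows(fm[!vapply(fm, is.null, logical(1))])
      if (!nrow(fm)) abort("No evaluable fold.")
      full <- est$fit(ts$features, labels)
      raw <- est$predict(full, calib_feats)
      lo <- min(raw)
      hi <- max(raw)
      suit <- matrix(NA_real_, dims[1], dims[2])
      suit[calib_idx] <- if (hi > lo) (raw - lo) / (hi - lo) else 0.5
      structure(
        list(
          algorithm_id = est$id,
          fold_metrics = fm,
          mean_metric = mean(fm[[if (metric == "jaccard") "jaccard_max" else "auc"]]),
          metric = metric,
          suitability = suit,
          model = full,
          estimator = est,
          scale = c(lo = lo, hi = hi),
          calibration_mask = ts$calibration_mask
        ),
        class = "estimator_result"
      )
    }, error = function(e) {
      warn(paste0("Estimator ", est$id, " failed and was excluded: ",
                  conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) abort("Every estimator failed; no models fitted.")
  out
}

#' @export
print.estimator_result <- function(x, ...) {
  cat("<estimator_result> ", x$algorithm_id, ": mean ", x$metric, " ",
      round(x$mean_metric, 3), " over ", nrow(x$fold_metrics), " fold(s)\n",
      sep = "")
  invisible(x)
}

#' Average above-average algorithms into an ensemble
#'
#' Ensemble forecasting by consensus: algorithms whose mean evaluation
#' metric is at or above the mean of all algorithms' metrics are retained,
#' and the ensemble suitability is the plain cell-wise average of their
#' rescaled maps. Under the at-or-above rule the retained set is never
#' empty (when all algorithms tie, all are retained).
#'
#' @param results list of `estimator_result` from [fit_estimators()].
#' @param taxon_id,scenario_id labels carried on the output.
#' @return An `ensemble_result`: retained algorithm ids, the averaged
#'   suitability matrix and the member results (kept so the ensemble can be
#'   projected onto other scenarios with [predict.ensemble_result()]).
#' @export
ensemble <- function(results, taxon_id = NA_character_,
                     scenario_id = "present") {
  stopifnot(length(results) >= 1L)
  mm <- map_dbl(results, "mean_metric")
  retained <- mm >= mean(mm) - 1e-12
  maps <- purrr::map(results[retained], "suitability")
  suit <- Reduce(`+`, maps) / length(maps)
  structure(
    list(
      taxon_id = taxon_id,
      scenario_id = scenario_id,
      retained_algorithms = map_chr(results[retained], "algorithm_id"),
      suitability = suit,
      members = results
    ),
    class = "ensemble_result"
  )
}

#' Project a fitted ensemble onto another scenario
#'
#' Each retained member predicts raw scores over the calibration region
#' from the new scenario's axis scores; scores are rescaled with the
#' member's present-fit min-max constants (clamped to `[0, 1]`, mirroring
#' the coefficient-reuse rule of the axis model) and averaged.
#'
#' @param object an `ensemble_result`.
#' @param scores a `score_stack` for the target scenario.
#' @param ... unused.
#' @return An `ensemble_result` for the new scenario.
#' @export
predict.ensemble_result <- function(object, scores, ...) {
  stopifnot(inherits(scores, "score_stack"))
  keep <- map_chr(object$members, "algorithm_id") %in%
    object$retained_algorithms
  members <- object$members[keep]
  calib <- members[[1]]$calibration_mask
  dims <- dim(calib)
  calib_idx <- which(calib)
  calib_cells <- cbind(
    row = as.integer((calib_idx - 1L) %% dims[1] + 1L),
    col = as.integer((calib_idx - 1L) %/% dims[1] + 1L)
  )
  feats <- score_features(scores, calib_cells)
  maps <- purrr::map(members, function(m) {
    raw <- m$estimator$predict(m$model, feats)
    sc <- if (m$scale["hi"] > m$scale["lo"]) {
      (raw - m$scale["lo"]) / (m$scale["hi"] - m$scale["lo"])
    } else {
      rep(0.5, length(raw))
    }
    suit <- matrix(NA_real_, dims[1], dims[2])
    suit[calib_idx] <- pmin(1, pmax(0, sc))
    suit
  })
  structure(
    list(
      taxon_id = object$taxon_id,
      scenario_id = scores$scenario_id,
      retained_algorithms = object$retained_algorithms,
      suitability = Reduce(`+`, maps) / length(maps),
      members = object$members
    ),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$taxon_id, " / ", x$scenario_id, ": ",
      length(x$retained_algorithms), " retained algorithm(s) [",
      paste(x$retained_algorithms, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Tidy an ensemble
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return `tidy()`: one row per member algorithm and fold with both
#'   metrics, the algorithm's mean metric and whether it was retained;
#'   `glance()`: a one-row ensemble summary.
#' @method tidy ensemble_result
#' @export
tidy.ensemble_result <- function(x, ...) {
  bind_rows(purrr::map(x$members, function(m) {
    mutate(m$fold_metrics,
           algorithm = m$algorithm_id,
           mean_metric = m$mean_metric,
           retained = m$algorithm_id %in% x$retained_algorithms,
           .before = 1L)
  })) |>
    mutate(taxon_id = x$taxon_id, .before = 1L)
}

#' @rdname tidy.ensemble_result
#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble(
    taxon_id = x$taxon_id,
    scenario_id = x$scenario_id,
    n_algorithms = length(x$members),
    n_retained = length(x$retained_algorithms),
    mean_metric_retained = mean(map_dbl(
      x$members[map_chr(x$members, "algorithm_id") %in% x$retained_algorithms],
      "mean_metric"
    ))
  )
}
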