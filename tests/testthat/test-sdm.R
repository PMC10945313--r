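make_training_fixture <- function(seed = 1, n_occ = 40, dims = c(40, 40)) {
  land <- generate_landscape(seed = seed, grid_shape = dims, n_vars = 4,
                             autocorr_scale = 4)
  sp <- make_species(land, seed = seed, range_cut = 0.35)
  occ <- sample_occurrences(sp, min(n_occ, sum(sp$true_range)), seed = seed)
  model <- fit_axes(land)
  scores <- project_scores(land, model)
  list(land = land, sp = sp, occ = occ, scores = scores)
}

test_that("pseudo-absences are disjoint, counted and reproducible", {
  fx <- make_training_fixture(seed = 2, n_occ = 10)
  ts <- build_training_set(fx$occ, fx$scores,
                           calibration_mask = fx$sp$endemism_region,
                           pa_ratio = 1, seed = 5)
  expect_equal(sum(ts$records$label == 0L), 10)
  pres <- dplyr::filter(ts$records, label == 1L)
  absc <- dplyr::filter(ts$records, label == 0L)
  expect_equal(nrow(dplyr::inner_join(pres[1:2], absc[1:2],
                                      by = c("row", "col"))), 0)
  # absences stay inside the calibration region
  expect_true(all(fx$sp$endemism_region[cbind(absc$row, absc$col)]))
  # same seed reproduces the draw; pa_ratio scales the count
  ts2 <- build_training_set(fx$occ, fx$scores, fx$sp$endemism_region,
                            pa_ratio = 1, seed = 5)
  expect_identical(ts$records, ts2$records)
  ts3 <- build_training_set(fx$occ, fx$scores, fx$sp$endemism_region,
                            pa_ratio = 2, seed = 5)
  expect_equal(sum(ts3$records$label == 0L), 20)
  # degenerate calibration area (presences only) rejected with counts
  tiny_mask <- matrix(FALSE, 40, 40)
  tiny_mask[cbind(fx$occ$row, fx$occ$col)] <- TRUE
  expect_error(build_training_set(fx$occ, fx$scores, tiny_mask), "candidate")
})

test_that("partition method follows the 15-occurrence rule", {
  fx15 <- make_training_fixture(seed = 3, n_occ = 15)
  ts15 <- build_training_set(fx15$occ, fx15$scores,
                             fx15$sp$endemism_region, seed = 1)
  sch15 <- partition(ts15, seed = 1)
  expect_equal(sch15$method, "checkerboard")
  expect_equal(sch15$n_folds, 2L)
  # checkerboard fold is the block-parity of the (zero-based) coordinates
  b <- sch15$block_size
  expected <- ((((ts15$records$row - 1) %/% b) +
                ((ts15$records$col - 1) %/% b)) %% 2)
  expect_equal(sch15$fold, as.integer(expected))
  # both folds carry presences
  expect_true(all(table(sch15$fold[ts15$records$label == 1L]) > 0))

  fx8 <- make_training_fixture(seed = 4, n_occ = 8)
  ts8 <- build_training_set(fx8$occ, fx8$scores, fx8$sp$endemism_region,
                            seed = 1)
  sch8 <- partition(ts8, seed = 1)
  expect_equal(sch8$method, "kfold")
  expect_equal(sch8$k, 5L)
  # every record gets exactly one fold; balanced within one record
  expect_length(sch8$fold, nrow(ts8$records))
  expect_true(all(sch8$fold %in% 0:4))
  counts <- table(sch8$fold[ts8$records$label == 1L])
  expect_lte(max(counts) - min(counts), 1)
  # k capped by occurrence count
  fx3 <- make_training_fixture(seed = 5, n_occ = 3)
  ts3 <- build_training_set(fx3$occ, fx3$scores, fx3$sp$endemism_region,
                            seed = 1)
  expect_equal(partition(ts3, seed = 1)$k, 3L)
  expect_error(partition(ts3, n_unique = 2), "at least 3")
})

test_that("rank-based AUC equals brute-force pairwise concordance", {
  expect_equal(auc(c(0.9, 0.8), c(0.3, 0.4)), 1)
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(auc(c(0.7, 0.2), c(0.5, 0.1)), 0.75)
  expect_error(auc(numeric(0), 1), "at least one")
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(1:50, 1)
    n2 <- sample(1:50, 1)
    # coarse grid of values forces plenty of ties
    pos <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), n2, replace = TRUE)
    expect_equal(auc(pos, neg), bf_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("jaccard follows the TP/(TP+FP+FN) definition", {
  expect_equal(jaccard(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  # TP = 3, FP = 1, FN = 0
  expect_equal(jaccard(c(TRUE, TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE, FALSE)),
               0.75)
  expect_equal(jaccard(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(jaccard(logical(2), logical(2)), 1)
})

test_that("held-out evaluation maximizes Jaccard over score thresholds", {
  # perfect separation: both metrics 1
  ev <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(ev$auc, 1)
  expect_equal(ev$jaccard_max, 1)
  # constant scores: single candidate threshold predicts everything present
  ev2 <- evaluate_predictions(rep(0.4, 5), c(1, 1, 1, 0, 0))
  expect_equal(ev2$jaccard_max, 3 / 5)
  # equals brute force over all thresholds in [0, 1] on random instances
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    sc <- round(runif(n), sample(c(1, 2, 3), 1))
    lab <- rbinom(n, 1, 0.4)
    if (!any(lab == 1) || !any(lab == 0)) next
    expect_equal(evaluate_predictions(sc, lab)$jaccard_max,
                 bf_best_jaccard(sc, lab), tolerance = 1e-12)
  }
  expect_error(evaluate_predictions(c(1, 0), c(1, 1)), "presence and")
})

test_that("both shipped estimators separate linearly separable data", {
  X <- rbind(matrix(rnorm(40, mean = 2, sd = 0.3), ncol = 2),
             matrix(rnorm(40, mean = -2, sd = 0.3), ncol = 2))
  colnames(X) <- c("PC1", "PC2")
  y <- rep(c(1L, 0L), each = 20)
  for (est in default_estimators()) {
    fitm <- est$fit(X, y)
    sc <- est$predict(fitm, X)
    expect_equal(auc(sc[y == 1], sc[y == 0]), 1)
  }
})

test_that("fit_estimators cross-validates and maps suitability in [0, 1]", {
  # strong-signal fixture: a narrow, range-restricted niche (the range
  # covers ~14% of the calibration region), 100 occurrences, 50 x 50 grid
  land <- generate_landscape(seed = 6, grid_shape = c(50, 50), n_vars = 4,
                             autocorr_scale = 5)
  np <- tibble::tibble(var = names(land$layers)[1:2],
                       optimum = c(0.8, -0.8), breadth = 0.5)
  sp <- generate_virtual_species(land, np, range_cut = 0.4,
                                 taxon_id = "sp6", endemism_margin = 10)
  occ <- sample_occurrences(sp, min(100, sum(sp$true_range)), seed = 6)
  fx <- list(land = land, sp = sp, occ = occ,
             scores = project_scores(land, fit_axes(land)))
  ts <- build_training_set(fx$occ, fx$scores, fx$sp$endemism_region,
                           seed = 2)
  sch <- partition(ts, seed = 2)
  res <- fit_estimators(ts, sch, fx$scores)
  expect_length(res, 2)
  for (r in res) {
    expect_true(all(r$fold_metrics$auc >= 0 & r$fold_metrics$auc <= 1))
    expect_true(all(r$fold_metrics$jaccard_max >= 0 &
                    r$fold_metrics$jaccard_max <= 1))
    suit <- r$suitability[ts$calibration_mask]
    expect_false(anyNA(suit))
    expect_gte(min(suit), 0)
    expect_lte(max(suit), 1)
    # outside the calibration region the map is undefined
    expect_true(all(is.na(r$suitability[!ts$calibration_mask])))
  }
  # strong synthetic signal: at least one estimator performs well
  expect_gte(max(purrr::map_dbl(res, "mean_metric")), 0.7)
})

test_that("ensembling keeps algorithms at or above the mean metric", {
  fake <- function(id, mm, fill) {
    structure(list(algorithm_id = id, mean_metric = mm,
                   fold_metrics = tibble::tibble(fold = 0L, auc = mm,
                                                 jaccard_max = mm),
                   suitability = matrix(fill, 2, 2)),
              class = "estimator_result")
  }
  res <- list(fake("a", 0.9, 0.8), fake("b", 0.7, 0.4), fake("c", 0.5, 0.2))
  ens <- ensemble(res, taxon_id = "t", scenario_id = "present")
  # mean is 0.7; the >= rule keeps 0.9 and 0.7
  expect_setequal(ens$retained_algorithms, c("a", "b"))
  expect_equal(ens$suitability, matrix(0.6, 2, 2))
  # all tied: everything retained, plain mean
  res_tied <- list(fake("a", 0.5, 0.2), fake("b", 0.5, 0.6))
  ens_tied <- ensemble(res_tied)
  expect_setequal(ens_tied$retained_algorithms, c("a", "b"))
  expect_equal(ens_tied$suitability, matrix(0.4, 2, 2))
  # single algorithm: the ensemble is that map
  ens1 <- ensemble(res[1])
  expect_equal(ens1$suitability, res[[1]]$suitability)
  # ensemble bounded by member maps cell-wise
  fx <- make_training_fixture(seed = 7, n_occ = 30)
  ts <- build_training_set(fx$occ, fx$scores, fx$sp$endemism_region,
                           seed = 3)
  sch <- partition(ts, seed = 3)
  fitted <- fit_estimators(ts, sch, fx$scores)
  ens2 <- ensemble(fitted, "t", "present")
  kept <- fitted[purrr::map_chr(fitted, "algorithm_id") %in%
                   ens2$retained_algorithms]
  lo <- Reduce(pmin, purrr::map(kept, "suitability"))
  hi <- Reduce(pmax, purrr::map(kept, "suitability"))
  ok <- ts$calibration_mask
  expect_true(all(ens2$suitability[ok] >= lo[ok] - 1e-12))
  expect_true(all(ens2$suitability[ok] <= hi[ok] + 1e-12))
})

test_that("ensembles project onto future scenarios with present scaling", {
  fx <- make_training_fixture(seed = 8, n_occ = 50)
  ts <- build_training_set(fx$occ, fx$scores, fx$sp$endemism_region,
                           seed = 4)
  sch <- partition(ts, seed = 4)
  ens <- ensemble(fit_estimators(ts, sch, fx$scores), "t", "present")
  model <- fit_axes(fx$land)
  fut <- generate_future(fx$land, shift = 0, noise_sd = 0, seed = 1,
                         scenario_id = "future-null")
  pf <- predict(ens, project_scores(fut, model))
  expect_equal(pf$scenario_id, "future-null")
  ok <- ts$calibration_mask
  expect_true(all(pf$suitability[ok] >= 0 & pf$suitability[ok] <= 1))
  # a no-change future reproduces the present ensemble map
  pres_sc <- project_scores(fx$land, model)
  pp <- predict(ens, pres_sc)
  expect_equal(pp$suitability[ok], ens$suitability[ok], tolerance = 1e-8)
})
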