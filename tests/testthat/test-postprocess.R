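test_that("threshold selection equals the exhaustive-search oracle", {
  # presences at 0.8 / 0.6, absence at 0.3: cut at 0.6 gives Jaccard 1
  suit <- matrix(c(0.8, 0.6, 0.3, 0.1), 2, 2)
  thr <- select_threshold(suit, rbind(c(1, 1), c(2, 1)), rbind(c(1, 2)))
  expect_equal(thr, 0.6)
  # perfectly inverted scores: the all-positive prediction wins, so the
  # minimum candidate is selected
  suit2 <- matrix(c(0.1, 0.2, 0.8, 0.9), 2, 2)
  thr2 <- select_threshold(suit2, rbind(c(1, 1), c(2, 1)),
                           rbind(c(1, 2), c(2, 2)))
  expect_equal(thr2, 0.1)
  # constant suitability returns the constant with a warning
  expect_warning(
    thr3 <- select_threshold(matrix(0.5, 2, 2), rbind(c(1, 1)),
                             rbind(c(2, 2))),
    "constant"
  )
  expect_equal(thr3, 0.5)
  # oracle equivalence on 100 random instances
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    sc <- round(runif(n), sample(1:3, 1))
    lab <- rbinom(n, 1, 0.5)
    if (!any(lab == 1) || !any(lab == 0)) next
    suit <- matrix(sc, nrow = 1)
    pres <- cbind(1L, which(lab == 1L))
    absc <- cbind(1L, which(lab == 0L))
    thr <- suppressWarnings(select_threshold(suit, pres, absc))
    achieved <- jaccard(sc >= thr, lab == 1L)
    expect_equal(achieved, bf_best_jaccard(sc, lab), tolerance = 1e-12)
  }
})

test_that("binarization is monotone and computes areas", {
  suit <- matrix(runif(100), 10, 10)
  all_in <- binarize(suit, 0, cell_area = 25)
  expect_true(all(all_in$cells))
  none <- binarize(suit, 1, cell_area = 25)
  expect_equal(none$area_km2, ifelse(any(suit == 1), 25 * sum(suit == 1), 0))
  # cells at the threshold count as suitable
  suit2 <- matrix(c(0.4, 0.5, 0.6, 0.2), 2, 2)
  b <- binarize(suit2, 0.5)
  expect_identical(as.vector(b$cells), c(FALSE, TRUE, TRUE, FALSE))
  # area arithmetic: 37 cells at 25 km2
  suit3 <- matrix(0, 10, 10)
  suit3[1:37] <- 1
  expect_equal(binarize(suit3, 0.5, cell_area = 25)$area_km2, 925)
  # monotone in threshold
  set.seed(3)
  suit4 <- matrix(runif(400), 20, 20)
  cuts <- sort(runif(5))
  for (i in seq_len(length(cuts) - 1)) {
    lo <- binarize(suit4, cuts[i])
    hi <- binarize(suit4, cuts[i + 1])
    expect_true(all(hi$cells <= lo$cells))
  }
  expect_error(binarize(suit4, 1.2), "0, 1")
})

test_that("forest masking and floodplain restriction shrink ranges", {
  suit <- matrix(runif(400), 20, 20)
  rng <- binarize(suit, 0.5, taxon_id = "t", scenario_id = "present")
  all_forest <- generate_landcover(c(20, 20), forest_fraction = 1, seed = 1)
  expect_equal(apply_forest_mask(rng, all_forest)$cells, rng$cells)
  no_forest <- generate_landcover(c(20, 20), forest_fraction = 0, seed = 1)
  expect_equal(sum(apply_forest_mask(rng, no_forest)$cells), 0)
  some <- generate_landcover(c(20, 20), forest_fraction = 0.5, seed = 2)
  masked <- apply_forest_mask(rng, some)
  expect_lte(masked$area_km2, rng$area_km2)
  expect_true(all(!masked$cells | rng$cells))
  mismatched <- generate_landcover(c(10, 10), forest_fraction = 0.5, seed = 2)
  expect_error(apply_forest_mask(rng, mismatched), "dimensions")

  fut <- binarize(suit, 0.3, taxon_id = "t", scenario_id = "future")
  restr <- restrict_future_to_present(fut, rng)
  expect_true(all(!restr$cells | fut$cells))
  expect_true(all(!restr$cells | rng$cells))
  # future within present stays unchanged; disjoint futures empty out
  sub <- binarize(suit, 0.7, taxon_id = "t", scenario_id = "future")
  expect_equal(restrict_future_to_present(sub, rng)$cells, sub$cells)
  inv <- binarize(-suit + 1, 0.51, taxon_id = "t", scenario_id = "future")
  joint <- restrict_future_to_present(inv, binarize(suit, 0.5))
  expect_equal(sum(joint$cells), sum(inv$cells & suit >= 0.5))
})

test_that("area change is the percent difference of stored areas", {
  mk <- function(n_cells, scen) {
    suit <- matrix(0, 10, 10)
    if (n_cells > 0) suit[seq_len(n_cells)] <- 1
    binarize(suit, 0.5, cell_area = 25, taxon_id = "t", scenario_id = scen)
  }
  expect_equal(area_change(mk(4, "p"), mk(4, "f")), 0)
  # 100 km2 -> 25 km2 is a 75% loss
  expect_equal(area_change(mk(4, "p"), mk(1, "f")), -75)
  expect_equal(area_change(mk(4, "p"), mk(0, "f")), -100)
  expect_equal(area_change(mk(2, "p"), mk(3, "f")), 50)
  expect_error(area_change(mk(0, "p"), mk(1, "f")), "undefined")
  # recoverable from the stored areas alone
  p <- mk(7, "p")
  f <- mk(3, "f")
  expect_equal(area_change(p, f),
               100 * (f$area_km2 - p$area_km2) / p$area_km2)
})

test_that("richness stacking counts overlaps and is order-invariant", {
  one_cell <- function(r, c, id) {
    suit <- matrix(0, 5, 5)
    suit[r, c] <- 1
    binarize(suit, 0.5, taxon_id = id, scenario_id = "s")
  }
  a <- one_cell(2, 2, "a")
  b <- one_cell(2, 2, "b")
  rm2 <- stack_richness(list(a, b))
  expect_equal(rm2$richness[2, 2], 2L)
  expect_equal(sum(rm2$richness), 2L)
  # empty list gives the all-zero map
  rm0 <- stack_richness(list(), dims = c(5, 5), scenario_id = "s")
  expect_true(all(rm0$richness == 0L))
  # double-counting identity over random stacks
  set.seed(9)
  ranges <- lapply(1:6, function(i) {
    binarize(matrix(runif(100), 10, 10), runif(1), taxon_id = paste0("t", i),
             scenario_id = "s")
  })
  rm <- stack_richness(ranges)
  expect_equal(sum(rm$richness), sum(purrr::map_int(ranges,
                                                    ~ sum(.x$cells))))
  # permutation of the taxa changes nothing
  rm_perm <- stack_richness(ranges[c(4, 2, 6, 1, 5, 3)])
  expect_equal(rm_perm$richness, rm$richness)
  # mixed scenarios rejected
  other <- binarize(matrix(runif(100), 10, 10), 0.5, taxon_id = "x",
                    scenario_id = "other")
  expect_error(stack_richness(c(ranges, list(other))), "mix")
})
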