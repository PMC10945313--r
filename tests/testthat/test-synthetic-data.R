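test_that("landscape layers are standardized, deterministic and autocorrelated", {
  land <- generate_landscape(seed = 1, grid_shape = c(50, 50), n_vars = 6,
                             autocorr_scale = 5)
  expect_length(land$layers, 6)
  for (m in land$layers) {
    v <- m[land$valid_mask]
    expect_lt(abs(mean(v)), 1e-6)
    expect_equal(sd(v), 1, tolerance = 1e-8)
  }
  # bit-identical rerun
  land2 <- generate_landscape(seed = 1, grid_shape = c(50, 50), n_vars = 6,
                              autocorr_scale = 5)
  expect_identical(land$layers, land2$layers)
  # different seed differs
  land3 <- generate_landscape(seed = 2, grid_shape = c(50, 50), n_vars = 6,
                              autocorr_scale = 5)
  expect_false(identical(land$layers[[1]], land3$layers[[1]]))
  # longer smoothing scale -> strictly larger lag-1 autocorrelation
  rough <- generate_landscape(seed = 1, grid_shape = c(50, 50), n_vars = 2,
                              autocorr_scale = 1)
  smooth <- generate_landscape(seed = 1, grid_shape = c(50, 50), n_vars = 2,
                               autocorr_scale = 10)
  expect_gt(lag1_autocorrelation(smooth$layers[[1]]),
            lag1_autocorrelation(rough$layers[[1]]))
  # invalid arguments rejected
  expect_error(generate_landscape(1, c(0, 10)), "positive")
  expect_error(generate_landscape(1, c(10, 10), n_vars = 1), "at least 2")
  expect_error(generate_landscape(1, c(10, 10), autocorr_scale = 0),
               "positive")
})

test_that("future scenarios shift the present deterministically", {
  land <- make_landscape(seed = 3, dims = c(20, 20), n_vars = 3)
  # zero shift, zero noise: identical values
  fut0 <- generate_future(land, shift = 0, noise_sd = 0, seed = 1)
  expect_equal(fut0$layers, land$layers)
  # +2 on one layer only
  fut2 <- generate_future(land, shift = c(2, 0, 0), noise_sd = 0, seed = 1)
  expect_equal(fut2$layers[[1]] - land$layers[[1]],
               matrix(2, 20, 20))
  expect_equal(fut2$layers[[2]], land$layers[[2]])
  # reproducible under noise
  futa <- generate_future(land, shift = 1, noise_sd = 0.5, seed = 9)
  futb <- generate_future(land, shift = 1, noise_sd = 0.5, seed = 9)
  expect_identical(futa$layers, futb$layers)
  expect_false(identical(futa$layers[[1]], fut0$layers[[1]]))
  # shape mismatch in shift rejected
  expect_error(generate_future(land, shift = c(1, 2)), "one entry per layer")
})

test_that("virtual species follow the Gaussian-response contract", {
  land <- make_landscape(seed = 5)
  sp <- make_species(land, range_cut = 0.4)
  # rescaled to max 1; the best cell's climate attains the optimum closest
  expect_equal(max(sp$true_suitability, na.rm = TRUE), 1)
  # optimum placed at an actual cell's climate gives that cell suitability 1
  cell <- c(7, 11)
  np <- tibble::tibble(
    var = names(land$layers)[1:2],
    optimum = c(land$layers[[1]][cell[1], cell[2]],
                land$layers[[2]][cell[1], cell[2]]),
    breadth = 1
  )
  sp2 <- generate_virtual_species(land, np, range_cut = 0.2)
  expect_equal(sp2$true_suitability[cell[1], cell[2]], 1)
  # range_cut = 0 covers every valid cell
  sp0 <- generate_virtual_species(land, np, range_cut = 0)
  expect_identical(sp0$true_range, land$valid_mask)
  # narrower breadth never grows the range
  wide <- make_species(land, range_cut = 0.4, breadth = c(1.5, 1.5))
  narrow <- make_species(land, range_cut = 0.4, breadth = c(0.6, 0.6))
  expect_lte(sum(narrow$true_range), sum(wide$true_range))
  # monotone in range_cut
  lo <- make_species(land, range_cut = 0.2)
  hi <- make_species(land, range_cut = 0.6)
  expect_true(all(hi$true_range <= lo$true_range))
  # containment chain: range within endemism region within valid mask
  expect_true(all(!sp$true_range | sp$endemism_region))
  expect_true(all(!sp$endemism_region | land$valid_mask))
  # unknown niche variable rejected; empty range warns
  expect_error(
    generate_virtual_species(land, tibble::tibble(var = "nope", optimum = 0,
                                                  breadth = 1)),
    "unknown layers"
  )
  expect_warning(
    generate_virtual_species(land, tibble::tibble(var = "var1", optimum = 99,
                                                  breadth = 0.1),
                             range_cut = 0.99),
    "empty true range"
  )
})

test_that("occurrence sampling draws unique in-range cells", {
  land <- make_landscape(seed = 6)
  sp <- make_species(land, range_cut = 0.5)
  n_range <- sum(sp$true_range)
  occ <- sample_occurrences(sp, 8, seed = 1)
  expect_equal(nrow(occ), 8)
  expect_equal(nrow(dplyr::distinct(occ, row, col)), 8)
  expect_true(all(sp$true_range[cbind(occ$row, occ$col)]))
  # two seeds: different draws, both contained in the true range
  occ2 <- sample_occurrences(sp, 8, seed = 2)
  expect_true(all(sp$true_range[cbind(occ2$row, occ2$col)]))
  # n equal to the range size returns the range exactly
  occ_all <- sample_occurrences(sp, n_range, seed = 3)
  expect_equal(nrow(occ_all), n_range)
  got <- sort(occ_all$row * 1000 + occ_all$col)
  idx <- which(sp$true_range, arr.ind = TRUE)
  expect_equal(got, sort(idx[, 1] * 1000 + idx[, 2]))
  # oversampling rejected
  expect_error(sample_occurrences(sp, n_range + 1, seed = 1), "only")
})

test_that("protected-area generation respects counts, sizes and categories", {
  pas <- generate_protected_areas(c(40, 40), n_areas = 347,
                                  size_range = c(1, 12), seed = 4)
  expect_equal(nrow(pas), 347)
  expect_true(all(pas$category %in% c("SPA", "SUA", "IT")))
  sizes <- purrr::map_int(pas$footprint, nrow)
  expect_true(all(sizes >= 1 & sizes <= 12))
  for (fp in pas$footprint[1:20]) {
    expect_true(all(fp[, "row"] >= 1 & fp[, "row"] <= 40))
    expect_true(all(fp[, "col"] >= 1 & fp[, "col"] <= 40))
    expect_equal(nrow(unique(fp)), nrow(fp))
  }
  # unit-size range gives single-cell footprints
  singles <- generate_protected_areas(c(20, 20), n_areas = 10,
                                      size_range = c(1, 1), seed = 1)
  expect_true(all(purrr::map_int(singles$footprint, nrow) == 1L))
  # reproducible placement
  pas2 <- generate_protected_areas(c(40, 40), n_areas = 347,
                                   size_range = c(1, 12), seed = 4)
  expect_identical(pas$footprint, pas2$footprint)
})

test_that("land-cover grids hit the forest fraction and are clumped", {
  lc <- generate_landcover(c(100, 100), forest_fraction = 0.5,
                           autocorr_scale = 5, seed = 2)
  share <- mean(lc$category %in% lc$forest_codes)
  expect_gte(share, 0.45)
  expect_lte(share, 0.55)
  # clumped: forest indicator has positive lag-1 autocorrelation
  forest <- matrix(as.numeric(lc$category %in% lc$forest_codes), 100, 100)
  expect_gt(lag1_autocorrelation(forest), 0.3)
  # extremes
  all_f <- generate_landcover(c(20, 20), forest_fraction = 1, seed = 1)
  expect_true(all(all_f$category %in% all_f$forest_codes))
  no_f <- generate_landcover(c(20, 20), forest_fraction = 0, seed = 1)
  expect_false(any(no_f$category %in% no_f$forest_codes))
  expect_error(generate_landcover(c(20, 20), forest_fraction = 1.2), "0, 1")
})
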