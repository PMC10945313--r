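#' Fit the full distribution-model workflow for one taxon
#'
#' Convenience wrapper chaining the per-taxon stages: training-set
#' assembly, partitioning, estimator fitting and cross-validation,
#' ensembling, and selection of the Jaccard-maximizing binarization
#' threshold on the present-scenario training records. The threshold is
#' selected once per taxon and reused for that taxon's future
#' binarizations so present and future ranges stay comparable.
#'
#' @param occ tibble of unique presence cells (`taxon_id`, `row`, `col`).
#' @param scores present-scenario `score_stack`.
#' @param calibration_mask logical calibration-region matrix.
#' @param pa_ratio pseudo-absences per presence.
#' @param seed integer seed.
#' @param k maximum k for k-fold partitioning.
#' @param estimators estimator registry (default both shipped ones).
#' @param metric ranking metric, `"jaccard"` or `"auc"`.
#' @return An `sdm_fit`: the present `ensemble_result`, the selected
#'   `threshold`, the `training_set` and `partition_scheme`.
#' @export
fit_sdm <- function(occ, scores, calibration_mask = NULL, pa_ratio = 1,
                    seed = 1, k = 5, estimators = default_estimators(),
                    metric = "jaccard") {
  ts <- build_training_set(occ, scores, calibration_mask, pa_ratio, seed)
  scheme <- partition(ts, n_unique = sum(ts$records$label == 1L),
                      seed = derive_seed(seed, 2), k = k)
  results <- fit_estimators(ts, scheme, scores, estimators, metric)
  taxon <- ts$taxon_id %||% NA_character_
  ens <- ensemble(results, taxon_id = taxon,
                  scenario_id = scores$scenario_id)
  pres <- filter(ts$records, .data$label == 1L)
  absc <- filter(ts$records, .data$label == 0L)
  thr <- select_threshold(ens$suitability, pres, absc)
  structure(
    list(ensemble = ens, threshold = thr, training_set = ts,
         scheme = scheme),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat("<sdm_fit> ", x$ensemble$taxon_id, ": threshold ",
      signif(x$threshold, 4), ", ", x$scheme$method, " validation\n",
      sep = "")
  print(x$ensemble)
  invisible(x)
}

#' Binary range of a fitted taxon under any scenario
#'
#' Projects the fitted ensemble onto the scenario's axis scores and
#' binarizes at the taxon's present-fit threshold.
#'
#' @param fit an `sdm_fit`.
#' @param scores a `score_stack` (present or future).
#' @return A `binary_range`.
#' @export
project_range <- function(fit, scores) {
  ens <- if (identical(scores$scenario_id, fit$ensemble$scenario_id)) {
    fit$ensemble
  } else {
    predict(fit$ensemble, scores)
  }
  binarize(ens, fit$threshold, cell_area = scores$cell_area)
}

#' Bundled demonstration configuration
#'
#' The configuration driving [run_pipeline()]'s synthetic demonstration: a
#' 50 x 50 landscape of six climate variables, one optimistic (+1 sd mean
#' shift) and one pessimistic (+2 sd) future with spatially autocorrelated
#' anomalies, 12 virtual taxa with 8-120 unique occurrences, 60 protected
#' areas across the three categories, 70% forest cover, and 999
#' null-model randomizations. The first taxon is treated as
#' floodplain-restricted (future ranges limited to the present range).
#'
#' @param seed master seed.
#' @param output_dir output directory (default a tempdir subfolder).
#' @return A named configuration list.
#' @export
demo_config <- function(seed = 42,
                        output_dir = file.path(tempdir(), "rangegap-demo")) {
  list(
    seed = seed,
    output_dir = output_dir,
    grid = list(nrow = 50, ncol = 50, n_vars = 6, autocorr_scale = 6,
                cell_area = 25),
    scenarios = list(
      `future-optimistic` = list(shift = 1, noise_sd = 0.3),
      `future-pessimistic` = list(shift = 2, noise_sd = 0.3)
    ),
    variance_target = 0.95,
    taxa = list(n_taxa = 12, n_occ_min = 8, n_occ_max = 120,
                range_cut = 0.35, breadth_min = 0.75, breadth_max = 1.5,
                n_niche_vars = 3, endemism_margin = 6),
    landcover = list(forest_fraction = 0.7, autocorr_scale = 5),
    pa = list(n_areas = 60, size_min = 2, size_max = 30,
              category_weights = list(SPA = 1, SUA = 1.2, IT = 0.8)),
    sdm = list(pa_ratio = 1, k = 5, metric = "jaccard"),
    null_model = list(n_randomizations = 999),
    floodplain_taxa = "taxon01"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the end-to-end assessment pipeline
#'
#' Executes every stage in order — synthetic generation (or file input),
#' axis fitting and projection, per-taxon ensemble models, binarization
#' and land-cover masking, richness stacking, the protected-area null
#' model and the gap analysis — writing all tabular outputs as CSV,
#' gridded outputs as ASCII rasters, and a provenance file echoing the
#' configuration and seeds. Given the same configuration and seeds the
#' run is fully deterministic and its CSV outputs are byte-identical
#' across reruns. A failing stage aborts with the stage named; outputs
#' written by earlier stages are retained.
#'
#' @param config configuration list (see [demo_config()]) or the path of
#'   a YAML file holding one.
#' @param out_dir output directory; overrides `config$output_dir`.
#' @return Invisibly, a list with the output directory and the main result
#'   tables (`evaluation`, `area_change`, `effectiveness`,
#'   `effectiveness_summary`, `gap_results`, `gap_summary`), the richness
#'   maps and the per-taxon fits.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  g <- config$grid

  # --- climate ------------------------------------------------------------
  stacks <- run_stage("climate", {
    present <- generate_landscape(
      seed = derive_seed(seed, 1),
      grid_shape = c(g$nrow, g$ncol), n_vars = g$n_vars,
      autocorr_scale = g$autocorr_scale, cell_area = g$cell_area
    )
    futures <- purrr::imap(config$scenarios, function(sc, nm) {
      generate_future(present, shift = sc$shift, noise_sd = sc$noise_sd,
                      seed = seed_from_id(seed, nm),
                      autocorr_scale = g$autocorr_scale, scenario_id = nm)
    })
    c(list(present = present), futures)
  })
  inform(paste0("Climate: ", length(stacks), " scenarios on a ", g$nrow,
                "x", g$ncol, " grid."))

  # --- land cover and protected areas --------------------------------------
  lc <- run_stage("landcover", {
    generate_landcover(c(g$nrow, g$ncol),
                       forest_fraction = config$landcover$forest_fraction,
                       autocorr_scale = config$landcover$autocorr_scale,
                       seed = derive_seed(seed, 3),
                       cell_area = g$cell_area)
  })
  pas <- run_stage("protected_areas", {
    generate_protected_areas(
      c(g$nrow, g$ncol), n_areas = config$pa$n_areas,
      size_range = c(config$pa$size_min, config$pa$size_max),
      category_weights = unlist(config$pa$category_weights),
      seed = derive_seed(seed, 4)
    )
  })
  write_grid_asc(lc, file.path(out_dir, "landcover.asc"))
  write_pa_mask_csv(pas, file.path(out_dir, "protected_areas.csv"))
  write_pa_geojson(pas, file.path(out_dir, "protected_areas.geojson"),
                   dims = c(g$nrow, g$ncol),
                   cellsize = grid_cellsize(g$cell_area))

  # --- virtual taxa ---------------------------------------------------------
  tx <- config$taxa
  species <- run_stage("virtual_taxa", {
    purrr::map(seq_len(tx$n_taxa), function(i) {
      sp_seed <- derive_seed(seed, 100 + i)
      np <- with_seed(sp_seed, {
        vars <- sample(names(stacks$present$layers), tx$n_niche_vars)
        tibble(
          var = vars,
          optimum = runif(length(vars), -1.2, 1.2),
          breadth = runif(length(vars), tx$breadth_min, tx$breadth_max)
        )
      })
      generate_virtual_species(stacks$present, np,
                               range_cut = tx$range_cut,
                               taxon_id = sprintf("taxon%02d", i),
                               endemism_margin = tx$endemism_margin)
    })
  })
  occurrences <- run_stage("occurrences", {
    purrr::imap(species, function(sp, i) {
      n_range <- sum(sp$true_range)
      n <- with_seed(derive_seed(seed, 200 + i), {
        round(exp(runif(1, log(tx$n_occ_min), log(tx$n_occ_max))))
      })
      sample_occurrences(sp, min(n, n_range),
                         seed = derive_seed(seed, 300 + i))
    })
  })
  all_occ <- bind_rows(occurrences)
  write_occurrences(all_occ, file.path(out_dir, "occurrences.csv"),
                    dims = c(g$nrow, g$ncol),
                    cellsize = grid_cellsize(g$cell_area))

  # --- axes -----------------------------------------------------------------
  axes <- run_stage("axes", fit_axes(stacks$present, config$variance_target))
  write_axis_model(axes, file.path(out_dir, "axis_model.json"))
  score_stacks <- purrr::map(stacks, project_scores, model = axes)
  inform(paste0("Axes: kept ", axes$n_axes_kept, " of ",
                length(axes$var_names), " variables' components."))

  # --- per-taxon models ------------------------------------------------------
  sdm <- config$sdm
  fits <- run_stage("sdm", {
    purrr::imap(species, function(sp, i) {
      inform(paste0("SDM ", sp$taxon_id, ": ", nrow(occurrences[[i]]),
                    " occurrences."))
      fit_sdm(occurrences[[i]], score_stacks$present,
              calibration_mask = sp$endemism_region,
              pa_ratio = sdm$pa_ratio, seed = derive_seed(seed, 400 + i),
              k = sdm$k, metric = sdm$metric)
    })
  })
  names(fits) <- map_chr(species, "taxon_id")
  evaluation <- bind_rows(purrr::map(fits, function(f) tidy(f$ensemble)))
  readr::write_csv(evaluation, file.path(out_dir, "evaluation_report.csv"))

  # --- ranges ---------------------------------------------------------------
  ranges <- run_stage("ranges", {
    purrr::imap(fits, function(f, taxon) {
      rs <- purrr::map(score_stacks, function(sc) {
        r <- project_range(f, sc)
        apply_forest_mask(r, lc)
      })
      if (taxon %in% (config$floodplain_taxa %||% character(0))) {
        for (nm in setdiff(names(rs), "present")) {
          rs[[nm]] <- restrict_future_to_present(rs[[nm]], rs$present)
        }
      }
      rs
    })
  })
  area_tbl <- bind_rows(purrr::imap(ranges, function(rs, taxon) {
    bind_rows(purrr::map(
      rs[setdiff(names(rs), "present")],
      function(fr) {
        pc <- area_change(rs$present, fr)
        tibble(
          taxon_id = taxon, scenario_id = fr$scenario_id,
          present_km2 = rs$present$area_km2, future_km2 = fr$area_km2,
          pct_change = pc, lost_all = pc < -99
        )
      }
    ))
  }))
  readr::write_csv(area_tbl, file.path(out_dir, "area_change.csv"))

  # --- richness -------------------------------------------------------------
  richness <- run_stage("richness", {
    purrr::map(names(score_stacks), function(nm) {
      stack_richness(purrr::map(ranges, nm))
    }) |> stats::setNames(names(score_stacks))
  })
  for (nm in names(richness)) {
    write_grid_asc(richness[[nm]],
                   file.path(out_dir, paste0("richness_", nm, ".asc")))
  }

  # --- protected-area null model ---------------------------------------------
  effectiveness <- run_stage("pa_null_model", {
    bind_rows(purrr::map(richness, function(rm) {
      pa_effectiveness(pas, rm,
                       n_randomizations = config$null_model$n_randomizations,
                       seed = derive_seed(seed, 5),
                       study_mask = stacks$present$valid_mask)
    }))
  })
  eff_summary <- summarize_effectiveness(effectiveness)
  readr::write_csv(select(effectiveness, -"null_values"),
                   file.path(out_dir, "effectiveness.csv"))
  readr::write_csv(eff_summary,
                   file.path(out_dir, "effectiveness_summary.csv"))

  # --- gap analysis -----------------------------------------------------------
  gap_results <- run_stage("gap_analysis", {
    run_gap_scenarios(purrr::flatten(ranges), pas)
  })
  gap_tbl <- gap_summary(gap_results)
  readr::write_csv(gap_results, file.path(out_dir, "gap_results.csv"))
  readr::write_csv(gap_tbl, file.path(out_dir, "gap_summary.csv"))

  # --- provenance --------------------------------------------------------------
  prov <- list(
    package_version = as.character(utils::packageVersion("rangegap")),
    master_seed = seed,
    derived_seeds = list(
      climate = derive_seed(seed, 1), landcover = derive_seed(seed, 3),
      protected_areas = derive_seed(seed, 4), null_model = derive_seed(seed, 5)
    ),
    config = config[setdiff(names(config), "output_dir")]
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    dir = out_dir,
    evaluation = evaluation,
    area_change = area_tbl,
    effectiveness = effectiveness,
    effectiveness_summary = eff_summary,
    gap_results = gap_results,
    gap_summary = gap_tbl,
    richness = richness,
    fits = fits,
    pas = pas,
    species = species
  ))
}
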