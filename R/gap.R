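#' Area-scaled protection target
#'
#' The representation target of conservation gap analysis, after Rodrigues
#' et al. (2004): taxa with ranges below 1,000 km² should be fully (100%)
#' covered by protected areas, taxa above 250,000 km² need at least 10%
#' coverage, and targets in between are interpolated linearly on
#' log10(area):
#' `100 - 90 * (log10(a) - log10(1000)) / (log10(250000) - log10(1000))`.
#' The function is continuous and non-increasing and meets both anchors
#' exactly.
#'
#' @param area_km2 range area(s) in km², non-negative (vectorized).
#' @return Target percentage(s) in `[10, 100]`.
#' @examples
#' protection_target(c(500, 1000, 250000, 1e6)) # 100 100 10 10
#' @export
protection_target <- function(area_km2) {
  if (any(area_km2 < 0)) abort("area_km2 must be non-negative.")
  out <- 100 - 90 * (log10(area_km2) - 3) / (log10(250000) - 3)
  out[area_km2 <= 1000] <- 100
  out[area_km2 >= 250000] <- 10
  out
}

#' Percent of a range covered by protected areas
#'
#' `100 * |range AND pa_union| / |range|`; 0 for an empty range (taxa
#' lacking climatically suitable area count as having no representation).
#'
#' @param range a `binary_range`.
#' @param pa_union logical matrix — the cell-level union of the protected
#'   areas considered (see [pa_union_mask()]), same grid as the range.
#' @return Achieved representation percentage in `[0, 100]`.
#' @export
achieved_representation <- function(range, pa_union) {
  stopifnot(inherits(range, "binary_range"))
  if (!identical(dim(range), dim(pa_union))) {
    abort("Range and protected-area union have different dimensions.")
  }
  n_range <- sum(range$cells)
  if (n_range == 0) return(0)
  100 * sum(range$cells & pa_union) / n_range
}

#' Classify goal attainment into protection categories
#'
#' Categories follow the gap-analysis convention: a taxon is `Protected`
#' when it reaches at least 90% of its goal, `Partial gap` above 20% and
#' below 90%, `Gap` above 0% and up to 20%, and `Not protected` at 0% —
#' or whenever its range is empty (taxa lacking climate suitability in a
#' scenario are treated as unprotected regardless of nominal attainment).
#'
#' @param goal_attainment_pct attainment as a percentage of the target
#'   (vectorized, `>= 0`; values above 100 are allowed).
#' @param range_empty logical flag(s) for empty ranges.
#' @return Factor with levels `Protected`, `Partial gap`, `Gap`,
#'   `Not protected`.
#' @export
classify_protection <- function(goal_attainment_pct, range_empty = FALSE) {
  if (any(goal_attainment_pct < 0)) abort("Attainment must be >= 0.")
  n <- max(length(goal_attainment_pct), length(range_empty))
  g <- rep_len(goal_attainment_pct, n)
  e <- rep_len(range_empty, n)
  out <- ifelse(
    e | g == 0, "Not protected",
    ifelse(g >= 90, "Protected",
           ifelse(g > 20, "Partial gap", "Gap"))
  )
  factor(out, levels = c("Protected", "Partial gap", "Gap", "Not protected"))
}

#' Gap analysis across nested protected-area scenarios
#'
#' For every binary range (taxon x climate scenario) and each nested
#' protected-area scenario — strictly protected areas only (`SPA`), plus
#' sustainable use areas (`SPA+SUA`), plus indigenous territories
#' (`SPA+SUA+IT`) — computes the range area, its area-scaled target, the
#' achieved representation inside the scenario's cell-level PA union, the
#' goal attainment (`100 * achieved / target`) and the protection
#' category. Because the PA scenarios are nested, achieved representation
#' is monotonically non-decreasing along the nesting for every taxon.
#'
#' @param ranges list of `binary_range`s (any mix of taxa and climate
#'   scenarios).
#' @param pas a `pa_set`.
#' @param pa_scenarios named list mapping scenario label to the PA
#'   categories it includes; default the three nested scenarios.
#' @return A `gap_results` tibble: `taxon_id`, `climate_scenario`,
#'   `pa_scenario`, `range_area_km2`, `target_pct`, `achieved_pct`,
#'   `goal_attainment_pct`, `range_empty`, `category`.
#' @seealso [gap_summary()] for the category x scenario count table.
#' @export
run_gap_scenarios <- function(ranges, pas,
                              pa_scenarios = list(
                                "SPA" = "SPA",
                                "SPA+SUA" = c("SPA", "SUA"),
                                "SPA+SUA+IT" = c("SPA", "SUA", "IT")
                              )) {
  stopifnot(length(ranges) >= 1L, inherits(pas, "pa_set"))
  dims <- dim(ranges[[1]])
  unions <- purrr::map(pa_scenarios, function(cats) {
    pa_union_mask(pas, dims, categories = cats)
  })
  rows <- purrr::map(ranges, function(rg) {
    empty <- sum(rg$cells) == 0
    target <- protection_target(rg$area_km2)
    purrr::imap(unions, function(u, lab) {
      achieved <- achieved_representation(rg, u)
      attain <- if (empty) 0 else 100 * achieved / target
      tibble(
        taxon_id = rg$taxon_id,
        climate_scenario = rg$scenario_id,
        pa_scenario = lab,
        range_area_km2 = rg$area_km2,
        target_pct = target,
        achieved_pct = achieved,
        goal_attainment_pct = attain,
        range_empty = empty,
        category = classify_protection(attain, empty)
      )
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  out$pa_scenario <- factor(out$pa_scenario, levels = names(pa_scenarios))
  class(out) <- c("gap_results", class(out))
  out
}

#' Category-by-scenario count table for gap results
#'
#' Pivots gap results into the familiar summary shape: one row per
#' protection category (plus a `Total` row), one column per climate x PA
#' scenario, each column summing to the number of taxa.
#'
#' @param gap_results tibble from [run_gap_scenarios()].
#' @return A tibble of counts with `category` in the first column.
#' @export
gap_summary <- function(gap_results) {
  column <- paste(gap_results$climate_scenario, gap_results$pa_scenario,
                  sep = " / ")
  column <- factor(column, levels = unique(column))
  tab <- table(gap_results$category, column)
  counts <- tibble(category = rownames(tab))
  for (j in colnames(tab)) counts[[j]] <- as.integer(tab[, j])
  total <- counts[1, ]
  total$category <- "Total"
  for (j in setdiff(names(counts), "category")) {
    total[[j]] <- sum(counts[[j]])
  }
  bind_rows(counts, total)
}
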