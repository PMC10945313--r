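#' Mean richness inside a footprint
#'
#' @param footprint `(row, col)` cell matrix or tibble (non-empty).
#' @param richness a `richness_map`.
#' @return Arithmetic mean of richness over the footprint cells.
#' @export
mean_richness_in <- function(footprint, richness) {
  fp <- as_cell_matrix(footprint)
  if (!nrow(fp)) abort("Footprint is empty.")
  mean(richness$richness[fp])
}

#' Randomly relocate a footprint within the study area
#'
#' Translates the footprint by a uniformly drawn `(delta_row, delta_col)`
#' that keeps its bounding box on the grid; a draw is accepted only when
#' every translated cell lies inside the study mask, and draws are repeated
#' until acceptance (capped). Translation only — size, shape and
#' orientation are preserved, so no rotation or reflection is applied.
#'
#' @param footprint `(row, col)` cell matrix.
#' @param study_mask logical matrix of the study area.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap (default 10000).
#' @return The translated footprint, or `NULL` (with a warning) when no
#'   placement is found within the cap — the area is then untestable.
#' @export
relocate_footprint <- function(footprint, study_mask, seed,
                               max_attempts = 10000) {
  fp <- as_cell_matrix(footprint)
  sh <- relocation_shifts(fp, study_mask, 1L, seed, max_attempts)
  if (is.null(sh)) {
    warn("No valid relocation found within the attempt cap.")
    return(NULL)
  }
  cbind(row = fp[, 1] + sh[1, 1], col = fp[, 2] + sh[1, 2])
}

# Draw `n` accepted (drow, dcol) translations of fp inside study_mask.
# Returns an n x 2 matrix, or NULL if acceptance fails within the cap.
relocation_shifts <- function(fp, study_mask, n, seed, max_attempts = 10000) {
  nr <- nrow(study_mask)
  nc <- ncol(study_mask)
  dr_rng <- c(1L - min(fp[, 1]), nr - max(fp[, 1]))
  dc_rng <- c(1L - min(fp[, 2]), nc - max(fp[, 2]))
  if (dr_rng[2] < dr_rng[1] || dc_rng[2] < dc_rng[1]) return(NULL)
  base_idx <- (fp[, 2] - 1L) * nr + fp[, 1]
  mask_vec <- as.vector(study_mask)
  with_seed(seed, {
    acc <- matrix(0L, 0, 2)
    attempts <- 0L
    while (nrow(acc) < n && attempts < max_attempts) {
      batch <- min(max(2L * (n - nrow(acc)), 32L), max_attempts - attempts)
      attempts <- attempts + batch
      dr <- sample(dr_rng[1]:dr_rng[2], batch, replace = TRUE)
      dc <- sample(dc_rng[1]:dc_rng[2], batch, replace = TRUE)
      off <- dc * nr + dr
      ok <- vapply(seq_len(batch),
                   function(i) all(mask_vec[base_idx + off[i]]),
                   logical(1))
      if (any(ok)) {
        acc <- rbind(acc, cbind(dr[ok], dc[ok]))
      }
    }
    if (nrow(acc) < n) NULL else acc[seq_len(n), , drop = FALSE]
  })
}

#' Null-model effectiveness test for one protected area
#'
#' Compares the observed mean richness inside a protected area's footprint
#' with the distribution of mean richness over `n_randomizations` random
#' relocations of the same footprint (size, shape and orientation
#' preserved) within the study area. The area is effective when its
#' observed value is strictly greater than the null value in at least 95%
#' of randomizations (`n_observed_greater >= ceiling(0.95 * n)`); ties
#' count against effectiveness. The reported p-value uses the add-one
#' permutation formula `(1 + #(null >= observed)) / (1 + n)`, which can
#' never be exactly zero.
#'
#' @param footprint `(row, col)` cell matrix or tibble.
#' @param richness a `richness_map`.
#' @param n_randomizations number of relocations (default 999).
#' @param seed integer seed (this area's private stream).
#' @param study_mask logical matrix; defaults to the full grid.
#' @param pa_id,category labels carried on the output.
#' @return One-row tibble: `pa_id`, `category`, `scenario_id`,
#'   `observed_mean_richness`, `null_mean`, `null_sd`,
#'   `n_observed_greater`, `p_value`, `effective`, `untestable`, and the
#'   null values as a list-column.
#' @export
effectiveness_test <- function(footprint, richness, n_randomizations = 999,
                               seed = 1, study_mask = NULL,
                               pa_id = NA_character_,
                               category = NA_character_) {
  fp <- as_cell_matrix(footprint)
  if (!nrow(fp)) abort("Footprint is empty.")
  if (is.null(study_mask)) {
    study_mask <- matrix(TRUE, nrow(richness$richness),
                         ncol(richness$richness))
  }
  observed <- mean_richness_in(fp, richness)
  shifts <- relocation_shifts(fp, study_mask, n_randomizations, seed)
  if (is.null(shifts)) {
    warn(paste0("Protected area ", pa_id,
                " could not be relocated; flagged untestable."))
    return(tibble(
      pa_id = pa_id, category = category, scenario_id = richness$scenario_id,
      observed_mean_richness = observed, null_mean = NA_real_,
      null_sd = NA_real_, n_observed_greater = NA_integer_,
      p_value = NA_real_, effective = NA, untestable = TRUE,
      n_randomizations = n_randomizations, null_values = list(numeric(0))
    ))
  }
  nr <- nrow(richness$richness)
  base_idx <- (fp[, 2] - 1L) * nr + fp[, 1]
  rich_vec <- as.vector(richness$richness)
  offsets <- shifts[, 2] * nr + shifts[, 1]
  nulls <- vapply(offsets, function(o) mean(rich_vec[base_idx + o]),
                  numeric(1))
  n_greater <- sum(observed > nulls)
  tibble(
    pa_id = pa_id, category = category, scenario_id = richness$scenario_id,
    observed_mean_richness = observed,
    null_mean = mean(nulls), null_sd = sd(nulls),
    n_observed_greater = n_greater,
    p_value = (1 + sum(nulls >= observed)) / (1 + n_randomizations),
    effective = n_greater >= ceiling(0.95 * n_randomizations),
    untestable = FALSE,
    n_randomizations = n_randomizations,
    null_values = list(nulls)
  )
}

#' Test every protected area against the richness null model
#'
#' Runs [effectiveness_test()] for each area of a `pa_set`. Each area's
#' random stream is derived deterministically from the master seed and its
#' `pa_id`, so results are reproducible and independent of the order in
#' which areas are tested; areas with identical footprints but different
#' ids get independent streams.
#'
#' @param pas a `pa_set`.
#' @param richness a `richness_map`.
#' @param n_randomizations relocations per area (default 999).
#' @param seed master seed.
#' @param study_mask logical study-area matrix (default full grid).
#' @return Tibble with one row per protected area (see
#'   [effectiveness_test()]).
#' @export
pa_effectiveness <- function(pas, richness, n_randomizations = 999,
                             seed = 1, study_mask = NULL) {
  stopifnot(inherits(pas, "pa_set"))
  rows <- purrr::pmap(
    list(pas$pa_id, pas$category, pas$footprint),
    function(id, cat, fp) {
      effectiveness_test(fp, richness, n_randomizations,
                         seed = seed_from_id(seed, id),
                         study_mask = study_mask, pa_id = id, category = cat)
    }
  )
  bind_rows(rows)
}

#' Summarize effectiveness results per scenario
#'
#' @param results tibble from [pa_effectiveness()], possibly covering
#'   several scenarios.
#' @return Per-scenario tallies: effective, non-effective and untestable
#'   counts and the percentage of all areas flagged effective.
#' @export
summarize_effectiveness <- function(results) {
  stopifnot(nrow(results) >= 1L)
  results |>
    group_by(.data$scenario_id) |>
    summarise(
      n_total = dplyr::n(),
      n_effective = sum(.data$effective, na.rm = TRUE),
      n_non_effective = sum(!.data$effective, na.rm = TRUE),
      n_untestable = sum(is.na(.data$effective)),
      pct_effective = 100 * sum(.data$effective, na.rm = TRUE) / dplyr::n(),
      .groups = "drop"
    )
}
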