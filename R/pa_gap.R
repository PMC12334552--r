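#' @title Protected-area gap analysis
#' @name pa_gap
#' @description Overlay binary habitat with a protected-area mask to get
#'   Inside/Outside-PA areas and proportions per species and scenario, and
#'   the genus-level protected-habitat trend across scenarios.
NULL

#' Overlay a habitat map with a protected-area mask
#'
#' @param habitat a `binary_habitat_map`.
#' @param pa a `pa_mask` on the same grid.
#' @return one-row data.frame (`pa_coverage`): species_id, scenario_id,
#'   inside_km2, outside_km2, inside_pct (`NA`, flagged, for an empty
#'   habitat).
#' @export
overlay_pa <- function(habitat, pa) {
  stop_if_not_conformant(habitat$grid, pa$grid)
  hab <- habitat$suitable & !is.na(habitat$suitable)
  inside <- masked_area_km2(hab & pa$covered, habitat$grid)
  outside <- masked_area_km2(hab & !pa$covered, habitat$grid)
  tot <- inside + outside
  data.frame(
    species_id = habitat$species_id, scenario_id = habitat$scenario_id,
    inside_km2 = inside, outside_km2 = outside,
    inside_pct = if (tot > 0) 100 * inside / tot else NA_real_,
    empty_habitat = tot <= 0
  )
}

#' Genus-level protected-habitat trend
#'
#' Sums per-species protected habitat within each scenario (species
#' overlap is intentionally summed, not unioned, so the totals match the
#' per-species accounting) and reports the percent change of each future
#' scenario against the current total.
#'
#' @param coverages data.frame of [overlay_pa()] rows over species and
#'   scenarios; must include the `"current"` scenario.
#' @param current_id scenario label of the baseline, default `"current"`.
#' @return data.frame per scenario: total_inside_km2, change_pct vs the
#'   baseline (0 for the baseline itself).
#' @export
genus_pa_trend <- function(coverages, current_id = "current") {
  if (!current_id %in% coverages$scenario_id) {
    stop("baseline scenario '", current_id, "' missing from coverages")
  }
  tot <- stats::aggregate(inside_km2 ~ scenario_id, data = coverages, sum)
  names(tot)[2] <- "total_inside_km2"
  base <- tot$total_inside_km2[tot$scenario_id == current_id]
  tot$change_pct <- 100 * (tot$total_inside_km2 - base) / base
  tot
}

#' Unprotected-habitat (conservation gap) mask
#'
#' Cells suitable for at least one species but not covered by the PA mask.
#'
#' @param habitats list of `binary_habitat_map`s (one scenario).
#' @param pa a `pa_mask`.
#' @return a logical vector over cells (row-major).
#' @export
conservation_gap_mask <- function(habitats, pa) {
  grid <- pa$grid
  any_hab <- rep(FALSE, grid$n_rows * grid$n_cols)
  for (h in habitats) {
    stop_if_not_conformant(grid, h$grid)
    any_hab <- any_hab | (h$suitable & !is.na(h$suitable))
  }
  any_hab & !pa$covered
}
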