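#' @title Habitat binarization and change accounting
#' @name habitat_change
#' @description Binarize ensemble suitability at a fixed cutoff (with a
#'   Fisher-Jenks diagnostic), compute suitable areas, and produce the
#'   retained/lost/gained change accounting and the species-level change
#'   histogram.
NULL

#' Binary habitat map
#'
#' @param species_id,scenario_id labels.
#' @param suitable logical vector, row-major; `NA` for nodata cells.
#' @param grid a [grid_spec()].
#' @return a `binary_habitat_map`.
#' @export
binary_habitat_map <- function(species_id, scenario_id, suitable, grid) {
  if (length(suitable) != grid$n_rows * grid$n_cols) {
    stop("habitat length does not match grid")
  }
  structure(list(species_id = species_id, scenario_id = scenario_id,
                 suitable = as.logical(suitable), grid = grid),
            class = "binary_habitat_map")
}

#' Binarize a suitability map
#'
#' A cell is suitable iff its ensemble score is `>= cutoff` (inclusive).
#' As a diagnostic, Fisher-Jenks breaks of the scores are computed (on a
#' subsample when the map is large) and the break nearest the cutoff is
#' attached to the result; the classification itself always uses the fixed
#' cutoff.
#'
#' @param map a `suitability_map`.
#' @param cutoff suitability cutoff in (0, 1), default 0.6.
#' @param jenks_classes classes for the diagnostic, default 4; set to 0 to
#'   skip the diagnostic.
#' @param jenks_sample_max subsample size for the diagnostic, default 1000.
#' @return a `binary_habitat_map` with attribute-style fields
#'   `jenks_breaks` and `nearest_break`.
#' @export
binarize <- function(map, cutoff = 0.6, jenks_classes = 4,
                     jenks_sample_max = 1000) {
  stopifnot(cutoff > 0, cutoff < 1)
  vals <- map$values
  if (all(is.na(vals))) {
    warning("all-nodata suitability map for ", map$species_id)
    return(binary_habitat_map(map$species_id, map$scenario_id,
                              rep(NA, length(vals)), map$grid))
  }
  out <- binary_habitat_map(map$species_id, map$scenario_id,
                            vals >= cutoff, map$grid)
  if (jenks_classes >= 2) {
    v <- vals[!is.na(vals)]
    if (length(v) > jenks_sample_max) {
      v <- stats::quantile(v, probs = seq(0, 1, length.out = jenks_sample_max),
                           names = FALSE, type = 1)
    }
    br <- tryCatch(jenks_breaks(v, jenks_classes), error = function(e) NULL)
    out$jenks_breaks <- br
    if (!is.null(br) && length(br) > 0) {
      out$nearest_break <- br[which.min(abs(br - cutoff))]
    }
  }
  out
}

#' Categorical change map between two binary habitats
#'
#' @param current,future `binary_habitat_map`s on the same grid for the
#'   same species.
#' @return integer vector over cells coded 0 = absent, 1 = retained,
#'   2 = lost, 3 = gained (`NA` where either input is nodata), with class
#'   `change_map` and the grid attached.
#' @export
change_map <- function(current, future) {
  stop_if_not_conformant(current$grid, future$grid)
  if (!identical(current$species_id, future$species_id)) {
    stop("change_map requires the same species on both sides")
  }
  cur <- current$suitable
  fut <- future$suitable
  code <- ifelse(cur & fut, 1L, ifelse(cur & !fut, 2L,
                 ifelse(!cur & fut, 3L, 0L)))
  structure(list(species_id = current$species_id,
                 scenario_id = future$scenario_id,
                 code = as.integer(code), grid = current$grid),
            class = "change_map")
}

#' Area accounting of habitat change
#'
#' Retained/lost/gained areas via spherical cell areas; by construction
#' `retained + lost = current` and `retained + gained = future`. Net change
#' is `100 * (future - current) / current`; species with zero current area
#' are flagged and get `NA` net change.
#'
#' @param current,future `binary_habitat_map`s on the same grid.
#' @return one-row data.frame (`change_summary`): species_id, scenario_id,
#'   current_km2, future_km2, retained_km2, lost_km2, gained_km2,
#'   net_change_pct, lost_frac_pct, undefined_pct flag.
#' @export
change_summary <- function(current, future) {
  cm <- change_map(current, future)
  area <- grid_cell_areas(cm$grid)
  a <- function(code) sum(area[which(cm$code == code)])
  retained <- a(1L); lost <- a(2L); gained <- a(3L)
  cur <- retained + lost
  fut <- retained + gained
  undefined <- cur <= 0
  data.frame(
    species_id = cm$species_id, scenario_id = cm$scenario_id,
    current_km2 = cur, future_km2 = fut, retained_km2 = retained,
    lost_km2 = lost, gained_km2 = gained,
    net_change_pct = if (undefined) NA_real_ else 100 * (fut - cur) / cur,
    lost_frac_pct = if (undefined) NA_real_ else 100 * lost / cur,
    undefined_pct = undefined
  )
}

#' Histogram of species by net habitat change
#'
#' Default bins follow the change-histogram convention: losses
#' `{-100}`, `(-100, -70]`, `(-70, -50]`, `(-50, -30]`, `(-30, 0)` and
#' gains `[0, 200]`, `(200, 400]`, `(400, Inf)`. A species whose future
#' area is zero counts as total (-100%) loss. Each species counts once per
#' scenario.
#'
#' @param summaries data.frame of [change_summary()] rows (possibly several
#'   scenarios).
#' @param loss_edges,gain_edges internal bin edges, strictly monotone;
#'   defaults `c(-100, -70, -50, -30, 0)` and `c(0, 200, 400)`.
#' @return data.frame with scenario_id, bin label and species count.
#' @export
bin_species_by_change <- function(summaries,
                                  loss_edges = c(-100, -70, -50, -30, 0),
                                  gain_edges = c(0, 200, 400)) {
  if (is.unsorted(loss_edges, strictly = TRUE) ||
      is.unsorted(gain_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  bin_of <- function(pct, future_km2) {
    if (is.na(pct)) return(NA_character_)
    if (pct <= -100 || future_km2 <= 0) return("loss_100")
    if (pct < 0) {
      lo <- loss_edges[-length(loss_edges)]
      hi <- loss_edges[-1]
      k <- which(pct > lo & pct <= hi)[1]   # (lo, hi] closure
      return(sprintf("loss_(%g,%g]", lo[k], hi[k]))
    }
    his <- c(gain_edges[-1], Inf)
    los <- gain_edges
    if (pct <= his[1]) return(sprintf("gain_[%g,%g]", los[1], his[1]))
    k <- max(which(pct > los))                        # (lo, hi] above bin 1
    sprintf("gain_(%g,%g]", los[k], his[k])
  }
  labs <- mapply(bin_of, summaries$net_change_pct, summaries$future_km2)
  out <- as.data.frame(table(scenario_id = summaries$scenario_id,
                             bin = labs), stringsAsFactors = FALSE)
  names(out)[3] <- "n_species"
  out
}
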