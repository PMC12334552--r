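#' @title Red List Criterion-B metrics and climate-driven reclassification
#' @name redlist
#' @description Extent of occurrence, area of occupancy and location counts
#'   on an equal-area projection; a rule-based Criterion-B categorizer; the
#'   max-risk combination of two assessments; and the decision table that
#'   reclassifies a species' Red List category from the projected change in
#'   its suitable range.
NULL

#' Ordered Red List category scale
#'
#' LC < NT < VU < EN < CR < EX; NE is unranked and acts as an identity
#' element in [combine_max_risk()].
#' @export
RL_RANK <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L, EX = 5L,
             NE = NA_integer_)

#' Categories conventionally counted as threatened
#' @export
RL_THREATENED <- c("VU", "EN", "CR")

check_category <- function(code, allow_ne = FALSE) {
  if (!code %in% names(RL_RANK)) stop("unknown Red List category: ", code)
  if (!allow_ne && is.na(RL_RANK[[code]])) {
    stop("category must be ranked (not NE)")
  }
  code
}

# ---- equal-area projection and Criterion-B metrics -------------------------

# cylindrical equal-area projection: standard parallel = data centroid
# latitude, x-origin at 0 deg longitude, y-origin at the equator; so the
# occupancy grids below have a fixed, reproducible anchoring.
cea_project <- function(lon, lat, lat_ts, radius_km = EARTH_RADIUS_KM) {
  k <- cos(lat_ts * pi / 180)
  list(x = radius_km * (lon * pi / 180) * k,
       y = radius_km * sin(lat * pi / 180) / k)
}

unique_points <- function(points) {
  unique(data.frame(lon = points$lon, lat = points$lat))
}

#' Extent of occurrence (EOO)
#'
#' Area of the convex hull of the records, computed on a cylindrical
#' equal-area projection whose standard parallel is the centroid latitude
#' of the unique points. Fewer than 3 non-collinear points give 0.
#'
#' @param points data.frame with `lon`, `lat` (one species).
#' @return hull area in km^2.
#' @export
eoo_km2 <- function(points) {
  pts <- unique_points(points)
  if (nrow(pts) == 0) stop("eoo_km2 needs at least one point")
  if (nrow(pts) < 3) return(0)
  pr <- cea_project(pts$lon, pts$lat, mean(pts$lat))
  h <- grDevices::chull(pr$x, pr$y)
  x <- pr$x[h]; y <- pr$y[h]
  n <- length(h)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

occupied_grid_cells <- function(points, cell_km) {
  pts <- unique_points(points)
  if (nrow(pts) == 0) stop("need at least one point")
  pr <- cea_project(pts$lon, pts$lat, mean(pts$lat))
  nrow(unique(data.frame(i = floor(pr$x / cell_km),
                         j = floor(pr$y / cell_km))))
}

#' Area of occupancy (AOO)
#'
#' Number of occupied `cell_km x cell_km` squares (grid anchored at the
#' projection origin) times the cell area; IUCN convention uses 2-km cells.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param cell_km occupancy cell edge in km, default 2.
#' @return occupied area in km^2 (a multiple of `cell_km^2`).
#' @export
aoo_km2 <- function(points, cell_km = 2) {
  occupied_grid_cells(points, cell_km) * cell_km^2
}

#' Number of locations
#'
#' Occupied 10-km grid squares, same anchoring as [aoo_km2()].
#'
#' @param points data.frame with `lon`, `lat`.
#' @param cell_km location cell edge in km, default 10.
#' @return location count (>= 1 for any non-empty input).
#' @export
count_locations <- function(points, cell_km = 10) {
  occupied_grid_cells(points, cell_km)
}

#' Criterion-B metrics for one species
#'
#' @param points data.frame with `lon`, `lat`.
#' @return list with `eoo_km2`, `aoo_km2`, `n_locations`.
#' @export
criterion_b_metrics <- function(points) {
  list(eoo_km2 = eoo_km2(points), aoo_km2 = aoo_km2(points),
       n_locations = count_locations(points))
}

#' Preliminary category from Criterion-B thresholds
#'
#' Geographic-range rules with location-count conditions as the operative
#' proxy for the subcriteria: CR if (EOO < 100 or AOO < 10) and exactly one
#' location; EN if (EOO < 5000 or AOO < 500) and <= 5 locations; VU if
#' (EOO < 20000 or AOO < 2000) and <= 10 locations; NT if within 20% above
#' any VU bound (EOO < 24000 or AOO < 2400, with <= 12 locations); else LC.
#' When EOO < AOO (possible for degenerate hulls), EOO is replaced by AOO
#' before thresholding.
#'
#' @param metrics list from [criterion_b_metrics()] (or any list with
#'   `eoo_km2`, `aoo_km2`, `n_locations`).
#' @return a category code.
#' @export
criterion_b <- function(metrics) {
  eoo <- metrics$eoo_km2
  aoo <- metrics$aoo_km2
  loc <- metrics$n_locations
  if (eoo < aoo) eoo <- aoo
  if ((eoo < 100 || aoo < 10) && loc == 1) return("CR")
  if ((eoo < 5000 || aoo < 500) && loc <= 5) return("EN")
  if ((eoo < 20000 || aoo < 2000) && loc <= 10) return("VU")
  if ((eoo < 24000 || aoo < 2400) && loc <= 12) return("NT")
  "LC"
}

#' Combine two assessments by maximum risk
#'
#' Returns the higher-ranked category; NE acts as an identity element, and
#' the operation is commutative, associative and idempotent.
#'
#' @param a,b category codes.
#' @return the higher-risk category (NE only if both are NE).
#' @export
combine_max_risk <- function(a, b) {
  check_category(a, allow_ne = TRUE)
  check_category(b, allow_ne = TRUE)
  if (a == "NE") return(b)
  if (b == "NE") return(a)
  if (RL_RANK[[a]] >= RL_RANK[[b]]) a else b
}

# ---- reclassification decision table ---------------------------------------

# loss side: rows = start category, thresholds on L = -net_change_pct
# (strict lower bound, inclusive upper bound, per the stated conventions:
# "exceeds 90%" -> L > 90; "between 90% and 70%" -> 70 < L <= 90;
# "between 70% and 50%" -> 50 < L <= 70)
.loss_rules <- list(
  CR = list(list(90, Inf, "EX")),
  EN = list(list(90, Inf, "CR"), list(70, 90, "EN")),
  VU = list(list(90, Inf, "CR"), list(70, 90, "EN"), list(50, 70, "NT")),
  NT = list(list(90, Inf, "CR"), list(70, 90, "EN"), list(50, 70, "VU")),
  LC = list(list(90, Inf, "EN"), list(70, 90, "VU"), list(50, 70, "NT"))
)

# expansion side, thresholds on G = net_change_pct ("expansions of
# 100%-150%" -> 100 <= G <= 150, "exceeding 150%" -> G > 150; NT drops to
# LC for any expansion exceeding 100%)
.gain_rules <- list(
  CR = list(list(100, 150, "EN"), list(150, Inf, "VU")),
  EN = list(list(100, 150, "VU"), list(150, Inf, "NT")),
  VU = list(list(100, 150, "NT"), list(150, Inf, "LC")),
  NT = list(list(100, Inf, "LC"))
)

#' Reclassify a category from projected range change
#'
#' The climate-driven decision table. Any species whose projected future
#' range is exactly zero becomes EX ("extinct in the wild" as used here);
#' EX otherwise requires a CR start with a loss exceeding 90%. Loss-side
#' rules use strict lower / inclusive upper interval closure; the
#' expansion-side band 100%-150% is closed on both ends. All other cases
#' retain the start category. Exactly one rule fires per call and its
#' identifier is returned.
#'
#' @param start ranked start category code.
#' @param net_change_pct percent change of suitable area (negative = loss);
#'   may be `NA` only when `future_km2 = 0`.
#' @param future_km2 projected future suitable area.
#' @return list with `category` and `rule_fired`.
#' @export
reclassify <- function(start, net_change_pct, future_km2) {
  check_category(start)
  if (start == "EX") return(list(category = "EX", rule_fired = "already_EX"))
  if (!is.na(future_km2) && future_km2 <= 0) {
    return(list(category = "EX", rule_fired = "total_loss_EX"))
  }
  if (is.na(net_change_pct)) {
    stop("net_change_pct undefined but future area positive")
  }
  if (net_change_pct < 0) {
    L <- -net_change_pct
    for (r in .loss_rules[[start]]) {
      if (L > r[[1]] && L <= r[[2]]) {
        return(list(category = r[[3]],
                    rule_fired = sprintf("%s_loss_(%g,%g]", start,
                                         r[[1]], r[[2]])))
      }
    }
  } else if (start %in% names(.gain_rules)) {
    G <- net_change_pct
    for (r in .gain_rules[[start]]) {
      # the 100-150 bands are closed at both ends; open bands are strict
      if (r[[2]] < Inf) {
        if (G >= r[[1]] && G <= r[[2]]) {
          return(list(category = r[[3]],
                      rule_fired = sprintf("%s_gain_[%g,%g]", start,
                                           r[[1]], r[[2]])))
        }
      } else if (G > r[[1]]) {
        return(list(category = r[[3]],
                    rule_fired = sprintf("%s_gain_(%g,Inf)", start, r[[1]])))
      }
    }
  }
  list(category = start, rule_fired = paste0(start, "_retain"))
}

#' Assess a whole genus table
#'
#' Applies [reclassify()] to every species and counts the threatened
#' outcome. The threatened count is `|{VU, EN, CR}|`, plus `|{EX}|` when
#' `count_ex_as_threatened` is TRUE (the default), since species going
#' extinct in the wild remain conservation-relevant.
#'
#' @param records data.frame with columns `species`, `category_start`
#'   (ranked codes), `net_change_pct`, `future_km2`.
#' @param count_ex_as_threatened include EX in the threatened count.
#' @return list with `assessments` (data.frame: species, category_start,
#'   net_change_pct, future_km2, category_end, rule_fired),
#'   `threatened_count`, `ex_count` and `transitions` (a start x end count
#'   matrix).
#' @export
assess_genus <- function(records, count_ex_as_threatened = TRUE) {
  need <- c("species", "category_start", "net_change_pct", "future_km2")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  unranked <- is.na(RL_RANK[records$category_start])
  if (any(unranked)) {
    stop("unresolved NE start category for: ",
         paste(records$species[unranked], collapse = ", "),
         " (resolve via criterion_b / combine_max_risk first)")
  }
  res <- lapply(seq_len(nrow(records)), function(i) {
    reclassify(records$category_start[i], records$net_change_pct[i],
               records$future_km2[i])
  })
  out <- records[need]
  out$category_end <- vapply(res, `[[`, character(1), "category")
  out$rule_fired <- vapply(res, `[[`, character(1), "rule_fired")
  threatened <- sum(out$category_end %in% RL_THREATENED) +
    if (count_ex_as_threatened) sum(out$category_end == "EX") else 0L
  lv <- names(RL_RANK)[!is.na(RL_RANK)]
  transitions <- table(factor(out$category_start, levels = lv),
                       factor(out$category_end, levels = lv))
  list(assessments = out, threatened_count = as.integer(threatened),
       ex_count = sum(out$category_end == "EX"), transitions = transitions)
}

#' Resolve a start category for an unevaluated species
#'
#' For species without a published category, the Criterion-B preliminary
#' category from the occurrence records and an optional prior category
#' (e.g. from an external predictor) are combined by maximum risk.
#'
#' @param published published category code or `"NE"`.
#' @param points occurrence data.frame for the species (used when NE).
#' @param prior optional prior category code (default `"NE"`).
#' @return a ranked category code.
#' @export
resolve_start_category <- function(published, points = NULL, prior = "NE") {
  check_category(published, allow_ne = TRUE)
  if (published != "NE") return(published)
  prelim <- if (!is.null(points) && nrow(points) > 0) {
    criterion_b(criterion_b_metrics(points))
  } else {
    "NE"
  }
  out <- combine_max_risk(prelim, prior)
  if (out == "NE") stop("cannot resolve NE: no records and no prior")
  out
}
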