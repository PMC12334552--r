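#' @title Pipeline orchestration
#' @name pipeline_cli
#' @description Occurrence cleaning, configuration, seeding and the stage
#'   graph: simulate (or load) -> filter -> fit -> project -> change ->
#'   assess -> gap -> report. Identical (config, seed) pairs reproduce
#'   identical outputs, and per-species sub-seeds make each species' result
#'   independent of the species list ordering.
NULL

#' Clean an occurrence table
#'
#' Applies, in order: drop records outside the study bounding box (or off
#' the grid), drop records in excluded cells (e.g. urban areas), collapse
#' exact duplicate (species, cell) pairs, and drop species with
#' `min_records` or fewer remaining records (strictly more than
#' `min_records` are required to keep a species).
#'
#' @param raw occurrence data.frame (species, lon, lat, source).
#' @param grid a [grid_spec()].
#' @param study_bbox list with `lon = c(min, max)`, `lat = c(min, max)`;
#'   default the grid extent.
#' @param exclusion_mask optional logical vector over cells (TRUE = drop).
#' @param min_records species gate, default 5 (a species needs > 5 records).
#' @return list with `clean` (the retained table plus a `cell` column) and
#'   `report` (per-species counts removed by each rule).
#' @export
clean_occurrences <- function(raw, grid, study_bbox = NULL,
                              exclusion_mask = NULL, min_records = 5) {
  if (is.null(study_bbox)) {
    study_bbox <- list(
      lon = c(grid$lon_left, grid$lon_left + grid$n_cols * grid$res_deg),
      lat = c(grid$lat_top - grid$n_rows * grid$res_deg, grid$lat_top))
  }
  df <- raw
  df$cell <- point_to_cell(df$lon, df$lat, grid)$cell
  in_bbox <- df$lon >= study_bbox$lon[1] & df$lon <= study_bbox$lon[2] &
    df$lat >= study_bbox$lat[1] & df$lat <= study_bbox$lat[2] &
    !is.na(df$cell)
  n_bbox <- tapply(!in_bbox, df$species, sum)
  df <- df[in_bbox, , drop = FALSE]
  if (!is.null(exclusion_mask)) {
    if (is.list(exclusion_mask)) exclusion_mask <- exclusion_mask$covered
    excl <- exclusion_mask[df$cell]
    n_excl <- tapply(excl, df$species, sum)
    df <- df[!excl, , drop = FALSE]
  } else {
    n_excl <- NULL
  }
  dup <- duplicated(df[c("species", "cell")])
  n_dup <- tapply(dup, df$species, sum)
  df <- df[!dup, , drop = FALSE]
  counts <- table(df$species)
  keep_species <- names(counts)[counts > min_records]
  n_gate <- as.integer(counts[!names(counts) %in% keep_species])
  dropped_species <- setdiff(names(counts), keep_species)
  df <- df[df$species %in% keep_species, , drop = FALSE]
  species_all <- unique(raw$species)
  rep_df <- data.frame(
    species = species_all,
    removed_bbox = as.integer(n_bbox[species_all]),
    removed_excluded = if (is.null(n_excl)) 0L else
      as.integer(ifelse(is.na(n_excl[species_all]), 0, n_excl[species_all])),
    removed_duplicate = as.integer(
      ifelse(is.na(n_dup[species_all]), 0, n_dup[species_all])),
    retained = as.integer(ifelse(is.na(counts[species_all]), 0,
                                 counts[species_all])),
    dropped_by_gate = species_all %in% dropped_species
  )
  rep_df$removed_bbox[is.na(rep_df$removed_bbox)] <- 0L
  if (nrow(df) == 0) stop("occurrence cleaning removed every record")
  rownames(df) <- NULL
  list(clean = df, report = rep_df)
}

#' Default pipeline configuration
#'
#' A self-contained simulated-study configuration: a 60 x 60 grid, three
#' autocorrelated layers, two Gaussian virtual species, one future scenario
#' with an additive shift on the first layer, a 30%-coverage blocky PA
#' mask, and the standard modelling block (all five algorithms, 0.7 gates,
#' 20 x 70/30 validation, 0.6 binarization cutoff).
#'
#' @return nested configuration list; every field can be overridden before
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(
    grid = list(n_rows = 60, n_cols = 60, res_deg = 2.5 / 60,
                lat_top = -15, lon_left = 44),
    landscape = list(n_layers = 3, autocorrelation_range_cells = 5,
                     layer_names = c("bio6", "bio12", "bio15")),
    species = list(
      list(species_id = "species_a",
           optima = c(bio12 = 0), breadths = c(bio12 = 0.12),
           n_presences = 150, category = "NE", prior = "NE"),
      list(species_id = "species_b",
           optima = c(bio6 = 0.5, bio15 = -0.5),
           breadths = c(bio6 = 0.12, bio15 = 0.12),
           n_presences = 150, category = "LC", prior = "NE")
    ),
    scenarios = list(ssp585 = list(bio12 = 1.5, bio6 = 0.75)),
    cleaning = list(min_records = 5),
    collinearity = list(threshold = 0.75),
    modelling = list(algorithms = SDM_ALGORITHMS, gate_auc = 0.7,
                     gate_tss = 0.7, n_reps = 20, train_frac = 0.7,
                     n_pa = NULL),
    binarization = list(cutoff = 0.6, jenks_classes = 4),
    redlist = list(count_ex_as_threatened = TRUE),
    pa = list(coverage_frac = 0.3, n_blocks = 8)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override [default_config()]; nested blocks
#' are merged shallowly.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Simulate the pipeline inputs described by a configuration
#'
#' @param config configuration list (see [default_config()]).
#' @param seed master integer seed.
#' @return list with `stacks` (current + futures), `occurrences`,
#'   `pa` mask, `truth` (per-species true suitability maps) and
#'   `categories`.
#' @export
simulate_inputs <- function(config, seed = 1) {
  g <- config$grid
  grid <- grid_spec(g$n_rows, g$n_cols, g$res_deg, g$lat_top, g$lon_left)
  ls <- config$landscape
  current <- make_landscape(grid, ls$n_layers, ls$autocorrelation_range_cells,
                            seed = sub_seed(seed, "landscape"),
                            layer_names = ls$layer_names)
  stacks <- c(list(current = current),
              lapply(stats::setNames(names(config$scenarios),
                                     names(config$scenarios)), function(sc) {
                perturb_climate(current, config$scenarios[[sc]], sc)
              }))
  occ <- do.call(rbind, lapply(config$species, function(sp) {
    vs <- virtual_species_spec(sp$species_id, unlist(sp$optima),
                               unlist(sp$breadths))
    truth <- true_suitability(vs, current)
    sample_presences(truth, sp$n_presences,
                     seed = sub_seed(seed, "presences", sp$species_id))
  }))
  truth <- lapply(config$species, function(sp) {
    vs <- virtual_species_spec(sp$species_id, unlist(sp$optima),
                               unlist(sp$breadths))
    true_suitability(vs, current)
  })
  names(truth) <- vapply(config$species, `[[`, character(1), "species_id")
  pa <- make_pa_mask(grid, config$pa$coverage_frac, config$pa$n_blocks,
                     seed = sub_seed(seed, "pa_mask"))
  categories <- data.frame(
    species = names(truth),
    category = vapply(config$species, function(sp) sp$category %||% "NE",
                      character(1)),
    prior = vapply(config$species, function(sp) sp$prior %||% "NE",
                   character(1))
  )
  list(grid = grid, stacks = stacks, occurrences = occ, pa = pa,
       truth = truth, categories = categories)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> clean -> filter -> fit -> project ->
#' change -> assess -> gap, optionally writing all stage outputs and a JSON
#' manifest to `out_dir`.
#'
#' @param config configuration list; see [default_config()]. If
#'   `config$inputs` is set, it must be a list like the output of
#'   [simulate_inputs()] (externally loaded data can be supplied this way).
#' @param seed master integer seed; every stochastic stage derives a
#'   sub-seed from it.
#' @param out_dir optional output directory for CSV/raster/manifest files.
#' @return list with `inputs`, `retained_layers`, per-species `fits`,
#'   `summaries` (change accounting), `assessments` per scenario,
#'   `pa_coverage`, `pa_trend`, `cleaning_report` and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = NULL) {
  inputs <- config$inputs %||% simulate_inputs(config, seed)
  grid <- inputs$grid
  current <- inputs$stacks$current
  future_ids <- setdiff(names(inputs$stacks), "current")
  warnings_log <- character(0)

  cleaned <- clean_occurrences(inputs$occurrences, grid,
                               min_records = config$cleaning$min_records)
  occ <- cleaned$clean
  species_ids <- sort(unique(occ$species))

  retained <- withCallingHandlers(
    filter_collinear(current, config$collinearity$threshold),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  mb <- config$modelling
  bb <- config$binarization
  fits <- list()
  summaries <- list()
  habitats <- list()
  coverages <- list()
  for (sp in species_ids) {
    sp_occ <- occ[occ$species == sp, , drop = FALSE]
    pa_set <- build_pa_set(sp_occ, current, retained, n_pa = mb$n_pa,
                           seed = sub_seed(seed, "pseudo_absence", sp))
    fit <- ensemble_sdm(pa_set, current, algorithms = mb$algorithms,
                        gate_auc = mb$gate_auc, gate_tss = mb$gate_tss,
                        n_reps = mb$n_reps, train_frac = mb$train_frac,
                        seed = sub_seed(seed, "ensemble", sp))
    fits[[sp]] <- fit
    hab_cur <- binarize(fit$best$map, bb$cutoff, bb$jenks_classes)
    habitats[["current"]][[sp]] <- hab_cur
    coverages[[length(coverages) + 1]] <- overlay_pa(hab_cur, inputs$pa)
    for (fid in future_ids) {
      proj <- project_ensemble(fit, inputs$stacks[[fid]])
      hab_fut <- binarize(proj$map, bb$cutoff, bb$jenks_classes)
      habitats[[fid]][[sp]] <- hab_fut
      summaries[[length(summaries) + 1]] <- change_summary(hab_cur, hab_fut)
      coverages[[length(coverages) + 1]] <- overlay_pa(hab_fut, inputs$pa)
    }
  }
  summaries <- if (length(summaries) > 0) do.call(rbind, summaries) else NULL
  coverages <- do.call(rbind, coverages)

  start_cat <- vapply(species_ids, function(sp) {
    row <- inputs$categories[inputs$categories$species == sp, ]
    resolve_start_category(
      if (nrow(row) > 0) row$category[1] else "NE",
      points = occ[occ$species == sp, , drop = FALSE],
      prior = if (nrow(row) > 0) row$prior[1] %||% "NE" else "NE")
  }, character(1))

  assessments <- lapply(stats::setNames(future_ids, future_ids),
                        function(fid) {
    sm <- summaries[summaries$scenario_id == fid, , drop = FALSE]
    recs <- data.frame(species = sm$species_id,
                       category_start = start_cat[sm$species_id],
                       net_change_pct = sm$net_change_pct,
                       future_km2 = sm$future_km2)
    assess_genus(recs, config$redlist$count_ex_as_threatened)
  })

  pa_trend <- genus_pa_trend(coverages)

  manifest <- list(
    seed = seed, earth_radius_km = EARTH_RADIUS_KM,
    package_version = as.character(utils::packageVersion("sdmrisk")),
    species = species_ids, retained_layers = retained,
    scenarios = future_ids, config = config[setdiff(names(config), "inputs")],
    warnings = warnings_log
  )
  result <- list(inputs = inputs, cleaning_report = cleaned$report,
                 retained_layers = retained, fits = fits,
                 habitats = habitats, summaries = summaries,
                 start_categories = start_cat, assessments = assessments,
                 pa_coverage = coverages, pa_trend = pa_trend,
                 manifest = manifest)
  if (!is.null(out_dir)) write_outputs(result, out_dir)
  result
}

write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  eval_table <- do.call(rbind, lapply(result$fits, `[[`, "eval_table"))
  wcsv(eval_table, "model_evaluation.csv")
  if (!is.null(result$summaries)) wcsv(result$summaries, "change_summary.csv")
  wcsv(result$pa_coverage, "pa_coverage.csv")
  wcsv(result$pa_trend, "pa_trend.csv")
  wcsv(result$cleaning_report, "cleaning_report.csv")
  for (fid in names(result$assessments)) {
    wcsv(result$assessments[[fid]]$assessments,
         paste0("assessment_", fid, ".csv"))
    tr <- as.data.frame(result$assessments[[fid]]$transitions)
    names(tr) <- c("category_start", "category_end", "n_species")
    wcsv(tr, paste0("transitions_", fid, ".csv"))
  }
  for (scn in names(result$habitats)) {
    for (sp in names(result$habitats[[scn]])) {
      write_asc(result$habitats[[scn]][[sp]],
                file.path(out_dir, sprintf("habitat_%s_%s.asc", sp, scn)))
    }
  }
  write_mask_geojson(result$inputs$pa, file.path(out_dir, "pa_mask.geojson"))
  manifest <- result$manifest
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Human-readable run summary
#'
#' @param result output of [run_pipeline()].
#' @param file optional path; default prints to the console.
#' @return the report lines, invisibly.
#' @export
write_report <- function(result, file = "") {
  lines <- c("=== sdmrisk run report ===",
             sprintf("seed: %d | species: %d | scenarios: %s",
                     result$manifest$seed, length(result$manifest$species),
                     paste(result$manifest$scenarios, collapse = ", ")),
             sprintf("retained layers: %s",
                     paste(result$retained_layers, collapse = ", ")), "")
  if (!is.null(result$summaries)) {
    for (i in seq_len(nrow(result$summaries))) {
      s <- result$summaries[i, ]
      asmt <- result$assessments[[s$scenario_id]]$assessments
      arow <- asmt[asmt$species == s$species_id, ]
      cov <- result$pa_coverage
      crow <- cov[cov$species_id == s$species_id &
                    cov$scenario_id == s$scenario_id, ]
      lines <- c(lines, sprintf(
        "%s [%s]: current %.1f km2 -> future %.1f km2 (%+.1f%%); %s -> %s (%s); inside PA %.1f%%",
        s$species_id, s$scenario_id, s$current_km2, s$future_km2,
        ifelse(is.na(s$net_change_pct), NA, s$net_change_pct),
        arow$category_start, arow$category_end, arow$rule_fired,
        ifelse(is.na(crow$inside_pct), NA, crow$inside_pct)))
    }
  }
  lines <- c(lines, "")
  for (fid in names(result$assessments)) {
    lines <- c(lines, sprintf("threatened under %s: %d (EX: %d)", fid,
                              result$assessments[[fid]]$threatened_count,
                              result$assessments[[fid]]$ex_count))
  }
  for (i in seq_len(nrow(result$pa_trend))) {
    t <- result$pa_trend[i, ]
    lines <- c(lines, sprintf("protected habitat [%s]: %.1f km2 (%+.1f%%)",
                              t$scenario_id, t$total_inside_km2, t$change_pct))
  }
  if (nzchar(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
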