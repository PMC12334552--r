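#' Synthetic Pachypodium genus assessment table
#'
#' A worked-example input for the reclassification engine: the 20
#' Pachypodium species modelled in genus-wide climate-change assessments,
#' with their published IUCN category (NE where unassessed), a resolved
#' start category (NE species filled by a rule-based Criterion-B style
#' assessment: 7 VU, 3 NT), and projected net suitable-range change under
#' an intermediate (SSP2-4.5) and a high (SSP5-8.5) emission scenario by
#' 2100. The area and percentage values are synthetic stand-ins constructed
#' to be internally consistent with genus-level outcomes of this kind of
#' analysis (three species losing their entire range, narrow-ranged
#' Malagasy endemics contracting, coastal species expanding); they are not
#' measured values.
#'
#' @param scenario `"ssp245"` or `"ssp585"`; selects which change column is
#'   exposed as `net_change_pct`.
#' @return data.frame with columns species, category_start,
#'   net_change_pct, future_km2 (zero where the whole range is lost),
#'   ready for [assess_genus()]; plus the raw columns.
#' @export
pachypodium_example <- function(scenario = c("ssp245", "ssp585")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", "pachypodium_changes_synthetic.csv",
                      package = "sdmrisk", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pct <- df[[paste0("net_change_pct_", scenario)]]
  data.frame(
    species = df$species,
    iucn_category = df$iucn_category,
    category_start = df$category_start,
    net_change_pct = pct,
    current_km2 = df$current_km2,
    future_km2 = df$current_km2 * (1 + pct / 100)
  )
}
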