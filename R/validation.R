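#' @title Virtual-species parameter recovery
#' @name validation
#' @description A self-contained validation study: can the full modelling
#'   protocol recover a known Gaussian niche from suitability-biased samples
#'   on a simulated landscape, and does an imposed climate shift translate
#'   into the expected range contraction?
NULL

#' Run one parameter-recovery replicate
#'
#' Simulates a two-layer uncorrelated landscape, a Gaussian virtual species
#' with its optimum at the current layer mean, suitability-biased presence
#' records and uniform pseudo-absences; fits the full ensemble protocol;
#' and measures how well the ensemble recovers the true niche:
#' \itemize{
#'   \item `truth_r` — Pearson correlation between the ensemble suitability
#'     and the true suitability over valid cells;
#'   \item `truth_auc` — AUC of the ensemble suitability against the true
#'     binary habitat (`truth >= habitat_cutoff`) over the cells held out
#'     of training (not in the presence/pseudo-absence set);
#'   \item `shift_net_change_pct` — net suitable-area change after an
#'     additive `shift_sd` shift of the niche-dominant layer.
#' }
#' Ensemble skill against the *sample* labels is bounded well below 1 for a
#' broad niche (the background contains genuinely suitable cells), so this
#' study evaluates recovery against the known truth and builds the ensemble
#' from all base learners without AUC/TSS gating; gate behaviour is a
#' separate concern with its own tests.
#'
#' @param seed integer seed for the replicate.
#' @param n_rows,n_cols landscape size, default 100 x 100.
#' @param breadth niche breadth (sd in standardized layer units), default 0.7.
#' @param n_presences presence records, default 300.
#' @param n_pa pseudo-absences, default 1000.
#' @param n_reps validation splits, default 20.
#' @param shift_sd additive shift applied to the first layer (in layer sd
#'   units, = layer units after standardization), default 1.5.
#' @param habitat_cutoff binarization cutoff, default 0.6.
#' @param combiner ensemble combiner to score, default `"EMca"`.
#' @return one-row data.frame with `truth_r`, `truth_auc`,
#'   `shift_net_change_pct`, `sample_auc` (the pooled held-out AUC against
#'   sample labels, for reference) and `seed`.
#' @export
parameter_recovery_study <- function(seed, n_rows = 100, n_cols = 100,
                                     breadth = 0.7, n_presences = 300,
                                     n_pa = 1000, n_reps = 20,
                                     shift_sd = 1.5, habitat_cutoff = 0.6,
                                     combiner = "EMca") {
  grid <- grid_spec(n_rows, n_cols, 2.5 / 60, lat_top = -15, lon_left = 44)
  land <- make_landscape(grid, 2, autocorrelation_range_cells = 5,
                         seed = sub_seed(seed, "landscape"),
                         layer_names = c("bio12", "bio15"))
  vs <- virtual_species_spec("virtual", c(bio12 = 0, bio15 = 0),
                             c(bio12 = breadth, bio15 = breadth))
  truth <- true_suitability(vs, land)
  occ <- sample_presences(truth, n_presences,
                          seed = sub_seed(seed, "presences"))
  pa <- build_pa_set(occ, land, n_pa = n_pa,
                     seed = sub_seed(seed, "pseudo_absence"))
  fit <- ensemble_sdm(pa, land, n_reps = n_reps, gate_auc = 0, gate_tss = -1,
                      seed = sub_seed(seed, "ensemble"))
  ens <- fit$ensembles[[combiner]]
  ok <- !is.na(ens$map$values)
  truth_r <- stats::cor(ens$map$values[ok], truth$values[ok])
  held <- setdiff(which(ok), pa$cells)
  truth_auc <- auc(ens$map$values[held],
                   as.integer(truth$values[held] >= habitat_cutoff))
  fut <- perturb_climate(land, c(bio12 = shift_sd), "shifted")
  hab_cur <- binarize(ens$map, habitat_cutoff)
  hab_fut <- binarize(combine_ensemble(fit$members, combiner, fut,
                                       "virtual")$map, habitat_cutoff)
  cs <- change_summary(hab_cur, hab_fut)
  data.frame(seed = seed, truth_r = truth_r, truth_auc = truth_auc,
             sample_auc = ens$eval$auc,
             shift_net_change_pct = cs$net_change_pct)
}
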