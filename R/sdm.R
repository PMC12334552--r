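#' @title Ensemble habitat-suitability modelling
#' @name sdm_ensemble
#' @description The modelling protocol: pseudo-absence generation, repeated
#'   stratified 70/30 validation, five base learners (GLM, CTA, GBM, RF and
#'   a MAXENT-style regularized logistic model), AUC/TSS gating, four
#'   ensemble combiners (mean, median, committee averaging, TSS-weighted
#'   mean), combiner selection and permutation variable importance.
NULL

SDM_ALGORITHMS <- c("GLM", "CTA", "GBM", "RF", "MAXENT")

#' Presence / pseudo-absence training set
#'
#' @param species_id species label.
#' @param cells 1-based linear cell index of each row.
#' @param features numeric matrix (rows = points, columns = retained layers).
#' @param labels 0/1 vector (1 = presence).
#' @param provenance character vector describing each row's origin.
#' @return a `presence_absence_set`.
#' @export
presence_absence_set <- function(species_id, cells, features, labels,
                                 provenance = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), length(cells) == length(labels))
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1) {
    stop("need at least one presence and one pseudo-absence")
  }
  if (is.null(provenance)) {
    provenance <- ifelse(labels == 1, "presence", "pseudo_absence")
  }
  structure(list(species_id = species_id, cells = cells, features = features,
                 labels = as.integer(labels), provenance = provenance),
            class = "presence_absence_set")
}

#' Sample pseudo-absence cells
#'
#' Uniform draw without replacement from the valid cells that contain no
#' presence record.
#'
#' @param grid a [grid_spec()].
#' @param presences occurrence data.frame (species, lon, lat) or a vector of
#'   presence cell indices.
#' @param n_pa number of pseudo-absences.
#' @param seed integer seed.
#' @param valid optional logical vector marking usable cells (default all).
#' @return integer vector of cell indices.
#' @export
sample_pseudo_absences <- function(grid, presences, n_pa, seed = 1,
                                   valid = NULL) {
  stopifnot(n_pa >= 1)
  pres_cells <- if (is.data.frame(presences)) {
    point_to_cell(presences$lon, presences$lat, grid)$cell
  } else {
    as.integer(presences)
  }
  ok <- rep(TRUE, grid$n_rows * grid$n_cols)
  if (!is.null(valid)) ok <- ok & valid
  ok[pres_cells[!is.na(pres_cells)]] <- FALSE
  candidates <- which(ok)
  if (length(candidates) < n_pa) {
    stop("not enough empty cells for ", n_pa, " pseudo-absences")
  }
  with_seed(seed, sort(sample(candidates, n_pa)))
}

#' Build a presence/pseudo-absence set from occurrences and a stack
#'
#' Presence rows are the unique occupied cells; pseudo-absence rows are a
#' uniform draw from the remaining valid cells.
#'
#' @param occurrences occurrence data.frame for one species.
#' @param stack an [env_stack()] (the "current" scenario).
#' @param layer_names retained layers used as features.
#' @param n_pa number of pseudo-absences; default `max(1000, 10 * n_presence)`.
#' @param seed integer seed.
#' @return a [presence_absence_set()].
#' @export
build_pa_set <- function(occurrences, stack, layer_names = names(stack$layers),
                         n_pa = NULL, seed = 1) {
  grid <- stack$grid
  species_id <- unique(occurrences$species)
  stopifnot(length(species_id) == 1)
  cells <- point_to_cell(occurrences$lon, occurrences$lat, grid)$cell
  cells <- sort(unique(cells[!is.na(cells)]))
  ok <- valid_cells(stack)
  cells <- cells[ok[cells]]
  if (length(cells) == 0) stop("no presence falls on a valid grid cell")
  if (is.null(n_pa)) n_pa <- max(1000, 10 * length(cells))
  pa_cells <- sample_pseudo_absences(grid, cells, n_pa, seed, valid = ok)
  all_cells <- c(cells, pa_cells)
  x <- stack_matrix(stack, layer_names)[all_cells, , drop = FALSE]
  presence_absence_set(species_id, all_cells, x,
                       c(rep(1L, length(cells)), rep(0L, length(pa_cells))))
}

#' Repeated stratified train/test splits
#'
#' `n_reps` independent random splits; within each class a `train_frac`
#' share (rounded) goes to training, the rest to testing, so every test set
#' contains at least one example of each class.
#'
#' @param labels 0/1 vector (or a [presence_absence_set()]).
#' @param train_frac training fraction, default 0.7.
#' @param n_reps number of repetitions, default 20.
#' @param seed integer seed.
#' @return list of `n_reps` lists with integer index vectors `train`, `test`.
#' @export
cv_splits <- function(labels, train_frac = 0.7, n_reps = 20, seed = 1) {
  if (inherits(labels, "presence_absence_set")) labels <- labels$labels
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == 0)
  if (length(idx_pos) < 2 || length(idx_neg) < 2) {
    stop("each class needs at least 2 rows to split")
  }
  n_tr_pos <- min(max(round(train_frac * length(idx_pos)), 1),
                  length(idx_pos) - 1)
  n_tr_neg <- min(max(round(train_frac * length(idx_neg)), 1),
                  length(idx_neg) - 1)
  with_seed(seed, lapply(seq_len(n_reps), function(r) {
    tr <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
    list(train = sort(tr), test = sort(setdiff(seq_along(labels), tr)))
  }))
}

# ---- base learners ---------------------------------------------------------

# linear + quadratic + pairwise-product basis for the MAXENT-style learner
expand_basis <- function(x) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(x)))
  out <- list(x, x^2)
  names_out <- c(nm, paste0(nm, "_sq"))
  if (ncol(x) >= 2) {
    pr <- utils::combn(seq_len(ncol(x)), 2)
    out[[3]] <- apply(pr, 2, function(ij) x[, ij[1]] * x[, ij[2]])
    names_out <- c(names_out,
                   apply(pr, 2, function(ij) paste(nm[ij], collapse = "_x_")))
  }
  m <- do.call(cbind, out)
  colnames(m) <- names_out
  m
}

#' Fit one base suitability model
#'
#' The five supported algorithm families and their implementations:
#' `GLM` (binomial linear logistic), `CTA` (classification tree), `GBM`
#' (gradient-boosted trees), `RF` (random forest), `MAXENT` (ridge-penalized
#' logistic regression on a linear + quadratic + pairwise-product feature
#' basis, the standard presence/background approximation). Every fitted
#' model maps a feature vector to a score in `[0, 1]` and is deterministic
#' given (data, hyper, seed).
#'
#' @param algorithm one of `"GLM"`, `"CTA"`, `"GBM"`, `"RF"`, `"MAXENT"`.
#' @param x feature matrix (columns named by layer).
#' @param y 0/1 labels.
#' @param hyper named list of hyperparameters: `ntree` (RF, default 200),
#'   `nrounds`/`max_depth`/`eta` (GBM, defaults 60/3/0.1), `lambda`
#'   (MAXENT ridge penalty, default 0.01), `cp`/`minbucket` (CTA).
#' @param seed integer seed for the stochastic learners.
#' @param replicate_id replicate label stored on the run.
#' @return a `model_run` with a `$fit` handle and `$algorithm`.
#' @export
fit_base_model <- function(algorithm, x, y, hyper = list(), seed = 1,
                           replicate_id = NA_integer_) {
  algorithm <- match.arg(algorithm, SDM_ALGORITHMS)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("degenerate single-class training set")
  sds <- apply(x, 2, stats::sd)
  fit <- if (all(sds == 0)) {
    list(kind = "constant", p = mean(y))
  } else if (algorithm == "GLM") {
    df <- data.frame(y = y, x)
    list(kind = "glm",
         obj = suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = stats::binomial())))
  } else if (algorithm == "CTA") {
    df <- data.frame(y = factor(y, levels = c(0, 1)), x)
    ctl <- rpart::rpart.control(
      cp = hyper$cp %||% 0.001, minbucket = hyper$minbucket %||% 5,
      xval = 0)
    list(kind = "rpart",
         obj = with_seed(seed, rpart::rpart(y ~ ., data = df,
                                            method = "class", control = ctl)))
  } else if (algorithm == "GBM") {
    list(kind = "xgb",
         obj = with_seed(seed, xgboost::xgb.train(
           params = list(objective = "binary:logistic",
                         max_depth = hyper$max_depth %||% 3,
                         eta = hyper$eta %||% 0.1,
                         nthread = 1),
           data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
           nrounds = hyper$nrounds %||% 60,
           verbose = 0)))
  } else if (algorithm == "RF") {
    list(kind = "rf",
         obj = with_seed(seed, randomForest::randomForest(
           x = x, y = factor(y, levels = c(0, 1)),
           ntree = hyper$ntree %||% 200)))
  } else { # MAXENT
    xb <- expand_basis(x)
    keep <- apply(xb, 2, stats::sd) > 0
    list(kind = "glmnet",
         keep = keep,
         obj = glmnet::glmnet(xb[, keep, drop = FALSE], y,
                              family = "binomial", alpha = 0,
                              lambda = hyper$lambda %||% 0.01))
  }
  structure(list(algorithm = algorithm, replicate_id = replicate_id,
                 fit = fit, layer_names = colnames(x),
                 eval = NULL, passed_gate = NA),
            class = "model_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict suitability scores for feature rows
#'
#' @param model a `model_run` from [fit_base_model()].
#' @param x feature matrix with the columns the model was trained on.
#' @return numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model$layer_names, colnames(x))
  if (!is.null(colnames(x)) && length(missing) > 0) {
    stop("features missing: ", paste(missing, collapse = ", "))
  }
  if (!is.null(colnames(x))) x <- x[, model$layer_names, drop = FALSE]
  f <- model$fit
  p <- switch(f$kind,
    constant = rep(f$p, nrow(x)),
    glm = suppressWarnings(
      stats::predict(f$obj, newdata = as.data.frame(x), type = "response")),
    rpart = rpart_prob(f$obj, x),
    xgb = stats::predict(f$obj, xgboost::xgb.DMatrix(x, nthread = 1)),
    rf = stats::predict(f$obj, x, type = "prob")[, "1"],
    glmnet = as.numeric(stats::predict(
      f$obj, expand_basis(x)[, f$keep, drop = FALSE], type = "response"))
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

rpart_prob <- function(obj, x) {
  p <- stats::predict(obj, newdata = as.data.frame(x), type = "prob")
  if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(x))
}

#' Project a fitted model over a landscape
#'
#' @param model a `model_run`.
#' @param stack an [env_stack()] with the training layers.
#' @param species_id label for the output map.
#' @return a `suitability_map`; nodata cells stay `NA`.
#' @export
predict_map <- function(model, stack, species_id = "species") {
  x <- stack_matrix(stack, model$layer_names)
  ok <- stats::complete.cases(x)
  vals <- rep(NA_real_, nrow(x))
  if (any(ok)) vals[ok] <- predict_scores(model, x[ok, , drop = FALSE])
  suitability_map(species_id, stack$scenario_id, vals, stack$grid)
}

#' Filter model runs by the performance gates
#'
#' Strict inequalities on both metrics (`auc > gate_auc` and
#' `tss > gate_tss`); input order preserved.
#'
#' @param runs list of `model_run`s carrying `$eval$auc` and `$eval$tss`.
#' @param gate_auc,gate_tss gate values, default 0.7 each.
#' @return the passing subset.
#' @export
gate_models <- function(runs, gate_auc = 0.7, gate_tss = 0.7) {
  Filter(function(r) {
    !is.null(r$eval) && r$eval$auc > gate_auc && r$eval$tss > gate_tss
  }, runs)
}

# ---- ensembles -------------------------------------------------------------

combine_scores <- function(score_matrix, method, tss_thresholds = NULL,
                           weights = NULL) {
  m <- ncol(score_matrix)
  switch(method,
    EMmean = rowMeans(score_matrix),
    EMmedian = apply(score_matrix, 1, stats::median),
    EMca = {
      stopifnot(length(tss_thresholds) == m)
      votes <- sweep(score_matrix, 2, tss_thresholds, `>=`)
      rowMeans(votes)
    },
    EMwmean = {
      stopifnot(length(weights) == m)
      w <- if (sum(weights) > 0) weights / sum(weights) else rep(1 / m, m)
      as.numeric(score_matrix %*% w)
    },
    stop("unknown ensemble method: ", method)
  )
}

#' Combine gated members into an ensemble map
#'
#' Cellwise combination of the member suitability maps: `EMmean` arithmetic
#' mean, `EMmedian` median, `EMca` committee average (each member binarized
#' at its own TSS-optimal threshold, so values are multiples of `1/m`),
#' `EMwmean` TSS-weighted mean.
#'
#' @param members list of `model_run`s that passed the gates, each carrying
#'   `$eval$tss` and `$eval$tss_threshold`.
#' @param method one of `"EMmean"`, `"EMmedian"`, `"EMca"`, `"EMwmean"`.
#' @param stack the [env_stack()] to project onto.
#' @param species_id label for the output map.
#' @return an `ensemble_result` with `method`, `member_algorithms`, `map`
#'   and (initially `NULL`) `eval`.
#' @export
combine_ensemble <- function(members, method, stack, species_id = "species") {
  if (length(members) == 0) stop("no gated members to combine")
  maps <- vapply(members, function(mr) predict_map(mr, stack, species_id)$values,
                 numeric(stack$grid$n_rows * stack$grid$n_cols))
  vals <- rep(NA_real_, nrow(maps))
  ok <- stats::complete.cases(maps)
  vals[ok] <- combine_scores(
    maps[ok, , drop = FALSE], method,
    tss_thresholds = vapply(members, function(mr) mr$eval$tss_threshold,
                            numeric(1)),
    weights = vapply(members, function(mr) mr$eval$tss, numeric(1)))
  structure(list(method = method,
                 member_algorithms = vapply(members, `[[`, character(1),
                                            "algorithm"),
                 map = suitability_map(species_id, stack$scenario_id, vals,
                                       stack$grid),
                 eval = NULL),
            class = "ensemble_result")
}

#' Select the best ensemble combiner
#'
#' Maximizes `auc + tss`; exact ties resolved by the precedence
#' EMca > EMwmean > EMmean > EMmedian.
#'
#' @param candidates list of `ensemble_result`s with `$eval`.
#' @return the selected `ensemble_result`.
#' @export
select_best_combiner <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  prec <- c(EMca = 1, EMwmean = 2, EMmean = 3, EMmedian = 4)
  score <- vapply(candidates, function(cd) cd$eval$auc + cd$eval$tss,
                  numeric(1))
  tie <- prec[vapply(candidates, `[[`, character(1), "method")]
  candidates[[order(-score, tie)[1]]]
}

#' Permutation variable importance
#'
#' For each feature, importance is `1 - cor(predictions on the original
#' data, predictions with that column permuted)`, averaged over shuffles and
#' floored at 0, then normalized to sum to one when any importance is
#' positive (all-zero importances are returned unnormalized).
#'
#' @param model a fitted `model_run`.
#' @param x feature matrix (e.g. the training features).
#' @param n_shuffles permutations per feature, default 5.
#' @param seed integer seed.
#' @return named numeric vector of importance fractions.
#' @export
variable_importance <- function(model, x, n_shuffles = 5, seed = 1) {
  stopifnot(n_shuffles >= 1)
  x <- as.matrix(x)
  p0 <- predict_scores(model, x)
  imp <- with_seed(seed, vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      xp <- x
      xp[, j] <- x[sample(nrow(x)), j]
      pj <- predict_scores(model, xp)
      if (stats::sd(p0) == 0 || stats::sd(pj) == 0) return(0)
      1 - stats::cor(p0, pj)
    }, numeric(1))
    mean(drops)
  }, numeric(1)))
  imp <- pmax(imp, 0)
  names(imp) <- colnames(x)
  if (any(imp > 0)) imp <- imp / sum(imp)
  imp
}

#' Run the full ensemble protocol for one species
#'
#' Evaluates every algorithm over `n_reps` stratified 70/30 splits, gates
#' algorithms on their mean held-out AUC and TSS (strict >), refits the
#' passing algorithms on all data, builds the four ensemble maps, scores
#' each combiner on the pooled held-out predictions, and selects the best
#' combiner by `auc + tss`.
#'
#' @param pa a [presence_absence_set()].
#' @param stack the current-scenario [env_stack()].
#' @param algorithms algorithm subset, default all five.
#' @param gate_auc,gate_tss performance gates (strict >), default 0.7.
#' @param n_reps number of validation splits, default 20.
#' @param train_frac training fraction, default 0.7.
#' @param hyper per-algorithm hyperparameter lists, e.g.
#'   `list(RF = list(ntree = 100))`.
#' @param seed integer seed.
#' @return list with `eval_table` (per algorithm x replicate), `members`
#'   (refit gated `model_run`s), `ensembles` (the four scored
#'   `ensemble_result`s), `best` (the selected combiner) and
#'   `member_summary`.
#' @export
ensemble_sdm <- function(pa, stack, algorithms = SDM_ALGORITHMS,
                         gate_auc = 0.7, gate_tss = 0.7,
                         n_reps = 20, train_frac = 0.7, hyper = list(),
                         seed = 1) {
  splits <- cv_splits(pa$labels, train_frac, n_reps,
                      sub_seed(seed, "cv_splits", pa$species_id))
  x <- pa$features
  y <- pa$labels
  eval_rows <- list()
  heldout <- list()   # [[algorithm]][[rep]] = scores on test rows
  for (alg in algorithms) {
    heldout[[alg]] <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      sp <- splits[[r]]
      run <- fit_base_model(alg, x[sp$train, , drop = FALSE], y[sp$train],
                            hyper = hyper[[alg]] %||% list(),
                            seed = sub_seed(seed, paste0("fit_", alg, "_", r),
                                            pa$species_id),
                            replicate_id = r)
      sc <- predict_scores(run, x[sp$test, , drop = FALSE])
      mt <- max_tss(sc, y[sp$test])
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        species = pa$species_id, algorithm = alg, replicate = r,
        auc = auc(sc, y[sp$test]), tss = mt$tss,
        tss_threshold = mt$threshold)
      heldout[[alg]][[r]] <- sc
    }
  }
  eval_table <- do.call(rbind, eval_rows)
  agg <- stats::aggregate(eval_table[c("auc", "tss", "tss_threshold")],
                          by = list(algorithm = eval_table$algorithm), mean)
  agg <- agg[match(algorithms, agg$algorithm), ]
  agg$passed_gate <- agg$auc > gate_auc & agg$tss > gate_tss
  passing <- agg$algorithm[agg$passed_gate]
  if (length(passing) == 0) {
    stop("no algorithm passed the AUC/TSS gates; ensemble impossible")
  }
  # refit the passing algorithms on all data; per-member eval = mean metrics
  members <- lapply(passing, function(alg) {
    run <- fit_base_model(alg, x, y, hyper = hyper[[alg]] %||% list(),
                          seed = sub_seed(seed, paste0("refit_", alg),
                                          pa$species_id),
                          replicate_id = 0L)
    a <- agg[agg$algorithm == alg, ]
    run$eval <- list(auc = a$auc, tss = a$tss,
                     tss_threshold = a$tss_threshold)
    run$passed_gate <- TRUE
    run
  })
  names(members) <- passing
  # pooled held-out combiner evaluation
  mean_tss <- agg$tss[match(passing, agg$algorithm)]
  pooled_labels <- unlist(lapply(splits, function(sp) y[sp$test]))
  ensembles <- lapply(c("EMmean", "EMmedian", "EMca", "EMwmean"),
                      function(method) {
    pooled <- unlist(lapply(seq_len(n_reps), function(r) {
      sm <- vapply(passing, function(alg) heldout[[alg]][[r]],
                   numeric(length(splits[[r]]$test)))
      th <- vapply(passing, function(alg) {
        eval_table$tss_threshold[eval_table$algorithm == alg &
                                   eval_table$replicate == r]
      }, numeric(1))
      combine_scores(sm, method, tss_thresholds = th, weights = mean_tss)
    }))
    res <- combine_ensemble(members, method, stack, pa$species_id)
    mt <- max_tss(pooled, pooled_labels)
    res$eval <- list(auc = auc(pooled, pooled_labels), tss = mt$tss,
                     tss_threshold = mt$threshold)
    res
  })
  names(ensembles) <- c("EMmean", "EMmedian", "EMca", "EMwmean")
  best <- select_best_combiner(ensembles)
  list(eval_table = eval_table, member_summary = agg, members = members,
       ensembles = ensembles, best = best)
}

#' Project an ensemble onto another scenario
#'
#' Rebuilds the selected combiner's map from the same refit members on a
#' different (e.g. future) environmental stack.
#'
#' @param fit result of [ensemble_sdm()].
#' @param stack the scenario [env_stack()].
#' @param method combiner; defaults to the selected best.
#' @return an `ensemble_result` for that scenario.
#' @export
project_ensemble <- function(fit, stack, method = fit$best$method) {
  res <- combine_ensemble(fit$members, method, stack,
                          fit$best$map$species_id)
  res$eval <- fit$ensembles[[method]]$eval
  res
}
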