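test_that("pseudo-absences avoid presence cells and are seed-stable", {
  g <- grid_spec(5, 5, 1, lat_top = 0)
  # grid fully occupied except 3 cells -> exactly those cells
  pres <- setdiff(1:25, c(4, 12, 19))
  expect_identical(sample_pseudo_absences(g, pres, 3, seed = 1),
                   c(4L, 12L, 19L))
  expect_identical(sample_pseudo_absences(g, c(1L, 2L), 10, seed = 7),
                   sample_pseudo_absences(g, c(1L, 2L), 10, seed = 7))
  expect_error(sample_pseudo_absences(g, pres, 4), "not enough")

  # uniformity over an empty grid: all cells selected with similar frequency
  g2 <- grid_spec(10, 10, 1, lat_top = 0)
  counts <- integer(100)
  for (s in 1:200) {
    drawn <- sample_pseudo_absences(g2, integer(0), 50, seed = s)
    counts[drawn] <- counts[drawn] + 1
  }
  # each cell's count ~ Binomial(200, 0.5); 99.9% bounds
  expect_true(all(counts > 100 - 3.3 * sqrt(200 * 0.25) &
                    counts < 100 + 3.3 * sqrt(200 * 0.25)))
})

test_that("cv splits are stratified partitions", {
  labels <- c(rep(1, 10), rep(0, 10))
  sp <- cv_splits(labels, 0.7, 20, seed = 3)
  expect_length(sp, 20)
  expect_gt(length(unique(vapply(sp, function(s) paste(s$train, collapse = ","),
                                 character(1)))), 1)
  for (s in sp) {
    expect_identical(sort(c(s$train, s$test)), 1:20)
    expect_identical(sum(labels[s$train] == 1), 7L)
    expect_identical(sum(labels[s$train] == 0), 7L)
    expect_identical(length(s$test), 6L)
  }
  expect_error(cv_splits(c(1, 0, 0, 0), 0.7, 2), "at least 2")
})

test_that("every algorithm separates a linearly separable set perfectly", {
  set.seed(13)
  d <- make_separable(30)
  for (alg in c("GLM", "CTA", "GBM", "RF", "MAXENT")) {
    run <- fit_base_model(alg, d$x, d$y, seed = 1)
    expect_equal(auc(predict_scores(run, d$x), d$y), 1, info = alg)
  }
})

test_that("constant features give constant predictions", {
  x <- matrix(1, nrow = 40, ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 20)
  for (alg in c("GLM", "CTA", "GBM", "RF", "MAXENT")) {
    run <- fit_base_model(alg, x, y, seed = 1)
    expect_length(unique(predict_scores(run, x)), 1)
  }
  expect_error(fit_base_model("GLM", x, rep(1L, 40)), "single-class")
})

test_that("a GLM on labels independent of features stays near chance", {
  set.seed(17)
  x <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "a"))
  y <- rbinom(400, 1, 0.5)
  tr <- 1:280
  run <- fit_base_model("GLM", x[tr, , drop = FALSE], y[tr])
  a <- auc(predict_scores(run, x[-tr, , drop = FALSE]), y[-tr])
  expect_gt(a, 0.35)
  expect_lt(a, 0.65)
})

test_that("map projection propagates nodata and respects monotone models", {
  g <- grid_spec(4, 5, 1, lat_top = 0)
  vals <- c(seq(-2, 2, length.out = 19), NA)
  st <- env_stack(list(env_layer("a", vals, g)))
  set.seed(19)
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "a"))
  y <- as.integer(x[, 1] + rnorm(60, sd = 0.3) > 0)
  run <- fit_base_model("GLM", x, y)
  m <- predict_map(run, st)
  expect_true(is.na(m$values[20]))
  finite <- m$values[1:19]
  expect_true(all(diff(finite) > 0))       # monotone in the single layer
  # projecting onto an identical copy gives an identical map
  st2 <- env_stack(list(env_layer("a", vals, g)), scenario_id = "current")
  expect_identical(predict_map(run, st2)$values, m$values)
  expect_error(predict_map(run, env_stack(list(env_layer("zz", vals, g)))),
               "layers not in stack")
})

fake_run <- function(alg, auc, tss, threshold = 0.5) {
  structure(list(algorithm = alg, replicate_id = 1L,
                 fit = list(kind = "constant", p = 0.5),
                 layer_names = "a",
                 eval = list(auc = auc, tss = tss, tss_threshold = threshold),
                 passed_gate = NA),
            class = "model_run")
}

test_that("gates are strict on both metrics and preserve order", {
  runs <- list(fake_run("GLM", 0.7, 0.9),    # auc exactly at gate: out
               fake_run("RF", 0.9, 0.69),    # tss below: out
               fake_run("GBM", 0.71, 0.71),
               fake_run("CTA", 0.9, 0.9))
  kept <- gate_models(runs)
  expect_identical(vapply(kept, `[[`, character(1), "algorithm"),
                   c("GBM", "CTA"))
  expect_length(gate_models(runs, 0.5, 0.5), 4)
})

test_that("ensemble combiners follow their definitions", {
  g <- grid_spec(1, 4, 1, lat_top = 0)
  st <- env_stack(list(env_layer("a", c(-1, 0, 1, 2), g)))
  d <- make_tiny_study(seed = 77, n = 12, n_presences = 40, n_pa = 60)
  fit <- ensemble_sdm(d$pa, d$land, n_reps = 3, gate_auc = 0, gate_tss = -1,
                      seed = 5)
  m <- length(fit$members)
  for (meth in names(fit$ensembles)) {
    v <- fit$ensembles[[meth]]$map$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE), info = meth)
  }
  ca <- fit$ensembles$EMca$map$values
  expect_true(all(abs(ca * m - round(ca * m)) < 1e-9, na.rm = TRUE))

  # EMwmean weights proportional to member TSS: check against direct formula
  maps <- vapply(fit$members, function(mr) predict_map(mr, d$land)$values,
                 numeric(12 * 12))
  tss <- vapply(fit$members, function(mr) mr$eval$tss, numeric(1))
  w <- tss / sum(tss)
  expect_equal(fit$ensembles$EMwmean$map$values,
               as.numeric(maps %*% w), tolerance = 1e-12)
  expect_equal(fit$ensembles$EMmean$map$values, rowMeans(maps))
  expect_equal(fit$ensembles$EMmedian$map$values,
               apply(maps, 1, median))
  # identical members: all methods reproduce the member map (EMca binarized)
  one <- fit$members[[1]]
  twin <- list(one, one)
  mm <- combine_ensemble(twin, "EMmean", d$land, "s")$map$values
  expect_equal(mm, predict_map(one, d$land)$values)
  caa <- combine_ensemble(twin, "EMca", d$land, "s")$map$values
  expect_true(all(caa %in% c(0, 1)))
})

test_that("the best combiner maximizes auc + tss with EMca precedence", {
  mk <- function(method, auc, tss) {
    structure(list(method = method, eval = list(auc = auc, tss = tss)),
              class = "ensemble_result")
  }
  a <- mk("EMmean", 0.9, 0.8)
  b <- mk("EMwmean", 0.85, 0.7)
  expect_identical(select_best_combiner(list(b, a))$method, "EMmean")
  expect_identical(select_best_combiner(list(a))$method, "EMmean")
  tie <- list(mk("EMmedian", 0.8, 0.8), mk("EMca", 0.8, 0.8),
              mk("EMwmean", 0.8, 0.8))
  expect_identical(select_best_combiner(tie)$method, "EMca")
})

test_that("permutation importance isolates the informative layer", {
  set.seed(23)
  x <- cbind(a = rnorm(300), b = rnorm(300))
  y <- as.integer(x[, "a"] > 0)
  run <- fit_base_model("GLM", x, y)
  vi <- variable_importance(run, x, n_shuffles = 5, seed = 2)
  expect_equal(sum(vi), 1)
  expect_gt(vi[["a"]], 0.95)
  expect_lt(vi[["b"]], 0.05)
  # a constant model has no importance to distribute
  const <- fit_base_model("CTA", cbind(a = rep(1, 40), b = rep(2, 40)),
                          rep(c(0L, 1L), 20))
  expect_identical(unname(variable_importance(const, cbind(a = rnorm(40),
                                                           b = rnorm(40)),
                                              n_shuffles = 2)), c(0, 0))
})

test_that("the full protocol is deterministic per seed", {
  d <- make_tiny_study(seed = 99, n = 15, n_presences = 40, n_pa = 80)
  f1 <- ensemble_sdm(d$pa, d$land, algorithms = c("GLM", "CTA", "MAXENT"),
                     n_reps = 3, gate_auc = 0, gate_tss = -1, seed = 8)
  f2 <- ensemble_sdm(d$pa, d$land, algorithms = c("GLM", "CTA", "MAXENT"),
                     n_reps = 3, gate_auc = 0, gate_tss = -1, seed = 8)
  expect_identical(f1$eval_table, f2$eval_table)
  expect_identical(f1$best$map$values, f2$best$map$values)
})
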