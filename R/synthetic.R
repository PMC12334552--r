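#' @title Virtual landscapes and virtual species
#' @name synthetic_data
#' @description Generators for spatially autocorrelated environmental
#'   layers, Gaussian-niche virtual species, suitability-biased occurrence
#'   samples, additive future-climate scenarios and blocky protected-area
#'   masks. Every generator is a pure function of its spec and seed, so the
#'   whole downstream pipeline can be exercised against known truth.
NULL

# box-filter smoothing with edge-normalized counts, separable in rows/cols
smooth_box <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- 2 * radius + 1
  run <- function(x) {
    cs <- cumsum(c(0, x))
    n <- length(x)
    lo <- pmax(seq_len(n) - radius, 1)
    hi <- pmin(seq_len(n) + radius, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- t(apply(m, 1, run))
  t(apply(t(m), 1, run))
}

#' Generate a spatially autocorrelated landscape
#'
#' Each layer is independent Gaussian white noise smoothed with a square
#' moving-average window of the stated radius (in cells), then standardized
#' to zero mean and unit variance. Deterministic per seed.
#'
#' @param grid a [grid_spec()].
#' @param n_layers number of layers (>= 1).
#' @param autocorrelation_range_cells moving-average radius in cells (>= 0;
#'   0 gives white noise).
#' @param seed integer seed.
#' @param layer_names names for the layers; defaults to bioclim-style
#'   `"bio1"`, `"bio2"`, ...
#' @return an [env_stack()] with `scenario_id = "current"`.
#' @export
make_landscape <- function(grid, n_layers, autocorrelation_range_cells = 0,
                           seed = 1,
                           layer_names = paste0("bio", seq_len(n_layers))) {
  stopifnot(n_layers >= 1, autocorrelation_range_cells >= 0,
            length(layer_names) == n_layers)
  if (grid$n_rows * grid$n_cols == 0) stop("zero-size grid")
  layers <- with_seed(seed, lapply(seq_len(n_layers), function(l) {
    m <- matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                nrow = grid$n_rows, ncol = grid$n_cols)
    m <- smooth_box(m, round(autocorrelation_range_cells))
    v <- as.numeric(t(m))                      # row-major
    v <- (v - mean(v)) / stats::sd(v)
    env_layer(layer_names[l], v, grid)
  }))
  env_stack(layers, scenario_id = "current")
}

#' Apply additive shifts to make a future scenario
#'
#' @param stack an [env_stack()].
#' @param deltas named numeric vector/list of per-layer additive shifts;
#'   layers not named are copied unchanged.
#' @param scenario_id label for the new stack (e.g. `"ssp585"`).
#' @return a new [env_stack()].
#' @export
perturb_climate <- function(stack, deltas, scenario_id) {
  deltas <- unlist(deltas)
  unknown <- setdiff(names(deltas), names(stack$layers))
  if (length(unknown) > 0) {
    stop("deltas name unknown layer(s): ", paste(unknown, collapse = ", "))
  }
  layers <- lapply(stack$layers, function(l) {
    d <- if (l$name %in% names(deltas)) deltas[[l$name]] else 0
    env_layer(l$name, l$values + d, l$grid)
  })
  env_stack(layers, scenario_id = scenario_id)
}

#' Define a Gaussian-niche virtual species
#'
#' @param species_id label.
#' @param optima named numeric vector of niche optima (layer units).
#' @param breadths named numeric vector of niche breadths (sd, > 0), same
#'   names as `optima`.
#' @return a `virtual_species_spec`.
#' @export
virtual_species_spec <- function(species_id, optima, breadths) {
  stopifnot(setequal(names(optima), names(breadths)), all(breadths > 0))
  structure(list(species_id = species_id, optima = optima,
                 breadths = breadths[names(optima)]),
            class = "virtual_species_spec")
}

#' True suitability of a virtual species on a landscape
#'
#' Cellwise product over the referenced layers of the bell curve
#' `exp(-(x - mu)^2 / (2 sigma^2))`, rescaled so the maximum over valid
#' cells is 1 (niche intersection across layers).
#'
#' @param vspec a [virtual_species_spec()].
#' @param stack an [env_stack()] containing every referenced layer.
#' @return a `suitability_map` (values in `[0, 1]`, `NA` on nodata cells).
#' @export
true_suitability <- function(vspec, stack) {
  x <- stack_matrix(stack, names(vspec$optima))
  z <- sweep(x, 2, vspec$optima, `-`)
  z <- sweep(z, 2, vspec$breadths, `/`)
  s <- exp(-rowSums(z^2) / 2)
  mx <- max(s, na.rm = TRUE)
  if (mx > 0) s <- s / mx
  suitability_map(vspec$species_id, stack$scenario_id, s, stack$grid)
}

#' A continuous suitability surface
#'
#' @param species_id,scenario_id labels.
#' @param values numeric vector in `[0, 1]`, row-major, `NA` = nodata.
#' @param grid a [grid_spec()].
#' @return a `suitability_map`.
#' @export
suitability_map <- function(species_id, scenario_id, values, grid) {
  if (length(values) != grid$n_rows * grid$n_cols) {
    stop("suitability length does not match grid")
  }
  if (any(!is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("suitability values must lie in [0, 1]")
    }
  }
  structure(list(species_id = species_id, scenario_id = scenario_id,
                 values = pmin(pmax(values, 0), 1), grid = grid),
            class = "suitability_map")
}

#' Sample presence records biased by suitability
#'
#' Cells are drawn with probability proportional to suitability (with
#' replacement, emulating repeat collections) and each record is jittered
#' uniformly within its cell, so downstream cleaning/deduplication has
#' realistic work to do.
#'
#' @param truth a `suitability_map` with at least one positive cell.
#' @param n_target number of records to generate.
#' @param seed integer seed.
#' @param species_id species label; defaults to the map's.
#' @return occurrence data.frame (species, lon, lat, source = "synthetic").
#' @export
sample_presences <- function(truth, n_target, seed = 1,
                             species_id = truth$species_id) {
  if (n_target == 0) {
    return(data.frame(species = character(0), lon = numeric(0),
                      lat = numeric(0), source = character(0)))
  }
  w <- truth$values
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("all-zero suitability: cannot sample presences")
  with_seed(seed, {
    cells <- sample.int(length(w), n_target, replace = TRUE, prob = w)
    ctr <- cell_center(cells, truth$grid)
    half <- truth$grid$res_deg / 2
    data.frame(
      species = species_id,
      lon = ctr$lon + stats::runif(n_target, -half, half),
      lat = ctr$lat + stats::runif(n_target, -half, half),
      source = "synthetic"
    )
  })
}

#' Protected-area mask
#'
#' @param covered logical vector, row-major.
#' @param grid a [grid_spec()].
#' @param source label describing provenance.
#' @return a `pa_mask`.
#' @export
pa_mask <- function(covered, grid, source = "mask") {
  if (length(covered) != grid$n_rows * grid$n_cols) {
    stop("mask length does not match grid")
  }
  structure(list(covered = as.logical(covered), grid = grid, source = source),
            class = "pa_mask")
}

#' Generate a blocky protected-area mask
#'
#' Unions `n_blocks` random rectangles, then trims or grows the last block
#' until the covered-cell fraction is within +/- 2 percentage points of the
#' target. Deterministic per seed.
#'
#' @param grid a [grid_spec()].
#' @param coverage_frac target covered fraction in `[0, 1]`.
#' @param n_blocks number of rectangles.
#' @param seed integer seed.
#' @return a `pa_mask`.
#' @export
make_pa_mask <- function(grid, coverage_frac, n_blocks = 5, seed = 1) {
  stopifnot(coverage_frac >= 0, coverage_frac <= 1)
  nr <- grid$n_rows; nc <- grid$n_cols
  if (coverage_frac == 0) return(pa_mask(rep(FALSE, nr * nc), grid, "synthetic"))
  if (coverage_frac == 1) return(pa_mask(rep(TRUE, nr * nc), grid, "synthetic"))
  if (n_blocks < 1) stop("coverage > 0 requires n_blocks >= 1")
  with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    target <- coverage_frac * nr * nc
    # aim each block at roughly its share of the target area
    side <- max(1, round(sqrt(target / n_blocks)))
    for (b in seq_len(n_blocks)) {
      h <- max(1, min(nr, round(side * stats::runif(1, 0.6, 1.6))))
      w <- max(1, min(nc, round(side * stats::runif(1, 0.6, 1.6))))
      i0 <- sample.int(nr - h + 1, 1)
      j0 <- sample.int(nc - w + 1, 1)
      m[i0:(i0 + h - 1), j0:(j0 + w - 1)] <- TRUE
    }
    # trim or grow random single cells until within +/- 2 points of target
    tol <- 0.02 * nr * nc
    excess <- sum(m) - target
    if (excess > tol) {
      on <- which(m)
      m[sample(on, ceiling(excess))] <- FALSE
    } else if (-excess > tol) {
      m[sample(which(!m), ceiling(-excess))] <- TRUE
    }
    pa_mask(as.logical(t(m)), grid, "synthetic")
  })
}

#' Lag-1 neighbor correlation of a layer
#'
#' Pearson correlation between horizontally and vertically adjacent cell
#' pairs; a cheap Moran-style measure of spatial autocorrelation used to
#' verify landscape generation.
#'
#' @param layer an [env_layer()].
#' @return correlation in `[-1, 1]`.
#' @export
neighbor_correlation <- function(layer) {
  g <- layer$grid
  m <- matrix(layer$values, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  h <- cbind(as.numeric(m[, -g$n_cols]), as.numeric(m[, -1]))
  v <- cbind(as.numeric(m[-g$n_rows, ]), as.numeric(m[-1, ]))
  p <- rbind(h, v)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  stats::cor(p[, 1], p[, 2])
}
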