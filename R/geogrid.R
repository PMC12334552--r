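#' @title Grid geometry and area-true accounting
#' @name geogrid
#' @description Raster grid geometry on a WGS84 latitude/longitude grid,
#'   spherical cell areas, collinearity filtering of environmental layers,
#'   and the Fisher-Jenks natural-breaks classifier.
NULL

#' IUGG mean Earth radius in kilometres
#'
#' Used for all spherical area accounting; recorded in output metadata.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Define a latitude/longitude grid
#'
#' Cell-center registered grid: row 0 is the northernmost row, indices are
#' 0-based, and the center of cell (i, j) lies at
#' `lat_top - (i + 0.5) * res_deg`, `lon_left + (j + 0.5) * res_deg`.
#' Point-to-cell assignment uses half-open intervals `[west, east)` in
#' longitude and `(south, north]` in latitude.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param res_deg cell edge in degrees (> 0), e.g. `2.5 / 60` for a
#'   2.5-arc-minute grid.
#' @param lat_top latitude of the grid's northern edge (degrees).
#' @param lon_left longitude of the grid's western edge (degrees).
#' @param nodata sentinel value used when rasters are written to disk.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, res_deg, lat_top = 0, lon_left = 0,
                      nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, res_deg > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         res_deg = res_deg, lat_top = lat_top, lon_left = lon_left,
         nodata = nodata),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6g deg, top-left (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$res_deg, x$lat_top, x$lon_left))
  invisible(x)
}

grid_conformant <- function(grid_a, grid_b, tol = 1e-9) {
  grid_a$n_rows == grid_b$n_rows && grid_a$n_cols == grid_b$n_cols &&
    abs(grid_a$res_deg - grid_b$res_deg) < tol &&
    abs(grid_a$lat_top - grid_b$lat_top) < tol &&
    abs(grid_a$lon_left - grid_b$lon_left) < tol
}

stop_if_not_conformant <- function(grid_a, grid_b) {
  if (!grid_conformant(grid_a, grid_b)) {
    stop("grids are not conformant (dimensions or registration differ)")
  }
  invisible(TRUE)
}

#' Row/column of the cell containing a point
#'
#' Half-open convention: a point on a cell's western edge belongs to that
#' cell, as does a point on its northern edge.
#'
#' @param lon,lat point coordinates (degrees); vectors of equal length.
#' @param grid a [grid_spec()].
#' @return data.frame with 0-based `row`, `col` and the linear `cell` index
#'   (row-major, 1-based, as used by layer value vectors); `NA` for points
#'   outside the grid.
#' @export
point_to_cell <- function(lon, lat, grid) {
  col <- floor((lon - grid$lon_left) / grid$res_deg)
  row <- floor((grid$lat_top - lat) / grid$res_deg)
  # northern grid edge is inclusive
  row[!is.na(lat) & lat == grid$lat_top] <- 0
  bad <- is.na(row) | is.na(col) | row < 0 | row >= grid$n_rows |
    col < 0 | col >= grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer(row * grid$n_cols + col + 1L))
}

#' Coordinates of cell centers
#'
#' @param cell 1-based row-major linear cell indices.
#' @param grid a [grid_spec()].
#' @return data.frame with `lon`, `lat` of each cell center.
#' @export
cell_center <- function(cell, grid) {
  i <- (cell - 1L) %/% grid$n_cols
  j <- (cell - 1L) %% grid$n_cols
  data.frame(lon = grid$lon_left + (j + 0.5) * grid$res_deg,
             lat = grid$lat_top - (i + 0.5) * grid$res_deg)
}

#' Spherical area of one grid cell
#'
#' Area of the spherical zone slice `R^2 * dlam * (sin phi_n - sin phi_s)`
#' for the cell row; equal for all cells in one row.
#'
#' @param row_index 0-based row index (vectorized).
#' @param grid a [grid_spec()].
#' @param earth_radius_km sphere radius; defaults to the IUGG mean radius.
#' @return cell area in km^2.
#' @export
cell_area_km2 <- function(row_index, grid, earth_radius_km = EARTH_RADIUS_KM) {
  if (any(row_index < 0 | row_index >= grid$n_rows)) {
    stop("row_index outside grid")
  }
  lat_n <- (grid$lat_top - row_index * grid$res_deg) * pi / 180
  lat_s <- (grid$lat_top - (row_index + 1) * grid$res_deg) * pi / 180
  dlam <- grid$res_deg * pi / 180
  earth_radius_km^2 * dlam * (sin(lat_n) - sin(lat_s))
}

#' Per-cell areas for a whole grid
#'
#' @param grid a [grid_spec()].
#' @return numeric vector of length `n_rows * n_cols`, row-major.
#' @export
grid_cell_areas <- function(grid) {
  rep(cell_area_km2(seq_len(grid$n_rows) - 1L, grid), each = grid$n_cols)
}

#' Area of a binary mask in km^2
#'
#' @param mask logical vector (row-major, `length == n_rows * n_cols`) or a
#'   [binary_habitat_map()] / [pa_mask()] object. `NA` cells count as FALSE.
#' @param grid a [grid_spec()]; taken from the object when omitted.
#' @return total spherical area of the TRUE cells, km^2.
#' @export
masked_area_km2 <- function(mask, grid = NULL) {
  if (is.list(mask) && !is.null(mask$grid)) {
    if (!is.null(grid)) stop_if_not_conformant(grid, mask$grid)
    grid <- mask$grid
    mask <- if (!is.null(mask$suitable)) mask$suitable else mask$covered
  }
  if (length(mask) != grid$n_rows * grid$n_cols) {
    stop("mask length does not match grid dimensions")
  }
  sum(grid_cell_areas(grid)[which(mask)])
}

# ---- environmental layers --------------------------------------------------

#' Construct an environmental layer
#'
#' @param name layer identifier, bioclim convention (`"bio12"`, `"bio6"`, ...).
#' @param values numeric vector, row-major, `NA` for nodata cells.
#' @param grid a [grid_spec()].
#' @return an `env_layer` object.
#' @export
env_layer <- function(name, values, grid) {
  if (length(values) != grid$n_rows * grid$n_cols) {
    stop("layer '", name, "': values length does not match grid")
  }
  structure(list(name = name, values = as.numeric(values), grid = grid),
            class = "env_layer")
}

#' Construct a stack of environmental layers
#'
#' All layers must share one grid and have unique names.
#'
#' @param layers list of [env_layer()] objects.
#' @param scenario_id scenario label (`"current"`, `"ssp245"`, `"ssp585"`).
#' @return an `env_stack` object.
#' @export
env_stack <- function(layers, scenario_id = "current") {
  stopifnot(length(layers) >= 1)
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique")
  grid <- layers[[1]]$grid
  for (l in layers) stop_if_not_conformant(grid, l$grid)
  names(layers) <- nms
  structure(list(layers = layers, grid = grid, scenario_id = scenario_id),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack '%s': %d layer(s) [%s] on %d x %d grid\n",
              x$scenario_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Layer values as a cells-by-layers matrix
#'
#' @param stack an [env_stack()].
#' @param layer_names subset/order of layers; default all.
#' @return numeric matrix, one column per layer.
#' @export
stack_matrix <- function(stack, layer_names = names(stack$layers)) {
  missing <- setdiff(layer_names, names(stack$layers))
  if (length(missing) > 0) {
    stop("layers not in stack: ", paste(missing, collapse = ", "))
  }
  do.call(cbind, lapply(stack$layers[layer_names], function(l) l$values))
}

#' Cells valid (non-nodata) in every layer of a stack
#'
#' @param stack an [env_stack()].
#' @return logical vector over cells.
#' @export
valid_cells <- function(stack) {
  stats::complete.cases(stack_matrix(stack))
}

#' Greedy collinearity filter for environmental layers
#'
#' Pairwise Pearson correlations are computed over the cells valid in all
#' layers. Pairs are scanned in decreasing `|r|`; whenever a pair still
#' exceeds the threshold, the member ranking lower in `priority` is dropped.
#' Layers with zero variance yield undefined correlations, treated as
#' `|r| = 0` with a warning.
#'
#' @param stack an [env_stack()].
#' @param threshold maximum allowed pairwise `|r|`, in (0, 1); default 0.75.
#' @param priority character vector, a permutation of the layer names;
#'   earlier entries are kept preferentially. Defaults to stack order.
#' @return character vector of retained layer names, in stack order.
#' @export
filter_collinear <- function(stack, threshold = 0.75,
                             priority = names(stack$layers)) {
  nms <- names(stack$layers)
  stopifnot(threshold > 0, threshold < 1)
  if (!setequal(priority, nms) || length(priority) != length(nms)) {
    stop("priority must be a permutation of the layer names")
  }
  if (length(nms) == 1) return(nms)
  m <- stack_matrix(stack)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning("zero-variance layer(s): ",
            paste(nms[sds == 0 | is.na(sds)], collapse = ", "),
            "; their correlations treated as 0")
  }
  cm <- suppressWarnings(stats::cor(m))
  cm[!is.finite(cm)] <- 0
  rank_of <- match(nms, priority)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  ord <- order(-abs(cm[pairs]), pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  alive <- rep(TRUE, length(nms))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (!alive[i] || !alive[j]) next
    if (abs(cm[i, j]) > threshold) {
      drop <- if (rank_of[i] > rank_of[j]) i else j
      alive[drop] <- FALSE
    }
  }
  nms[alive]
}

# ---- Fisher-Jenks natural breaks -------------------------------------------

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification into `k` contiguous classes minimizing the
#' total within-class sum of squared deviations, by dynamic programming over
#' the sorted values. Among optimal partitions, the one with the smallest
#' first break (then second, ...) is returned.
#'
#' @param values numeric vector; must contain at least `k` distinct values.
#' @param k number of classes (>= 1).
#' @return numeric vector of `k - 1` ascending internal break values, each
#'   the midpoint between the last value of one class and the first value of
#'   the next (empty for `k = 1`). The class of a value `v` is
#'   `1 + sum(v > breaks)`.
#' @export
jenks_breaks <- function(values, k) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (k < 1) stop("k must be >= 1")
  if (length(unique(v)) < k) stop("k exceeds the number of distinct values")
  if (k == 1) return(numeric(0))
  s1 <- c(0, cumsum(v)); s2 <- c(0, cumsum(v^2))
  # ssd of v[i..j], vectorized over i or j (padded prefix sums)
  ssd <- function(i, j) {
    s <- s1[j + 1] - s1[i]
    q <- s2[j + 1] - s2[i]
    pmax(q - s^2 / (j - i + 1), 0)
  }
  # suffix DP: E[m, i] = min cost of splitting v[i..n] into m classes
  E <- matrix(Inf, nrow = k, ncol = n + 1)
  E[1, 1:n] <- ssd(1:n, n)
  for (m in 2:k) {
    # v[i..n] into m classes needs at least m values
    for (i in 1:(n - m + 1)) {
      j <- i:(n - m + 1)              # end of the first class
      E[m, i] <- min(ssd(i, j) + E[m - 1, j + 1])
    }
  }
  # walk from the left, taking the smallest class end achieving the optimum
  breaks <- numeric(k - 1)
  i <- 1
  for (m in k:2) {
    j <- i:(n - m + 1)
    tot <- ssd(i, j) + E[m - 1, j + 1]
    jstar <- j[which(tot <= E[m, i] + 1e-9 * (1 + abs(E[m, i])))[1]]
    breaks[k - m + 1] <- (v[jstar] + v[jstar + 1]) / 2
    i <- jstar + 1
  }
  breaks
}

#' Class assignment from Jenks breaks
#'
#' @param values numeric vector.
#' @param breaks output of [jenks_breaks()].
#' @return integer class labels `1..(length(breaks) + 1)`.
#' @export
jenks_classify <- function(values, breaks) {
  as.integer(1L + rowSums(outer(values, breaks, `>`)))
}
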