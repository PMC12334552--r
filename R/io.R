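#' @title Text raster and table I/O
#' @name io
#' @description Readers and writers for the exchange formats the pipeline
#'   uses: ESRI ASCII grid (.asc) rasters (square-cell WGS84 lat/lon grids),
#'   occurrence and category CSVs, and GeoJSON rectangle output for
#'   protected-area masks. The .asc format is plain text and round-trips the
#'   full grid registration (corner, cell size, nodata).
NULL

#' Write a layer or mask as an ESRI ASCII grid
#'
#' @param values numeric or logical vector (row-major, north row first) or an
#'   `env_layer`; logical masks are written as 0/1.
#' @param grid a [grid_spec()]; taken from the object when omitted.
#' @param path output file path (conventionally `.asc`).
#' @export
write_asc <- function(values, path, grid = NULL) {
  if (inherits(values, "env_layer")) {
    grid <- values$grid
    values <- values$values
  }
  if (is.list(values) && !is.null(values$grid)) {
    grid <- values$grid
    values <- if (!is.null(values$suitable)) values$suitable else values$covered
  }
  stopifnot(!is.null(grid), length(values) == grid$n_rows * grid$n_cols)
  values <- as.numeric(values)
  values[is.na(values)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$lon_left),
    sprintf("yllcorner %.17g", grid$lat_top - grid$n_rows * grid$res_deg),
    sprintf("cellsize %.17g", grid$res_deg),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  m <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param name layer name; defaults to the file name stem.
#' @return an [env_layer()] (nodata cells become `NA`).
#' @export
read_asc <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed .asc header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  grid <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                    lat_top = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    lon_left = hdr$xllcorner, nodata = nodata)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != grid$n_rows * grid$n_cols) {
    stop("cell count does not match header in ", path)
  }
  vals[vals == nodata] <- NA_real_
  env_layer(name, vals, grid)
}

#' Read an occurrence table CSV
#'
#' Expected columns: `species`, `lon`, `lat` and optionally `source`.
#'
#' @param path CSV file path.
#' @return data.frame with columns species, lon, lat, source.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have columns species, lon, lat")
  }
  if (is.null(df$source)) df$source <- "unknown"
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90,
          na.rm = TRUE)) {
    stop("occurrence coordinates outside valid lon/lat ranges")
  }
  df[c("species", "lon", "lat", "source")]
}

#' Read a species category table CSV
#'
#' Expected columns: `species`, `category` with categories among
#' LC, NT, VU, EN, CR, EX, NE.
#'
#' @param path CSV file path.
#' @return data.frame with species and category.
#' @export
read_categories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(df))) {
    stop("category CSV must have columns species, category")
  }
  bad <- setdiff(unique(df$category), names(RL_RANK))
  if (length(bad) > 0) stop("unknown categories: ", paste(bad, collapse = ", "))
  df
}

#' Write a boolean mask as GeoJSON rectangles
#'
#' Each maximal run of covered cells within a row becomes one rectangle
#' polygon; a compact, lossless vector representation of a blocky mask.
#'
#' @param mask logical vector (row-major) or a `pa_mask`.
#' @param path output path.
#' @param grid a [grid_spec()]; taken from the mask when omitted.
#' @export
write_mask_geojson <- function(mask, path, grid = NULL) {
  if (is.list(mask) && !is.null(mask$grid)) {
    grid <- mask$grid
    mask <- mask$covered
  }
  m <- matrix(mask, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  feats <- list()
  for (i in seq_len(grid$n_rows)) {
    r <- rle(as.logical(m[i, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (s in which(r$values)) {
      w <- grid$lon_left + (starts[s] - 1) * grid$res_deg
      e <- grid$lon_left + ends[s] * grid$res_deg
      n <- grid$lat_top - (i - 1) * grid$res_deg
      so <- grid$lat_top - i * grid$res_deg
      ring <- list(c(w, so), c(e, so), c(e, n), c(w, n), c(w, so))
      feats[[length(feats) + 1]] <- list(
        type = "Feature", properties = list(row = i - 1L),
        geometry = list(type = "Polygon", coordinates = list(ring))
      )
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
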