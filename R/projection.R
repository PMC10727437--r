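#' Georeferenced single-band grid
#'
#' A light container for the temperature and suitability rasters the
#' pipeline consumes and produces: a numeric matrix (row 1 = northernmost
#' row) with lower-left-corner georeferencing and square cells. Missing
#' cells (ocean, outside the clip region) are held as `NA` internally and
#' mapped to the `nodata` sentinel on write.
#'
#' @param values Numeric matrix; `NA` marks nodata cells.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length, in CRS units.
#' @param nodata Sentinel written to files for `NA` cells (default -9999).
#' @param crs Optional CRS description (e.g. WKT or "EPSG:4326") carried to
#'   a `.prj` sidecar on write.
#' @param layer What the values are: `"temperature_C"`, `"rgr_per_day"`, or
#'   `"rgr_diff_per_day"`.
#' @return An object of class `azolla_grid`.
#' @export
azolla_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999, crs = NA,
                        layer = "temperature_C") {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs,
                 layer = layer),
            class = "azolla_grid")
}

#' @export
print.azolla_grid <- function(x, ...) {
  nv <- sum(is.finite(x$values))
  cat(sprintf("azolla_grid [%s]: %d x %d cells (%d valid), cellsize %g, origin (%g, %g)\n",
              x$layer, nrow(x$values), ncol(x$values), nv, x$cellsize,
              x$xll, x$yll))
  invisible(x)
}

#' @export
dim.azolla_grid <- function(x) dim(x$values)

grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize)))
}

#' Project a fitted thermal performance curve onto a temperature grid
#'
#' Evaluates [room_performance()] at every valid pixel of a mean-annual-
#' temperature grid; nodata cells propagate unchanged, so the output mask is
#' identical to the input mask. This is the habitat-suitability map: the
#' predicted growth rate a population would achieve at each location's
#' annual mean temperature.
#'
#' @param grid An [azolla_grid()] of temperatures, degrees C.
#' @param params A [room_params()] object (or a `tpc_fit`, whose params are
#'   used).
#' @return An [azolla_grid()] with `layer = "rgr_per_day"`.
#' @export
project_suitability <- function(grid, params) {
  stopifnot(inherits(grid, "azolla_grid"))
  if (inherits(params, "tpc_fit")) params <- params$params
  out <- grid
  valid <- is.finite(grid$values)
  out$values[valid] <- room_performance(grid$values[valid], params)
  out$layer <- "rgr_per_day"
  out
}

#' Clip a grid to a region mask
#'
#' Pixels outside the mask become nodata; georeferencing is unchanged.
#' The mask must align with the grid — resampling is deliberately out of
#' scope, so a shape mismatch is an error rather than a silent
#' interpolation.
#'
#' @param grid An [azolla_grid()].
#' @param mask A logical matrix (`TRUE` = inside region) or an
#'   [azolla_grid()] of 0/1 values with matching shape.
#' @return The clipped [azolla_grid()].
#' @export
clip_grid <- function(grid, mask) {
  stopifnot(inherits(grid, "azolla_grid"))
  if (inherits(mask, "azolla_grid")) {
    if (!grids_aligned(grid, mask)) {
      stop(sprintf("mask grid (%d x %d) does not align with grid (%d x %d)",
                   nrow(mask$values), ncol(mask$values),
                   nrow(grid$values), ncol(grid$values)), call. = FALSE)
    }
    mask <- is.finite(mask$values) & mask$values != 0
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(grid$values))) {
    stop(sprintf("mask shape (%s) does not match grid shape (%d x %d)",
                 paste(dim(mask), collapse = " x "),
                 nrow(grid$values), ncol(grid$values)), call. = FALSE)
  }
  out <- grid
  out$values[!mask] <- NA_real_
  out
}

#' Regional mean over valid pixels
#'
#' Unweighted arithmetic mean of all valid (non-nodata) pixels, the summary
#' used for the continental growth-rate tables. Optional cosine-latitude
#' weighting corrects for the shrinking area of graticule cells toward the
#' poles, for users working on geographic grids.
#'
#' @param grid An [azolla_grid()] with at least one valid pixel.
#' @param weighted Use cos(latitude) area weights (default `FALSE`).
#' @return The mean pixel value (scalar).
#' @export
regional_mean <- function(grid, weighted = FALSE) {
  stopifnot(inherits(grid, "azolla_grid"))
  valid <- is.finite(grid$values)
  if (!any(valid)) stop("no valid pixels", call. = FALSE)
  if (!weighted) return(mean(grid$values[valid]))
  nr <- nrow(grid$values)
  # row i (top = 1) centre latitude
  lat <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  w <- matrix(cos(lat * pi / 180), nr, ncol(grid$values))
  sum(grid$values[valid] * w[valid]) / sum(w[valid])
}

#' Pixel-wise difference between two suitability grids
#'
#' `future - current` at every pixel valid in both; the output mask is the
#' intersection of the input masks (a difference is undefined where either
#' layer is missing). Grids must share shape and georeferencing.
#'
#' @param future,current Aligned [azolla_grid()] objects.
#' @return An [azolla_grid()] with `layer = "rgr_diff_per_day"`.
#' @export
difference_map <- function(future, current) {
  stopifnot(inherits(future, "azolla_grid"), inherits(current, "azolla_grid"))
  if (!grids_aligned(future, current)) {
    stop(sprintf("grids do not align: %d x %d vs %d x %d",
                 nrow(future$values), ncol(future$values),
                 nrow(current$values), ncol(current$values)), call. = FALSE)
  }
  out <- future
  both <- is.finite(future$values) & is.finite(current$values)
  out$values[] <- NA_real_
  out$values[both] <- future$values[both] - current$values[both]
  out$layer <- "rgr_diff_per_day"
  out
}

#' Percent change in regional mean growth rate
#'
#' `100 * mean_diff / current_mean`: the scenario-table summary relating
#' the mean pixel-wise change to the current regional mean.
#'
#' @param mean_diff Mean pixel-wise difference (future - current), per day.
#' @param current_mean Current regional mean growth rate, per day (nonzero).
#' @return Percent change (scalar).
#' @export
percent_change <- function(mean_diff, current_mean) {
  if (any(current_mean == 0)) stop("current_mean must be nonzero", call. = FALSE)
  100 * mean_diff / current_mean
}

#' Summarize current and future scenarios for one species
#'
#' Orchestrates the projection pipeline: clips every temperature layer to
#' the region mask, projects the fitted curve pixel-wise, and tabulates the
#' regional mean RGR per scenario, plus the mean pixel-wise difference from
#' current and the percent change for each future scenario. By
#' construction `pct_change = 100 * mean_diff / current mean` on the shared
#' mask.
#'
#' @param current A temperature [azolla_grid()] for the baseline period.
#' @param futures Named list of future temperature grids (names are the
#'   scenario labels, e.g. `"RCP4.5-2050"`).
#' @param params A [room_params()] or `tpc_fit`.
#' @param mask Optional region mask (see [clip_grid()]).
#' @param species Species label stamped on the summary rows.
#' @param weighted Passed to [regional_mean()].
#' @return A tibble with columns `species`, `scenario`, `mean_rgr`,
#'   `mean_diff`, `pct_change` (`NA` for the current row).
#' @export
summarize_scenarios <- function(current, futures, params, mask = NULL,
                                species = NA_character_, weighted = FALSE) {
  if (inherits(params, "tpc_fit")) {
    if (is.na(species)) species <- params$species
    params <- params$params
  }
  if (inherits(futures, "azolla_grid")) futures <- list(future = futures)
  if (is.null(names(futures)) || any(names(futures) == "")) {
    stop("`futures` must be a named list of scenario grids", call. = FALSE)
  }
  prep <- function(g) {
    if (!is.null(mask)) g <- clip_grid(g, mask)
    project_suitability(g, params)
  }
  suit_cur <- prep(current)
  cur_mean <- regional_mean(suit_cur, weighted = weighted)
  rows <- list(tibble::tibble(species = species, scenario = "current",
                              mean_rgr = cur_mean, mean_diff = NA_real_,
                              pct_change = NA_real_))
  for (lab in names(futures)) {
    suit_fut <- prep(futures[[lab]])
    diff <- difference_map(suit_fut, suit_cur)
    md <- regional_mean(diff, weighted = weighted)
    rows[[length(rows) + 1]] <- tibble::tibble(
      species = species, scenario = lab,
      mean_rgr = regional_mean(suit_fut, weighted = weighted),
      mean_diff = md,
      pct_change = percent_change(md, cur_mean)
    )
  }
  dplyr::bind_rows(rows)
}

#' Read / write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster I/O in the Arc/Info ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows north to south), which GIS tools read natively. A CRS, when set,
#' is written to a `.prj` sidecar next to the raster. `scale_factor`
#' divides stored values on read (WorldClim-style layers are sometimes
#' stored as degrees C x 10; pass `scale_factor = 10` for those).
#'
#' @param path Raster path (`.asc`).
#' @param scale_factor Divisor applied to stored values on read (default 1).
#' @param layer Layer tag for the returned grid.
#' @return `read_raster` returns an [azolla_grid()]; `write_raster` returns
#'   `path` invisibly. Values round-trip exactly at 15 significant digits.
#' @export
read_raster <- function(path, scale_factor = 1, layer = "temperature_C") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  header <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header))) {
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(header)), collapse = ", "), call. = FALSE)
  }
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  m <- m / scale_factor
  crs <- NA
  prj <- sub("\\.[^.]*$", ".prj", path)
  if (file.exists(prj)) crs <- paste(readLines(prj), collapse = "\n")
  azolla_grid(m, xll = header$xllcorner, yll = header$yllcorner,
              cellsize = header$cellsize, nodata = nodata, crs = crs,
              layer = layer)
}

#' @rdname read_raster
#' @param grid An [azolla_grid()].
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "azolla_grid"))
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(header, body), path)
  if (!is.na(grid$crs)) {
    writeLines(grid$crs, sub("\\.[^.]*$", ".prj", path))
  }
  invisible(path)
}
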