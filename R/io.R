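#' Read and write occurrence CSV files
#'
#' The interchange format is a plain CSV with header
#' `lon,lat,source,error_km`. On read, rows with missing/non-numeric
#' coordinates, coordinates off the globe, or negative error are rejected and
#' reported with their line numbers; valid rows are returned.
#'
#' @param path file path.
#' @return `read_occurrences`: data.frame with the four columns and an
#'   attribute `rejected` (line numbers of rejected rows).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "source", "error_km")
  if (!all(need %in% names(df)))
    stop(sprintf("occurrence file missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  err <- suppressWarnings(as.numeric(df$error_km))
  bad <- is.na(lon) | is.na(lat) | is.na(err) |
    abs(lat) > 90 | abs(lon) > 360 | err < 0
  if (any(bad))
    message(sprintf("read_occurrences: rejected row(s) at line(s) %s",
                    paste(which(bad) + 1L, collapse = ", ")))
  out <- data.frame(lon = lon[!bad], lat = lat[!bad],
                    source = as.character(df$source)[!bad],
                    error_km = err[!bad])
  attr(out, "rejected") <- which(bad) + 1L
  out
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("lon", "lat", "source", "error_km")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rasters as headered ASCII grids
#'
#' Plain-text ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header, then rows north to south). This is the
#' package's raster interchange format: text-only, round-trip exact at 17
#' significant digits, no GDAL dependency.
#'
#' @param path file path.
#' @return `read_raster`: list with `grid` (a [geo_grid()]) and `values`
#'   matrix (NA where nodata).
#' @export
read_raster <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  ncols <- as.integer(hdr[["ncols"]]); nrows <- as.integer(hdr[["nrows"]])
  res <- hdr[["cellsize"]]
  grid <- geo_grid(hdr[["xllcorner"]], hdr[["xllcorner"]] + ncols * res,
                   hdr[["yllcorner"]], hdr[["yllcorner"]] + nrows * res,
                   resolution = res)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop(sprintf("raster %s: expected %d values, found %d", path,
                 ncols * nrows, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  list(grid = grid, values = m)
}

#' @rdname read_raster
#' @param values numeric matrix (`nlat x nlon`, row 1 = north).
#' @param grid a [geo_grid()].
#' @param nodata sentinel written for NA cells.
#' @export
write_raster <- function(values, grid, path, nodata = -9999) {
  stopifnot(all(dim(values) == dim_grid(grid)))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$nlon),
           sprintf("nrows %d", grid$nlat),
           sprintf("xllcorner %.10g", grid$lon_min),
           sprintf("yllcorner %.10g", grid$lat_min),
           sprintf("cellsize %.10g", grid$resolution),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble monthly climate from per-field rasters
#'
#' Validates that all layers share one grid; any mismatch errors naming the
#' offending field.
#'
#' @param tmean,tmin,tmax,prec lists of 12 `read_raster()` results each.
#' @param land_mask logical matrix (default: cells finite in all layers).
#' @param slice_label slice name.
#' @return a `monthly_climate`.
#' @export
assemble_climate <- function(tmean, tmin, tmax, prec, land_mask = NULL,
                             slice_label = "present") {
  fields <- list(tmean = tmean, tmin = tmin, tmax = tmax, prec = prec)
  g <- tmean[[1]]$grid
  arr <- lapply(names(fields), function(nm) {
    f <- fields[[nm]]
    if (length(f) != 12L)
      stop(sprintf("field %s: expected 12 monthly layers", nm), call. = FALSE)
    a <- array(NA_real_, c(g$nlat, g$nlon, 12))
    for (m in 1:12) {
      if (!grids_equal(g, f[[m]]$grid))
        stop(sprintf("layer %s month %d on a different grid", nm, m),
             call. = FALSE)
      a[, , m] <- f[[m]]$values
    }
    a
  })
  names(arr) <- names(fields)
  if (is.null(land_mask))
    land_mask <- Reduce(`&`, lapply(arr, function(a)
      apply(is.finite(a), c(1, 2), all)))
  structure(list(grid = g, tmean = arr$tmean, tmin = arr$tmin,
                 tmax = arr$tmax, prec = arr$prec, land_mask = land_mask,
                 slice_label = slice_label),
            class = "monthly_climate")
}

#' Serialise / restore a stratification model as JSON
#'
#' @param model a `strat_model`.
#' @param path file path.
#' @export
write_strat_model <- function(model, path) {
  obj <- model
  obj$rotation <- list(values = as.vector(model$rotation),
                       dim = dim(model$rotation),
                       rn = rownames(model$rotation),
                       cn = colnames(model$rotation))
  obj$centroids <- list(values = as.vector(model$centroids),
                        dim = dim(model$centroids))
  obj$centroids_orig <- list(values = as.vector(model$centroids_orig),
                             dim = dim(model$centroids_orig))
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_strat_model
#' @export
read_strat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  remat <- function(x) {
    m <- matrix(x$values, nrow = x$dim[1], ncol = x$dim[2])
    if (!is.null(x$rn)) rownames(m) <- x$rn
    if (!is.null(x$cn)) colnames(m) <- x$cn
    m
  }
  obj$rotation <- remat(obj$rotation)
  obj$centroids <- remat(obj$centroids)
  obj$centroids_orig <- remat(obj$centroids_orig)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$training$cells <- as.integer(obj$training$cells)
  obj$training$labels <- as.integer(obj$training$labels)
  structure(obj, class = "strat_model")
}

#' Serialise / restore a fitted niche model as JSON
#'
#' @param model a `niche_model`.
#' @param path file path.
#' @export
write_niche_model <- function(model, path) {
  obj <- unclass(model)
  obj$spec <- unclass(model$spec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_niche_model
#' @export
read_niche_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$w <- stats::setNames(as.numeric(obj$w), obj$feature_names)
  obj$f_center <- stats::setNames(as.numeric(obj$f_center), obj$feature_names)
  obj$f_scale <- stats::setNames(as.numeric(obj$f_scale), obj$feature_names)
  obj$background <- as.integer(obj$background)
  obj$spec <- structure(obj$spec, class = "feature_spec")
  structure(obj, class = "niche_model")
}
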