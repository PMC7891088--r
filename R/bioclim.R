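DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
# mid-month Julian day for the fixed 365-day calendar
MID_MONTH_DOY <- cumsum(c(0, DAYS_IN_MONTH[-12])) + DAYS_IN_MONTH / 2

#' Extraterrestrial radiation (mm/day water equivalent)
#'
#' Standard solar-geometry radiation at the top of the atmosphere for a given
#' latitude and day of year, converted from MJ m-2 day-1 to evaporation
#' equivalent by the factor 0.408.
#'
#' @param lat latitude, degrees.
#' @param doy day of year (1..365), vectorised against `lat`.
#' @return radiation in mm/day equivalent.
#' @export
extraterrestrial_radiation <- function(lat, doy) {
  gsc <- 0.0820 # solar constant, MJ m-2 min-1
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(pmax(x, -1), 1)) # clamp for polar day/night
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  0.408 * pmax(ra, 0)
}

#' Monthly potential evapotranspiration (Hargreaves)
#'
#' `PET_m = 0.0023 * RA * (tmean + 17.8) * sqrt(tmax - tmin) * days_m`,
#' clamped at zero, with RA the extraterrestrial radiation (mm/day equivalent)
#' at mid-month. This is the formulation behind the global aridity/PET
#' datasets used for environmental stratification; a temperature-only
#' alternative can be substituted via `method`.
#'
#' @param tmean,tmin,tmax numeric arrays/matrices/vectors of 12 monthly
#'   values per cell; either vectors of length 12 (one cell) or arrays with
#'   the month as last dimension.
#' @param lat latitude in degrees: a scalar, or a matrix matching the spatial
#'   dimensions of the inputs.
#' @param method currently only "hargreaves".
#' @return monthly PET, mm/month, same shape as `tmean`.
#' @export
compute_pet <- function(tmean, tmin, tmax, lat, method = "hargreaves") {
  method <- match.arg(method, "hargreaves")
  if (any(tmin > tmax + 1e-12, na.rm = TRUE))
    stop("tmin exceeds tmax", call. = FALSE)
  shp <- dim(tmean)
  m12 <- function(x, m) {
    if (is.null(shp)) x[m]
    else if (length(shp) == 3L) x[, , m] else x[, m]
  }
  out <- tmean * 0
  for (m in 1:12) {
    ra <- extraterrestrial_radiation(lat, MID_MONTH_DOY[m])
    tm <- m12(tmean, m)
    dtr <- pmax(m12(tmax, m) - m12(tmin, m), 0)
    pet <- pmax(0.0023 * ra * (tm + 17.8) * sqrt(dtr), 0) * DAYS_IN_MONTH[m]
    if (is.null(shp)) out[m] <- pet
    else if (length(shp) == 3L) out[, , m] <- pet else out[, m] <- pet
  }
  out
}

#' Growing degree-days on a 0 degC base
#'
#' `sum_m max(tmean_m, 0) * days_m` on the fixed 365-day calendar.
#'
#' @param tmean 12 monthly mean temperatures (vector), or an array with month
#'   as the last dimension.
#' @return degC-days per year (same spatial shape as the input).
#' @export
compute_gdd0 <- function(tmean) {
  apply_months(tmean, function(x) sum(pmax(x, 0) * DAYS_IN_MONTH))
}

#' Temperature seasonality (SD of monthly means x 100)
#'
#' Population standard deviation of the 12 monthly mean temperatures,
#' multiplied by 100 (the bio4 convention).
#' @inheritParams compute_gdd0
#' @return degC x 100.
#' @export
compute_temp_seasonality <- function(tmean) {
  apply_months(tmean, function(x) 100 * pop_sd(x))
}

#' Annual aridity index
#'
#' Annual precipitation divided by annual potential evapotranspiration.
#' A zero-PET cell (possible only in a permanently frozen synthetic world)
#' returns `cap`, the configured hyper-humid ceiling.
#'
#' @param prec monthly precipitation, mm (12 values per cell).
#' @param pet monthly PET, mm.
#' @param cap value returned where annual PET is zero.
#' @return dimensionless index, same spatial shape as the input.
#' @export
compute_aridity_index <- function(prec, pet, cap = 100) {
  if (any(prec < 0, na.rm = TRUE))
    stop("negative precipitation", call. = FALSE)
  p <- apply_months(prec, sum)
  e <- apply_months(pet, sum)
  out <- ifelse(e > 0, p / e, cap)
  out
}

#' PET seasonality (coefficient of variation x 100)
#'
#' `100 * SD(monthly PET) / mean(monthly PET)` (population SD); defined as 0
#' where mean PET is zero.
#' @param pet monthly PET, mm.
#' @return percent CV, same spatial shape as the input.
#' @export
compute_pet_seasonality <- function(pet) {
  m <- apply_months(pet, mean)
  s <- apply_months(pet, pop_sd)
  ifelse(m > 0, 100 * s / m, 0)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# reduce the month dimension (last) of a vector/matrix/3-d array
apply_months <- function(x, f) {
  d <- dim(x)
  if (is.null(d)) {
    if (length(x) != 12L) stop("expected 12 monthly values", call. = FALSE)
    return(f(x))
  }
  if (d[length(d)] != 12L)
    stop("expected month as the last dimension (length 12)", call. = FALSE)
  if (length(d) == 2L) return(apply(x, 1, f))
  apply(x, c(1, 2), f)
}

#' Build the four-variable bioclimatic stack from a monthly climate
#'
#' Computes growing degree-days (0 degC base), temperature seasonality
#' (SD x 100), the annual aridity index, and PET seasonality (CV x 100) from
#' monthly climate grids; cells off the land mask are set to NA (nodata).
#'
#' @param climate a `monthly_climate` (see [generate_climate()]).
#' @return an object of class `bioclim_stack`: `grid`, logical `land_mask`,
#'   and matrix `layers` `gdd0`, `temp_seasonality`, `aridity_index`,
#'   `pet_seasonality`.
#' @export
build_bioclim_stack <- function(climate) {
  stopifnot(inherits(climate, "monthly_climate"))
  lat <- lat_matrix(climate$grid)
  pet <- compute_pet(climate$tmean, climate$tmin, climate$tmax, lat)
  layers <- list(
    gdd0 = compute_gdd0(climate$tmean),
    temp_seasonality = compute_temp_seasonality(climate$tmean),
    aridity_index = compute_aridity_index(climate$prec, pet),
    pet_seasonality = compute_pet_seasonality(pet))
  layers <- lapply(layers, function(l) {
    l[!climate$land_mask] <- NA_real_
    l
  })
  structure(list(grid = climate$grid, land_mask = climate$land_mask,
                 layers = layers, slice_label = climate$slice_label),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack [%s]: %d land cells on a %d x %d grid\n",
              x$slice_label %||% "?", sum(x$land_mask),
              x$grid$nlat, x$grid$nlon))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BIOCLIM_VARS <- c("gdd0", "temp_seasonality", "aridity_index",
                  "pet_seasonality")

# land-cell values of a stack as an n x 4 matrix, plus the cell indices
stack_values <- function(stack, cells = NULL) {
  mask <- stack$land_mask & !is.na(stack$layers[[1]])
  if (is.null(cells)) cells <- which(mask)
  X <- vapply(stack$layers[BIOCLIM_VARS], function(l) l[cells],
              numeric(length(cells)))
  if (length(cells) == 1L) X <- matrix(X, nrow = 1,
                                       dimnames = list(NULL, BIOCLIM_VARS))
  list(cells = cells, X = X)
}
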