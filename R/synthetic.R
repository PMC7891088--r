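#' Scenario specification for the synthetic climate generator
#'
#' Encodes a parametric world: a latitudinal temperature gradient with
#' seasonal amplitude growing towards the poles, and a movable "pluvial belt"
#' of high precipitation (a Gaussian ridge in latitude) over a dry background.
#' Moving `pluvial_center_lat` between time slices emulates pluvial versus
#' interpluvial phases; `sea_level_offset` widens the land mask to emulate
#' lowered glacial sea levels.
#'
#' @param base_temp annual-mean temperature at the equator, degC.
#' @param lat_lapse cooling per degree of absolute latitude, degC/deg.
#' @param seasonal_amp seasonal half-amplitude at the pole, degC; the local
#'   amplitude scales linearly with |lat|/90 so the equator is aseasonal.
#' @param pluvial_center_lat latitude of the precipitation belt centre, deg.
#' @param pluvial_width Gaussian standard deviation of the belt, degrees (> 0).
#' @param pluvial_peak_precip belt peak precipitation, mm/month.
#' @param background_precip precipitation away from the belt, mm/month.
#' @param noise_sd standard deviation of cellwise monthly noise (degC for
#'   temperature, mm/month for precipitation; one knob for both, >= 0).
#' @param sea_level_offset extra coastal land, in grid cells, for the glacial
#'   slice (>= 0).
#' @param diurnal_range spread between tmax and tmin, degC (tmin/tmax are
#'   tmean -/+ half this).
#' @param zonal_precip_mod relative amplitude of a deterministic sinusoidal
#'   longitudinal modulation of precipitation (0 disables); keeps the derived
#'   bioclimatic fields two-dimensional rather than pure latitude bands.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(base_temp = 28, lat_lapse = 0.55, seasonal_amp = 18,
                          pluvial_center_lat = 8, pluvial_width = 12,
                          pluvial_peak_precip = 220, background_precip = 15,
                          noise_sd = 1, sea_level_offset = 0,
                          diurnal_range = 10, zonal_precip_mod = 0.3) {
  if (pluvial_width <= 0) stop("pluvial_width must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (sea_level_offset < 0) stop("sea_level_offset must be >= 0", call. = FALSE)
  if (diurnal_range < 0) stop("diurnal_range must be >= 0", call. = FALSE)
  structure(list(base_temp = base_temp, lat_lapse = lat_lapse,
                 seasonal_amp = seasonal_amp,
                 pluvial_center_lat = pluvial_center_lat,
                 pluvial_width = pluvial_width,
                 pluvial_peak_precip = pluvial_peak_precip,
                 background_precip = background_precip,
                 noise_sd = noise_sd,
                 sea_level_offset = as.integer(sea_level_offset),
                 diurnal_range = diurnal_range,
                 zonal_precip_mod = zonal_precip_mod),
            class = "scenario_spec")
}

#' Default test grid
#'
#' A 0.5 degree grid over 40W-60E, 40S-40N: a coarse sub-window of a
#' continental modelling extent, small enough for desk-scale tests.
#' @param resolution cell size in degrees.
#' @return a [geo_grid()].
#' @export
default_grid <- function(resolution = 0.5)
  geo_grid(-40, 60, -40, 40, resolution = resolution)

#' Generate a synthetic monthly climate slice
#'
#' Monthly mean temperature follows
#' `base_temp - lat_lapse * |lat| + A(lat) * cos(2*pi*(m - 7)/12) * sign(lat)`
#' with `A(lat) = seasonal_amp * |lat| / 90`, so the annual mean at every cell
#' is exactly the lapse-rate profile (the 12 cosine samples sum to zero) and
#' July is the warm month in the northern hemisphere. `tmin`/`tmax` are
#' `tmean -/+ diurnal_range/2`. Precipitation is `background_precip` plus a
#' Gaussian belt centred on `pluvial_center_lat`, optionally modulated in
#' longitude, clamped at zero. Gaussian noise of sd `noise_sd` is added per
#' cell and month (the same draw shifts tmean/tmin/tmax so their ordering is
#' preserved). Deterministic given `seed`.
#'
#' @param spec a [scenario_spec()].
#' @param grid a [geo_grid()].
#' @param seed integer seed.
#' @param land_mask optional logical matrix; defaults to all-land.
#' @param slice_label one of "present", "mid-holocene", "lgm".
#' @return an object of class `monthly_climate`: arrays `tmean`, `tmin`,
#'   `tmax`, `prec` of dim `c(nlat, nlon, 12)`, logical `land_mask`, the
#'   `grid`, and `slice_label`.
#' @export
generate_climate <- function(spec, grid, seed = 1L, land_mask = NULL,
                             slice_label = "present") {
  stopifnot(inherits(spec, "scenario_spec"), inherits(grid, "geo_grid"))
  nlat <- grid$nlat; nlon <- grid$nlon
  if (is.null(land_mask)) land_mask <- matrix(TRUE, nlat, nlon)
  lat <- lat_matrix(grid)
  lon <- matrix(grid_lons(grid), nlat, nlon, byrow = TRUE)

  base <- spec$base_temp - spec$lat_lapse * abs(lat)
  amp <- spec$seasonal_amp * lat / 90     # signed: flips phase across equator
  belt <- spec$pluvial_peak_precip *
    exp(-(lat - spec$pluvial_center_lat)^2 / (2 * spec$pluvial_width^2))
  zonal <- 1 + spec$zonal_precip_mod *
    sin(2 * pi * (lon - grid$lon_min) / (grid$lon_max - grid$lon_min))
  prec0 <- (spec$background_precip + belt) * zonal

  tmean <- array(0, c(nlat, nlon, 12))
  prec <- array(0, c(nlat, nlon, 12))
  with_seed(seed, {
    for (m in 1:12) {
      seas <- amp * cos(2 * pi * (m - 7) / 12)
      tn <- if (spec$noise_sd > 0)
        matrix(stats::rnorm(nlat * nlon, sd = spec$noise_sd), nlat, nlon)
      else 0
      pn <- if (spec$noise_sd > 0)
        matrix(stats::rnorm(nlat * nlon, sd = spec$noise_sd), nlat, nlon)
      else 0
      tmean[, , m] <- base + seas + tn
      prec[, , m] <- pmax(prec0 + pn, 0)
    }
  })
  half <- spec$diurnal_range / 2
  structure(list(grid = grid, tmean = tmean, tmin = tmean - half,
                 tmax = tmean + half, prec = prec,
                 land_mask = land_mask, slice_label = slice_label),
            class = "monthly_climate")
}

# bilinearly interpolated coarse Gaussian field; smooth spatial perturbation
smooth_field <- function(nlat, nlon, sd, scale_cells = 10L) {
  if (sd == 0) return(matrix(0, nlat, nlon))
  ni <- max(2L, ceiling(nlat / scale_cells) + 1L)
  nj <- max(2L, ceiling(nlon / scale_cells) + 1L)
  coarse <- matrix(stats::rnorm(ni * nj, sd = sd), ni, nj)
  ri <- seq(1, ni, length.out = nlat)
  rj <- seq(1, nj, length.out = nlon)
  i0 <- pmin(floor(ri), ni - 1L); fi <- ri - i0
  j0 <- pmin(floor(rj), nj - 1L); fj <- rj - j0
  a <- coarse[cbind(rep(i0, nlon), rep(j0, each = nlat))]
  b <- coarse[cbind(rep(i0 + 1, nlon), rep(j0, each = nlat))]
  cc <- coarse[cbind(rep(i0, nlon), rep(j0 + 1, each = nlat))]
  d <- coarse[cbind(rep(i0 + 1, nlon), rep(j0 + 1, each = nlat))]
  wfi <- rep(fi, nlon); wfj <- rep(fj, each = nlat)
  matrix(a * (1 - wfi) * (1 - wfj) + b * wfi * (1 - wfj) +
           cc * (1 - wfi) * wfj + d * wfi * wfj, nlat, nlon)
}

#' Generate a pseudo-GCM ensemble around a base climate
#'
#' Each member adds an independent smooth random field (bilinearly
#' interpolated coarse Gaussian noise) to the temperature fields and to
#' precipitation, emulating the spread of coupled general circulation models
#' around a common climatology. Member order is deterministic given `seed`.
#'
#' @param base a `monthly_climate`.
#' @param n_models number of members (>= 1).
#' @param perturb_sd named list with elements `temp` and `prec`: marginal sd
#'   of the perturbation fields (degC, mm/month).
#' @param seed integer seed.
#' @return list of `monthly_climate` objects, length `n_models`.
#' @export
generate_gcm_ensemble <- function(base, n_models,
                                  perturb_sd = list(temp = 2, prec = 20),
                                  seed = 1L) {
  stopifnot(inherits(base, "monthly_climate"))
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  nlat <- base$grid$nlat; nlon <- base$grid$nlon
  with_seed(seed, {
    lapply(seq_len(n_models), function(k) {
      ft <- smooth_field(nlat, nlon, perturb_sd$temp)
      fp <- smooth_field(nlat, nlon, perturb_sd$prec)
      m <- base
      for (mm in 1:12) {
        m$tmean[, , mm] <- m$tmean[, , mm] + ft
        m$tmin[, , mm] <- m$tmin[, , mm] + ft
        m$tmax[, , mm] <- m$tmax[, , mm] + ft
        m$prec[, , mm] <- pmax(m$prec[, , mm] + fp, 0)
      }
      m$slice_label <- paste0(base$slice_label, "_gcm", k)
      m
    })
  })
}

#' Generate land masks per time slice
#'
#' Builds a present-day mask with a wavy coastal sea margin along the grid
#' edges, and a glacial-maximum mask obtained by dilating the present land by
#' `sea_level_offset` cells (lower sea levels expose coastal shelf, so glacial
#' land is a superset of present land). The mid-Holocene mask equals the
#' present mask.
#'
#' @param grid a [geo_grid()].
#' @param sea_level_offset dilation radius in cells (>= 0); 0 gives identical
#'   masks.
#' @param seed integer seed (coastline waviness).
#' @return named list of logical matrices: `present`, `mid_holocene`, `lgm`.
#' @export
generate_masks <- function(grid, sea_level_offset = 2L, seed = 1L) {
  if (sea_level_offset < 0) stop("sea_level_offset must be >= 0", call. = FALSE)
  nlat <- grid$nlat; nlon <- grid$nlon
  base_margin <- max(2L, round(min(nlat, nlon) * 0.06))
  present <- with_seed(seed, {
    phase <- stats::runif(4, 0, 2 * pi)
    wob <- function(n, p) round(base_margin * 0.6 * sin(seq_len(n) / 7 + p))
    m <- matrix(TRUE, nlat, nlon)
    top <- base_margin + wob(nlon, phase[1])
    bot <- base_margin + wob(nlon, phase[2])
    lft <- base_margin + wob(nlat, phase[3])
    rgt <- base_margin + wob(nlat, phase[4])
    for (j in seq_len(nlon)) {
      if (top[j] > 0) m[seq_len(min(top[j], nlat)), j] <- FALSE
      if (bot[j] > 0) m[nlat - seq_len(min(bot[j], nlat)) + 1L, j] <- FALSE
    }
    for (i in seq_len(nlat)) {
      if (lft[i] > 0) m[i, seq_len(min(lft[i], nlon))] <- FALSE
      if (rgt[i] > 0) m[i, nlon - seq_len(min(rgt[i], nlon)) + 1L] <- FALSE
    }
    m
  })
  lgm <- dilate_mask(present, sea_level_offset)
  list(present = present, mid_holocene = present, lgm = lgm)
}

# binary dilation with a (2r+1)^2 square structuring element, by shifting
dilate_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r <= 0) return(mask)
  out <- mask
  nlat <- nrow(mask); nlon <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    si <- seq_len(nlat) - di
    sj <- seq_len(nlon) - dj
    ok_i <- si >= 1 & si <= nlat
    ok_j <- sj >= 1 & sj <= nlon
    out[ok_i, ok_j] <- out[ok_i, ok_j] | mask[si[ok_i], sj[ok_j]]
  }
  out
}

#' Sample occurrence records from a suitability surface
#'
#' Cells are drawn multinomially with probability proportional to the raw
#' suitability value (zero/NA cells never receive points); each point is
#' placed at its cell centre and jittered isotropically by at most
#' `jitter_km`, emulating positional error in locality compilations. The
#' `error_km` field of every record is set to `jitter_km`.
#'
#' @param suitability a `suitability_map` (see [predict_raw()]) or a list with
#'   fields `grid` and `raw` (matrix, NA off-mask).
#' @param n number of records.
#' @param jitter_km maximum positional error, km.
#' @param seed integer seed.
#' @param source label written to the `source` column.
#' @return a data.frame with columns `lon`, `lat`, `source`, `error_km`
#'   (an occurrence set).
#' @export
generate_occurrences <- function(suitability, n, jitter_km = 0, seed = 1L,
                                 source = "synthetic") {
  raw <- suitability$raw
  grid <- suitability$grid
  w <- as.vector(raw)
  w[is.na(w)] <- 0
  if (any(w < 0) || any(!is.finite(w)))
    stop("suitability must be non-negative and finite on land", call. = FALSE)
  if (n == 0)
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      source = character(0), error_km = numeric(0)))
  if (sum(w) <= 0)
    stop("all-zero suitability: cannot sample occurrences", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(length(w), size = n, replace = TRUE, prob = w)
    row <- (idx - 1L) %% grid$nlat + 1L
    col <- (idx - 1L) %/% grid$nlat + 1L
    lat <- grid_lats(grid)[row]
    lon <- grid_lons(grid)[col]
    if (jitter_km > 0) {
      # uniform in a disc of radius jitter_km, converted to degrees locally
      theta <- stats::runif(n, 0, 2 * pi)
      rad <- jitter_km * sqrt(stats::runif(n))
      km_per_deg <- 111.32
      lat <- lat + rad * sin(theta) / km_per_deg
      lon <- lon + rad * cos(theta) / (km_per_deg * pmax(cos(lat * pi / 180), 0.05))
      lat <- pmin(pmax(lat, grid$lat_min), grid$lat_max)
      lon <- pmin(pmax(lon, grid$lon_min), grid$lon_max)
    }
    data.frame(lon = lon, lat = lat, source = source, error_km = jitter_km)
  })
}

#' Filter occurrence records by maximum positional error
#'
#' Keeps records whose `error_km` is less than or equal to `max_error_km`
#' (inclusive), preserving order. The conventional cutoff for continental
#' niche modelling of wide-ranging carnivores is 50 km.
#'
#' @param occ occurrence data.frame with an `error_km` column.
#' @param max_error_km inclusive cutoff, km (>= 0).
#' @return the filtered data.frame.
#' @export
filter_occurrences <- function(occ, max_error_km = 50) {
  if (max_error_km < 0) stop("max_error_km must be >= 0", call. = FALSE)
  occ[occ$error_km <= max_error_km, , drop = FALSE]
}
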