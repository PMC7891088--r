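AUTHALIC_RADIUS_KM <- 6371.0072

#' Area of a grid cell at a given latitude
#'
#' Exact spherical band formula on the authalic-radius sphere: the area of a
#' cell of angular size `resolution` x `resolution` centred at latitude `lat`
#' is `(pi/180) * res * R^2 * (sin(lat + res/2) - sin(lat - res/2))` km^2.
#' Strictly decreasing in |lat| for fixed resolution.
#'
#' @param lat cell-centre latitude, degrees (vectorised), |lat| <= 90.
#' @param resolution cell size, degrees.
#' @return cell area in km^2.
#' @export
cell_area <- function(lat, resolution) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90", call. = FALSE)
  d2r <- pi / 180
  lat1 <- pmax((lat - resolution / 2), -90) * d2r
  lat2 <- pmin((lat + resolution / 2), 90) * d2r
  (d2r * resolution) * AUTHALIC_RADIUS_KM^2 * (sin(lat2) - sin(lat1))
}

# per-cell area matrix for a grid
cell_area_matrix <- function(grid) {
  matrix(cell_area(grid_lats(grid), grid$resolution),
         nrow = grid$nlat, ncol = grid$nlon)
}

#' Latitude-weighted area per category of a categorical map
#'
#' @param map a `category_map` (or any list with `grid` and integer `codes`).
#' @param slice_label label stored in the report (defaults to the map's).
#' @return an object of class `area_report`: data.frame `table` with
#'   `category` (code), `label`, `area_km2`, `pct` (% of slice land area, the
#'   cells carrying any category code), plus `total_km2` and `slice_label`.
#'   Percentages printed at 1 decimal; raw km^2 kept at full precision.
#' @export
area_by_category <- function(map, slice_label = NULL) {
  area <- cell_area_matrix(map$grid)
  ok <- !is.na(map$codes)
  total <- sum(area[ok])
  a <- tapply(area[ok], map$codes[ok], sum)
  tab <- data.frame(category = as.integer(names(a)),
                    label = category_labels(as.integer(names(a))),
                    area_km2 = as.numeric(a),
                    pct = 100 * as.numeric(a) / total)
  structure(list(table = tab, total_km2 = total,
                 slice_label = slice_label %||% map$slice_label),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("area_report [%s]: total land %.0f km2\n",
              x$slice_label %||% "?", x$total_km2))
  t <- x$table
  t$pct <- sprintf("%.1f", t$pct)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Between-slice change table for category areas
#'
#' Pairwise differences (absolute km^2 and percentage-point) of category
#' areas between successive reports, with a flag when the slices' total land
#' areas differ (sea-level masks).
#'
#' @param reports list of >= 2 `area_report`s.
#' @return data.frame with columns `from`, `to`, `category`, `label`,
#'   `area_from_km2`, `area_to_km2`, `delta_km2`, `pct_from`, `pct_to`,
#'   `delta_pct`, `total_area_differs`.
#' @export
compare_time_slices <- function(reports) {
  if (length(reports) < 2L) stop("need >= 2 reports", call. = FALSE)
  out <- NULL
  for (i in seq_len(length(reports) - 1L)) {
    a <- reports[[i]]; b <- reports[[i + 1L]]
    cats <- sort(union(a$table$category, b$table$category))
    ga <- a$table$area_km2[match(cats, a$table$category)]
    gb <- b$table$area_km2[match(cats, b$table$category)]
    pa <- a$table$pct[match(cats, a$table$category)]
    pb <- b$table$pct[match(cats, b$table$category)]
    ga[is.na(ga)] <- 0; gb[is.na(gb)] <- 0
    pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
    out <- rbind(out, data.frame(
      from = a$slice_label %||% paste0("slice", i),
      to = b$slice_label %||% paste0("slice", i + 1),
      category = cats, label = category_labels(cats),
      area_from_km2 = ga, area_to_km2 = gb, delta_km2 = gb - ga,
      pct_from = pa, pct_to = pb, delta_pct = pb - pa,
      total_area_differs =
        abs(a$total_km2 - b$total_km2) > 1e-6 * max(a$total_km2, b$total_km2)))
  }
  out
}

#' Zone areas inside and outside a range mask (fundamental vs realized)
#'
#' For each zone: total latitude-weighted area, the area inside the supplied
#' range mask (e.g. a rasterised extant-range polygon), and the within-range
#' fraction — contrasting climatically suitable space with occupied space.
#'
#' @param strata a `strata_map` (its `zone` grid is used).
#' @param range_mask logical matrix aligned with the map.
#' @return data.frame `zone`, `total_km2`, `in_range_km2`, `fraction`.
#' @export
zone_area_within_range <- function(strata, range_mask) {
  if (!all(dim(range_mask) == dim(strata$zone)))
    stop("misaligned grids: range mask and zone map differ", call. = FALSE)
  area <- cell_area_matrix(strata$grid)
  ok <- !is.na(strata$zone)
  z <- strata$zone[ok]
  tot <- tapply(area[ok], z, sum)
  inr <- tapply(area[ok] * (range_mask[ok] > 0), z, sum)
  data.frame(zone = as.integer(names(tot)),
             total_km2 = as.numeric(tot),
             in_range_km2 = as.numeric(inr),
             fraction = as.numeric(inr / tot))
}

#' Area-weighted cross-tabulation of two categorical rasters
#'
#' Contingency table of latitude-weighted area between e.g. strata/zones and
#' land-cover classes, plus row proportions.
#'
#' @param a,b aligned integer matrices (NA = nodata; cells NA in either are
#'   excluded).
#' @param grid the shared [geo_grid()].
#' @return list with `area` (matrix of km^2, rows = classes of `a`) and
#'   `row_prop` (rows summing to 1).
#' @export
crosstab_categories <- function(a, b, grid) {
  if (!all(dim(a) == dim(b)))
    stop("misaligned grids: rasters differ in dimension", call. = FALSE)
  area <- cell_area_matrix(grid)
  ok <- !is.na(a) & !is.na(b)
  t <- tapply(area[ok], list(a[ok], b[ok]), sum)
  t[is.na(t)] <- 0
  rp <- sweep(t, 1, rowSums(t), "/")
  list(area = t, row_prop = rp)
}
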