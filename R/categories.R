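#' Favourability category codes and labels
#'
#' Base categories are an ordered five-class scheme coded 1..5:
#' unsuitable < low use < utilised < favoured < highly favoured.
#' Joint classes (split ensemble agreement between two categories) are coded
#' `10 * lower + upper` (e.g. 45 = "favoured/highly favoured"); the
#' "uncertain" class is coded 99. `category_labels()` returns the display
#' names for a vector of codes; names are configurable for display via
#' `base_names`.
#'
#' @param codes integer vector of category codes.
#' @param base_names character(5) display names for codes 1..5.
#' @return character vector of labels.
#' @export
category_labels <- function(codes,
                            base_names = c("unsuitable", "low use",
                                           "utilised", "favoured",
                                           "highly favoured")) {
  vapply(codes, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k == 99) return("uncertain")
    if (k >= 1 && k <= 5) return(base_names[k])
    lo <- k %/% 10; hi <- k %% 10
    if (lo >= 1 && hi <= 5 && lo < hi)
      return(paste(base_names[lo], base_names[hi], sep = "/"))
    stop(sprintf("unknown category code %s", k), call. = FALSE)
  }, character(1))
}

#' Classify a suitable-habitat fraction into the five-class scheme
#'
#' Interval scheme (fractions of a stratum's area meeting the binary
#' suitability threshold): `[0, 0.10)` unsuitable, `[0.10, 0.40)` low use,
#' `[0.40, 0.60)` utilised, `[0.60, 0.80)` favoured, `[0.80, 1]` highly
#' favoured. Intervals are left-closed/right-open (the printed "<10%" upper
#' bound of "unsuitable" forces 0.10 into "low use"); the top interval is
#' closed at 1.
#'
#' @param fraction numeric in `[0, 1]`, vectorised.
#' @return integer category codes 1..5.
#' @export
categorize <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("fraction must lie in [0, 1]", call. = FALSE)
  # right = FALSE: left-closed intervals; include.lowest closes the top at 1
  as.integer(cut(fraction, breaks = c(0, 0.10, 0.40, 0.60, 0.80, 1),
                 right = FALSE, include.lowest = TRUE))
}

#' Area-weighted suitable fraction per stratum
#'
#' For every stratum present in the map, sums the latitude-weighted area of
#' its cells and of its binary-suitable cells, and classifies the fraction.
#' Strata absent from the extent are omitted (logged).
#'
#' @param binary logical matrix (suitable / not; NA off-mask), aligned with
#'   `strata`.
#' @param strata a `strata_map`.
#' @param level `"stratum"` or `"zone"`.
#' @return a data.frame (`stratum` (or `zone`), `suitable_km2`, `total_km2`,
#'   `fraction`, `category`, `label`).
#' @export
suitable_fraction_by_stratum <- function(binary, strata, level = "stratum") {
  level <- match.arg(level, c("stratum", "zone"))
  lab_grid <- strata[[level]]
  if (!all(dim(binary) == dim(lab_grid)))
    stop("misaligned grids: binary and strata dimensions differ",
         call. = FALSE)
  area <- cell_area_matrix(strata$grid)
  ok <- !is.na(lab_grid) & !is.na(binary)
  ids <- lab_grid[ok]
  tot <- tapply(area[ok], ids, sum)
  suit <- tapply(area[ok] * (binary[ok] > 0), ids, sum)
  frac <- as.numeric(suit / tot)
  out <- data.frame(id = as.integer(names(tot)),
                    suitable_km2 = as.numeric(suit),
                    total_km2 = as.numeric(tot),
                    fraction = frac,
                    category = categorize(frac))
  out$label <- category_labels(out$category)
  names(out)[1] <- level
  n_all <- if (level == "stratum") strata$n_strata else strata$n_zones
  missing <- setdiff(seq_len(n_all), out[[level]])
  if (length(missing) > 0)
    message(sprintf("suitable_fraction_by_stratum: %d %s absent from extent",
                    length(missing), level))
  out
}

#' Paint per-stratum categories onto the map
#'
#' @param strata a `strata_map`.
#' @param table output of [suitable_fraction_by_stratum()].
#' @param level `"stratum"` or `"zone"`.
#' @return an object of class `category_map`: `grid` plus integer `codes`
#'   matrix (NA preserved off-mask).
#' @export
apply_categories <- function(strata, table, level = "stratum") {
  level <- match.arg(level, c("stratum", "zone"))
  lab_grid <- strata[[level]]
  present <- sort(unique(lab_grid[!is.na(lab_grid)]))
  missing <- setdiff(present, table[[level]])
  if (length(missing) > 0)
    stop(sprintf("strata missing from category table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lut <- rep(NA_integer_, max(table[[level]]))
  lut[table[[level]]] <- table$category
  codes <- new_layer(strata$grid)
  ok <- !is.na(lab_grid)
  codes[ok] <- lut[lab_grid[ok]]
  structure(list(grid = strata$grid, codes = codes,
                 slice_label = strata$slice_label),
            class = "category_map")
}

# ensemble cell rule: strict mode; two-way adjacent tie -> joint class;
# any other tie -> uncertain
combine_cell <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  tab <- tabulate(x, nbins = 5L)
  top <- max(tab)
  winners <- which(tab == top)
  if (length(winners) == 1L) return(winners)
  if (length(winners) == 2L && diff(winners) == 1L)
    return(10L * winners[1] + winners[2])
  99L
}

#' Combine an ensemble of categorical maps (modal / joint / uncertain)
#'
#' Cellwise over aligned base-category maps (one per pseudo-GCM member): the
#' strict modal category if unique; a joint class if the top count is tied
#' between exactly two ADJACENT categories ("split agreement"); otherwise —
#' a tie between non-adjacent categories or a three-or-more-way tie —
#' "uncertain".
#'
#' @param maps non-empty list of `category_map`s holding base codes 1..5.
#' @return a `category_map` possibly containing joint codes and 99
#'   (uncertain).
#' @export
combine_ensemble <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  g <- maps[[1]]$grid
  for (m in maps) stop_if_misaligned(g, m$grid, "ensemble maps")
  codes_in <- matrix(unlist(lapply(maps, function(m) as.vector(m$codes))),
                     nrow = g$nlat * g$nlon, ncol = length(maps))
  if (any(codes_in > 5, na.rm = TRUE))
    stop("ensemble members must contain base categories only", call. = FALSE)
  out <- apply(codes_in, 1, combine_cell)
  structure(list(grid = g, codes = matrix(out, g$nlat, g$nlon),
                 slice_label = maps[[1]]$slice_label),
            class = "category_map")
}

# printed collapse table for area accounting of split-agreement maps:
# joint code -> base code. The asymmetric last entry is deliberate.
COLLAPSE_TABLE <- c("45" = 5L,  # highly favoured/favoured -> highly favoured
                    "34" = 4L,  # favoured/utilised        -> favoured
                    "23" = 3L,  # low use/utilised         -> utilised
                    "13" = 2L)  # unsuitable/utilised      -> low use

#' Collapse joint classes to base categories for area accounting
#'
#' Applies the fixed mapping table: "favoured/highly favoured" to "highly
#' favoured", "utilised/favoured" to "favoured", "low use/utilised" to
#' "utilised", and "unsuitable/utilised" to "low use". Base categories pass
#' through; "uncertain" and joint classes outside the table (only
#' "unsuitable/low use" is constructible) pass through unchanged; codes
#' outside the category system raise an error. Idempotent.
#'
#' @param map a `category_map`.
#' @param table named integer vector (joint code as name, base code as
#'   value); default the standard collapse table.
#' @return a `category_map` whose mapped joint classes are collapsed.
#' @export
collapse_classes <- function(map, table = COLLAPSE_TABLE) {
  codes <- map$codes
  vals <- codes[!is.na(codes)]
  category_labels(unique(vals)) # validates codes
  for (nm in names(table)) {
    codes[!is.na(codes) & codes == as.integer(nm)] <- table[[nm]]
  }
  map$codes <- codes
  map
}
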