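#' Fit an environmental stratification from a bioclimatic stack
#'
#' Standardises the four bioclimatic variables over land cells, takes their
#' principal components, partitions the cells into `n_strata` multivariate
#' strata by k-means (multiple restarts, seeded), and aggregates the stratum
#' centroids into `n_zones` zones by Ward agglomerative clustering. Zones are
#' numbered by descending centroid growing degree-days, so zone 1 is the
#' warmest.
#'
#' @param stack a `bioclim_stack` on the baseline (present-day) climate.
#' @param n_strata number of strata S (default 125).
#' @param n_zones number of zones Z (default 18), Z <= S.
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @param iter_max k-means iteration cap.
#' @return an object of class `strat_model`: standardisation (`center`,
#'   `scale`), PCA `rotation` and `ev_fraction`, k-means `centroids` in PC
#'   space (S x nPC), `stratum_zone` (integer S-vector), `n_strata`,
#'   `n_zones`, and `training` (cells + labels of the fitted stack).
#' @export
fit_stratification <- function(stack, n_strata = 125L, n_zones = 18L,
                               seed = 1L, nstart = 5L, iter_max = 100L) {
  stopifnot(inherits(stack, "bioclim_stack"))
  if (n_zones > n_strata || n_zones < 1L)
    stop("need 1 <= n_zones <= n_strata", call. = FALSE)
  sv <- stack_values(stack)
  if (nrow(sv$X) < n_strata)
    stop(sprintf("n_strata (%d) exceeds the number of land cells (%d)",
                 n_strata, nrow(sv$X)), call. = FALSE)
  ctr <- colMeans(sv$X)
  scl <- apply(sv$X, 2, stats::sd)
  scl[scl == 0] <- 1 # constant variable: leave centred at zero
  Z <- sweep(sweep(sv$X, 2, ctr), 2, scl, "/")
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- pca$x # all components retained

  km <- with_seed(seed, {
    if (n_strata == 1L) {
      list(centers = matrix(colMeans(scores), nrow = 1),
           cluster = rep(1L, nrow(scores)))
    } else {
      stats::kmeans(scores, centers = n_strata, nstart = nstart,
                    iter.max = iter_max)
    }
  })

  # zones: Ward clustering of stratum centroids, then warmth ordering
  if (n_zones == n_strata) {
    raw_zone <- seq_len(n_strata)
  } else if (n_zones == 1L) {
    raw_zone <- rep(1L, n_strata)
  } else {
    hc <- stats::hclust(stats::dist(km$centers), method = "ward.D2")
    raw_zone <- stats::cutree(hc, k = n_zones)
  }
  # centroid gdd0 in original units: invert PCA and standardisation
  cent_orig <- sweep(sweep(km$centers %*% t(pca$rotation), 2, scl, "*"),
                     2, -ctr, "-")
  colnames(cent_orig) <- BIOCLIM_VARS
  zone_warmth <- tapply(cent_orig[, "gdd0"], raw_zone, mean)
  # warmest raw zone becomes zone 1; ties broken by lower raw id
  ord <- order(-zone_warmth, as.integer(names(zone_warmth)))
  relabel <- integer(n_zones)
  relabel[as.integer(names(zone_warmth))[ord]] <- seq_len(n_zones)
  stratum_zone <- relabel[raw_zone]

  structure(list(center = ctr, scale = scl,
                 rotation = pca$rotation, ev_fraction = ev,
                 centroids = km$centers, centroids_orig = cent_orig,
                 stratum_zone = as.integer(stratum_zone),
                 n_strata = as.integer(n_strata),
                 n_zones = as.integer(n_zones),
                 variables = BIOCLIM_VARS,
                 # labels re-derived by nearest centroid so the training map
                 # is exactly what classify_grid() reproduces
                 training = list(cells = sv$cells,
                                 labels = nearest_centroid(scores, km$centers)),
                 fitted = TRUE),
            class = "strat_model")
}

#' @export
print.strat_model <- function(x, ...) {
  cat(sprintf("strat_model: %d strata, %d zones; PC variance fractions %s\n",
              x$n_strata, x$n_zones,
              paste(sprintf("%.3f", x$ev_fraction), collapse = " ")))
  invisible(x)
}

#' Explained-variance fractions of the stratification PCA
#'
#' @param model a fitted `strat_model`.
#' @return non-increasing fractions summing to 1, one per principal component.
#' @export
explained_variance <- function(model) {
  if (!isTRUE(model$fitted)) stop("model is not fitted", call. = FALSE)
  model$ev_fraction
}

# project a stack's land-cell values into the model's PC space
project_scores <- function(model, X) {
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Z %*% model$rotation
}

#' Classify a bioclimatic stack into fitted strata and zones
#'
#' Assigns every land cell the stratum whose centroid is nearest in the
#' model's standardised principal-component space (ties broken by the lowest
#' stratum id), and looks up the stratum's zone. Deterministic; applicable to
#' any grid and any climate (paleoclimate projection, perturbed ensemble
#' member).
#'
#' @param model a fitted `strat_model`.
#' @param stack a `bioclim_stack` on any grid.
#' @return an object of class `strata_map`: `grid`, integer matrices
#'   `stratum` and `zone` (NA off-mask), and the source `model` dimensions.
#' @export
classify_grid <- function(model, stack) {
  if (!isTRUE(model$fitted)) stop("model is not fitted", call. = FALSE)
  stopifnot(inherits(stack, "bioclim_stack"))
  stratum <- new_layer(stack$grid)
  zone <- new_layer(stack$grid)
  sv <- stack_values(stack)
  if (length(sv$cells) > 0) {
    sc <- project_scores(model, sv$X)
    lab <- nearest_centroid(sc, model$centroids)
    stratum[sv$cells] <- lab
    zone[sv$cells] <- model$stratum_zone[lab]
  }
  structure(list(grid = stack$grid, stratum = stratum, zone = zone,
                 n_strata = model$n_strata, n_zones = model$n_zones,
                 slice_label = stack$slice_label),
            class = "strata_map")
}

# row-wise nearest centroid; ties -> lowest centroid index.
# squared distances via the expansion |x|^2 - 2 x.c + |c|^2 (|x|^2 constant
# per row, dropped); max.col(ties.method = "first") on the negated distances
# gives the lowest-index tie-break.
nearest_centroid <- function(scores, centroids) {
  cross <- scores %*% t(centroids)
  d2 <- sweep(-2 * cross, 2, rowSums(centroids^2), "+")
  max.col(-d2, ties.method = "first")
}
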