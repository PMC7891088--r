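test_that("fit_stratification produces S strata, Z zones, warmth-ordered", {
  st <- make_test_stack(resolution = 2)
  m <- fit_stratification(st, n_strata = 20, n_zones = 5, seed = 1)
  expect_equal(nrow(m$centroids), 20)
  expect_equal(length(unique(m$stratum_zone)), 5)
  expect_true(all(m$stratum_zone %in% 1:5))
  # zone 1 is the warmest by centroid growing degree-days
  zw <- tapply(m$centroids_orig[, "gdd0"], m$stratum_zone, mean)
  expect_true(all(diff(zw[order(as.integer(names(zw)))]) <= 1e-9))
  # explained variance fractions: non-increasing, sum to one
  ev <- explained_variance(m)
  expect_equal(sum(ev), 1)
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(length(ev) <= 4)

  # n_strata = 1: one stratum, constant zone map
  m1 <- fit_stratification(st, n_strata = 1, n_zones = 1, seed = 1)
  mp1 <- classify_grid(m1, st)
  expect_true(all(mp1$stratum[st$land_mask] == 1))
  expect_error(fit_stratification(st, n_strata = 1e7, n_zones = 2, seed = 1),
               "exceeds")
})

test_that("two well-separated clusters match the exhaustive 2-means oracle", {
  # 20-cell grid, two tight clusters in climate space
  g <- geo_grid(0, 5, 0, 4, 1)
  set.seed(5)
  grp <- rep(c(0, 1), each = 10)
  layers <- list(
    gdd0 = matrix(3000 + 4000 * grp + rnorm(20, 0, 50), 4, 5),
    temp_seasonality = matrix(300 + 200 * grp + rnorm(20, 0, 10), 4, 5),
    aridity_index = matrix(0.3 + 0.8 * grp + rnorm(20, 0, 0.02), 4, 5),
    pet_seasonality = matrix(30 + 20 * grp + rnorm(20, 0, 1), 4, 5))
  st <- structure(list(grid = g, land_mask = matrix(TRUE, 4, 5),
                       layers = layers, slice_label = "toy"),
                  class = "bioclim_stack")
  m <- fit_stratification(st, n_strata = 2, n_zones = 2, seed = 1)
  lab <- classify_grid(m, st)$stratum

  # exhaustive oracle: best 2-partition over all assignments (cell 20 fixed
  # in group B, halving the scan) by within-cluster sum of squares on the
  # standardised PCs; SS_within = SS_total - |sum_A|^2/n_A - |sum_B|^2/n_B
  sv <- paleorange:::stack_values(st)
  Z <- scale(sv$X)
  pcs <- prcomp(Z, center = FALSE)$x
  codes <- 1:(2^19 - 1)
  B <- vapply(0:18, function(b) bitwAnd(codes, 2^b) > 0,
              logical(length(codes)))
  B <- cbind(B, FALSE)
  sumA <- B %*% pcs
  nA <- rowSums(B)
  total <- colSums(pcs)
  sumB <- sweep(-sumA, 2, total, "+")
  ss <- -(rowSums(sumA^2) / nA + rowSums(sumB^2) / (20 - nA))
  best <- B[which.min(ss), ]
  got <- lab[sv$cells] == lab[sv$cells][1]
  expect_true(identical(unname(got), unname(best)) ||
                identical(unname(got), unname(!best)))
})

test_that("classify_grid is a nearest-centroid scan, idempotent, stable", {
  st <- make_test_stack(resolution = 2)
  m <- fit_stratification(st, n_strata = 15, n_zones = 4, seed = 3)

  # classifying the training stack reproduces the fitted labels exactly
  mp <- classify_grid(m, st)
  expect_equal(mp$stratum[m$training$cells], as.numeric(m$training$labels))

  # 30-cell perturbed stack equals a brute-force distance scan
  g <- geo_grid(0, 6, 0, 5, 1)
  set.seed(8)
  pert <- structure(list(
    grid = g, land_mask = matrix(TRUE, 5, 6),
    layers = lapply(st$layers, function(l)
      matrix(sample(l[!is.na(l)], 30) * runif(30, 0.9, 1.1), 5, 6)),
    slice_label = "pert"), class = "bioclim_stack")
  lab <- classify_grid(m, pert)$stratum
  sv <- paleorange:::stack_values(pert)
  Z <- sweep(sweep(sv$X, 2, m$center), 2, m$scale, "/")
  pcs <- Z %*% m$rotation
  for (r in seq_along(sv$cells)) {
    d <- apply(m$centroids, 1, function(cen) sum((pcs[r, ] - cen)^2))
    expect_equal(lab[sv$cells[r]], unname(which.min(d)))
  }

  # all-nodata stack classifies to all-nodata
  empty <- pert; empty$land_mask[] <- FALSE
  for (nm in names(empty$layers)) empty$layers[[nm]][] <- NA_real_
  expect_true(all(is.na(classify_grid(m, empty)$stratum)))

  # determinism across refits with the same seed
  m2 <- fit_stratification(st, n_strata = 15, n_zones = 4, seed = 3)
  expect_identical(m$centroids, m2$centroids)
  expect_identical(m$stratum_zone, m2$stratum_zone)
})

test_that("explained variance matches an independent eigendecomposition", {
  st <- make_test_stack(resolution = 2)
  m <- fit_stratification(st, n_strata = 5, n_zones = 2, seed = 1)
  sv <- paleorange:::stack_values(st)
  ev_or <- eigen(cov(scale(sv$X)))$values
  expect_equal(explained_variance(m), ev_or / sum(ev_or), tolerance = 1e-8)

  # duplicated-variable rank deficiency: first PC takes all the variance
  st2 <- st
  st2$layers$temp_seasonality <- st2$layers$gdd0
  st2$layers$aridity_index <- st2$layers$gdd0
  st2$layers$pet_seasonality <- st2$layers$gdd0
  m2 <- fit_stratification(st2, n_strata = 3, n_zones = 2, seed = 1)
  expect_equal(explained_variance(m2)[1], 1, tolerance = 1e-8)
})

test_that("fitted centroids are invariant to cell-order permutation", {
  st <- make_test_stack(resolution = 4)
  m <- fit_stratification(st, n_strata = 8, n_zones = 3, seed = 9)
  # permute cells by transposing the world: same multiset of climates
  st2 <- st
  st2$grid <- geo_grid(st$grid$lat_min, st$grid$lat_max,
                       st$grid$lon_min, st$grid$lon_max, st$grid$resolution)
  st2$land_mask <- t(st$land_mask)
  st2$layers <- lapply(st$layers, t)
  m2 <- fit_stratification(st2, n_strata = 8, n_zones = 3, seed = 9)
  # compare in original variable units: PC axes may flip sign between fits
  ord1 <- do.call(order, as.data.frame(m$centroids_orig))
  ord2 <- do.call(order, as.data.frame(m2$centroids_orig))
  expect_equal(m$centroids_orig[ord1, ], m2$centroids_orig[ord2, ],
               ignore_attr = TRUE, tolerance = 1e-6)
})
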