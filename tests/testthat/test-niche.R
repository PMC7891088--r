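test_that("background sampling is uniform, distinct, clamped", {
  mask <- matrix(TRUE, 50, 100)
  mask[1:10, ] <- FALSE # 4000 land cells

  # B above the land-cell count: clamped to all land cells, no duplicates
  bg <- sample_background(mask, 100000, seed = 1)
  expect_equal(length(bg), sum(mask))
  expect_false(any(duplicated(bg)))

  # same seed, same sample
  b1 <- sample_background(mask, 500, seed = 7)
  b2 <- sample_background(mask, 500, seed = 7)
  expect_identical(b1, b2)
  expect_false(any(duplicated(b1)))

  # inclusion frequency uniform within binomial error over repeats
  land <- which(mask)
  hits <- integer(length(land))
  R <- 200
  for (r in seq_len(R))
    hits <- hits + as.integer(land %in% sample_background(mask, 2000, seed = r))
  p <- 2000 / length(land)
  se <- sqrt(R * p * (1 - p))
  expect_lt(max(abs(hits - R * p)), 6 * se)

  expect_error(sample_background(matrix(FALSE, 2, 2), 10, seed = 1), "empty")
  expect_error(sample_background(mask, 0, seed = 1), "B must be")
})

test_that("presence cells retain duplicates and drop off-mask records", {
  g <- geo_grid(0, 10, 0, 10, 1)
  mask <- matrix(TRUE, 10, 10); mask[1, 1] <- FALSE # NW sea cell
  occ <- data.frame(lon = c(2.5, 2.5, 0.5, 50), lat = c(2.5, 2.5, 9.5, 5),
                    source = "x", error_km = 0)
  expect_message(counts <- assign_presence_cells(occ, g, mask), "dropped 2")
  expect_equal(sum(counts), 2)
  idx <- cell_index(g, 2.5, 2.5)
  expect_equal(counts[idx$row, idx$col], 2L) # duplicates kept as counts
  empty <- assign_presence_cells(occ[0, ], g, mask)
  expect_true(all(empty == 0))
})

test_that("the fitted PPM matches a brute-force optimization of the same
           objective, and shrinks to zero without signal", {
  st <- make_tiny_stack()
  g <- st$grid
  set.seed(3)
  counts <- matrix(rpois(25, 1.5), 5, 5)
  bg <- which(st$land_mask)
  sv <- paleorange:::stack_values(st, bg)
  Fb <- sv$X
  pres <- which(counts > 0)
  Fp <- paleorange:::stack_values(st, pres)$X
  cp <- counts[pres]

  for (beta in c(1e-6, 2)) {
    spec <- feature_spec(classes = "linear", beta = beta)
    m <- fit_ppm(counts, bg, st, spec)
    # back-transform the standardised-space coefficients to raw units
    w_raw <- m$w / m$f_scale
    or <- oracle_ppm_fit(Fp, cp, Fb, beta)
    expect_equal(unname(w_raw), or$w, tolerance = 1e-4)
    # fitted penalized likelihood at least as good as the oracle's and
    # better than 1,000 random coefficient vectors
    f_fit <- oracle_ppm_objective(
      c(m$alpha - sum(m$w * m$f_center / m$f_scale), w_raw),
      Fp, cp, Fb, beta, or$s)
    expect_lte(f_fit, or$value + 1e-6)
    set.seed(42)
    for (r in 1:1000) {
      rnd <- c(or$alpha, or$w) * runif(5, 0.5, 1.5) + rnorm(5, 0, 0.01)
      expect_lte(f_fit,
                 oracle_ppm_objective(rnd, Fp, cp, Fb, beta, or$s) + 1e-9)
    }
  }

  # presences uniform over background + strong penalty: slopes shrink to 0
  uni <- matrix(1L, 5, 5)
  m0 <- fit_ppm(uni, bg, st, feature_spec(classes = "linear", beta = 50))
  expect_equal(unname(m0$w), rep(0, 4), tolerance = 1e-6)

  expect_error(fit_ppm(matrix(0L, 5, 5), bg, st), "presence")
  expect_error(fit_ppm(counts, bg[1], st), "background")
})

test_that("raw predictions normalize over background and obey log-ratios", {
  st <- make_test_stack(resolution = 4)
  truth <- make_truth_map(st, c(0, 0, 2, 0))
  occ <- generate_occurrences(truth, 200, jitter_km = 0, seed = 2)
  counts <- assign_presence_cells(occ, st$grid, st$land_mask)
  bg <- sample_background(st$land_mask, 100000, seed = 1)
  m <- fit_ppm(counts, bg, st)
  suit <- predict_raw(m, st)

  expect_equal(sum(suit$raw, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(suit$raw[st$land_mask] >= 0))

  # log-ratio identity: log raw_i - log raw_j = (z_i - z_j) . w
  cells <- which(st$land_mask & suit$raw > 0)[c(3, 50)]
  eta <- paleorange:::ppm_eta(m, st, cells)
  expect_equal(log(suit$raw[cells[1]]) - log(suit$raw[cells[2]]),
               eta[1] - eta[2], tolerance = 1e-9)

  # equal features give equal raw values: duplicate a cell's covariates
  st2 <- st
  for (nm in names(st2$layers)) st2$layers[[nm]][2, 2] <- st2$layers[[nm]][3, 3]
  s2 <- predict_raw(m, st2)
  expect_equal(s2$raw[2, 2], s2$raw[3, 3], tolerance = 1e-12)
})

test_that("k-fold AUC behaves at its separable and null limits", {
  st <- make_test_stack(resolution = 4)
  bg <- sample_background(st$land_mask, 100000, seed = 1)

  # perfectly separable synthetic signal: presences confined to the extreme
  # aridity cells, model recovers them, AUC = 1 on held-out folds
  # (background disjoint from presence cells: with overlap the rank AUC has a
  # ceiling of 1 - n_pres/(2 n_bg) even under perfect separation)
  ar <- st$layers$aridity_index
  top <- order(ar, decreasing = TRUE)[1:40]
  counts <- matrix(0L, st$grid$nlat, st$grid$nlon)
  counts[top] <- 3L
  # (penalty strong enough to bound the separated likelihood; ranking,
  # hence AUC, is unaffected)
  a <- kfold_auc(counts, setdiff(bg, top), st,
                 feature_spec(classes = "linear", beta = 50),
                 k = 5, seed = 1)
  expect_equal(as.numeric(a), 1)

  # null: presences drawn uniformly, AUC near 0.5
  set.seed(4)
  counts0 <- matrix(0L, st$grid$nlat, st$grid$nlon)
  counts0[sample(which(st$land_mask), 150)] <- 1L
  a0 <- kfold_auc(counts0, bg, st, k = 5, seed = 2)
  # SE of a rank AUC with ~30 positives per fold is ~0.05; 3 SE band
  expect_lt(abs(as.numeric(a0) - 0.5), 0.15)

  expect_error(kfold_auc(counts, bg, st, k = 1, seed = 1), "k must be")
})

test_that("checkerboard folds follow the two-scale parity rule", {
  g <- geo_grid(0, 16, 0, 16, 1)
  # hand-worked: with aggregation 2, cell (row, col) 1-based ->
  # fine block (floor((r-1)/2), floor((c-1)/2)), fold = 1 + pf + 2 pc
  hand <- function(r, c) {
    fi <- (r - 1) %/% 2; fj <- (c - 1) %/% 2
    pf <- (fi + fj) %% 2
    pc <- (fi %/% 2 + fj %/% 2) %% 2
    1 + pf + 2 * pc
  }
  pts <- rbind(c(1, 1), c(1, 3), c(3, 1), c(3, 3),
               c(5, 1), c(1, 5), c(5, 5), c(8, 8))
  cells <- pts[, 1] + (pts[, 2] - 1) * g$nlat
  expect_equal(checkerboard_fold(g, cells, aggregation = 2),
               apply(pts, 1, function(p) hand(p[1], p[2])))

  # presences spread over all four phases give 4 non-empty folds
  st <- make_test_stack(resolution = 4)
  truth <- make_truth_map(st, c(0, 0, 2, 0))
  occ <- generate_occurrences(truth, 300, jitter_km = 0, seed = 5)
  counts <- assign_presence_cells(occ, st$grid, st$land_mask)
  bg <- sample_background(st$land_mask, 100000, seed = 1)
  a <- checkerboard_cv_auc(counts, bg, st, aggregation = 2, seed = 1)
  expect_length(attr(a, "folds"), 4)

  # an empty fold errors with occupancy
  counts1 <- matrix(0L, st$grid$nlat, st$grid$nlon)
  counts1[which(st$land_mask)[1]] <- 1L
  expect_error(checkerboard_cv_auc(counts1, bg, st), "occupancy")
})

test_that("lowest-presence threshold matches the exhaustive-scan oracle", {
  # worked example: deciles
  r <- lowest_presence_threshold(seq(0.1, 1, by = 0.1), e = 0.10)
  expect_equal(r$t, 0.2)
  expect_equal(r$realized_omission, 0.1)

  # e = 0: classical lowest presence
  r0 <- lowest_presence_threshold(c(0.4, 0.2, 0.9), e = 0)
  expect_equal(r0$t, 0.2)
  expect_equal(r0$realized_omission, 0)

  # ties at the minimum: omitting one of a tied pair is impossible
  rt <- lowest_presence_threshold(c(0.1, 0.1, 0.9), e = 0.10)
  expect_equal(rt$t, 0.1)
  expect_equal(rt$realized_omission, 0)

  expect_error(lowest_presence_threshold(c(0.1), e = 1), "e must be")

  # property: oracle agreement and omission bound over random vectors
  set.seed(1)
  for (case in 1:300) {
    n <- sample(1:40, 1)
    v <- round(runif(n), sample(1:3, 1)) # induce ties
    e <- runif(1, 0, 0.5)
    r <- lowest_presence_threshold(v, e)
    expect_equal(r$t, oracle_threshold(v, e))
    expect_lte(r$realized_omission, e)
  }
})

test_that("binarize is monotone in the threshold and preserves nodata", {
  st <- make_test_stack(resolution = 4)
  truth <- make_truth_map(st, c(0.5, -0.5, 1, -0.5))
  expect_true(all(binarize(truth, 0)[st$land_mask]))
  expect_false(any(binarize(truth, max(truth$raw, na.rm = TRUE) * 1.01),
                   na.rm = TRUE))
  counts_at <- vapply(quantile(truth$raw, c(0.1, 0.5, 0.9), na.rm = TRUE),
                      function(t) sum(binarize(truth, t), na.rm = TRUE),
                      numeric(1))
  expect_true(all(diff(counts_at) <= 0))
  expect_error(binarize(truth, -1), "t must be")
})
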