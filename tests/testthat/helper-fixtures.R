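# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain scalar code, separate from the vectorised package paths they check.

make_test_climate <- function(resolution = 2, seed = 1, spec = scenario_spec(),
                              mask = NULL) {
  g <- default_grid(resolution)
  generate_climate(spec, g, seed = seed, land_mask = mask)
}

make_test_stack <- function(resolution = 2, seed = 1, spec = scenario_spec()) {
  build_bioclim_stack(make_test_climate(resolution, seed, spec))
}

# suitability map from a log-linear truth over the standardised bioclim
# variables (the known generating intensity for recovery experiments)
make_truth_map <- function(stack, w) {
  sv <- paleorange:::stack_values(stack)
  Z <- scale(sv$X)
  eta <- drop(Z %*% w)
  raw <- matrix(NA_real_, stack$grid$nlat, stack$grid$nlon)
  raw[sv$cells] <- exp(eta - max(eta))
  raw[sv$cells] <- raw[sv$cells] / sum(raw[sv$cells])
  structure(list(grid = stack$grid, raw = raw, slice_label = "truth"),
            class = "suitability_map")
}

# ---- independent oracles ---------------------------------------------------

# Hargreaves PET for one cell-month, hand-coded from the standard
# solar-geometry formulae (FAO-56 style), scalar arithmetic only.
oracle_pet_month <- function(tmean, tmin, tmax, lat_deg, month) {
  dim <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  doy <- sum(dim[seq_len(month - 1)]) + dim[month] / 2
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- -tan(phi) * tan(dec)
  if (x > 1) x <- 1
  if (x < -1) x <- -1
  ws <- acos(x)
  ra_mj <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  ra_mm <- 0.408 * max(ra_mj, 0)
  pet_day <- 0.0023 * ra_mm * (tmean + 17.8) * sqrt(max(tmax - tmin, 0))
  max(pet_day, 0) * dim[month]
}

# exhaustive-scan threshold oracle: loop over every observed value
oracle_threshold <- function(v, e) {
  best <- min(v)
  for (t in v) {
    omitted <- 0
    for (x in v) if (x < t) omitted <- omitted + 1
    if (omitted / length(v) <= e && t > best) best <- t
  }
  best
}

# penalized PPM objective in ORIGINAL feature space (not the package's
# standardised parameterisation): direct transcription of the likelihood
oracle_ppm_objective <- function(par, Fp, cp, Fb, beta, s) {
  alpha <- par[1]; w <- par[-1]
  ll <- sum(cp * (alpha + Fp %*% w)) - sum(exp(alpha + Fb %*% w))
  -ll + beta * sum(s * abs(w))
}

# brute-force generic optimisation of the oracle objective (Nelder-Mead with
# restarts, then a quasi-Newton polish)
oracle_ppm_fit <- function(Fp, cp, Fb, beta) {
  s <- apply(Fb, 2, sd)
  k <- ncol(Fb)
  best <- NULL
  par <- c(log(sum(cp) / nrow(Fb)), rep(0, k))
  for (r in 1:6) {
    o <- optim(par, oracle_ppm_objective, Fp = Fp, cp = cp, Fb = Fb,
               beta = beta, s = s, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
    par <- best$par
  }
  list(alpha = best$par[1], w = best$par[-1], value = best$value, s = s)
}

# tiny 5x5 single-variable world for exact PPM comparisons: a bioclim_stack
# whose four layers are constructed directly (no climate generator)
make_tiny_stack <- function(n = 5, seed = 42) {
  g <- geo_grid(0, n, 0, n, 1)
  set.seed(seed)
  layers <- list(gdd0 = matrix(runif(n * n, 1000, 9000), n, n),
                 temp_seasonality = matrix(runif(n * n, 100, 900), n, n),
                 aridity_index = matrix(runif(n * n, 0.05, 2), n, n),
                 pet_seasonality = matrix(runif(n * n, 10, 90), n, n))
  structure(list(grid = g, land_mask = matrix(TRUE, n, n), layers = layers,
                 slice_label = "tiny"),
            class = "bioclim_stack")
}

# category map literal for ensemble tests
make_cat_map <- function(codes_matrix, grid = NULL) {
  if (is.null(grid))
    grid <- geo_grid(0, ncol(codes_matrix), 0, nrow(codes_matrix), 1)
  structure(list(grid = grid, codes = codes_matrix, slice_label = "test"),
            class = "category_map")
}
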