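#' Feature specification for the point-process niche model
#'
#' @param classes subset of `c("linear", "quadratic", "product")`; default
#'   linear + quadratic (no hinge features: the model stays smooth and has an
#'   exact likelihood oracle).
#' @param beta L1 regularization multiplier (> 0, default 2). The penalty on
#'   feature j is `beta * s_j * |w_j|` with `s_j` the feature's standard
#'   deviation over the background.
#' @param n_background background points requested (default 100000); clamped
#'   to the number of land cells on desk-scale grids.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic"), beta = 2,
                         n_background = 100000L) {
  classes <- match.arg(classes, c("linear", "quadratic", "product"),
                       several.ok = TRUE)
  if (length(classes) < 1L) stop("need at least one feature class",
                                 call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(classes = classes, beta = beta,
                 n_background = as.integer(n_background)),
            class = "feature_spec")
}

# expand an n x 4 covariate matrix into the requested feature classes
expand_features <- function(X, classes) {
  out <- NULL
  nm <- colnames(X)
  if ("linear" %in% classes) out <- X
  if ("quadratic" %in% classes) {
    Q <- X^2
    colnames(Q) <- paste0(nm, "^2")
    out <- cbind(out, Q)
  }
  if ("product" %in% classes) {
    pairs <- utils::combn(ncol(X), 2)
    P <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(P) <- paste0(nm[pairs[1, ]], ":", nm[pairs[2, ]])
    out <- cbind(out, P)
  }
  out
}

#' Sample background cells uniformly from a land mask
#'
#' Draws `min(B, n_land)` distinct land cells uniformly without replacement.
#' Presence cells are never added to the background (they participate only
#' through the presence term of the likelihood).
#'
#' @param mask logical land-mask matrix.
#' @param B requested number of background points; clamped to the land-cell
#'   count.
#' @param seed integer seed.
#' @return integer vector of cell indices (column-major, sorted).
#' @export
sample_background <- function(mask, B = 100000L, seed = 1L) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  land <- which(mask)
  if (length(land) == 0L) stop("empty land mask", call. = FALSE)
  if (B >= length(land)) return(land)
  with_seed(seed, sort(sample(land, B)))
}

#' Map occurrence records to per-cell presence counts
#'
#' Duplicate records in a cell are retained as counts (no deduplication).
#' Records falling outside the grid or on non-land cells are dropped and the
#' dropped count reported via a message and the `dropped` attribute.
#'
#' @param occ occurrence data.frame (`lon`, `lat`, ...).
#' @param grid a [geo_grid()].
#' @param mask optional logical land mask; sea cells drop their records.
#' @return integer matrix of per-cell counts with attribute `dropped`.
#' @export
assign_presence_cells <- function(occ, grid, mask = NULL) {
  counts <- matrix(0L, grid$nlat, grid$nlon)
  idx <- cell_index(grid, occ$lon, occ$lat)
  ok <- !is.na(idx$row)
  if (!is.null(mask)) {
    onland <- ok
    onland[ok] <- mask[cbind(idx$row[ok], idx$col[ok])]
    ok <- ok & onland
  }
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("assign_presence_cells: dropped %d record(s) off grid/mask",
                    dropped))
  if (any(ok)) {
    cell <- idx$row[ok] + (idx$col[ok] - 1L) * grid$nlat
    tab <- tabulate(cell, nbins = grid$nlat * grid$nlon)
    counts[tab > 0] <- as.integer(tab[tab > 0])
  }
  attr(counts, "dropped") <- dropped
  counts
}

# penalized negative log-likelihood of the Poisson point process and its
# gradient, in standardised feature space. theta = (alpha, wplus, wminus),
# w = wplus - wminus, both nonnegative; L1 penalty beta * sum(wplus + wminus)
# is linear, so L-BFGS-B with lower bounds solves the L1 problem exactly.
ppm_objective <- function(theta, Zp, cp, Zb, beta) {
  k <- ncol(Zb)
  alpha <- theta[1]
  w <- theta[2:(k + 1)] - theta[(k + 2):(2 * k + 1)]
  eta_b <- alpha + drop(Zb %*% w)
  mu <- exp(eta_b)
  nll <- -(sum(cp * (alpha + drop(Zp %*% w))) ) + sum(mu)
  nll + beta * sum(theta[-1])
}

ppm_gradient <- function(theta, Zp, cp, Zb, beta) {
  k <- ncol(Zb)
  alpha <- theta[1]
  w <- theta[2:(k + 1)] - theta[(k + 2):(2 * k + 1)]
  mu <- exp(alpha + drop(Zb %*% w))
  g_alpha <- -sum(cp) + sum(mu)
  g_w <- -drop(crossprod(Zp, cp)) + drop(crossprod(Zb, mu))
  c(g_alpha, g_w + beta, -g_w + beta)
}

#' Fit the MaxEnt-style Poisson point-process model
#'
#' Maximises the penalized log-likelihood of an inhomogeneous Poisson point
#' process with intensity `lambda(x) = exp(alpha + f(x) . w)` over the
#' background quadrature cells (weight 1 per cell), where `f` is the feature
#' expansion of the four bioclimatic covariates. The L1 penalty is
#' `beta * sum_j s_j |w_j|` with `s_j` the background standard deviation of
#' feature j. Internally features are standardised by their background
#' mean/sd (so the penalty is `beta * |w|` in standardised space) and the
#' problem is solved exactly by L-BFGS-B on the split `w = w+ - w-`
#' formulation with nonnegativity bounds; the intercept is unpenalized.
#'
#' @param presence_counts integer per-cell count matrix
#'   (see [assign_presence_cells()]).
#' @param background integer vector of background cell indices.
#' @param stack a `bioclim_stack` supplying the covariates.
#' @param spec a [feature_spec()].
#' @param tol convergence tolerance passed to the optimizer (factr scale).
#' @return an object of class `niche_model`: standardised-space coefficients
#'   (`alpha`, `w`), feature names and background standardisation
#'   (`f_center`, `f_scale`), the `spec`, background cell indices, and
#'   convergence diagnostics.
#' @export
fit_ppm <- function(presence_counts, background, stack, spec = feature_spec(),
                    tol = 1e-9) {
  stopifnot(inherits(spec, "feature_spec"), inherits(stack, "bioclim_stack"))
  pres_cells <- which(presence_counts > 0)
  if (length(pres_cells) < 1L) stop("need at least one presence",
                                    call. = FALSE)
  if (length(background) < 2L) stop("need at least two background cells",
                                    call. = FALSE)
  cp <- as.numeric(presence_counts[pres_cells])
  Xb <- stack_values(stack, background)$X
  Xp <- stack_values(stack, pres_cells)$X
  if (anyNA(Xp))
    stop("presence cell with nodata covariates", call. = FALSE)
  Fb <- expand_features(Xb, spec$classes)
  Fp <- expand_features(Xp, spec$classes)
  f_center <- colMeans(Fb)
  f_scale <- apply(Fb, 2, stats::sd)
  f_scale[f_scale == 0] <- 1
  Zb <- sweep(sweep(Fb, 2, f_center), 2, f_scale, "/")
  Zp <- sweep(sweep(Fp, 2, f_center), 2, f_scale, "/")
  k <- ncol(Zb)

  theta0 <- c(log(sum(cp) / nrow(Zb)), rep(0, 2 * k))
  opt <- stats::optim(theta0, ppm_objective, ppm_gradient,
                      Zp = Zp, cp = cp, Zb = Zb, beta = spec$beta,
                      method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * k)),
                      control = list(maxit = 5000L, factr = tol / 1e-15))
  if (opt$convergence != 0)
    stop(sprintf("point-process fit did not converge (code %d): %s",
                 opt$convergence, opt$message), call. = FALSE)
  w <- opt$par[2:(k + 1)] - opt$par[(k + 2):(2 * k + 1)]
  names(w) <- colnames(Fb)
  structure(list(alpha = opt$par[1], w = w,
                 feature_names = colnames(Fb),
                 f_center = f_center, f_scale = f_scale,
                 spec = spec, background = background,
                 objective = opt$value, fitted = TRUE),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model: %d features, beta = %g, penalized NLL = %.4f\n",
              length(x$w), x$spec$beta, x$objective))
  print(round(x$w, 4))
  invisible(x)
}

# linear predictor (standardised space) for arbitrary cells of a stack
ppm_eta <- function(model, stack, cells) {
  X <- stack_values(stack, cells)$X
  Fe <- expand_features(X, model$spec$classes)
  Z <- sweep(sweep(Fe, 2, model$f_center), 2, model$f_scale, "/")
  model$alpha + drop(Z %*% model$w)
}

#' Predict the raw relative occurrence rate
#'
#' `raw(x) = lambda(x) / sum_background lambda`, the MaxEnt "raw" output: a
#' relative occurrence rate normalized to sum to exactly 1 over the
#' background cells. When projecting onto another time slice's stack the
#' default background is that slice's own land cells, so per-slice maps are
#' comparable as relative rates.
#'
#' @param model a fitted `niche_model`.
#' @param stack a `bioclim_stack` (training slice or projection slice).
#' @param background integer cell indices over which to normalize; default
#'   all land cells of `stack`.
#' @return an object of class `suitability_map`: `grid`, matrix `raw`
#'   (NA off-mask), and the normalization `background` indices.
#' @export
predict_raw <- function(model, stack, background = NULL) {
  if (!isTRUE(model$fitted)) stop("model is not fitted", call. = FALSE)
  mask <- stack$land_mask & !is.na(stack$layers[[1]])
  cells <- which(mask)
  if (is.null(background)) background <- cells
  eta <- ppm_eta(model, stack, cells)
  eta_b <- ppm_eta(model, stack, background)
  m <- max(eta_b)
  denom <- sum(exp(eta_b - m))
  raw <- new_layer(stack$grid)
  raw[cells] <- exp(eta - m) / denom
  structure(list(grid = stack$grid, raw = raw, background = background,
                 slice_label = stack$slice_label),
            class = "suitability_map")
}

# rank-based AUC: probability a positive outranks a negative (ties 1/2)
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# shared CV engine: folds is an integer vector over presence cells
cv_auc <- function(pres_cells, counts, fold_of_pres, background,
                   fold_of_bg = NULL, stack, spec) {
  folds <- sort(unique(fold_of_pres))
  vapply(folds, function(f) {
    test_p <- pres_cells[fold_of_pres == f]
    train_p <- pres_cells[fold_of_pres != f]
    if (length(test_p) == 0L || length(train_p) == 0L)
      stop(sprintf("cross-validation fold %d has no presences", f),
           call. = FALSE)
    if (is.null(fold_of_bg)) {
      train_b <- background
      test_b <- background
    } else {
      train_b <- background[fold_of_bg != f]
      test_b <- background[fold_of_bg == f]
    }
    cmat <- matrix(0L, nrow(counts), ncol(counts))
    cmat[train_p] <- counts[train_p]
    m <- fit_ppm(cmat, train_b, stack, spec)
    pos <- ppm_eta(m, stack, test_p)
    neg <- ppm_eta(m, stack, test_b)
    auc_rank(pos, neg)
  }, numeric(1))
}

#' Random k-fold cross-validated AUC
#'
#' Presence cells are split into k seeded folds; for each fold the model is
#' refitted on the remaining presences (full background) and the AUC is the
#' rank probability that a held-out presence cell outranks a background cell.
#'
#' @param presence_counts per-cell count matrix.
#' @param background background cell indices.
#' @param stack covariate stack.
#' @param spec a [feature_spec()].
#' @param k number of folds (>= 2, default 10).
#' @param seed integer seed for the fold split.
#' @return mean AUC over folds, with per-fold values as attribute `folds`.
#' @export
kfold_auc <- function(presence_counts, background, stack,
                      spec = feature_spec(), k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  pres_cells <- which(presence_counts > 0)
  if (length(pres_cells) < k)
    stop("fewer presence cells than folds", call. = FALSE)
  fold <- with_seed(seed,
    sample(rep(seq_len(k), length.out = length(pres_cells))))
  aucs <- cv_auc(pres_cells, presence_counts, fold, background,
                 NULL, stack, spec)
  structure(mean(aucs), folds = aucs)
}

#' Two-scale checkerboard fold of grid cells
#'
#' Assigns every cell a fold in 1..4 from the parities of its aggregated
#' block indices at two scales: fine blocks of `aggregation` cells and coarse
#' blocks of `2 * aggregation` cells. `fold = 1 + fine_parity +
#' 2 * coarse_parity` where each parity is `(block_x + block_y) mod 2`.
#'
#' @param grid a [geo_grid()].
#' @param cells integer cell indices (column-major).
#' @param aggregation fine block size in cells (>= 1).
#' @return integer vector of folds in 1..4.
#' @export
checkerboard_fold <- function(grid, cells, aggregation = 2L) {
  if (aggregation < 1L) stop("aggregation must be >= 1", call. = FALSE)
  row <- (cells - 1L) %% grid$nlat
  col <- (cells - 1L) %/% grid$nlat
  fi <- row %/% aggregation
  fj <- col %/% aggregation
  pf <- (fi + fj) %% 2L
  pc <- (fi %/% 2L + fj %/% 2L) %% 2L
  as.integer(1L + pf + 2L * pc)
}

#' Spatially independent cross-validated AUC (two-scale checkerboard)
#'
#' Four folds are built from a two-scale checkerboard over grid blocks
#' (see [checkerboard_fold()]); presences AND background cells are
#' partitioned, so train and test data are spatially disjoint. Errors if any
#' fold holds no presences, listing fold occupancy.
#'
#' @inheritParams kfold_auc
#' @param aggregation fine checkerboard block size in cells.
#' @return mean AUC over the 4 folds, per-fold values as attribute `folds`.
#' @export
checkerboard_cv_auc <- function(presence_counts, background, stack,
                                spec = feature_spec(), aggregation = 2L,
                                seed = 1L) {
  grid <- stack$grid
  pres_cells <- which(presence_counts > 0)
  fold_p <- checkerboard_fold(grid, pres_cells, aggregation)
  occupancy <- tabulate(fold_p, nbins = 4L)
  if (any(occupancy == 0L))
    stop(sprintf("empty checkerboard fold(s); occupancy = [%s]",
                 paste(occupancy, collapse = ", ")), call. = FALSE)
  fold_b <- checkerboard_fold(grid, background, aggregation)
  aucs <- cv_auc(pres_cells, presence_counts, fold_p, background, fold_b,
                 stack, spec)
  structure(mean(aucs), folds = aucs)
}

#' Modified lowest-presence threshold with omission allowance
#'
#' Scans the observed presence suitability values and returns the largest
#' one such that the fraction of presences STRICTLY below it is at most `e`
#' (the allowed omission). With `e = 0` this is the classical lowest-presence
#' threshold; the allowance discounts the least-suitable records, absorbing
#' positional uncertainty in locality data. The binary rule downstream is
#' suitable iff `raw >= t`.
#'
#' @param presence_suits numeric vector of raw suitabilities at presences.
#' @param e allowed omission fraction in `[0, 1)` (default 0.10).
#' @return an object of class `threshold_result`: `t`, `realized_omission`,
#'   `e`.
#' @export
lowest_presence_threshold <- function(presence_suits, e = 0.10) {
  if (e < 0 || e >= 1) stop("e must be in [0, 1)", call. = FALSE)
  if (length(presence_suits) < 1L) stop("need >= 1 presence value",
                                        call. = FALSE)
  cand <- sort(unique(presence_suits))
  omis <- vapply(cand, function(t) mean(presence_suits < t), numeric(1))
  t <- max(cand[omis <= e])
  structure(list(t = t, realized_omission = mean(presence_suits < t), e = e),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold t = %.6g (allowed omission %.1f%%, realized %.1f%%)\n",
              x$t, 100 * x$e, 100 * x$realized_omission))
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' @param map a `suitability_map`.
#' @param t threshold on the raw scale (>= 0); suitable iff `raw >= t`.
#' @return logical matrix (NA preserved off-mask).
#' @export
binarize <- function(map, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  map$raw >= t
}
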