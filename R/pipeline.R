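#' Default run configuration
#'
#' Field defaults mirror the published analysis constants: 125 strata
#' aggregated into 18 zones, regularization multiplier 2 with 100,000
#' background points (clamped to the land-cell count on desk-scale grids),
#' a 10% omission allowance, and pseudo-GCM ensembles of nine mid-Holocene
#' and three glacial-maximum members. The three scenario specs move the
#' pluvial belt south and strengthen it for the glacial slice, and expose
#' extra coastal land (`sea_level_offset`) there.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param resolution grid resolution, degrees.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, resolution = 0.5) {
  structure(list(
    grid = list(lon_min = -40, lon_max = 60, lat_min = -40, lat_max = 40,
                resolution = resolution),
    slices = list(
      present = list(spec = scenario_spec(), n_gcm = 1L),
      mid_holocene = list(
        spec = scenario_spec(pluvial_center_lat = 14,
                             pluvial_peak_precip = 260),
        n_gcm = 9L),
      lgm = list(
        spec = scenario_spec(base_temp = 24, pluvial_center_lat = 2,
                             pluvial_peak_precip = 300,
                             sea_level_offset = 2L),
        n_gcm = 3L)),
    n_strata = 125L, n_zones = 18L,
    features = list(classes = c("linear", "quadratic"), beta = 2,
                    n_background = 100000L),
    omission = 0.10,
    n_occurrences = 1135L, jitter_km = 25, max_error_km = 50,
    truth_weights = c(gdd0 = 0.5, temp_seasonality = -0.5,
                      aridity_index = 1.5, pet_seasonality = -0.5),
    gcm_perturb = list(temp = 2, prec = 25),
    seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a JSON document
#'
#' Any field present overrides the default configuration; absent fields keep
#' their defaults, so a minimal config can set only a seed and grid.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  for (nm in names(user)) {
    if (nm == "slices") {
      for (sl in names(user$slices)) {
        u <- user$slices[[sl]]
        base <- cfg$slices[[sl]] %||% list(spec = scenario_spec(), n_gcm = 1L)
        if (!is.null(u$spec))
          base$spec <- do.call(scenario_spec,
                               utils::modifyList(unclass(base$spec),
                                                 as.list(u$spec)))
        if (!is.null(u$n_gcm)) base$n_gcm <- as.integer(u$n_gcm)
        cfg$slices[[sl]] <- base
      }
    } else if (nm == "truth_weights") {
      cfg$truth_weights <- unlist(user$truth_weights)
    } else if (nm %in% names(cfg)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$omission < 0 || cfg$omission >= 1)
    stop("omission must be in [0, 1)", call. = FALSE)
  cfg
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes)
  else if (!is.null(names(x))) as.list(x) # keep names through JSON
  else x
}

#' Write a run configuration as JSON
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(strip_classes(cfg), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

cfg_grid <- function(cfg)
  geo_grid(cfg$grid$lon_min, cfg$grid$lon_max, cfg$grid$lat_min,
           cfg$grid$lat_max, cfg$grid$resolution)

state_path <- function(dir, stage) file.path(dir, paste0("state_", stage, ".rds"))

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Pipeline stages
#'
#' Each stage reads the artefact directory written by its predecessors and
#' writes its own artefacts plus an internal state file, so the CLI
#' subcommands compose to the same result as [run_pipeline()].
#'
#' `stage_simulate` generates land masks, base climates and pseudo-GCM
#' ensembles; `stage_bioclim` derives the bioclimatic stacks, the known
#' log-linear truth suitability and the occurrence CSV; `stage_stratify`
#' fits the stratification and classifies every member; `stage_fit` fits the
#' point-process model and derives the omission-controlled threshold;
#' `stage_project` builds per-member categorical maps; `stage_combine`
#' combines each paleo ensemble with modal/joint/uncertain semantics;
#' `stage_report` writes area reports and the change table.
#'
#' @param cfg a `run_config`.
#' @param dir artefact directory.
#' @return the directory, invisibly.
#' @export
stage_simulate <- function(cfg, dir) {
  grid <- cfg_grid(cfg)
  offs <- max(vapply(cfg$slices,
                     function(s) s$spec$sea_level_offset, numeric(1)))
  masks <- generate_masks(grid, sea_level_offset = offs,
                          seed = derive_seed(cfg$seed, 1L))
  climates <- list()
  for (sl in names(cfg$slices)) {
    s <- cfg$slices[[sl]]
    mask <- if (s$spec$sea_level_offset > 0) masks$lgm else masks$present
    base <- generate_climate(s$spec, grid, seed = derive_seed(cfg$seed, 2L),
                             land_mask = mask, slice_label = sl)
    members <- if (s$n_gcm > 1L)
      generate_gcm_ensemble(base, s$n_gcm, perturb_sd = cfg$gcm_perturb,
                            seed = derive_seed(cfg$seed, 3L + match(sl, names(cfg$slices))))
    else list(base)
    climates[[sl]] <- members
    log_stage("simulate", "slice %s: %d member(s), %d land cells",
              sl, length(members), sum(mask))
  }
  saveRDS(list(grid = grid, masks = masks, climates = climates),
          state_path(dir, "simulate"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_bioclim <- function(cfg, dir) {
  st <- readRDS(state_path(dir, "simulate"))
  stacks <- lapply(st$climates, function(members)
    lapply(members, build_bioclim_stack))
  present <- stacks$present[[1]]
  sv <- stack_values(present)
  Z <- scale(sv$X)
  eta <- drop(Z %*% cfg$truth_weights[BIOCLIM_VARS])
  raw <- new_layer(present$grid)
  raw[sv$cells] <- exp(eta - max(eta))
  raw[sv$cells] <- raw[sv$cells] / sum(raw[sv$cells])
  truth <- structure(list(grid = present$grid, raw = raw,
                          slice_label = "truth"), class = "suitability_map")
  occ <- generate_occurrences(truth, n = cfg$n_occurrences,
                              jitter_km = cfg$jitter_km,
                              seed = derive_seed(cfg$seed, 10L))
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  log_stage("bioclim", "%d stacks; %d occurrence records",
            sum(lengths(stacks)), nrow(occ))
  saveRDS(list(stacks = stacks, truth = truth), state_path(dir, "bioclim"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_stratify <- function(cfg, dir) {
  bc <- readRDS(state_path(dir, "bioclim"))
  model <- fit_stratification(bc$stacks$present[[1]],
                              n_strata = cfg$n_strata, n_zones = cfg$n_zones,
                              seed = derive_seed(cfg$seed, 20L))
  strata <- lapply(bc$stacks, function(members)
    lapply(members, function(s) classify_grid(model, s)))
  write_strat_model(model, file.path(dir, "strat_model.json"))
  log_stage("stratify", "fitted %d strata / %d zones",
            model$n_strata, model$n_zones)
  saveRDS(list(model = model, strata = strata), state_path(dir, "stratify"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_fit <- function(cfg, dir) {
  bc <- readRDS(state_path(dir, "bioclim"))
  st <- readRDS(state_path(dir, "simulate"))
  present <- bc$stacks$present[[1]]
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  occ <- filter_occurrences(occ, cfg$max_error_km)
  counts <- assign_presence_cells(occ, present$grid, present$land_mask)
  bg <- sample_background(present$land_mask, cfg$features$n_background,
                          seed = derive_seed(cfg$seed, 30L))
  fspec <- feature_spec(classes = cfg$features$classes,
                        beta = cfg$features$beta,
                        n_background = cfg$features$n_background)
  model <- fit_ppm(counts, bg, present, fspec)
  suit <- predict_raw(model, present)
  pres_cells <- which(counts > 0)
  pres_suits <- rep(suit$raw[pres_cells], counts[pres_cells])
  thr <- lowest_presence_threshold(pres_suits, e = cfg$omission)
  write_niche_model(model, file.path(dir, "niche_model.json"))
  jsonlite::write_json(unclass(thr), file.path(dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  write_raster(suit$raw, present$grid,
               file.path(dir, "suitability_present.asc"))
  log_stage("fit", "t = %.3g, realized omission %.1f%%",
            thr$t, 100 * thr$realized_omission)
  saveRDS(list(model = model, threshold = thr, suit = suit, counts = counts,
               background = bg), state_path(dir, "fit"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_project <- function(cfg, dir) {
  bc <- readRDS(state_path(dir, "bioclim"))
  sf <- readRDS(state_path(dir, "stratify"))
  ft <- readRDS(state_path(dir, "fit"))
  catmaps <- list()
  for (sl in names(bc$stacks)) {
    catmaps[[sl]] <- lapply(seq_along(bc$stacks[[sl]]), function(k) {
      stack <- bc$stacks[[sl]][[k]]
      raw <- predict_raw(ft$model, stack) # renormalized over own background
      bin <- binarize(raw, ft$threshold$t)
      tab <- suppressMessages(
        suitable_fraction_by_stratum(bin, sf$strata[[sl]][[k]]))
      apply_categories(sf$strata[[sl]][[k]], tab)
    })
    log_stage("project", "slice %s: %d member map(s)", sl,
              length(catmaps[[sl]]))
  }
  saveRDS(list(catmaps = catmaps), state_path(dir, "project"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_combine <- function(cfg, dir) {
  pj <- readRDS(state_path(dir, "project"))
  combined <- lapply(names(pj$catmaps), function(sl) {
    m <- combine_ensemble(pj$catmaps[[sl]])
    m$slice_label <- sl
    m
  })
  names(combined) <- names(pj$catmaps)
  for (sl in names(combined))
    write_raster(combined[[sl]]$codes, combined[[sl]]$grid,
                 file.path(dir, sprintf("categories_%s.asc", sl)))
  log_stage("combine", "%d slice map(s)", length(combined))
  saveRDS(list(combined = combined), state_path(dir, "combine"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_report <- function(cfg, dir) {
  cb <- readRDS(state_path(dir, "combine"))
  reports <- lapply(cb$combined, function(m)
    area_by_category(collapse_classes(m)))
  tabs <- do.call(rbind, lapply(reports, function(r) {
    t <- r$table
    t$slice <- r$slice_label
    t$total_km2 <- r$total_km2
    t
  }))
  utils::write.csv(tabs, file.path(dir, "area_by_category.csv"),
                   row.names = FALSE)
  changes <- compare_time_slices(reports)
  utils::write.csv(changes, file.path(dir, "area_changes.csv"),
                   row.names = FALSE)
  manifest <- build_manifest(cfg, dir)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("report", "wrote area tables and manifest (%d artefacts)",
            length(manifest$artifacts))
  invisible(dir)
}

build_manifest <- function(cfg, dir) {
  files <- sort(setdiff(list.files(dir),
                        c("manifest.json", grep("^state_", list.files(dir),
                                                value = TRUE))))
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  list(seed = cfg$seed,
       config_hash = unname(tools::md5sum(write_config_tmp(cfg))),
       artifacts = hashes)
}

write_config_tmp <- function(cfg) {
  f <- tempfile(fileext = ".json")
  write_run_config(cfg, f)
  f
}

#' Run the full pipeline
#'
#' simulate -> bioclim -> stratify -> fit -> project -> combine -> report,
#' deterministic given the config seed; writes models (JSON), the occurrence
#' CSV, suitability and category rasters (ASCII grid), area tables (CSV) and
#' a manifest of artefact hashes to `dir`.
#'
#' @param cfg a `run_config` (see [default_run_config()]).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
run_pipeline <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_simulate(cfg, dir)
  stage_bioclim(cfg, dir)
  stage_stratify(cfg, dir)
  stage_fit(cfg, dir)
  stage_project(cfg, dir)
  stage_combine(cfg, dir)
  stage_report(cfg, dir)
  invisible(dir)
}

#' Command-line entry point
#'
#' `paleorange <subcommand> --config cfg.json [--seed N] [--out DIR]` with
#' subcommands `run`, `simulate`, `bioclim`, `stratify`, `fit`, `project`,
#' `combine`, `report`. Exit codes: 0 success, 1 user error, 2 internal
#' error.
#'
#' @param args character vector (defaults to the process arguments).
#' @return exit status, invisibly.
#' @export
paleorange_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c(run = run_pipeline, simulate = stage_simulate,
              bioclim = stage_bioclim, stratify = stage_stratify,
              fit = stage_fit, project = stage_project,
              combine = stage_combine, report = stage_report)
  usage <- paste0("usage: paleorange <",
                  paste(names(stages), collapse = "|"),
                  "> [--config cfg.json] [--seed N] [--out DIR]")
  status <- tryCatch({
    if (length(args) < 1L || !(args[1] %in% names(stages))) {
      message(usage)
      return(invisible(1L))
    }
    opt <- function(flag, default) {
      i <- which(args == flag)
      if (length(i) == 1L && i < length(args)) args[i + 1L] else default
    }
    cfg <- if (!is.null(p <- opt("--config", NULL))) read_run_config(p)
           else default_run_config()
    if (!is.null(s <- opt("--seed", NULL))) cfg$seed <- as.integer(s)
    out <- opt("--out", "paleorange_out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stages[[args[1]]](cfg, out)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
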