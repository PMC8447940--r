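# End-to-end driver: simulate/load -> rasterize -> sample -> train ->
# predict -> classify -> abundance -> validate, writing every intermediate
# artifact plus a machine-readable run manifest.

#' Configuration of a pipeline run
#'
#' Paths are optional: stages with `NULL` paths fall back to the synthetic
#' generator driven by `landscape`. Every defaulted parameter is recorded in
#' the run manifest with its value and source.
#'
#' @param landscape A [landscape_config()] used when inputs are synthetic.
#' @param cloud_path,features_path,presences_path,validation_path Optional
#'   input files (XYZC CSV, GeoJSON, points CSV, points CSV).
#' @param n_absence Pseudo-absence count (default 600).
#' @param boost Named list of [rio_boost()] hyper-parameters to override.
#' @param lattice_spacing Lattice spacing (m); default the cell size.
#' @param idw_power,idw_k IDW parameters.
#' @param coverage Presence coverage for the occupancy threshold.
#' @param max_secondary Secondary middens per squirrel for abundance bounds.
#' @param n_validation Synthetic independent-survey size (default 28,
#'   matching the emulated earlier survey) when no validation file is given.
#' @param seed Master seed for the run.
#' @param write_cloud Also write the (large) point cloud artifact.
#' @return An object of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       cloud_path = NULL, features_path = NULL,
                       presences_path = NULL, validation_path = NULL,
                       n_absence = 600, boost = list(),
                       lattice_spacing = NULL, idw_power = 2, idw_k = 12,
                       coverage = 0.95, max_secondary = 3,
                       n_validation = 28, seed = 1L, write_cloud = FALSE) {
  defaults <- list(n_trees = 400, max_depth = 10, min_leaf = 2,
                   shrinkage = 0.01, subsample = 0.5)
  src <- ifelse(names(defaults) %in% names(boost), "user", "default")
  names(src) <- names(defaults)
  boost_full <- utils::modifyList(defaults, boost[names(boost) %in% names(defaults)])
  structure(list(landscape = landscape, cloud_path = cloud_path,
                 features_path = features_path,
                 presences_path = presences_path,
                 validation_path = validation_path,
                 n_absence = n_absence, boost = boost_full,
                 boost_source = as.list(src),
                 lattice_spacing = lattice_spacing,
                 idw_power = idw_power, idw_k = idw_k,
                 coverage = coverage, max_secondary = max_secondary,
                 n_validation = n_validation, seed = as.integer(seed),
                 write_cloud = isTRUE(write_cloud)),
            class = "run_config")
}

stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %s: done", name))
  out
}

require_path <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s input not found: %s", what, path))
  }
  path
}

#' Run the full midden-distribution pipeline
#'
#' Executes rasterize, sample, train, predict, classify, abundance and
#' validate in order, writing every intermediate artifact into `out_dir`
#' together with a manifest (parameters with default/user provenance, seeds,
#' package version, md5 checksum of every artifact). Reruns with the same
#' config and seed produce bit-identical artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the main in-memory results (`model`,
#'   `stack`, `surface`, `occupancy`, `abundance`, `validation`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  lc <- config$landscape
  g <- lc$grid
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  # --- inputs: synthetic generation or files -------------------------------
  inputs <- stage("inputs", log, {
    if (is.null(config$cloud_path) || is.null(config$features_path) ||
          is.null(config$presences_path)) {
      s <- simulate_landscape(lc)
      list(synth = s, cloud = s$cloud, features = s$features,
           presences = s$middens)
    } else {
      list(synth = NULL,
           cloud = read_xyzc(require_path(config$cloud_path, "point cloud")),
           features = read_features_geojson(
             require_path(config$features_path, "features")),
           presences = read_points_csv(
             require_path(config$presences_path, "presences")))
    }
  })
  synth <- inputs$synth
  if (!is.null(synth)) {
    keep(write_truth_json(synth$truth, file.path(out_dir, "truth.json")))
  }
  keep(write_features_geojson(inputs$features,
                              file.path(out_dir, "features.geojson")))
  keep(write_points_csv(inputs$presences,
                        file.path(out_dir, "presences.csv")))
  if (config$write_cloud) {
    keep(write_xyzc(inputs$cloud, file.path(out_dir, "cloud.csv")))
  }

  # --- rasterize -----------------------------------------------------------
  stack <- stage("rasterize", log,
                 build_predictor_stack(inputs$cloud, inputs$features, g))
  keep(write_stack(stack, file.path(out_dir, "predictors")))

  # --- sample --------------------------------------------------------------
  table <- stage("sample", log, {
    tab <- build_sample_table(inputs$presences, lc$area_polygon, stack,
                              n_absence = config$n_absence, seed = config$seed)
    log(sprintf("sampling density: %.2f points per hectare",
                attr(tab, "sampling_density")))
    tab
  })
  keep(write_sample_table(table, file.path(out_dir, "sample_table.csv")))

  # --- train ---------------------------------------------------------------
  model <- stage("train", log, {
    for (nm in names(config$boost)) {
      log(sprintf("boost parameter %s = %s (%s)", nm, config$boost[[nm]],
                  config$boost_source[[nm]]))
    }
    fml <- stats::as.formula(paste("label ~",
                                   paste(names(stack), collapse = " + ")))
    rio_boost(fml, table, weights = table$weight,
              n_trees = config$boost$n_trees,
              max_depth = config$boost$max_depth,
              min_leaf = config$boost$min_leaf,
              shrinkage = config$boost$shrinkage,
              subsample = config$boost$subsample, seed = config$seed)
  })
  keep(write_rio_model(model, file.path(out_dir, "model.json")))
  imp <- variable_importance(model)
  keep(file.path(out_dir, "importance.csv"))
  write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  log(sprintf("training AUC: %.4f", model$train_auc))

  # --- predict -------------------------------------------------------------
  surface_parts <- stage("predict", log, {
    spacing <- if (is.null(config$lattice_spacing)) g$cell_size else config$lattice_spacing
    lattice <- make_lattice(lc$area_polygon, g, spacing)
    scored <- score_lattice(model, lattice, stack)
    surface <- idw_interpolate(scored, g, power = config$idw_power,
                               k = config$idw_k)
    list(lattice = lattice, scored = scored, surface = surface)
  })
  keep(write_scored_lattice(surface_parts$scored,
                            file.path(out_dir, "lattice_scored.csv")))
  keep(write_ascii_grid(surface_parts$surface, file.path(out_dir, "rio.asc")))

  # --- classify ------------------------------------------------------------
  occ <- stage("classify", log, {
    cl <- point_cell(surface_parts$surface, inputs$presences$x,
                     inputs$presences$y)
    rio_pres <- surface_parts$surface$values[cbind(cl$row, cl$col)]
    t_occ <- occupancy_threshold(rio_pres, config$coverage)
    log(sprintf("occupancy threshold t >= %.4f", t_occ))
    classify_occupancy(surface_parts$surface, t_occ,
                       presences = inputs$presences,
                       area_polygon = lc$area_polygon)
  })
  keep(write_ascii_grid(occ$raster, file.path(out_dir, "occupancy.asc")))

  # --- abundance -----------------------------------------------------------
  abund <- stage("abundance", log, {
    area_ha <- polygon_area(lc$area_polygon) / 1e4
    whole <- abundance_summary(nrow(inputs$presences), area_ha,
                               config$max_secondary)
    occupied <- abundance_summary(max(1L, occ$n_presences_occupied),
                                  occ$occupied_area_ha, config$max_secondary)
    list(whole_area = whole, occupied_area = occupied)
  })
  keep(file.path(out_dir, "abundance.json"))
  jsonlite::write_json(lapply(abund, unclass),
                       file.path(out_dir, "abundance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- validate ------------------------------------------------------------
  validation <- stage("validate", log, {
    vpts <- if (!is.null(config$validation_path)) {
      read_points_csv(require_path(config$validation_path, "validation points"))
    } else if (!is.null(synth)) {
      # independent synthetic survey: a second, smaller presence draw
      vt <- synth$truth
      sim2 <- simulate_middens(synth$stack, vt, lc$seed + 7777L,
                               area_polygon = lc$area_polygon)
      pts <- thin_middens(sim2$points, 10)
      n <- min(config$n_validation, nrow(pts))
      pts[seq_len(n), , drop = FALSE]
    } else NULL
    if (is.null(vpts) || nrow(vpts) == 0L) return(NULL)
    validate_points(surface_parts$surface, vpts, surface_parts$scored)
  })
  if (!is.null(validation)) {
    keep(file.path(out_dir, "validation.json"))
    jsonlite::write_json(validation[setdiff(names(validation), "rio")],
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- manifest ------------------------------------------------------------
  files <- sort(unique(c(artifacts,
                         list.files(file.path(out_dir, "predictors"),
                                    full.names = TRUE))))
  files <- files[file.exists(files)]
  checks <- tools::md5sum(files)
  manifest <- list(
    package = "middensdm",
    version = as.character(utils::packageVersion("middensdm")),
    seed = config$seed,
    parameters = list(
      cell_size = g$cell_size, n_absence = config$n_absence,
      boost = config$boost, boost_source = config$boost_source,
      lattice_spacing = if (is.null(config$lattice_spacing)) g$cell_size
                        else config$lattice_spacing,
      idw_power = config$idw_power, idw_k = config$idw_k,
      coverage = config$coverage, max_secondary = config$max_secondary
    ),
    log = log_lines,
    artifacts = lapply(seq_along(files), function(i) {
      list(file = sub(paste0("^", out_dir, "/?"), "", files[i]),
           md5 = unname(checks[i]))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(stack = stack, table = table, model = model,
                 lattice = surface_parts$lattice,
                 scored = surface_parts$scored,
                 surface = surface_parts$surface, occupancy = occ,
                 abundance = abund, validation = validation,
                 manifest = manifest))
}
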