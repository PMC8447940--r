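# Plain-text adapters: ESRI ASCII grids for rasters, the XYZC CSV dialect for
# point clouds, GeoJSON for vector features, CSV for point/sample tables and
# JSON for models, truth records and manifests. Every writer/reader pair
# round-trips losslessly at full decimal precision.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param grid A [raster_grid()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[!is.finite(v)] <- -9999
  header <- c(
    sprintf("NCOLS %d", grid$ncol),
    sprintf("NROWS %d", grid$nrow),
    sprintf("XLLCORNER %s", fmt_num(grid$origin_x)),
    sprintf("YLLCORNER %s", fmt_num(grid$origin_y - grid$nrow * grid$cell_size)),
    sprintf("CELLSIZE %s", fmt_num(grid$cell_size)),
    "NODATA_VALUE -9999"
  )
  rows <- apply(v, 1L, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @param name,units,crs Metadata for the resulting [raster_grid()] (the
#'   format itself carries none).
#' @return A [raster_grid()]; `NODATA` cells become `NA`.
#' @export
read_ascii_grid <- function(path, name = "value", units = "",
                            crs = "LOCAL_METERS") {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("malformed ASCII grid (too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed ASCII grid header at line %d: '%s'", i, lines[i]))
    }
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
  }
  nc <- as.integer(hdr$NCOLS); nr <- as.integer(hdr$NROWS)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("malformed ASCII grid: expected %d values, found %d",
                 nr * nc, length(vals)))
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr$NODATA_VALUE] <- NA_real_
  spec <- grid_spec(hdr$XLLCORNER, hdr$YLLCORNER + nr * hdr$CELLSIZE,
                    hdr$CELLSIZE, nr, nc, crs)
  raster_grid(m, spec, name, units)
}

#' Write a point cloud in the XYZC CSV dialect
#'
#' Columns `x`, `y`, `z`, `class` with class in
#' `{ground, vegetation, unclassified}`.
#'
#' @param cloud Point-cloud data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_xyzc <- function(cloud, path) {
  check_cloud(cloud)
  writeLines(c("x,y,z,class",
               sprintf("%s,%s,%s,%s", fmt_num(cloud$x), fmt_num(cloud$y),
                       fmt_num(cloud$z), cloud$class)), path)
  invisible(path)
}

#' Read an XYZC CSV point cloud
#'
#' @param path CSV path with columns `x`, `y`, `z`, `class`.
#' @return A validated point-cloud data.frame.
#' @export
read_xyzc <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "class")
  if (!all(need %in% names(df))) {
    stop("malformed XYZC file (need columns x,y,z,class): ", path)
  }
  bad <- setdiff(unique(df$class), CLOUD_CLASSES)
  if (length(bad)) {
    stop("unknown point class token: ", paste(bad, collapse = ", "))
  }
  check_cloud(df[need])
}

geom_to_geojson <- function(geom, type) {
  coords <- lapply(seq_len(nrow(geom)), function(i) c(geom[i, 1], geom[i, 2]))
  if (type == "Polygon") {
    ring <- c(coords, coords[1])
    list(type = "Polygon", coordinates = list(ring))
  } else {
    list(type = "LineString", coordinates = coords)
  }
}

#' Write a feature set as GeoJSON
#'
#' One Feature per geometry with property `class`; polygons for lake and
#' buildings, LineStrings for the trail classes.
#'
#' @param features A `feature_set`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_features_geojson <- function(features, path) {
  polys <- c("lake", "buildings")
  feats <- list()
  for (cls in names(features)) {
    for (geom in features[[cls]]) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(class = cls),
        geometry = geom_to_geojson(as.matrix(geom),
                                   if (cls %in% polys) "Polygon" else "LineString")
      )
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' Read a feature-set GeoJSON
#'
#' @param path GeoJSON path written by [write_features_geojson()] (or any
#'   FeatureCollection of Polygons/LineStrings with a `class` property).
#' @return A `feature_set`.
#' @export
read_features_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("malformed GeoJSON (not a FeatureCollection): ", path)
  }
  out <- list(lake = list(), trails = list(), dogtrail = list(),
              highway = list(), buildings = list())
  for (f in fc$features) {
    cls <- f$properties$class
    if (is.null(cls)) stop("GeoJSON feature without a class property")
    g <- f$geometry
    coords <- if (g$type == "Polygon") g$coordinates[[1]] else g$coordinates
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    if (g$type == "Polygon") m <- m[-nrow(m), , drop = FALSE] # drop closure
    if (!cls %in% names(out)) out[[cls]] <- list()
    out[[cls]][[length(out[[cls]]) + 1L]] <- m
  }
  structure(out, class = "feature_set")
}

#' Write / read point tables
#'
#' Points CSV has columns `id`, `x`, `y` and optionally `label`. The reader
#' also accepts upper-case `X`/`Y` or `POINT_X`/`POINT_Y` coordinate columns
#' as deposited attribute exports use.
#'
#' @param points Data.frame of points.
#' @param path CSV path.
#' @return `path` (writer) or the points data.frame (reader).
#' @export
write_points_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  pick <- function(cands) {
    hit <- nm[tolower(nm) %in% tolower(cands)]
    if (length(hit)) hit[1] else NA_character_
  }
  xc <- pick(c("x", "point_x", "easting"))
  yc <- pick(c("y", "point_y", "northing"))
  if (is.na(xc) || is.na(yc)) stop("points file lacks x/y columns: ", path)
  out <- data.frame(x = as.numeric(df[[xc]]), y = as.numeric(df[[yc]]))
  idc <- pick(c("id", "oid", "objectid", "fid"))
  out$id <- if (!is.na(idc)) df[[idc]] else seq_len(nrow(out))
  lc <- pick(c("label", "pa", "presence", "response"))
  if (!is.na(lc)) out$label <- as.integer(df[[lc]])
  out[c("id", "x", "y", intersect("label", names(out)))]
}

#' Write / read the training sample table
#'
#' The sample table ("data cube") CSV mirrors deposited presence/absence
#' extractions: `id`, `x`, `y`, `label`, `weight` plus one column per
#' predictor. The reader tolerates alternative coordinate/label column names
#' and recomputes balancing weights when absent.
#'
#' @param table Sample-table data.frame.
#' @param path CSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_sample_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df) <- nm
  lc <- intersect(c("label", "pa", "presence", "response"), nm)
  if (!length(lc)) stop("sample table lacks a label column: ", path)
  names(df)[match(lc[1], names(df))] <- "label"
  for (pair in list(c("point_x", "x"), c("point_y", "y"))) {
    if (pair[1] %in% names(df) && !(pair[2] %in% names(df))) {
      names(df)[match(pair[1], names(df))] <- pair[2]
    }
  }
  if (!"weight" %in% names(df)) df <- balance_weights(df)
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df
}

#' Write / read a scored lattice
#'
#' Columns `id`, `x`, `y`, `PROB_0`, `PROB_1` (`PROB_1` = RIO). The reader
#' accepts any case for the probability columns.
#'
#' @param scored Scored-lattice data.frame.
#' @param path CSV path.
#' @return `path` (writer) or the scored lattice (reader).
#' @export
write_scored_lattice <- function(scored, path) {
  write.csv(scored, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scored_lattice
#' @export
read_scored_lattice <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  p1 <- nm[toupper(nm) == "PROB_1"]
  p0 <- nm[toupper(nm) == "PROB_0"]
  if (!length(p1)) stop("scored lattice lacks a PROB_1 column: ", path)
  out <- data.frame(
    id = if ("id" %in% tolower(nm)) df[[nm[tolower(nm) == "id"][1]]] else seq_len(nrow(df)),
    x = df[[nm[tolower(nm) == "x"][1]]],
    y = df[[nm[tolower(nm) == "y"][1]]],
    PROB_1 = as.numeric(df[[p1[1]]])
  )
  out$PROB_0 <- if (length(p0)) as.numeric(df[[p0[1]]]) else 1 - out$PROB_1
  out[c("id", "x", "y", "PROB_0", "PROB_1")]
}

tree_to_list <- function(tr) {
  list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
       left = as.integer(tr$left), right = as.integer(tr$right),
       value = as.numeric(tr$value),
       improvement = as.numeric(tr$improvement))
}

#' Serialize / load a boosted model as JSON
#'
#' Stores the initial log-odds, every tree (split features, thresholds, leaf
#' values, per-split improvements), shrinkage, feature names, config and
#' seed at full precision, so predictions from the loaded model are identical.
#' The training rows are not stored; pass `newdata` when predicting from a
#' loaded model.
#'
#' @param model A fitted [rio_boost()] model.
#' @param path JSON path.
#' @return `path` (writer) or a `rio_boost` object (reader).
#' @export
write_rio_model <- function(model, path) {
  stopifnot(inherits(model, "rio_boost"))
  obj <- list(
    format = "rio_boost-1",
    F0 = model$F0, shrinkage = model$shrinkage,
    feature_names = model$feature_names,
    config = model$config,
    trees = lapply(model$trees, tree_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_rio_model
#' @export
read_rio_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "rio_boost-1") {
    stop("not a serialized rio_boost model: ", path)
  }
  num <- function(v) vapply(v, function(x) if (is.null(x)) NA_real_
                            else as.numeric(x), numeric(1))
  trees <- lapply(obj$trees, function(tr) {
    list(feature = as.integer(num(tr$feature)),
         threshold = num(tr$threshold),
         left = as.integer(num(tr$left)), right = as.integer(num(tr$right)),
         value = num(tr$value), improvement = num(tr$improvement))
  })
  structure(
    list(F0 = as.numeric(obj$F0), trees = trees,
         shrinkage = as.numeric(obj$shrinkage),
         feature_names = unlist(obj$feature_names),
         config = lapply(obj$config, function(x) x), formula = NULL,
         train = NULL, deviance = NULL, train_auc = NA_real_),
    class = "rio_boost"
  )
}

#' Write a predictor stack to a directory
#'
#' One ASCII grid per layer plus a JSON manifest recording layer order,
#' names, units, file names and the shared grid spec.
#'
#' @param stack A `predictor_stack`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- attr(stack, "spec")
  layers <- lapply(names(stack), function(nm) {
    file <- paste0(nm, ".asc")
    write_ascii_grid(stack[[nm]], file.path(dir, file))
    list(name = nm, file = file, units = stack[[nm]]$units)
  })
  manifest <- list(
    format = "predictor_stack-1",
    grid = list(origin_x = sp$origin_x, origin_y = sp$origin_y,
                cell_size = sp$cell_size, nrow = sp$nrow, ncol = sp$ncol,
                crs = sp$crs),
    layers = layers
  )
  mp <- file.path(dir, "stack.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = TRUE)
  invisible(mp)
}

#' Read a predictor stack from its manifest
#'
#' @param manifest_path Path to `stack.json` written by [write_stack()].
#' @return A `predictor_stack` with the original layer order and names.
#' @export
read_stack <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$format) || man$format != "predictor_stack-1") {
    stop("not a stack manifest: ", manifest_path)
  }
  dir <- dirname(manifest_path)
  layers <- list()
  for (l in man$layers) {
    layers[[l$name]] <- read_ascii_grid(file.path(dir, l$file), l$name,
                                        l$units, man$grid$crs)
  }
  stack_predictors(layers)
}

#' Write / read a response-truth record
#'
#' @param truth A [response_truth()].
#' @param path JSON path.
#' @return `path` (writer) or a `response_truth` (reader).
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(intercept = truth$intercept,
              realized_count = truth$realized_count,
              responses = lapply(truth$responses, function(k) {
                list(x = k[, 1], y = k[, 2])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- response_truth(
    intercept = obj$intercept,
    responses = lapply(obj$responses, function(k) cbind(k$x, k$y))
  )
  tr$realized_count <- obj$realized_count
  tr
}
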