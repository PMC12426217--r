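# Readers and writers for the pipeline's artifacts. Rasters travel as ESRI
# ASCII grids (plain text, georeferenced, readable by standard GIS tools),
# municipality zones as GeoJSON polygons, tables as CSV, configuration as
# YAML, and the run manifest / normalization statistics as JSON.

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param mat Numeric matrix (row 1 = northernmost row).
#' @param path Output file path.
#' @param cellsize Cell size in meters.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel value.
#' @export
write_ascii_grid <- function(mat, path, cellsize = 100, xll = 0, yll = 0,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return Numeric matrix with `cellsize`, `xllcorner`, `yllcorner`
#'   attributes; NODATA cells become NA.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == h[["nrows"]], ncol(m) == h[["ncols"]])
  m[m == h[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- h[["cellsize"]]
  attr(m, "xllcorner") <- h[["xllcorner"]]
  attr(m, "yllcorner") <- h[["yllcorner"]]
  m
}

# polygon ring (closed, counter-clockwise) around a zone: convex hull of its
# pixel corners. Voronoi cells are convex, so this is exact up to pixel size.
zone_ring <- function(zones, id, res_m) {
  nr <- nrow(zones)
  cells <- which(zones == id)
  i <- (cells - 1) %% nr + 1
  j <- (cells - 1) %/% nr + 1
  # all four corners of each pixel, in map coordinates (y up)
  x <- c((j - 1), j, (j - 1), j) * res_m
  y <- c(nr - i + 1, nr - i + 1, nr - i, nr - i) * res_m
  h <- grDevices::chull(x, y)
  h <- rev(h)                       # chull is clockwise; GeoJSON wants CCW
  cbind(x[c(h, h[1])], y[c(h, h[1])])
}

#' Write municipality zones as GeoJSON polygons
#'
#' Each municipality becomes a Polygon feature (the convex hull of its pixel
#' footprint; exact for convex Voronoi zones) with its id and any extra
#' per-municipality properties.
#'
#' @param stack A `landscape_stack`.
#' @param path Output path.
#' @param properties Optional data frame of extra per-municipality columns,
#'   with a municipality_id column (e.g. cluster assignments).
#' @export
write_zones_geojson <- function(stack, path, properties = NULL) {
  feats <- lapply(stack$zone_ids, function(id) {
    ring <- zone_ring(stack$zones, id, stack$res_m)
    props <- list(municipality_id = id)
    if (!is.null(properties)) {
      row <- properties[properties$municipality_id == id, , drop = FALSE]
      for (nm in setdiff(names(row), "municipality_id"))
        props[[nm]] <- row[[nm]][1]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read a zones GeoJSON written by [write_zones_geojson()]
#'
#' @param path GeoJSON path.
#' @return Data frame of feature properties, one row per municipality, plus
#'   a `rings` attribute holding the polygon coordinate matrices.
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  props <- do.call(rbind, lapply(gj$features, function(f)
    as.data.frame(f$properties)))
  rings <- lapply(gj$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates[[1]],
                          function(p) unlist(p)))
  })
  attr(props, "rings") <- rings
  props
}

#' Write / read pipeline tables as CSV
#'
#' Thin wrappers fixing the CSV dialect so round-trips are lossless to
#' full double precision.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `read_table_csv` returns the data frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a region spec as YAML
#'
#' @param spec A [region_spec()].
#' @param path YAML path.
#' @export
write_region_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
}

#' @rdname write_region_spec_yaml
#' @export
read_region_spec_yaml <- function(path) {
  do.call(region_spec, yaml::read_yaml(path))
}

#' Validate a landscape stack
#'
#' Checks grid alignment across all layers, closure of the land-cover class
#' set, non-negative population, protection-level codes and timestep
#' completeness; returns a machine-readable issue list rather than failing.
#'
#' @param stack A `landscape_stack`.
#' @return Data frame with columns layer, issue (zero rows when valid).
#' @export
validate_stack <- function(stack) {
  issues <- list()
  note <- function(layer, msg)
    issues[[length(issues) + 1L]] <<- data.frame(layer = layer, issue = msg)
  shp <- dim(stack$zones)
  Tn <- length(stack$timesteps)
  for (nm in c("land_cover", "population", "threat_layers")) {
    if (length(stack[[nm]]) != Tn)
      note(nm, sprintf("expected %d timesteps, found %d", Tn, length(stack[[nm]])))
  }
  chk_shape <- function(m, layer) {
    if (!identical(dim(m), shp)) note(layer, "grid shape differs from zones")
  }
  for (t in seq_along(stack$land_cover)) {
    chk_shape(stack$land_cover[[t]], paste0("land_cover[", t, "]"))
    codes <- unique(as.vector(stack$land_cover[[t]]))
    bad <- setdiff(codes, seq_along(stack$classes))
    if (length(bad))
      note(paste0("land_cover[", t, "]"),
           paste("unknown class code(s):", paste(bad, collapse = ", ")))
  }
  for (t in seq_along(stack$population)) {
    chk_shape(stack$population[[t]], paste0("population[", t, "]"))
    if (any(stack$population[[t]] < 0))
      note(paste0("population[", t, "]"), "negative population")
  }
  for (nm in c("precipitation", "pet"))
    chk_shape(stack[[nm]], nm)
  prots <- if (is.list(stack$protection)) stack$protection else list(stack$protection)
  for (t in seq_along(prots)) {
    chk_shape(prots[[t]], paste0("protection[", t, "]"))
    if (any(!prots[[t]] %in% 0:4))
      note(paste0("protection[", t, "]"), "levels outside 0..4")
  }
  for (t in seq_along(stack$threat_layers))
    for (r in names(stack$threat_layers[[t]])) {
      m <- stack$threat_layers[[t]][[r]]
      chk_shape(m, paste0("threat:", r, "[", t, "]"))
      if (any(m < 0 | m > 1))
        note(paste0("threat:", r, "[", t, "]"), "intensity outside [0, 1]")
    }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(layer = character(), issue = character())
}
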