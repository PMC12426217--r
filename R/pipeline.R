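# End-to-end orchestration: synthetic region -> indicators -> indices ->
# trends -> clustering, with every intermediate table written to disk and a
# manifest recording the configuration hash and per-stage checksums.

#' Default pipeline configuration
#'
#' Every stage parameter with its default, as a plain named list (printable,
#' YAML-serializable). A config containing nothing but `mode = "synthetic"`
#' is runnable end-to-end.
#'
#' @param seed Master seed forwarded to the region spec.
#' @return Named list of class `ncp_config`.
#' @export
default_config <- function(seed = 42) {
  structure(list(
    mode = "synthetic",
    region = unclass(region_spec(seed = seed)),
    ncps = ncp_codes(),
    kernel_params = default_kernel_params(),
    indicator_config = default_indicator_config(),
    npp_backcast_timesteps = c(1L, 2L),  # timesteps refilled by regression
    ratio_cap = 99,
    ratio_shift = TRUE,
    trend_regressor = "ordinal",         # or "calendar"
    calendar_years = c(1982, 1994.5, 2006.5, 2015.5),
    linkage = "ward",
    k = NULL,                            # NULL: select via k_range
    k_range = 2:8,
    k_method = "silhouette",
    standardize_features = TRUE,
    out_dir = NULL,                      # NULL: nothing written
    seed = seed
  ), class = "ncp_config")
}

#' Run the full assessment pipeline
#'
#' Generates (or receives) a landscape stack, computes the supply/demand
#' table for the selected NCPs at every timestep, applies the per-capita
#' transform, builds budget and ratio indices, derives the trend table,
#' assembles the feature matrix, selects k (unless fixed) and clusters.
#' When `config$out_dir` is set, all tables (CSV), the zones GeoJSON
#' (carrying cluster ids), per-NCP bubble-plot data, the normalization
#' sidecar and a manifest (JSON) are written there.
#'
#' @param config A [default_config()] list (possibly modified).
#' @param region Optional pre-built list(stack, econ) to analyse instead of
#'   generating one (e.g. from user-supplied files).
#' @return List with elements spec, stack, econ, labels (synthetic mode),
#'   ncp_table, index_table, trend_table, features, k, clusters, profiles,
#'   manifest.
#' @examples
#' \donttest{
#' cfg <- default_config(seed = 1)
#' cfg$region$grid_shape <- c(60, 60); cfg$region$n_municipalities <- 16
#' res <- run_pipeline(cfg)
#' table(res$clusters$assignment)
#' }
#' @export
run_pipeline <- function(config = default_config(), region = NULL) {
  stage <- "configuration"
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  spec <- do.call(region_spec, config$region)
  labels <- NULL
  if (is.null(region)) {
    reg <- run("synth", generate_region(spec))
    labels <- reg$labels
  } else {
    reg <- region
  }
  stack <- reg$stack
  econ <- reg$econ

  ncp_table <- run("indicators", compute_ncp_table(
    stack, econ,
    params = config$kernel_params,
    config = config$indicator_config,
    ncps = config$ncps,
    npp_mask_timesteps = config$npp_backcast_timesteps %||% integer()))

  population <- zone_population(stack)
  ncp_pc <- run("per_capita", per_capita_transform(ncp_table, population))
  index_table <- run("indices", build_index_table(
    ncp_pc, ratio_cap = config$ratio_cap, ratio_shift = config$ratio_shift))

  t_reg <- if (identical(config$trend_regressor, "calendar"))
    config$calendar_years[seq_along(stack$timesteps)] else NULL
  trend_table <- run("trends", build_trend_table(
    index_table, timesteps = stack$timesteps, t = t_reg))

  features <- run("features", assemble_features(
    trend_table, standardize = config$standardize_features))
  k <- config$k
  if (is.null(k))
    k <- run("select_k", as.integer(select_k(
      features, k_range = config$k_range,
      method = config$k_method, linkage = config$linkage)))
  clusters <- run("cluster", hierarchical_cluster(features, k = k,
                                                  linkage = config$linkage))
  profiles <- run("profiles", profile_clusters(clusters, trend_table, stack))

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_municipalities = length(stack$zone_ids),
    n_timesteps = length(stack$timesteps),
    ncps = config$ncps,
    k = k,
    stage_checksums = list(
      ncp_table = rlang::hash(ncp_table),
      index_table = rlang::hash(index_table),
      trend_table = rlang::hash(trend_table),
      assignment = rlang::hash(clusters$assignment)
    )
  )

  result <- list(spec = spec, stack = stack, econ = econ, labels = labels,
                 ncp_table = ncp_pc, index_table = index_table,
                 trend_table = trend_table, features = features,
                 k = k, clusters = clusters, profiles = profiles,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    run("write_outputs", write_pipeline_outputs(result, config$out_dir))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all pipeline artifacts to a directory
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_table_csv(result$ncp_table, p("ncp_table.csv"))
  write_table_csv(result$index_table, p("index_table.csv"))
  write_table_csv(result$trend_table, p("trend_table.csv"))
  write_table_csv(data.frame(municipality_id = as.integer(names(result$clusters$assignment)),
                             cluster = result$clusters$assignment),
                  p("cluster_assignment.csv"))
  merges <- result$clusters$tree
  write_table_csv(data.frame(merge1 = merges$merge[, 1],
                             merge2 = merges$merge[, 2],
                             height = merges$height),
                  p("linkage.csv"))
  write_table_csv(as.data.frame(result$profiles$profiles), p("cluster_profiles.csv"))
  if (!is.null(result$profiles$composition))
    write_table_csv(as.data.frame(result$profiles$composition),
                    p("cluster_composition.csv"))
  for (code in unique(result$trend_table$ncp)) {
    pd <- trend_plot_data(result$trend_table[result$trend_table$ncp == code, ])
    write_table_csv(pd, p(paste0("bubble_", code, ".csv")))
  }
  jsonlite::write_json(attr(result$index_table, "norm_stats"),
                       p("normalization.json"), auto_unbox = TRUE, digits = NA)
  write_zones_geojson(result$stack, p("zones.geojson"),
                      properties = data.frame(
                        municipality_id = as.integer(names(result$clusters$assignment)),
                        cluster = result$clusters$assignment))
  for (t in seq_along(result$stack$timesteps))
    write_ascii_grid(result$stack$land_cover[[t]],
                     p(sprintf("land_cover_%s.asc", result$stack$timesteps[t])),
                     cellsize = result$stack$res_m)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
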