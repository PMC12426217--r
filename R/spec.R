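#' Land-cover classes used throughout the package
#'
#' The categorical land-cover nomenclature shared by the synthetic generator
#' and all indicator models. The class set is closed: rasters may not contain
#' codes outside this vector.
#'
#' @return Character vector of the eight class names, in canonical order.
#' @export
lc_classes <- function() {
  c("settlement", "cropland", "horticulture", "forest",
    "meadow_pasture", "water", "park_public", "other")
}

#' NCP codes assessed by the pipeline
#'
#' @return Character vector: pollination (POL), habitat preservation (HAB),
#'   recreation (REC), food (FOD), water regulation (WAT), climate
#'   regulation (CLI).
#' @export
ncp_codes <- function() {
  c("POL", "HAB", "REC", "FOD", "WAT", "CLI")
}

#' NCPs whose supply and demand are expressed per capita
#'
#' Food, water regulation and climate regulation are divided by municipal
#' population before budget and ratio indices are formed, so that large
#' cities do not dominate the index scale.
#'
#' @return Character vector of NCP codes.
#' @export
per_capita_ncps <- function() {
  c("FOD", "WAT", "CLI")
}

#' Specification of a synthetic study region
#'
#' Bundles every knob of the synthetic-landscape generator: grid geometry,
#' number of municipalities and timesteps, the number of planted archetypes,
#' how strongly municipalities are blended towards the regional mean
#' (`archetype_mixing`) and how much municipality-level noise is injected
#' (`noise_sd`, the standard deviation of multiplicative log-scale
#' perturbations of class fractions and population weights).
#'
#' @param n_municipalities Number of municipality zones (Voronoi cells).
#' @param grid_shape Integer vector (rows, cols) of the raster grid.
#' @param pixel_area Pixel area in square meters (default 10000 = 1 ha).
#' @param n_timesteps Number of timesteps (>= 2).
#' @param timestep_labels Ordered labels, one per timestep.
#' @param n_archetypes Number of planted archetypes (1..n_municipalities).
#' @param archetype_mixing Fraction in [0, 1] blending each archetype's
#'   class-fraction trajectory towards the across-archetype mean.
#' @param noise_sd Standard deviation of log-scale municipality noise
#'   (dimensionless; 0 gives a fully deterministic archetype signal).
#' @param pop_growth Regional population growth factor over the whole study
#'   window (default 1.6, i.e. about +60\% over four decades).
#' @param seed Integer master seed; all layer-specific randomness is drawn
#'   from named substreams derived from it.
#' @return An object of class `region_spec`.
#' @examples
#' spec <- region_spec(n_municipalities = 12, grid_shape = c(40, 40))
#' @export
region_spec <- function(n_municipalities = 60,
                        grid_shape = c(200, 200),
                        pixel_area = 10000,
                        n_timesteps = 4,
                        timestep_labels = c("1980s", "1990s", "2000s", "current"),
                        n_archetypes = 4,
                        archetype_mixing = 0.1,
                        noise_sd = 0.3,
                        pop_growth = 1.6,
                        seed = 42) {
  if (length(grid_shape) != 2L || any(grid_shape < 4))
    stop("grid_shape must be two integers >= 4", call. = FALSE)
  if (n_timesteps < 2L)
    stop("n_timesteps must be >= 2", call. = FALSE)
  if (n_archetypes < 1L || n_archetypes > n_municipalities)
    stop("n_archetypes must be in 1..n_municipalities", call. = FALSE)
  if (archetype_mixing < 0 || archetype_mixing > 1)
    stop("archetype_mixing must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (length(timestep_labels) != n_timesteps)
    timestep_labels <- paste0("t", seq_len(n_timesteps))
  structure(
    list(
      n_municipalities = as.integer(n_municipalities),
      grid_shape = as.integer(grid_shape),
      pixel_area = pixel_area,
      n_timesteps = as.integer(n_timesteps),
      timestep_labels = as.character(timestep_labels),
      n_archetypes = as.integer(n_archetypes),
      archetype_mixing = archetype_mixing,
      noise_sd = noise_sd,
      pop_growth = pop_growth,
      seed = as.integer(seed)
    ),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  cat("Synthetic region specification\n")
  cat(sprintf("  grid: %d x %d pixels (%.0f m2/pixel)\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_area))
  cat(sprintf("  municipalities: %d, archetypes: %d\n",
              x$n_municipalities, x$n_archetypes))
  cat(sprintf("  timesteps: %s\n", paste(x$timestep_labels, collapse = ", ")))
  cat(sprintf("  mixing: %.2f, noise_sd: %.2f, pop growth: x%.2f, seed: %d\n",
              x$archetype_mixing, x$noise_sd, x$pop_growth, x$seed))
  invisible(x)
}

# Deterministic integer seed for a named substream of the master seed, so each
# layer's randomness is reproducible independently of the others.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) * 1009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Evaluate expr with the RNG seeded from a named substream, restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}
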