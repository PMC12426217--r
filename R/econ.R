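#' Default economic and consumption tables
#'
#' Rates linking land cover and population to the material NCPs: crop yields,
#' pollinator dependence of crop categories, livestock stocking and meat
#' yield, per-capita food and water consumption, sectoral water use,
#' per-capita greenhouse-gas emissions per timestep, net primary productivity
#' by land-cover class and recreation parameters. Values are round,
#' temperate-European magnitudes; every rate is configurable because the
#' indices downstream are relative (min-max normalized), so only contrasts
#' between municipalities and timesteps matter.
#'
#' @param n_timesteps Number of timesteps the emission series must cover.
#' @return An object of class `econ_tables`: a named list of rate tables.
#' @examples
#' econ <- default_econ_tables()
#' econ$crop_yield
#' @export
default_econ_tables <- function(n_timesteps = 4) {
  co2 <- c(7.5, 7.0, 6.5, 5.5) # tCO2e/person/yr, slowly decarbonizing
  if (n_timesteps != 4L)
    co2 <- stats::approx(seq_len(4), co2, n = max(n_timesteps, 2L))$y
  structure(
    list(
      # kg/ha/yr by cultivated class
      crop_yield = c(cropland = 6000, horticulture = 25000),
      # yield-reduction fraction without pollinators, by crop category
      crop_pollinator_dependence = c(cropland = 0.25, horticulture = 0.65),
      # animals/ha of pasture, and carcass yield
      livestock_density = c(meadow_pasture = 1.2),
      meat_per_animal = 120,               # kg/animal/yr
      per_capita_food_demand = 700,        # kg/person/yr
      per_capita_water_demand = 100,       # m3/person/yr (household)
      # m3/pixel/yr of non-household use by land-cover class
      sectoral_water_demand = c(
        settlement = 80, cropland = 150, horticulture = 400, forest = 0,
        meadow_pasture = 10, water = 0, park_public = 20, other = 0
      ),
      per_capita_co2e = co2,
      # tC/ha/yr net primary productivity proxy by class
      npp_by_class = c(
        settlement = 0.5, cropland = 3.5, horticulture = 3.0, forest = 6.0,
        meadow_pasture = 4.0, water = 0.1, park_public = 2.5, other = 1.0
      ),
      # attractiveness for outdoor recreation, index [0,1] by class
      recreation_value_by_class = c(
        settlement = 0.1, cropland = 0.3, horticulture = 0.3, forest = 0.9,
        meadow_pasture = 0.7, water = 0.85, park_public = 1.0, other = 0.4
      ),
      per_capita_recreation_need = 30      # m2/person
    ),
    class = "econ_tables"
  )
}

validate_econ_tables <- function(econ) {
  stopifnot(inherits(econ, "econ_tables") || is.list(econ))
  rates <- c(econ$crop_yield, econ$livestock_density, econ$meat_per_animal,
             econ$per_capita_food_demand, econ$per_capita_water_demand,
             econ$sectoral_water_demand, econ$per_capita_co2e,
             econ$npp_by_class, econ$per_capita_recreation_need)
  if (any(rates < 0))
    stop("econ tables: all rates must be >= 0", call. = FALSE)
  dep <- econ$crop_pollinator_dependence
  if (any(dep < 0 | dep > 1))
    stop("econ tables: pollinator-dependence fractions must be in [0, 1]",
         call. = FALSE)
  invisible(TRUE)
}
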