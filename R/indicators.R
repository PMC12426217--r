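# The six NCP supply/demand indicator models. Each operation maps a
# landscape stack (+ rate tables and kernel parameters) at one timestep to a
# per-municipality value in the NCP's native unit: index [0,1] for
# pollination and habitat, m2 for recreation, kg for food, m3 for water,
# tC for climate. All are simplified, self-contained raster models in the
# spirit of the widely used ecosystem-service engines (distance-decay
# pollinator kernel, threat-decay habitat degradation, Budyko-Fu water
# yield), kept deliberately transparent so they can be verified against
# brute-force oracles.

#' Default kernel parameters for the distance-based indicators
#'
#' @param res_m Pixel resolution in meters (used only for documentation;
#'   kernels read the resolution from the stack).
#' @return Named list: `foraging_distance_alpha` (m) and `truncation_radius`
#'   (m) for the pollination kernel; per-threat `threat_decay`
#'   ("linear"/"exponential"), `threat_max_distance` (m) and `threat_weight`
#'   in [0,1]; `habitat_sensitivity` (class x threat matrix in [0,1]).
#' @export
default_kernel_params <- function(res_m = 100) {
  cls <- lc_classes()
  sens <- rbind(
    urban =       c(settlement = 0, cropland = .3, horticulture = .3,
                    forest = .9, meadow_pasture = .7, water = .5,
                    park_public = .6, other = .4),
    agriculture = c(settlement = 0, cropland = 0, horticulture = .1,
                    forest = .6, meadow_pasture = .5, water = .4,
                    park_public = .3, other = .3)
  )[, cls]
  list(
    foraging_distance_alpha = 500,
    truncation_radius = 1000,
    threat_decay = c(urban = "linear", agriculture = "linear"),
    threat_max_distance = c(urban = 500, agriculture = 300),
    threat_weight = c(urban = 1.0, agriculture = 0.6),
    habitat_sensitivity = sens
  )
}

#' Default indicator configuration
#'
#' All tunable constants of the indicator models, gathered in one place so
#' none is hard-coded: pollinator nesting suitability and floral resources by
#' class, protection-level values, recreation threshold/usable-space/walking
#' distance, water-proximity distance and Budyko omega by class.
#'
#' @return Named list of indicator settings.
#' @export
default_indicator_config <- function() {
  cls <- lc_classes()
  vegetated <- c("cropland", "horticulture", "forest", "meadow_pasture",
                 "park_public", "other")
  omega <- ifelse(cls %in% vegetated, 2.6, 2.0)
  names(omega) <- cls
  list(
    nesting_suitability = c(settlement = .1, cropland = .2, horticulture = .3,
                            forest = .9, meadow_pasture = .7, water = 0,
                            park_public = .6, other = .4)[cls],
    floral_resources = c(settlement = .1, cropland = .3, horticulture = .7,
                         forest = .6, meadow_pasture = .9, water = 0,
                         park_public = .7, other = .3)[cls],
    protection_values = c(`0` = 0, `1` = .25, `2` = .5, `3` = .75, `4` = 1),
    recreation_threshold = 0.4,      # keep pixels with value >= threshold
    usable_space_fraction = 0.5,     # share of a pixel usable for recreation
    water_proximity_distance = 200,  # m, bonus band around water bodies
    walk_distance = 1000,            # m, recreation-demand buffer radius
    budyko_omega = omega
  )
}

# zone means / sums of a per-pixel vector or matrix
zonal_mean <- function(values, stack) {
  v <- tapply(as.vector(values), as.vector(stack$zones), mean)
  data.frame(municipality_id = as.integer(names(v)), value = as.numeric(v))
}
zonal_sum <- function(values, stack) {
  v <- tapply(as.vector(values), as.vector(stack$zones), sum)
  data.frame(municipality_id = as.integer(names(v)), value = as.numeric(v))
}

lookup_by_class <- function(stack, t, table, what) {
  miss <- setdiff(stack$classes, names(table))
  if (length(miss))
    stop(sprintf("%s: no value for land-cover class(es): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  matrix(table[stack$classes][as.vector(stack$land_cover[[t]])],
         nrow(stack$zones), ncol(stack$zones))
}

#' Pollination supply: kernel-averaged pollinator abundance
#'
#' Abundance at a pixel is its nesting suitability times the kernel-weighted
#' mean of floral resources within foraging range,
#' `K(d) = exp(-d / alpha)` truncated at `truncation_radius` and normalized
#' by the in-grid kernel mass. The municipal value is the mean over zone
#' pixels, clipped to [0, 1].
#'
#' @param stack A `landscape_stack`.
#' @param t Timestep index.
#' @param params [default_kernel_params()].
#' @param config [default_indicator_config()] (nesting/floral lookups).
#' @return Data frame municipality_id, value (index in [0, 1]).
#' @export
pollination_supply <- function(stack, t, params = default_kernel_params(),
                               config = default_indicator_config()) {
  N <- lookup_by_class(stack, t, config$nesting_suitability, "nesting suitability")
  F <- lookup_by_class(stack, t, config$floral_resources, "floral resources")
  off <- kernel_offsets(params$truncation_radius, stack$res_m)
  w <- exp(-off$dist / params$foraging_distance_alpha)
  abundance <- pmin(pmax(N * kernel_average(F, off, w), 0), 1)
  zonal_mean(abundance, stack)
}

#' Pollination demand: pollinator dependence of the crop mix
#'
#' Mean pollinator-dependence fraction over a municipality's cultivated area
#' (area-share weighted), rescaled by the maximum attainable dependence so
#' the index spans [0, 1]. Municipalities with no cropland score 0.
#'
#' @inheritParams pollination_supply
#' @param econ [default_econ_tables()] (crop_pollinator_dependence).
#' @return Data frame municipality_id, value (index in [0, 1]).
#' @export
pollination_demand <- function(stack, t, econ = default_econ_tables()) {
  dep <- econ$crop_pollinator_dependence
  if (!length(dep)) stop("no crop pollinator-dependence table", call. = FALSE)
  crop_cls <- names(dep)
  lc <- as.vector(stack$land_cover[[t]])
  z <- as.vector(stack$zones)
  out <- data.frame(municipality_id = stack$zone_ids, value = 0)
  crop_code <- match(crop_cls, stack$classes)
  is_crop <- lc %in% crop_code
  if (any(is_crop)) {
    depv <- dep[match(stack$classes[lc[is_crop]], crop_cls)]
    num <- tapply(depv, factor(z[is_crop], levels = stack$zone_ids), sum)
    den <- tapply(rep(1, sum(is_crop)), factor(z[is_crop], levels = stack$zone_ids), sum)
    v <- as.numeric(num) / as.numeric(den) / max(dep)
    v[is.na(v)] <- 0
    out$value <- v
  }
  out
}

#' Habitat-preservation supply: mean protection value
#'
#' Protection levels 0..4 are mapped to values (default 0, .25, .5, .75, 1)
#' and averaged over the zone. Accepts either a static protection raster or
#' one raster per timestep.
#'
#' @inheritParams pollination_supply
#' @return Data frame municipality_id, value (index in [0, 1]).
#' @export
habitat_supply <- function(stack, t = NULL,
                           config = default_indicator_config()) {
  pv <- config$protection_values
  prot <- if (is.list(stack$protection)) {
    stack$protection[[if (is.null(t)) length(stack$protection) else t]]
  } else stack$protection
  lev <- as.vector(prot)
  bad <- setdiff(unique(lev), as.integer(names(pv)))
  if (length(bad))
    stop("unknown protection level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  zonal_mean(matrix(pv[as.character(lev)], nrow(stack$zones)), stack)
}

# Raw (un-rescaled) per-pixel habitat degradation at timestep t.
habitat_degradation_raw <- function(stack, t, params) {
  threats <- stack$threat_layers[[t]]
  if (!length(threats)) stop("no threat layers", call. = FALSE)
  total <- matrix(0, nrow(stack$zones), ncol(stack$zones))
  for (r in names(threats)) {
    dmax <- params$threat_max_distance[[r]]
    off <- kernel_offsets(dmax, stack$res_m)
    w <- decay_weights(off$dist, params$threat_decay[[r]], dmax)
    exposure <- kernel_average(threats[[r]], off, w)
    sens <- params$habitat_sensitivity[r, ]
    sens_px <- matrix(sens[stack$classes][as.vector(stack$land_cover[[t]])],
                      nrow(stack$zones))
    total <- total + params$threat_weight[[r]] * exposure * sens_px
  }
  total
}

#' Habitat-preservation demand: rescaled habitat degradation
#'
#' Per-pixel degradation is the threat-weighted sum over threat layers of the
#' kernel-averaged threat intensity (linear or exponential decay, clipped at
#' the threat's maximum distance) times the focal class's sensitivity to that
#' threat. The field is rescaled to [0, 1] by `rescale_max` (by default the
#' regional maximum of the current field; the pipeline passes the maximum
#' over all timesteps so temporal trends survive rescaling) and averaged per
#' zone. All-zero threats yield 0 everywhere.
#'
#' @inheritParams pollination_supply
#' @param rescale_max Positive scalar used as the rescaling denominator, or
#'   NULL to use the field's own maximum.
#' @return Data frame municipality_id, value (index in [0, 1]).
#' @export
habitat_demand <- function(stack, t, params = default_kernel_params(),
                           rescale_max = NULL) {
  total <- habitat_degradation_raw(stack, t, params)
  mx <- if (is.null(rescale_max)) max(total) else rescale_max
  if (mx > 0) total <- total / mx
  zonal_mean(pmin(total, 1), stack)
}

# Per-pixel recreation value: mean of the class attractiveness layer, a
# water-proximity flag and a public-park flag.
recreation_value <- function(stack, t, econ, config) {
  val <- lookup_by_class(stack, t, econ$recreation_value_by_class,
                         "recreation value")
  water <- stack$land_cover[[t]] == match("water", stack$classes)
  near_water <- within_distance(water, config$water_proximity_distance,
                                stack$res_m) * 1
  park <- (stack$land_cover[[t]] == match("park_public", stack$classes)) * 1
  (val + near_water + park) / 3
}

#' Recreation supply: usable recreation space
#'
#' The per-pixel recreation value (mean of class attractiveness, water
#' proximity and park flags) is thresholded at `recreation_threshold`;
#' retained pixels contribute value x pixel area x usable-space fraction
#' (m2), and the municipal value is the zone mean of these contributions.
#'
#' @inheritParams pollination_supply
#' @param econ [default_econ_tables()].
#' @return Data frame municipality_id, value (m2).
#' @export
recreation_supply <- function(stack, t, econ = default_econ_tables(),
                              config = default_indicator_config()) {
  theta <- config$recreation_threshold
  if (theta <= 0 || theta >= 1)
    stop("recreation_threshold must be in (0, 1)", call. = FALSE)
  v <- recreation_value(stack, t, econ, config)
  contrib <- ifelse(v >= theta,
                    v * stack$pixel_area * config$usable_space_fraction, 0)
  zonal_mean(contrib, stack)
}

#' Recreation demand: population-weighted need for recreation space
#'
#' Per pixel, the mean population within walking distance (uniform disc
#' buffer of radius `walk_distance`, normalized by the in-grid buffer pixel
#' count) times the per-capita recreation need (m2/person); the municipal
#' value is the zone mean.
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (m2).
#' @export
recreation_demand <- function(stack, t, econ = default_econ_tables(),
                              config = default_indicator_config()) {
  off <- kernel_offsets(config$walk_distance, stack$res_m)
  mean_pop <- kernel_average(stack$population[[t]], off, rep(1, nrow(off)))
  zonal_mean(mean_pop * econ$per_capita_recreation_need, stack)
}

#' Food supply: crop and livestock production
#'
#' Sum over crop classes of yield (kg/ha) x cultivated area (ha) plus meat
#' production, `livestock_density` (animals/ha of pasture) x pasture area x
#' `meat_per_animal` (kg).
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (kg).
#' @export
food_supply <- function(stack, t, econ = default_econ_tables()) {
  px_ha <- stack$pixel_area / 1e4
  lc <- as.vector(stack$land_cover[[t]])
  z <- factor(as.vector(stack$zones), levels = stack$zone_ids)
  total <- numeric(length(stack$zone_ids))
  for (cl in names(econ$crop_yield)) {
    cnt <- tapply(lc == match(cl, stack$classes), z, sum)
    total <- total + econ$crop_yield[[cl]] * as.numeric(cnt) * px_ha
  }
  for (cl in names(econ$livestock_density)) {
    cnt <- tapply(lc == match(cl, stack$classes), z, sum)
    animals <- econ$livestock_density[[cl]] * as.numeric(cnt) * px_ha
    total <- total + animals * econ$meat_per_animal
  }
  data.frame(municipality_id = stack$zone_ids, value = total)
}

#' Food demand: per-capita consumption times population
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (kg).
#' @export
food_demand <- function(stack, t, econ = default_econ_tables()) {
  pop <- zonal_sum(stack$population[[t]], stack)
  data.frame(municipality_id = pop$municipality_id,
             value = pop$value * econ$per_capita_food_demand)
}

#' Budyko-Fu annual water yield (mm)
#'
#' Actual evapotranspiration follows Fu's form of the Budyko curve,
#' `AET/P = 1 + PET/P - (1 + (PET/P)^omega)^(1/omega)`, so yield is
#' `Y = P - AET`. Pixels with P <= 0 yield 0 (with a warning).
#'
#' @param p Precipitation (mm/yr), vector or matrix.
#' @param pet Potential evapotranspiration (mm/yr), same shape.
#' @param omega Budyko shape parameter (> 1), scalar or same shape.
#' @return Water yield in mm/yr, same shape as `p`.
#' @examples
#' budyko_yield(1000, 800, 2.6)
#' @export
budyko_yield <- function(p, pet, omega) {
  bad <- p <= 0
  if (any(bad)) warning("precipitation <= 0 at ", sum(bad),
                        " pixel(s); yield set to 0")
  phi <- ifelse(bad, 0, pet / pmax(p, .Machine$double.eps))
  y <- p * ((1 + phi^omega)^(1 / omega) - phi)
  y[bad] <- 0
  pmax(y, 0)
}

#' Water-regulation supply: municipal water yield volume
#'
#' Per-pixel Budyko-Fu yield (mm/yr) with class-specific omega, averaged over
#' the zone and converted to m3/yr (mean mm x zone area m2 x 1e-3).
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (m3).
#' @export
water_supply <- function(stack, t, config = default_indicator_config()) {
  omega <- lookup_by_class(stack, t, config$budyko_omega, "budyko omega")
  y_mm <- budyko_yield(stack$precipitation, stack$pet, omega)
  mean_mm <- zonal_mean(y_mm, stack)
  zone_px <- as.numeric(table(factor(as.vector(stack$zones),
                                     levels = stack$zone_ids)))
  data.frame(municipality_id = mean_mm$municipality_id,
             value = mean_mm$value * zone_px * stack$pixel_area * 1e-3)
}

#' Water-regulation demand: household plus sectoral consumption
#'
#' Per-capita household demand times municipal population, plus the sum over
#' zone pixels of the sectoral rate of each pixel's land-cover class.
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (m3).
#' @export
water_demand <- function(stack, t, econ = default_econ_tables()) {
  pop <- zonal_sum(stack$population[[t]], stack)
  sect <- lookup_by_class(stack, t, econ$sectoral_water_demand,
                          "sectoral water demand")
  sect_sum <- zonal_sum(sect, stack)
  data.frame(municipality_id = pop$municipality_id,
             value = pop$value * econ$per_capita_water_demand + sect_sum$value)
}

#' Climate-regulation supply: net primary productivity
#'
#' NPP (tC/ha/yr) by land-cover class, summed over zone pixels, as the
#' carbon-sequestration proxy.
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (tC).
#' @export
climate_supply <- function(stack, t, econ = default_econ_tables()) {
  npp <- lookup_by_class(stack, t, econ$npp_by_class, "npp")
  out <- zonal_sum(npp, stack)
  out$value <- out$value * stack$pixel_area / 1e4
  out
}

#' Climate-regulation demand: per-capita emissions as carbon
#'
#' Per-capita CO2-equivalent emissions for the timestep times municipal
#' population, converted from CO2e to carbon by the molar-mass ratio 12/44.
#'
#' @inheritParams recreation_supply
#' @return Data frame municipality_id, value (tC).
#' @export
climate_demand <- function(stack, t, econ = default_econ_tables()) {
  pop <- zonal_sum(stack$population[[t]], stack)
  rate <- econ$per_capita_co2e[min(t, length(econ$per_capita_co2e))]
  data.frame(municipality_id = pop$municipality_id,
             value = pop$value * rate * 12 / 44)
}

#' Backcast a partially observed NPP series by linear regression
#'
#' Fits ordinary least squares of the observed values on the timestep index
#' and fills missing entries by (extra)polation, clipping fills at 0. Mirrors
#' the treatment of satellite NPP that only exists for recent timesteps.
#'
#' @param series Numeric vector over timesteps, NA where unobserved.
#' @return The completed series.
#' @examples
#' npp_backcast(c(NA, NA, 100, 110))
#' @export
npp_backcast <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) < 2L)
    stop("npp_backcast needs >= 2 observed timesteps", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = obs, y = series[obs]))
  fill <- which(is.na(series))
  if (length(fill)) {
    pred <- stats::predict(fit, newdata = data.frame(x = fill))
    series[fill] <- pmax(0, pred)
  }
  series
}

#' Compute the full supply/demand table for all NCPs and timesteps
#'
#' Runs every indicator for every timestep and stacks the results into the
#' long-form NCP table. Habitat degradation is rescaled by its maximum over
#' all timesteps (one shared denominator) so its temporal trend is preserved.
#' If `npp_mask_timesteps` is non-empty, climate supply at those timesteps is
#' discarded and refilled per municipality with [npp_backcast()], emulating
#' an NPP record that only exists for later timesteps.
#'
#' @param stack A `landscape_stack`.
#' @param econ [default_econ_tables()].
#' @param params [default_kernel_params()].
#' @param config [default_indicator_config()].
#' @param ncps Subset of [ncp_codes()] to compute.
#' @param npp_mask_timesteps Integer timestep indices whose climate supply is
#'   reconstructed by regression instead of computed directly.
#' @return Data frame with columns municipality_id, ncp, timestep, supply,
#'   demand, unit, per_capita (FALSE; see [per_capita_transform()]).
#' @export
compute_ncp_table <- function(stack, econ = default_econ_tables(length(stack$timesteps)),
                              params = default_kernel_params(),
                              config = default_indicator_config(),
                              ncps = ncp_codes(),
                              npp_mask_timesteps = integer()) {
  stopifnot(all(ncps %in% ncp_codes()))
  Tn <- length(stack$timesteps)
  units <- c(POL = "index", HAB = "index", REC = "m2", FOD = "kg",
             WAT = "m3", CLI = "tC")

  hab_max <- if ("HAB" %in% ncps) {
    max(vapply(seq_len(Tn),
               function(t) max(habitat_degradation_raw(stack, t, params)),
               numeric(1)))
  } else NA_real_

  rows <- list()
  for (t in seq_len(Tn)) {
    for (code in ncps) {
      sd <- switch(code,
        POL = list(pollination_supply(stack, t, params, config),
                   pollination_demand(stack, t, econ)),
        HAB = list(habitat_supply(stack, t, config),
                   habitat_demand(stack, t, params, rescale_max = hab_max)),
        REC = list(recreation_supply(stack, t, econ, config),
                   recreation_demand(stack, t, econ, config)),
        FOD = list(food_supply(stack, t, econ),
                   food_demand(stack, t, econ)),
        WAT = list(water_supply(stack, t, config),
                   water_demand(stack, t, econ)),
        CLI = list(climate_supply(stack, t, econ),
                   climate_demand(stack, t, econ))
      )
      rows[[length(rows) + 1L]] <- data.frame(
        municipality_id = sd[[1]]$municipality_id,
        ncp = code,
        timestep = stack$timesteps[t],
        supply = sd[[1]]$value,
        demand = sd[[2]]$value,
        unit = units[[code]],
        per_capita = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  if (length(npp_mask_timesteps) && "CLI" %in% ncps) {
    keep_obs <- setdiff(seq_len(Tn), npp_mask_timesteps)
    if (length(keep_obs) < 2L)
      stop("npp backcast needs >= 2 unmasked timesteps", call. = FALSE)
    cli <- tab$ncp == "CLI"
    for (mun in unique(tab$municipality_id[cli])) {
      sel <- cli & tab$municipality_id == mun
      ord <- match(stack$timesteps, tab$timestep[sel])
      series <- tab$supply[sel][ord]
      series[npp_mask_timesteps] <- NA
      tab$supply[sel][ord] <- npp_backcast(series)
    }
  }
  tab
}
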