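# Unit tests of the six indicator models on hand-built stacks where every
# expected value is either a closed-form hand evaluation or a brute-force
# enumeration.

const_config <- function(N = 0.5, F = 0.8) {
  cfg <- default_indicator_config()
  cfg$nesting_suitability[] <- N
  cfg$floral_resources[] <- F
  cfg
}

test_that("pollination abundance of a uniform landscape is N * F everywhere", {
  st <- manual_stack(matrix(cls_code("meadow_pasture"), 10, 10))
  out <- pollination_supply(st, 1, config = const_config(0.5, 0.8))
  expect_equal(out$value, 0.4, tolerance = 1e-12)
  out0 <- pollination_supply(st, 1, config = const_config(0, 0.8))
  expect_equal(out0$value, 0)
})

test_that("two-pixel pollination kernel matches the hand-evaluated sum", {
  # pixels 100 m apart, alpha 500: abundance at the floral pixel is
  # (1 + e^-0.2 * 0) / (1 + e^-0.2)
  st <- manual_stack(matrix(c(cls_code("meadow_pasture"),
                              cls_code("water")), 1, 2))
  cfg <- default_indicator_config()
  cfg$nesting_suitability[] <- 1
  cfg$floral_resources[] <- 0
  cfg$floral_resources["meadow_pasture"] <- 1
  st$zones <- matrix(c(1L, 2L), 1, 2); st$zone_ids <- 1:2
  out <- pollination_supply(st, 1, config = cfg)
  expect_equal(out$value[1], 1 / (1 + exp(-0.2)), tolerance = 1e-12)
  expect_equal(out$value[2], exp(-0.2) / (1 + exp(-0.2)), tolerance = 1e-12)
})

test_that("pollination demand is the rescaled dependence-weighted crop share", {
  lc <- matrix(cls_code("forest"), 4, 4)
  lc[1, 1:2] <- cls_code("cropland")
  lc[2, 1:2] <- cls_code("horticulture")
  st <- manual_stack(lc)
  econ <- default_econ_tables()
  econ$crop_pollinator_dependence <- c(cropland = 0.65, horticulture = 0.05)
  out <- pollination_demand(st, 1, econ)
  expect_equal(out$value, (0.5 * 0.65 + 0.5 * 0.05) / 0.65, tolerance = 1e-12)
  # no cropland at all -> 0
  st2 <- manual_stack(matrix(cls_code("forest"), 3, 3))
  expect_equal(pollination_demand(st2, 1, econ)$value, 0)
  # all cropland in the maximally dependent class -> 1
  st3 <- manual_stack(matrix(cls_code("cropland"), 3, 3))
  expect_equal(pollination_demand(st3, 1, econ)$value, 1)
})

test_that("habitat supply maps protection levels onto the unit interval", {
  st <- manual_stack(matrix(cls_code("forest"), 4, 4))
  expect_equal(habitat_supply(st, 1)$value, 0)
  st$protection <- matrix(4L, 4, 4)
  expect_equal(habitat_supply(st, 1)$value, 1)
  st$protection <- matrix(c(2L, 0L), 4, 4)   # half level 2, half level 0
  expect_equal(habitat_supply(st, 1)$value, 0.25)
  st$protection <- matrix(7L, 4, 4)
  expect_error(habitat_supply(st, 1), "protection level")
})

test_that("habitat degradation decays linearly from a point threat", {
  n <- 15
  lc <- matrix(cls_code("forest"), n, n)
  thr <- matrix(0, n, n); thr[8, 8] <- 1
  st <- manual_stack(lc, threats = list(urban = thr, agriculture = matrix(0, n, n)))
  params <- default_kernel_params()
  raw <- ncpscape:::habitat_degradation_raw(st, 1, params)
  # interior pixels share the kernel denominator, so degradation relative to
  # the threat pixel falls as decay(d)/decay(0) = 1 - d/d_max (d_max = 500)
  expect_equal(raw[8, 8 + 2] / raw[8, 8], (1 - 200 / 500) / 1, tolerance = 1e-9)
  expect_equal(raw[8 + 3, 8] / raw[8, 8], (1 - 300 / 500) / 1, tolerance = 1e-9)
  # insensitive class scores zero regardless of threats
  st$land_cover[[1]][] <- cls_code("settlement")
  expect_equal(habitat_demand(st, 1, params)$value, 0)
  # no threats anywhere -> 0, not an error
  st$threat_layers[[1]]$urban[] <- 0
  expect_equal(habitat_demand(st, 1, params)$value, 0)
})

test_that("habitat degradation kernel matches brute force on a small grid", {
  set.seed(5)
  n <- 12
  thr <- matrix(rbinom(n * n, 1, 0.2), n, n)
  st <- manual_stack(matrix(cls_code("forest"), n, n),
                     threats = list(urban = thr, agriculture = matrix(0, n, n)))
  params <- default_kernel_params()
  raw <- ncpscape:::habitat_degradation_raw(st, 1, params)
  slow <- ncpscape:::kernel_average_bruteforce(
    thr, function(d) 1 - d / 500, 500, 100)
  expect_equal(raw, params$threat_weight[["urban"]] * slow * 0.9,
               tolerance = 1e-9)
})

test_that("recreation supply thresholds and scales pixel values", {
  # single-pixel park municipality beside water: value (1 + 1 + 1)/3 = 1,
  # contribution 1 * 10000 m2 * 0.5
  lc <- matrix(cls_code("forest"), 5, 5)
  lc[3, 3] <- cls_code("park_public")
  lc[3, 2] <- cls_code("water")
  zones <- matrix(1L, 5, 5); zones[3, 3] <- 2L
  st <- manual_stack(lc, zones = zones)
  out <- recreation_supply(st, 1)
  expect_equal(out$value[out$municipality_id == 2], 5000, tolerance = 1e-9)
  # a threshold nobody reaches yields zero supply
  cfg <- default_indicator_config()
  cfg$recreation_threshold <- 0.99
  out2 <- recreation_supply(st, 1, config = cfg)
  expect_equal(out2$value[out2$municipality_id == 1], 0)
  # raising the threshold never increases supply
  cfg_lo <- default_indicator_config(); cfg_lo$recreation_threshold <- 0.2
  cfg_hi <- default_indicator_config(); cfg_hi$recreation_threshold <- 0.6
  reg <- tiny_region()
  lo <- recreation_supply(reg$stack, 1, reg$econ, cfg_lo)$value
  hi <- recreation_supply(reg$stack, 1, reg$econ, cfg_hi)$value
  expect_true(all(hi <= lo + 1e-12))
  cfg_bad <- default_indicator_config(); cfg_bad$recreation_threshold <- 1.5
  expect_error(recreation_supply(st, 1, config = cfg_bad), "threshold")
})

test_that("recreation demand equals the buffer-averaged population times need", {
  # uniform population p per pixel: interior demand is exactly p * q
  st <- manual_stack(matrix(cls_code("meadow_pasture"), 12, 12),
                     population = matrix(2.5, 12, 12))
  out <- recreation_demand(st, 1)
  expect_equal(out$value, 2.5 * 30, tolerance = 1e-12)
  # single person at the center of a 3x3 grid, walking radius one pixel:
  # brute-force enumeration of the plus-shaped buffer
  pop <- matrix(0, 3, 3); pop[2, 2] <- 1
  st3 <- manual_stack(matrix(cls_code("meadow_pasture"), 3, 3),
                      population = pop)
  cfg <- default_indicator_config(); cfg$walk_distance <- 100
  q <- 30
  per_pixel <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    buf <- 0; cnt <- 0
    for (p in 1:3) for (r in 1:3) {
      if (sqrt((i - p)^2 + (j - r)^2) <= 1) { buf <- buf + pop[p, r]; cnt <- cnt + 1 }
    }
    per_pixel[i, j] <- buf / cnt * q
  }
  out3 <- recreation_demand(st3, 1, config = cfg)
  expect_equal(out3$value, mean(per_pixel), tolerance = 1e-12)
  # zero population -> zero demand
  st3$population[[1]][] <- 0
  expect_equal(recreation_demand(st3, 1, config = cfg)$value, 0)
})

test_that("food supply adds crop yield and livestock production linearly", {
  econ <- default_econ_tables()
  lc <- matrix(cls_code("forest"), 10, 10)
  lc[, 1:5] <- cls_code("cropland")            # 50 px = 50 ha
  st <- manual_stack(lc)
  out <- food_supply(st, 1, econ)
  expect_equal(out$value, 6000 * 50)
  # doubling cropland area doubles the crop contribution
  lc2 <- matrix(cls_code("cropland"), 10, 10)  # 100 ha
  expect_equal(food_supply(manual_stack(lc2), 1, econ)$value, 6000 * 100)
  # livestock on pasture
  lc3 <- matrix(cls_code("meadow_pasture"), 10, 10)
  expect_equal(food_supply(manual_stack(lc3), 1, econ)$value,
               1.2 * 100 * 120)
  # nothing agricultural -> 0
  expect_equal(food_supply(manual_stack(matrix(cls_code("water"), 4, 4)), 1,
                           econ)$value, 0)
})

test_that("food demand is per-capita rate times population and is additive", {
  reg <- tiny_region()
  econ <- reg$econ
  out <- food_demand(reg$stack, 2, econ)
  pop <- zone_population(reg$stack)
  pop2 <- pop$population[pop$timestep == reg$stack$timesteps[2]]
  expect_equal(out$value, pop2 * econ$per_capita_food_demand, tolerance = 1e-9)
  expect_equal(sum(out$value), sum(pop2) * econ$per_capita_food_demand,
               tolerance = 1e-9)
})

test_that("Budyko-Fu yield honors its limits and matches direct evaluation", {
  # energy limit: no evaporative demand returns all precipitation
  expect_equal(budyko_yield(1000, 0, 2.6), 1000)
  # water limit: infinite aridity returns nothing
  expect_lt(budyko_yield(100, 1e9, 2.6), 1e-3)
  # independent high-precision re-evaluation of Fu's form
  p <- 1000; pet <- 800; om <- 2.6
  aet_over_p <- 1 + pet / p - (1 + (pet / p)^om)^(1 / om)
  expect_equal(budyko_yield(p, pet, om), p * (1 - aet_over_p), tolerance = 1e-12)
  expect_warning(y0 <- budyko_yield(c(0, 500), c(100, 100), 2), "precipitation")
  expect_equal(y0[1], 0)
})

test_that("water supply converts mean yield to municipal volume", {
  st <- manual_stack(matrix(cls_code("forest"), 6, 6),
                     precipitation = 1000, pet = 800)
  out <- water_supply(st, 1)
  y <- budyko_yield(1000, 800, 2.6)
  expect_equal(out$value, y * 36 * 10000 * 1e-3, tolerance = 1e-9)
})

test_that("water demand combines household and sectoral terms", {
  lc <- matrix(cls_code("forest"), 10, 10)
  lc[, 1:5] <- cls_code("cropland")
  pop <- matrix(0.1, 10, 10)   # 10 persons
  st <- manual_stack(lc, population = pop)
  econ <- default_econ_tables()
  expected <- 10 * econ$per_capita_water_demand +
    50 * econ$sectoral_water_demand[["cropland"]]
  expect_equal(water_demand(st, 1, econ)$value, expected, tolerance = 1e-9)
  # household term is linear in population
  st$population[[1]] <- pop * 3
  expect_equal(water_demand(st, 1, econ)$value,
               30 * econ$per_capita_water_demand +
                 50 * econ$sectoral_water_demand[["cropland"]],
               tolerance = 1e-9)
})

test_that("climate supply sums class NPP over the zone", {
  st <- manual_stack(matrix(cls_code("forest"), 10, 20))  # 200 ha
  expect_equal(climate_supply(st, 1)$value, 200 * 6)
  st2 <- manual_stack(matrix(cls_code("water"), 5, 5))
  expect_equal(climate_supply(st2, 1)$value, 25 * 0.1)
})

test_that("climate demand converts CO2e to carbon by 12/44", {
  pop <- matrix(0, 5, 5); pop[1, 1] <- 8   # 8 persons
  st <- manual_stack(matrix(cls_code("settlement"), 5, 5), population = pop)
  econ <- default_econ_tables()
  econ$per_capita_co2e <- c(5.5, 5.5)
  out <- climate_demand(st, 1, econ)
  expect_equal(out$value, 8 * 5.5 * 12 / 44, tolerance = 1e-12)
  # 44 t CO2e correspond to 12 t carbon
  econ$per_capita_co2e <- c(44, 44)
  pop1 <- matrix(0, 5, 5); pop1[1, 1] <- 1
  st$population[[1]] <- pop1
  expect_equal(climate_demand(st, 1, econ)$value, 12, tolerance = 1e-12)
})

test_that("npp backcast extrapolates the two-point line and clips at zero", {
  expect_equal(npp_backcast(c(NA, NA, 100, 110)), c(80, 90, 100, 110))
  expect_equal(npp_backcast(c(NA, 50, 50, NA)), c(50, 50, 50, 50))
  expect_equal(npp_backcast(c(NA, NA, 10, 200))[1], 0)  # clipped
  expect_error(npp_backcast(c(NA, NA, NA, 5)), ">= 2")
})

test_that("regional totals of mass-unit NCPs equal the sum over municipalities", {
  reg <- tiny_region()
  st <- reg$stack
  one_zone <- st
  one_zone$zones <- matrix(1L, nrow(st$zones), ncol(st$zones))
  one_zone$zone_ids <- 1L
  for (f in list(food_supply, water_demand, climate_supply)) {
    per_mun <- f(st, 1, reg$econ)
    regional <- f(one_zone, 1, reg$econ)
    expect_equal(sum(per_mun$value), regional$value, tolerance = 1e-9)
  }
})

test_that("missing class lookups raise configuration errors", {
  st <- manual_stack(matrix(cls_code("forest"), 3, 3))
  cfg <- default_indicator_config()
  cfg$nesting_suitability <- cfg$nesting_suitability[-4]
  expect_error(pollination_supply(st, 1, config = cfg), "forest")
})

test_that("the assembled NCP table covers every municipality, NCP and timestep", {
  reg <- tiny_region()
  tab <- compute_ncp_table(reg$stack, reg$econ)
  expect_equal(nrow(tab), 10 * 6 * 4)
  expect_true(all(tab$supply >= 0) && all(tab$demand >= 0))
  pol <- tab[tab$ncp %in% c("POL", "HAB"), ]
  expect_true(all(pol$supply <= 1) && all(pol$demand <= 1))
  # masked climate supply is refilled on the fitted line through later points
  tab_bc <- compute_ncp_table(reg$stack, reg$econ, npp_mask_timesteps = 1:2)
  cli <- tab_bc[tab_bc$ncp == "CLI" & tab_bc$municipality_id == 1, ]
  cli0 <- tab[tab$ncp == "CLI" & tab$municipality_id == 1, ]
  y <- cli0$supply[3:4]
  expect_equal(cli$supply[1:2], pmax(0, c(y[1] - 2 * (y[2] - y[1]),
                                          y[1] - (y[2] - y[1]))),
               tolerance = 1e-9)
  expect_equal(cli$supply[3:4], y)
})

test_that("raising a threat layer never decreases habitat demand", {
  reg <- tiny_region()
  st <- reg$stack
  base <- habitat_demand(st, 1, rescale_max = 1)
  st2 <- st
  st2$threat_layers[[1]]$agriculture <-
    pmin(st2$threat_layers[[1]]$agriculture + 0.2, 1)
  more <- habitat_demand(st2, 1, rescale_max = 1)
  expect_true(all(more$value >= base$value - 1e-12))
})
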