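# Synthetic study-region generator. Emulates the statistical structure the
# downstream analysis assumes -- a canton-scale mosaic of municipalities with
# decadal land-use change, an urbanization gradient, ~60% population growth
# over the window, and a planted archetype structure that should reappear in
# the spatiotemporal NCP trend profiles.

# The four canonical archetypes: starting land-cover class fractions, a
# per-step Markov transition of those fractions, a settlement population
# density scale (persons per settlement-hectare) and a relative growth factor.
archetype_definitions <- function() {
  cls <- lc_classes()
  frac <- function(...) {
    f <- c(...)
    stopifnot(setequal(names(f), cls))
    f <- f[cls]
    f / sum(f)
  }
  list(
    urbanizing_core = list(
      start = frac(settlement = .30, cropland = .18, horticulture = .04,
                   forest = .13, meadow_pasture = .15, water = .02,
                   park_public = .07, other = .11),
      moves = list(c("cropland", "settlement", .22),
                   c("meadow_pasture", "settlement", .15),
                   c("horticulture", "settlement", .08),
                   c("other", "settlement", .10),
                   c("other", "park_public", .04),
                   c("meadow_pasture", "park_public", .05)),
      density = 80, growth = 2.2
    ),
    stable_highlands = list(
      start = frac(settlement = .05, cropland = .05, horticulture = .01,
                   forest = .45, meadow_pasture = .34, water = .02,
                   park_public = .01, other = .07),
      moves = list(c("meadow_pasture", "forest", .01),
                   c("cropland", "settlement", .02)),
      density = 30, growth = 1.15
    ),
    agro_plain = list(
      start = frac(settlement = .08, cropland = .52, horticulture = .04,
                   forest = .12, meadow_pasture = .16, water = .01,
                   park_public = .01, other = .06),
      moves = list(c("meadow_pasture", "cropland", .12),
                   c("forest", "cropland", .05),
                   c("cropland", "horticulture", .10),
                   c("cropland", "settlement", .02)),
      density = 25, growth = 1.35
    ),
    blue_green_belt = list(
      start = frac(settlement = .12, cropland = .12, horticulture = .02,
                   forest = .22, meadow_pasture = .23, water = .14,
                   park_public = .08, other = .07),
      moves = list(c("cropland", "settlement", .06),
                   c("meadow_pasture", "park_public", .08),
                   c("meadow_pasture", "settlement", .03)),
      density = 45, growth = 1.5
    )
  )
}

# Row-stochastic 8x8 transition matrix from a list of (from, to, rate) moves.
transition_matrix <- function(moves) {
  cls <- lc_classes()
  T <- diag(length(cls))
  dimnames(T) <- list(cls, cls)
  for (m in moves) {
    rate <- as.numeric(m[3])
    T[m[1], m[1]] <- T[m[1], m[1]] - rate
    T[m[1], m[2]] <- T[m[1], m[2]] + rate
  }
  if (any(T < -1e-12))
    stop("archetype transition rates leave a class share negative", call. = FALSE)
  T
}

# Class-fraction trajectory of one archetype: n_timesteps x n_classes matrix.
archetype_trajectory <- function(arch, n_timesteps) {
  T <- transition_matrix(arch$moves)
  f <- arch$start
  out <- matrix(NA_real_, n_timesteps, length(f), dimnames = list(NULL, names(f)))
  for (t in seq_len(n_timesteps)) {
    out[t, ] <- f
    f <- as.numeric(f %*% T)
    names(f) <- colnames(T)
  }
  out
}

#' Planted archetype labels of a synthetic region
#'
#' Ground-truth archetype membership of every municipality, drawn from the
#' `labels` substream of the spec's seed: label counts are as balanced as
#' `n_municipalities` allows, and the assignment is identical to the one
#' [generate_region()] uses internally.
#'
#' @param spec A [region_spec()].
#' @return Integer vector of archetype ids (1..n_archetypes) named by
#'   municipality id, with a `archetype_names` attribute.
#' @examples
#' table(planted_labels(region_spec(n_municipalities = 8, n_archetypes = 4)))
#' @export
planted_labels <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  base <- rep_len(seq_len(spec$n_archetypes), spec$n_municipalities)
  lab <- with_substream(spec$seed, "labels", sample(base))
  names(lab) <- seq_len(spec$n_municipalities)
  nm <- names(archetype_definitions())
  attr(lab, "archetype_names") <-
    nm[((seq_len(spec$n_archetypes) - 1) %% length(nm)) + 1]
  lab
}

# Standard-normal white noise smoothed over a disc, standardized to mean 0 /
# sd 1. Gives spatially autocorrelated suitability surfaces.
smooth_field <- function(spec, name, radius_m = 600) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  res_m <- sqrt(spec$pixel_area)
  z <- with_substream(spec$seed, name,
                      matrix(stats::rnorm(nr * nc), nr, nc))
  off <- kernel_offsets(radius_m, res_m)
  s <- kernel_average(z, off, rep(1, nrow(off)))
  (s - mean(s)) / stats::sd(s)
}

# Voronoi partition of the grid into municipality zones around seed pixels.
voronoi_zones <- function(spec) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  n <- spec$n_municipalities
  seeds <- with_substream(spec$seed, "zones", sample.int(nr * nc, n))
  si <- (seeds - 1) %% nr + 1
  sj <- (seeds - 1) %/% nr + 1
  pi <- rep(seq_len(nr), times = nc)
  pj <- rep(seq_len(nc), each = nr)
  # nearest seed per pixel; ties broken by lowest municipality id
  best <- rep(1L, nr * nc)
  bestd <- (pi - si[1])^2 + (pj - sj[1])^2
  for (m in seq_len(n)[-1]) {
    d <- (pi - si[m])^2 + (pj - sj[m])^2
    hit <- d < bestd
    best[hit] <- m
    bestd[hit] <- d[hit]
  }
  list(zones = matrix(best, nr, nc), seed_idx = seeds,
       seed_row = si, seed_col = sj)
}

#' Generate a synthetic study region
#'
#' Builds a complete multi-timestep landscape: Voronoi municipality zones,
#' categorical land cover evolving by per-archetype Markov transitions of
#' class fractions (spatially allocated by fixed per-class suitability
#' surfaces, so class growth is nested and spatially contiguous), population
#' rasters distributed by a settlement-weighted kernel and rescaled so the
#' regional total grows by `spec$pop_growth` over the window, expanding
#' protection rasters, per-timestep urban and agricultural threat intensity
#' layers, and static precipitation / potential-evapotranspiration surfaces.
#' Deterministic for a fixed seed; each layer draws from its own named
#' substream.
#'
#' @param spec A [region_spec()].
#' @param econ Optional [default_econ_tables()] override.
#' @return A list with elements `stack` (class `landscape_stack`), `econ`
#'   (class `econ_tables`) and `labels` (the planted archetype labels, as
#'   returned by [planted_labels()]).
#' @examples
#' reg <- generate_region(region_spec(n_municipalities = 10,
#'                                    grid_shape = c(40, 40)))
#' table(reg$stack$land_cover[[1]])
#' @export
generate_region <- function(spec, econ = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  cls <- lc_classes()
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  npx <- nr * nc
  res_m <- sqrt(spec$pixel_area)
  Tn <- spec$n_timesteps
  n <- spec$n_municipalities
  if (is.null(econ)) econ <- default_econ_tables(Tn)
  validate_econ_tables(econ)

  labels <- planted_labels(spec)
  defs <- archetype_definitions()
  defs <- defs[((seq_len(spec$n_archetypes) - 1) %% length(defs)) + 1]

  # archetype class-fraction trajectories, blended toward the regional mean
  trajs <- lapply(defs, archetype_trajectory, n_timesteps = Tn)
  mean_traj <- Reduce(`+`, trajs) / length(trajs)
  m <- spec$archetype_mixing
  trajs <- lapply(trajs, function(tr) (1 - m) * tr + m * mean_traj)

  # municipality-level class noise: one multiplicative log-normal perturbation
  # per municipality x class, constant in time so trends are preserved
  zcls <- with_substream(spec$seed, "classnoise",
                         matrix(stats::rnorm(n * length(cls)), n, length(cls)))
  muni_frac <- function(mun, t) {
    f <- trajs[[labels[mun]]][t, ] * exp(spec$noise_sd * zcls[mun, ])
    f / sum(f)
  }

  vz <- voronoi_zones(spec)
  zones <- vz$zones
  zone_cells <- split(seq_len(npx), as.vector(zones))

  # distance from each pixel to its municipality's seed (urban core)
  pi <- rep(seq_len(nr), times = nc)
  pj <- rep(seq_len(nc), each = nr)
  dcore <- sqrt((pi - vz$seed_row[as.vector(zones)])^2 +
                (pj - vz$seed_col[as.vector(zones)])^2) * res_m
  dcore_n <- dcore / max(dcore)

  # fixed per-class suitability surfaces (higher = allocated earlier)
  g <- function(nm, r = 600) as.vector(smooth_field(spec, nm, r))
  suit <- list(
    settlement   = -3 * dcore_n + 0.3 * g("field_settlement"),
    water        = g("field_water", 900),
    forest       = g("field_forest", 800),
    cropland     = g("field_cropland", 800),
    horticulture = 0.7 * g("field_cropland", 800) + 0.5 * g("field_hort"),
    park_public  = -1.5 * dcore_n + g("field_park"),
    meadow_pasture = g("field_meadow", 800),
    other        = g("field_other")
  )
  alloc_order <- c("settlement", "water", "forest", "cropland",
                   "horticulture", "park_public", "meadow_pasture", "other")

  # largest-remainder apportionment of zone pixels to classes
  apportion <- function(frac, npix) {
    raw <- frac * npix
    cnt <- floor(raw)
    left <- npix - sum(cnt)
    if (left > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
      cnt[extra] <- cnt[extra] + 1
    }
    cnt
  }

  land_cover <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    lc <- integer(npx)
    for (mun in seq_len(n)) {
      cells <- zone_cells[[as.character(mun)]]
      cnt <- apportion(muni_frac(mun, t), length(cells))
      names(cnt) <- cls
      remaining <- cells
      for (cl in alloc_order) {
        k <- cnt[[cl]]
        if (k == 0L || length(remaining) == 0L) next
        pick <- order(suit[[cl]][remaining], decreasing = TRUE)[seq_len(k)]
        lc[remaining[pick]] <- match(cl, cls)
        remaining <- remaining[-pick]
      }
      if (length(remaining)) lc[remaining] <- match("other", cls)
    }
    land_cover[[t]] <- matrix(lc, nr, nc)
  }

  # population: municipal totals follow archetype density x settlement area x
  # relative growth, rescaled so the regional total follows pop_growth exactly
  zpop <- with_substream(spec$seed, "popnoise", stats::rnorm(n))
  p0_total <- 3 * npx * spec$pixel_area / 1e4   # ~3 persons/ha at t1
  pop_targets <- matrix(NA_real_, n, Tn)
  for (t in seq_len(Tn)) {
    phase <- (t - 1) / (Tn - 1)
    raw <- vapply(seq_len(n), function(mun) {
      a <- defs[[labels[mun]]]
      set_px <- sum(land_cover[[t]][zone_cells[[as.character(mun)]]] == 1L)
      a$density * a$growth^phase * (set_px + 2) * exp(spec$noise_sd * 0.5 * zpop[mun])
    }, numeric(1))
    pop_targets[, t] <- raw / sum(raw) * p0_total * spec$pop_growth^phase
  }

  pop_weight <- c(settlement = 1, cropland = .03, horticulture = .03,
                  forest = .01, meadow_pasture = .01, water = 0,
                  park_public = .05, other = .01)[cls]
  population <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    w <- pop_weight[as.vector(land_cover[[t]])]
    pop <- numeric(npx)
    for (mun in seq_len(n)) {
      cells <- zone_cells[[as.character(mun)]]
      ws <- w[cells]
      if (sum(ws) == 0) ws <- rep(1, length(cells))
      pop[cells] <- pop_targets[mun, t] * ws / sum(ws)
    }
    population[[t]] <- matrix(pop, nr, nc)
  }

  # protection rasters: protected-area networks expand over the decades at
  # archetype-specific rates. Natural-class pixels (first-timestep cover) are
  # designated in a fixed suitability order, so reserves grow nested; levels
  # are graded within the designated set (core zones highest).
  gp <- as.vector(smooth_field(spec, "field_protection", 700))
  lc1 <- as.vector(land_cover[[1]])
  natural <- lc1 %in% match(c("forest", "meadow_pasture", "water"), cls)
  prot_share <- list( # share of zone pixels protected, start -> end
    c(.08, .10), c(.30, .45), c(.10, .15), c(.25, .40)
  )
  zprot <- with_substream(spec$seed, "protnoise", stats::rnorm(n))
  protection <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    phase <- (t - 1) / (Tn - 1)
    prot <- integer(npx)
    for (mun in seq_len(n)) {
      cells <- zone_cells[[as.character(mun)]]
      sh <- prot_share[[((labels[mun] - 1) %% 4) + 1]]
      target <- (sh[1] + phase * (sh[2] - sh[1])) *
        exp(spec$noise_sd * 0.5 * zprot[mun])
      cand <- cells[natural[cells]]
      cand <- cand[order(gp[cand], decreasing = TRUE)]
      k <- min(length(cand), round(target * length(cells)))
      if (k > 0) {
        sel <- cand[seq_len(k)]
        q <- seq_along(sel) / k
        prot[sel] <- ifelse(q <= .15, 4L, ifelse(q <= .4, 3L,
                     ifelse(q <= .7, 2L, 1L)))
      }
      parks <- cells[lc1[cells] == match("park_public", cls)]
      prot[parks[prot[parks] == 0L]] <- 2L
    }
    protection[[t]] <- matrix(prot, nr, nc)
  }

  threat_layers <- lapply(seq_len(Tn), function(t) {
    lc <- land_cover[[t]]
    list(
      urban = (lc == match("settlement", cls)) * 1.0,
      agriculture = (lc == match("cropland", cls)) * 0.8 +
                    (lc == match("horticulture", cls)) * 0.6
    )
  })

  precipitation <- matrix(pmax(500, 1100 + 250 *
    as.vector(smooth_field(spec, "field_precip", 1200))), nr, nc)
  pet <- matrix(pmax(300, 650 + 80 *
    as.vector(smooth_field(spec, "field_pet", 1200))), nr, nc)

  stack <- structure(
    list(
      land_cover = land_cover,
      classes = cls,
      population = population,
      protection = protection,
      threat_layers = threat_layers,
      precipitation = precipitation,
      pet = pet,
      zones = zones,
      zone_ids = seq_len(n),
      res_m = res_m,
      pixel_area = spec$pixel_area,
      timesteps = spec$timestep_labels
    ),
    class = "landscape_stack"
  )
  list(stack = stack, econ = econ, labels = labels)
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("Landscape stack: %d x %d pixels (%.0f m), %d municipalities, %d timesteps\n",
              nrow(x$zones), ncol(x$zones), x$res_m,
              length(x$zone_ids), length(x$timesteps)))
  invisible(x)
}

#' Municipal population totals
#'
#' @param stack A `landscape_stack`.
#' @return Data frame with columns municipality_id, timestep, population.
#' @export
zone_population <- function(stack) {
  out <- do.call(rbind, lapply(seq_along(stack$timesteps), function(t) {
    tot <- tapply(as.vector(stack$population[[t]]), as.vector(stack$zones), sum)
    data.frame(municipality_id = as.integer(names(tot)),
               timestep = stack$timesteps[t],
               population = as.numeric(tot))
  }))
  rownames(out) <- NULL
  out
}

#' Rescale a timestep's population raster to a target regional total
#'
#' Per-pixel values are scaled proportionally so the regional sum equals
#' `target_total` exactly.
#'
#' @param stack A `landscape_stack`.
#' @param t Timestep index.
#' @param target_total Target total population (persons).
#' @return The modified stack.
#' @export
rescale_population <- function(stack, t, target_total) {
  cur <- sum(stack$population[[t]])
  if (cur <= 0) stop("cannot rescale an all-zero population raster", call. = FALSE)
  stack$population[[t]] <- stack$population[[t]] * (target_total / cur)
  stack
}

# per-municipality land-cover class shares at timestep t
zone_class_shares <- function(stack, t) {
  z <- as.vector(stack$zones)
  lc <- as.vector(stack$land_cover[[t]])
  tab <- table(factor(z, levels = stack$zone_ids),
               factor(lc, levels = seq_along(stack$classes)))
  shares <- sweep(unclass(tab), 1, rowSums(tab), "/")
  colnames(shares) <- stack$classes
  shares
}
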