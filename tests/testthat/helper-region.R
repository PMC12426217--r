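# Small fixture regions built in code. tiny_spec() keeps grids small enough
# for brute-force oracles; the full-size default region is only built in the
# acceptance tests.

tiny_spec <- function(seed = 7, ...) {
  args <- list(n_municipalities = 10, grid_shape = c(30, 30),
               n_archetypes = 4, noise_sd = 0.2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(region_spec, args)
}

tiny_region <- local({
  cache <- new.env()
  function(seed = 7, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]])) cache[[key]] <- generate_region(tiny_spec(seed, ...))
    cache[[key]]
  }
})

# Hand-built 1-municipality stack over a given land-cover matrix, for
# indicator unit tests where every input must be controlled exactly.
manual_stack <- function(lc_codes, population = NULL, protection = NULL,
                         precipitation = 1000, pet = 600,
                         threats = NULL, zones = NULL, res_m = 100,
                         timesteps = c("t1", "t2")) {
  nr <- nrow(lc_codes); nc <- ncol(lc_codes)
  blank <- matrix(0, nr, nc)
  if (is.null(population)) population <- blank
  if (is.null(protection)) protection <- matrix(0L, nr, nc)
  if (is.null(zones)) zones <- matrix(1L, nr, nc)
  if (is.null(threats)) threats <- list(urban = blank, agriculture = blank)
  Tn <- length(timesteps)
  structure(list(
    land_cover = rep(list(lc_codes), Tn),
    classes = lc_classes(),
    population = rep(list(population), Tn),
    protection = protection,
    threat_layers = rep(list(threats), Tn),
    precipitation = matrix(precipitation, nr, nc),
    pet = matrix(pet, nr, nc),
    zones = zones,
    zone_ids = sort(unique(as.vector(zones))),
    res_m = res_m,
    pixel_area = res_m^2,
    timesteps = timesteps
  ), class = "landscape_stack")
}

cls_code <- function(name) match(name, lc_classes())
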