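# Budget and ratio indices. The budget is formed on jointly min-max
# normalized supply and demand (shared scaling statistics per NCP, pooled
# over municipalities and timesteps), which is the only construction that
# bounds it in [-1, 1] while keeping temporal trends meaningful. The ratio
# is formed on raw same-unit values and shifted by -1 so that 0 means demand
# exactly met and -1 means no supply at all.

#' Convert food, water and climate records to per-capita values
#'
#' Divides supply and demand of the per-capita NCPs ([per_capita_ncps()]) by
#' municipal population at the matching timestep and flags the records.
#' Pollination, habitat and recreation records pass through untouched.
#'
#' @param ncp_table Output of [compute_ncp_table()].
#' @param population Data frame municipality_id, timestep, population (see
#'   [zone_population()]).
#' @return The transformed table, with per-capita units suffixed "/person".
#' @export
per_capita_transform <- function(ncp_table, population) {
  idx <- ncp_table$ncp %in% per_capita_ncps()
  if (!any(idx)) return(ncp_table)
  key <- paste(ncp_table$municipality_id, ncp_table$timestep)
  pkey <- paste(population$municipality_id, population$timestep)
  pop <- population$population[match(key, pkey)]
  if (anyNA(pop[idx]))
    stop("population missing for some municipality x timestep", call. = FALSE)
  zero <- idx & pop == 0 & ncp_table$demand > 0
  if (any(zero))
    stop("zero population with nonzero demand (municipality ",
         paste(unique(ncp_table$municipality_id[zero]), collapse = ", "),
         "): per-capita value undefined", call. = FALSE)
  ncp_table$supply[idx] <- ncp_table$supply[idx] / pop[idx]
  ncp_table$demand[idx] <- ncp_table$demand[idx] / pop[idx]
  ncp_table$per_capita[idx] <- TRUE
  ncp_table$unit[idx] <- paste0(ncp_table$unit[idx], "/person")
  ncp_table
}

#' Budget index from normalized supply and demand
#'
#' @param supply_norm,demand_norm Values in [0, 1].
#' @return supply_norm - demand_norm, bounded in [-1, 1].
#' @export
budget_index <- function(supply_norm, demand_norm) {
  supply_norm - demand_norm
}

#' Ratio index from raw same-unit supply and demand
#'
#' `supply / demand - 1`: 0 when demand is exactly met, -1 when there is no
#' supply, unbounded above. Demand 0 with positive supply maps to `cap`
#' (default 99); demand 0 with supply 0 maps to 0. Set `shift = FALSE` for
#' the plain quotient.
#'
#' @param supply,demand Raw non-negative values in the same unit.
#' @param cap Value used when demand is 0 but supply is positive.
#' @param shift Subtract 1 from the quotient (default TRUE).
#' @return Numeric vector, >= -1 when `shift` is TRUE.
#' @export
ratio_index <- function(supply, demand, cap = 99, shift = TRUE) {
  if (any(supply < 0) || any(demand < 0))
    stop("ratio_index: supply and demand must be >= 0", call. = FALSE)
  r <- ifelse(demand > 0, supply / demand,
              ifelse(supply > 0, cap + as.numeric(shift), 0 + as.numeric(shift)))
  if (shift) r - 1 else r
}

#' Build the normalized index table (budget and ratio per record)
#'
#' Per NCP, supply and demand are min-max scaled with shared statistics (one
#' min and one max over both variables, all municipalities and all
#' timesteps), so `supply_norm - demand_norm` lies in [-1, 1] and temporal
#' comparability is preserved. The ratio is computed from the raw (possibly
#' per-capita) values. A degenerate NCP (max equals min) maps to all-zero
#' normalized values with a warning.
#'
#' @param ncp_table Output of [compute_ncp_table()], usually after
#'   [per_capita_transform()].
#' @param ratio_cap Cap for supply > 0 / demand = 0 records.
#' @param ratio_shift Use the shifted ratio (quotient minus 1, default).
#' @return Data frame municipality_id, ncp, timestep, supply_norm,
#'   demand_norm, budget, ratio, with the per-NCP scaling statistics in
#'   `attr(, "norm_stats")`.
#' @export
build_index_table <- function(ncp_table, ratio_cap = 99, ratio_shift = TRUE) {
  out <- ncp_table[c("municipality_id", "ncp", "timestep")]
  out$supply_norm <- NA_real_
  out$demand_norm <- NA_real_
  stats_list <- list()
  for (code in unique(ncp_table$ncp)) {
    sel <- ncp_table$ncp == code
    vals <- c(ncp_table$supply[sel], ncp_table$demand[sel])
    lo <- min(vals); hi <- max(vals)
    if (hi - lo <= 0) {
      warning("NCP ", code, " is degenerate (max = min); normalized to 0")
      out$supply_norm[sel] <- 0
      out$demand_norm[sel] <- 0
    } else {
      out$supply_norm[sel] <- (ncp_table$supply[sel] - lo) / (hi - lo)
      out$demand_norm[sel] <- (ncp_table$demand[sel] - lo) / (hi - lo)
    }
    stats_list[[code]] <- c(min = lo, max = hi)
  }
  out$budget <- budget_index(out$supply_norm, out$demand_norm)
  out$ratio <- ratio_index(ncp_table$supply, ncp_table$demand,
                           cap = ratio_cap, shift = ratio_shift)
  attr(out, "norm_stats") <- stats_list
  out
}
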