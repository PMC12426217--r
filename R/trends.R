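# Temporal trend descriptors: the current budget plus the OLS slopes of the
# budget and ratio series over the ordered timesteps (budget coefficient and
# ratio coefficient). Slopes are purely descriptive; no inference is
# attached to 4-point regressions.

#' OLS slope of a series over its timestep index
#'
#' Ordinary least squares of the values on the (by default ordinal, 0-based)
#' timestep index. Invariant to adding a constant to the series or shifting
#' the index.
#'
#' @param y Numeric series, all finite, length >= 2.
#' @param t Regressor; defaults to 0, 1, ..., length(y) - 1. Pass calendar
#'   mid-years for a calendar-scaled slope.
#' @return The slope coefficient.
#' @examples
#' trend_slope(c(0.1, 0.2, 0.3, 0.4))
#' @export
trend_slope <- function(y, t = seq_along(y) - 1) {
  if (length(y) < 2L)
    stop("trend_slope needs >= 2 values", call. = FALSE)
  if (any(!is.finite(y)))
    stop("trend_slope: non-finite value in series", call. = FALSE)
  unname(stats::coef(stats::lm(y ~ t))[2L])
}

#' Build the trend table (current budget, budget and ratio coefficients)
#'
#' One row per municipality x NCP: the budget at the last timestep
#' (`current_budget`), the OLS slope of the budget series (`b_coeff`) and of
#' the ratio series (`r_coeff`) over the ordered timesteps.
#'
#' @param index_table Output of [build_index_table()].
#' @param timesteps Ordered timestep labels; defaults to the order of first
#'   appearance in the table.
#' @param t Optional numeric regressor (e.g. calendar mid-years); default
#'   ordinal 0..T-1.
#' @return Data frame municipality_id, ncp, current_budget, b_coeff, r_coeff.
#' @export
build_trend_table <- function(index_table,
                              timesteps = unique(index_table$timestep),
                              t = NULL) {
  Tn <- length(timesteps)
  if (is.null(t)) t <- seq_len(Tn) - 1
  groups <- split(index_table,
                  list(index_table$ncp, index_table$municipality_id),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    ord <- match(timesteps, g$timestep)
    if (anyNA(ord))
      stop(sprintf("municipality %s, NCP %s: missing timestep(s) %s",
                   g$municipality_id[1], g$ncp[1],
                   paste(timesteps[is.na(ord)], collapse = ", ")),
           call. = FALSE)
    g <- g[ord, ]
    data.frame(municipality_id = g$municipality_id[1],
               ncp = g$ncp[1],
               current_budget = g$budget[Tn],
               b_coeff = trend_slope(g$budget, t),
               r_coeff = trend_slope(g$ratio, t))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$municipality_id, match(out$ncp, ncp_codes())), ]
  rownames(out) <- NULL
  out
}

#' Stability label from the sign pattern of the two trend coefficients
#'
#' A municipality-NCP trend is `stable_improving` when both coefficients
#' exceed +eps, `stable_declining` when both fall below -eps, `mixed` when
#' they disagree in sign beyond eps, and `neutral` when both lie within
#' the eps band.
#'
#' @param b_coeff,r_coeff Trend coefficients (vectors recycle).
#' @param eps Half-width of the neutral band (default 1e-6).
#' @return Factor with levels stable_improving, stable_declining, mixed,
#'   neutral.
#' @export
classify_quadrant <- function(b_coeff, r_coeff, eps = 1e-6) {
  sb <- ifelse(b_coeff > eps, 1L, ifelse(b_coeff < -eps, -1L, 0L))
  sr <- ifelse(r_coeff > eps, 1L, ifelse(r_coeff < -eps, -1L, 0L))
  lab <- ifelse(sb == 1L & sr == 1L, "stable_improving",
         ifelse(sb == -1L & sr == -1L, "stable_declining",
         ifelse(sb == 0L & sr == 0L, "neutral", "mixed")))
  factor(lab, levels = c("stable_improving", "stable_declining",
                         "mixed", "neutral"))
}

#' Sign-preserving cube-root transform for plotting exports
#'
#' `sign(x) * |x|^(1/3)`; spreads small coefficient values for bubble-plot
#' axes. Used only for exported plot data, never in clustering.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @examples
#' cube_root_transform(c(-0.008, 0, 1))
#' @export
cube_root_transform <- function(x) {
  sign(x) * abs(x)^(1 / 3)
}

#' Plot-ready bubble data per NCP
#'
#' Cube-root transformed coefficients plus the current budget's magnitude
#' and sign, matching the conventional budget/ratio trend bubble plots.
#'
#' @param trend_table Output of [build_trend_table()].
#' @return Data frame with municipality_id, ncp, r_coeff_cbrt, b_coeff_cbrt,
#'   budget_magnitude, budget_sign.
#' @export
trend_plot_data <- function(trend_table) {
  data.frame(
    municipality_id = trend_table$municipality_id,
    ncp = trend_table$ncp,
    r_coeff_cbrt = cube_root_transform(trend_table$r_coeff),
    b_coeff_cbrt = cube_root_transform(trend_table$b_coeff),
    budget_magnitude = abs(trend_table$current_budget),
    budget_sign = ifelse(trend_table$current_budget >= 0, "positive", "negative")
  )
}
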