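# Moving-window kernel machinery shared by the pollination, habitat-
# degradation and recreation indicators. Distances are Euclidean between
# pixel centers, in projected meters; kernels are truncated at a finite
# radius and normalized by the sum of weights of the neighbours that fall
# inside the grid, which makes a uniform field an exact fixed point of the
# smoother (no edge attenuation).

# Offsets (di, dj) and center-to-center distances (m) of all pixels within
# max_dist of a focal pixel. Always contains the (0, 0) offset.
kernel_offsets <- function(max_dist, res_m) {
  r <- floor(max_dist / res_m)
  g <- expand.grid(di = -r:r, dj = -r:r)
  d <- sqrt(g$di^2 + g$dj^2) * res_m
  keep <- d <= max_dist
  data.frame(di = g$di[keep], dj = g$dj[keep], dist = d[keep])
}

# Weighted local mean of `x` under precomputed offsets/weights: at each pixel,
# sum(w * x[neighbour]) / sum(w) over in-grid neighbours. Implemented as
# shift-and-add over offsets, O(n_offsets * n_pixels).
kernel_average <- function(x, offsets, weights) {
  nr <- nrow(x); nc <- ncol(x)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (k in seq_along(weights)) {
    w <- weights[k]
    if (w == 0) next
    di <- offsets$di[k]; dj <- offsets$dj[k]
    # focal rows/cols whose neighbour at this offset is inside the grid
    r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
    c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
    if (r1 > r2 || c1 > c2) next
    ti <- r1:r2
    tj <- c1:c2
    num[ti, tj] <- num[ti, tj] + w * x[ti + di, tj + dj]
    den[ti, tj] <- den[ti, tj] + w
  }
  num / den
}

# TRUE wherever any cell of `mask` lies within max_dist (inclusive).
within_distance <- function(mask, max_dist, res_m) {
  off <- kernel_offsets(max_dist, res_m)
  kernel_average(mask * 1, off, rep(1, nrow(off))) > 0
}

# Reference implementation used by the test-suite oracles: direct double loop
# over all pixel pairs. Quadratic; only viable on small grids.
kernel_average_bruteforce <- function(x, weight_fun, max_dist, res_m) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0
    for (p in seq_len(nr)) for (q in seq_len(nc)) {
      d <- sqrt((i - p)^2 + (j - q)^2) * res_m
      if (d <= max_dist) {
        w <- weight_fun(d)
        num <- num + w * x[p, q]
        den <- den + w
      }
    }
    out[i, j] <- num / den
  }
  out
}

# Distance-decay weight profiles for threat kernels. `linear` falls to 0 at
# max_dist; `exponential` falls to ~5% of its center value at max_dist.
decay_weights <- function(dist, type, max_dist) {
  switch(type,
    linear = pmax(0, 1 - dist / max_dist),
    exponential = exp(-2.99 * dist / max_dist),
    stop("unknown decay type: ", type, call. = FALSE)
  )
}
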