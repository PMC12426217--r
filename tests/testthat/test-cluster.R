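trend_fixture <- function() {
  reg <- tiny_region()
  tab <- compute_ncp_table(reg$stack, reg$econ)
  idx <- build_index_table(per_capita_transform(tab, zone_population(reg$stack)))
  list(reg = reg,
       tt = build_trend_table(idx, timesteps = reg$stack$timesteps))
}

test_that("the feature matrix has 3 columns per NCP and unit z-scores", {
  f <- trend_fixture()
  X <- assemble_features(f$tt)
  expect_equal(dim(X), c(10, 18))
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-12)
  # restricting the NCP set shrinks the matrix to 3 columns per kept NCP
  X1 <- assemble_features(f$tt[f$tt$ncp == "WAT", ])
  expect_equal(ncol(X1), 3)
})

test_that("missing municipality x NCP combinations are reported", {
  f <- trend_fixture()
  broken <- f$tt[!(f$tt$municipality_id == 3 & f$tt$ncp == "REC"), ]
  expect_error(assemble_features(broken), "3.*REC|REC.*3")
})

test_that("constant columns error by default and zero-fill on request", {
  tt <- data.frame(municipality_id = rep(1:4, each = 1), ncp = "POL",
                   current_budget = c(1, 2, 3, 4),
                   b_coeff = 0.5, r_coeff = c(0, 1, 0, 1))
  expect_error(assemble_features(tt), "constant")
  X <- assemble_features(tt, constant_col = "zero")
  expect_equal(unname(X[, "POL_b_coeff"]), rep(0, 4))
})

test_that("degenerate cuts behave: k = 1 and k = n", {
  f <- trend_fixture()
  X <- assemble_features(f$tt)
  expect_equal(unname(hierarchical_cluster(X, k = 1)$assignment), rep(1L, 10))
  singles <- hierarchical_cluster(X, k = 10)$assignment
  expect_equal(sort(unique(singles)), 1:10)
  expect_error(hierarchical_cluster(X, k = 11), "k must be")
})

test_that("two well-separated clouds are split perfectly", {
  set.seed(21)
  X <- rbind(matrix(rnorm(5 * 3, mean = 0, sd = 0.1), 5, 3),
             matrix(rnorm(5 * 3, mean = 10, sd = 0.1), 5, 3))
  rownames(X) <- 1:10
  res <- hierarchical_cluster(X, k = 2)
  # brute-force nearest-centroid oracle
  cent <- rbind(colMeans(X[1:5, ]), colMeans(X[6:10, ]))
  oracle <- apply(X, 1, function(p)
    which.min(c(sum((p - cent[1, ])^2), sum((p - cent[2, ])^2))))
  expect_equal(length(unique(res$assignment[oracle == 1])), 1)
  expect_equal(length(unique(res$assignment[oracle == 2])), 1)
})

test_that("silhouette selection favors the smallest k on a single blob", {
  set.seed(33)
  X <- matrix(rnorm(20 * 2), 20, 2)
  rownames(X) <- 1:20
  k <- select_k(X, k_range = 2:6)
  # independent silhouette evaluation over the same tree
  d <- dist(X)
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(2:6, function(k) {
    mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"])
  }, numeric(1))
  expect_equal(as.integer(k), (2:6)[which.max(sil)])
})

test_that("a singleton k_range is forced and an empty one errors", {
  f <- trend_fixture()
  X <- assemble_features(f$tt)
  expect_equal(as.integer(select_k(X, k_range = 3)), 3)
  expect_error(select_k(X, k_range = integer()), "empty")
})

test_that("cluster ids are canonical under row permutation", {
  f <- trend_fixture()
  X <- assemble_features(f$tt)
  res1 <- hierarchical_cluster(X, k = 3)
  set.seed(4)
  Xp <- X[sample(nrow(X)), ]
  res2 <- hierarchical_cluster(Xp, k = 3)
  ids <- rownames(X)
  expect_equal(res1$assignment[ids], res2$assignment[ids])
})

test_that("ward merge heights are non-decreasing", {
  f <- trend_fixture()
  X <- assemble_features(f$tt)
  hc <- hierarchical_cluster(X, k = 2)$tree
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("cluster profiles are size-weighted means of member rows", {
  f <- trend_fixture()
  X <- assemble_features(f$tt, standardize = FALSE)
  res <- hierarchical_cluster(assemble_features(f$tt), k = 3)
  prof <- profile_clusters(res, f$tt, f$reg$stack)
  for (k in sort(unique(res$assignment))) {
    members <- names(res$assignment)[res$assignment == k]
    expect_equal(unname(prof$profiles[as.character(k), ]),
                 unname(colMeans(X[members, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  # single-member cluster profile equals that municipality's row
  singles <- hierarchical_cluster(assemble_features(f$tt), k = 10)
  prof1 <- profile_clusters(singles, f$tt)
  m <- names(singles$assignment)[singles$assignment == 5]
  expect_equal(unname(prof1$profiles["5", ]), unname(X[m, ]), tolerance = 1e-12)
  # composition rows are probability vectors
  expect_equal(unname(rowSums(prof$composition)), rep(1, 3), tolerance = 1e-9)
  # signs summarize the profile matrix
  expect_true(all(prof$signs %in% c("+", "-", "0")))
})

test_that("the planted urban archetype has the highest settlement share", {
  reg <- tiny_region(seed = 12, n_municipalities = 12, grid_shape = c(60, 60),
                     noise_sd = 0.2)
  tab <- compute_ncp_table(reg$stack, reg$econ)
  idx <- build_index_table(per_capita_transform(tab, zone_population(reg$stack)))
  tt <- build_trend_table(idx, timesteps = reg$stack$timesteps)
  res <- hierarchical_cluster(assemble_features(tt), k = 4)
  prof <- profile_clusters(res, tt, reg$stack)
  # the cluster holding most urban-archetype municipalities leads in settlement
  urban_munis <- names(reg$labels)[reg$labels == 1]
  urban_cluster <- names(which.max(table(res$assignment[urban_munis])))
  expect_equal(rownames(prof$composition)[which.max(prof$composition[, "settlement"])],
               urban_cluster)
})
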