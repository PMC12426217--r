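# Spatiotemporal archetype detection: the 18-column feature matrix (current
# budget, budget coefficient, ratio coefficient for each of the six NCPs),
# agglomerative hierarchical clustering with Ward linkage on z-scored
# features, a silhouette-based stand-in for dendrogram inspection when
# choosing k, and per-cluster profiling.

#' Assemble the municipality x feature matrix for clustering
#'
#' One row per municipality, three columns per NCP
#' (`<NCP>_current_budget`, `<NCP>_b_coeff`, `<NCP>_r_coeff`), z-score
#' standardized by default; the per-column means and standard deviations are
#' stored in `attr(, "scaling")` for inversion.
#'
#' @param trend_table Output of [build_trend_table()].
#' @param standardize Z-score the columns (default TRUE).
#' @param constant_col One of "error" (default) or "zero": what to do with a
#'   zero-variance column under standardization.
#' @return Numeric matrix with municipality ids as row names.
#' @export
assemble_features <- function(trend_table, standardize = TRUE,
                              constant_col = c("error", "zero")) {
  constant_col <- match.arg(constant_col)
  munis <- sort(unique(trend_table$municipality_id))
  ncps <- intersect(ncp_codes(), unique(trend_table$ncp))
  vars <- c("current_budget", "b_coeff", "r_coeff")
  cols <- as.vector(t(outer(ncps, vars, paste, sep = "_")))
  X <- matrix(NA_real_, length(munis), length(cols),
              dimnames = list(munis, cols))
  key <- paste(trend_table$municipality_id, trend_table$ncp)
  for (code in ncps) {
    idx <- match(paste(munis, code), key)
    if (anyNA(idx))
      stop("municipality ", paste(munis[is.na(idx)], collapse = ", "),
           " missing NCP ", code, call. = FALSE)
    for (v in vars)
      X[, paste(code, v, sep = "_")] <- trend_table[[v]][idx]
  }
  if (anyNA(X)) stop("missing values in feature matrix", call. = FALSE)
  scaling <- data.frame(column = cols,
                        mean = colMeans(X),
                        sd = apply(X, 2, stats::sd))
  if (standardize) {
    zero <- scaling$sd == 0
    if (any(zero)) {
      if (constant_col == "error")
        stop("constant feature column(s): ",
             paste(cols[zero], collapse = ", "), call. = FALSE)
      scaling$sd[zero] <- 1   # zero-fill: column becomes all 0
    }
    X <- sweep(sweep(X, 2, scaling$mean, "-"), 2, scaling$sd, "/")
  }
  attr(X, "scaling") <- scaling
  attr(X, "standardized") <- standardize
  X
}

# canonical cluster ids: descending size, ties by lowest member id
canonicalize_clusters <- function(assignment) {
  ids <- sort(unique(assignment))
  size <- vapply(ids, function(i) sum(assignment == i), integer(1))
  lowest <- vapply(ids, function(i) min(as.integer(names(assignment)[assignment == i])),
                   integer(1))
  new_order <- ids[order(-size, lowest)]
  out <- match(assignment, new_order)
  names(out) <- names(assignment)
  out
}

#' Hierarchical clustering of the feature matrix
#'
#' Euclidean distance and agglomerative clustering with Ward (ward.D2),
#' average or complete linkage; the tree is cut into `k` groups and cluster
#' ids are relabeled canonically (descending size, ties by lowest member
#' id) so outputs are stable under row permutations.
#'
#' @param features Matrix from [assemble_features()].
#' @param k Number of clusters (1..nrow).
#' @param linkage One of "ward", "average", "complete".
#' @return List of class `ncp_clusters`: `assignment` (named integer
#'   vector), `tree` (the [stats::hclust] object), `k`, `linkage`.
#' @export
hierarchical_cluster <- function(features, k, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(features)
  if (k < 1 || k > n)
    stop("k must be in 1..", n, call. = FALSE)
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  # order rows by id so distance ties resolve identically for any input order
  features <- features[order(as.integer(rownames(features))), , drop = FALSE]
  hc <- stats::hclust(stats::dist(features, method = "euclidean"), method = method)
  assignment <- stats::cutree(hc, k = k)
  names(assignment) <- rownames(features)
  structure(list(assignment = canonicalize_clusters(assignment),
                 tree = hc, k = as.integer(k), linkage = linkage),
            class = "ncp_clusters")
}

#' @export
print.ncp_clusters <- function(x, ...) {
  cat(sprintf("Hierarchical NCP clustering (%s linkage): %d municipalities, k = %d\n",
              x$linkage, length(x$assignment), x$k))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Choose the number of clusters
#'
#' A reproducible stand-in for visual dendrogram inspection: either maximize
#' the mean silhouette width over `k_range` (default) or pick the k at the
#' largest relative gap between successive merge heights. Ties go to the
#' smaller k.
#'
#' @param features Matrix from [assemble_features()].
#' @param k_range Candidate cluster counts (default 2:8).
#' @param method "silhouette" or "gap".
#' @param linkage Linkage passed to [hierarchical_cluster()].
#' @return The selected k, with the per-k criterion values in
#'   `attr(, "criterion")`.
#' @export
select_k <- function(features, k_range = 2:8,
                     method = c("silhouette", "gap"),
                     linkage = "ward") {
  method <- match.arg(method)
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 1L) return(k_range)
  n <- nrow(features)
  k_range <- k_range[k_range >= 1 & k_range <= n]
  d <- stats::dist(features, method = "euclidean")
  meth <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  hc <- stats::hclust(d, method = meth)
  if (method == "silhouette") {
    crit <- vapply(k_range, function(k) {
      if (k < 2 || k >= n) return(-Inf)
      mean(cluster::silhouette(stats::cutree(hc, k = k), d)[, "sil_width"])
    }, numeric(1))
  } else {
    heights <- rev(hc$height)          # heights[k-1]: merge taking k -> k-1
    crit <- vapply(k_range, function(k) {
      if (k < 2 || k > length(heights)) return(-Inf)
      below <- if (k <= length(heights) - 1) heights[k] else heights[k - 1] * .Machine$double.eps
      (heights[k - 1] - below) / max(below, .Machine$double.eps)
    }, numeric(1))
  }
  k <- k_range[which.max(crit)]        # which.max takes the first (smallest) tie
  attr(k, "criterion") <- stats::setNames(crit, k_range)
  k
}

#' Profile clusters: mean trends, land-cover composition, sign summary
#'
#' Per-cluster means of the unstandardized 18 features (the archetype
#' profile), per-cluster land-cover class shares at the chosen timestep, and
#' a machine-readable sign summary ("+", "-", "0") of each profile entry for
#' narrative generation.
#'
#' @param result An `ncp_clusters` object.
#' @param trend_table The trend table the features came from.
#' @param stack Optional `landscape_stack` for land-cover composition.
#' @param t Timestep index for the composition (default: last).
#' @param eps Neutral band for the sign summary.
#' @return List with `profiles` (cluster x feature matrix, raw scale),
#'   `composition` (cluster x class share matrix or NULL), `signs`
#'   (character matrix), `sizes` (cluster sizes).
#' @export
profile_clusters <- function(result, trend_table, stack = NULL, t = NULL,
                             eps = 1e-6) {
  X <- assemble_features(trend_table, standardize = FALSE)
  X <- X[names(result$assignment), , drop = FALSE]
  ks <- sort(unique(result$assignment))
  profiles <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[result$assignment == k, , drop = FALSE])))
  rownames(profiles) <- ks
  signs <- ifelse(profiles > eps, "+", ifelse(profiles < -eps, "-", "0"))
  composition <- NULL
  if (!is.null(stack)) {
    if (is.null(t)) t <- length(stack$timesteps)
    shares <- zone_class_shares(stack, t)
    zone_px <- table(factor(as.vector(stack$zones), levels = stack$zone_ids))
    composition <- do.call(rbind, lapply(ks, function(k) {
      ids <- as.integer(names(result$assignment)[result$assignment == k])
      w <- as.numeric(zone_px[as.character(ids)])
      colSums(shares[as.character(ids), , drop = FALSE] * w) / sum(w)
    }))
    rownames(composition) <- ks
  }
  sizes <- vapply(ks, function(k) sum(result$assignment == k), integer(1))
  list(profiles = profiles, composition = composition,
       signs = signs, sizes = stats::setNames(sizes, ks))
}
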