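# Cluster formation on z-scored phenotype vectors: k-means with k-means++
# initialization under squared-Euclidean ("sed") or cosine ("cd") metric, and
# DBSCAN. Reference phenotypes (raw-space centroids zeta) are per-dimension
# medians of the raw vectors assigned to each cluster.

#' Fit / apply z-score normalization
#'
#' Normalizes each phenotype dimension to mean 0 and sample standard
#' deviation 1 (denominator n - 1), so that no dimension dominates the
#' distance computation through its scale.
#'
#' @param X Numeric matrix, one row per phenotype vector.
#' @return `zscore_fit`: a `normalization_model` with per-dimension `mean`
#'   and `sd`. `zscore_apply`: the z-scored matrix.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 vectors to fit z-scores")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  zero <- which(sdev == 0 | !is.finite(sdev))
  if (length(zero)) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-spread dimension(s): ", paste(nm, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev), class = "normalization_model")
}

#' @rdname zscore_fit
#' @param model A `normalization_model` from `zscore_fit`.
#' @export
zscore_apply <- function(model, X) {
  X <- as.matrix(X)
  stopifnot(inherits(model, "normalization_model"),
            ncol(X) == length(model$mean))
  sweep(sweep(X, 2, model$mean, "-"), 2, model$sd, "/")
}

#' Dissimilarity metrics between phenotype vectors
#'
#' `dist_sed` is the squared Euclidean distance; `dist_cd` the cosine
#' distance `1 - cos(theta)`, in \[0, 2\], which compares the direction of
#' two phenotype vectors irrespective of their magnitude.
#'
#' @param u,v Numeric vectors of equal length.
#' @export
dist_sed <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  sum((u - v)^2)
}

#' @rdname dist_sed
#' @export
dist_cd <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero-norm vector")
  1 - sum(u * v) / (nu * nv)
}

unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero-norm vector(s) at row(s): ",
                          paste(which(nrm == 0), collapse = ", "))
  X / nrm
}

# squared euclidean distances from each row of X to each row of C
cross_sed <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
}

# metric distances rows(X) -> rows(C); for cd both are assumed unit rows
cross_dist <- function(X, C, metric) {
  if (metric == "sed") pmax(cross_sed(X, C), 0) else pmax(1 - tcrossprod(X, C), 0)
}

# full pairwise dissimilarity matrix under a metric
pairwise_dist <- function(Z, metric) {
  if (metric == "sed") {
    as.matrix(stats::dist(Z))^2
  } else {
    D <- 1 - tcrossprod(unit_rows(Z))
    diag(D) <- 0
    pmax(D, 0)
  }
}

# k-means++ seeding: returns row indices of the chosen centers
kmeanspp_init <- function(X, k, metric) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- cross_dist(X, X[centers[1], , drop = FALSE], metric)[, 1]
    for (i in 2:k) {
      if (all(d2 == 0)) {
        centers[i] <- sample.int(n, 1)
      } else {
        centers[i] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, cross_dist(X, X[centers[i], , drop = FALSE], metric)[, 1])
    }
  }
  centers
}

kmeans_single <- function(X, k, metric, max_iter = 100) {
  n <- nrow(X)
  C <- X[kmeanspp_init(X, k, metric), , drop = FALSE]
  labels <- integer(n)
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    D <- cross_dist(X, C, metric)
    labels_new <- max.col(-D, ties.method = "first")
    obj <- sum(D[cbind(seq_len(n), labels_new)])
    # Lloyd iterations never increase the objective
    stopifnot(obj <= obj_prev + 1e-8 * max(1, abs(obj_prev)))
    # centroid update; empty clusters reseeded with the farthest point
    for (cl in seq_len(k)) {
      members <- which(labels_new == cl)
      if (!length(members)) {
        far <- which.max(D[cbind(seq_len(n), labels_new)])
        members <- far
        labels_new[far] <- cl
      }
      cm <- colMeans(X[members, , drop = FALSE])
      if (metric == "cd") {
        nm <- sqrt(sum(cm^2))
        cm <- if (nm > 0) cm / nm else X[members[1], ]
      }
      C[cl, ] <- cm
    }
    if (identical(labels_new, labels) && iter > 1) break
    labels <- labels_new
    obj_prev <- obj
  }
  D <- cross_dist(X, C, metric)
  labels <- max.col(-D, ties.method = "first")
  list(labels = labels, centroids = C,
       objective = sum(D[cbind(seq_len(n), labels)]), iterations = iter)
}

#' Per-cluster raw-space reference phenotypes (medians)
#'
#' The reference phenotype zeta of a cluster is the per-dimension median of
#' the raw (un-normalized) rate vectors assigned to it.
#'
#' @param labels Integer cluster labels (0 = noise, excluded).
#' @param raw Raw phenotype matrix matching `labels` row-for-row.
#' @return k x m matrix of medians, one row per cluster.
#' @export
raw_centroids <- function(labels, raw) {
  stopifnot(length(labels) == nrow(raw))
  ks <- sort(unique(labels[labels > 0]))
  out <- t(vapply(ks, function(cl) {
    apply(raw[labels == cl, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(raw))))
  rownames(out) <- paste0("CL", ks)
  colnames(out) <- colnames(raw)
  out
}

new_cluster_model <- function(method, metric, labels, z_centroids, raw, ids,
                              params, objective = NA_real_,
                              diagnostics = NULL) {
  structure(list(
    method = method, metric = metric,
    k = length(unique(labels[labels > 0])),
    labels = labels, ids = ids,
    z_centroids = z_centroids,
    raw_centroids = if (is.null(raw)) NULL else raw_centroids(labels, raw),
    objective = objective, params = params, diagnostics = diagnostics
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s (%s metric), k = %d, n = %d\n",
              x$method, x$metric, x$k, length(x$labels)))
  if (!is.na(x$objective)) cat("  objective:", format(x$objective), "\n")
  if (any(x$labels == 0)) cat("  noise points:", sum(x$labels == 0), "\n")
  invisible(x)
}

#' k-means clustering of z-scored phenotype vectors
#'
#' Lloyd iterations with k-means++ center initialization, repeated
#' `replicates` times; the replicate with the lowest total point-to-centroid
#' distance wins. Under the cosine metric the vectors are unit-normalized
#' and centroids are renormalized means of the assigned unit vectors
#' (spherical k-means). Deterministic for a given `seed`.
#'
#' @param Z z-scored phenotype matrix (rows = vectors).
#' @param k Number of clusters (`k <= nrow(Z)`).
#' @param metric `"cd"` (cosine) or `"sed"` (squared Euclidean).
#' @param replicates Number of k-means++ restarts.
#' @param seed Integer seed.
#' @param raw Optional raw phenotype matrix (same rows as `Z`) from which the
#'   median reference phenotypes are computed.
#' @param ids Optional data frame identifying each row (experiment, time).
#' @return A `cluster_model` with fields `labels`, `z_centroids`,
#'   `raw_centroids`, `objective` and `params`.
#' @export
kmeans_cluster <- function(Z, k, metric = c("cd", "sed"), replicates = 20,
                           seed = 1, raw = NULL, ids = NULL) {
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  stopifnot(k >= 1, k <= nrow(Z), replicates >= 1)
  X <- if (metric == "cd") unit_rows(Z) else Z
  best <- NULL
  withr_seed(seed, {
    for (r in seq_len(replicates)) {
      fit <- kmeans_single(X, k, metric)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  new_cluster_model("kmeans", metric, best$labels, best$centroids, raw, ids,
                    params = list(k = k, replicates = replicates, seed = seed,
                                  iterations = best$iterations),
                    objective = best$objective)
}

# evaluate expr with a temporarily-set RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Default DBSCAN minimum-neighbor count
#'
#' The common rule of thumb sets the minimum number of neighbors of a core
#' point to twice the dimensionality of the data (22 for the 11-dimensional
#' phenotype vectors used here).
#'
#' @param n_dims Number of phenotype dimensions.
#' @export
dbscan_default_npmin <- function(n_dims) 2L * as.integer(n_dims)

#' DBSCAN clustering of z-scored phenotype vectors
#'
#' Standard density-based clustering: points with at least `np_min`
#' neighbors within dissimilarity `eps` are core points; clusters are the
#' connected components of core points plus their border points, numbered in
#' discovery order; everything else is noise (label 0).
#'
#' @inheritParams kmeans_cluster
#' @param eps Neighborhood radius in the chosen dissimilarity.
#' @param np_min Minimum neighbors (the point itself counts); default
#'   `2 * ncol(Z)`.
#' @return A `cluster_model`; `diagnostics` holds `n_clusters`,
#'   `frac_clustered` (non-noise share of all points) and
#'   `frac_in_cluster1` (share of clustered points in cluster 1).
#' @export
dbscan_cluster <- function(Z, eps, np_min = NULL, metric = c("cd", "sed"),
                           raw = NULL, ids = NULL) {
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  stopifnot(eps > 0)
  if (is.null(np_min)) np_min <- dbscan_default_npmin(ncol(Z))
  stopifnot(np_min >= 1)
  D <- pairwise_dist(Z, metric)
  n <- nrow(Z)
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= np_min
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in neighbors[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  n_clustered <- sum(labels > 0)
  diagnostics <- list(
    n_clusters = cl,
    frac_clustered = n_clustered / n,
    frac_in_cluster1 = if (n_clustered) sum(labels == 1L) / n_clustered else NA_real_
  )
  zc <- if (cl > 0) {
    t(vapply(seq_len(cl), function(j) colMeans(Z[labels == j, , drop = FALSE]),
             numeric(ncol(Z))))
  } else matrix(numeric(0), 0, ncol(Z))
  new_cluster_model("dbscan", metric, labels, zc, raw, ids,
                    params = list(eps = eps, np_min = np_min),
                    diagnostics = diagnostics)
}
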