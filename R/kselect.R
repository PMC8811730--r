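# Choosing the number of clusters: silhouette and gap (SED or CD),
# Davies-Bouldin and Calinski-Harabasz (SED only), each scored over
# k = 1|2 .. k_max with a single k-means++ run per k; plus the DBSCAN
# epsilon sweep used to screen density parameters.

#' Mean silhouette width for a labeling under an arbitrary dissimilarity
#'
#' For each point, `a` is its mean dissimilarity to its own cluster and `b`
#' the smallest mean dissimilarity to any other cluster; the silhouette is
#' `(b - a) / max(a, b)` (0 for singleton clusters). Returns the mean over
#' all points.
#'
#' @param labels Integer cluster labels (>= 1).
#' @param D Square dissimilarity matrix.
#' @export
silhouette_score <- function(labels, D) {
  stopifnot(nrow(D) == length(labels), ncol(D) == length(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters")
  s <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- sum(D[i, own]) / (length(own) - 1)
    b <- min(vapply(ks[ks != labels[i]], function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

db_index <- function(labels, Z) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(cl) colMeans(Z[labels == cl, , drop = FALSE]),
                   numeric(ncol(Z))))
  scatter <- vapply(seq_along(ks), function(j) {
    mean(sqrt(rowSums(sweep(Z[labels == ks[j], , drop = FALSE], 2,
                            cent[j, ], "-")^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cent))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      (scatter[i] + scatter[j]) / dc[i, j]
    }, numeric(1)))
  }, numeric(1)))
}

ch_index <- function(labels, Z) {
  n <- nrow(Z); k <- length(unique(labels))
  gmean <- colMeans(Z)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    Xc <- Z[labels == cl, , drop = FALSE]
    cm <- colMeans(Xc)
    W <- W + sum(sweep(Xc, 2, cm, "-")^2)
    B <- B + nrow(Xc) * sum((cm - gmean)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of k-means clusters by a clustering criterion
#'
#' Runs one k-means++ clustering per candidate k (no replication during the
#' sweep) and scores it. Silhouette and the gap statistic accept either
#' metric; Davies-Bouldin and Calinski-Harabasz are defined for squared
#' Euclidean space only. The optimum is the argmax (silhouette,
#' Calinski-Harabasz), the argmin (Davies-Bouldin), or for the gap statistic
#' the smallest k with `Gap(k) >= Gap(k+1) - s(k+1)` (one-standard-error
#' rule, B reference draws from a uniform box over the data range).
#'
#' @inheritParams kmeans_cluster
#' @param criterion One of `"silhouette"`, `"gap"`, `"davies_bouldin"`,
#'   `"calinski_harabasz"`.
#' @param k_max Largest k tried (k starts at 2, or 1 for gap).
#' @param gap_B Number of uniform reference datasets for the gap statistic.
#' @return List with `table` (data frame of k, score) and `best_k`.
#' @export
evaluate_k <- function(Z, criterion = c("silhouette", "gap", "davies_bouldin",
                                        "calinski_harabasz"),
                       metric = c("cd", "sed"), k_max = 30, seed = 1,
                       gap_B = 50) {
  criterion <- match.arg(criterion)
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  if (criterion %in% c("davies_bouldin", "calinski_harabasz") && metric != "sed") {
    stop(criterion, " is only defined for the sed metric")
  }
  k_max <- min(k_max, nrow(Z) - 1)
  if (criterion == "gap") {
    return(evaluate_gap(Z, metric, k_max, seed, gap_B))
  }
  D <- if (criterion == "silhouette") pairwise_dist(Z, metric) else NULL
  ks <- 2:k_max
  scores <- vapply(ks, function(k) {
    fit <- kmeans_cluster(Z, k, metric = metric, replicates = 1,
                          seed = seed + k)
    switch(criterion,
           silhouette = silhouette_score(fit$labels, D),
           davies_bouldin = db_index(fit$labels, Z),
           calinski_harabasz = ch_index(fit$labels, Z))
  }, numeric(1))
  best <- if (criterion == "davies_bouldin") ks[which.min(scores)] else ks[which.max(scores)]
  list(criterion = criterion, metric = metric,
       table = data.frame(k = ks, score = scores), best_k = best)
}

evaluate_gap <- function(Z, metric, k_max, seed, B) {
  ks <- 1:k_max
  logW <- function(X, k, sd_) {
    if (k == 1) {
      X0 <- if (metric == "cd") unit_rows(X) else X
      cm <- colMeans(X0)
      if (metric == "cd") {
        nm <- sqrt(sum(cm^2))
        cm <- if (nm > 0) cm / nm else cm
        return(log(max(sum(1 - X0 %*% cm), .Machine$double.eps)))
      }
      return(log(max(sum(sweep(X0, 2, cm, "-")^2), .Machine$double.eps)))
    }
    fit <- kmeans_cluster(X, k, metric = metric, replicates = 1,
                          seed = sd_ + k)
    log(max(fit$objective, .Machine$double.eps))
  }
  obs <- vapply(ks, function(k) logW(Z, k, seed), numeric(1))
  lo <- apply(Z, 2, min); hi <- apply(Z, 2, max)
  ref <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      R <- vapply(seq_along(lo), function(j) stats::runif(nrow(Z), lo[j], hi[j]),
                  numeric(nrow(Z)))
      vapply(ks, function(k) logW(R, k, seed + 1000 * b), numeric(1))
    }, numeric(length(ks)))
  })
  gap <- rowMeans(ref) - obs
  s <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B)
  best <- NA_integer_
  for (i in seq_len(length(ks) - 1)) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) { best <- ks[i]; break }
  }
  if (is.na(best)) best <- ks[which.max(gap)]
  list(criterion = "gap", metric = metric,
       table = data.frame(k = ks, score = gap, se = s), best_k = best)
}

#' Screen DBSCAN neighborhood radii
#'
#' Runs [dbscan_cluster()] once per candidate `eps` and tabulates the
#' diagnostics used to judge density-based clusterings: number of clusters
#' found, fraction of points assigned to any cluster, and fraction of
#' assigned points sitting in the first cluster.
#'
#' @inheritParams dbscan_cluster
#' @param eps_grid Numeric vector of radii to try.
#' @return Data frame with one row per `eps`.
#' @export
sweep_dbscan <- function(Z, eps_grid, np_min = NULL, metric = c("cd", "sed")) {
  metric <- match.arg(metric)
  stopifnot(length(eps_grid) > 0)
  rows <- lapply(eps_grid, function(e) {
    fit <- dbscan_cluster(Z, eps = e, np_min = np_min, metric = metric)
    data.frame(eps = e,
               n_clusters = fit$diagnostics$n_clusters,
               frac_clustered = fit$diagnostics$frac_clustered,
               frac_in_cluster1 = fit$diagnostics$frac_in_cluster1)
  })
  do.call(rbind, rows)
}
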