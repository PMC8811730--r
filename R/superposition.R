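# Superposition decomposition: express a phenotype vector (or a whole time
# course) as a non-negative mixture of the reference-cluster centroids via
# NNLS, after per-dimension [0, 1] rescaling so that no dimension dominates
# the fit through its scale.

#' Rescale centroids and query vectors to \[0, 1\] per dimension
#'
#' For each dimension, the minimum and maximum are taken over the pooled set
#' of centroid values and query values (or over the centroids alone with
#' `scaling = "centroids"`, in which case queries may leave \[0, 1\]; they
#' are not clipped). The same affine map is applied to both. Dimensions
#' with no spread are dropped with a warning.
#'
#' @param centroids k x m matrix of raw reference phenotypes (rows =
#'   clusters).
#' @param queries n x m matrix (or single vector) of raw phenotype vectors.
#' @param scaling `"pooled"` (default) or `"centroids"`.
#' @return List with `A` (m' x k rescaled centroid matrix, one column per
#'   cluster), `queries` (n x m' rescaled queries), `dims` (kept dimension
#'   names), `lo`, `hi`.
#' @export
rescale_01 <- function(centroids, queries, scaling = c("pooled", "centroids")) {
  scaling <- match.arg(scaling)
  centroids <- as.matrix(centroids)
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1,
                                               dimnames = list(NULL, names(queries)))
  queries <- as.matrix(queries)
  stopifnot(ncol(centroids) == ncol(queries))
  pool <- if (scaling == "pooled") rbind(centroids, queries) else centroids
  lo <- apply(pool, 2, min); hi <- apply(pool, 2, max)
  keep <- hi > lo
  if (!any(keep)) stop("all dimensions are constant; nothing to rescale")
  if (!all(keep)) {
    warning("dropping zero-spread dimension(s): ",
            paste(colnames(centroids)[!keep], collapse = ", "))
  }
  sc <- function(M) {
    out <- sweep(sweep(M[, keep, drop = FALSE], 2, lo[keep], "-"),
                 2, (hi - lo)[keep], "/")
    colnames(out) <- colnames(centroids)[keep]
    out
  }
  list(A = t(sc(centroids)), queries = sc(queries),
       dims = colnames(centroids)[keep], lo = lo[keep], hi = hi[keep])
}

#' Non-negative least-squares decomposition of one phenotype vector
#'
#' Solves `min || A x - a ||^2` subject to `x >= 0` (Lawson-Hanson active
#' set) and renders the coefficients as cluster proportions summing to
#' 100 %. If every coefficient is zero the proportions are undefined
#' (`NA`) and the residual is the query itself.
#'
#' @param A m x k matrix of rescaled centroids (one column per cluster).
#' @param a Rescaled query vector of length m.
#' @return A `superposition_fit`: `coefficients` (k, >= 0), `proportions`
#'   (k, percent, `NA` if undefined), `residual` (m), `rss`.
#' @export
nnls_decompose <- function(A, a) {
  A <- as.matrix(A)
  a <- as.numeric(a)
  stopifnot(nrow(A) == length(a), ncol(A) >= 1)
  x <- pracma::lsqnonneg(A, a)$x
  x[x < 0] <- 0
  resid <- as.numeric(A %*% x - a)
  props <- if (sum(x) > 0) 100 * x / sum(x) else rep(NA_real_, length(x))
  structure(list(coefficients = x, proportions = props,
                 residual = resid, rss = sum(resid^2)),
            class = "superposition_fit")
}

#' @export
print.superposition_fit <- function(x, ...) {
  cat("<superposition_fit> RSS =", format(x$rss), "\n")
  top <- order(x$proportions, decreasing = TRUE)
  top <- top[seq_len(min(3, length(top)))]
  cat("  top proportions:",
      paste(sprintf("CL%d %.1f%%", top, x$proportions[top]), collapse = ", "),
      "\n")
  invisible(x)
}

# Gaussian-weighted moving average, centered window of `window` points,
# sigma = (window - 1) / 5 in index units; edge and NA handling by weight
# renormalization over the available points.
gaussian_smooth <- function(y, window = 5) {
  stopifnot(window >= 1)
  if (window == 1) return(y)
  half <- (window - 1) %/% 2
  sigma <- (window - 1) / 5
  w0 <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= n
    idx <- idx[ok]; w <- w0[ok]
    use <- !is.na(y[idx])
    if (!any(use)) next
    out[i] <- sum(w[use] * y[idx[use]]) / sum(w[use])
  }
  out
}

#' Decompose a phenotype time course into cluster proportions
#'
#' Runs the \[0, 1\] rescaling and NNLS decomposition at every time point of
#' one experiment's rate vectors, then smooths each cluster's proportion
#' trace with a Gaussian-weighted moving average over a centered window
#' (default five vectors) and renormalizes the smoothed proportions to sum
#' to 100 %.
#'
#' @param rates `rate_table` of a single experiment, time-ordered.
#' @param model Fitted `cluster_model` with `raw_centroids`.
#' @param smooth_window Centered window length (1 disables smoothing).
#' @param scaling Passed to [rescale_01()].
#' @return A `timecourse_decomposition`: data frame `proportions`
#'   (`time_h`, `rss`, `pct_CL*`, smoothed), `proportions_raw`
#'   (unsmoothed), and the per-point `fits`.
#' @export
decompose_timecourse <- function(rates, model, smooth_window = 5,
                                 scaling = c("pooled", "centroids")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(model, "cluster_model"), !is.null(model$raw_centroids))
  if (length(unique(rates$experiment_id)) > 1) {
    stop("decompose_timecourse expects a single experiment")
  }
  if (nrow(rates) < 1) stop("no rate vectors to decompose")
  rates <- rates[order(rates$time_h), , drop = FALSE]
  Q <- rate_matrix(rates)
  cent <- model$raw_centroids[, colnames(Q), drop = FALSE]
  k <- nrow(cent)
  fits <- lapply(seq_len(nrow(Q)), function(i) {
    rs <- rescale_01(cent, Q[i, , drop = FALSE], scaling = scaling)
    nnls_decompose(rs$A, rs$queries[1, ])
  })
  prop_raw <- t(vapply(fits, function(f) f$proportions, numeric(k)))
  colnames(prop_raw) <- paste0("pct_", rownames(cent))
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  time_h <- attr(Q, "ids")$time_h
  smoothed <- apply(prop_raw, 2, gaussian_smooth, window = smooth_window)
  smoothed <- matrix(smoothed, ncol = k,
                     dimnames = list(NULL, colnames(prop_raw)))
  tot <- rowSums(smoothed)
  ok <- !is.na(tot) & tot > 0
  smoothed[ok, ] <- 100 * smoothed[ok, , drop = FALSE] / tot[ok]
  structure(list(
    proportions = data.frame(time_h = time_h, rss = rss, smoothed,
                             check.names = FALSE),
    proportions_raw = data.frame(time_h = time_h, rss = rss, prop_raw,
                                 check.names = FALSE),
    fits = fits, smooth_window = smooth_window, scaling = scaling
  ), class = "timecourse_decomposition")
}

#' @export
print.timecourse_decomposition <- function(x, ...) {
  cat(sprintf("<timecourse_decomposition> %d time points, %d clusters, window %d\n",
              nrow(x$proportions), length(x$fits[[1]]$coefficients),
              x$smooth_window))
  invisible(x)
}
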