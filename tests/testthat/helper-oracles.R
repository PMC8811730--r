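# Independent oracles used to cross-check the package implementations.
# Each is written directly from the defining algorithm or formula and shares
# no code with the package.

# Fritsch-Carlson shape-preserving Hermite interpolation (MATLAB pchip
# derivative rule), written from the published algorithm.
oracle_pchip <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  del <- diff(y) / h
  d <- numeric(n)
  for (k in 2:(n - 1)) {
    if (del[k - 1] * del[k] > 0) {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / del[k - 1] + w2 / del[k])
    } else d[k] <- 0
  }
  endslope <- function(h1, h2, del1, del2) {
    dd <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
    if (sign(dd) != sign(del1)) dd <- 0
    else if (sign(del1) != sign(del2) && abs(dd) > 3 * abs(del1)) dd <- 3 * del1
    dd
  }
  d[1] <- endslope(h[1], h[2], del[1], del[2])
  d[n] <- endslope(h[n - 1], h[n - 2], del[n - 1], del[n - 2])
  vapply(xq, function(q) {
    k <- max(1, min(n - 1, findInterval(q, x)))
    t <- (q - x[k]) / h[k]
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    h00 * y[k] + h10 * h[k] * d[k] + h01 * y[k + 1] + h11 * h[k] * d[k + 1]
  }, numeric(1))
}

# exhaustive best 2-partition objective for squared-Euclidean k-means
oracle_best_bipartition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- c(0, as.integer(intToBits(code))[1:(n - 1)])
    obj <- 0
    for (g in 0:1) {
      M <- X[grp == g, , drop = FALSE]
      obj <- obj + sum(sweep(M, 2, colMeans(M), "-")^2)
    }
    best <- min(best, obj)
  }
  best
}

# DBSCAN from the definition: connected components of the eps-graph over
# core points, border points joining the earliest-numbered adjacent cluster
oracle_dbscan <- function(D, eps, np_min) {
  n <- nrow(D)
  adj <- D <= eps
  core <- rowSums(adj) >= np_min
  labels <- rep(0L, n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] > 0) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & !seq_len(n) %in% comp &
                      colSums(adj[comp, , drop = FALSE]) > 0)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  for (i in which(!core)) {
    nb <- labels[which(adj[i, ] & core)]
    if (length(nb)) labels[i] <- min(nb)
  }
  labels
}

# ordinary least squares through the normal equations
oracle_ls <- function(A, b) as.numeric(solve(crossprod(A), crossprod(A, b)))

# isolated Gaussian blobs in m dimensions, for separable clustering cases
make_blobs <- function(n_per, centers, sd = 0.05) {
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
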