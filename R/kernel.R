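## Kernel k-means for categorical data: an exponential Hamming-distance
## kernel over parent variables, and kernelised Lloyd iterations using the
## kernel-distance identity
##   d^2(x, C_j) = K(x,x) - 2 mean_{y in j} K(x,y) + mean_{y,z in j} K(y,z).

#' Hamming-distance kernel for one-hot categorical data
#'
#' `K(x, y) = exp(-gamma * d_H(x, y))` where `d_H` counts the parent
#' variables on which two patients take different categories. The Hamming
#' distance is conditionally negative definite, so this kernel is positive
#' semidefinite; it is symmetric with unit diagonal. For full indicator
#' rows, `d_H(x, y) = Q - <x, y>` with Q the number of parent variables, so
#' the matrix is computed with one cross-product.
#'
#' @param x a `feature_matrix` (expanded internally) or an indicator matrix
#'   whose one-hot groups each sum to 1 per row.
#' @param gamma positive kernel bandwidth; default `1 / Q` so that the
#'   exponent is the fraction of disagreeing variables.
#' @return n x n kernel matrix.
#' @export
hamming_kernel <- function(x, gamma = NULL) {
  if (inherits(x, "feature_matrix")) {
    ind <- as_indicator_matrix(x)
    z <- ind$z
    q <- length(unique(ind$parent))
  } else {
    z <- as.matrix(x)
    rs <- unique(rowSums(z))
    if (length(rs) != 1L)
      stop("rows must all sum to the number of parent variables",
           call. = FALSE)
    q <- rs
  }
  if (is.null(gamma)) gamma <- 1 / q
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be > 0", call. = FALSE)
  d <- q - tcrossprod(z)
  K <- exp(-gamma * d)
  dimnames(K) <- list(rownames(z), rownames(z))
  K
}

kernel_wss <- function(K, labels, k) {
  ## sum_j [ sum_{i in j} K_ii - (1/n_j) sum_{y,z in j} K_yz ]
  tot <- 0
  for (j in seq_len(k)) {
    idx <- which(labels == j)
    if (!length(idx)) next
    tot <- tot + sum(diag(K)[idx]) - sum(K[idx, idx]) / length(idx)
  }
  tot
}

kernel_lloyd <- function(K, k, init_exemplars, iter_max = 100) {
  n <- nrow(K)
  dK <- diag(K)
  ## initial assignment: nearest initial exemplar in kernel distance
  d0 <- outer(dK, dK[init_exemplars], `+`) - 2 * K[, init_exemplars,
                                                   drop = FALSE]
  labels <- max.col(-d0, ties.method = "first")
  trace_obj <- numeric(0)
  for (it in seq_len(iter_max)) {
    ## distances to current implicit centroids
    d2 <- matrix(0, n, k)
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (!length(idx)) {  # empty-cluster repair: farthest point re-seeds
        own <- vapply(seq_len(n), function(i) {
          jj <- labels[i]; ii <- which(labels == jj)
          dK[i] - 2 * mean(K[i, ii]) + mean(K[ii, ii])
        }, numeric(1))
        far <- which.max(own)
        labels[far] <- j
        idx <- far
      }
      mj <- mean(K[idx, idx])
      d2[, j] <- dK - 2 * rowMeans(K[, idx, drop = FALSE]) + mj
    }
    new_labels <- max.col(-d2, ties.method = "first")
    trace_obj <- c(trace_obj, kernel_wss(K, new_labels, k))
    if (all(new_labels == labels)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  list(labels = labels, objective = kernel_wss(K, labels, k),
       trace = trace_obj, iterations = it)
}

#' Kernel k-means with restarts
#'
#' Lloyd iterations in the feature space induced by a positive-semidefinite
#' kernel, using the kernel-distance identity; no explicit coordinates are
#' ever formed. Each restart is initialised from `k` distinct points drawn
#' at random (or from `init`); the restart with the lowest kernel
#' within-cluster sum of squares is returned. With a linear kernel
#' (`K = X X'`) the updates coincide exactly with plain k-means on `X` from
#' the same initial points. Ties in assignment go to the lowest cluster
#' index.
#'
#' @param K symmetric positive-semidefinite kernel matrix.
#' @param k number of clusters.
#' @param n_restarts number of random restarts. Default 100.
#' @param seed integer RNG seed.
#' @param init optional integer vector of `k` initial exemplar row indices;
#'   when given, a single run from that initialisation is performed.
#' @param iter_max maximum Lloyd iterations per restart.
#' @return A `cluster_solution` (method `"kernel_kmeans"`); `objective` is
#'   the kernel WSS.
#' @export
run_kernel_kmeans <- function(K, k, n_restarts = 100, seed = 1, init = NULL,
                              iter_max = 100) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("kernel matrix must be symmetric", call. = FALSE)
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)
  if (!is.null(init)) {
    stopifnot(length(init) == k, !anyDuplicated(init))
    best <- kernel_lloyd(K, k, as.integer(init), iter_max)
    restarts <- 1L
  } else {
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      ex <- sample.int(n, k)
      fit <- kernel_lloyd(K, k, ex, iter_max)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    restarts <- as.integer(n_restarts)
  }
  new_cluster_solution(
    "kernel_kmeans", best$labels, k, objective = best$objective,
    extras = list(iterations = best$iterations, trace = best$trace),
    seed = as.integer(seed), n_restarts = restarts
  )
}
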