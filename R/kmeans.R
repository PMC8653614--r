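## Plain k-means on MCA coordinates (Lloyd iterations, best of restarts)
## and the three-rule k-selection procedure (within-cluster sum of squares
## elbow, mean silhouette, BIC under the spherical-Gaussian reading of
## k-means).

new_cluster_solution <- function(method, labels, k, objective, extras = list(),
                                 seed = NA_integer_, n_restarts = NA_integer_,
                                 converged = TRUE) {
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L), all(labels <= k))
  if (length(unique(labels)) < k)
    warning(method, ": solution has empty cluster(s)")
  structure(
    list(method = method, labels = labels, k = as.integer(k),
         objective = objective, extras = extras,
         seed = seed, n_restarts = n_restarts, converged = converged),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution [%s]: k = %d, n = %d, objective = %s\n",
              x$method, x$k, length(x$labels), format(x$objective)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' K-means clustering with restarts
#'
#' Lloyd's algorithm on the MCA row coordinates, repeated `n_restarts` times
#' from random initial centres; the restart with the lowest total
#' within-cluster sum of squares is returned. Deterministic for a fixed
#' seed.
#'
#' @param coords numeric matrix, patients x components.
#' @param k number of clusters, `2 <= k <= n` (k = n gives zero WSS).
#' @param n_restarts number of random restarts. Default 100.
#' @param seed integer RNG seed.
#' @param iter_max maximum Lloyd iterations per restart.
#' @return A `cluster_solution` (method `"kmeans"`); `objective` is the
#'   total within-cluster sum of squares, `extras$centers` the centroids.
#' @export
run_kmeans <- function(coords, k, n_restarts = 100, seed = 1,
                       iter_max = 100) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coords must be finite", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of points", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- suppressWarnings(
    stats::kmeans(coords, centers = k, iter.max = iter_max,
                  nstart = n_restarts, algorithm = "Lloyd")
  )
  new_cluster_solution(
    "kmeans", fit$cluster, k, objective = fit$tot.withinss,
    extras = list(centers = fit$centers, size = fit$size),
    seed = as.integer(seed), n_restarts = as.integer(n_restarts)
  )
}

#' BIC of a k-means solution under the spherical-Gaussian model
#'
#' Interprets k-means as maximum likelihood for a mixture of spherical
#' Gaussians with a shared variance: `sigma^2 = WSS / (d (n - k))`,
#' `logL = sum_j n_j log(n_j / n) - n d / 2 log(2 pi sigma^2) - d (n - k)/2`,
#' and `BIC = -2 logL + p log n` with `p = k (d + 1)` free parameters (k
#' centroids in d dimensions plus mixing weights and the shared variance).
#' Lower is better.
#'
#' @param wss total within-cluster sum of squares.
#' @param sizes per-cluster sizes.
#' @param d dimensionality of the coordinates.
#' @return Numeric BIC value.
#' @export
kmeans_bic <- function(wss, sizes, d) {
  n <- sum(sizes)
  k <- length(sizes)
  if (n <= k) return(Inf)
  sigma2 <- max(wss / (d * (n - k)), .Machine$double.eps)
  logl <- sum(sizes * log(sizes / n)) -
    n * d / 2 * log(2 * pi * sigma2) - d * (n - k) / 2
  p <- k * (d + 1)
  -2 * logl + p * log(n)
}

second_difference_elbow <- function(y) {
  ## index (into y) of max curvature of a decreasing profile; interior only
  if (length(y) < 3) return(NA_integer_)
  i <- 2:(length(y) - 1)
  d2 <- y[i - 1] - 2 * y[i] + y[i + 1]
  i[which.max(d2)]
}

#' Select the number of k-means clusters
#'
#' Runs [run_kmeans()] for every k in `k_range` and applies three selection
#' rules: the elbow (maximum second difference) of the total within-cluster
#' sum of squares, the maximum mean silhouette, and the minimum BIC
#' ([kmeans_bic()]). The chosen k is the majority vote of the three rules,
#' with ties broken by the silhouette rule. All three curves are reported
#' for inspection.
#'
#' @param coords numeric matrix of MCA coordinates.
#' @param k_range candidate values of k. Default 2:14.
#' @param n_restarts restarts per k. Default 100.
#' @param seed integer RNG seed.
#' @return Object of class `k_selection`: data frame `curves` (k, wss,
#'   silhouette, bic), `chosen_k`, `rule` and the per-rule picks. A
#'   `no_structure` flag is set when the best mean silhouette is below 0.1.
#' @export
select_k <- function(coords, k_range = 2:14, n_restarts = 100, seed = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n-1]", call. = FALSE)
  if (nrow(unique(coords)) == 1L)
    stop("degenerate data: all points identical; no k > 1 is meaningful",
         call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  wss <- sil <- bic <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sol <- run_kmeans(coords, k, n_restarts, seed = seed + i - 1)
    wss[i] <- sol$objective
    sil[i] <- silhouette_score(d, sol$labels)$mean
    bic[i] <- kmeans_bic(sol$objective, tabulate(sol$labels, k), ncol(coords))
  }
  pick_wss <- if (length(k_range) >= 3)
    k_range[second_difference_elbow(wss)] else k_range[which.min(wss)]
  pick_sil <- k_range[which.max(sil)]
  pick_bic <- k_range[which.min(bic)]
  votes <- table(c(pick_wss, pick_sil, pick_bic))
  chosen <- if (max(votes) >= 2) {
    as.integer(names(votes)[which.max(votes)])
  } else {
    pick_sil
  }
  rule <- if (max(votes) >= 2) "majority" else "silhouette-tiebreak"
  structure(
    list(
      curves = data.frame(k = k_range, wss = wss, silhouette = sil,
                          bic = bic),
      chosen_k = chosen, rule = rule,
      picks = c(wss = pick_wss, silhouette = pick_sil, bic = pick_bic),
      ## Kaufman-Rousseeuw convention: mean silhouette below 0.25 indicates
      ## no substantial structure
      no_structure = max(sil) < 0.25
    ),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k selection over k =", paste(range(x$curves$k), collapse = "-"),
      "-> chosen k =", x$chosen_k, sprintf("(%s)\n", x$rule))
  cat("  picks: wss elbow", x$picks["wss"], "| silhouette",
      x$picks["silhouette"], "| BIC", x$picks["bic"], "\n")
  if (x$no_structure)
    cat("  warning: low silhouette throughout; little cluster structure\n")
  invisible(x)
}

#' @export
plot.k_selection <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  with(x$curves, {
    graphics::plot(k, wss, type = "b", main = "Total WSS", ...)
    graphics::plot(k, silhouette, type = "b", main = "Mean silhouette", ...)
    graphics::plot(k, bic, type = "b", main = "BIC", ...)
  })
  invisible(x)
}
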