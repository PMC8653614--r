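## Affinity propagation: exemplar-based clustering by damped
## responsibility/availability message passing over a pairwise similarity
## matrix (negative squared Euclidean distance on MCA coordinates), with a
## preference sweep and net-similarity elbow for model selection.

#' Similarity matrix for affinity propagation
#'
#' Negative squared Euclidean distances between rows of the coordinate
#' matrix; the diagonal is left at 0 and is overwritten by the preference
#' inside [run_affinity_propagation()].
#'
#' @param coords numeric matrix, patients x components.
#' @return n x n similarity matrix.
#' @export
negative_sqdist <- function(coords) {
  coords <- as.matrix(coords)
  -as.matrix(stats::dist(coords))^2
}

#' Affinity propagation clustering
#'
#' Standard message passing: responsibilities
#' `r(i,k) <- s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))` and availabilities
#' `a(i,k) <- min(0, r(k,k) + sum_{i' notin {i,k}} max(0, r(i',k)))`
#' (`a(k,k) <- sum_{i' != k} max(0, r(i',k))`), each update damped by
#' `damping`. Exemplars are points with `r(k,k) + a(k,k) > 0`; every other
#' point joins its most similar exemplar, and each cluster's exemplar is
#' refined to the member maximising total within-cluster similarity.
#' Convergence is declared when the exemplar set is unchanged for
#' `conv_iter` sweeps; otherwise the state at `max_iter` is returned with
#' `converged = FALSE`.
#'
#' @param similarity n x n similarity matrix (e.g. [negative_sqdist()]).
#' @param preference diagonal self-similarity controlling the number of
#'   exemplars; larger values give more clusters. Default: median of the
#'   off-diagonal similarities.
#' @param damping damping factor in `[0.5, 1)`. Default 0.9.
#' @param max_iter maximum sweeps. Default 1000.
#' @param conv_iter sweeps of unchanged exemplar set declaring convergence.
#' @return A `cluster_solution` (method `"affinity_propagation"`);
#'   `objective` is the net similarity (sum of similarities of points to
#'   their exemplars), `extras$exemplars` the exemplar row indices.
#' @export
run_affinity_propagation <- function(similarity, preference = NULL,
                                     damping = 0.9, max_iter = 1000,
                                     conv_iter = 50) {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (damping < 0.5 || damping >= 1)
    stop("damping must lie in [0.5, 1)", call. = FALSE)
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  ## tiny deterministic jitter removes degenerate ties (standard practice);
  ## the caller's RNG stream is left untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(20211208L)
  rng <- abs(range(S))
  S <- S + max(rng) * 1e-12 * matrix(stats::runif(n * n), n, n)

  R <- A <- matrix(0, n, n)
  last_ex <- NULL
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## responsibilities
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rmax <- matrix(mx1, n, n)
    Rmax[cbind(seq_len(n), w1)] <- mx2
    R <- damping * R + (1 - damping) * (S - Rmax)
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (length(ex) && stable >= conv_iter) {
      converged <- TRUE
      break
    }
  }
  ex <- last_ex
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))

  ## assignment and exemplar refinement
  assign_idx <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  assign_idx[ex] <- seq_along(ex)
  for (j in seq_along(ex)) {
    members <- which(assign_idx == j)
    if (length(members) > 1) {
      within <- colSums(S[members, members, drop = FALSE])
      ex[j] <- members[which.max(within)]
    }
  }
  ex <- sort(unique(ex))
  assign_idx <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  assign_idx[ex] <- match(ex, ex)

  Sraw <- as.matrix(similarity)
  diag(Sraw) <- 0
  net <- sum(Sraw[cbind(seq_len(n), ex[assign_idx])])
  new_cluster_solution(
    "affinity_propagation", assign_idx, length(ex), objective = net,
    extras = list(exemplars = ex, preference = preference,
                  iterations = it),
    converged = converged
  )
}

#' Preference sweep for affinity propagation
#'
#' Runs [run_affinity_propagation()] over a grid of preferences (default: a
#' grid spanning the minimum to the median off-diagonal similarity),
#' recording the number of clusters and net similarity of each run, and
#' picks the solution at the elbow (maximum second difference) of the
#' best-net-similarity-versus-K curve.
#'
#' @param similarity n x n similarity matrix.
#' @param preference_grid numeric vector of at least 5 preferences; `NULL`
#'   builds a default grid of `n_grid` points.
#' @param n_grid default grid size. Default 20.
#' @param ... passed to [run_affinity_propagation()].
#' @return Object of class `ap_sweep`: data frame `sweep` (preference, k,
#'   net_similarity, converged), `chosen`, the `cluster_solution` at the
#'   chosen preference, and `chosen_k`.
#' @export
sweep_preference <- function(similarity, preference_grid = NULL,
                             n_grid = 20, ...) {
  S <- as.matrix(similarity)
  off <- S[row(S) != col(S)]
  if (is.null(preference_grid))
    preference_grid <- seq(min(off), stats::median(off),
                           length.out = n_grid)
  if (length(preference_grid) < 5)
    stop("preference grid must have at least 5 points", call. = FALSE)
  sols <- lapply(preference_grid, function(p)
    run_affinity_propagation(S, preference = p, ...))
  sw <- data.frame(
    preference = preference_grid,
    k = vapply(sols, `[[`, integer(1), "k"),
    net_similarity = vapply(sols, `[[`, numeric(1), "objective"),
    converged = vapply(sols, `[[`, logical(1), "converged")
  )
  ## best net similarity per distinct K, ascending in K
  agg <- stats::aggregate(net_similarity ~ k, data = sw, FUN = max)
  agg <- agg[order(agg$k), ]
  if (nrow(agg) == 1L) {
    warning("all preferences gave the same number of clusters (k = ",
            agg$k[1], ")")
    chosen_k <- agg$k[1]
  } else if (nrow(agg) < 3L) {
    chosen_k <- agg$k[which.max(agg$net_similarity)]
  } else {
    i <- 2:(nrow(agg) - 1)
    d2 <- agg$net_similarity[i - 1] - 2 * agg$net_similarity[i] +
      agg$net_similarity[i + 1]
    ## net similarity increases and saturates with K; the elbow is the K
    ## after which gains collapse (most negative curvature)
    chosen_k <- agg$k[i[which.min(d2)]]
  }
  cand <- which(sw$k == chosen_k)
  best <- cand[which.max(sw$net_similarity[cand])]
  structure(
    list(sweep = sw, chosen = sols[[best]], chosen_k = as.integer(chosen_k),
         preference = preference_grid[best]),
    class = "ap_sweep"
  )
}

#' @export
print.ap_sweep <- function(x, ...) {
  cat("Affinity-propagation preference sweep:", nrow(x$sweep),
      "grid points, k in", paste(range(x$sweep$k), collapse = "-"),
      "-> chosen k =", x$chosen_k, "\n")
  invisible(x)
}
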