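## Evaluation framework: cluster structure (silhouette), label alignment
## under label switching, bootstrap stability (clusterwise Jaccard) and
## replicability in held-out data (decision-tree label concordance).

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean
#' dissimilarity of point i to its own cluster (excluding itself) and
#' `b(i)` the smallest mean dissimilarity to any other cluster. Points in
#' singleton clusters score 0. All values lie in [-1, 1].
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (or a `dist`).
#' @param labels integer cluster labels (>= 2 distinct clusters required).
#' @return List with `widths` (per point) and `mean`.
#' @export
silhouette_score <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  ## mean dissimilarity of each point to each cluster
  member <- outer(labels, ks, `==`) * 1           # n x K
  sums <- d %*% member                            # includes self (d_ii = 0)
  sizes <- colSums(member)
  own <- match(labels, ks)
  a_size <- sizes[own] - 1
  a <- ifelse(a_size > 0,
              (sums[cbind(seq_len(n), own)]) / a_size, NA_real_)
  means_other <- sweep(sums, 2, sizes, `/`)
  means_other[cbind(seq_len(n), own)] <- Inf
  b <- apply(means_other, 1, min)
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0  # a = b = 0 (coincident points): no preference
  list(widths = s, mean = mean(s))
}

## exact maximum-agreement assignment of candidate clusters to reference
## clusters: Held-Karp bitmask DP over the reference columns, O(k 2^k)
max_trace_assignment <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  k <- max(nr, nc)
  A <- matrix(0, k, k)
  A[seq_len(nr), seq_len(nc)] <- M
  full <- bitwShiftL(1L, k) - 1L
  dp <- rep(-Inf, full + 1L)
  choice <- matrix(NA_integer_, k, full + 1L)
  dp[1L] <- 0
  masks_by_count <- split(0:full, vapply(0:full, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0), numeric(1)))
  for (cnt in 0:(k - 1)) {
    row <- cnt + 1L
    for (m in masks_by_count[[as.character(cnt)]]) {
      base <- dp[m + 1L]
      if (!is.finite(base)) next
      for (j in seq_len(k)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(m, bit) != 0) next
        nm <- bitwOr(m, bit)
        val <- base + A[row, j]
        if (val > dp[nm + 1L]) {
          dp[nm + 1L] <- val
          choice[row, nm + 1L] <- j
        }
      }
    }
  }
  ## backtrack
  assign <- integer(k)
  m <- full
  for (row in k:1) {
    j <- choice[row, m + 1L]
    assign[row] <- j
    m <- bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  list(assignment = assign[seq_len(nr)], value = dp[full + 1L])
}

#' Align candidate cluster labels to reference labels
#'
#' Finds the one-to-one mapping of candidate clusters to reference clusters
#' maximising total agreement on the contingency table (exact assignment;
#' rectangular cases are padded, and candidate clusters left unmatched keep
#' fresh labels beyond the reference range). This makes agreement measures
#' well defined under label switching.
#'
#' @param reference integer reference labels.
#' @param candidate integer candidate labels over the same points.
#' @return List with `mapping` (named: candidate label -> aligned label),
#'   `aligned` (candidate labels after mapping), `agreement` (fraction of
#'   points whose aligned label equals the reference) and `table` (the
#'   aligned contingency table, reference x aligned).
#' @export
align_labels <- function(reference, candidate) {
  stopifnot(length(reference) == length(candidate))
  ref_lv <- sort(unique(reference))
  cand_lv <- sort(unique(candidate))
  M <- table(factor(candidate, levels = cand_lv),
             factor(reference, levels = ref_lv))
  fit <- max_trace_assignment(unclass(M))
  to <- fit$assignment
  mapping <- integer(length(cand_lv))
  fresh <- length(ref_lv)
  for (i in seq_along(cand_lv)) {
    if (to[i] <= length(ref_lv)) {
      mapping[i] <- ref_lv[to[i]]
    } else {
      fresh <- fresh + 1L
      mapping[i] <- fresh
    }
  }
  names(mapping) <- cand_lv
  aligned <- mapping[match(candidate, cand_lv)]
  list(
    mapping = mapping,
    aligned = unname(aligned),
    agreement = mean(aligned == reference),
    table = table(reference = reference, aligned = unname(aligned))
  )
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, used as the
#' parameter-recovery metric on planted synthetic data.
#'
#' @param a,b integer label vectors over the same points.
#' @return Numeric ARI.
#' @export
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Bootstrap stability of a clustering procedure
#'
#' Repeats the frozen clustering procedure on `n_bootstraps` resamples drawn
#' with replacement. For each original cluster the maximum Jaccard index
#' against any bootstrap cluster is computed on sets of unique original
#' indices present in the resample (clusterwise maximum matching, the
#' standard bootstrap-stability scheme); the per-bootstrap score is the mean
#' over original clusters, and the overall score the mean over bootstraps.
#' Scores of at least `threshold` (default 0.75) are conventionally
#' considered stable.
#'
#' @param data matrix/data frame consumed by `cluster_fun` (rows = points).
#' @param cluster_fun function `(data, seed) -> integer labels` with all
#'   hyperparameters (including k) frozen.
#' @param n_bootstraps number of bootstrap resamples. Default 100.
#' @param seed integer RNG seed.
#' @param threshold stability threshold on the overall mean Jaccard.
#' @param matching `"clusterwise"` (default: per original cluster, max over
#'   bootstrap clusters) or `"assignment"` (one-to-one assignment).
#' @return Object of class `stability_report`: `n_bootstraps`,
#'   `per_bootstrap_jaccard`, `overall_mean_jaccard`,
#'   `per_cluster_mean_jaccard`, `stable` and `threshold`.
#' @export
bootstrap_stability <- function(data, cluster_fun, n_bootstraps = 100,
                                seed = 1, threshold = 0.75,
                                matching = c("clusterwise", "assignment")) {
  matching <- match.arg(matching)
  if (!is.numeric(n_bootstraps) || n_bootstraps < 1)
    stop("n_bootstraps must be >= 1", call. = FALSE)
  data <- as.matrix(data)
  n <- nrow(data)
  base_labels <- cluster_fun(data, seed)
  ks <- sort(unique(base_labels))
  orig <- lapply(ks, function(j) which(base_labels == j))
  per_boot <- matrix(NA_real_, n_bootstraps, length(ks))
  set.seed(as.integer(seed))
  boot_seeds <- sample.int(.Machine$integer.max, n_bootstraps)
  for (b in seq_len(n_bootstraps)) {
    idx <- sample.int(n, n, replace = TRUE)
    lab_b <- cluster_fun(data[idx, , drop = FALSE], boot_seeds[b])
    present <- unique(idx)
    boot_sets <- lapply(sort(unique(lab_b)), function(j)
      unique(idx[lab_b == j]))
    J <- vapply(orig, function(A) {
      Ar <- intersect(A, present)
      vapply(boot_sets, function(B)
        length(intersect(Ar, B)) / max(length(union(Ar, B)), 1L),
        numeric(1))
    }, numeric(length(boot_sets)))
    J <- matrix(J, nrow = length(boot_sets))
    if (matching == "clusterwise") {
      per_boot[b, ] <- apply(J, 2, max)
    } else {
      fit <- max_trace_assignment(t(J))
      per_boot[b, ] <- vapply(seq_along(orig), function(i) {
        j <- fit$assignment[i]
        if (j <= nrow(J)) J[j, i] else 0
      }, numeric(1))
    }
  }
  per_bootstrap <- rowMeans(per_boot)
  structure(
    list(
      n_bootstraps = as.integer(n_bootstraps),
      per_bootstrap_jaccard = per_bootstrap,
      overall_mean_jaccard = mean(per_bootstrap),
      per_cluster_mean_jaccard = stats::setNames(colMeans(per_boot),
                                                 paste0("cluster", ks)),
      stable = mean(per_bootstrap) >= threshold,
      threshold = threshold,
      matching = matching
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "Bootstrap stability (%d resamples): mean Jaccard %.3f [%s at %.2f]\n",
    x$n_bootstraps, x$overall_mean_jaccard,
    if (x$stable) "stable" else "unstable", x$threshold))
  print(round(x$per_cluster_mean_jaccard, 3))
  invisible(x)
}

#' Replicability of a clustering in held-out data
#'
#' Implements the decision-tree replication protocol: a classification tree
#' is trained on the training features with cluster membership as the
#' outcome (an internal 80/20 split selects the cost-complexity pruning
#' parameter on held-out misclassification); the tree labels the test set
#' ("gold standard" labels); the clustering procedure is run independently
#' on the test set; and the aligned label agreement between the two is the
#' concordance.
#'
#' @param train_features data frame / matrix of training features.
#' @param train_labels integer cluster labels for the training rows.
#' @param test_features features for the held-out set (same columns).
#' @param cluster_fun function `(data, seed) -> integer labels`, frozen
#'   hyperparameters.
#' @param seed integer RNG seed (internal split and clustering).
#' @param val_fraction internal validation fraction for pruning.
#' @return Object of class `replicability_report`: `concordance`,
#'   `confusion` (gold x aligned cluster counts), `n_test`, `mapping` and
#'   the fitted `tree`.
#' @export
replicability <- function(train_features, train_labels, test_features,
                          cluster_fun, seed = 1, val_fraction = 0.2) {
  train_features <- as.data.frame(as.matrix(train_features))
  test_features <- as.data.frame(as.matrix(test_features))
  stopifnot(identical(names(train_features), names(test_features)))
  n <- nrow(train_features)
  k_train <- length(unique(train_labels))
  if (nrow(test_features) < k_train)
    warning("test set smaller than the number of training clusters")
  set.seed(as.integer(seed))
  val <- sample.int(n, max(1, round(val_fraction * n)))
  df <- train_features
  df$.cluster <- factor(train_labels)
  fit <- rpart::rpart(.cluster ~ ., data = df[-val, ], method = "class",
                      cp = 0, minsplit = 10)
  ## prune at the cp minimising held-out misclassification
  cps <- fit$cptable[, "CP"]
  val_err <- vapply(cps, function(cp) {
    pr <- stats::predict(rpart::prune(fit, cp = cp), df[val, ],
                         type = "class")
    mean(pr != df$.cluster[val])
  }, numeric(1))
  tree <- rpart::prune(fit, cp = cps[which.min(val_err)])

  gold <- as.integer(as.character(
    stats::predict(tree, test_features, type = "class")))
  test_labels <- cluster_fun(as.matrix(test_features), seed + 1L)
  al <- align_labels(gold, test_labels)
  structure(
    list(
      concordance = al$agreement,
      confusion = al$table,
      n_test = nrow(test_features),
      mapping = al$mapping,
      tree = tree
    ),
    class = "replicability_report"
  )
}

#' @export
print.replicability_report <- function(x, ...) {
  cat(sprintf("Replicability: %.1f%% concordance on %d held-out patients\n",
              100 * x$concordance, x$n_test))
  invisible(x)
}
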