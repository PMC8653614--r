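test_that("silhouette matches brute force to 1e-12 on small instances", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    x <- matrix(rnorm(n * 3), n)
    labels <- sample(1:4, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    d <- as.matrix(dist(x))
    mine <- silhouette_score(d, labels)
    expect_equal(mine$widths, brute_silhouette(d, labels),
                 tolerance = 1e-12)
    expect_equal(mine$mean, mean(brute_silhouette(d, labels)),
                 tolerance = 1e-12)
    expect_true(all(mine$widths >= -1 & mine$widths <= 1))
  }
})

test_that("silhouette agrees with the cluster package reference", {
  skip_if_not_installed("cluster")
  set.seed(52)
  x <- matrix(rnorm(80), 40)
  labels <- rep(1:2, each = 20)
  d <- dist(x)
  mine <- silhouette_score(as.matrix(d), labels)
  ref <- cluster::silhouette(labels, d)
  expect_equal(mine$widths, ref[, "sil_width"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("silhouette limits and degenerate cases behave as defined", {
  # two clusters, zero within-cluster spread -> mean silhouette 1
  x <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  d <- as.matrix(dist(x))
  expect_equal(silhouette_score(d, rep(1:2, each = 3))$mean, 1)
  # singleton cluster scores 0
  s <- silhouette_score(d, c(1, 1, 1, 2, 2, 3))
  expect_equal(s$widths[6], 0)
  expect_error(silhouette_score(d, rep(1, 6)), "single cluster")
})

test_that("random labels on structureless data score near zero", {
  set.seed(53)
  x <- matrix(rnorm(500 * 4), 500)
  labels <- sample(1:5, 500, replace = TRUE)
  s <- silhouette_score(as.matrix(dist(x)), labels)
  expect_lt(abs(s$mean), 0.1)
})

test_that("label alignment undoes permutations and handles mismatches", {
  ref <- c(1, 1, 2, 2, 3, 3)
  # swapped labels align perfectly
  cand <- c(3, 3, 1, 1, 2, 2)
  al <- align_labels(ref, cand)
  expect_equal(al$agreement, 1)
  expect_equal(al$aligned, ref)
  # one point moved: agreement (n-1)/n
  cand2 <- c(3, 3, 1, 2, 2, 2)
  expect_equal(align_labels(ref, cand2)$agreement, 5 / 6)
  # 3 reference vs 2 candidate clusters: best over all label maps
  ref3 <- c(1, 1, 2, 2, 3, 3)
  cand3 <- c(1, 1, 2, 2, 2, 2)
  brute <- max(vapply(list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1),
                           c(3, 2)), function(mp)
    mean(mp[cand3] == ref3), numeric(1)))
  expect_equal(align_labels(ref3, cand3)$agreement, brute)
  # extra candidate clusters get fresh labels, never stealing a match
  cand4 <- c(1, 4, 2, 2, 3, 3)
  al4 <- align_labels(ref, cand4)
  expect_equal(al4$agreement, 5 / 6)
})

test_that("evaluation metrics are invariant to cluster relabeling", {
  set.seed(54)
  x <- matrix(rnorm(60 * 2), 60)
  labels <- sample(1:3, 60, replace = TRUE)
  d <- as.matrix(dist(x))
  perm <- c(2, 3, 1)
  expect_equal(silhouette_score(d, perm[labels])$mean,
               silhouette_score(d, labels)$mean, tolerance = 1e-12)
  expect_equal(adjusted_rand(labels, perm[labels]), 1)
})

test_that("planted clusters are bootstrap-stable, noise is not", {
  blobs <- gaussian_blobs(40, rbind(c(0, 0), c(8, 0), c(4, 8)), sd = 0.5,
                          seed = 55)
  proc <- function(x, seed) run_kmeans(x, 3, n_restarts = 5,
                                       seed = seed)$labels
  st <- bootstrap_stability(blobs$x, proc, n_bootstraps = 30, seed = 55)
  expect_gte(st$overall_mean_jaccard, 0.95)
  expect_true(st$stable)
  expect_equal(st$overall_mean_jaccard, mean(st$per_bootstrap_jaccard),
               tolerance = 1e-12)
  expect_true(all(st$per_bootstrap_jaccard >= 0 &
                    st$per_bootstrap_jaccard <= 1))
  # pure noise forced into 5 clusters is unstable
  set.seed(56)
  noise <- matrix(rnorm(150 * 2), 150)
  proc5 <- function(x, seed) run_kmeans(x, 5, n_restarts = 5,
                                        seed = seed)$labels
  st0 <- bootstrap_stability(noise, proc5, n_bootstraps = 30, seed = 56)
  expect_lt(st0$overall_mean_jaccard, 0.75)
  expect_false(st0$stable)
  expect_error(bootstrap_stability(noise, proc5, n_bootstraps = 0), ">= 1")
})

test_that("stability reports are reproducible under a fixed seed", {
  blobs <- gaussian_blobs(30, rbind(c(0, 0), c(6, 0)), sd = 0.6, seed = 57)
  proc <- function(x, seed) run_kmeans(x, 2, n_restarts = 3,
                                       seed = seed)$labels
  a <- bootstrap_stability(blobs$x, proc, n_bootstraps = 10, seed = 3)
  b <- bootstrap_stability(blobs$x, proc, n_bootstraps = 10, seed = 3)
  expect_identical(a, b)
})

test_that("replicability is high for a replicable planted structure", {
  blobs_tr <- gaussian_blobs(60, rbind(c(0, 0), c(8, 0), c(4, 8)),
                             sd = 0.6, seed = 58)
  blobs_te <- gaussian_blobs(40, rbind(c(0, 0), c(8, 0), c(4, 8)),
                             sd = 0.6, seed = 59)
  proc <- function(x, seed) run_kmeans(x, 3, n_restarts = 5,
                                       seed = seed)$labels
  rep1 <- replicability(blobs_tr$x, blobs_tr$labels, blobs_te$x, proc,
                        seed = 58)
  expect_gte(rep1$concordance, 0.9)
  expect_lte(rep1$concordance, 1)
  expect_equal(sum(rep1$confusion), rep1$n_test)
  # concordance equals the trace of the aligned confusion table / n
  expect_equal(rep1$concordance,
               sum(diag(rep1$confusion[, intersect(colnames(rep1$confusion),
                                                   rownames(rep1$confusion)),
                                       drop = FALSE])) / rep1$n_test,
               tolerance = 1e-12)
})

test_that("random re-clustering gives baseline concordance", {
  set.seed(60)
  x_tr <- matrix(rnorm(200 * 3), 200)
  lab_tr <- sample(1:4, 200, replace = TRUE)
  x_te <- matrix(rnorm(150 * 3), 150)
  rand_proc <- function(x, seed) {
    set.seed(seed)
    sample(1:4, nrow(x), replace = TRUE)
  }
  reps <- vapply(1:10, function(s)
    suppressWarnings(replicability(x_tr, lab_tr, x_te, rand_proc,
                                   seed = s)$concordance), numeric(1))
  # permutation-null level: around the max gold-cluster share, far below 1
  expect_lt(mean(reps), 0.6)
  expect_gt(mean(reps), 0.15)
})
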