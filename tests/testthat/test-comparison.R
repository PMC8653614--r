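# small synthetic feature matrix with a planted high-depression cluster
planted_fm <- function(n = 1000, seed = 71) {
  set.seed(seed)
  cl <- rep(1:2, c(n / 4, 3 * n / 4))
  dep <- rbinom(n, 1, ifelse(cl == 1, 0.9, 0.20))
  mem <- rbinom(n, 1, 0.7)
  noise <- rbinom(n, 1, 0.3)
  fm <- tiny_feature_matrix(
    cbind(depression = dep, memory = mem, cancer = noise),
    parents = c("depression", "memory", "cancer"),
    roles = c("comorbidity", "symptom", "comorbidity")
  )
  list(fm = fm, labels = cl)
}

test_that("a planted high-depression cluster is characterised as such", {
  p <- planted_fm()
  ch <- characterize(p$fm, p$labels)
  tj <- ch$table[ch$table$cluster == 1 & ch$table$feature == "depression", ]
  expect_true(tj$significant)
  expect_equal(tj$direction, "higher")
  expect_gt(tj$cluster_prevalence, 0.8)
  # oracle: the same two-proportion test computed directly
  a <- sum(p$fm$x[p$labels == 1, "depression"])
  b <- sum(p$fm$x[p$labels == 2, "depression"])
  pref <- prop.test(c(a, b), c(sum(p$labels == 1), sum(p$labels == 2)))
  expect_equal(tj$p, pref$p.value, tolerance = 1e-12)
  # family size is exactly clusters x features
  expect_equal(ch$family_size, 2 * 3)
})

test_that("uniformly sampled clusters yield no significant features", {
  clean <- 0L
  n_rep <- 40
  for (s in 1:n_rep) {
    set.seed(900 + s)
    n <- 400
    x <- cbind(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.5),
               c = rbinom(n, 1, 0.7))
    fm <- tiny_feature_matrix(x, parents = colnames(x))
    labels <- sample(1:3, n, replace = TRUE)
    ch <- characterize(fm, labels)
    if (!any(ch$table$significant)) clean <- clean + 1L
  }
  expect_gte(clean / n_rep, 0.95)  # Bonferroni family-wise control
})

test_that("special naming rules for typical and non-typical AD apply", {
  set.seed(72)
  n <- 800
  cl <- rep(1:2, each = n / 2)
  # cluster 1: memory only elevated; cluster 2: all except memory elevated
  mk <- function(p1, p2) rbinom(n, 1, ifelse(cl == 1, p1, p2))
  x <- cbind(memory = mk(0.95, 0.3), confusion = mk(0.05, 0.8),
             neuropsychological = mk(0.1, 0.9), motor = mk(0.05, 0.7))
  fm <- tiny_feature_matrix(x, parents = colnames(x),
                            roles = rep("symptom", 4))
  ch <- characterize(fm, cl)
  expect_equal(unname(ch$names["1"]), "Typical AD")
  expect_equal(unname(ch$names["2"]), "Non-typical AD")
})

test_that("characterisation is invariant to feature column order", {
  p <- planted_fm(600, seed = 73)
  ch1 <- characterize(p$fm, p$labels)
  perm <- c(3, 1, 2)
  fm2 <- tiny_feature_matrix(p$fm$x[, perm], p$fm$meta$parent[perm],
                             p$fm$meta$role[perm])
  ch2 <- characterize(fm2, p$labels)
  t1 <- ch1$table[order(ch1$table$cluster, ch1$table$feature), ]
  t2 <- ch2$table[order(t2order <- ch2$table$cluster, ch2$table$feature), ]
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$significant, t2$significant)
})

test_that("tiny clusters are reported with a warning and no tests", {
  p <- planted_fm(100, seed = 74)
  labels <- p$labels
  labels[1:3] <- 3
  labels[labels == 1] <- 2
  expect_warning(ch <- characterize(p$fm, labels, min_size = 5),
                 "fewer than")
  expect_true(all(is.na(ch$table$p[ch$table$cluster == 3])))
})

test_that("flow tables account for every patient pair of methods", {
  set.seed(75)
  a <- new_solution <- list(method = "kmeans", labels = rep(1:3, 20), k = 3)
  class(a) <- "cluster_solution"
  b <- list(method = "lca", labels = c(rep(2, 20), rep(3, 20), rep(1, 20)),
            k = 3)
  class(b) <- "cluster_solution"
  fl <- cross_method_flow(list(m1 = a, m2 = b))
  expect_equal(sum(fl$flows$count), 60)
  expect_equal(dim(fl$labels), c(60, 2))
  # identical solutions give a diagonal table after alignment
  fl2 <- cross_method_flow(list(m1 = a, m2 = a))
  al <- align_labels(fl2$labels[, 1], fl2$labels[, 2])
  expect_equal(al$agreement, 1)
  bad <- list(method = "x", labels = 1:10, k = 10)
  class(bad) <- "cluster_solution"
  expect_error(cross_method_flow(list(a, bad)), "different patient sets")
})

test_that("independent random labelings agree only at baseline", {
  set.seed(76)
  n <- 3000
  a <- list(method = "m1", labels = sample(1:4, n, TRUE), k = 4)
  b <- list(method = "m2", labels = sample(1:4, n, TRUE), k = 4)
  class(a) <- class(b) <- "cluster_solution"
  al <- align_labels(a$labels, b$labels)
  expect_lt(al$agreement, 1 / 4 + 0.05)
})

test_that("the consistent cluster is recovered across methods", {
  # three methods, all recovering a planted class with known signature
  p <- planted_fm(900, seed = 77)
  ch <- characterize(p$fm, p$labels)
  sols <- lapply(c("kmeans", "affinity_propagation", "lca"), function(m) {
    s <- list(method = m, labels = p$labels, k = 2)
    class(s) <- "cluster_solution"
    s
  })
  names(sols) <- vapply(sols, `[[`, character(1), "method")
  chars <- stats::setNames(rep(list(ch), 3), names(sols))
  cc <- consistent_cluster(sols, chars, "depression")
  expect_setequal(cc$patients, which(p$labels == 1))
  expect_equal(cc$count, sum(p$labels == 1))
  # signature matching nothing gives an empty set
  none <- consistent_cluster(sols, chars, c("depression", "cancer"))
  expect_equal(none$count, 0)
  # single method returns that cluster's patients unchanged
  one <- consistent_cluster(sols[1], chars[1], "depression")
  expect_setequal(one$patients, which(p$labels == 1))
})
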