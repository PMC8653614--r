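# shared fixture builders: everything is generated in code at test time

# minimal events/demographics pair for one hand-crafted patient
one_patient_events <- function(codes, dates) {
  data.frame(patient_id = "p1", code = codes, date = as.Date(dates),
             stringsAsFactors = FALSE)
}

# a tiny feature_matrix built directly (bypassing event tables) for metric
# tests: `parents` gives the parent variable of each column
tiny_feature_matrix <- function(x, parents, roles = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(roles)) roles <- rep("comorbidity", ncol(x))
  structure(
    list(x = x,
         meta = data.frame(column = colnames(x), parent = parents,
                           role = roles, stringsAsFactors = FALSE),
         patients = rownames(x) %||% paste0("p", seq_len(nrow(x)))),
    class = "feature_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# well separated Gaussian blobs in d dimensions
gaussian_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# brute-force silhouette, O(n^2 k), straight from the definition
brute_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(ks, labels[i]), function(j)
      mean(d[i, labels == j]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}
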