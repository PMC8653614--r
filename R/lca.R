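## Latent class analysis by expectation maximisation, with BIC model
## selection over a range of class counts and maximum-posterior assignment.
## Two observation models share one EM engine:
##   "gaussian":  diagonal-covariance Gaussian mixture on MCA coordinates
##                (the pipeline's default, matching MCA-then-LCA usage);
##   "bernoulli": classical LCA with independent Bernoulli indicators on the
##                raw one-hot features.

lca_em_once <- function(x, k, mode, tol, max_iter, var_floor = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  ## initialise responsibilities from a random hard partition
  labels <- sample.int(k, n, replace = TRUE)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), labels)] <- 1
  resp <- resp + 0.1
  resp <- resp / rowSums(resp)
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    ## M step
    nk <- colSums(resp)
    if (any(nk < 1)) return(list(degenerate = TRUE))
    w <- nk / n
    mu <- crossprod(resp, x) / nk           # k x d
    if (mode == "gaussian") {
      sig2 <- sapply(seq_len(k), function(j) {
        colSums(resp[, j] * (x - matrix(mu[j, ], n, d, byrow = TRUE))^2) /
          nk[j]
      })                                    # d x k
      sig2 <- pmax(sig2, var_floor)
    } else {
      mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)  # Bernoulli success probs
    }
    ## E step: log densities
    logdens <- matrix(0, n, k)
    for (j in seq_len(k)) {
      if (mode == "gaussian") {
        ctr <- x - matrix(mu[j, ], n, d, byrow = TRUE)
        logdens[, j] <- -0.5 * (sum(log(2 * pi * sig2[, j])) +
                                  colSums(t(ctr^2) / sig2[, j]))
      } else {
        logdens[, j] <- x %*% log(mu[j, ]) + (1 - x) %*% log(1 - mu[j, ])
      }
    }
    lw <- sweep(logdens, 2, log(w), `+`)
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    new_loglik <- sum(lse)
    resp <- exp(lw - lse)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  if (min(colSums(resp)) < 1) return(list(degenerate = TRUE))
  params <- if (mode == "gaussian") list(weights = w, means = mu,
                                         variances = t(sig2))
            else list(weights = w, probs = mu)
  list(degenerate = FALSE, loglik = loglik, resp = resp, params = params,
       iterations = it)
}

lca_n_params <- function(k, d, mode) {
  if (mode == "gaussian") (k - 1) + 2 * k * d else (k - 1) + k * d
}

#' Latent class analysis with BIC model selection
#'
#' Fits a finite mixture for each candidate number of classes by EM
#' (`n_starts` random initialisations each; a start whose smallest expected
#' class count falls below 1 is discarded as degenerate and redrawn), scores
#' each fitted model with `BIC = -2 logL + p log(n)`, and returns the
#' minimum-BIC model. Patients are assigned to the class with the greatest
#' posterior probability (ties to the lowest class index).
#'
#' @param x numeric matrix: MCA coordinates (`mode = "gaussian"`, default)
#'   or a binary feature matrix (`mode = "bernoulli"`).
#' @param k_range candidate class counts. Default 2:8.
#' @param n_starts random EM initialisations per k. Default 5.
#' @param seed integer RNG seed.
#' @param mode observation model, `"gaussian"` or `"bernoulli"`.
#' @param tol log-likelihood convergence tolerance. Default 1e-6.
#' @param max_iter maximum EM iterations per start. Default 500.
#' @return A `cluster_solution` (method `"lca"`); `objective` is the
#'   log-likelihood of the selected model, `extras` holds the posterior
#'   matrix, mixture parameters and the per-k BIC table.
#' @export
run_latent_class <- function(x, k_range = 2:8, n_starts = 5, seed = 1,
                             mode = c("gaussian", "bernoulli"),
                             tol = 1e-6, max_iter = 500) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (mode == "bernoulli" && any(!(x %in% c(0, 1))))
    stop("bernoulli mode requires a binary matrix", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  set.seed(as.integer(seed))
  per_k <- list()
  for (k in k_range) {
    best <- NULL
    tries <- 0L
    good <- 0L
    while (good < n_starts && tries < n_starts * 4L) {
      tries <- tries + 1L
      fit <- lca_em_once(x, k, mode, tol, max_iter)
      if (isTRUE(fit$degenerate)) next
      good <- good + 1L
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best))
      stop("all EM restarts degenerate at k = ", k, call. = FALSE)
    best$bic <- -2 * best$loglik + lca_n_params(k, d, mode) * log(n)
    best$k <- k
    per_k[[as.character(k)]] <- best
  }
  bics <- vapply(per_k, `[[`, numeric(1), "bic")
  sel <- per_k[[which.min(bics)]]
  labels <- max.col(sel$resp, ties.method = "first")
  new_cluster_solution(
    "lca", labels, sel$k, objective = sel$loglik,
    extras = list(
      posterior = sel$resp, params = sel$params,
      bic_table = data.frame(k = k_range, bic = unname(bics)),
      mode = mode
    ),
    seed = as.integer(seed), n_restarts = as.integer(n_starts)
  )
}
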