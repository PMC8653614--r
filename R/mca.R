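## Multiple correspondence analysis of the one-hot feature matrix:
## correspondence analysis of the full indicator matrix via generalized SVD
## with row/column masses. Indicator-matrix variant, no inertia correction
## by default (Benzecri correction available as an option).

#' Fit multiple correspondence analysis
#'
#' Computes the correspondence-analysis decomposition of the indicator
#' matrix: with `P = Z / sum(Z)`, row masses `r` and column masses `c`, the
#' SVD of `diag(r)^-1/2 (P - r c') diag(c)^-1/2` gives principal inertias
#' (squared singular values) and row/column principal coordinates. Row
#' coordinates are returned in principal coordinates (scaled by singular
#' values), so Euclidean distances between rows approximate chi-square
#' distances between patient profiles. Categories never observed (zero
#' column mass) are dropped with a warning. The sign of each component is
#' fixed by forcing its first nonzero column loading positive.
#'
#' @param x a `feature_matrix` (expanded internally via
#'   [as_indicator_matrix()]) or an indicator matrix whose rows all sum to
#'   the number of parent variables.
#' @param n_components number of components to retain; `NULL` keeps the full
#'   rank. Values beyond the rank are truncated with a warning.
#' @param correction `"none"` (default) or `"benzecri"`: Benzecri
#'   re-weighting of inertias above the 1/Q threshold, affecting only the
#'   reported explained-inertia fractions.
#'
#' @return Object of class `mca_result`: `row_coordinates`,
#'   `column_coordinates`, `eigenvalues` (principal inertias),
#'   `explained_inertia`, `total_inertia`, `n_components`, `n_parents`.
#' @export
#' @examples
#' ch <- generate_cohort(default_profiles(), 200, 4, seed = 1)
#' fx <- extract_features(ch$events, ch$demographics)
#' m <- fit_mca(fx$features, n_components = 5)
#' m$explained_inertia
fit_mca <- function(x, n_components = NULL, correction = c("none", "benzecri")) {
  correction <- match.arg(correction)
  if (inherits(x, "feature_matrix")) {
    ind <- as_indicator_matrix(x)
    z <- ind$z
    q <- length(unique(ind$parent))
  } else {
    z <- as.matrix(x)
    rs <- unique(rowSums(z))
    if (length(rs) != 1L)
      stop("indicator matrix rows must all sum to the number of parent ",
           "variables", call. = FALSE)
    q <- rs
  }
  if (any(!(z %in% c(0, 1)))) stop("matrix must be binary", call. = FALSE)

  zero <- colSums(z) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-mass categor",
            if (sum(zero) == 1) "y" else "ies", ": ",
            paste(colnames(z)[zero], collapse = ", "))
    z <- z[, !zero, drop = FALSE]
  }
  n <- nrow(z); jj <- ncol(z)
  P <- z / sum(z)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(S)
  tol <- max(dim(S)) * .Machine$double.eps * sv$d[1]
  keep <- which(sv$d > max(tol, 1e-12))
  rank <- length(keep)
  if (is.null(n_components)) {
    n_components <- rank  # may be 0 for degenerate (constant) data
  } else if (n_components < 1) {
    stop("n_components must be >= 1", call. = FALSE)
  }
  if (n_components > rank) {
    if (rank > 0)
      warning("n_components exceeds rank (", rank, "); truncating")
    n_components <- max(rank, 0L)
  }
  eig <- sv$d[keep]^2
  total_inertia <- sum(S^2)

  expl <- if (correction == "benzecri") {
    thr <- 1 / q
    adj <- ifelse(eig > thr, (q / (q - 1) * (eig - thr))^2, 0)
    if (sum(adj) > 0) adj / sum(adj) else rep(0, length(adj))
  } else {
    eig / total_inertia
  }

  m <- n_components
  if (m > 0) {
    u <- sv$u[, keep[seq_len(m)], drop = FALSE]
    v <- sv$v[, keep[seq_len(m)], drop = FALSE]
    sg <- sv$d[keep[seq_len(m)]]
    rowc <- u * (1 / sqrt(r))
    rowc <- sweep(rowc, 2, sg, `*`)
    colc <- v * (1 / sqrt(cc))
    colc <- sweep(colc, 2, sg, `*`)
    ## deterministic sign: first nonzero column loading positive
    for (jcomp in seq_len(m)) {
      nz <- which(abs(colc[, jcomp]) > 1e-12)
      if (length(nz) && colc[nz[1], jcomp] < 0) {
        colc[, jcomp] <- -colc[, jcomp]
        rowc[, jcomp] <- -rowc[, jcomp]
      }
    }
    dimnames(rowc) <- list(rownames(z), paste0("comp", seq_len(m)))
    dimnames(colc) <- list(colnames(z), paste0("comp", seq_len(m)))
  } else {
    rowc <- matrix(0, n, 0)
    colc <- matrix(0, jj, 0)
  }

  structure(
    list(
      row_coordinates = rowc,
      column_coordinates = colc,
      eigenvalues = eig,
      explained_inertia = expl,
      total_inertia = total_inertia,
      n_components = m,
      n_parents = q,
      correction = correction
    ),
    class = "mca_result"
  )
}

#' @export
print.mca_result <- function(x, ...) {
  cat("MCA:", nrow(x$row_coordinates), "rows,", x$n_components,
      "components retained; total inertia", format(x$total_inertia), "\n")
  cat("Explained inertia:",
      paste(sprintf("%.3f", utils::head(x$explained_inertia, 8)),
            collapse = " "), "\n")
  invisible(x)
}

#' Scree data for an MCA fit
#'
#' @param m an `mca_result`.
#' @return Data frame: component, inertia, fraction.
#' @export
mca_scree <- function(m) {
  data.frame(component = seq_along(m$eigenvalues),
             inertia = m$eigenvalues,
             fraction = m$explained_inertia)
}

#' Choose the number of MCA components by the elbow rule
#'
#' Returns the component index after which the drop in explained inertia
#' collapses, located as the maximum second difference of the
#' explained-inertia sequence: `argmax_i f(i) - 2 f(i+1) + f(i+2)`. With a
#' profile free of curvature (strictly linear), 1 is returned with a
#' warning; fewer than 3 fitted components returns all of them with a
#' warning. Never returns 0.
#'
#' @param m an `mca_result` (or a numeric explained-inertia profile).
#' @return Integer number of components to retain.
#' @export
#' @examples
#' select_components(c(0.40, 0.30, 0.05, 0.04, 0.03))  # 2
select_components <- function(m) {
  f <- if (inherits(m, "mca_result")) m$explained_inertia else as.numeric(m)
  if (length(f) < 3) {
    warning("fewer than 3 components fitted; retaining all")
    return(max(1L, length(f)))
  }
  d2 <- f[seq_len(length(f) - 2)] - 2 * f[seq_len(length(f) - 2) + 1] +
    f[seq_len(length(f) - 2) + 2]
  if (max(d2) <= 1e-12) {
    warning("no curvature in explained-inertia profile (degenerate elbow)")
    return(1L)
  }
  as.integer(which.max(d2))
}
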