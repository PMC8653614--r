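## Cluster characterisation (naming clusters by features that deviate
## significantly from the cohort) and cross-method consistency analysis
## (pairwise flow tables for alluvial plots, consistent-cluster detection).

#' Characterise clusters against the whole cohort
#'
#' For each cluster and each binary feature column, a two-sided
#' two-proportion z-test (with continuity correction) compares the
#' cluster's prevalence against the rest of the cohort; p-values are
#' Bonferroni-adjusted over the full family (clusters x features).
#' Features with adjusted p below `alpha` are listed with their direction.
#' Cluster names concatenate the top deviating elevated features by
#' absolute prevalence difference, with two special rules: a cluster whose
#' only elevated symptom category is memory is named "Typical AD", and a
#' cluster where all symptom categories except memory are elevated is named
#' "Non-typical AD". Clusters smaller than `min_size` are reported without
#' tests.
#'
#' @param fm a `feature_matrix` (only binary columns are tested; one-hot
#'   demographic levels count as binary features).
#' @param labels integer cluster labels.
#' @param alpha family-wise significance level. Default 0.05.
#' @param adjust `"bonferroni"` (default, conservative naming) or any
#'   [stats::p.adjust()] method such as `"fdr"`.
#' @param min_size minimum cluster size for testing. Default 5.
#' @param name_top number of features concatenated into a name. Default 3.
#' @return Object of class `cluster_characterisation`: `table` (long data
#'   frame: cluster, feature, role, cluster_prevalence, cohort_prevalence,
#'   direction, p, p_adjusted, significant), `names` (cluster -> name) and
#'   `family_size`.
#' @export
characterize <- function(fm, labels, alpha = 0.05,
                         adjust = "bonferroni", min_size = 5,
                         name_top = 3) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  x <- fm$x
  stopifnot(nrow(x) == length(labels))
  cls <- sort(unique(labels))
  feats <- fm$meta$column
  family_size <- length(cls) * length(feats)

  rows <- list()
  for (j in cls) {
    sel <- labels == j
    small <- sum(sel) < min_size
    if (small)
      warning("cluster ", j, " has fewer than ", min_size,
              " patients; tests skipped")
    for (i in seq_along(feats)) {
      a <- sum(x[sel, i]); na <- sum(sel)
      b <- sum(x[!sel, i]); nb <- sum(!sel)
      p_in <- a / na; p_out <- b / nb
      pval <- if (small || min(a + b, na + nb - a - b) == 0) NA_real_ else
        suppressWarnings(
          stats::prop.test(c(a, b), c(na, nb), correct = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = j, feature = feats[i], role = fm$meta$role[i],
        cluster_prevalence = p_in, cohort_prevalence = p_out,
        direction = if (p_in >= p_out) "higher" else "lower",
        p = pval, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  ## Bonferroni over the full family, including untestable cells in the
  ## family size (their p is NA and never significant)
  tab$p_adjusted <- if (adjust == "bonferroni")
    pmin(tab$p * family_size, 1) else stats::p.adjust(tab$p, method = adjust)
  tab$significant <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha

  sym_cats <- unique(fm$meta$parent[fm$meta$role == "symptom"])
  nm <- vapply(cls, function(j) {
    tj <- tab[tab$cluster == j & tab$significant &
                tab$direction == "higher", ]
    up_sym <- intersect(tj$feature, sym_cats)
    other_sym <- setdiff(sym_cats, "memory")
    if (identical(up_sym, "memory")) return("Typical AD")
    if (setequal(up_sym, other_sym)) return("Non-typical AD")
    if (!nrow(tj)) return(paste0("cluster ", j))
    eff <- abs(tj$cluster_prevalence - tj$cohort_prevalence)
    top <- tj$feature[order(-eff)][seq_len(min(name_top, nrow(tj)))]
    paste(top, collapse = " + ")
  }, character(1))
  structure(
    list(table = tab, names = stats::setNames(nm, cls),
         family_size = family_size, alpha = alpha, adjust = adjust),
    class = "cluster_characterisation"
  )
}

#' @export
print.cluster_characterisation <- function(x, ...) {
  cat("Cluster characterisation (", x$adjust, ", alpha = ", x$alpha,
      ", family = ", x$family_size, " tests):\n", sep = "")
  for (j in names(x$names))
    cat(sprintf("  cluster %s: %s (%d significant features)\n", j,
                x$names[[j]],
                sum(x$table$significant[x$table$cluster == as.integer(j)])))
  invisible(x)
}

#' Cross-method flow tables (alluvial data)
#'
#' Builds the per-patient label matrix across cluster solutions and all
#' pairwise contingency tables in long, plotting-ready format.
#'
#' @param solutions named list of `cluster_solution` objects over an
#'   identical patient set (same length and order of labels).
#' @return Object of class `flow_table`: `labels` (patients x methods
#'   matrix) and `flows` (long data frame: method_from, cluster_from,
#'   method_to, cluster_to, count).
#' @export
cross_method_flow <- function(solutions) {
  stopifnot(length(solutions) >= 2)
  if (is.null(names(solutions)))
    names(solutions) <- vapply(solutions, `[[`, character(1), "method")
  ns <- vapply(solutions, function(s) length(s$labels), integer(1))
  if (length(unique(ns)) != 1L)
    stop("solutions cover different patient sets (sizes ",
         paste(unique(ns), collapse = " vs "), ")", call. = FALSE)
  lab <- do.call(cbind, lapply(solutions, `[[`, "labels"))
  colnames(lab) <- names(solutions)
  pairs <- utils::combn(names(solutions), 2, simplify = FALSE)
  flows <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- table(lab[, pr[1]], lab[, pr[2]])
    df <- as.data.frame(tt, stringsAsFactors = FALSE)
    names(df) <- c("cluster_from", "cluster_to", "count")
    df <- df[df$count > 0, ]
    data.frame(method_from = pr[1], cluster_from = df$cluster_from,
               method_to = pr[2], cluster_to = df$cluster_to,
               count = df$count, stringsAsFactors = FALSE)
  }))
  rownames(flows) <- NULL
  structure(list(labels = lab, flows = flows), class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("Cross-method flow over", nrow(x$labels), "patients and",
      ncol(x$labels), "methods\n")
  invisible(x)
}

#' Detect a consistent cluster across methods
#'
#' Given per-method characterisations and a feature signature (features
#' that must be significantly elevated, e.g. depression, anxiety, the
#' earliest onset band and current smoking), finds in each method the
#' cluster(s) whose elevated-feature set contains the signature and returns
#' the intersection of their patient sets across methods.
#'
#' @param solutions named list of `cluster_solution` objects (same patient
#'   order); patient ids taken from `patient_ids` or seq_len(n).
#' @param characterisations named list of `cluster_characterisation`
#'   objects matching `solutions`.
#' @param feature_signature character vector of feature column names that
#'   must be flagged significantly "higher".
#' @param patient_ids optional patient identifiers.
#' @return List with `patients` (ids in the intersection), `count` and
#'   `per_method` (matched cluster ids per method). Empty when no method
#'   matches the signature.
#' @export
consistent_cluster <- function(solutions, characterisations,
                               feature_signature, patient_ids = NULL) {
  if (is.null(names(solutions)))
    names(solutions) <- vapply(solutions, `[[`, character(1), "method")
  n <- length(solutions[[1]]$labels)
  if (is.null(patient_ids)) patient_ids <- seq_len(n)
  per_method <- list()
  sets <- list()
  for (m in names(solutions)) {
    ch <- characterisations[[m]]
    tab <- ch$table
    hits <- integer(0)
    for (j in unique(tab$cluster)) {
      up <- tab$feature[tab$cluster == j & tab$significant &
                          tab$direction == "higher"]
      if (all(feature_signature %in% up)) hits <- c(hits, j)
    }
    per_method[[m]] <- hits
    if (length(hits))
      sets[[m]] <- patient_ids[solutions[[m]]$labels %in% hits]
  }
  ## intersect across the methods in which the signature appears at all;
  ## no matching method anywhere -> empty set
  inter <- if (length(sets)) Reduce(intersect, sets) else patient_ids[0]
  list(patients = inter, count = length(inter), per_method = per_method,
       matched_methods = names(sets))
}
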