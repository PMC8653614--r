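## The five clinical outcomes per cluster and the clinical-utility
## comparison of cluster labels against individual features: per-patient
## MMSE decline slopes, Kaplan-Meier curves with Greenwood intervals,
## log-rank tests, Cox proportional hazards and per-cluster summaries.

#' Per-patient MMSE decline slopes
#'
#' Ordinary least-squares slope of MMSE score against time (years) for each
#' patient; equals the two-point slope when only two scores exist. Patients
#' with fewer than two dated scores, or a zero time span, are excluded and
#' counted.
#'
#' @param mmse_series data frame with `patient_id`, `t_years`, `mmse`.
#' @return Data frame (patient_id, slope, n_scores) with the number of
#'   excluded patients attached as `attr(, "n_excluded")`.
#' @export
#' @examples
#' s <- data.frame(patient_id = "a", t_years = c(0, 2), mmse = c(30, 24))
#' mmse_slopes(s)$slope  # -3
mmse_slopes <- function(mmse_series) {
  stopifnot(all(c("patient_id", "t_years", "mmse") %in% names(mmse_series)))
  sp <- split(mmse_series[, c("t_years", "mmse")], mmse_series$patient_id)
  res <- lapply(sp, function(d) {
    d <- d[is.finite(d$t_years) & is.finite(d$mmse), ]
    if (nrow(d) < 2 || diff(range(d$t_years)) == 0) return(NULL)
    tc <- d$t_years - mean(d$t_years)
    slope <- sum(tc * (d$mmse - mean(d$mmse))) / sum(tc^2)
    c(slope = slope, n = nrow(d))
  })
  keep <- !vapply(res, is.null, logical(1))
  n_excl <- sum(!keep)
  if (n_excl)
    message("mmse_slopes: excluding ", n_excl,
            " patient(s) with < 2 usable scores")
  out <- data.frame(
    patient_id = names(res)[keep],
    slope = vapply(res[keep], `[[`, numeric(1), "slope"),
    n_scores = vapply(res[keep], `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}

#' Kaplan-Meier estimate with Greenwood 95% confidence interval
#'
#' Product-limit estimator of the survival function; with no censoring it
#' equals one minus the empirical CDF at every event time.
#'
#' @param times non-negative event/censoring times.
#' @param events logical/0-1 event indicators.
#' @return Data frame: time, n_risk, n_event, survival, lower, upper.
#' @export
km_estimate <- function(times, events) {
  stopifnot(all(times >= 0))
  events <- as.logical(events)
  if (!any(events)) warning("no events: survival curve is flat at 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "plain")
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, lower = fit$lower, upper = fit$upper
  )
}

#' Log-rank test across groups
#'
#' @param times,events survival data.
#' @param groups group labels (>= 2 groups, >= 1 event required).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
log_rank <- function(times, events, groups) {
  events <- as.logical(events)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("log-rank test requires at least 2 groups", call. = FALSE)
  if (!any(events)) stop("log-rank test requires at least 1 event",
                         call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(chisq = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for a single predictor
#'
#' Partial-likelihood maximisation with Breslow tie handling. For a
#' categorical predictor the reference level is its most frequent level, so
#' cluster membership is compared against the largest cluster. Monotone
#' likelihood (complete separation) is flagged and the affected confidence
#' bound reported as unbounded.
#'
#' @param covariate numeric binary vector or factor.
#' @param times,events survival data.
#' @return List with `hr` (named vector of hazard ratios), `ci` (matrix,
#'   2.5%/97.5%), `loglik` (fitted partial log-likelihood), `separation`
#'   flag and the `coxph` fit.
#' @export
cox_hazard <- function(covariate, times, events) {
  events <- as.logical(events)
  if (sum(events) == 0) stop("no events", call. = FALSE)
  if (is.factor(covariate) || is.character(covariate)) {
    covariate <- as.factor(covariate)
    ref <- names(which.max(table(covariate)))
    covariate <- stats::relevel(covariate, ref = ref)
  }
  df <- data.frame(t = times, e = events, x = covariate)
  fit <- survival::coxph(survival::Surv(t, e) ~ x, data = df,
                         ties = "breslow")
  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  separation <- any(!is.finite(se)) || any(se > 100) ||
    any(abs(co) > 10)
  if (separation) warning("possible monotone likelihood; CI unbounded")
  ci <- cbind(lower = exp(co - 1.96 * se), upper = exp(co + 1.96 * se))
  list(hr = exp(co), ci = ci, loglik = fit$loglik[2],
       separation = separation, fit = fit)
}

mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2)
    return(c(mean = if (n) mean(x) else NA_real_, lower = NA_real_,
             upper = NA_real_, n = n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- stats::sd(x) / sqrt(n)
  c(mean = mean(x), lower = mean(x) - z * se, upper = mean(x) + z * se,
    n = n)
}

#' Clinical-utility comparison of cluster labels versus single features
#'
#' For every binary/categorical feature and for cluster membership (as a
#' categorical predictor): fits a univariable linear model for the MMSE
#' decline slope and records the adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - p - 1)`; fits a univariable Cox model for time
#' to assisted living and records the partial log-likelihood and hazard
#' ratios. Predictors are ranked on each criterion; if cluster membership
#' outranks every individual feature, the clustering carries more
#' predictive value than any single variable. Constant predictors are
#' skipped.
#'
#' @param features a `feature_matrix`, or a data frame of per-patient
#'   predictors (binary columns and/or factors).
#' @param cluster_labels integer labels, one per patient.
#' @param outcome_table data frame with `mmse_slope`,
#'   `time_to_assisted_living`, `al_event` (one row per patient, aligned).
#' @return Object of class `utility_report`: data frame `ranking`
#'   (predictor, adj_r2, cox_loglik, ranks) and flags
#'   `cluster_best_r2` / `cluster_best_cox`.
#' @export
utility_comparison <- function(features, cluster_labels, outcome_table) {
  if (inherits(features, "feature_matrix")) {
    ## collapse one-hot groups back to factors, keep binary parents 0/1
    meta <- features$meta
    df <- list()
    for (p in unique(meta$parent)) {
      idx <- which(meta$parent == p)
      if (length(idx) == 1L) {
        df[[p]] <- features$x[, idx]
      } else {
        lev <- sub(paste0("^", p, ":"), "", meta$column[idx])
        df[[p]] <- factor(lev[max.col(features$x[, idx, drop = FALSE],
                                      ties.method = "first")], levels = lev)
      }
    }
    features <- as.data.frame(df, check.names = TRUE)
  } else {
    features <- as.data.frame(features)
  }
  n <- nrow(features)
  stopifnot(length(cluster_labels) == n, nrow(outcome_table) == n)
  preds <- features
  preds[["cluster"]] <- factor(cluster_labels)

  rows <- list()
  for (nm in names(preds)) {
    x <- preds[[nm]]
    if (length(unique(x)) < 2) {
      message("utility_comparison: skipping constant predictor ", nm)
      next
    }
    lmfit <- stats::lm(outcome_table$mmse_slope ~ x)
    adj <- summary(lmfit)$adj.r.squared
    cox <- tryCatch(
      cox_hazard(if (is.factor(x)) x else as.numeric(x),
                 outcome_table$time_to_assisted_living,
                 outcome_table$al_event),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(cox_hazard(if (is.factor(x)) x else as.numeric(x),
                                    outcome_table$time_to_assisted_living,
                                    outcome_table$al_event))
      })
    rows[[nm]] <- data.frame(
      predictor = nm, adj_r2 = adj,
      cox_loglik = if (is.null(cox)) NA_real_ else cox$loglik,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$rank_r2 <- rank(-tab$adj_r2, ties.method = "min")
  tab$rank_cox <- rank(-tab$cox_loglik, ties.method = "min",
                       na.last = "keep")
  tab <- tab[order(tab$rank_r2), ]
  structure(
    list(
      ranking = tab,
      cluster_best_r2 = tab$predictor[which.min(tab$rank_r2)] == "cluster",
      cluster_best_cox =
        !is.na(tab$rank_cox[tab$predictor == "cluster"]) &&
        tab$rank_cox[tab$predictor == "cluster"] == 1
    ),
    class = "utility_report"
  )
}

#' @export
print.utility_report <- function(x, ...) {
  cat("Clinical-utility ranking (top 6 by adjusted R2):\n")
  print(utils::head(x$ranking, 6), row.names = FALSE)
  cat("cluster membership ranks first:",
      if (x$cluster_best_r2) "yes" else "no", "(R2);",
      if (x$cluster_best_cox) "yes" else "no", "(Cox)\n")
  invisible(x)
}

#' Per-cluster outcome summary
#'
#' Means with normal-approximation 95% confidence intervals per cluster for
#' consultations/year, missed appointments/year, ChEI duration and MMSE
#' slope; Kaplan-Meier curves per cluster and pairwise log-rank tests for
#' death and assisted living. Clusters with fewer than 2 patients have
#' undefined intervals.
#'
#' @param outcome_table per-patient outcomes: `mmse_slope`,
#'   `consultations_per_year`, `missed_per_year`, `chei_duration`,
#'   `time_to_death`, `death_event`, `time_to_assisted_living`, `al_event`.
#' @param cluster_labels integer labels covering all patients.
#' @return List with `means` (long data frame: cluster, outcome, mean,
#'   lower, upper, n), `km` (tidy per-cluster curves for both endpoints)
#'   and `log_rank` (overall tests).
#' @export
outcome_summary <- function(outcome_table, cluster_labels) {
  stopifnot(nrow(outcome_table) == length(cluster_labels))
  cls <- sort(unique(cluster_labels))
  cont <- c("consultations_per_year", "missed_per_year", "chei_duration",
            "mmse_slope")
  cont <- intersect(cont, names(outcome_table))
  means <- do.call(rbind, lapply(cls, function(j) {
    sel <- cluster_labels == j
    do.call(rbind, lapply(cont, function(v) {
      ci <- mean_ci(outcome_table[[v]][sel])
      data.frame(cluster = j, outcome = v, mean = ci["mean"],
                 lower = ci["lower"], upper = ci["upper"], n = ci["n"],
                 row.names = NULL)
    }))
  }))
  km <- list()
  lr <- list()
  for (ep in c("death", "assisted_living")) {
    tv <- if (ep == "death") "time_to_death" else "time_to_assisted_living"
    evv <- if (ep == "death") "death_event" else "al_event"
    if (!all(c(tv, evv) %in% names(outcome_table))) next
    km[[ep]] <- do.call(rbind, lapply(cls, function(j) {
      sel <- cluster_labels == j
      if (!any(outcome_table[[evv]][sel])) return(NULL)
      cbind(cluster = j,
            km_estimate(outcome_table[[tv]][sel],
                        outcome_table[[evv]][sel]))
    }))
    lr[[ep]] <- tryCatch(
      log_rank(outcome_table[[tv]], outcome_table[[evv]], cluster_labels),
      error = function(e) NULL)
  }
  list(means = means, km = km, log_rank = lr)
}
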