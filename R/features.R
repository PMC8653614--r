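## Cohort selection and construction of the one-hot clinical feature matrix:
## temporal symptom attribution, symptom grouping, comorbidity flags and
## demographic one-hot encoding. Input schema: an events table
## (patient_id, code, date) and a demographics table (patient_id, birth_year,
## gender, practice_id, smoking, drinking).

#' Apply cohort inclusion rules
#'
#' Selects eligible patients from raw event and demographics tables. A
#' patient is retained iff all of the following hold:
#' a diagnosis event is present; birth year and gender are recorded;
#' age at diagnosis is at least 40; there is at least one year of
#' observation before and after the diagnosis date; and at least one symptom
#' or comorbidity event is recorded. Observation start/end default to the
#' study window and are tightened by per-patient `observation_start` /
#' `observation_end` columns in `demographics` when present. Events with
#' unparseable dates are dropped row-wise and counted.
#'
#' @param events data frame with `patient_id`, `code`, `date`.
#' @param demographics data frame with `patient_id`, `birth_year`, `gender`,
#'   `practice_id` and optionally `smoking`, `drinking`,
#'   `observation_start`, `observation_end`.
#' @param study_window Date vector (start, end).
#' @param diagnosis_code event code marking the diagnosis. Default `"dx:AD"`.
#' @param min_age minimum age at diagnosis. Default 40.
#' @param min_followup_years minimum follow-up either side of diagnosis.
#'
#' @return Data frame (class `cohort_table`) with one row per retained
#'   patient: patient_id, diagnosis_date, age_at_diagnosis, birth_year,
#'   gender, practice_id, observation_start, observation_end. Exclusion
#'   counts by rule are attached as `attr(, "exclusions")`.
#' @export
select_cohort <- function(events, demographics,
                          study_window = default_study_window(),
                          diagnosis_code = "dx:AD",
                          min_age = 40, min_followup_years = 1) {
  win <- as.Date(study_window)
  empty <- data.frame(
    patient_id = character(0), diagnosis_date = as.Date(character(0)),
    age_at_diagnosis = numeric(0), birth_year = integer(0),
    gender = character(0), practice_id = character(0),
    observation_start = as.Date(character(0)),
    observation_end = as.Date(character(0)), stringsAsFactors = FALSE
  )
  if (!nrow(events) || !nrow(demographics)) {
    class(empty) <- c("cohort_table", "data.frame")
    return(empty)
  }
  ev <- events
  ev$date <- as.Date(ev$date)
  n_bad <- sum(is.na(ev$date) | !nzchar(ev$code))
  if (n_bad) {
    message("select_cohort: dropping ", n_bad,
            " event rows with malformed dates or empty codes")
    ev <- ev[!is.na(ev$date) & nzchar(ev$code), ]
  }

  dx <- ev[ev$code == diagnosis_code, ]
  dx <- dx[order(dx$patient_id, dx$date), ]
  dx <- dx[!duplicated(dx$patient_id), c("patient_id", "date")]
  names(dx)[2] <- "diagnosis_date"

  d <- merge(demographics, dx, by = "patient_id")
  excl <- c(no_diagnosis = nrow(demographics) - nrow(d))

  obs_start <- if ("observation_start" %in% names(d))
    pmax(as.Date(d$observation_start), win[1]) else rep(win[1], nrow(d))
  obs_end <- if ("observation_end" %in% names(d))
    pmin(as.Date(d$observation_end), win[2]) else rep(win[2], nrow(d))
  d$observation_start <- obs_start
  d$observation_end <- obs_end

  keep <- !is.na(d$birth_year) & !is.na(d$gender) & nzchar(d$gender)
  excl["missing_demographics"] <- sum(!keep)
  d <- d[keep, ]

  d$age_at_diagnosis <-
    as.integer(format(d$diagnosis_date, "%Y")) - d$birth_year
  keep <- d$age_at_diagnosis >= min_age
  excl["age_below_minimum"] <- sum(!keep)
  d <- d[keep, ]

  fup <- min_followup_years * 365.25
  keep <- as.numeric(d$diagnosis_date - d$observation_start) >= fup &
    as.numeric(d$observation_end - d$diagnosis_date) >= fup
  excl["insufficient_followup"] <- sum(!keep)
  d <- d[keep, ]

  has_clin <- unique(ev$patient_id[grepl("^(sx:|cm:)", ev$code)])
  keep <- d$patient_id %in% has_clin
  excl["no_symptom_or_comorbidity"] <- sum(!keep)
  d <- d[keep, ]

  out <- d[, c("patient_id", "diagnosis_date", "age_at_diagnosis",
               "birth_year", "gender", "practice_id")]
  out$observation_start <- d$observation_start
  out$observation_end <- d$observation_end
  for (extra in c("smoking", "drinking"))
    if (extra %in% names(d)) out[[extra]] <- d[[extra]]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Attribute post-diagnosis symptoms for one patient
#'
#' A raw symptom is flagged for a patient iff (a) its earliest record falls
#' strictly after the diagnosis date and (b) no explaining comorbidity is
#' recorded before that earliest post-diagnosis symptom record. A symptom
#' coded on the diagnosis day itself is not attributed.
#'
#' @param patient_events data frame of this patient's events (`code`, `date`).
#' @param diagnosis_date Date.
#' @param symptom_map named character vector: event code -> raw symptom name.
#' @param explanation_map named list: symptom name -> comorbidity names that
#'   explain it (see [default_explanation_map()]).
#' @param comorbidity_map named character vector: event code -> comorbidity
#'   name.
#'
#' @return Named logical vector over all symptom names in `symptom_map`.
#' @export
attribute_symptoms <- function(patient_events, diagnosis_date,
                               symptom_map = default_symptom_map(),
                               explanation_map = default_explanation_map(),
                               comorbidity_map = default_comorbidity_map()) {
  sym_names <- unique(unname(symptom_map))
  flags <- stats::setNames(rep(FALSE, length(sym_names)), sym_names)
  if (!length(symptom_map) || !nrow(patient_events)) return(flags)
  ev <- patient_events
  ev$date <- as.Date(ev$date)
  dx <- as.Date(diagnosis_date)

  sx <- ev[ev$code %in% names(symptom_map) & ev$date > dx, ]
  if (!nrow(sx)) return(flags)
  sx$symptom <- unname(symptom_map[sx$code])
  cm <- ev[ev$code %in% names(comorbidity_map), ]
  cm$comorbidity <- unname(comorbidity_map[cm$code])

  for (s in unique(sx$symptom)) {
    first <- min(sx$date[sx$symptom == s])
    explainers <- explanation_map[[s]]
    explained <- length(explainers) &&
      any(cm$comorbidity %in% explainers & cm$date < first)
    flags[s] <- !explained
  }
  flags
}

#' Raw symptom flags for every patient in a cohort
#'
#' Applies [attribute_symptoms()] patient by patient.
#'
#' @param events full events table.
#' @param cohort a `cohort_table` from [select_cohort()].
#' @inheritParams attribute_symptoms
#' @return Logical matrix, patients (rows, in cohort order) x raw symptoms.
#' @export
symptom_flags <- function(events, cohort,
                          symptom_map = default_symptom_map(),
                          explanation_map = default_explanation_map(),
                          comorbidity_map = default_comorbidity_map()) {
  ev <- events[events$patient_id %in% cohort$patient_id, ]
  ev$date <- as.Date(ev$date)
  split_ev <- split(ev[, c("code", "date")], ev$patient_id)
  sym_names <- unique(unname(symptom_map))
  out <- matrix(FALSE, nrow(cohort), length(sym_names),
                dimnames = list(cohort$patient_id, sym_names))
  for (i in seq_len(nrow(cohort))) {
    pe <- split_ev[[cohort$patient_id[i]]]
    if (is.null(pe)) next
    out[i, ] <- attribute_symptoms(pe, cohort$diagnosis_date[i],
                                   symptom_map, explanation_map,
                                   comorbidity_map)
  }
  out
}

#' Collapse raw symptom flags into the four symptom categories
#'
#' `memory` and `confusion` map one to one; `neuropsychological` is the OR
#' over its member symptoms; `motor` is the OR over difficulty walking and
#' orientation problems. Raw symptoms recognised by [default_symptom_map()]
#' but outside all categories are ignored; names outside the dictionary are
#' a configuration error.
#'
#' @param flags named logical/0-1 vector, or matrix with symptom columns.
#' @param confusion_in_neuropsychological see [symptom_category_map()].
#' @return Same shape as the input, over the four category names.
#' @export
group_symptoms <- function(flags, confusion_in_neuropsychological = FALSE) {
  cmap <- symptom_category_map(confusion_in_neuropsychological)
  if (is.matrix(flags)) {
    known <- c(unique(unlist(cmap)), unname(default_symptom_map()))
    unknown <- setdiff(colnames(flags), known)
    if (length(unknown))
      stop("unknown symptom name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out <- sapply(cmap, function(members) {
      m <- intersect(members, colnames(flags))
      if (!length(m)) rep(0L, nrow(flags))
      else as.integer(rowSums(flags[, m, drop = FALSE] != 0) > 0)
    })
    rownames(out) <- rownames(flags)
    return(out)
  }
  known <- c(unique(unlist(cmap)), unname(default_symptom_map()))
  unknown <- setdiff(names(flags), known)
  if (length(unknown))
    stop("unknown symptom name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vapply(cmap, function(members) {
    m <- intersect(members, names(flags))
    length(m) > 0 && any(flags[m] != 0)
  }, logical(1))
}

#' Pre-diagnosis comorbidity flags
#'
#' A comorbidity is flagged iff any matching event is recorded strictly
#' before the diagnosis date (comorbidities arising after diagnosis may be
#' consequences of the disease and are not counted as features).
#'
#' @inheritParams symptom_flags
#' @return Logical matrix, patients x comorbidities.
#' @export
comorbidity_flags <- function(events, cohort,
                              comorbidity_map = default_comorbidity_map()) {
  ev <- events[events$code %in% names(comorbidity_map), ]
  ev$date <- as.Date(ev$date)
  ev$comorbidity <- unname(comorbidity_map[ev$code])
  cm_names <- unique(unname(comorbidity_map))
  out <- matrix(FALSE, nrow(cohort), length(cm_names),
                dimnames = list(cohort$patient_id, cm_names))
  ev <- merge(ev, cohort[, c("patient_id", "diagnosis_date")],
              by = "patient_id")
  ev <- ev[ev$date < ev$diagnosis_date, ]
  if (nrow(ev)) {
    idx <- cbind(match(ev$patient_id, cohort$patient_id),
                 match(ev$comorbidity, cm_names))
    out[idx] <- TRUE
  }
  out
}

#' Build the one-hot clinical feature matrix
#'
#' Assembles the binary patient x feature matrix used for clustering:
#' the 4 symptom-category flags, the 13 comorbidity flags, and one-hot
#' encoded demographics (5 age bands at diagnosis, gender, smoking status,
#' drinking status) — 21 parent variables in total with the default
#' dictionary. Missing smoking is encoded as "non-smoker"; missing drinking
#' as "drinking status not specified". Column order is deterministic.
#'
#' @param cohort a `cohort_table` (must carry `smoking`/`drinking` columns,
#'   or pass `demographics` to supply them).
#' @param symptom_categories integer/logical matrix patients x 4 categories
#'   (rows in cohort order), e.g. from [group_symptoms()].
#' @param comorbidities integer/logical matrix patients x comorbidities.
#' @param demographics optional demographics table to merge smoking/drinking
#'   from; every cohort patient must be present.
#' @param age_bands list with `breaks` and `labels`
#'   (default [default_age_bands()]).
#'
#' @return Object of class `feature_matrix`: list with `x` (integer matrix,
#'   patients x feature columns), `meta` (data frame: column, parent, role)
#'   and `patients`.
#' @export
build_feature_matrix <- function(cohort, symptom_categories, comorbidities,
                                 demographics = NULL,
                                 age_bands = default_age_bands()) {
  n <- nrow(cohort)
  stopifnot(nrow(symptom_categories) == n, nrow(comorbidities) == n)
  if (!is.null(demographics)) {
    i <- match(cohort$patient_id, demographics$patient_id)
    if (anyNA(i))
      stop("patient(s) in cohort absent from demographics: ",
           paste(utils::head(cohort$patient_id[is.na(i)], 5), collapse = ", "),
           call. = FALSE)
    smoking <- demographics$smoking[i]
    drinking <- demographics$drinking[i]
  } else {
    if (!all(c("smoking", "drinking") %in% names(cohort)))
      stop("cohort lacks smoking/drinking; pass `demographics`",
           call. = FALSE)
    smoking <- cohort$smoking
    drinking <- cohort$drinking
  }
  lv <- demographic_levels()
  smoking[is.na(smoking) | !nzchar(smoking)] <- "non-smoker"
  drinking[is.na(drinking) | !nzchar(drinking)] <-
    "drinking status not specified"
  bad_s <- setdiff(unique(smoking), lv$smoking)
  bad_d <- setdiff(unique(drinking), lv$drinking)
  bad_g <- setdiff(unique(cohort$gender), lv$gender)
  if (length(c(bad_s, bad_d, bad_g)))
    stop("unrecognised demographic level(s): ",
         paste(c(bad_s, bad_d, bad_g), collapse = ", "), call. = FALSE)

  onehot <- function(values, levels, parent) {
    m <- outer(values, levels, `==`) * 1L
    colnames(m) <- paste0(parent, ":", levels)
    m
  }
  band <- cut(cohort$age_at_diagnosis, breaks = age_bands$breaks,
              labels = age_bands$labels, right = TRUE)
  blocks <- list(
    symptom = symptom_categories * 1L,
    comorbidity = comorbidities * 1L,
    age_band = onehot(as.character(band), age_bands$labels, "age_band"),
    gender = onehot(cohort$gender, lv$gender, "gender"),
    smoking = onehot(smoking, lv$smoking, "smoking"),
    drinking = onehot(drinking, lv$drinking, "drinking")
  )
  x <- do.call(cbind, unname(blocks))
  rownames(x) <- cohort$patient_id
  meta <- data.frame(
    column = colnames(x),
    parent = c(colnames(symptom_categories), colnames(comorbidities),
               rep(c("age_band", "gender", "smoking", "drinking"),
                   c(length(age_bands$labels), length(lv$gender),
                     length(lv$smoking), length(lv$drinking)))),
    role = rep(c("symptom", "comorbidity", "demographic"),
               c(ncol(symptom_categories), ncol(comorbidities),
                 length(age_bands$labels) + length(lv$gender) +
                   length(lv$smoking) + length(lv$drinking))),
    stringsAsFactors = FALSE
  )
  structure(list(x = x, meta = meta, patients = cohort$patient_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "patients x", ncol(x$x), "columns (",
      length(unique(x$meta$parent)), "parent variables )\n")
  invisible(x)
}

#' Number of parent variables in a feature matrix
#' @param fm a `feature_matrix`.
#' @return Integer count of distinct parent variables.
#' @export
n_parent_variables <- function(fm) length(unique(fm$meta$parent))

#' Expand a feature matrix to a full MCA indicator matrix
#'
#' Binary presence/absence parents are expanded into explicit yes/no column
#' pairs so that every parent variable contributes a one-hot group summing
#' to exactly 1 per row — the form required by multiple correspondence
#' analysis (row sums all equal the number of parent variables).
#'
#' @param fm a `feature_matrix`.
#' @return List with `z` (indicator matrix) and `parent` (character vector
#'   assigning each column to its parent variable).
#' @export
as_indicator_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- list()
  parents <- character(0)
  for (p in unique(fm$meta$parent)) {
    idx <- which(fm$meta$parent == p)
    block <- fm$x[, idx, drop = FALSE]
    if (length(idx) == 1L) {  # binary parent -> yes/no pair
      block <- cbind(block, 1L - block)
      colnames(block) <- paste0(p, c(":yes", ":no"))
    }
    cols[[p]] <- block
    parents <- c(parents, rep(p, ncol(block)))
  }
  z <- do.call(cbind, unname(cols))
  rownames(z) <- rownames(fm$x)
  list(z = z, parent = parents)
}

#' Split a cohort into train and test sets by practice
#'
#' Samples `ceiling(test_fraction * n_practices)` practices without
#' replacement; all patients of a sampled practice form the test set,
#' mimicking replication in an external data set.
#'
#' @param cohort a `cohort_table` (needs `practice_id`).
#' @param test_fraction fraction of practices in the test set, in (0, 1).
#' @param seed integer RNG seed.
#' @return List with `train` and `test` patient-id character vectors and
#'   `test_practices`.
#' @export
split_by_practice <- function(cohort, test_fraction = 0.25, seed = 1) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  practices <- sort(unique(cohort$practice_id))
  if (length(practices) < 2)
    stop("need at least 2 practices to split", call. = FALSE)
  n_test <- ceiling(test_fraction * length(practices))
  set.seed(as.integer(seed))
  test_pr <- sample(practices, n_test)
  test <- cohort$patient_id[cohort$practice_id %in% test_pr]
  train <- setdiff(cohort$patient_id, test)
  list(train = train, test = test, test_practices = test_pr)
}

#' End-to-end feature extraction from raw tables
#'
#' Convenience wrapper: [select_cohort()] then [symptom_flags()],
#' [group_symptoms()], [comorbidity_flags()] and [build_feature_matrix()].
#'
#' @inheritParams select_cohort
#' @inheritParams group_symptoms
#' @return List with `cohort` and `features` (a `feature_matrix`).
#' @export
extract_features <- function(events, demographics,
                             study_window = default_study_window(),
                             diagnosis_code = "dx:AD",
                             confusion_in_neuropsychological = FALSE) {
  cohort <- select_cohort(events, demographics, study_window, diagnosis_code)
  raw <- symptom_flags(events, cohort)
  cats <- group_symptoms(raw, confusion_in_neuropsychological)
  cms <- comorbidity_flags(events, cohort)
  fm <- build_feature_matrix(cohort, cats, cms, demographics = demographics)
  list(cohort = cohort, features = fm)
}
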