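## Default clinical vocabulary: symptom codes, symptom-category grouping,
## comorbidity codes, demographic levels and age banding. These are plain
## lookup tables; real deployments replace them with site-specific code lists
## supplied in the same shapes.

#' Default comorbidity dictionary
#'
#' The 13 comorbidities retained in the default feature set (after dropping
#' hypercholesterolemia, whose recorded prevalence in primary-care data is
#' too low to be informative). Names are internal event codes of the form
#' `cm:<name>`; values are feature names.
#'
#' @return Named character vector mapping event codes to comorbidity names.
#' @export
#' @examples
#' default_comorbidity_map()
default_comorbidity_map <- function() {
  nm <- c(
    "anxiety", "atherosclerosis", "atrial_fibrillation", "cancer",
    "depression", "diabetes", "haemorrhagic_stroke", "hearing_loss",
    "heart_failure", "hyperglycaemia", "hypertension", "kidney_disease",
    "rheumatoid_arthritis"
  )
  stats::setNames(nm, paste0("cm:", nm))
}

#' Default symptom dictionary
#'
#' Maps internal symptom event codes (`sx:<name>`) to the raw symptom names
#' drawn from the published symptom literature for Alzheimer's disease.
#'
#' @return Named character vector mapping event codes to raw symptom names.
#' @export
default_symptom_map <- function() {
  nm <- c(
    "agitation", "aggression", "anxiety", "apathy", "confusion", "delirium",
    "delusion", "depression", "difficulty_walking", "eating", "fainting",
    "falls", "hallucinations", "incontinence", "language", "memory",
    "mood_disorders", "orientation", "paranoia", "seizure", "sleep"
  )
  stats::setNames(nm, paste0("sx:", nm))
}

#' Symptom-to-category grouping
#'
#' Raw symptoms are collapsed into four broader categories because most raw
#' symptoms have low recorded prevalence: `memory`, `confusion`,
#' `neuropsychological` (aggression, agitation, anxiety, apathy, delirium,
#' delusion, depression, hallucinations, sleep, eating, paranoia, mood
#' disorders) and `motor` (difficulty walking, orientation problems).
#' Raw symptoms outside these lists (fainting, falls, incontinence,
#' language, seizure) are recorded but not mapped to any category.
#'
#' Confusion appears in published groupings both as its own category and
#' inside the neuropsychological list; the default keeps it in the confusion
#' category only, with `confusion_in_neuropsychological = TRUE` adding it to
#' the neuropsychological OR as well.
#'
#' @param confusion_in_neuropsychological logical; also count confusion
#'   towards the neuropsychological category. Default `FALSE`.
#' @return Named list of character vectors, one per category.
#' @export
symptom_category_map <- function(confusion_in_neuropsychological = FALSE) {
  neuro <- c(
    "aggression", "agitation", "anxiety", "apathy", "delirium", "delusion",
    "depression", "hallucinations", "sleep", "eating", "paranoia",
    "mood_disorders"
  )
  if (confusion_in_neuropsychological) neuro <- c(neuro, "confusion")
  list(
    memory = "memory",
    confusion = "confusion",
    neuropsychological = neuro,
    motor = c("difficulty_walking", "orientation")
  )
}

#' Symptom explanation map
#'
#' A post-diagnosis symptom record is only attributed to Alzheimer's disease
#' if it cannot be explained by a comorbidity recorded before that symptom
#' (for example a depression symptom in a patient with a previous diagnosis
#' of depression). The default map covers the symptom/comorbidity name
#' collisions in the default dictionaries.
#'
#' @return Named list: symptom name -> character vector of comorbidity names
#'   that explain it.
#' @export
default_explanation_map <- function() {
  list(
    depression = "depression",
    anxiety = "anxiety",
    mood_disorders = "depression"
  )
}

#' Default age bands at diagnosis
#'
#' Quintile edges of age at diagnosis in the source cohort: 42-73, 74-78,
#' 79-82, 83-87, 88+. Returned as `cut()` breaks plus labels. Ages below the
#' first edge fall into the first band.
#'
#' @return List with `breaks` (length 6 numeric) and `labels` (length 5).
#' @export
default_age_bands <- function() {
  list(
    breaks = c(-Inf, 73, 78, 82, 87, Inf),
    labels = c("42-73", "74-78", "79-82", "83-87", "88+")
  )
}

#' Demographic factor levels
#'
#' Levels used for one-hot encoding the demographic parent variables.
#' Missing smoking status is interpreted as "non-smoker"; missing drinking
#' status maps to its own "not specified" level, which is part of the
#' drinking phenotype itself.
#'
#' @return Named list of character vectors.
#' @export
demographic_levels <- function() {
  list(
    gender = c("female", "male"),
    smoking = c("non-smoker", "ex-smoker", "current smoker"),
    drinking = c("non-drinker", "ex-drinker", "occasional drinker",
                 "current drinker", "drinking status not specified")
  )
}

#' Default study window
#'
#' @return Date vector of length 2 (start, end).
#' @export
default_study_window <- function() {
  as.Date(c("1997-01-01", "2016-06-30"))
}
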