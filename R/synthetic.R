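## Synthetic EHR cohort generator: raw event tables with planted latent
## subtypes, plus class-dependent clinical outcomes. Everything downstream
## (feature construction, clustering, evaluation) runs off these tables in
## exactly the schema a real extract would use.

#' Generate a synthetic EHR cohort with planted latent subtypes
#'
#' Draws `n_patients` patients from the mixture defined by `profiles` and
#' emits raw longitudinal event records: one diagnosis event (`dx:AD`) per
#' patient, comorbidity events (`cm:*`) dated strictly before diagnosis, and
#' raw symptom events (`sx:*`) dated strictly after diagnosis, so that the
#' temporal attribution rules of the feature-construction stage are
#' exercised end to end. A configurable fraction of patients additionally
#' receive a "contaminating" pre-diagnosis comorbidity record that explains
#' one of their post-diagnosis symptoms (e.g. a depression diagnosis before
#' a depression symptom), exercising the explained-symptom rule.
#'
#' Symptom-category draws are realised as a raw symptom code from that
#' category, chosen among codes not explained by the patient's own
#' pre-diagnosis comorbidities so that observed category prevalence tracks
#' the profile probabilities.
#'
#' @param profiles list of [subtype_profile()] objects; weights must sum to 1.
#' @param n_patients number of patients (>= 1).
#' @param n_practices number of primary-care practices (>= 2); patients are
#'   assigned to practices uniformly at random.
#' @param seed integer RNG seed; the cohort is bit-identical for a fixed seed.
#' @param study_window Date vector (start, end); all events fall inside it
#'   and diagnoses leave at least `margin_years` on either side.
#' @param margin_years guaranteed follow-up before and after diagnosis, years.
#' @param contamination_fraction fraction of patients eligible for a
#'   contaminating explained-symptom record. Default 0.05.
#'
#' @return An object of class `synthetic_cohort`: list with `events`
#'   (patient_id, code, date), `demographics` (patient_id, birth_year,
#'   gender, practice_id, smoking, drinking; smoking/drinking may be `NA`),
#'   `truth` (patient_id, class_id), and the call parameters.
#' @seealso [generate_outcomes()], [write_cohort()]
#' @export
#' @examples
#' ch <- generate_cohort(default_profiles(), n_patients = 50,
#'                       n_practices = 4, seed = 1)
#' table(ch$truth$class_id)
generate_cohort <- function(profiles, n_patients, n_practices, seed,
                            study_window = default_study_window(),
                            margin_years = 1.5,
                            contamination_fraction = 0.05) {
  validate_profiles(profiles)
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  if (!is.numeric(n_practices) || n_practices < 2)
    stop("n_practices must be >= 2", call. = FALSE)
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must be in [0, 1]", call. = FALSE)
  n <- as.integer(n_patients)
  set.seed(as.integer(seed))

  w <- vapply(profiles, `[[`, numeric(1), "mixing_weight")
  ids <- vapply(profiles, `[[`, integer(1), "class_id")
  cls_idx <- sample.int(length(profiles), n, replace = TRUE, prob = w)
  class_id <- ids[cls_idx]

  pid <- sprintf("pt%06d", seq_len(n))
  practice <- sprintf("pr%03d", sample.int(n_practices, n, replace = TRUE))

  win <- as.Date(study_window)
  margin <- round(margin_years * 365.25)
  lo <- as.numeric(win[1]) + margin
  hi <- as.numeric(win[2]) - margin
  if (hi <= lo) stop("study window too short for margin", call. = FALSE)
  dx_date <- as.Date(round(stats::runif(n, lo, hi)), origin = "1970-01-01")

  bands <- default_age_bands()
  band_lo <- c(42, 74, 79, 83, 88)
  band_hi <- c(73, 78, 82, 87, 95)
  age <- integer(n)
  gender <- character(n)
  smoking <- character(n)
  drinking <- character(n)
  lv <- demographic_levels()
  smoking_lv <- c(lv$smoking, NA)
  drinking_lv <- c(lv$drinking[1:4], NA)
  for (j in seq_along(profiles)) {
    sel <- which(cls_idx == j)
    if (!length(sel)) next
    p <- profiles[[j]]
    b <- sample.int(5, length(sel), replace = TRUE, prob = p$age_probs)
    age[sel] <- band_lo[b] +
      floor(stats::runif(length(sel)) * (band_hi[b] - band_lo[b] + 1))
    gender[sel] <- ifelse(stats::runif(length(sel)) < p$gender_prob_female,
                          "female", "male")
    smoking[sel] <- smoking_lv[sample.int(4, length(sel), replace = TRUE,
                                          prob = p$smoking_probs)]
    drinking[sel] <- drinking_lv[sample.int(5, length(sel), replace = TRUE,
                                            prob = p$drinking_probs)]
  }
  birth_year <- as.integer(format(dx_date, "%Y")) - age

  ## events -----------------------------------------------------------------
  cm_map <- default_comorbidity_map()
  cm_names <- unname(cm_map)
  sx_cat <- symptom_category_map()
  expl <- default_explanation_map()

  ev_pid <- list(pid)
  ev_code <- list(rep("dx:AD", n))
  ev_date <- list(dx_date)

  ## comorbidity events: uniform in [window start, diagnosis)
  cm_flag <- matrix(FALSE, n, length(cm_names),
                    dimnames = list(NULL, cm_names))
  for (j in seq_along(profiles)) {
    sel <- which(cls_idx == j)
    if (!length(sel)) next
    pr <- profiles[[j]]$comorbidity_probs[cm_names]
    cm_flag[sel, ] <- matrix(
      stats::runif(length(sel) * length(cm_names)) <
        rep(pr, each = length(sel)),
      nrow = length(sel)
    )
  }
  for (cm in cm_names) {
    sel <- which(cm_flag[, cm])
    if (!length(sel)) next
    d <- as.Date(
      floor(stats::runif(length(sel), as.numeric(win[1]),
                         as.numeric(dx_date[sel]))),
      origin = "1970-01-01"
    )
    ev_pid <- c(ev_pid, list(pid[sel]))
    ev_code <- c(ev_code, list(rep(paste0("cm:", cm), length(sel))))
    ev_date <- c(ev_date, list(d))
  }

  ## symptom events: category draw realised as one raw code, dated after dx
  cats <- names(sx_cat)
  sx_flag <- matrix(FALSE, n, length(cats), dimnames = list(NULL, cats))
  for (j in seq_along(profiles)) {
    sel <- which(cls_idx == j)
    if (!length(sel)) next
    pr <- profiles[[j]]$symptom_probs[cats]
    sx_flag[sel, ] <- matrix(
      stats::runif(length(sel) * length(cats)) <
        rep(pr, each = length(sel)),
      nrow = length(sel)
    )
  }
  explained_by_own <- function(i, code_pool) {
    ## raw codes in the pool explained by patient i's own comorbidities
    bad <- vapply(code_pool, function(s) {
      e <- expl[[s]]
      !is.null(e) && any(cm_flag[i, e])
    }, logical(1))
    code_pool[!bad]
  }
  sx_rows_pid <- character(0); sx_rows_code <- character(0)
  sx_rows_date <- numeric(0)
  for (cat in cats) {
    pool0 <- sx_cat[[cat]]
    sel <- which(sx_flag[, cat])
    if (!length(sel)) next
    for (i in sel) {
      pool <- explained_by_own(i, pool0)
      if (!length(pool)) pool <- pool0  # fall back; rare
      code <- if (length(pool) == 1L) pool else
        pool[sample.int(length(pool), 1L)]
      d <- floor(stats::runif(1, as.numeric(dx_date[i]) + 1,
                              as.numeric(win[2]) + 1))
      sx_rows_pid <- c(sx_rows_pid, pid[i])
      sx_rows_code <- c(sx_rows_code, paste0("sx:", code))
      sx_rows_date <- c(sx_rows_date, d)
    }
  }
  ev_pid <- c(ev_pid, list(sx_rows_pid))
  ev_code <- c(ev_code, list(sx_rows_code))
  ev_date <- c(ev_date, list(as.Date(sx_rows_date, origin = "1970-01-01")))

  ## contamination: pre-diagnosis comorbidity explaining one symptom
  contam <- which(stats::runif(n) < contamination_fraction)
  add_pid <- character(0); add_code <- character(0); add_date <- numeric(0)
  for (i in contam) {
    ## pick a symptom this patient has whose explanation is a comorbidity
    cand <- names(expl)[vapply(names(expl), function(s) {
      cat <- cats[vapply(sx_cat, function(p) s %in% p, logical(1))][1]
      !is.na(cat) && sx_flag[i, cat]
    }, logical(1))]
    if (!length(cand)) next
    s <- cand[1]
    cm <- expl[[s]][1]
    if (cm_flag[i, cm]) next  # already has it
    ## ensure the symptom event emitted for patient i is the explained code
    k <- which(sx_rows_pid == pid[i] &
                 sx_rows_code %in% paste0("sx:", sx_cat[["neuropsychological"]]))
    if (length(k)) sx_rows_code[k[1]] <- paste0("sx:", s)
    add_pid <- c(add_pid, pid[i])
    add_code <- c(add_code, paste0("cm:", cm))
    add_date <- c(add_date,
                  floor(stats::runif(1, as.numeric(win[1]),
                                     as.numeric(dx_date[i]))))
    cm_flag[i, cm] <- TRUE
  }
  ## rebuild symptom event block (codes may have been rewritten)
  ev_code[[length(ev_code)]] <- sx_rows_code
  if (length(add_pid)) {
    ev_pid <- c(ev_pid, list(add_pid))
    ev_code <- c(ev_code, list(add_code))
    ev_date <- c(ev_date, list(as.Date(add_date, origin = "1970-01-01")))
  }

  events <- data.frame(
    patient_id = unlist(ev_pid),
    code = unlist(ev_code),
    date = as.Date(unlist(lapply(ev_date, as.numeric)), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$patient_id, events$date, events$code), ]
  rownames(events) <- NULL

  demographics <- data.frame(
    patient_id = pid, birth_year = birth_year, gender = gender,
    practice_id = practice, smoking = smoking, drinking = drinking,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      events = events,
      demographics = demographics,
      truth = data.frame(patient_id = pid, class_id = class_id,
                         stringsAsFactors = FALSE),
      study_window = win,
      n_practices = as.integer(n_practices),
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$demographics), "patients,",
      nrow(x$events), "events,",
      length(unique(x$demographics$practice_id)), "practices\n")
  cat("Planted classes:",
      paste(sprintf("%d (n=%d)", as.integer(names(table(x$truth$class_id))),
                    as.integer(table(x$truth$class_id))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generate class-dependent clinical outcomes for a synthetic cohort
#'
#' Draws the five clinical outcomes used for cluster validation:
#' a per-patient MMSE series (one visit just before diagnosis, then annual
#' visits; score = baseline - rate * t + Gaussian measurement noise, with the
#' latent rate drawn from the patient's class), time to assisted living and
#' time to death (exponential hazards, right-censored at end of follow-up),
#' consultation and missed-appointment counts (Poisson), and time on
#' cholinesterase inhibitors (normal around the class mean, truncated at 0
#' and censored at end of follow-up).
#'
#' @param cohort a `synthetic_cohort`.
#' @param profiles the profile list used to generate it.
#' @param followup_years follow-up after diagnosis, years (> 0).
#' @param seed integer RNG seed.
#' @param mmse_baseline mean MMSE at diagnosis (default 26, mild-stage).
#' @param mmse_noise_sd per-visit measurement noise SD, points. Default 1.
#' @param chei_sd SD of ChEI duration around the class mean, years.
#' @param missed_fraction missed appointments as a fraction of the
#'   consultation rate. Default 0.15.
#'
#' @return List of class `synthetic_outcomes` with `visits` (patient_id,
#'   t_years, mmse) and `table`, a per-patient data frame: class_id,
#'   true_decline_rate, time_to_assisted_living + al_event,
#'   time_to_death + death_event, consultations_per_year, missed_per_year,
#'   chei_duration + chei_event.
#' @export
generate_outcomes <- function(cohort, profiles, followup_years = 5, seed = 1,
                              mmse_baseline = 26, mmse_noise_sd = 1,
                              chei_sd = 0.5, missed_fraction = 0.15) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.numeric(followup_years) || followup_years <= 0)
    stop("followup_years must be > 0", call. = FALSE)
  validate_profiles(profiles)
  set.seed(as.integer(seed))

  ids <- vapply(profiles, `[[`, integer(1), "class_id")
  cls <- match(cohort$truth$class_id, ids)
  if (anyNA(cls)) stop("cohort classes not covered by profiles", call. = FALSE)
  n <- length(cls)
  C <- followup_years

  mean_r <- vapply(profiles, `[[`, numeric(1), "mmse_decline_mean")[cls]
  sd_r <- vapply(profiles, `[[`, numeric(1), "mmse_decline_sd")[cls]
  rate <- stats::rnorm(n, mean_r, sd_r)

  ## MMSE visits: one pre-diagnosis, then annual to end of follow-up
  tt <- c(-0.1, seq_len(max(2, floor(C))))
  tt <- tt[tt <= C]
  visits <- data.frame(
    patient_id = rep(cohort$truth$patient_id, each = length(tt)),
    t_years = rep(tt, n),
    stringsAsFactors = FALSE
  )
  mu <- mmse_baseline - rep(rate, each = length(tt)) * visits$t_years
  visits$mmse <- mu + stats::rnorm(nrow(visits), 0, mmse_noise_sd)

  h_al <- vapply(profiles, `[[`, numeric(1), "assisted_living_hazard")[cls]
  h_dt <- vapply(profiles, `[[`, numeric(1), "mortality_hazard")[cls]
  t_al <- stats::rexp(n, h_al)
  t_dt <- stats::rexp(n, h_dt)
  crate <- vapply(profiles, `[[`, numeric(1), "consultation_rate")[cls]
  consult <- stats::rpois(n, crate * C)
  missed <- stats::rpois(n, missed_fraction * crate * C)
  chei_mu <- vapply(profiles, `[[`, numeric(1), "chei_duration_mean")[cls]
  chei <- pmax(0, stats::rnorm(n, chei_mu, chei_sd))

  tab <- data.frame(
    patient_id = cohort$truth$patient_id,
    class_id = cohort$truth$class_id,
    true_decline_rate = rate,
    time_to_assisted_living = pmin(t_al, C),
    al_event = t_al <= C,
    time_to_death = pmin(t_dt, C),
    death_event = t_dt <= C,
    consultations_per_year = consult / C,
    missed_per_year = missed / C,
    chei_duration = pmin(chei, C),
    chei_event = chei <= C,
    stringsAsFactors = FALSE
  )
  structure(list(visits = visits, table = tab, followup_years = C,
                 seed = as.integer(seed)),
            class = "synthetic_outcomes")
}

#' Write / read a synthetic cohort as delimited text
#'
#' `write_cohort()` writes `events.csv`, `demographics.csv` and `truth.csv`
#' (ISO-8601 dates) into `dir`; `read_cohort()` reads them back into the
#' schema consumed by [select_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: list with
#'   `events`, `demographics`, `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  ev$date <- as.Date(ev$date)
  dm <- utils::read.csv(file.path(dir, "demographics.csv"),
                        stringsAsFactors = FALSE)
  tr_path <- file.path(dir, "truth.csv")
  tr <- if (file.exists(tr_path))
    utils::read.csv(tr_path, stringsAsFactors = FALSE) else NULL
  list(events = ev, demographics = dm, truth = tr)
}
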