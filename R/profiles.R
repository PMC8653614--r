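## Subtype profiles: the generative description of one latent patient class
## used by the synthetic cohort generator.

#' Construct a latent subtype profile
#'
#' A subtype profile fully describes one latent patient class for the
#' synthetic cohort generator: its mixing weight, per-comorbidity and
#' per-symptom-category Bernoulli probabilities, demographic distributions,
#' and the parameters of its class-dependent clinical outcomes.
#'
#' @param class_id integer class identifier (unique across a profile set).
#' @param mixing_weight probability of a patient belonging to this class;
#'   weights over a profile set must sum to 1.
#' @param comorbidity_probs named numeric vector of Bernoulli probabilities,
#'   names from `default_comorbidity_map()`.
#' @param symptom_probs named numeric vector over the four symptom
#'   categories `memory`, `confusion`, `neuropsychological`, `motor`.
#' @param age_probs numeric length-5 distribution over the age bands of
#'   `default_age_bands()`; must sum to 1.
#' @param gender_prob_female probability of female gender.
#' @param smoking_probs numeric length-4 distribution over
#'   (non-smoker, ex-smoker, current smoker, missing); must sum to 1.
#' @param drinking_probs numeric length-5 distribution over (non-drinker,
#'   ex-drinker, occasional drinker, current drinker, missing); must sum to 1.
#' @param mmse_decline_mean mean MMSE decline, points/year (positive =
#'   decline).
#' @param mmse_decline_sd between-patient SD of the decline rate,
#'   points/year.
#' @param assisted_living_hazard exponential hazard (events/year) of moving
#'   to assisted living; strictly positive.
#' @param mortality_hazard exponential all-cause mortality hazard
#'   (events/year); strictly positive.
#' @param consultation_rate Poisson rate of GP consultations, visits/year.
#' @param chei_duration_mean mean time on cholinesterase inhibitors, years.
#'
#' @return An object of class `subtype_profile`.
#' @seealso [default_profiles()], [generate_cohort()]
#' @export
subtype_profile <- function(class_id, mixing_weight,
                            comorbidity_probs, symptom_probs, age_probs,
                            gender_prob_female, smoking_probs, drinking_probs,
                            mmse_decline_mean, mmse_decline_sd,
                            assisted_living_hazard, mortality_hazard,
                            consultation_rate, chei_duration_mean) {
  p <- structure(
    list(
      class_id = as.integer(class_id),
      mixing_weight = mixing_weight,
      comorbidity_probs = comorbidity_probs,
      symptom_probs = symptom_probs,
      age_probs = age_probs,
      gender_prob_female = gender_prob_female,
      smoking_probs = smoking_probs,
      drinking_probs = drinking_probs,
      mmse_decline_mean = mmse_decline_mean,
      mmse_decline_sd = mmse_decline_sd,
      assisted_living_hazard = assisted_living_hazard,
      mortality_hazard = mortality_hazard,
      consultation_rate = consultation_rate,
      chei_duration_mean = chei_duration_mean
    ),
    class = "subtype_profile"
  )
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "subtype_profile"))
  probs01 <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(what, ": probabilities must lie in [0, 1]", call. = FALSE)
  }
  sums1 <- function(x, what) {
    probs01(x, what)
    if (abs(sum(x) - 1) > 1e-9)
      stop(what, ": distribution must sum to 1", call. = FALSE)
  }
  comorb <- unname(default_comorbidity_map())
  if (!all(comorb %in% names(p$comorbidity_probs)))
    stop("comorbidity_probs must be named over the default comorbidities",
         call. = FALSE)
  probs01(p$comorbidity_probs, "comorbidity_probs")
  cats <- names(symptom_category_map())
  if (!all(cats %in% names(p$symptom_probs)))
    stop("symptom_probs must cover the four symptom categories", call. = FALSE)
  probs01(p$symptom_probs, "symptom_probs")
  probs01(p$gender_prob_female, "gender_prob_female")
  probs01(p$mixing_weight, "mixing_weight")
  sums1(p$age_probs, "age_probs")
  sums1(p$smoking_probs, "smoking_probs")
  sums1(p$drinking_probs, "drinking_probs")
  pos <- c(assisted_living_hazard = p$assisted_living_hazard,
           mortality_hazard = p$mortality_hazard,
           consultation_rate = p$consultation_rate,
           chei_duration_mean = p$chei_duration_mean)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("hazards and rates must be strictly positive", call. = FALSE)
  if (!is.finite(p$mmse_decline_sd) || p$mmse_decline_sd < 0)
    stop("mmse_decline_sd must be non-negative", call. = FALSE)
  invisible(p)
}

#' Validate a set of subtype profiles
#'
#' Checks each profile and that mixing weights sum to 1 (within 1e-9) with
#' unique class ids.
#'
#' @param profiles list of `subtype_profile` objects.
#' @return The profiles, invisibly.
#' @export
validate_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  lapply(profiles, validate_profile)
  w <- vapply(profiles, `[[`, numeric(1), "mixing_weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixing weights must sum to 1 (got ", format(sum(w)), ")",
         call. = FALSE)
  ids <- vapply(profiles, `[[`, integer(1), "class_id")
  if (anyDuplicated(ids)) stop("class ids must be unique", call. = FALSE)
  invisible(profiles)
}

#' @export
print.subtype_profile <- function(x, ...) {
  cat("Subtype profile", x$class_id,
      sprintf("(weight %.3f)\n", x$mixing_weight))
  cat("  MMSE decline:", x$mmse_decline_mean, "+/-", x$mmse_decline_sd,
      "pts/yr; AL hazard", x$assisted_living_hazard,
      "/yr; mortality", x$mortality_hazard, "/yr\n")
  invisible(x)
}

## shared helper: a comorbidity probability vector at cohort-like baseline
## levels, with named overrides
comorb_probs <- function(...) {
  base <- c(
    anxiety = 0.08, atherosclerosis = 0.04, atrial_fibrillation = 0.08,
    cancer = 0.10, depression = 0.10, diabetes = 0.15,
    haemorrhagic_stroke = 0.02, hearing_loss = 0.35, heart_failure = 0.05,
    hyperglycaemia = 0.05, hypertension = 0.20, kidney_disease = 0.29,
    rheumatoid_arthritis = 0.03
  )
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

#' Default five-class subtype configuration
#'
#' A five-profile configuration emulating the subtype structure reported in
#' UK primary-care Alzheimer's cohorts: (1) an anxiety/depression, early
#' onset, smoking class with roughly three times the typical MMSE decline
#' rate; (2) a typical-AD class with high hypertension; (3) a typical-AD
#' class with high cancer prevalence, mostly male; (4) a non-typical class
#' (high confusion, neuropsychological and motor symptoms, relatively spared
#' memory); (5) a cardiovascular-disease class. Non-signature comorbidities
#' sit at cohort-like baseline prevalences, so these profiles emulate the
#' noisy regime of real primary-care data; for the strongly separated
#' regime used in recovery benchmarks see [separated_profiles()].
#'
#' All distributional choices are synthetic stand-ins: no generative model of
#' the real cohort exists, so these defaults reproduce reported prevalence
#' patterns and outcome orderings, not any real-data likelihood.
#'
#' @return List of five `subtype_profile` objects.
#' @export
#' @examples
#' profs <- default_profiles()
#' sum(vapply(profs, `[[`, numeric(1), "mixing_weight"))
default_profiles <- function() {
  sym <- function(memory, confusion, neuropsychological, motor) {
    c(memory = memory, confusion = confusion,
      neuropsychological = neuropsychological, motor = motor)
  }
  smoking_base <- c(0.50, 0.33, 0.07, 0.10)
  drinking_base <- c(0.28, 0.07, 0.17, 0.01, 0.47)
  list(
    # anxiety / depression / early onset / smoking; fastest progression
    subtype_profile(
      class_id = 1L, mixing_weight = 0.13,
      comorbidity_probs = comorb_probs(depression = 0.90, anxiety = 0.85),
      symptom_probs = sym(0.70, 0.15, 0.90, 0.05),
      age_probs = c(0.55, 0.20, 0.10, 0.10, 0.05),
      gender_prob_female = 0.75,
      smoking_probs = c(0.18, 0.17, 0.60, 0.05),
      drinking_probs = c(0.15, 0.05, 0.25, 0.30, 0.25),
      mmse_decline_mean = 3.0, mmse_decline_sd = 0.3,
      assisted_living_hazard = 0.30, mortality_hazard = 0.10,
      consultation_rate = 8, chei_duration_mean = 1.5
    ),
    # typical AD with hypertension (and kidney disease, which co-travels
    # with hypertension in reported latent-class solutions)
    subtype_profile(
      class_id = 2L, mixing_weight = 0.27,
      comorbidity_probs = comorb_probs(hypertension = 0.90,
                                       kidney_disease = 0.60),
      symptom_probs = sym(0.90, 0.10, 0.15, 0.02),
      age_probs = c(0.15, 0.22, 0.25, 0.22, 0.16),
      gender_prob_female = 0.70,
      smoking_probs = smoking_base,
      drinking_probs = drinking_base,
      mmse_decline_mean = 1.0, mmse_decline_sd = 0.3,
      assisted_living_hazard = 0.08, mortality_hazard = 0.10,
      consultation_rate = 4, chei_duration_mean = 3.0
    ),
    # typical AD with cancer (and hearing loss), mostly male
    subtype_profile(
      class_id = 3L, mixing_weight = 0.20,
      comorbidity_probs = comorb_probs(cancer = 0.90, hearing_loss = 0.70),
      symptom_probs = sym(0.90, 0.10, 0.15, 0.02),
      age_probs = c(0.10, 0.20, 0.25, 0.25, 0.20),
      gender_prob_female = 0.35,
      smoking_probs = smoking_base,
      drinking_probs = drinking_base,
      mmse_decline_mean = 1.0, mmse_decline_sd = 0.3,
      assisted_living_hazard = 0.08, mortality_hazard = 0.20,
      consultation_rate = 5, chei_duration_mean = 3.0
    ),
    # non-typical AD: broad non-memory symptoms, spared memory
    subtype_profile(
      class_id = 4L, mixing_weight = 0.22,
      comorbidity_probs = comorb_probs(),
      symptom_probs = sym(0.25, 0.85, 0.90, 0.65),
      age_probs = c(0.10, 0.15, 0.20, 0.25, 0.30),
      gender_prob_female = 0.70,
      smoking_probs = smoking_base,
      drinking_probs = drinking_base,
      mmse_decline_mean = 1.5, mmse_decline_sd = 0.3,
      assisted_living_hazard = 0.25, mortality_hazard = 0.15,
      consultation_rate = 7, chei_duration_mean = 2.0
    ),
    # cardiovascular disease class (hypertension spared, per reported
    # separation of hypertension from the CVD cluster)
    subtype_profile(
      class_id = 5L, mixing_weight = 0.18,
      comorbidity_probs = comorb_probs(
        atrial_fibrillation = 0.85, heart_failure = 0.80,
        atherosclerosis = 0.70, haemorrhagic_stroke = 0.40,
        hypertension = 0.15
      ),
      symptom_probs = sym(0.75, 0.20, 0.25, 0.10),
      age_probs = c(0.05, 0.15, 0.20, 0.25, 0.35),
      gender_prob_female = 0.55,
      smoking_probs = smoking_base,
      drinking_probs = drinking_base,
      mmse_decline_mean = 1.2, mmse_decline_sd = 0.3,
      assisted_living_hazard = 0.15, mortality_hazard = 0.25,
      consultation_rate = 6, chei_duration_mean = 2.5
    )
  )
}

#' Strongly separated five-class configuration
#'
#' A five-class configuration in the strongly separated regime used for
#' parameter-recovery checks: every class carries a block of signature
#' features at probability 0.9 against baselines of at most 0.10, so every
#' pair of classes differs on several parent variables with probability
#' gaps of at least 0.6 (most around 0.8). Non-signature prevalences and
#' the shared demographic distributions are kept close to deterministic so
#' that planted structure, not baseline noise, dominates the geometry. In
#' this regime the pipeline (MCA then k-means with k-selection) is expected
#' to choose k = 5 and recover the planted partition with adjusted Rand
#' index above 0.9 at n = 2,000.
#'
#' The class themes mirror [default_profiles()] (anxiety/depression early
#' onset; typical + hypertension/kidney; typical + cancer/hearing loss,
#' mostly male; non-typical; cardiovascular), as do the outcome parameters.
#'
#' @return List of five `subtype_profile` objects.
#' @export
separated_profiles <- function() {
  base <- c(
    anxiety = 0.05, atherosclerosis = 0.04, atrial_fibrillation = 0.05,
    cancer = 0.06, depression = 0.06, diabetes = 0.08,
    haemorrhagic_stroke = 0.02, hearing_loss = 0.10, heart_failure = 0.04,
    hyperglycaemia = 0.04, hypertension = 0.10, kidney_disease = 0.08,
    rheumatoid_arthritis = 0.03
  )
  drink <- c(0.10, 0.05, 0.05, 0.05, 0.75)
  smoke <- c(0.70, 0.20, 0.05, 0.05)
  mk <- function(id, w, ov, sym, age, pf, smokep = smoke) {
    cp <- base
    cp[names(ov)] <- ov
    subtype_profile(
      id, w, cp, sym, age, pf, smokep, drink,
      mmse_decline_mean = c(3, 1, 1, 1.5, 1.2)[id], mmse_decline_sd = 0.3,
      assisted_living_hazard = c(0.30, 0.08, 0.08, 0.25, 0.15)[id],
      mortality_hazard = c(0.10, 0.10, 0.20, 0.15, 0.25)[id],
      consultation_rate = c(8, 4, 5, 7, 6)[id],
      chei_duration_mean = c(1.5, 3, 3, 2, 2.5)[id]
    )
  }
  sy <- function(m, c, n, mo)
    c(memory = m, confusion = c, neuropsychological = n, motor = mo)
  list(
    mk(1L, 0.13, c(depression = 0.9, anxiety = 0.9),
       sy(0.70, 0.10, 0.90, 0.05), c(0.60, 0.20, 0.10, 0.07, 0.03), 0.75,
       c(0.10, 0.10, 0.75, 0.05)),
    mk(2L, 0.27, c(hypertension = 0.9, kidney_disease = 0.9),
       sy(0.90, 0.05, 0.10, 0.02), c(0.15, 0.22, 0.25, 0.22, 0.16), 0.70),
    mk(3L, 0.20, c(cancer = 0.9, hearing_loss = 0.9),
       sy(0.90, 0.05, 0.10, 0.02), c(0.10, 0.20, 0.25, 0.25, 0.20), 0.25),
    mk(4L, 0.22, c(),
       sy(0.15, 0.90, 0.90, 0.70), c(0.10, 0.15, 0.20, 0.25, 0.30), 0.70),
    mk(5L, 0.18, c(atrial_fibrillation = 0.9, heart_failure = 0.9,
                   atherosclerosis = 0.9, haemorrhagic_stroke = 0.85),
       sy(0.80, 0.10, 0.15, 0.10), c(0.05, 0.15, 0.20, 0.25, 0.35), 0.55)
  )
}
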