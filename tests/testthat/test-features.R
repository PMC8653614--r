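make_demo <- function(ids, practice = "pr01", birth_year = 1940,
                      gender = "female") {
  data.frame(patient_id = ids, birth_year = birth_year, gender = gender,
             practice_id = practice, smoking = NA_character_,
             drinking = NA_character_, stringsAsFactors = FALSE)
}

test_that("cohort inclusion rules exclude the right patients", {
  win <- as.Date(c("1997-01-01", "2016-06-30"))
  ev <- data.frame(
    patient_id = c("young", "late", "ok", "nodx", "noclin", "nogender"),
    code = "dx:AD",
    date = as.Date(c("2005-06-01", "2016-01-15", "2005-06-01",
                     "2005-06-01", "2005-06-01", "2005-06-01")),
    stringsAsFactors = FALSE
  )
  ev$code[ev$patient_id == "nodx"] <- "cm:cancer"
  clin <- data.frame(
    patient_id = c("young", "late", "ok", "nogender"),
    code = "cm:cancer",
    date = as.Date("2000-01-01"), stringsAsFactors = FALSE
  )
  ev <- rbind(ev, clin)
  dm <- make_demo(unique(ev$patient_id))
  dm$birth_year[dm$patient_id == "young"] <- 1967  # age 38 at diagnosis
  dm$gender[dm$patient_id == "nogender"] <- NA
  cohort <- select_cohort(ev, dm, win)
  expect_setequal(cohort$patient_id, "ok")
  expect_equal(cohort$observation_start, win[1])
  expect_equal(cohort$observation_end, win[2])
  excl <- attr(cohort, "exclusions")
  expect_equal(unname(excl["age_below_minimum"]), 1)
  expect_equal(unname(excl["insufficient_followup"]), 1)
  # diagnosis six months before window end: excluded by follow-up rule
  expect_false("late" %in% cohort$patient_id)
})

test_that("empty input gives an empty cohort, not an error", {
  out <- select_cohort(data.frame(patient_id = character(0),
                                  code = character(0), date = character(0)),
                       make_demo(character(0)))
  expect_s3_class(out, "cohort_table")
  expect_equal(nrow(out), 0)
})

test_that("malformed event dates are dropped row-wise with a count", {
  ev <- data.frame(
    patient_id = c("a", "a", "a"),
    code = c("dx:AD", "cm:cancer", "cm:diabetes"),
    date = c("2005-06-01", "not-a-date", "2000-01-01"),
    stringsAsFactors = FALSE
  )
  expect_message(
    cohort <- suppressWarnings(select_cohort(ev, make_demo("a"))),
    "malformed")
  expect_equal(cohort$patient_id, "a")
})

test_that("symptom attribution honours the two temporal conditions", {
  dx <- as.Date("2005-06-01")
  # depression symptom after diagnosis, but prior depression comorbidity
  ev <- one_patient_events(
    c("cm:depression", "sx:depression", "sx:hallucinations", "sx:memory"),
    c("2003-01-01", "2006-01-01", "2006-02-01", "2004-01-01")
  )
  flags <- attribute_symptoms(ev, dx)
  expect_false(flags["depression"])     # explained by prior comorbidity
  expect_true(flags["hallucinations"])  # no explaining disease
  expect_false(flags["memory"])         # recorded before diagnosis only
  # symptom coded on the diagnosis day is not attributed (strict inequality)
  ev2 <- one_patient_events("sx:memory", "2005-06-01")
  expect_false(attribute_symptoms(ev2, dx)["memory"])
  # explaining comorbidity recorded between diagnosis and symptom also blocks
  ev3 <- one_patient_events(c("sx:anxiety", "cm:anxiety"),
                            c("2007-01-01", "2006-01-01"))
  expect_false(attribute_symptoms(ev3, dx)["anxiety"])
})

test_that("attribution is monotone in the explaining comorbidities", {
  # removing an explaining comorbidity can flip flags only 0 -> 1
  set.seed(42)
  dx <- as.Date("2005-06-01")
  for (rep in 1:20) {
    codes <- sample(c(names(default_symptom_map()),
                      names(default_comorbidity_map())), 8, replace = TRUE)
    dates <- as.Date("2000-01-01") + sample.int(4000, 8)
    ev <- one_patient_events(codes, dates)
    full <- attribute_symptoms(ev, dx)
    ev_wo <- ev[!grepl("^cm:", ev$code), ]
    reduced <- attribute_symptoms(ev_wo, dx)
    expect_true(all(reduced >= full))
  }
})

test_that("symptom grouping follows the four-category dictionary", {
  flags <- stats::setNames(rep(FALSE, 21), unname(default_symptom_map()))
  f <- flags; f["apathy"] <- TRUE
  g <- group_symptoms(f)
  expect_equal(unname(g[c("memory", "confusion", "neuropsychological",
                          "motor")]), c(FALSE, FALSE, TRUE, FALSE))
  f <- flags; f["difficulty_walking"] <- TRUE
  expect_true(group_symptoms(f)["motor"])
  expect_false(any(group_symptoms(flags)))
  # confusion stays out of neuropsychological by default, switchable
  f <- flags; f["confusion"] <- TRUE
  expect_false(group_symptoms(f)["neuropsychological"])
  expect_true(group_symptoms(f, confusion_in_neuropsychological = TRUE)[
    "neuropsychological"])
  # unknown names are a configuration error
  expect_error(group_symptoms(c(wandering = TRUE)), "wandering")
})

test_that("feature matrix has 21 parents and valid one-hot groups", {
  ch <- generate_cohort(default_profiles(), 250, 5, seed = 11)
  fx <- extract_features(ch$events, ch$demographics)
  fm <- fx$features
  expect_equal(n_parent_variables(fm), 21)
  expect_equal(sum(fm$meta$role == "symptom" &
                     !duplicated(fm$meta$parent[fm$meta$role == "symptom"])),
               4)
  expect_equal(length(unique(fm$meta$parent[fm$meta$role == "comorbidity"])),
               13)
  expect_true(all(fm$x %in% 0:1))
  # hypercholesterolemia is not in the default dictionary
  expect_false(any(grepl("hypercholesterolemia", fm$meta$column)))
  # each demographic one-hot group sums to exactly 1 per patient
  for (p in c("age_band", "gender", "smoking", "drinking")) {
    idx <- fm$meta$parent == p
    expect_true(all(rowSums(fm$x[, idx, drop = FALSE]) == 1))
  }
  # missing smoking/drinking handled per the coding rules
  miss <- is.na(ch$demographics$smoking)
  covered <- fm$patients %in% ch$demographics$patient_id[miss]
  expect_true(all(fm$x[covered, "smoking:non-smoker"] == 1))
})

test_that("a five-level categorical becomes five binary columns", {
  ch <- generate_cohort(default_profiles(), 100, 4, seed = 12)
  fm <- extract_features(ch$events, ch$demographics)$features
  expect_equal(sum(fm$meta$parent == "drinking"), 5)
  expect_equal(sum(fm$meta$parent == "age_band"), 5)
})

test_that("patients missing from demographics are a hard error", {
  ch <- generate_cohort(default_profiles(), 60, 3, seed = 13)
  fx <- extract_features(ch$events, ch$demographics)
  dm_miss <- ch$demographics[-1, ]
  raw <- symptom_flags(ch$events, fx$cohort)
  cats <- group_symptoms(raw)
  cms <- comorbidity_flags(ch$events, fx$cohort)
  expect_error(build_feature_matrix(fx$cohort, cats, cms,
                                    demographics = dm_miss),
               "absent from demographics")
})

test_that("practice split is by whole practices, disjoint and seeded", {
  ch <- generate_cohort(default_profiles(), 300, 8, seed = 14)
  fx <- extract_features(ch$events, ch$demographics)
  sp <- split_by_practice(fx$cohort, 0.25, seed = 3)
  expect_equal(length(sp$test_practices), ceiling(0.25 * 8))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), fx$cohort$patient_id)
  # all patients of a test practice are in the test set
  pr <- fx$cohort$practice_id[match(sp$test, fx$cohort$patient_id)]
  expect_true(all(pr %in% sp$test_practices))
  expect_identical(sp, split_by_practice(fx$cohort, 0.25, seed = 3))
  # 4 practices at fraction 0.25 -> exactly 1 test practice
  co4 <- fx$cohort[fx$cohort$practice_id %in%
                     unique(fx$cohort$practice_id)[1:4], ]
  expect_length(split_by_practice(co4, 0.25, seed = 1)$test_practices, 1)
  expect_error(split_by_practice(fx$cohort, 0), "test_fraction")
  co1 <- fx$cohort[fx$cohort$practice_id == fx$cohort$practice_id[1], ]
  expect_error(split_by_practice(co1, 0.25), "practices")
})

test_that("no retained patient is all-zero across one-hot groups", {
  ch <- generate_cohort(default_profiles(), 200, 5, seed = 15)
  fm <- extract_features(ch$events, ch$demographics)$features
  ind <- as_indicator_matrix(fm)
  expect_true(all(rowSums(ind$z) == 21))
  for (p in unique(ind$parent)) {
    expect_true(all(rowSums(ind$z[, ind$parent == p, drop = FALSE]) == 1))
  }
})
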