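test_that("profile validation rejects malformed configurations", {
  profs <- default_profiles()
  expect_silent(validate_profiles(profs))
  bad <- profs
  bad[[1]]$mixing_weight <- bad[[1]]$mixing_weight + 0.01
  expect_error(validate_profiles(bad), "sum to 1")
  bad <- profs
  bad[[2]]$comorbidity_probs["cancer"] <- 1.2
  expect_error(validate_profiles(bad), "\\[0, 1\\]")
  bad <- profs
  bad[[3]]$mortality_hazard <- 0
  expect_error(validate_profiles(bad), "strictly positive")
  expect_error(generate_cohort(profs, 0, 5, seed = 1), "n_patients")
  expect_error(generate_cohort(profs, 10, 1, seed = 1), "n_practices")
})

test_that("fixed seed reproduces the cohort and outcomes bit-identically", {
  a <- generate_cohort(default_profiles(), 120, 5, seed = 7)
  b <- generate_cohort(default_profiles(), 120, 5, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth, b$truth)
  oa <- generate_outcomes(a, default_profiles(), 5, seed = 3)
  ob <- generate_outcomes(b, default_profiles(), 5, seed = 3)
  expect_identical(oa$visits, ob$visits)
  expect_identical(oa$table, ob$table)
})

test_that("event structure matches the attribution contract", {
  ch <- generate_cohort(default_profiles(), 150, 6, seed = 2)
  ev <- ch$events
  # every patient appears in demographics and has a diagnosis
  expect_true(all(ev$patient_id %in% ch$demographics$patient_id))
  dx <- ev[ev$code == "dx:AD", ]
  expect_setequal(dx$patient_id, ch$demographics$patient_id)
  # comorbidities strictly before diagnosis, symptoms strictly after
  m <- merge(ev, dx[, c("patient_id", "date")], by = "patient_id",
             suffixes = c("", "_dx"))
  cm <- m[grepl("^cm:", m$code), ]
  sx <- m[grepl("^sx:", m$code), ]
  expect_true(all(cm$date < cm$date_dx))
  expect_true(all(sx$date > sx$date_dx))
  # all dates inside the study window
  expect_true(all(ev$date >= ch$study_window[1] &
                    ev$date <= ch$study_window[2]))
})

test_that("class proportions match mixing weights (goodness of fit)", {
  profs <- default_profiles()
  ch <- generate_cohort(profs, 5000, 20, seed = 1)
  w <- vapply(profs, `[[`, numeric(1), "mixing_weight")
  counts <- tabulate(ch$truth$class_id, length(w))
  gof <- suppressWarnings(stats::chisq.test(counts, p = w))
  expect_gt(gof$p.value, 0.01)
  # each class within 3 binomial SEs of its weight
  se <- sqrt(w * (1 - w) / 5000)
  expect_true(all(abs(counts / 5000 - w) < 3 * se + 1e-12))
})

test_that("a degenerate all-zero profile yields no clinical events", {
  p <- default_profiles()[[1]]
  p$mixing_weight <- 1
  p$comorbidity_probs[] <- 0
  p$symptom_probs[] <- 0
  ch <- generate_cohort(list(p), 60, 3, seed = 4,
                        contamination_fraction = 0)
  expect_false(any(grepl("^(cm:|sx:)", ch$events$code)))
})

test_that("a planted high-depression class shows matching prevalence", {
  profs <- default_profiles()
  # class 1 has depression prob 0.9; others ~0.1
  ch <- generate_cohort(profs, 2000, 10, seed = 5)
  dep <- unique(ch$events$patient_id[ch$events$code == "cm:depression"])
  in_class1 <- ch$truth$patient_id[ch$truth$class_id == 1]
  prev <- mean(in_class1 %in% dep)
  expect_gt(prev, 0.8)
})

test_that("survival outcomes follow the exponential event fraction", {
  p <- default_profiles()[[2]]
  p$mixing_weight <- 1
  profs <- list(p)
  ch <- generate_cohort(profs, 5000, 5, seed = 6)
  C <- 5
  out <- generate_outcomes(ch, profs, followup_years = C, seed = 6)
  for (v in c("mortality_hazard", "assisted_living_hazard")) {
    h <- p[[v]]
    expected <- 1 - exp(-h * C)
    ev <- if (v == "mortality_hazard") out$table$death_event else
      out$table$al_event
    se <- sqrt(expected * (1 - expected) / 5000)
    expect_lt(abs(mean(ev) - expected), 3 * se)
  }
  expect_error(generate_outcomes(ch, profs, followup_years = 0),
               "followup_years")
})

test_that("noiseless MMSE series give exact class slopes", {
  p <- default_profiles()[[1]]
  p$mixing_weight <- 1
  p$mmse_decline_sd <- 0
  profs <- list(p)
  ch <- generate_cohort(profs, 25, 3, seed = 8)
  out <- generate_outcomes(ch, profs, followup_years = 4, seed = 8,
                           mmse_noise_sd = 0)
  sl <- mmse_slopes(out$visits)
  expect_equal(sl$slope, rep(-p$mmse_decline_mean, nrow(sl)),
               tolerance = 1e-10)
})

test_that("planted decline-rate contrast is recovered from the series", {
  profs <- default_profiles()[c(1, 2)]  # decline 3.0 vs 1.0
  profs[[1]]$mixing_weight <- 0.5
  profs[[2]]$mixing_weight <- 0.5
  ch <- generate_cohort(profs, 1000, 5, seed = 9)
  out <- generate_outcomes(ch, profs, followup_years = 5, seed = 9,
                           mmse_noise_sd = 0.5)
  sl <- mmse_slopes(out$visits)
  cls <- out$table$class_id[match(sl$patient_id, out$table$patient_id)]
  m1 <- mean(sl$slope[cls == 1])
  m2 <- mean(sl$slope[cls == 2])
  expect_gt(abs(m1 - m2), 1.5)
  expect_true(m1/m2 > 2.5 && m1/m2 < 3.5)
})

test_that("cohort round-trips through csv files", {
  ch <- generate_cohort(default_profiles(), 40, 3, seed = 10)
  d <- file.path(tempdir(), "adsubtype-io-test")
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_equal(back$events$date, ch$events$date)
  expect_equal(back$demographics$patient_id, ch$demographics$patient_id)
  expect_equal(back$truth$class_id, ch$truth$class_id)
  unlink(d, recursive = TRUE)
})
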