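test_that("simulation is deterministic and the empty case degenerates cleanly", {
  cfg <- simulation_config(n_patients = 300, seed = 11)
  a <- simulate_ehr(cfg)
  b <- simulate_ehr(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$contacts, b$contacts)
  expect_identical(a$truth$contacts, b$truth$contacts)
  expect_identical(a$truth$denominators, b$truth$denominators)

  empty <- simulate_ehr(simulation_config(n_patients = 0, seed = 1))
  expect_identical(nrow(empty$patients), 0L)
  expect_identical(nrow(empty$contacts), 0L)
  expect_identical(nrow(empty$truth$patients), 0L)
  expect_named(empty$contacts,
               c("contact_id", "patient_id", "date", "icpc_codes",
                 "note_text", "contact_type", "in_office_hours"))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(pregnancy_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_patients = -5), ">= 0")
  expect_error(simulation_config(date_range = c("2020-01-01", "2019-01-01")),
               "date_range")
  bad_mix <- default_contact_type_mix()
  bad_mix$clinic[1] <- bad_mix$clinic[1] + 0.01
  expect_error(simulation_config(contact_type_mix = bad_mix), "sum to 1")
  # negative implied intensity surfaces when contacts are generated
  params <- default_rate_params()
  params$slope[params$subphase == "0"] <- -1
  cfg <- simulation_config(n_patients = 50, phase_rate_params = params)
  pop <- generate_population(cfg)
  expect_error(generate_contacts(pop$patients, pop$truth, cfg),
               "negative intensity")
})

test_that("population ages, sex and pregnancy prevalence match the design", {
  cfg <- simulation_config(n_patients = 10000, seed = 5)
  pop <- generate_population(cfg)
  expect_true(all(pop$patients$sex == "female"))
  bd <- pop$patients$birth_date
  age_start <- as.numeric(as.Date("2019-01-01") - bd[!is.na(bd)]) / 365.25
  expect_true(all(age_start >= 20 & age_start <= 45))
  # truth-pregnant fraction within the exact binomial 99% interval
  k <- sum(pop$truth$patients$pregnant)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.139)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # exclusion traits present in roughly the configured (small) fractions
  expect_gt(sum(!pop$truth$patients$eligible), 0)
})

test_that("every truth-pregnant contact lies inside a pregnancy episode", {
  sim <- small_sim()
  tc <- sim$truth$contacts[sim$truth$contacts$truth_pregnant, ]
  tp <- sim$truth$patients
  i <- match(tc$patient_id, tp$patient_id)
  expect_true(all(tp$pregnant[i]))
  expect_true(all(tc$date >= tp$episode_start[i] &
                    tc$date <= tp$episode_end[i]))
})

test_that("total cohort contacts fall in the exact Poisson 99% interval", {
  # constant intensity 10/1000/weekday, no trend, no seasonal offsets
  params <- default_rate_params()
  params$intercept <- 10; params$slope <- 0
  params$winter <- 0; params$summer <- 0; params$autumn <- 0
  cfg <- simulation_config(
    n_patients = 4000, seed = 21, phase_rate_params = params,
    background_rate = 0, out_of_hours_rate = 0,
    exclusion_fractions = c(died_in_period = 0, deregistered = 0,
                            dereg_reason_without_date = 0,
                            unknown_birth_date = 0,
                            registered_under_minimum = 0,
                            pseudonymization_incomplete = 0)
  )
  sim <- simulate_ehr(cfg)
  lambda_total <- sum(10 * sim$truth$denominators$denominator / 1000)
  n <- nrow(sim$contacts)
  expect_gte(n, qpois(0.005, lambda_total))
  expect_lte(n, qpois(0.995, lambda_total))
  # zero intensity produces zero contacts
  params$intercept <- 0
  cfg0 <- simulation_config(n_patients = 200, seed = 3,
                            phase_rate_params = params,
                            background_rate = 0, out_of_hours_rate = 0)
  expect_identical(nrow(simulate_ehr(cfg0)$contacts), 0L)
})

test_that("contacts avoid weekends and holidays and carry valid fields", {
  sim <- small_sim()
  expect_true(all(as.integer(format(sim$contacts$date, "%u")) <= 5))
  expect_false(any(sim$contacts$date %in% default_holidays()))
  expect_true(all(sim$contacts$contact_type %in%
                    c("clinic", "home_visit", "telephone", "digital")))
  expect_true(all(grepl("^[A-Z][0-9]{2}", sim$contacts$icpc_codes)))
  # text-only channel contacts carry a lexicon phrase but no pregnancy code
  tc <- sim$truth$contacts
  txt <- sim$contacts[tc$channel == "text_only", ]
  if (nrow(txt) > 0) {
    expect_true(all(flag_by_text(txt$note_text)$flag))
    expect_false(any(flag_by_icpc(txt$icpc_codes)$flag))
  }
  icpc <- sim$contacts[tc$channel == "icpc", ]
  expect_true(all(flag_by_icpc(icpc$icpc_codes)$flag))
})

test_that("contact-type mix matches the configured probabilities per subphase", {
  sim <- small_sim()
  cal <- build_phase_calendar()
  sp <- subphase_of(cal, sim$contacts$date)
  mix <- default_contact_type_mix()
  types <- c("clinic", "home_visit", "telephone", "digital")
  phases <- names(which(table(sp) >= 500))
  # ~50 binomial cells tested jointly: Bonferroni-share the 1% error rate
  alpha <- 0.01 / (4 * max(length(phases), 1))
  for (ph in phases) {
    sel <- sim$contacts[sp == ph, ]
    p <- as.numeric(mix[mix$subphase == ph, types])
    cnt <- table(factor(sel$contact_type, levels = types))
    for (j in seq_along(types)) {
      bounds <- qbinom(c(alpha / 2, 1 - alpha / 2), nrow(sel), p[j])
      expect_gte(as.integer(cnt[j]), bounds[1])
      expect_lte(as.integer(cnt[j]), bounds[2])
    }
  }
})

test_that("datasets round-trip through CSV and the truth ledger is complete", {
  dir <- withr::local_tempdir()
  sim <- simulate_ehr(simulation_config(n_patients = 250, seed = 9))
  paths <- write_dataset(sim$patients, sim$contacts, sim$truth, dir)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(sim$patients))
  expect_equal(as.data.frame(back$contacts), as.data.frame(sim$contacts))
  expect_equal(as.data.frame(back$denominators),
               as.data.frame(sim$truth$denominators))
  # combined ledger: one row per patient plus one per contact
  expect_identical(nrow(back$truth),
                   nrow(sim$patients) + nrow(sim$contacts))
  # headers-only files for the empty dataset
  dir2 <- withr::local_tempdir()
  empty <- simulate_ehr(simulation_config(n_patients = 0, seed = 1))
  write_dataset(empty$patients, empty$contacts, empty$truth, dir2)
  back2 <- read_dataset(dir2)
  expect_identical(nrow(back2$patients), 0L)
  expect_identical(nrow(back2$contacts), 0L)
})
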