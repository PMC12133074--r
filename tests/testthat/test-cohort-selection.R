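test_that("ICPC flagging follows the defining code set, W90 never included", {
  res <- flag_by_icpc(c("W78", "U71", "W90", "W78;U71", "W84.02"))
  expect_identical(res$flag, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(res$matched_codes[[1]], "W78")
  expect_identical(res$matched_codes[[4]], "W78")
  expect_identical(res$matched_codes[[5]], "W84.02")
  expect_error(flag_by_icpc("W78", pregnancy_codes = c("W78", "W90")),
               "W90")
  expect_error(flag_by_icpc("W78", pregnancy_codes = character()), "nonempty")
})

test_that("malformed ICPC fields are rejected with the row named", {
  expect_error(flag_by_icpc(c("W78", "pregnant", "U71")), "row\\(s\\): 2")
  expect_error(flag_by_icpc(c("W78", "")), "row\\(s\\): 2")
})

test_that("text screening returns match spans and treats decoys as candidates", {
  res <- flag_by_text(c("", "patiente is 12 weken zwanger",
                        "ZWANGERSCHAPSTEST negatief", "geen klachten"))
  expect_identical(res$flag, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(tolower(res$matches[[2]]), "zwanger")
  # pattern-level match on the negated note: candidate only, resolved by
  # manual labelling downstream
  expect_identical(tolower(res$matches[[3]]), "zwanger")
  expect_error(flag_by_text("x", pattern = "("), "invalid regular expression")
})

test_that("evidence merging implements the three-method rule", {
  expect_identical(merge_evidence(TRUE, FALSE, "absent"), "confirmed_icpc")
  expect_identical(merge_evidence(FALSE, TRUE, "absent"), "excluded_indeterminate")
  expect_identical(merge_evidence(FALSE, TRUE, "confirm"), "confirmed_text_manual")
  expect_identical(merge_evidence(FALSE, FALSE, "confirm"), "excluded_indeterminate")
  expect_identical(merge_evidence(TRUE, TRUE, "reject"), "excluded_indeterminate")
  expect_identical(merge_evidence(TRUE, FALSE, "confirm"), "confirmed_icpc")
  expect_error(merge_evidence(TRUE, TRUE, "maybe"), "confirm")
})

test_that("conflicting duplicate manual labels are a validation error", {
  contacts <- fix_contacts("P001", "2019-03-04", codes = "U71",
                           note = "zwanger?")
  ml <- tibble::tibble(contact_id = c("C0001", "C0001"),
                       verdict = c("confirm", "reject"))
  expect_error(label_cohort(contacts, manual_labels = ml), "conflicting")
})

test_that("patient exclusion rules remove the documented cases", {
  pats <- dplyr::bind_rows(
    fix_patients(1, patient_id = "P001"),
    fix_patients(1, patient_id = "P002", birth_date = as.Date(NA)),
    fix_patients(1, patient_id = "P003",
                 registration_start = as.Date("2019-05-01"),
                 registration_end = as.Date("2019-06-30"),
                 deregistration_reason = "verhuisd"),
    fix_patients(1, patient_id = "P004", death_in_period = TRUE),
    fix_patients(1, patient_id = "P005", zip_available = FALSE),
    fix_patients(1, patient_id = "P006", deregistration_reason = "verhuisd")
  )
  contacts <- fix_contacts(
    patient_id = c("P001", "P002", "P003", "P004", "P005", "P006"),
    dates = "2019-03-04"
  )
  res <- apply_exclusions(pats, contacts, pregnant_patients = pats$patient_id,
                          study_range = c("2019-01-01", "2021-12-31"))
  expect_identical(res$patients$patient_id, "P001")
  pr <- res$audit$patient_rules
  expect_identical(pr[["unknown_birth_date"]], 1L)
  # a 2-month registration window is deregistered *and* under the minimum:
  # audited once, at the first matching rule
  expect_identical(pr[["deregistered"]], 1L)
  expect_identical(pr[["registered_under_minimum"]], 0L)
  expect_identical(pr[["died_in_period"]], 1L)
  expect_identical(pr[["dereg_reason_without_date"]], 1L)
  expect_identical(pr[["pseudonymization_incomplete"]], 1L)
})

test_that("short registration alone is excluded under the 90-day default", {
  pats <- fix_patients(1, patient_id = "P001",
                       registration_start = as.Date("2019-05-01"),
                       registration_end = NA)
  # registration runs to the end of the window: included
  contacts <- fix_contacts("P001", "2019-06-03")
  ok <- apply_exclusions(pats, contacts, "P001",
                         study_range = c("2019-01-01", "2019-12-31"))
  expect_identical(nrow(ok$patients), 1L)
  # truncate the study window so only ~61 days of registration overlap
  short <- apply_exclusions(pats, contacts, "P001",
                            study_range = c("2019-01-01", "2019-06-30"))
  expect_identical(short$audit$patient_rules[["registered_under_minimum"]], 1L)
  expect_identical(nrow(short$patients), 0L)
})

test_that("weekend, holiday, office-hours and age rules drop contacts only", {
  pats <- fix_patients(1, patient_id = "P001")
  contacts <- dplyr::bind_rows(
    fix_contacts("P001", "2019-03-04"),              # Monday, kept
    fix_contacts("P001", "2019-03-09"),              # Saturday
    fix_contacts("P001", "2019-04-22"),              # Easter Monday
    fix_contacts("P001", "2019-03-05", office = FALSE)
  )
  contacts$contact_id <- sprintf("C%04d", 1:4)
  res <- apply_exclusions(pats, contacts, "P001",
                          study_range = c("2019-01-01", "2019-12-31"))
  expect_identical(res$contacts$contact_id, "C0001")
  expect_identical(nrow(res$patients), 1L)  # patient retained throughout
  cr <- res$audit$contact_rules
  expect_identical(cr[["weekend"]], 1L)
  expect_identical(cr[["holiday"]], 1L)
  expect_identical(cr[["outside_office_hours"]], 1L)

  # age at contact outside 20-45 drops the contact up front
  young <- fix_patients(1, patient_id = "P001",
                        birth_date = as.Date("2001-01-01"))
  res2 <- apply_exclusions(young, fix_contacts("P001", "2019-03-04"), "P001",
                           study_range = c("2019-01-01", "2019-12-31"))
  expect_identical(res2$audit$contact_rules[["age_outside_range"]], 1L)
})

test_that("contacts referencing unknown patients are a validation error", {
  pats <- fix_patients(1, patient_id = "P001")
  expect_error(
    apply_exclusions(pats, fix_contacts("P999", "2019-03-04"), "P001"),
    "unknown patient"
  )
})

test_that("exclusion audit conserves patient and contact counts", {
  sim <- small_sim()
  sel <- select_cohort(sim$patients, sim$contacts,
                       manual_labels = generate_manual_labels(sim$truth))
  a <- sel$audit
  expect_identical(a$n_patients_in,
                   a$n_patients_included + sum(a$patient_rules))
  expect_identical(a$n_contacts_in,
                   a$n_contacts_included + sum(a$contact_rules))
  expect_true(all(a$patient_rules >= 0), all(a$contact_rules >= 0))
})

test_that("selection recovers the synthetic ground truth exactly", {
  sim <- small_sim()
  sel <- select_cohort(sim$patients, sim$contacts,
                       manual_labels = generate_manual_labels(sim$truth))
  tc <- sim$truth$contacts
  tp <- sim$truth$patients
  # every truth-pregnant contact detectable by ICPC is confirmed via ICPC
  icpc_ids <- tc$contact_id[tc$channel == "icpc"]
  st <- sel$labels$status[match(icpc_ids, sel$labels$contact_id)]
  expect_true(all(st == "confirmed_icpc"))
  # with the complete manual-label file, patient-level labelling equals truth
  detected <- unique(tc$patient_id[tc$truth_pregnant])
  expect_setequal(sel$pregnant_patients,
                  tp$patient_id[tp$pregnant & tp$patient_id %in% detected])
  # decoy notes never confirm a non-pregnant patient
  expect_false(any(sel$pregnant_patients %in% tp$patient_id[!tp$pregnant]))
})

test_that("selection is idempotent on its own output", {
  sim <- small_sim()
  ml <- generate_manual_labels(sim$truth)
  s1 <- select_cohort(sim$patients, sim$contacts, manual_labels = ml,
                      study_range = c("2019-01-01", "2021-12-31"))
  s2 <- select_cohort(s1$patients, s1$contacts, manual_labels = ml,
                      study_range = c("2019-01-01", "2021-12-31"))
  expect_identical(s2$patients$patient_id, s1$patients$patient_id)
  expect_identical(s2$contacts$contact_id, s1$contacts$contact_id)
  expect_identical(sum(s2$audit$patient_rules), 0L)
  expect_identical(sum(s2$audit$contact_rules), 0L)
})
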