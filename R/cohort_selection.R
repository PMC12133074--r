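#' Default pregnancy-defining ICPC code set
#'
#' ICPC chapter-W pregnancy and childbearing codes shipped as configurable
#' data (`inst/extdata/pregnancy_icpc_codes.csv`). W90 ("normal delivery
#' liveborn") is deliberately absent: it is excluded as pregnancy-defining
#' because it is prone to late or false registrations from previous
#' pregnancies. Substitute your own list via the `pregnancy_codes` argument
#' of the selection functions.
#'
#' @return Character vector of ICPC codes.
#' @export
default_pregnancy_codes <- function() {
  path <- system.file("extdata", "pregnancy_icpc_codes.csv",
                      package = "prenatalITS", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)$code
}

#' Default pregnancy-relevant ICPC codes for frequency analysis
#'
#' Codes for symptoms and diagnoses that commonly occur in, or need clinical
#' attention during, pregnancy, each tagged `pregnancy_related` or `general`.
#' A configurable stand-in for a study-specific clinician-validated list.
#'
#' @return Tibble with `code`, `description`, `category`.
#' @export
default_relevant_codes <- function() {
  path <- system.file("extdata", "pregnancy_relevant_codes.csv",
                      package = "prenatalITS", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default Dutch free-text pregnancy pattern and lexicon
#'
#' `default_text_pattern()` returns a regular expression over Dutch
#' pregnancy terms ("zwanger", "graviditeit", "amenorroe"); matching is
#' case-insensitive. A text match only marks a contact as a *candidate*:
#' confirmation requires a manual label, because notes such as
#' "zwangerschapstest negatief" match the pattern while refuting pregnancy.
#' `default_lexicon()` returns the phrase table (signal and decoy phrases)
#' used by the synthetic note generator.
#'
#' @return A single regex string / a tibble with `phrase`, `kind`.
#' @export
default_text_pattern <- function() {
  "zwanger|gravid[ia]|amenorroe"
}

#' @rdname default_text_pattern
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "pregnancy_lexicon.csv",
                      package = "prenatalITS", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# split ";"-separated ICPC fields into a list of code vectors
split_icpc <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), trimws)
}

validate_icpc_codes <- function(code_list, what = "contact") {
  ok <- vapply(code_list, function(cc) {
    length(cc) >= 1L && all(grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", cc))
  }, logical(1))
  if (!all(ok)) {
    bad <- which(!ok)
    stop("malformed or empty ICPC code field in ", what, " row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# a code matches the set if either the full code (W84.02) or its base (W84) is listed
icpc_in_set <- function(codes, set) {
  base <- sub("\\..*$", "", codes)
  codes %in% set | base %in% set
}

#' Flag contacts carrying a pregnancy-defining ICPC code
#'
#' A contact is flagged when at least one of its ICPC codes (or the base
#' code of a sub-coded registration such as W84.02) is in `pregnancy_codes`.
#' W90 never defines pregnancy and is rejected if present in the set.
#'
#' @param icpc_codes Character vector, one `;`-separated ICPC field per
#'   contact, or a list of code vectors.
#' @param pregnancy_codes Character vector of defining codes.
#' @return Tibble with logical `flag` and list-column `matched_codes`.
#' @export
flag_by_icpc <- function(icpc_codes, pregnancy_codes = default_pregnancy_codes()) {
  if (length(pregnancy_codes) == 0L) {
    stop("`pregnancy_codes` must be nonempty", call. = FALSE)
  }
  if ("W90" %in% sub("\\..*$", "", pregnancy_codes)) {
    stop("W90 must not be part of the pregnancy-defining code set", call. = FALSE)
  }
  code_list <- if (is.list(icpc_codes)) lapply(icpc_codes, trimws) else split_icpc(icpc_codes)
  validate_icpc_codes(code_list)
  matched <- lapply(code_list, function(cc) cc[icpc_in_set(cc, pregnancy_codes)])
  tibble::tibble(
    flag = lengths(matched) > 0L,
    matched_codes = matched
  )
}

#' Flag contacts whose note matches a pregnancy text pattern
#'
#' Case-insensitive regular-expression screening of free-text physician
#' notes. All non-overlapping match spans are returned. A match makes the
#' contact a pregnancy *candidate* only; confirmation requires a manual
#' label (see [merge_evidence()]).
#'
#' @param note_text Character vector of notes (`NA` treated as empty).
#' @param pattern Regular expression; must compile.
#' @return Tibble with logical `flag` and list-column `matches` of matched
#'   substrings.
#' @export
flag_by_text <- function(note_text, pattern = default_text_pattern()) {
  ok <- tryCatch({suppressWarnings(grepl(pattern, "x", ignore.case = TRUE)); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern, call. = FALSE)
  note_text <- ifelse(is.na(note_text), "", as.character(note_text))
  m <- gregexpr(pattern, note_text, ignore.case = TRUE, perl = TRUE)
  matches <- regmatches(note_text, m)
  matches <- lapply(matches, function(x) x[nzchar(x)])
  tibble::tibble(flag = lengths(matches) > 0L, matches = matches)
}

#' Combine ICPC, text and manual pregnancy evidence
#'
#' Evidence is merged per contact: an ICPC match confirms pregnancy outright
#' (`confirmed_icpc`) unless a manual label explicitly rejects it; a text
#' match without ICPC evidence is confirmed only by a manual confirmation
#' (`confirmed_text_manual`); anything else is `excluded_indeterminate`.
#' Miscarriage codes sit in the defining code set, so they confirm via the
#' ICPC route.
#'
#' @param icpc_flag,text_flag Logical vectors.
#' @param manual_label Character vector in `c("confirm", "reject", "absent")`
#'   (`NA` treated as `"absent"`).
#' @return Character vector of statuses.
#' @export
merge_evidence <- function(icpc_flag, text_flag, manual_label = "absent") {
  n <- max(length(icpc_flag), length(text_flag), length(manual_label))
  icpc_flag <- rep_len(as.logical(icpc_flag), n)
  text_flag <- rep_len(as.logical(text_flag), n)
  manual_label <- rep_len(as.character(manual_label), n)
  manual_label[is.na(manual_label)] <- "absent"
  if (!all(manual_label %in% c("confirm", "reject", "absent"))) {
    stop("manual labels must be 'confirm', 'reject' or 'absent'", call. = FALSE)
  }
  status <- rep("excluded_indeterminate", n)
  status[icpc_flag & manual_label != "reject"] <- "confirmed_icpc"
  status[!icpc_flag & text_flag & manual_label == "confirm"] <- "confirmed_text_manual"
  status
}

#' Label contacts and patients for pregnancy
#'
#' Runs the three selection methods over a contact table: ICPC codes, the
#' free-text pattern, and a manual-label table standing in for the study
#' team's note review. A patient is labelled pregnant when at least one of
#' her contacts is confirmed.
#'
#' @param contacts Contact tibble (`contact_id`, `patient_id`, `date`,
#'   `icpc_codes`, `note_text`, ...).
#' @param pregnancy_codes,pattern See [flag_by_icpc()], [flag_by_text()].
#' @param manual_labels Optional tibble (`contact_id`, `verdict` in
#'   confirm/reject); duplicate conflicting verdicts are an error.
#' @return List with `contact_labels` (per-contact status + evidence) and
#'   `pregnant_patients` (character vector of patient ids).
#' @export
label_cohort <- function(contacts,
                         pregnancy_codes = default_pregnancy_codes(),
                         pattern = default_text_pattern(),
                         manual_labels = NULL) {
  icpc <- flag_by_icpc(contacts$icpc_codes, pregnancy_codes)
  text <- flag_by_text(contacts$note_text, pattern)
  manual <- rep("absent", nrow(contacts))
  if (!is.null(manual_labels) && nrow(manual_labels) > 0L) {
    ml <- unique(manual_labels[, c("contact_id", "verdict")])
    if (anyDuplicated(ml$contact_id)) {
      stop("conflicting duplicate manual labels for contact(s): ",
           paste(unique(ml$contact_id[duplicated(ml$contact_id)]),
                 collapse = ", "), call. = FALSE)
    }
    i <- match(contacts$contact_id, ml$contact_id)
    manual[!is.na(i)] <- ml$verdict[i[!is.na(i)]]
  }
  status <- merge_evidence(icpc$flag, text$flag, manual)
  labels <- tibble::tibble(
    contact_id = contacts$contact_id,
    patient_id = contacts$patient_id,
    date = as.Date(contacts$date),
    status = status,
    matched_codes = vapply(icpc$matched_codes, paste, "", collapse = ";"),
    matched_text = vapply(text$matches, paste, "", collapse = ";")
  )
  list(
    contact_labels = labels,
    pregnant_patients = unique(labels$patient_id[startsWith(labels$status, "confirmed")])
  )
}

#' Apply the patient and contact exclusion cascade
#'
#' Reproduces the study-style inclusion flowchart. The 20-45 age-at-contact
#' filter is applied first; patient-level rules then run in a fixed order
#' (sex, no confirmed pregnancy, death in period, deregistration,
#' deregistration reason without date, unknown birth date, registration
#' shorter than `min_registration_days` within the study window, data
#' hindering pseudonymisation) with each patient audited once at the first
#' rule that removes her; finally contact-level rules drop weekend, holiday
#' and out-of-office-hours contacts.
#'
#' @param patients Patient tibble (see package vignette for the schema).
#' @param contacts Contact tibble; every `patient_id` must exist in
#'   `patients`.
#' @param pregnant_patients Character vector of patient ids labelled
#'   pregnant ([label_cohort()]).
#' @param holidays Date vector of holidays to exclude.
#' @param study_range Length-2 Date vector; defaults to the contact span.
#' @param min_registration_days Minimum registration overlap with the study
#'   window, in days (default 90, standing in for "registered less than 3
#'   months").
#' @param age_range Inclusive completed-years age bounds at contact date.
#' @return List with `patients`, `contacts` (included rows) and `audit`, an
#'   `exclusion_audit` with per-rule removal counts in application order.
#' @export
apply_exclusions <- function(patients, contacts, pregnant_patients,
                             holidays = default_holidays(),
                             study_range = NULL,
                             min_registration_days = 90,
                             age_range = c(20, 45)) {
  if (!all(contacts$patient_id %in% patients$patient_id)) {
    bad <- setdiff(contacts$patient_id, patients$patient_id)
    stop("contacts reference unknown patient(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  contacts$date <- as.Date(contacts$date)
  if (is.null(study_range)) {
    study_range <- range(contacts$date)
  }
  study_range <- as.Date(study_range)

  contact_rules <- c()
  n_contacts_in <- nrow(contacts)

  # age at contact (completed years); unknown birth dates resolved by the
  # patient-level rule below
  bd <- as.Date(patients$birth_date)[match(contacts$patient_id, patients$patient_id)]
  age <- floor(as.numeric(contacts$date - bd) / 365.25)
  keep <- is.na(age) | (age >= age_range[1] & age <= age_range[2])
  contact_rules["age_outside_range"] <- sum(!keep)
  contacts <- contacts[keep, ]

  reg_start <- as.Date(patients$registration_start)
  reg_end <- as.Date(patients$registration_end)
  dereg_reason <- as.character(patients$deregistration_reason)
  has_reason <- !is.na(dereg_reason) & nzchar(dereg_reason)
  rs <- reg_start
  rs[is.na(rs)] <- study_range[1]
  re <- reg_end
  re[is.na(re)] <- study_range[2]
  reg_days <- as.numeric(pmin(re, study_range[2]) - pmax(rs, study_range[1])) + 1

  rule_masks <- list(
    not_female = patients$sex != "female",
    no_confirmed_pregnancy = !(patients$patient_id %in% pregnant_patients),
    died_in_period = as.logical(patients$death_in_period),
    deregistered = !is.na(reg_end) & reg_end >= study_range[1] & reg_end <= study_range[2],
    dereg_reason_without_date = has_reason & is.na(reg_end),
    unknown_birth_date = is.na(as.Date(patients$birth_date)),
    registered_under_minimum = reg_days < min_registration_days,
    pseudonymization_incomplete = !as.logical(patients$zip_available)
  )

  n_patients_in <- nrow(patients)
  removed <- rep(FALSE, n_patients_in)
  patient_rules <- c()
  for (rule in names(rule_masks)) {
    hit <- rule_masks[[rule]] & !removed
    hit[is.na(hit)] <- FALSE
    patient_rules[rule] <- sum(hit)
    removed <- removed | hit
  }
  included_patients <- patients[!removed, ]

  keep <- contacts$patient_id %in% included_patients$patient_id
  contact_rules["patient_excluded"] <- sum(!keep)
  contacts <- contacts[keep, ]

  keep <- is_weekday(contacts$date)
  contact_rules["weekend"] <- sum(!keep)
  contacts <- contacts[keep, ]

  keep <- !(contacts$date %in% as.Date(holidays))
  contact_rules["holiday"] <- sum(!keep)
  contacts <- contacts[keep, ]

  keep <- as.logical(contacts$in_office_hours)
  contact_rules["outside_office_hours"] <- sum(!keep)
  contacts <- contacts[keep, ]

  audit <- structure(
    list(
      patient_rules = patient_rules,
      contact_rules = contact_rules,
      n_patients_in = n_patients_in,
      n_patients_included = nrow(included_patients),
      n_contacts_in = n_contacts_in,
      n_contacts_included = nrow(contacts)
    ),
    class = "exclusion_audit"
  )
  list(patients = included_patients, contacts = contacts, audit = audit)
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat("Exclusion audit\n")
  cat(sprintf("  patients: %d in -> %d included\n", x$n_patients_in, x$n_patients_included))
  for (r in names(x$patient_rules)) {
    cat(sprintf("    - %-28s %d removed\n", r, x$patient_rules[[r]]))
  }
  cat(sprintf("  contacts: %d in -> %d included\n", x$n_contacts_in, x$n_contacts_included))
  for (r in names(x$contact_rules)) {
    cat(sprintf("    - %-28s %d removed\n", r, x$contact_rules[[r]]))
  }
  invisible(x)
}

#' Identify the pregnancy cohort and its eligible contacts
#'
#' Convenience wrapper: [label_cohort()] followed by [apply_exclusions()].
#'
#' @inheritParams label_cohort
#' @inheritParams apply_exclusions
#' @param patients Patient tibble.
#' @return List with `labels`, `pregnant_patients`, `patients`, `contacts`,
#'   `audit`.
#' @export
select_cohort <- function(patients, contacts,
                          manual_labels = NULL,
                          pregnancy_codes = default_pregnancy_codes(),
                          pattern = default_text_pattern(),
                          holidays = default_holidays(),
                          study_range = NULL,
                          min_registration_days = 90,
                          age_range = c(20, 45)) {
  lab <- label_cohort(contacts, pregnancy_codes, pattern, manual_labels)
  excl <- apply_exclusions(patients, contacts, lab$pregnant_patients,
                           holidays = holidays, study_range = study_range,
                           min_registration_days = min_registration_days,
                           age_range = age_range)
  # the analysed cohort is women with at least one included contact (the
  # per-year population framing); this also makes the selection idempotent
  keep <- excl$patients$patient_id %in% excl$contacts$patient_id
  audit <- excl$audit
  audit$patient_rules["no_included_contacts"] <- sum(!keep)
  audit$n_patients_included <- sum(keep)
  list(
    labels = lab$contact_labels,
    pregnant_patients = lab$pregnant_patients,
    patients = excl$patients[keep, ],
    contacts = excl$contacts,
    audit = audit
  )
}
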