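#' Validate a patient/contact dataset
#'
#' Schema, date-format, ICPC-format and referential-integrity checks for the
#' two input tables. Problems are reported row-counted, never silently
#' fixed; a contact without at least one well-formed ICPC code violates the
#' registration rule that every contact carries a physician's note and at
#' least one ICPC code.
#'
#' @param patients,contacts Tibbles (e.g. from [read_dataset()]).
#' @return List with `valid` (logical) and `problems` (tibble `check`,
#'   `n_rows`, `example`).
#' @export
validate_dataset <- function(patients, contacts) {
  problems <- list()
  note <- function(check, rows) {
    if (length(rows) > 0L) {
      problems[[length(problems) + 1L]] <<- tibble::tibble(
        check = check, n_rows = length(rows),
        example = as.character(rows[1])
      )
    }
  }
  need_p <- c("patient_id", "birth_date", "sex", "practice_id",
              "registration_start", "registration_end",
              "deregistration_reason", "death_in_period", "zip_available")
  need_c <- c("contact_id", "patient_id", "date", "icpc_codes", "note_text",
              "contact_type", "in_office_hours")
  note("patients: missing column", setdiff(need_p, names(patients)))
  note("contacts: missing column", setdiff(need_c, names(contacts)))
  if (length(problems) > 0L) {
    return(list(valid = FALSE, problems = dplyr::bind_rows(problems)))
  }
  note("patients: duplicate patient_id",
       which(duplicated(patients$patient_id)))
  note("contacts: duplicate contact_id",
       which(duplicated(contacts$contact_id)))
  note("patients: sex not female/male/other",
       which(!patients$sex %in% c("female", "male", "other")))
  note("contacts: unparseable date",
       which(is.na(as.Date(as.character(contacts$date),
                           format = "%Y-%m-%d"))))
  note("contacts: unknown patient_id",
       which(!contacts$patient_id %in% patients$patient_id))
  code_ok <- vapply(split_icpc(contacts$icpc_codes), function(cc) {
    length(cc) >= 1L && all(nzchar(cc)) &&
      all(grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", cc))
  }, logical(1))
  note("contacts: missing or malformed ICPC code (>=1 required)",
       which(!code_ok))
  note("contacts: unknown contact_type",
       which(!contacts$contact_type %in%
               c("clinic", "home_visit", "telephone", "digital")))
  rs <- as.Date(patients$registration_start)
  re <- as.Date(patients$registration_end)
  note("patients: registration_end before registration_start",
       which(!is.na(rs) & !is.na(re) & re < rs))
  problems <- if (length(problems) > 0L) dplyr::bind_rows(problems) else
    tibble::tibble(check = character(), n_rows = integer(), example = character())
  list(valid = nrow(problems) == 0L, problems = problems)
}

#' Assemble a pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list. When
#' `patients_csv`/`contacts_csv` are `NULL` a synthetic dataset is generated
#' with `n_patients` and `seed`, and the generator's true denominator series
#' is used; otherwise denominators come from `denominators_csv` or, failing
#' that, are rebuilt from the labels with [build_denominators()].
#'
#' @param out_dir Output directory for the report bundle.
#' @param patients_csv,contacts_csv,manual_labels_csv,denominators_csv
#'   Optional input paths.
#' @param n_patients,seed Synthetic-data size and seed (single source of
#'   randomness).
#' @param window Moving-average window in weekdays.
#' @param span LOESS span for the contact-mix display series.
#' @param k Number of top-ranked codes tested.
#' @param denominator_mode,min_registration_days,robust_se,adjust See the
#'   respective stage functions.
#' @param phase_spec,holidays Calendar inputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            patients_csv = NULL, contacts_csv = NULL,
                            manual_labels_csv = NULL, denominators_csv = NULL,
                            n_patients = 5000, seed = 1,
                            window = 15L, span = 0.75, k = 10L,
                            denominator_mode = "per_year",
                            min_registration_days = 90,
                            robust_se = FALSE, adjust = "none",
                            phase_spec = default_phase_spec(),
                            holidays = default_holidays()) {
  for (f in c(patients_csv, contacts_csv, manual_labels_csv, denominators_csv)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file does not exist: ", f, call. = FALSE)
    }
  }
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be odd and positive", call. = FALSE)
  }
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]", call. = FALSE)
  structure(list(
    out_dir = out_dir, patients_csv = patients_csv,
    contacts_csv = contacts_csv, manual_labels_csv = manual_labels_csv,
    denominators_csv = denominators_csv, n_patients = n_patients,
    seed = as.integer(seed), window = as.integer(window), span = span,
    k = as.integer(k), denominator_mode = denominator_mode,
    min_registration_days = min_registration_days, robust_se = robust_se,
    adjust = adjust, phase_spec = phase_spec, holidays = as.Date(holidays)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. `holidays` may be a list of dates; `phase_spec` a list of rows
#' with `subphase`, `iso_year`, `week_start`, `week_end`.
#'
#' @param path YAML file.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$phase_spec)) {
    raw$phase_spec <- dplyr::bind_rows(lapply(raw$phase_spec, tibble::as_tibble))
  }
  if (!is.null(raw$holidays)) raw$holidays <- as.Date(unlist(raw$holidays))
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) EHR tables, validate, select the pregnancy cohort,
#' fit the interrupted time series, test code frequencies, summarise the
#' contact mix and year-level descriptives, and write the report bundle:
#' `audit.json`, `labels.csv`, `included_contacts.csv`, `fits.csv`,
#' `comparisons.csv`, `code_tests.csv`, `mix.csv`, `summary.csv`,
#' `report.txt` (plus the generated `data/` when simulating). Deterministic
#' given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  calendar <- build_phase_calendar(config$phase_spec)

  truth <- NULL
  if (is.null(config$patients_csv)) {
    sim <- simulate_ehr(simulation_config(
      n_patients = config$n_patients, seed = config$seed,
      phase_spec = config$phase_spec, holidays = config$holidays
    ))
    patients <- sim$patients
    contacts <- sim$contacts
    truth <- sim$truth
    write_dataset(patients, contacts, truth, file.path(out, "data"))
    manual_labels <- generate_manual_labels(truth)
  } else {
    ds <- list(
      patients = readr::read_csv(config$patients_csv, show_col_types = FALSE),
      contacts = readr::read_csv(config$contacts_csv, show_col_types = FALSE)
    )
    patients <- ds$patients
    contacts <- ds$contacts
    manual_labels <- if (!is.null(config$manual_labels_csv)) {
      readr::read_csv(config$manual_labels_csv, show_col_types = FALSE)
    } else NULL
  }

  val <- validate_dataset(patients, contacts)
  if (!val$valid) {
    stop("stage validate: dataset invalid; first problem: ",
         val$problems$check[1], " (", val$problems$n_rows[1], " rows)",
         call. = FALSE)
  }

  sel <- select_cohort(
    patients, contacts, manual_labels = manual_labels,
    holidays = config$holidays,
    study_range = range(calendar$date),
    min_registration_days = config$min_registration_days
  )

  denominators <- if (!is.null(config$denominators_csv)) {
    readr::read_csv(config$denominators_csv, show_col_types = FALSE)
  } else if (!is.null(truth)) {
    truth$denominators
  } else {
    build_denominators(sel$patients, sel$labels, calendar,
                       holidays = config$holidays,
                       mode = config$denominator_mode)
  }

  its <- run_its(sel$contacts, denominators, calendar,
                 window = config$window, robust_se = config$robust_se)
  codes <- code_phase_tests(sel$contacts, calendar, k = config$k,
                            adjust = if (config$adjust == "BH") "BH" else "none")
  mix <- contact_type_proportions(sel$contacts, calendar,
                                  window = config$window)
  mix <- dplyr::mutate(
    dplyr::group_by(mix, .data$contact_type),
    loess = loess_smooth(as.numeric(.data$date), .data$smoothed,
                         span = config$span),
    .keep = "all"
  ) |> dplyr::ungroup()
  desc <- descriptive_summary(sel$patients, sel$contacts)

  paths <- c(
    audit = file.path(out, "audit.json"),
    labels = file.path(out, "labels.csv"),
    included_contacts = file.path(out, "included_contacts.csv"),
    fits = file.path(out, "fits.csv"),
    comparisons = file.path(out, "comparisons.csv"),
    code_tests = file.path(out, "code_tests.csv"),
    mix = file.path(out, "mix.csv"),
    summary = file.path(out, "summary.csv"),
    report = file.path(out, "report.txt")
  )
  jsonlite::write_json(
    list(patient_rules = as.list(sel$audit$patient_rules),
         contact_rules = as.list(sel$audit$contact_rules),
         n_patients_in = sel$audit$n_patients_in,
         n_patients_included = sel$audit$n_patients_included,
         n_contacts_in = sel$audit$n_contacts_in,
         n_contacts_included = sel$audit$n_contacts_included),
    paths["audit"], auto_unbox = TRUE, pretty = TRUE
  )
  readr::write_csv(sel$labels, paths["labels"], na = "")
  readr::write_csv(sel$contacts, paths["included_contacts"], na = "")
  readr::write_csv(its$fit_table, paths["fits"], na = "")
  readr::write_csv(its$comparisons, paths["comparisons"], na = "")
  readr::write_csv(codes, paths["code_tests"], na = "")
  readr::write_csv(mix, paths["mix"], na = "")
  readr::write_csv(desc$summary, paths["summary"], na = "")

  rpt <- c(
    "Pregnancy-cohort GP contact analysis",
    sprintf("generated: deterministic, seed %d", config$seed),
    "",
    utils::capture.output(print(sel$audit)),
    "",
    sprintf("Included: %d pregnant women, %d contacts",
            sel$audit$n_patients_included, sel$audit$n_contacts_included),
    "",
    "Segmented seasonal fits (per subphase):",
    utils::capture.output(print(as.data.frame(its$fit_table), digits = 3,
                                row.names = FALSE)),
    "",
    "Across-year G-tests:",
    utils::capture.output(print(as.data.frame(desc$g_tests), digits = 4,
                                row.names = FALSE)),
    "",
    sprintf("Code-frequency tests: %d Fisher tests at alpha = .05, %s",
            nrow(codes),
            if (config$adjust == "BH") "BH-adjusted p values included"
            else "no multiple-testing correction (interpret counts of significant codes with care)")
  )
  writeLines(rpt, paths["report"])

  invisible(list(
    patients = patients, contacts = contacts, truth = truth,
    validation = val, selection = sel, denominators = denominators,
    its = its, codes = codes, mix = mix, descriptives = desc, paths = paths
  ))
}
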