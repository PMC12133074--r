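#' Default per-subphase contact-rate parameters
#'
#' Generating parameters of the synthetic daily contact intensity for
#' pregnant women, on the scale of published GP-cohort fits: intercepts
#' around 8-11.5 contacts per 1000 registered pregnant patients per weekday,
#' slopes within +/-0.08 per weekday, plus additive seasonal offsets
#' (spring is the reference season). Within each subphase the intensity is
#' `intercept + slope * t + season_offset`, `t` the 0-based weekday index.
#'
#' @return Tibble with `subphase`, `intercept`, `slope`, `winter`, `summer`,
#'   `autumn`.
#' @export
default_rate_params <- function() {
  tibble::tribble(
    ~subphase, ~intercept, ~slope,
    "0",  10.22,  0.000,
    "1a", 10.54, -0.030,
    "1b",  9.97, -0.002,
    "2a",  9.62, -0.030,
    "2b",  8.16,  0.040,
    "3a",  9.88, -0.010,
    "3b",  9.92,  0.010,
    "3c",  9.92,  0.020,
    "4",  11.34, -0.010,
    "5a", 11.23, -0.040,
    "5b",  9.62,  0.002,
    "6a", 10.06, -0.010,
    "6b",  9.41, -0.080
  ) |>
    dplyr::mutate(winter = 0.4, summer = -0.6, autumn = 0.2)
}

#' Default per-subphase contact-type mix
#'
#' Prepandemic shares near 65% clinic / 32% telephone; a swing towards
#' telephone contacts in the first wave, partially reverting afterwards.
#' Rows sum to 1.
#'
#' @return Tibble with `subphase`, `clinic`, `home_visit`, `telephone`,
#'   `digital`.
#' @export
default_contact_type_mix <- function() {
  m <- tibble::tribble(
    ~subphase, ~clinic, ~home_visit, ~telephone, ~digital,
    "0",  0.649, 0.020, 0.317, 0.014,
    "1a", 0.400, 0.015, 0.555, 0.030,
    "1b", 0.430, 0.015, 0.525, 0.030,
    "2a", 0.500, 0.018, 0.452, 0.030,
    "2b", 0.540, 0.018, 0.412, 0.030,
    "3a", 0.520, 0.018, 0.432, 0.030,
    "3b", 0.500, 0.018, 0.452, 0.030,
    "3c", 0.500, 0.018, 0.452, 0.030,
    "4",  0.520, 0.018, 0.432, 0.030,
    "5a", 0.560, 0.018, 0.392, 0.030,
    "5b", 0.590, 0.018, 0.362, 0.030,
    "6a", 0.560, 0.018, 0.392, 0.030,
    "6b", 0.540, 0.018, 0.412, 0.030
  )
  m
}

default_code_multipliers <- function() {
  tibble::tribble(
    ~code, ~subphase, ~multiplier,
    "W84.02", "2a", 1.8, "W84.02", "4", 1.8, "W84.02", "5a", 1.8, "W84.02", "5b", 1.8,
    "W05", "2a", 1.5, "W05", "2b", 1.5, "W05", "3b", 1.5, "W05", "3c", 1.5,
    "W05", "4", 1.5, "W05", "5b", 1.5, "W05", "6b", 1.5,
    "W78", "1a", 0.7, "W78", "1b", 0.7, "W78", "4", 0.7, "W78", "6a", 0.7
  )
}

#' Build a synthetic-EHR simulation configuration
#'
#' Assembles and validates the parameters of the synthetic primary-care EHR
#' generator. Defaults emulate a Dutch GP-network population: women aged
#' 20-45, 13.9% with a pregnancy episode, phase-piecewise-linear daily
#' contact intensities with seasonal offsets, four contact types, Dutch
#' pregnancy phrases and decoys in the free-text notes, and small fractions
#' of patients carrying each exclusion trait.
#'
#' @param n_patients Number of women to simulate.
#' @param date_range Length-2 date vector, inclusive study window.
#' @param pregnancy_prevalence Proportion of patients given a pregnancy
#'   episode.
#' @param phase_rate_params See [default_rate_params()].
#' @param contact_type_mix See [default_contact_type_mix()]; rows must sum
#'   to 1 within 1e-9.
#' @param phase_spec Phase calendar spec; must cover `date_range`.
#' @param pregnancy_code_weights,general_code_weights Named sampling weights
#'   for the primary ICPC code of pregnancy-channel and general contacts.
#' @param code_multipliers Tibble (`code`, `subphase`, `multiplier`) scaling
#'   code weights in specific subphases.
#' @param extra_code_rate Probability that a contact carries a second
#'   (general) ICPC code, yielding ~1.13 registrations per contact.
#' @param text_signal_rate Proportion of truth-pregnant contacts detectable
#'   only through a note phrase (no pregnancy ICPC code).
#' @param undetected_rate Proportion of truth-pregnant contacts carrying
#'   neither code nor phrase; default 0 so that complete manual labels allow
#'   exact truth recovery.
#' @param decoy_rate Proportion of non-pregnant notes containing a decoy
#'   phrase ("niet zwanger", ...) that matches the text pattern but must be
#'   manually rejected.
#' @param background_rate Weekday contact intensity per 1000 non-cohort
#'   patients.
#' @param out_of_hours_rate Weekday intensity (per 1000 pregnant) of extra
#'   out-of-office-hours contacts, which the exclusion cascade removes.
#' @param exclusion_fractions Named proportions of patients assigned each
#'   exclusion trait (mutually exclusive assignment).
#' @param holidays Dates on which no contacts are generated.
#' @param n_practices Number of practice ids to assign.
#' @param seed Integer; single global seed feeding fixed per-stage
#'   substreams (`seed + 1e6 * stage`).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 5000,
                              date_range = c("2019-01-01", "2021-12-31"),
                              pregnancy_prevalence = 0.139,
                              phase_rate_params = default_rate_params(),
                              contact_type_mix = default_contact_type_mix(),
                              phase_spec = default_phase_spec(),
                              pregnancy_code_weights = c(
                                "W78" = 0.50, "W05" = 0.14, "W82" = 0.06,
                                "W79" = 0.05, "W84.02" = 0.06, "W03" = 0.04,
                                "W29" = 0.15),
                              general_code_weights = c(
                                "U71" = 0.22, "U02" = 0.10, "X72" = 0.08,
                                "D06" = 0.13, "D12" = 0.08, "P76" = 0.09,
                                "R74" = 0.19, "L03" = 0.11),
                              code_multipliers = default_code_multipliers(),
                              extra_code_rate = 0.13,
                              text_signal_rate = 0.05,
                              undetected_rate = 0,
                              decoy_rate = 0.05,
                              background_rate = 8,
                              out_of_hours_rate = 0.3,
                              exclusion_fractions = c(
                                died_in_period = 0.002,
                                deregistered = 0.010,
                                dereg_reason_without_date = 0.005,
                                unknown_birth_date = 0.010,
                                registered_under_minimum = 0.015,
                                pseudonymization_incomplete = 0.010),
                              holidays = default_holidays(),
                              n_practices = 12,
                              seed = 1) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[1] > date_range[2]) {
    stop("invalid `date_range`", call. = FALSE)
  }
  if (n_patients < 0) stop("`n_patients` must be >= 0", call. = FALSE)
  for (p in c(pregnancy_prevalence, text_signal_rate, undetected_rate,
              decoy_rate, extra_code_rate)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("proportions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (text_signal_rate + undetected_rate > 1) {
    stop("text_signal_rate + undetected_rate must not exceed 1", call. = FALSE)
  }
  mix_cols <- c("clinic", "home_visit", "telephone", "digital")
  sums <- rowSums(contact_type_mix[, mix_cols])
  if (any(abs(sums - 1) > 1e-9) || any(as.matrix(contact_type_mix[, mix_cols]) < 0)) {
    stop("contact_type_mix rows must be nonnegative and sum to 1", call. = FALSE)
  }
  needed <- unique(phase_spec$subphase)
  missing_rp <- setdiff(needed, phase_rate_params$subphase)
  if (length(missing_rp) > 0L) {
    stop("phase_rate_params missing subphase(s): ",
         paste(missing_rp, collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(needed, contact_type_mix$subphase)) > 0L) {
    stop("contact_type_mix must cover every subphase in phase_spec", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      date_range = date_range,
      pregnancy_prevalence = pregnancy_prevalence,
      phase_rate_params = phase_rate_params,
      contact_type_mix = contact_type_mix,
      phase_spec = phase_spec,
      pregnancy_code_weights = pregnancy_code_weights,
      general_code_weights = general_code_weights,
      code_multipliers = code_multipliers,
      extra_code_rate = extra_code_rate,
      text_signal_rate = text_signal_rate,
      undetected_rate = undetected_rate,
      decoy_rate = decoy_rate,
      background_rate = background_rate,
      out_of_hours_rate = out_of_hours_rate,
      exclusion_fractions = exclusion_fractions,
      holidays = as.Date(holidays),
      n_practices = as.integer(n_practices),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# fixed per-stage substreams of the single global seed
stage_seed <- function(seed, stage) {
  offset <- c(population = 1L, contacts = 2L, manual = 3L)[[stage]]
  as.integer((as.numeric(seed) + 1e6 * offset) %% 2147483629)
}

#' Generate the synthetic patient registry
#'
#' Simulates women of reproductive age (20-45 during the study window) with
#' practice registration, mutually exclusive exclusion traits in configured
#' fractions, and pregnancy episodes (~280 days) for a `pregnancy_prevalence`
#' share of patients.
#'
#' @param config A [simulation_config()].
#' @return List with `patients` (the registry tibble) and `truth`, a
#'   `synthetic_truth` ledger holding per-patient pregnancy episodes,
#'   eligibility and the generating rate parameters.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "population"))
  n <- config$n_patients
  d0 <- config$date_range[1]
  d1 <- config$date_range[2]

  if (n == 0L) {
    patients <- tibble::tibble(
      patient_id = character(), birth_date = as.Date(character()),
      sex = character(), practice_id = character(),
      registration_start = as.Date(character()),
      registration_end = as.Date(character()),
      deregistration_reason = character(), death_in_period = logical(),
      zip_available = logical()
    )
    truth <- structure(list(
      patients = tibble::tibble(
        patient_id = character(), pregnant = logical(),
        episode_start = as.Date(character()), episode_end = as.Date(character()),
        eligible = logical(), trait = character()
      ),
      params = config$phase_rate_params,
      config = config
    ), class = "synthetic_truth")
    return(list(patients = patients, truth = truth))
  }

  id <- sprintf("P%06d", seq_len(n))
  # ages stay within 20-45 over a 3-year window, so no cohort contact is
  # lost to the age-at-contact filter
  age_at_start <- stats::runif(n, 20, 41.5)
  birth_date <- d0 - round(age_at_start * 365.25)
  practice <- sprintf("PR%02d", sample.int(config$n_practices, n, replace = TRUE))

  fr <- config$exclusion_fractions
  trait <- sample(c(names(fr), "none"), n, replace = TRUE,
                  prob = c(fr, 1 - sum(fr)))

  registration_start <- rep(d0 - 365, n)
  registration_end <- as.Date(rep(NA, n))
  dereg_reason <- rep(NA_character_, n)
  death <- rep(FALSE, n)
  zip <- rep(TRUE, n)
  span <- as.numeric(d1 - d0)

  i <- trait == "died_in_period"
  death[i] <- TRUE
  registration_end[i] <- d0 + sample.int(span, sum(i), replace = TRUE)
  dereg_reason[i] <- "overleden"
  i <- trait == "deregistered"
  registration_end[i] <- d0 + sample.int(span, sum(i), replace = TRUE)
  dereg_reason[i] <- "verhuisd"
  i <- trait == "dereg_reason_without_date"
  dereg_reason[i] <- "verhuisd"
  i <- trait == "unknown_birth_date"
  birth_date[i] <- NA
  i <- trait == "registered_under_minimum"
  registration_start[i] <- d0 + sample.int(max(span - 100, 1), sum(i), replace = TRUE)
  registration_end[i] <- registration_start[i] + sample(10:80, sum(i), replace = TRUE)
  i <- trait == "pseudonymization_incomplete"
  zip[i] <- FALSE

  pregnant <- stats::runif(n) < config$pregnancy_prevalence
  episode_start <- as.Date(rep(NA, n))
  episode_end <- as.Date(rep(NA, n))
  np <- sum(pregnant)
  if (np > 0L) {
    episode_start[pregnant] <- d0 - 180 +
      sample.int(as.integer(span + 120), np, replace = TRUE)
    episode_end[pregnant] <- episode_start[pregnant] + 280
  }

  patients <- tibble::tibble(
    patient_id = id, birth_date = birth_date, sex = "female",
    practice_id = practice, registration_start = registration_start,
    registration_end = registration_end,
    deregistration_reason = dereg_reason, death_in_period = death,
    zip_available = zip
  )
  truth <- structure(list(
    patients = tibble::tibble(
      patient_id = id, pregnant = pregnant,
      episode_start = episode_start, episode_end = episode_end,
      eligible = trait == "none", trait = trait
    ),
    params = config$phase_rate_params,
    config = config
  ), class = "synthetic_truth")
  list(patients = patients, truth = truth)
}

# per-day generating intensity (contacts per 1000 pregnant per weekday)
phase_intensity <- function(calendar, phase_rate_params) {
  i <- match(as.character(calendar$subphase), phase_rate_params$subphase)
  offset <- rep(0, nrow(calendar))
  offset[calendar$season == "winter"] <- phase_rate_params$winter[i][calendar$season == "winter"]
  offset[calendar$season == "summer"] <- phase_rate_params$summer[i][calendar$season == "summer"]
  offset[calendar$season == "autumn"] <- phase_rate_params$autumn[i][calendar$season == "autumn"]
  lambda <- phase_rate_params$intercept[i] + phase_rate_params$slope[i] * calendar$t + offset
  if (any(lambda < 0)) {
    bad <- calendar$date[lambda < 0][1]
    stop("rate parameters imply negative intensity, first on ", format(bad),
         call. = FALSE)
  }
  lambda
}

#' Generate the synthetic contact table
#'
#' Draws population-level weekday contact counts for the pregnant cohort as
#' Poisson variates with mean `intensity(day) * denominator(day) / 1000`,
#' attributes them to patients whose pregnancy episode covers the day,
#' assigns contact types from the per-subphase mix and ICPC codes from the
#' code-emission weights, embeds pregnancy phrases in notes of text-only
#' contacts and decoy phrases in a fraction of non-pregnant notes, and adds
#' background contacts for non-cohort patients plus a small stream of
#' out-of-office-hours contacts. Weekends and holidays generate no contacts.
#'
#' @param patients Registry from [generate_population()].
#' @param truth Matching `synthetic_truth`.
#' @param config The [simulation_config()] used for generation.
#' @return List with `contacts` (the contact tibble) and `truth` extended
#'   with the per-contact ledger (`$contacts`) and the true
#'   registered-pregnant denominator series (`$denominators`).
#' @export
generate_contacts <- function(patients, truth, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "synthetic_truth"))
  set.seed(stage_seed(config$seed, "contacts"))
  cal <- build_phase_calendar(config$phase_spec, config$date_range)
  cal <- cal[!(cal$date %in% config$holidays), ]
  lambda <- phase_intensity(cal, config$phase_rate_params)

  tp <- truth$patients
  cohort <- tp[tp$pregnant & tp$eligible, ]
  years <- as.integer(format(cal$date, "%Y"))
  denom_by_year <- vapply(sort(unique(years)), function(y) {
    ys <- as.Date(sprintf("%d-01-01", y)); ye <- as.Date(sprintf("%d-12-31", y))
    sum(cohort$episode_start <= ye & cohort$episode_end >= ys)
  }, integer(1))
  names(denom_by_year) <- sort(unique(years))
  denom <- denom_by_year[as.character(years)]
  denominators <- tibble::tibble(date = cal$date, denominator = as.integer(denom))

  # population-level Poisson draws per weekday
  n_cohort <- stats::rpois(nrow(cal), lambda * denom / 1000)
  n_ooh <- stats::rpois(nrow(cal), config$out_of_hours_rate * denom / 1000)
  bg <- tp[!(tp$pregnant & tp$eligible), ]
  bg_reg <- patients[match(bg$patient_id, patients$patient_id), ]
  rs <- bg_reg$registration_start
  re <- bg_reg$registration_end
  re[is.na(re)] <- config$date_range[2]
  n_bg_active <- vapply(seq_len(nrow(cal)), function(i) {
    sum(rs <= cal$date[i] & re >= cal$date[i])
  }, numeric(1))
  n_background <- stats::rpois(nrow(cal), config$background_rate * n_bg_active / 1000)

  # attribute cohort contacts to episode-covering patients, day by day
  date_l <- list(); pat_l <- list(); office_l <- list()
  for (i in seq_len(nrow(cal))) {
    ntot <- n_cohort[i] + n_ooh[i]
    if (ntot == 0L) next
    pool <- cohort$patient_id[cohort$episode_start <= cal$date[i] &
                                cohort$episode_end >= cal$date[i]]
    if (length(pool) == 0L) next
    pick <- pool[sample.int(length(pool), ntot, replace = TRUE)]
    date_l[[length(date_l) + 1L]] <- rep(cal$date[i], ntot)
    pat_l[[length(pat_l) + 1L]] <- pick
    office_l[[length(office_l) + 1L]] <- rep(c(TRUE, FALSE), c(n_cohort[i], n_ooh[i]))
  }
  cohort_contacts <- tibble::tibble(
    date = as.Date(unlist(lapply(date_l, as.character))),
    patient_id = unlist(pat_l) %||% character(),
    in_office_hours = unlist(office_l) %||% logical(),
    truth_pregnant = TRUE
  )

  bg_date_l <- list(); bg_pat_l <- list()
  for (i in seq_len(nrow(cal))) {
    if (n_background[i] == 0L) next
    pool <- bg$patient_id[rs <= cal$date[i] & re >= cal$date[i]]
    if (length(pool) == 0L) next
    pick <- pool[sample.int(length(pool), n_background[i], replace = TRUE)]
    bg_date_l[[length(bg_date_l) + 1L]] <- rep(cal$date[i], n_background[i])
    bg_pat_l[[length(bg_pat_l) + 1L]] <- pick
  }
  bg_contacts <- tibble::tibble(
    date = as.Date(unlist(lapply(bg_date_l, as.character))),
    patient_id = unlist(bg_pat_l) %||% character(),
    in_office_hours = rep(TRUE, length(unlist(bg_pat_l) %||% character())),
    truth_pregnant = FALSE
  )

  # pregnant patients carrying an exclusion trait still present with
  # pregnancy-coded contacts (so the exclusion cascade, not the labelling,
  # removes them); they are outside the denominator and dropped downstream
  trait_preg <- tp[tp$pregnant & !tp$eligible, ]
  tr_date_l <- list(); tr_pat_l <- list()
  if (nrow(trait_preg) > 0L) {
    treg <- patients[match(trait_preg$patient_id, patients$patient_id), ]
    t_rs <- treg$registration_start
    t_re <- treg$registration_end
    t_re[is.na(t_re)] <- config$date_range[2]
    # contact propensity scales with the cohort intensity (zero intensity,
    # zero contacts), ~2.5 contacts per trait patient at the default scale
    k <- stats::rpois(nrow(trait_preg), 0.25 * mean(lambda))
    for (j in seq_len(nrow(trait_preg))) {
      if (k[j] == 0L) next
      ok <- cal$date >= trait_preg$episode_start[j] &
        cal$date <= trait_preg$episode_end[j] &
        cal$date >= t_rs[j] & cal$date <= t_re[j]
      if (!any(ok)) next
      pickable <- cal$date[ok]
      tr_date_l[[length(tr_date_l) + 1L]] <-
        pickable[sample.int(length(pickable), k[j], replace = TRUE)]
      tr_pat_l[[length(tr_pat_l) + 1L]] <- rep(trait_preg$patient_id[j], k[j])
    }
  }
  trait_contacts <- tibble::tibble(
    date = as.Date(unlist(lapply(tr_date_l, as.character))),
    patient_id = unlist(tr_pat_l) %||% character(),
    in_office_hours = rep(TRUE, length(unlist(tr_pat_l) %||% character())),
    truth_pregnant = TRUE
  )

  contacts <- dplyr::bind_rows(cohort_contacts, bg_contacts, trait_contacts)
  if (nrow(contacts) == 0L) {
    empty <- tibble::tibble(
      contact_id = character(), patient_id = character(),
      date = as.Date(character()), icpc_codes = character(),
      note_text = character(), contact_type = character(),
      in_office_hours = logical()
    )
    truth$contacts <- tibble::tibble(
      contact_id = character(), patient_id = character(),
      date = as.Date(character()), truth_pregnant = logical(),
      channel = character()
    )
    truth$denominators <- denominators
    return(list(contacts = empty, truth = truth))
  }
  contacts <- contacts[order(contacts$date, contacts$patient_id), ]
  nc <- nrow(contacts)
  contacts$subphase <- subphase_of(cal, contacts$date)

  # detection channel of truth-pregnant contacts
  u <- stats::runif(nc)
  channel <- rep("none", nc)
  channel[contacts$truth_pregnant & u < config$text_signal_rate] <- "text_only"
  channel[contacts$truth_pregnant &
            u >= config$text_signal_rate &
            u < 1 - config$undetected_rate] <- "icpc"

  # primary ICPC code: per-subphase weights (pregnancy codes for the icpc
  # channel, general codes otherwise), optional secondary general code
  draw_codes <- function(idx, weights) {
    out <- character(length(idx))
    mult <- config$code_multipliers
    for (sp in unique(contacts$subphase[idx])) {
      sel <- idx[contacts$subphase[idx] == sp]
      w <- weights
      msel <- mult[mult$subphase == sp & mult$code %in% names(w), ]
      if (nrow(msel) > 0L) w[msel$code] <- w[msel$code] * msel$multiplier
      out[match(sel, idx)] <- sample(names(w), length(sel), replace = TRUE, prob = w)
    }
    out
  }
  primary <- character(nc)
  i_icpc <- which(channel == "icpc")
  i_gen <- which(channel != "icpc")
  if (length(i_icpc) > 0L) primary[i_icpc] <- draw_codes(i_icpc, config$pregnancy_code_weights)
  if (length(i_gen) > 0L) primary[i_gen] <- draw_codes(i_gen, config$general_code_weights)
  extra <- stats::runif(nc) < config$extra_code_rate
  secondary <- rep(NA_character_, nc)
  if (any(extra)) {
    secondary[extra] <- sample(names(config$general_code_weights), sum(extra),
                               replace = TRUE, prob = config$general_code_weights)
  }
  icpc_field <- ifelse(is.na(secondary) | secondary == primary,
                       primary, paste(primary, secondary, sep = ";"))

  # notes: Dutch pregnancy phrases for text-only contacts, decoys on a
  # fraction of non-pregnant notes, bland phrases otherwise
  lex <- default_lexicon()
  signal <- lex$phrase[lex$kind == "signal"]
  decoy <- lex$phrase[lex$kind == "decoy"]
  bland <- c("controle, geen bijzonderheden", "advies gegeven",
             "recept herhaald", "lichamelijk onderzoek verricht",
             "overleg met praktijkondersteuner")
  note <- sample(bland, nc, replace = TRUE)
  i_txt <- which(channel == "text_only")
  if (length(i_txt) > 0L) {
    note[i_txt] <- paste0("patiente is ",
                          sample(signal, length(i_txt), replace = TRUE),
                          ", ", sample(bland, length(i_txt), replace = TRUE))
  }
  i_np <- which(!contacts$truth_pregnant)
  i_dec <- i_np[stats::runif(length(i_np)) < config$decoy_rate]
  if (length(i_dec) > 0L) {
    note[i_dec] <- paste0(sample(decoy, length(i_dec), replace = TRUE),
                          ", ", sample(bland, length(i_dec), replace = TRUE))
  }

  # contact type from the per-subphase mix
  mix <- config$contact_type_mix
  mix_cols <- c("clinic", "home_visit", "telephone", "digital")
  type <- character(nc)
  for (sp in unique(contacts$subphase)) {
    sel <- contacts$subphase == sp
    p <- as.numeric(mix[mix$subphase == sp, mix_cols][1, ])
    type[sel] <- sample(mix_cols, sum(sel), replace = TRUE, prob = p)
  }

  out <- tibble::tibble(
    contact_id = sprintf("C%07d", seq_len(nc)),
    patient_id = contacts$patient_id,
    date = contacts$date,
    icpc_codes = icpc_field,
    note_text = note,
    contact_type = type,
    in_office_hours = contacts$in_office_hours
  )
  truth$contacts <- tibble::tibble(
    contact_id = out$contact_id,
    patient_id = out$patient_id,
    date = out$date,
    truth_pregnant = contacts$truth_pregnant,
    channel = channel
  )
  truth$denominators <- denominators
  list(contacts = out, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic EHR dataset
#'
#' @param config A [simulation_config()].
#' @return List with `patients`, `contacts`, `truth` (including the
#'   per-contact ledger and true denominator series).
#' @export
simulate_ehr <- function(config = simulation_config()) {
  pop <- generate_population(config)
  gc_ <- generate_contacts(pop$patients, pop$truth, config)
  list(patients = pop$patients, contacts = gc_$contacts, truth = gc_$truth)
}

#' Machine-readable stand-in for the manual note review
#'
#' Derives a complete manual-label table from the synthetic truth ledger:
#' every contact of a truth-pregnant patient is confirmed, every other
#' contact rejected. Substitutes the human assessment step when exercising
#' the selection pipeline on synthetic data.
#'
#' @param truth A `synthetic_truth` with a `$contacts` ledger.
#' @return Tibble with `contact_id`, `verdict`.
#' @export
generate_manual_labels <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$contacts))
  tibble::tibble(
    contact_id = truth$contacts$contact_id,
    verdict = ifelse(truth$contacts$truth_pregnant, "confirm", "reject")
  )
}

#' Write / read a synthetic dataset as CSV
#'
#' `write_dataset()` writes `patients.csv`, `contacts.csv`, a combined
#' `truth.csv` ledger (one row per patient plus one row per contact) and
#' `denominators.csv` (true registered-pregnant counts per weekday); all
#' UTF-8 with ISO-8601 dates and a header row. `read_dataset()` reads them
#' back.
#'
#' @param patients,contacts Tibbles as produced by [simulate_ehr()].
#' @param truth Matching `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()`: named character vector of file paths;
#'   `read_dataset()`: list of tibbles `patients`, `contacts`, `truth`
#'   (combined ledger), `denominators`.
#' @export
write_dataset <- function(patients, contacts, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- truth$patients
  ledger <- dplyr::bind_rows(
    tibble::tibble(
      level = "patient", patient_id = tp$patient_id, contact_id = NA_character_,
      pregnant = tp$pregnant, episode_start = tp$episode_start,
      episode_end = tp$episode_end, eligible = tp$eligible, trait = tp$trait,
      channel = NA_character_, date = as.Date(NA)
    ),
    tibble::tibble(
      level = "contact", patient_id = truth$contacts$patient_id,
      contact_id = truth$contacts$contact_id,
      pregnant = truth$contacts$truth_pregnant,
      episode_start = as.Date(NA), episode_end = as.Date(NA),
      eligible = NA, trait = NA_character_,
      channel = truth$contacts$channel, date = truth$contacts$date
    )
  )
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    contacts = file.path(dir, "contacts.csv"),
    truth = file.path(dir, "truth.csv"),
    denominators = file.path(dir, "denominators.csv")
  )
  res <- tryCatch({
    readr::write_csv(patients, paths["patients"], na = "")
    readr::write_csv(contacts, paths["contacts"], na = "")
    readr::write_csv(ledger, paths["truth"], na = "")
    readr::write_csv(truth$denominators, paths["denominators"], na = "")
  }, error = function(e) {
    stop("failed writing dataset under ", dir, ": ", conditionMessage(e),
         call. = FALSE)
  })
  paths
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  list(
    patients = rd("patients.csv", readr::cols(
      patient_id = "c", birth_date = "D", sex = "c", practice_id = "c",
      registration_start = "D", registration_end = "D",
      deregistration_reason = "c", death_in_period = "l", zip_available = "l"
    )),
    contacts = rd("contacts.csv", readr::cols(
      contact_id = "c", patient_id = "c", date = "D", icpc_codes = "c",
      note_text = "c", contact_type = "c", in_office_hours = "l"
    )),
    truth = rd("truth.csv", readr::cols(
      level = "c", patient_id = "c", contact_id = "c", pregnant = "l",
      episode_start = "D", episode_end = "D", eligible = "l", trait = "c",
      channel = "c", date = "D"
    )),
    denominators = rd("denominators.csv", readr::cols(
      date = "D", denominator = "i"
    ))
  )
}
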