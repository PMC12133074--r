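# in-code fixture builders shared across test files

fix_patients <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    birth_date = as.Date("1990-06-15"),
    sex = "female",
    practice_id = "PR01",
    registration_start = as.Date("2018-01-01"),
    registration_end = as.Date(NA),
    deregistration_reason = NA_character_,
    death_in_period = FALSE,
    zip_available = TRUE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

fix_contacts <- function(patient_id, dates, codes = "W78",
                         note = "controle", type = "clinic", office = TRUE) {
  n <- max(length(patient_id), length(dates))
  tibble::tibble(
    contact_id = sprintf("C%04d", seq_len(n)),
    patient_id = rep_len(patient_id, n),
    date = as.Date(rep_len(dates, n)),
    icpc_codes = rep_len(codes, n),
    note_text = rep_len(note, n),
    contact_type = rep_len(type, n),
    in_office_hours = rep_len(office, n)
  )
}

# small, fast synthetic dataset reused by several files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_ehr(simulation_config(n_patients = 1500, seed = 42))
    }
    cache
  }
})

# two-sided Fisher exact P by direct hypergeometric enumeration over all
# tables with the observed margins (binomial coefficients only)
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  px <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  sum(px[px <= px[xs == a] * (1 + 1e-7)])
}

# OLS via explicit normal equations, for oracle comparisons
ols_normal_equations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(solve(XtX)) * s2))
}
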