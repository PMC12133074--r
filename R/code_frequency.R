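#' Rank pregnancy-relevant ICPC codes by registration count
#'
#' Counts registrations of each code in `relevant_codes` over the included
#' contacts (a contact carrying m relevant codes contributes m
#' registrations; a sub-coded registration such as W78.01 counts towards its
#' base code when only the base is listed) and returns the top `k`, ties
#' broken lexicographically.
#'
#' @param contacts Included contact tibble with `icpc_codes` (`;`-separated).
#' @param relevant_codes Character vector of codes, or a tibble with a
#'   `code` column ([default_relevant_codes()]).
#' @param k Number of codes returned.
#' @return Tibble `code`, `registrations`, sorted by count descending.
#' @export
rank_pregnancy_codes <- function(contacts,
                                 relevant_codes = default_relevant_codes(),
                                 k = 10L) {
  if (is.data.frame(relevant_codes)) relevant_codes <- relevant_codes$code
  if (length(relevant_codes) == 0L) {
    stop("`relevant_codes` must be nonempty", call. = FALSE)
  }
  if (k <= 0L) return(tibble::tibble(code = character(), registrations = integer()))
  all_codes <- unlist(split_icpc(contacts$icpc_codes))
  counts <- vapply(relevant_codes, function(r) {
    sum(all_codes == r | sub("\\..*$", "", all_codes) == r)
  }, integer(1))
  out <- tibble::tibble(code = relevant_codes, registrations = unname(counts))
  out <- out[order(-out$registrations, out$code), ]
  utils::head(out, k)
}

# does each contact carry the code (presence) / how many registrations of it
code_presence <- function(icpc_codes, code) {
  vapply(split_icpc(icpc_codes), function(cc) {
    any(cc == code | sub("\\..*$", "", cc) == code)
  }, logical(1))
}

code_registrations <- function(icpc_codes, code) {
  vapply(split_icpc(icpc_codes), function(cc) {
    sum(cc == code | sub("\\..*$", "", cc) == code)
  }, integer(1))
}

#' Fisher exact test of a code's frequency in a subphase vs baseline
#'
#' Builds the 2x2 table of contact-level code presence (`a` = contacts in
#' the subphase carrying the code, `b` = without it; `c`, `d` the same in
#' the baseline) and tests it with a two-sided Fisher exact test (sum of
#' hypergeometric probabilities not exceeding the observed table's). Both
#' normalisation views are attached: presence per 1000 contacts (`rate_*`)
#' and registrations per 1000 contacts (`reg_rate_*`, where a code
#' registered twice on one contact counts twice).
#'
#' @param code ICPC code.
#' @param phase_contacts,baseline_contacts Contact tibbles of the subphase
#'   and the baseline; both must be nonempty.
#' @param subphase Optional subphase id echoed in the output.
#' @return One-row tibble with the table cells, rates, `p`, and a
#'   `degenerate` flag (all-zero presence column, P reported as 1).
#' @export
fisher_code_phase <- function(code, phase_contacts, baseline_contacts,
                              subphase = NA_character_) {
  n1 <- nrow(phase_contacts)
  n0 <- nrow(baseline_contacts)
  if (n1 == 0L || n0 == 0L) {
    stop("both contact sets must be nonempty", call. = FALSE)
  }
  a <- sum(code_presence(phase_contacts$icpc_codes, code))
  c_ <- sum(code_presence(baseline_contacts$icpc_codes, code))
  b <- n1 - a
  d <- n0 - c_
  degenerate <- (a + c_ == 0L) || (b + d == 0L)
  p <- if (degenerate) 1 else
    stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))$p.value
  tibble::tibble(
    code = code,
    subphase = subphase,
    a = a, b = b, c = c_, d = d,
    rate_phase = 1000 * a / n1,
    rate_baseline = 1000 * c_ / n0,
    reg_rate_phase = 1000 * sum(code_registrations(phase_contacts$icpc_codes, code)) / n1,
    reg_rate_baseline = 1000 * sum(code_registrations(baseline_contacts$icpc_codes, code)) / n0,
    p = min(p, 1),
    degenerate = degenerate
  )
}

#' Per-code, per-subphase frequency surveillance grid
#'
#' Ranks the `k` most registered pregnancy-relevant codes, then tests each
#' against the baseline in every pandemic subphase with
#' [fisher_code_phase()]. No multiple-testing correction is applied by
#' default, mirroring the per-test alpha = .05 convention of the reference
#' analysis; `adjust = "BH"` appends Benjamini-Hochberg adjusted values in
#' `p_adjusted`.
#'
#' @param contacts Included contact tibble.
#' @param calendar Phase calendar used to assign contacts to subphases.
#' @param relevant_codes,k See [rank_pregnancy_codes()].
#' @param baseline Baseline subphase id.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble, one row per code x pandemic subphase.
#' @export
code_phase_tests <- function(contacts, calendar,
                             relevant_codes = default_relevant_codes(),
                             k = 10L, baseline = "0",
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  top <- rank_pregnancy_codes(contacts, relevant_codes, k)
  sp <- subphase_of(calendar, contacts$date)
  base_contacts <- contacts[sp == baseline, ]
  phases <- setdiff(unique(sp), baseline)
  phases <- phases[order(match(phases, levels(calendar$subphase)))]
  out <- dplyr::bind_rows(lapply(phases, function(ph) {
    pc <- contacts[sp == ph, ]
    dplyr::bind_rows(lapply(top$code, function(cd) {
      fisher_code_phase(cd, pc, base_contacts, subphase = ph)
    }))
  }))
  if (adjust == "BH" && nrow(out) > 0L) {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  }
  out
}
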