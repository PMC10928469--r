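# Fixture builders shared across test files. Everything is constructed in
# code; no stored data.

day0 <- as.Date("2019-01-01")

# one claim row; start/end given as integer day offsets from day0
claim_row <- function(id, start, end, dx, evidence = character(0),
                      patient = "p1", hospital = "h1", type = "tertiary") {
  tibble::tibble(
    claim_id = id, patient_id = patient, hospital_id = hospital,
    hospital_type = type, start_date = day0 + start, end_date = day0 + end,
    dx = list(dx), evidence = list(evidence)
  )
}

claims_tbl <- function(...) dplyr::bind_rows(...)

# one-row episode for exercising the rule engine directly
make_episode <- function(disease, prim = character(0), sec = character(0),
                         evidence = character(0), length_days = 1L,
                         death = FALSE) {
  tibble::tibble(
    patient_id = "p1", disease = disease, episode_index = 1L,
    episode_start = day0, episode_end = day0 + length_days - 1L,
    episode_length_days = as.integer(length_days), n_claims = 1L,
    in_episode_death = death, evidence_union = list(evidence),
    dx_primary_groups = list(prim), dx_secondary_groups = list(sec),
    first_visit_hospital_type = "tertiary",
    highest_level_hospital_type = "tertiary", claim_ids = list("c1")
  )
}

# random episode-grouping instance: <= 5 claims in a 120-day window
random_instance <- function(max_claims = 5L, window = 120L, max_stay = 40L) {
  n <- sample(seq_len(max_claims), 1L)
  s <- sample(0:window, n, replace = TRUE)
  e <- s + sample(0:max_stay, n, replace = TRUE)
  o <- order(s, e)
  tibble::tibble(
    claim_id = sprintf("c%02d", seq_len(n)), patient_id = "p1",
    hospital_id = "h1", hospital_type = "tertiary",
    start_date = day0 + s[o], end_date = day0 + e[o],
    dx = rep(list("I21.0"), n), evidence = rep(list(character(0)), n)
  )
}
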