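test_that("disease-stream selection is by code group at any position", {
  claims <- claims_tbl(
    claim_row("c1", 0, 1, "I21"),
    claim_row("c2", 10, 11, "I63"),
    claim_row("c3", 20, 21, c("I50", "J18", "I21.4")), # AMI at position 3
    claim_row("c4", 30, 31, c("I21", "I63")) # both streams
  )
  expect_setequal(select_disease_claims(claims, "AMI")$claim_id, c("c1", "c3", "c4"))
  expect_setequal(select_disease_claims(claims, "STROKE")$claim_id, c("c2", "c4"))
})

test_that("a single claim forms one episode with inclusive day count", {
  ep <- group_claims(claims_tbl(claim_row("c1", 3, 7, "I21", "ECG")), "AMI")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$episode_length_days, 5L)
  expect_equal(ep$n_claims, 1L)
  ep1 <- group_claims(claims_tbl(claim_row("c1", 3, 3, "I21")), "AMI")
  expect_equal(ep1$episode_length_days, 1L) # same-day admission/discharge
})

test_that("consecutive 30-day billing fragments merge despite the 28-day gap", {
  # fragment starts 30 days apart (gap 30 > 28) but discharge-to-admission
  # interval is 1 day (< 3): only one split condition holds, so merge
  claims <- claims_tbl(
    claim_row("c1", 0, 29, "I21", "PCI"),
    claim_row("c2", 30, 44, "I21")
  )
  ep <- group_claims(claims, "AMI")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$episode_length_days, 45L)
  expect_equal(ep$evidence_union[[1]], "PCI")
})

test_that("claims separated on both conditions split into two episodes", {
  claims <- claims_tbl(
    claim_row("c1", 0, 5, "I21"),
    claim_row("c2", 40, 42, "I21")
  )
  ep <- group_claims(claims, "AMI")
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$episode_index, 1:2)
})

test_that("chained merging follows the pairwise gap rule", {
  # A-B merge (first-date gap 20 <= 28); B-C split (gap 30 > 28 AND
  # interval 29 >= 3) -> {A,B}, {C}
  claims <- claims_tbl(
    claim_row("cA", 0, 5, "I21"),
    claim_row("cB", 20, 21, "I21"),
    claim_row("cC", 50, 51, "I21")
  )
  ep <- group_claims(claims, "AMI")
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$claim_ids, list(c("cA", "cB"), "cC"))
})

test_that("episode aggregates cover evidence, code positions and hospitals", {
  claims <- claims_tbl(
    claim_row("c1", 0, 2, c("I63.1", "I50"), "BRAIN_IMAGING", type = "secondary"),
    claim_row("c2", 3, 4, c("J18", "I63"), "STROKE_INTERVENTION", type = "tertiary")
  )
  ep <- group_claims(claims, "STROKE")
  expect_equal(ep$evidence_union[[1]], c("BRAIN_IMAGING", "STROKE_INTERVENTION"))
  expect_equal(ep$dx_primary_groups[[1]], c("I63", "J18"))
  expect_equal(ep$dx_secondary_groups[[1]], c("I50", "I63"))
  expect_equal(ep$first_visit_hospital_type, "secondary")
  expect_equal(ep$highest_level_hospital_type, "tertiary")
})

test_that("in-episode death requires the death date inside the episode span", {
  claims <- claims_tbl(claim_row("c1", 0, 5, "I21"))
  expect_true(group_claims(claims, "AMI", death_date = day0 + 5)$in_episode_death)
  expect_true(group_claims(claims, "AMI", death_date = day0)$in_episode_death)
  expect_false(group_claims(claims, "AMI", death_date = day0 + 6)$in_episode_death)
})

test_that("contract violations are rejected", {
  unsorted <- dplyr::bind_rows(
    claim_row("c2", 50, 51, "I21"),
    claim_row("c1", 0, 1, "I21")
  )
  expect_error(group_claims(unsorted, "AMI"), "sorted")
  two_patients <- claims_tbl(
    claim_row("c1", 0, 1, "I21", patient = "p1"),
    claim_row("c2", 5, 6, "I21", patient = "p2")
  )
  expect_error(group_claims(two_patients, "AMI"), "single patient")
})

test_that("grouping matches the brute-force partition oracle on random instances", {
  set.seed(42)
  for (i in 1:300) {
    inst <- random_instance()
    ep <- group_claims(inst, "AMI")
    expect_equal(
      ids_from_episodes(ep),
      oracle_episode_ids(as.integer(inst$start_date), as.integer(inst$end_date)),
      info = paste("instance", i)
    )
    # partition property: concatenated members reproduce the input order
    expect_equal(unlist(ep$claim_ids), inst$claim_id)
  }
})

test_that("episode grouping is idempotent and monotone in the gap threshold", {
  set.seed(43)
  for (i in 1:100) {
    inst <- random_instance()
    ep <- group_claims(inst, "AMI")
    # idempotence: regrouping one episode's claims yields one episode
    for (k in seq_len(nrow(ep))) {
      member <- inst[inst$claim_id %in% ep$claim_ids[[k]], ]
      expect_equal(nrow(group_claims(member, "AMI")), 1L)
    }
    # shrinking the gap threshold never decreases the episode count
    n28 <- nrow(ep)
    n14 <- nrow(group_claims(inst, "AMI", gap_days = 14L))
    n0 <- nrow(group_claims(inst, "AMI", gap_days = 0L))
    expect_true(n14 >= n28 && n0 >= n14)
  }
})

test_that("pairwise interval mode can split where the episode-max mode merges", {
  # nested claim: c2 lies inside c1; c3 starts 29+ days after c2 ends but
  # within 3 days of c1's end -> episode-max merges, pairwise splits
  claims <- claims_tbl(
    claim_row("c1", 0, 40, "I21"),
    claim_row("c2", 5, 6, "I21"),
    claim_row("c3", 42, 43, "I21")
  )
  expect_equal(nrow(group_claims(claims, "AMI")), 1L)
  expect_equal(nrow(group_claims(claims, "AMI", interval_mode = "pairwise")), 2L)
})

test_that("cohort episode building keeps disease streams independent", {
  claims <- claims_tbl(
    claim_row("c1", 0, 2, c("I21", "I63"), "PCI"),
    claim_row("c2", 100, 101, "I63", "BRAIN_IMAGING", patient = "p2")
  )
  deaths <- tibble::tibble(patient_id = "p2", death_date = day0 + 101)
  eps <- build_episodes(claims, deaths)
  expect_equal(nrow(eps), 3L) # p1 AMI, p1 STROKE, p2 STROKE
  expect_setequal(eps$disease[eps$patient_id == "p1"], c("AMI", "STROKE"))
  expect_true(eps$in_episode_death[eps$patient_id == "p2"])
  expect_false(any(eps$in_episode_death[eps$patient_id == "p1"]))
})
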