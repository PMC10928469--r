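test_that("claims CSV round-trips through write and read", {
  claims <- claims_tbl(
    claim_row("c1", 0, 5, c("I21.0", "I50.9"), c("ECG", "PCI")),
    claim_row("c2", 40, 41, "I63.1", "BRAIN_IMAGING", patient = "p2", type = "primary"),
    claim_row("c3", 10, 12, "I60", character(0), patient = "p2", type = "secondary")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_claims(claims, path)
  back <- read_claims(path)
  expect_equal(as.data.frame(back), as.data.frame(sort_claims <- claims[order(
    claims$patient_id, claims$start_date, claims$end_date, claims$claim_id
  ), ]), ignore_attr = TRUE)
})

test_that("header-only file yields an empty cohort and sorting is restored", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    "claim_id,patient_id,hospital_id,hospital_type,start_date,end_date,dx_codes,evidence",
    path
  )
  expect_equal(nrow(read_claims(path)), 0L)

  # rows written out of date order come back sorted by the full key
  shuffled <- claims_tbl(
    claim_row("c2", 30, 31, "I21"),
    claim_row("c1", 0, 2, "I21"),
    claim_row("c3", 30, 31, "I21")
  )
  write_claims(shuffled, path)
  back <- read_claims(path)
  o <- order(shuffled$start_date, shuffled$end_date, shuffled$claim_id)
  expect_equal(back$claim_id, shuffled$claim_id[o])
  expect_false(is.unsorted(back$start_date))
})

test_that("schema and parse errors are reported with names and lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "claim_id,patient_id,hospital_id,start_date,end_date,dx_codes,evidence",
    "c1,p1,h1,2019-01-01,2019-01-02,I21,"
  ), path)
  expect_error(read_claims(path), "hospital_type")

  writeLines(c(
    "claim_id,patient_id,hospital_id,hospital_type,start_date,end_date,dx_codes,evidence",
    "c1,p1,h1,tertiary,2019-01-01,2019-01-02,I21,",
    "c2,p1,h1,tertiary,not-a-date,2019-01-05,I21,"
  ), path)
  expect_error(read_claims(path), "start_date at line\\(s\\): 3")
})

test_that("raw service codes map through the evidence table; strict mode rejects unknowns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "claim_id,patient_id,hospital_id,hospital_type,start_date,end_date,dx_codes,evidence",
    "c1,p1,h1,tertiary,2019-01-01,2019-01-02,I21,E7071;ECG",
    "c2,p1,h1,tertiary,2019-02-20,2019-02-21,I21,XXXX"
  ), path)
  ev_map <- tibble::tibble(raw_code = "E7071", flag = "PCI")
  expect_error(read_claims(path, evidence_map = ev_map), "XXXX")
  claims <- suppressWarnings(
    read_claims(path, evidence_map = ev_map, strict = FALSE)
  )
  expect_setequal(claims$evidence[[1]], c("PCI", "ECG"))
  expect_length(claims$evidence[[2]], 0)
  expect_warning(
    read_claims(path, evidence_map = ev_map, strict = FALSE),
    "XXXX"
  )
})

test_that("claims validation enforces the record invariants", {
  expect_error(
    new_claims("c1", "p1", "h1", "tertiary", day0 + 5, day0, list("I21"), list(character(0))),
    "start_date after end_date"
  )
  expect_error(
    new_claims("c1", "p1", "h1", "tertiary", day0, day0, list(character(0)), list(character(0))),
    "without diagnosis"
  )
  expect_error(
    new_claims("c1", "p1", "h1", "tertiary", day0, day0, list("21I"), list(character(0))),
    "malformed"
  )
  expect_error(
    new_claims("c1", "p1", "h1", "tertiary", day0, day0, list("I21"), list("XRAY")),
    "unknown evidence"
  )
  expect_error(
    new_claims("c1", "p1", "h1", "clinic", day0, day0, list("I21"), list(character(0))),
    "hospital_type"
  )
})

test_that("code-group matching is prefix- and position-aware", {
  ami <- code_group("AMI")
  stroke <- code_group("STROKE")
  expect_true(matches_code_group("I21.0", ami, scope = "primary_only"))
  expect_false(matches_code_group(c("I50", "I63"), stroke, scope = "primary_only"))
  expect_true(matches_code_group(c("I50", "I639"), stroke, scope = "secondary_or_lower"))
  expect_false(matches_code_group("I219", stroke, scope = "any"))
  expect_error(matches_code_group("I21", character(0)), "non-empty")

  # brute force over a 6-code grid x positions x scopes against a literal
  # restatement of the position semantics
  codes <- c("I21.0", "I21", "I639", "I50", "I64.2", "J18")
  for (code in codes) {
    for (pos in 1:3) {
      for (group in list(ami, stroke)) {
        in_group <- substr(code, 1, 3) %in% group
        expect_equal(
          matches_code_group(code, group, "primary_only", positions = pos),
          in_group && pos == 1
        )
        expect_equal(
          matches_code_group(code, group, "secondary_or_lower", positions = pos),
          in_group && pos >= 2
        )
        expect_equal(
          matches_code_group(code, group, "any", positions = pos),
          in_group
        )
      }
    }
  }
})

test_that("any-position match equals primary OR secondary match", {
  set.seed(11)
  pool <- c("I21.0", "I22", "I23.9", "I60", "I61.1", "I63", "I64", "I50", "J18", "E11")
  for (i in 1:200) {
    codes <- sample(pool, sample(1:4, 1), replace = TRUE)
    group <- code_group(sample(c("AMI", "STROKE"), 1))
    expect_equal(
      matches_code_group(codes, group, "any"),
      matches_code_group(codes, group, "primary_only") ||
        matches_code_group(codes, group, "secondary_or_lower")
    )
  }
})

test_that("death consistency check flags claims after death", {
  claims <- claims_tbl(claim_row("c1", 10, 12, "I21"))
  deaths <- tibble::tibble(patient_id = "p1", death_date = day0 + 5)
  expect_error(check_death_consistency(claims, deaths), "after patient death")
  expect_true(check_death_consistency(
    claims, tibble::tibble(patient_id = "p1", death_date = day0 + 12)
  ))
})
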