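test_that("ppv point estimates and Wald intervals match hand-checked values", {
  r <- ppv(584, 617)
  expect_equal(r$ppv_percent, 100 * 584 / 617)
  expect_equal(format_ppv(r), "94.7 (92.9, 96.4)")
  expect_equal(format_ppv(ppv(57, 90)), "63.3 (53.4, 73.3)")

  # perfect agreement: upper bound capped at 100
  r100 <- ppv(25, 25)
  expect_equal(r100$ppv_percent, 100)
  expect_equal(r100$ci_high_percent, 100)

  # 0/1: point estimate defined at 0, interval undefined, displayed N/A
  r0 <- ppv(0, 1)
  expect_equal(r0$ppv_percent, 0)
  expect_true(is.na(r0$ci_low_percent))
  expect_equal(format_ppv(r0), "N/A")

  # nothing identified: everything undefined
  rna <- ppv(0, 0)
  expect_true(is.na(rna$ppv_percent))
  expect_equal(format_ppv(rna), "N/A")

  expect_error(ppv(5, 3), "n_true <= n_identified")
})

test_that("ppv is scale-free and its interval narrows with replication", {
  base <- ppv(30, 40)
  for (k in c(2L, 5L, 20L)) {
    scaled <- ppv(30L * k, 40L * k)
    expect_equal(scaled$ppv_percent, base$ppv_percent)
    expect_lt(
      scaled$ci_high_percent - scaled$ci_low_percent,
      base$ci_high_percent - base$ci_low_percent
    )
  }
})

test_that("wilson intervals are valid and contain the point estimate", {
  r <- ppv(57, 90, ci_method = "wilson")
  expect_true(r$ci_low_percent > 0 && r$ci_high_percent < 100)
  expect_true(r$ci_low_percent < r$ppv_percent &&
    r$ppv_percent < r$ci_high_percent)
  # wilson never collapses at the boundary the way wald does
  rw <- ppv(25, 25, ci_method = "wilson")
  expect_lt(rw$ci_low_percent, 100)
})

test_that("unweighted pooling aggregates raw counts", {
  strata <- validation_counts() |>
    dplyr::filter(disease == "AMI", kind == "FIRST")
  pooled <- unweighted_pooled_ppv(strata)
  expect_equal(pooled$n_true, 974L)
  expect_equal(pooled$n_identified, 1106L)
  expect_equal(round(pooled$ppv_percent, 1), 88.1)

  one <- ppv(10, 12)
  expect_equal(unweighted_pooled_ppv(one)$ppv_percent, one$ppv_percent)
  expect_equal(format_ppv(unweighted_pooled_ppv(ppv(0, 0))), "N/A")
})

test_that("weighted pooling reduces to known identities", {
  strata <- tibble::tibble(
    hospital_type = c("tertiary", "secondary", "primary"),
    n_true = c(90L, 80L, 50L), n_identified = c(100L, 100L, 100L),
    ppv_percent = c(90, 80, 50)
  )
  equal_w <- weighted_pooled_ppv(strata, c(tertiary = 1, secondary = 1, primary = 1))
  expect_equal(equal_w$ppv_percent, mean(strata$ppv_percent))

  single <- weighted_pooled_ppv(strata, c(tertiary = 1, secondary = 0, primary = 0))
  expect_equal(single$ppv_percent, 90)

  hand <- weighted_pooled_ppv(strata, c(tertiary = 5, secondary = 3, primary = 2))
  expect_equal(hand$ppv_percent, 79.0) # (5*90 + 3*80 + 2*50) / 10

  expect_error(
    weighted_pooled_ppv(strata, c(tertiary = 0, secondary = 0, primary = 0)),
    "positive-weight"
  )
})

test_that("weighted pooled PPV stays within the stratum range for any weights", {
  set.seed(31)
  counts <- validation_counts()
  groups <- split(counts, list(counts$disease, counts$kind), drop = TRUE)
  for (g in groups) {
    strata <- dplyr::bind_cols(
      g["hospital_type"], ppv(g$n_true, g$n_identified)
    )
    defined <- strata[!is.na(strata$ppv_percent), ]
    for (i in 1:25) {
      w <- stats::setNames(runif(3, 0.1, 100), strata$hospital_type)
      pooled <- suppressWarnings(weighted_pooled_ppv(strata, w))
      expect_gte(pooled$ppv_percent, min(defined$ppv_percent) - 1e-9)
      expect_lte(pooled$ppv_percent, max(defined$ppv_percent) + 1e-9)
    }
  }
})

test_that("published pooled PPVs are consistent with the stratum ranges", {
  # the external case-count weights behind the published pooled values are
  # not reproducible, but any weighting must land inside the stratum range
  counts <- validation_counts()
  pooled_published <- list(
    AMI_FIRST = c(92.0, 92.2), AMI_RECURRENT = c(77.8, 78.2),
    STROKE_FIRST = c(88.2, 88.1), STROKE_RECURRENT = c(80.8, 81.0)
  )
  for (key in names(pooled_published)) {
    parts <- strsplit(key, "_")[[1]]
    g <- counts[counts$disease == parts[1] & counts$kind == parts[2], ]
    p <- 100 * g$n_true / g$n_identified
    p <- p[g$n_identified > 1] # the 0/1 N/A cell carries no estimate
    expect_true(all(pooled_published[[key]] >= min(p) &
      pooled_published[[key]] <= max(p)))
  }
})

test_that("stratum assignment follows the first-visit and highest-level rules", {
  rec <- tibble::tibble(
    hospital_type_first_visit = c("secondary", "primary"),
    hospital_type_highest = c("tertiary", "primary")
  )
  expect_equal(assign_stratum(rec, "first_visit"), c("secondary", "primary"))
  expect_equal(assign_stratum(rec, "highest_level"), c("tertiary", "primary"))
})

test_that("validation_report tabulates strata and pooled rows with display cells", {
  rec <- tibble::tibble(
    patient_id = sprintf("p%d", 1:8),
    disease = "AMI",
    kind = c(rep("FIRST", 6), "RECURRENT", "RECURRENT"),
    episode_index = 1L,
    hospital_type_first_visit = c(rep("tertiary", 4), "secondary", "secondary", "tertiary", "tertiary"),
    hospital_type_highest = "tertiary",
    adjudicated_true = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  rep1 <- validation_report(rec, weights = c(tertiary = 2, secondary = 1))
  first_rows <- rep1[rep1$kind == "FIRST", ]
  expect_setequal(
    first_rows$hospital_type,
    c("tertiary", "secondary", "pooled_unweighted", "pooled_weighted")
  )
  tert <- first_rows[first_rows$hospital_type == "tertiary", ]
  expect_equal(tert$n_true, 3L)
  expect_equal(tert$n_identified, 4L)
  pooled <- first_rows[first_rows$hospital_type == "pooled_unweighted", ]
  expect_equal(pooled$n_identified, 6L)
  expect_true(all(grepl("^(N/A|[0-9.]+ \\()", rep1$display)))

  # highest-level rule moves the secondary first-visit events to tertiary
  rep2 <- validation_report(rec, rule = "highest_level")
  expect_false("secondary" %in% rep2$hospital_type)
})
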