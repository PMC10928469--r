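# Hospitalization-episode construction.
#
# Claims data fragment single disease events: stays longer than the billing
# cycle are submitted as distinct ~30-day claims, and complication
# readmissions shortly after discharge file fresh claims for the same event.
# Consecutive disease-coded claims A and B are therefore split into separate
# hospitalization episodes only when BOTH hold:
#   (1) the gap between the first dates of A and B exceeds `gap_days` (28),
#   (2) the interval from the last date of A to the first date of B spans
#       `interval_days` (3) days or longer.
# Either condition alone keeps them in one episode: 30-day billing fragments
# fail (2), early complication readmissions fail (1) or (2).

#' Select a patient's claims for one disease stream
#'
#' Returns the sorted subset of claims carrying a diagnosis code of the
#' disease's group ([code_group]) at any position. A claim carrying both AMI
#' and stroke codes appears in both disease streams.
#'
#' @param claims A claims tibble (any number of patients).
#' @param disease `"AMI"` or `"STROKE"`.
#' @return The filtered claims tibble, original sort order preserved.
#' @export
select_disease_claims <- function(claims, disease) {
  group <- code_group(disease)
  keep <- vapply(
    claims$dx, function(codes) any(dx_prefix(codes) %in% group), logical(1)
  )
  claims[keep, , drop = FALSE]
}

# Core episode assignment on date vectors. Returns an integer episode id per
# claim (1-based, nondecreasing). Claims must be in (start, end, id) order.
# interval_mode "episode_max" compares B.start against the running maximum
# end date of the current episode (robust to nested/overlapping claims);
# "pairwise" compares against the immediately preceding claim's end date
# (the literal pairwise reading, kept for sensitivity analysis).
episode_ids <- function(start, end, gap_days = 28L, interval_days = 3L,
                        interval_mode = c("episode_max", "pairwise")) {
  interval_mode <- match.arg(interval_mode)
  n <- length(start)
  if (n == 0L) {
    return(integer(0))
  }
  if (is.unsorted(start)) {
    stop("claims must be sorted by start date", call. = FALSE)
  }
  ids <- integer(n)
  ids[1L] <- 1L
  prev_start <- start[1L]
  ref_end <- end[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- start[i] - prev_start
    interval <- start[i] - ref_end
    if (gap > gap_days && interval >= interval_days) {
      ids[i] <- ids[i - 1L] + 1L
      ref_end <- end[i]
    } else {
      ids[i] <- ids[i - 1L]
      ref_end <- if (interval_mode == "episode_max") max(ref_end, end[i]) else end[i]
    }
    prev_start <- start[i]
  }
  ids
}

#' Group one patient's disease claims into hospitalization episodes
#'
#' Partitions sorted single-patient, single-disease claims into episodes
#' using the two split conditions (see the episode rule in the package
#' vignette): a claim starts a new episode only when its first date is both
#' more than `gap_days` after the first date of the previously appended
#' claim and at least `interval_days` after the episode's latest end date.
#'
#' @param claims Claims tibble for one patient, sorted by
#'   `(start_date, end_date, claim_id)`; all claims must carry a code of
#'   `disease`'s group.
#' @param disease `"AMI"` or `"STROKE"`.
#' @param death_date Optional `Date`; sets `in_episode_death` for the episode
#'   whose span contains it. A death after discharge does not count.
#' @param gap_days Split condition (1) threshold, strictly exceeded; default
#'   28 days.
#' @param interval_days Split condition (2) threshold, met at or above;
#'   default 3 days.
#' @param interval_mode `"episode_max"` (default) measures the interval from
#'   the episode's running maximum end date; `"pairwise"` from the preceding
#'   claim's end date only.
#' @return Episodes tibble: `patient_id, disease, episode_index,
#'   episode_start, episode_end, episode_length_days, n_claims,
#'   in_episode_death, evidence_union, dx_primary_groups,
#'   dx_secondary_groups, first_visit_hospital_type,
#'   highest_level_hospital_type, claim_ids` (the last five are list or
#'   derived columns; lengths in whole days, same-day admission/discharge = 1).
#' @export
group_claims <- function(claims, disease, death_date = NULL,
                         gap_days = 28L, interval_days = 3L,
                         interval_mode = c("episode_max", "pairwise")) {
  interval_mode <- match.arg(interval_mode)
  disease <- match.arg(disease, c("AMI", "STROKE"))
  if (nrow(claims) == 0) {
    return(empty_episodes())
  }
  if (length(unique(claims$patient_id)) > 1L) {
    stop("group_claims expects claims from a single patient", call. = FALSE)
  }
  key_order <- order(claims$start_date, claims$end_date, claims$claim_id)
  if (!identical(key_order, seq_len(nrow(claims)))) {
    stop("claims must be sorted by (start_date, end_date, claim_id)",
      call. = FALSE
    )
  }
  ids <- episode_ids(
    as.integer(claims$start_date), as.integer(claims$end_date),
    gap_days = gap_days, interval_days = interval_days,
    interval_mode = interval_mode
  )
  rows <- lapply(split(seq_len(nrow(claims)), factor(ids, levels = unique(ids))), function(idx) {
    member <- claims[idx, , drop = FALSE]
    ep_start <- min(member$start_date)
    ep_end <- max(member$end_date)
    prim <- unique(dx_prefix(vapply(member$dx, `[`, character(1), 1L)))
    sec <- unique(dx_prefix(unlist(
      lapply(member$dx, function(v) v[-1L]),
      use.names = FALSE
    )))
    lvl <- match(member$hospital_type, hospital_type_levels)
    tibble::tibble(
      patient_id = member$patient_id[1L],
      disease = disease,
      episode_start = ep_start,
      episode_end = ep_end,
      episode_length_days = as.integer(ep_end - ep_start) + 1L,
      n_claims = nrow(member),
      in_episode_death = !is.null(death_date) && !is.na(death_date) &&
        ep_start <= death_date && death_date <= ep_end,
      evidence_union = list(sort(unique(unlist(member$evidence, use.names = FALSE)))),
      dx_primary_groups = list(sort(prim)),
      dx_secondary_groups = list(sort(sec)),
      first_visit_hospital_type = member$hospital_type[1L],
      highest_level_hospital_type = hospital_type_levels[max(lvl)],
      claim_ids = list(member$claim_id)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$episode_index <- seq_len(nrow(out))
  out[c(
    "patient_id", "disease", "episode_index", "episode_start", "episode_end",
    "episode_length_days", "n_claims", "in_episode_death", "evidence_union",
    "dx_primary_groups", "dx_secondary_groups", "first_visit_hospital_type",
    "highest_level_hospital_type", "claim_ids"
  )]
}

empty_episodes <- function() {
  tibble::tibble(
    patient_id = character(0), disease = character(0),
    episode_index = integer(0),
    episode_start = as.Date(character(0)), episode_end = as.Date(character(0)),
    episode_length_days = integer(0), n_claims = integer(0),
    in_episode_death = logical(0), evidence_union = list(),
    dx_primary_groups = list(), dx_secondary_groups = list(),
    first_visit_hospital_type = character(0),
    highest_level_hospital_type = character(0), claim_ids = list()
  )
}

#' Build hospitalization episodes for a cohort
#'
#' Applies [select_disease_claims()] and [group_claims()] per patient and
#' disease stream. The AMI and stroke streams are independent; a claim with
#' both code groups contributes to both.
#'
#' @param claims A claims tibble (validated, any number of patients).
#' @param deaths Optional deaths tibble (`patient_id`, `death_date`).
#' @param disease `"both"` (default), `"AMI"`, or `"STROKE"`.
#' @inheritParams group_claims
#' @return Episodes tibble (see [group_claims()]), ordered by
#'   `(patient_id, disease, episode_index)`.
#' @export
build_episodes <- function(claims, deaths = NULL, disease = c("both", "AMI", "STROKE"),
                           gap_days = 28L, interval_days = 3L,
                           interval_mode = c("episode_max", "pairwise")) {
  disease <- match.arg(disease)
  interval_mode <- match.arg(interval_mode)
  validate_claims(claims)
  check_death_consistency(claims, deaths)
  claims <- sort_claims(claims)
  diseases <- if (disease == "both") c("AMI", "STROKE") else disease
  death_lookup <- if (is.null(deaths) || nrow(deaths) == 0) {
    stats::setNames(as.Date(character(0)), character(0))
  } else {
    stats::setNames(deaths$death_date, deaths$patient_id)
  }
  pieces <- list()
  for (dis in diseases) {
    stream <- select_disease_claims(claims, dis)
    if (nrow(stream) == 0) next
    for (pc in split(stream, stream$patient_id)) {
      dd <- death_lookup[pc$patient_id[1L]]
      pieces[[length(pieces) + 1L]] <- group_claims(
        pc, dis,
        death_date = if (is.na(dd)) NULL else dd,
        gap_days = gap_days, interval_days = interval_days,
        interval_mode = interval_mode
      )
    }
  }
  if (length(pieces) == 0) {
    return(empty_episodes())
  }
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$patient_id, .data$disease, .data$episode_index)
}

#' Write episodes to CSV
#'
#' List columns (evidence union, code-prefix sets, member claim ids) are
#' collapsed to semicolon-separated fields.
#'
#' @param episodes Episodes tibble from [build_episodes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  out <- tibble::tibble(
    patient_id = episodes$patient_id,
    disease = episodes$disease,
    episode_index = episodes$episode_index,
    episode_start = format(episodes$episode_start, "%Y-%m-%d"),
    episode_end = format(episodes$episode_end, "%Y-%m-%d"),
    episode_length_days = episodes$episode_length_days,
    n_claims = episodes$n_claims,
    in_episode_death = as.integer(episodes$in_episode_death),
    evidence_union = join_field(episodes$evidence_union),
    dx_primary_groups = join_field(episodes$dx_primary_groups),
    dx_secondary_groups = join_field(episodes$dx_secondary_groups),
    first_visit_hospital_type = episodes$first_visit_hospital_type,
    highest_level_hospital_type = episodes$highest_level_hospital_type,
    member_claim_ids = join_field(episodes$claim_ids)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
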