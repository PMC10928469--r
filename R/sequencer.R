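# Chronological sequencing of episodes into first/recurrent event calls.
#
# Per patient and disease: until a first event is found, each episode is
# tested with the first-event algorithm only; episodes that fail produce no
# event and do not block later first-event detection. From the first event
# onward, each episode is tested with the (stricter) recurrent-event
# algorithm only — an episode meeting the first-event criteria but not the
# recurrent criteria emits nothing.

#' Sequence one patient's episodes into event calls
#'
#' @param episodes Classified episodes ([classify_episodes()]) for a single
#'   patient and disease, sorted by `(episode_start, episode_end)`.
#' @return Event-call tibble: `patient_id, disease, kind, episode_index,
#'   event_date` (the episode start), `rule_branch`, plus the episode's
#'   hospital-type and length fields carried through for validation
#'   stratification.
#' @export
sequence_patient <- function(episodes) {
  n <- nrow(episodes)
  if (n > 0) {
    if (length(unique(episodes$patient_id)) > 1L ||
      length(unique(episodes$disease)) > 1L) {
      stop("sequence_patient expects one patient and one disease stream",
        call. = FALSE
      )
    }
    if (is.unsorted(episodes$episode_start)) {
      stop("episodes must be sorted by episode_start", call. = FALSE)
    }
  }
  keep <- integer(0)
  kind <- character(0)
  branch <- character(0)
  first_seen <- FALSE
  for (i in seq_len(n)) {
    if (!first_seen) {
      b <- episodes$first_branch[i]
      if (!is.na(b)) {
        keep <- c(keep, i)
        kind <- c(kind, "FIRST")
        branch <- c(branch, b)
        first_seen <- TRUE
      }
    } else {
      b <- episodes$recurrent_branch[i]
      if (!is.na(b)) {
        keep <- c(keep, i)
        kind <- c(kind, "RECURRENT")
        branch <- c(branch, b)
      }
    }
  }
  tibble::tibble(
    patient_id = episodes$patient_id[keep],
    disease = episodes$disease[keep],
    kind = kind,
    episode_index = episodes$episode_index[keep],
    event_date = episodes$episode_start[keep],
    rule_branch = branch,
    episode_length_days = episodes$episode_length_days[keep],
    in_episode_death = episodes$in_episode_death[keep],
    first_visit_hospital_type = episodes$first_visit_hospital_type[keep],
    highest_level_hospital_type = episodes$highest_level_hospital_type[keep]
  )
}

#' Identify first and recurrent events for a whole cohort
#'
#' Runs the full pipeline — disease-stream selection, episode grouping,
#' rule classification and chronological sequencing — for every patient and
#' requested disease stream. Deterministic given the input.
#'
#' @inheritParams build_episodes
#' @return Event-call tibble (see [sequence_patient()]) ordered by
#'   `(patient_id, disease, event_date)`.
#' @export
identify_events <- function(claims, deaths = NULL,
                            disease = c("both", "AMI", "STROKE"),
                            gap_days = 28L, interval_days = 3L,
                            interval_mode = c("episode_max", "pairwise")) {
  episodes <- build_episodes(claims, deaths,
    disease = match.arg(disease),
    gap_days = gap_days, interval_days = interval_days,
    interval_mode = match.arg(interval_mode)
  )
  sequence_episodes(episodes)
}

#' Sequence pre-built episodes into event calls
#'
#' Classifies and sequences an episodes table covering any number of
#' patients and both disease streams.
#'
#' @param episodes Episodes tibble from [build_episodes()].
#' @return Event-call tibble, ordered by `(patient_id, disease, event_date)`.
#' @export
sequence_episodes <- function(episodes) {
  if (nrow(episodes) == 0) {
    return(sequence_patient(classify_episodes(empty_episodes())))
  }
  episodes <- classify_episodes(episodes)
  parts <- split(
    episodes,
    list(episodes$patient_id, episodes$disease),
    drop = TRUE
  )
  out <- dplyr::bind_rows(lapply(parts, sequence_patient))
  dplyr::arrange(out, .data$patient_id, .data$disease, .data$event_date)
}

#' Write event calls to CSV
#'
#' @param events Event-call tibble from [identify_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$event_date <- format(out$event_date, "%Y-%m-%d")
  out$in_episode_death <- as.integer(out$in_episode_death)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
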