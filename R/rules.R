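# Rule tables for first and recurrent AMI/stroke event identification.
#
# Each algorithm is a short hierarchy of branches. A branch has a
# diagnosis-code precondition over the episode's primary/secondary code
# prefixes and a boolean criterion over procedure evidence, episode length
# and in-episode death. Branches are evaluated top to bottom: the FIRST
# branch whose code precondition matches selects the criterion; if that
# criterion fails the episode is not an event (no fall-through), mirroring
# the mutually exclusive (+)/(-) row preconditions of the published tables.
#
# The branches are kept as data (precondition + criterion closures) so the
# production engine stays declarative and shares no logic with the
# independent truth-table oracle used in the tests.

ami_evidence_first <- c("ECG", "CARDIAC_ENZYME", "CAG", "PCI", "CABG")
ami_evidence_confirmatory <- c("CAG", "PCI", "CABG")
ami_evidence_therapeutic <- c("PCI", "CABG")

# criterion helpers; ev = evidence character vector, len = days, death = flag
has_any <- function(ev, flags) any(flags %in% ev)
long_or_death <- function(len, death) len >= 3L || death

rule_branch_table <- function() {
  list(
    # --- first AMI: primary-position code needs any supporting evidence or
    # in-episode death (covers type 3 MI deaths before workup); a code only
    # at secondary or lower needs confirmatory CAG/PCI/CABG.
    list(
      id = "AMI_F1", disease = "AMI", kind = "FIRST",
      pre = function(prim, sec) any(c("I21", "I22", "I23") %in% prim),
      crit = function(ev, len, death) has_any(ev, ami_evidence_first) || death
    ),
    list(
      id = "AMI_F2", disease = "AMI", kind = "FIRST",
      pre = function(prim, sec) any(c("I21", "I22", "I23") %in% sec),
      crit = function(ev, len, death) has_any(ev, ami_evidence_confirmatory)
    ),
    # --- recurrent AMI: any-position code; therapeutic PCI/CABG plus a
    # >= 3-day episode unless interrupted by death (guards against angina
    # admissions carrying stale codes).
    list(
      id = "AMI_R", disease = "AMI", kind = "RECURRENT",
      pre = function(prim, sec) any(c("I21", "I22", "I23") %in% c(prim, sec)),
      crit = function(ev, len, death) {
        has_any(ev, ami_evidence_therapeutic) && long_or_death(len, death)
      }
    ),
    # --- first stroke: ischemic/unspecified (I63-I64) primary, or
    # hemorrhagic (I60-I61) in any position, accept brain imaging with an
    # acute-course stay (or death), a therapeutic intervention, or death
    # alone; I63-I64 only at secondary or lower needs an intervention plus
    # the acute-course condition.
    list(
      id = "STROKE_F1", disease = "STROKE", kind = "FIRST",
      pre = function(prim, sec) any(c("I63", "I64") %in% prim),
      crit = function(ev, len, death) {
        (has_any(ev, "BRAIN_IMAGING") && long_or_death(len, death)) ||
          has_any(ev, "STROKE_INTERVENTION") || death
      }
    ),
    list(
      id = "STROKE_F2", disease = "STROKE", kind = "FIRST",
      pre = function(prim, sec) any(c("I60", "I61") %in% c(prim, sec)),
      crit = function(ev, len, death) {
        (has_any(ev, "BRAIN_IMAGING") && long_or_death(len, death)) ||
          has_any(ev, "STROKE_INTERVENTION") || death
      }
    ),
    list(
      id = "STROKE_F3", disease = "STROKE", kind = "FIRST",
      pre = function(prim, sec) any(c("I63", "I64") %in% sec),
      crit = function(ev, len, death) {
        has_any(ev, "STROKE_INTERVENTION") && long_or_death(len, death)
      }
    ),
    # --- recurrent stroke: every branch requires the >= 3-day/death
    # condition; primary-position codes accept imaging or intervention,
    # secondary-only codes require an intervention.
    list(
      id = "STROKE_R1", disease = "STROKE", kind = "RECURRENT",
      pre = function(prim, sec) any(c("I63", "I64") %in% prim),
      crit = function(ev, len, death) {
        has_any(ev, c("BRAIN_IMAGING", "STROKE_INTERVENTION")) &&
          long_or_death(len, death)
      }
    ),
    list(
      id = "STROKE_R2", disease = "STROKE", kind = "RECURRENT",
      pre = function(prim, sec) any(c("I60", "I61") %in% prim),
      crit = function(ev, len, death) {
        has_any(ev, c("BRAIN_IMAGING", "STROKE_INTERVENTION")) &&
          long_or_death(len, death)
      }
    ),
    list(
      id = "STROKE_R3", disease = "STROKE", kind = "RECURRENT",
      pre = function(prim, sec) any(c("I60", "I61", "I63", "I64") %in% sec),
      crit = function(ev, len, death) {
        has_any(ev, "STROKE_INTERVENTION") && long_or_death(len, death)
      }
    )
  )
}

.branches <- NULL

branches_for <- function(disease, kind) {
  if (is.null(.branches)) {
    # memoised once per session
    utils::assignInMyNamespace(".branches", rule_branch_table())
  }
  Filter(function(b) b$disease == disease && b$kind == kind, .branches)
}

# Core branch evaluation on episode components. Returns the branch id that
# fires, or NA_character_.
classify_components <- function(prim, sec, evidence, length_days, death,
                                disease, kind) {
  for (b in branches_for(disease, kind)) {
    if (isTRUE(b$pre(prim, sec))) {
      return(if (isTRUE(b$crit(evidence, length_days, death))) b$id else NA_character_)
    }
  }
  NA_character_
}

episode_components <- function(episode) {
  if (!is.null(dim(episode))) {
    stopifnot(nrow(episode) == 1L)
    episode <- as.list(episode)
    episode$evidence_union <- episode$evidence_union[[1L]]
    episode$dx_primary_groups <- episode$dx_primary_groups[[1L]]
    episode$dx_secondary_groups <- episode$dx_secondary_groups[[1L]]
  }
  episode
}

classify_one <- function(episode, disease, kind) {
  e <- episode_components(episode)
  if (!identical(e$disease, disease)) {
    stop("episode is from the ", e$disease, " stream, not ", disease,
      call. = FALSE
    )
  }
  classify_components(
    e$dx_primary_groups, e$dx_secondary_groups, e$evidence_union,
    e$episode_length_days, isTRUE(e$in_episode_death), disease, kind
  )
}

#' First-AMI identification rule
#'
#' Tests one AMI-stream episode against the first-event algorithm. With an
#' I21-I23 code in the primary position on any member claim, any of ECG,
#' cardiac enzyme test, CAG, PCI or CABG — or an in-episode death — marks a
#' first AMI (`"AMI_F1"`). With the code only at secondary or lower,
#' confirmatory CAG, PCI or CABG is required (`"AMI_F2"`).
#'
#' @param episode One episode (a one-row episodes tibble or equivalent list)
#'   with `disease == "AMI"`.
#' @return The firing branch id, or `NA_character_` if no branch fires.
#' @export
ami_first <- function(episode) classify_one(episode, "AMI", "FIRST")

#' Recurrent-AMI identification rule
#'
#' An I21-I23 code at any position plus therapeutic PCI or CABG plus an
#' episode of 3 days or longer (or interrupted by in-episode death) marks a
#' recurrent AMI (`"AMI_R"`). Whether an earlier first event exists is the
#' sequencer's responsibility ([sequence_patient()]), not this rule's.
#'
#' @inheritParams ami_first
#' @return `"AMI_R"` or `NA_character_`.
#' @export
ami_recurrent <- function(episode) classify_one(episode, "AMI", "RECURRENT")

#' First-stroke identification rule
#'
#' Branch hierarchy (first matching code precondition decides): primary
#' I63-I64 (`"STROKE_F1"`), else I60-I61 at any position (`"STROKE_F2"`) —
#' both accept brain imaging with a >= 3-day stay or death, a therapeutic
#' intervention, or death alone; else I63-I64 at secondary or lower
#' (`"STROKE_F3"`), which requires an intervention plus the >= 3-day/death
#' condition.
#'
#' @param episode One episode with `disease == "STROKE"`.
#' @return The firing branch id, or `NA_character_`.
#' @export
stroke_first <- function(episode) classify_one(episode, "STROKE", "FIRST")

#' Recurrent-stroke identification rule
#'
#' Branch hierarchy: primary I63-I64 (`"STROKE_R1"`), else primary I60-I61
#' (`"STROKE_R2"`) — both accept brain imaging or intervention plus the
#' >= 3-day/death condition; else any stroke code at secondary or lower
#' (`"STROKE_R3"`), which requires an intervention plus the same condition.
#'
#' @inheritParams stroke_first
#' @return The firing branch id, or `NA_character_`.
#' @export
stroke_recurrent <- function(episode) classify_one(episode, "STROKE", "RECURRENT")

#' Classify every episode under both algorithms
#'
#' Adds `first_branch` and `recurrent_branch` columns giving the branch of
#' the disease's first- and recurrent-event algorithm that the episode
#' satisfies (`NA` when none). Which of the two applies to a given episode
#' is decided chronologically by [sequence_patient()].
#'
#' @param episodes Episodes tibble from [build_episodes()].
#' @return `episodes` with the two classification columns appended.
#' @export
classify_episodes <- function(episodes) {
  n <- nrow(episodes)
  fb <- rb <- character(n)
  for (i in seq_len(n)) {
    prim <- episodes$dx_primary_groups[[i]]
    sec <- episodes$dx_secondary_groups[[i]]
    ev <- episodes$evidence_union[[i]]
    len <- episodes$episode_length_days[i]
    death <- episodes$in_episode_death[i]
    dis <- episodes$disease[i]
    fb[i] <- classify_components(prim, sec, ev, len, death, dis, "FIRST")
    rb[i] <- classify_components(prim, sec, ev, len, death, dis, "RECURRENT")
  }
  episodes$first_branch <- fb
  episodes$recurrent_branch <- rb
  episodes
}
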