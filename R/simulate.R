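# Synthetic claims generator with known ground truth.
#
# Emulates the claim-fragmentation phenomena that make episode construction
# necessary: long stays split into ~30-day billing claims (consecutive
# fragments start 30 days apart but leave under 3 days between last and
# first dates, so they must merge), early complication readmissions inside
# the merge window, diagnosis codes carried over to later short visits
# without any procedure evidence (which must never be mistaken for recurrent
# events), rule-out claims, and in-hospital deaths before workup. Every true
# event targets a specific rule branch so each branch gets dedicated
# coverage, and the generator logs whether the emitted pattern qualifies by
# construction (`expected_detectable`).

#' Simulation configuration
#'
#' Builds and validates the parameter set for [generate_cohort()]. All
#' probabilities are in `[0, 1]`; a fixed `seed` makes the output
#' reproducible.
#'
#' @param n_patients Number of patients; default 500.
#' @param p_ami,p_stroke Probability that a patient has a true first event
#'   of each disease; defaults 0.30 each (streams independent).
#' @param p_recurrent Probability of one recurrent event after a detectable
#'   first event; default 0.35.
#' @param p_detectable Probability that a true event's claim pattern
#'   qualifies under its identification algorithm; 1 (default) is the
#'   all-canonical setting in which the pipeline must recover the ground
#'   truth exactly.
#' @param billing_split_period Billing cycle in days; stays longer than this
#'   are submitted as consecutive claim fragments. Default 30.
#' @param p_long_stay Probability that a non-fatal stay runs 35-70 days and
#'   is billing-split; default 0.20.
#' @param p_readmission Probability of a complication readmission claim
#'   inside the merge window; default 0.25.
#' @param p_carryover Probability of post-event carried-over-code noise
#'   claims (short, evidence-free); default 0.40.
#' @param p_ruleout Probability of pre-event or event-free rule-out claims;
#'   default 0.15.
#' @param p_death_arm Probability that a patient's final event is fatal
#'   (exercising the in-episode-death arms); default 0.12.
#' @param hospital_type_probs Named sampling probabilities for per-claim
#'   hospital type (claims within an episode may differ, emulating
#'   transfers).
#' @param start_window_days First events start uniformly within this many
#'   days of `origin`; default 365.
#' @param origin Calendar date of study day 0.
#' @param seed Integer RNG seed.
#' @return A `cvd_sim_config` list.
#' @export
simulation_config <- function(n_patients = 500L,
                              p_ami = 0.30, p_stroke = 0.30,
                              p_recurrent = 0.35,
                              p_detectable = 1,
                              billing_split_period = 30L,
                              p_long_stay = 0.20,
                              p_readmission = 0.25,
                              p_carryover = 0.40,
                              p_ruleout = 0.15,
                              p_death_arm = 0.12,
                              hospital_type_probs = c(
                                tertiary = 0.3, secondary = 0.4, primary = 0.3
                              ),
                              start_window_days = 365L,
                              origin = as.Date("2019-01-01"),
                              seed = 1L) {
  probs <- c(
    p_ami = p_ami, p_stroke = p_stroke, p_recurrent = p_recurrent,
    p_detectable = p_detectable, p_long_stay = p_long_stay,
    p_readmission = p_readmission, p_carryover = p_carryover,
    p_ruleout = p_ruleout, p_death_arm = p_death_arm
  )
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1]
    stop("probability out of [0, 1]: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (n_patients < 0) stop("n_patients must be nonnegative", call. = FALSE)
  if (!setequal(names(hospital_type_probs), hospital_type_levels) ||
    any(hospital_type_probs < 0) || sum(hospital_type_probs) <= 0) {
    stop("hospital_type_probs must be a nonnegative vector over ",
      paste(hospital_type_levels, collapse = "/"),
      call. = FALSE
    )
  }
  structure(
    list(
      n_patients = as.integer(n_patients), p_ami = p_ami, p_stroke = p_stroke,
      p_recurrent = p_recurrent, p_detectable = p_detectable,
      billing_split_period = as.integer(billing_split_period),
      p_long_stay = p_long_stay, p_readmission = p_readmission,
      p_carryover = p_carryover, p_ruleout = p_ruleout,
      p_death_arm = p_death_arm, hospital_type_probs = hospital_type_probs,
      start_window_days = as.integer(start_window_days),
      origin = as.Date(origin), seed = as.integer(seed)
    ),
    class = "cvd_sim_config"
  )
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

ami_code <- function() paste0(sample1(c("I21", "I22", "I23")), ".", sample1(0:9))
stroke_code <- function(prefixes) paste0(sample1(prefixes), ".", sample1(0:9))
filler_cardiac <- function() sample1(c("I50.9", "I10", "E11.9"))
filler_noncvd <- function() sample1(c("J18.9", "N18.3", "E11.9"))

# Materialise the claim-pattern components for one true event targeting a
# rule branch. Returns codes (ordered, position 1 = primary), evidence
# flags, stay length in days, and whether the episode ends in death.
event_pattern <- function(branch, detectable, fatal, config) {
  stroke_first_codes <- function(branch) {
    switch(branch,
      STROKE_F1 = ,
      STROKE_R1 = c(stroke_code(c("I63", "I64")), filler_cardiac()),
      STROKE_F2 = ,
      STROKE_R2 = if (branch == "STROKE_R2" || runif(1) < 0.6) {
        c(stroke_code(c("I60", "I61")), filler_cardiac())
      } else {
        c(filler_noncvd(), stroke_code(c("I60", "I61")))
      },
      STROKE_F3 = c(filler_noncvd(), stroke_code(c("I63", "I64"))),
      STROKE_R3 = c(filler_noncvd(), stroke_code(c("I60", "I61", "I63", "I64")))
    )
  }
  codes <- switch(branch,
    AMI_F1 = c(ami_code(), filler_cardiac()),
    AMI_F2 = c(filler_cardiac(), ami_code()),
    AMI_R = if (runif(1) < 0.5) {
      c(ami_code(), filler_cardiac())
    } else {
      c(filler_cardiac(), ami_code())
    },
    stroke_first_codes(branch)
  )
  if (!detectable) {
    return(list(
      codes = codes, evidence = character(0),
      stay = sample1(1:2), fatal = FALSE
    ))
  }
  long <- !fatal && runif(1) < config$p_long_stay
  stay_short <- function(lo) sample1(lo:12)
  stay <- if (fatal) 1L else if (long) sample1(35:70) else stay_short(1L)
  ev <- switch(branch,
    AMI_F1 = {
      if (fatal && runif(1) < 0.5) {
        character(0) # death before any workup (type 3 MI)
      } else {
        sample(ami_evidence_first, sample1(1:2))
      }
    },
    AMI_F2 = unique(c(sample1(ami_evidence_confirmatory), if (runif(1) < 0.5) "ECG")),
    AMI_R = {
      if (!fatal && stay < 3L) stay <- stay_short(3L)
      unique(c(sample1(ami_evidence_therapeutic), if (runif(1) < 0.4) "CAG"))
    },
    STROKE_F1 = ,
    STROKE_F2 = {
      if (fatal && runif(1) < 0.5) {
        character(0) # death before imaging or intervention
      } else if (runif(1) < 0.7) {
        if (!fatal && stay < 3L) stay <- stay_short(3L)
        unique(c("BRAIN_IMAGING", if (runif(1) < 0.3) "STROKE_INTERVENTION"))
      } else {
        "STROKE_INTERVENTION"
      }
    },
    STROKE_F3 = ,
    STROKE_R3 = {
      if (!fatal && stay < 3L) stay <- stay_short(3L)
      unique(c("STROKE_INTERVENTION", if (runif(1) < 0.3) "BRAIN_IMAGING"))
    },
    STROKE_R1 = ,
    STROKE_R2 = {
      if (!fatal && stay < 3L) stay <- stay_short(3L)
      sample(c("BRAIN_IMAGING", "STROKE_INTERVENTION"), sample1(1:2))
    }
  )
  list(codes = codes, evidence = ev, stay = stay, fatal = fatal)
}

first_branches <- list(
  AMI = c(AMI_F1 = 0.75, AMI_F2 = 0.25),
  STROKE = c(STROKE_F1 = 0.5, STROKE_F2 = 0.3, STROKE_F3 = 0.2)
)
recurrent_branches <- list(
  AMI = c(AMI_R = 1),
  STROKE = c(STROKE_R1 = 0.45, STROKE_R2 = 0.3, STROKE_R3 = 0.25)
)

sample_branch <- function(weights) {
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

#' Generate a synthetic cohort with ground-truth events
#'
#' For each scheduled true event the generator emits one to a few claims:
#' billing-split fragments for long stays, an optional complication
#' readmission inside the merge window, and optional carried-over-code noise
#' claims after the event. Diagnosis codes, procedure evidence, stay length
#' and death are chosen to satisfy (or, with probability
#' `1 - p_detectable`, to fail) the targeted rule branch, and the expected
#' outcome is logged per event.
#'
#' @param config A [simulation_config()].
#' @return List with `claims` (claims tibble), `deaths` (deaths tibble) and
#'   `truth`, a tibble of ground-truth events: `patient_id, disease, kind,
#'   true_event_date, expected_detectable, target_branch`. When noise claims
#'   merge into an event episode they can only add diagnosis positions or
#'   days, so `expected_detectable` events are always recovered with the
#'   logged kind and date (the fired branch may sit higher in the hierarchy
#'   than `target_branch` when merged noise promotes a code to the primary
#'   position).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "cvd_sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  claim_rows <- vector("list", 4L * max(1L, config$n_patients))
  n_claim_rows <- 0L
  claim_counter <- 0L
  truth_rows <- list()
  death_rows <- list()
  htypes <- names(config$hospital_type_probs)
  hprobs <- unname(config$hospital_type_probs)

  add_claim <- function(pid, s, e, codes, evidence) {
    claim_counter <<- claim_counter + 1L
    n_claim_rows <<- n_claim_rows + 1L
    claim_rows[[n_claim_rows]] <<- list(
      claim_id = sprintf("C%07d", claim_counter),
      patient_id = pid,
      hospital_id = sprintf("H%03d", sample.int(40L, 1L)),
      hospital_type = htypes[sample.int(length(htypes), 1L, prob = hprobs)],
      start_day = s, end_day = e,
      dx = list(codes), evidence = list(evidence)
    )
  }

  # Emit the claims of one event starting at day s; returns the final
  # episode end day (including merged readmission).
  emit_event <- function(pid, s, pat) {
    ep_end <- s + pat$stay - 1L
    frag_starts <- seq(s, ep_end, by = config$billing_split_period)
    n_frag <- length(frag_starts)
    ev_frag <- if (length(pat$evidence) > 0) {
      sample.int(n_frag, length(pat$evidence), replace = TRUE)
    } else {
      integer(0)
    }
    for (i in seq_len(n_frag)) {
      fe <- min(frag_starts[i] + config$billing_split_period - 1L, ep_end)
      add_claim(pid, frag_starts[i], fe, pat$codes, pat$evidence[ev_frag == i])
    }
    if (!pat$fatal && runif(1) < config$p_readmission) {
      # complication readmission: must merge back into the episode, either
      # via a < 3-day discharge-to-admission interval or a <= 28-day
      # first-date gap
      lo_gap <- ep_end + 3L
      hi_gap <- frag_starts[n_frag] + 28L
      use_gap <- lo_gap <= hi_gap && runif(1) < 0.5
      rs <- if (use_gap) sample1(lo_gap:hi_gap) else ep_end + sample1(1:2)
      re <- rs + sample1(0:3)
      add_claim(pid, rs, re, pat$codes, character(0))
      ep_end <- max(ep_end, re)
    }
    ep_end
  }

  emit_carryover <- function(pid, after_day, codes) {
    for (k in seq_len(sample1(1:2))) {
      cs <- after_day + sample1(4:25)
      primary_pos <- runif(1) < 0.5
      dx <- if (primary_pos) codes[1] else c(filler_noncvd(), codes[1])
      add_claim(pid, cs, cs + sample1(0:1), dx, character(0))
    }
  }

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", p)
    diseases <- c(
      if (runif(1) < config$p_ami) "AMI",
      if (runif(1) < config$p_stroke) "STROKE"
    )
    if (length(diseases) == 0) {
      if (runif(1) < config$p_ruleout) {
        # event-free rule-out presence: short evidence-free disease claims
        dis <- sample1(c("AMI", "STROKE"))
        cs <- sample1(0:config$start_window_days)
        code <- if (dis == "AMI") ami_code() else stroke_code(c("I60", "I61", "I63", "I64"))
        add_claim(pid, cs, cs + sample1(0:1), c(filler_noncvd(), code), character(0))
      }
      next
    }
    # plan events; death arms only for patients whose entire history is a
    # single event, so nothing can postdate the death
    plan <- list()
    for (dis in diseases) {
      detectable <- runif(1) < config$p_detectable
      want_recur <- detectable && runif(1) < config$p_recurrent
      plan[[dis]] <- list(detectable = detectable, recurrent = want_recur)
    }
    single_event <- length(diseases) == 1L && !plan[[diseases]]$recurrent
    fatal_first <- single_event && plan[[diseases]]$detectable &&
      runif(1) < config$p_death_arm
    fatal_recur <- length(diseases) == 1L && plan[[diseases]]$recurrent &&
      runif(1) < config$p_death_arm

    for (dis in diseases) {
      pl <- plan[[dis]]
      b1 <- sample_branch(first_branches[[dis]])
      s1 <- sample1(0:config$start_window_days)
      pat1 <- event_pattern(b1, pl$detectable, fatal_first && length(diseases) == 1L, config)
      if (runif(1) < config$p_ruleout) {
        # pre-event rule-out claim, placed clear of the merge window
        cs <- s1 - sample1(40:90)
        add_claim(pid, cs, cs + sample1(0:1), pat1$codes, character(0))
      }
      ep1_end <- emit_event(pid, s1, pat1)
      truth_rows[[length(truth_rows) + 1L]] <- list(
        patient_id = pid, disease = dis, kind = "FIRST",
        true_event_day = s1, expected_detectable = pl$detectable,
        target_branch = b1
      )
      if (pat1$fatal) {
        death_rows[[length(death_rows) + 1L]] <-
          list(patient_id = pid, death_day = ep1_end)
        next
      }
      if (runif(1) < config$p_carryover) {
        emit_carryover(pid, ep1_end, pat1$codes)
      }
      if (pl$recurrent) {
        b2 <- sample_branch(recurrent_branches[[dis]])
        recur_detectable <- runif(1) < config$p_detectable
        pat2 <- event_pattern(b2, recur_detectable, fatal_recur, config)
        s2 <- ep1_end + 70L + sample1(0:120)
        ep2_end <- emit_event(pid, s2, pat2)
        truth_rows[[length(truth_rows) + 1L]] <- list(
          patient_id = pid, disease = dis, kind = "RECURRENT",
          true_event_day = s2, expected_detectable = recur_detectable,
          target_branch = b2
        )
        if (pat2$fatal) {
          death_rows[[length(death_rows) + 1L]] <-
            list(patient_id = pid, death_day = ep2_end)
        } else if (runif(1) < config$p_carryover) {
          emit_carryover(pid, ep2_end, pat2$codes)
        }
      }
    }
  }

  claim_rows <- claim_rows[seq_len(n_claim_rows)]
  claims <- if (n_claim_rows == 0) {
    empty_claims()
  } else {
    new_claims(
      claim_id = vapply(claim_rows, `[[`, character(1), "claim_id"),
      patient_id = vapply(claim_rows, `[[`, character(1), "patient_id"),
      hospital_id = vapply(claim_rows, `[[`, character(1), "hospital_id"),
      hospital_type = vapply(claim_rows, `[[`, character(1), "hospital_type"),
      start_date = config$origin + vapply(claim_rows, `[[`, numeric(1), "start_day"),
      end_date = config$origin + vapply(claim_rows, `[[`, numeric(1), "end_day"),
      dx = lapply(claim_rows, function(r) r$dx[[1]]),
      evidence = lapply(claim_rows, function(r) r$evidence[[1]])
    )
  }
  deaths <- tibble::tibble(
    patient_id = vapply(death_rows, `[[`, character(1), "patient_id"),
    death_date = config$origin + vapply(death_rows, `[[`, numeric(1), "death_day")
  )
  truth <- tibble::tibble(
    patient_id = vapply(truth_rows, `[[`, character(1), "patient_id"),
    disease = vapply(truth_rows, `[[`, character(1), "disease"),
    kind = vapply(truth_rows, `[[`, character(1), "kind"),
    true_event_date = config$origin + vapply(truth_rows, `[[`, numeric(1), "true_event_day"),
    expected_detectable = vapply(truth_rows, `[[`, logical(1), "expected_detectable"),
    target_branch = vapply(truth_rows, `[[`, character(1), "target_branch")
  )
  list(claims = claims, deaths = deaths, truth = truth)
}

#' Simulate chart-review adjudication of identified events
#'
#' Each identified event is adjudicated as a true case independently with
#' its stratum's configured probability, emulating the medical-record review
#' that PPV validation rests on.
#'
#' @param events Event-call tibble from [identify_events()].
#' @param stratum_true_ppv Tibble with `disease, kind, hospital_type,
#'   true_ppv` (proportions in `[0, 1]`). Every stratum observed in `events`
#'   must be covered.
#' @param seed Integer RNG seed.
#' @param rule Which hospital stratification the configured PPVs refer to;
#'   see [assign_stratum()].
#' @return Adjudication tibble (see [ppv_by_stratum()]).
#' @export
simulate_chart_review <- function(events, stratum_true_ppv, seed,
                                  rule = c("first_visit", "highest_level")) {
  rule <- match.arg(rule)
  if (any(stratum_true_ppv$true_ppv < 0 | stratum_true_ppv$true_ppv > 1)) {
    stop("true_ppv values must be in [0, 1]", call. = FALSE)
  }
  records <- tibble::tibble(
    patient_id = events$patient_id,
    disease = events$disease,
    kind = events$kind,
    episode_index = events$episode_index,
    hospital_type_first_visit = events$first_visit_hospital_type,
    hospital_type_highest = events$highest_level_hospital_type,
    hospital_type = assign_stratum(tibble::tibble(
      hospital_type_first_visit = events$first_visit_hospital_type,
      hospital_type_highest = events$highest_level_hospital_type
    ), rule)
  )
  records <- dplyr::left_join(
    records, stratum_true_ppv,
    by = c("disease", "kind", "hospital_type")
  )
  if (anyNA(records$true_ppv)) {
    miss <- unique(records[is.na(records$true_ppv), c("disease", "kind", "hospital_type")])
    stop("no configured true PPV for stratum/strata: ",
      paste(paste(miss$disease, miss$kind, miss$hospital_type, sep = "/"),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  records$adjudicated_true <- withr::with_seed(
    seed, rbinom(nrow(records), 1L, records$true_ppv) == 1L
  )
  records[c(
    "patient_id", "disease", "kind", "episode_index",
    "hospital_type_first_visit", "hospital_type_highest", "adjudicated_true"
  )]
}

#' Write ground-truth events to CSV
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$true_event_date <- format(out$true_event_date, "%Y-%m-%d")
  out$expected_detectable <- as.integer(out$expected_detectable)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write adjudication records to CSV
#'
#' @param records Adjudication tibble from [simulate_chart_review()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjudications <- function(records, path) {
  out <- records
  out$adjudicated_true <- as.integer(out$adjudicated_true)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
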