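# Independent oracles. These re-derive expected results from the published
# rule statements by different means than the production code (literal
# nested conditionals here vs the declarative branch table in R/rules.R;
# exhaustive partition enumeration here vs the single greedy pass in
# R/episodes.R) so the two routes share no logic.

# ---- truth-table oracles for the four identification algorithms ----------
# prim/sec arguments are booleans saying whether the code family occupies
# the primary (any member claim) or secondary-or-lower position.

oracle_ami_first <- function(prim, sec, ev, len, death) {
  if (prim) {
    if (any(c("ECG", "CARDIAC_ENZYME", "CAG", "PCI", "CABG") %in% ev) || death) {
      return("AMI_F1")
    }
    return(NA_character_)
  }
  if (sec) {
    if (any(c("CAG", "PCI", "CABG") %in% ev)) {
      return("AMI_F2")
    }
  }
  NA_character_
}

oracle_ami_recurrent <- function(prim, sec, ev, len, death) {
  if ((prim || sec) &&
    any(c("PCI", "CABG") %in% ev) &&
    (len >= 3 || death)) {
    return("AMI_R")
  }
  NA_character_
}

# p63/p60: I63-I64 / I60-I61 in the primary position; s63/s60: the same
# families at secondary or lower.
oracle_stroke_first <- function(p63, p60, s63, s60, ev, len, death) {
  imaging <- "BRAIN_IMAGING" %in% ev
  interv <- "STROKE_INTERVENTION" %in% ev
  acute <- len >= 3 || death
  crit_a <- (imaging && acute) || interv || death
  crit_b <- interv && acute
  if (p63) {
    if (crit_a) {
      return("STROKE_F1")
    }
    return(NA_character_)
  }
  if (p60 || s60) {
    if (crit_a) {
      return("STROKE_F2")
    }
    return(NA_character_)
  }
  if (s63) {
    if (crit_b) {
      return("STROKE_F3")
    }
  }
  NA_character_
}

oracle_stroke_recurrent <- function(p63, p60, s63, s60, ev, len, death) {
  imaging <- "BRAIN_IMAGING" %in% ev
  interv <- "STROKE_INTERVENTION" %in% ev
  acute <- len >= 3 || death
  crit_r <- (imaging || interv) && acute
  crit_b <- interv && acute
  if (p63) {
    if (crit_r) {
      return("STROKE_R1")
    }
    return(NA_character_)
  }
  if (p60) {
    if (crit_r) {
      return("STROKE_R2")
    }
    return(NA_character_)
  }
  if (s63 || s60) {
    if (crit_b) {
      return("STROKE_R3")
    }
  }
  NA_character_
}

# all subsets of the evidence flags, as a list of character vectors
evidence_subsets <- function() {
  flags <- evidence_flags
  lapply(0:(2^length(flags) - 1), function(m) {
    flags[bitwAnd(m, 2^(seq_along(flags) - 1)) > 0]
  })
}

# the full boolean grid for one disease's algorithms: code placements x
# evidence subsets x {len 2, len 3} x {death, no death}
rule_grid_cases <- function(disease) {
  placements <- if (disease == "AMI") {
    expand.grid(prim = c(TRUE, FALSE), sec = c(TRUE, FALSE))
  } else {
    expand.grid(
      p63 = c(TRUE, FALSE), p60 = c(TRUE, FALSE),
      s63 = c(TRUE, FALSE), s60 = c(TRUE, FALSE)
    )
  }
  list(
    placements = placements, evidence = evidence_subsets(),
    lens = c(2L, 3L), deaths = c(FALSE, TRUE)
  )
}

# episode matching an abstract placement row (uses representative prefixes)
placement_episode <- function(disease, pl, ev, len, death) {
  if (disease == "AMI") {
    prim <- if (pl$prim) "I21" else "I50"
    sec <- if (pl$sec) "I22" else "I10"
  } else {
    prim <- c(
      if (pl$p63) "I63", if (pl$p60) "I60",
      if (!pl$p63 && !pl$p60) "I50"
    )
    sec <- c(
      if (pl$s63) "I64", if (pl$s60) "I61",
      if (!pl$s63 && !pl$s60) "I10"
    )
  }
  make_episode(disease,
    prim = prim, sec = sec, evidence = ev,
    length_days = len, death = death
  )
}

# ---- brute-force partition oracle for episode grouping -------------------
# Enumerates every contiguous partition of the sorted claims and keeps the
# one consistent with the pairwise split rules: at a block boundary the
# later claim must satisfy BOTH conditions against the previous claim's
# first date and the previous block's latest last date; inside a block no
# claim may satisfy both. Returns the unique consistent episode-id vector
# (errors if not exactly one partition is consistent).
oracle_episode_ids <- function(start, end, gap_days = 28, interval_days = 3) {
  n <- length(start)
  if (n == 0) {
    return(integer(0))
  }
  if (n == 1) {
    return(1L)
  }
  both <- function(b_start, a_start, prev_max_end) {
    (b_start - a_start > gap_days) && (b_start - prev_max_end >= interval_days)
  }
  consistent <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cut <- bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0
    ids <- cumsum(c(1L, as.integer(cut)))
    max_end <- end[1]
    ok <- TRUE
    for (i in 2:n) {
      split_here <- both(start[i], start[i - 1], max_end)
      if (ids[i] != ids[i - 1]) {
        if (!split_here) {
          ok <- FALSE
          break
        }
        max_end <- end[i]
      } else {
        if (split_here) {
          ok <- FALSE
          break
        }
        max_end <- max(max_end, end[i])
      }
    }
    if (ok) consistent[[length(consistent) + 1]] <- ids
  }
  if (length(consistent) != 1) {
    stop("partition oracle: ", length(consistent), " consistent partitions")
  }
  consistent[[1]]
}

# episode ids as implied by group_claims output (claim order is preserved)
ids_from_episodes <- function(episodes) {
  rep(episodes$episode_index, lengths(episodes$claim_ids))
}
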