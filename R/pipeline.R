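# Pipeline driver behind the command-line interface.
#
# Stages: simulate (synthetic cohort with ground truth), identify (claims ->
# episodes -> event calls), validate (adjudications -> stratified/pooled PPV
# report), or all three chained on the synthetic cohort. The identification
# thresholds (28-day gap, 3-day interval, hospital-level ordering) default
# to the published algorithm and are exposed through the config for
# sensitivity analyses.

pipeline_defaults <- function() {
  list(
    thresholds = list(
      gap_days = 28L, interval_days = 3L, interval_mode = "episode_max"
    ),
    simulate = list(),
    chart_review = list(
      first_true_ppv = 0.90, recurrent_true_ppv = 0.80, rule = "first_visit"
    )
  )
}

#' Read a pipeline configuration file
#'
#' YAML with optional blocks `thresholds` (`gap_days`, `interval_days`,
#' `interval_mode`), `simulate` (arguments of [simulation_config()]),
#' `chart_review` (`first_true_ppv`, `recurrent_true_ppv`, `rule`) and
#' `weights` (`hospital_type: count`). Missing entries fall back to the
#' published defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return Config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  config <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    for (block in names(user)) {
      if (is.list(user[[block]]) && is.list(config[[block]])) {
        config[[block]][names(user[[block]])] <- user[[block]]
      } else {
        config[[block]] <- user[[block]]
      }
    }
  }
  config
}

flat_true_ppv_table <- function(events, config) {
  strata <- unique(tibble::tibble(
    disease = events$disease, kind = events$kind
  ))
  out <- dplyr::cross_join(
    strata, tibble::tibble(hospital_type = hospital_type_levels)
  )
  out$true_ppv <- ifelse(
    out$kind == "FIRST",
    config$chart_review$first_true_ppv,
    config$chart_review$recurrent_true_ppv
  )
  out
}

#' Run a pipeline stage
#'
#' @param command One of `"simulate"`, `"identify"`, `"validate"`, `"all"`.
#' @param out_dir Output directory (created if needed).
#' @param config_path Optional YAML config; see [read_pipeline_config()].
#' @param claims_path,deaths_path Input CSVs for `identify`.
#' @param adjudications_path Input CSV for `validate`.
#' @param evidence_map_path Optional service-code mapping CSV.
#' @param seed Integer seed overriding the config for `simulate`/`all`.
#' @param disease `"both"`, `"AMI"` or `"STROKE"`.
#' @param strict Strict evidence-code ingest (see [read_claims()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(command = c("simulate", "identify", "validate", "all"),
                         out_dir,
                         config_path = NULL,
                         claims_path = NULL, deaths_path = NULL,
                         adjudications_path = NULL,
                         evidence_map_path = NULL,
                         seed = NULL,
                         disease = c("both", "AMI", "STROKE"),
                         strict = TRUE, quiet = FALSE) {
  command <- match.arg(command)
  disease <- match.arg(disease)
  config <- read_pipeline_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  written <- list()

  if (command %in% c("simulate", "all")) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    sim_config <- do.call(simulation_config, sim_args)
    cohort <- generate_cohort(sim_config)
    written$claims <- write_claims(cohort$claims, file.path(out_dir, "claims.csv"))
    written$deaths <- write_deaths(cohort$deaths, file.path(out_dir, "deaths.csv"))
    written$truth <- write_truth(cohort$truth, file.path(out_dir, "truth.csv"))
    say(
      "simulate: ", nrow(cohort$claims), " claims, ",
      nrow(cohort$deaths), " deaths, ", nrow(cohort$truth), " true events"
    )
    claims_path <- written$claims
    deaths_path <- written$deaths
  }

  events <- NULL
  if (command %in% c("identify", "all")) {
    if (is.null(claims_path)) {
      stop("identify requires claims_path", call. = FALSE)
    }
    evidence_map <- if (!is.null(evidence_map_path)) {
      read_evidence_map(evidence_map_path)
    }
    claims <- read_claims(claims_path, evidence_map = evidence_map, strict = strict)
    deaths <- if (!is.null(deaths_path)) read_deaths(deaths_path)
    th <- config$thresholds
    episodes <- build_episodes(claims, deaths,
      disease = disease, gap_days = th$gap_days,
      interval_days = th$interval_days, interval_mode = th$interval_mode
    )
    events <- sequence_episodes(episodes)
    written$episodes <- write_episodes(episodes, file.path(out_dir, "episodes.csv"))
    written$events <- write_events(events, file.path(out_dir, "events.csv"))
    say(
      "identify: ", nrow(claims), " claims -> ", nrow(episodes),
      " episodes -> ", nrow(events), " events"
    )
    if (nrow(events) > 0) {
      branch_counts <- table(events$rule_branch)
      say(
        "identify: events per branch: ",
        paste(names(branch_counts), branch_counts, sep = "=", collapse = ", ")
      )
    }
  }

  if (command %in% c("validate", "all")) {
    records <- if (command == "all") {
      cr_seed <- if (!is.null(seed)) seed + 1L else 1L
      recs <- simulate_chart_review(
        events, flat_true_ppv_table(events, config),
        seed = cr_seed, rule = config$chart_review$rule
      )
      written$adjudications <- write_adjudications(
        recs, file.path(out_dir, "adjudications.csv")
      )
      recs
    } else {
      if (is.null(adjudications_path)) {
        stop("validate requires adjudications_path", call. = FALSE)
      }
      read_adjudications(adjudications_path)
    }
    weights <- if (!is.null(config$weights)) unlist(config$weights)
    report <- dplyr::bind_rows(
      dplyr::mutate(
        validation_report(records, weights = weights, rule = "first_visit"),
        stratum_rule = "first_visit", .before = 1
      ),
      dplyr::mutate(
        validation_report(records, weights = weights, rule = "highest_level"),
        stratum_rule = "highest_level", .before = 1
      )
    )
    path <- file.path(out_dir, "validation_report.csv")
    readr::write_csv(report, path, progress = FALSE)
    written$validation_report <- path
    say("validate: ", nrow(records), " adjudication records -> ", path)
  }

  invisible(written)
}
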