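# Positive predictive value estimation for chart-review validation.
#
# PPV = 100 * (identified events adjudicated true) / (identified events
# examined), per (disease, kind, hospital type) stratum, with binomial
# confidence intervals; pooled either unweighted (simple aggregation of
# counts) or weighted by external per-hospital-type case counts.

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Positive predictive value with a binomial confidence interval
#'
#' `ppv = 100 * n_true / n_identified`. The default interval is the Wald
#' normal approximation `100 * (p +/- z * sqrt(p * (1 - p) / n))`, truncated
#' to `[0, 100]`; Wilson score intervals are available via `ci_method`. When
#' `n_identified = 0` the PPV is undefined; when `n_true = 0` the interval is
#' undefined (degenerate at 0) and reported as `NA` — [format_ppv()] renders
#' both as `"N/A"`.
#'
#' @param n_true Number of identified events adjudicated as true cases
#'   (vectorised).
#' @param n_identified Number of identified events examined (vectorised);
#'   `n_true <= n_identified` required.
#' @param conf_level Confidence level, default 0.95.
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @return Tibble with `n_true`, `n_identified`, `ppv_percent`,
#'   `ci_low_percent`, `ci_high_percent` (percent scale, `NA` when
#'   undefined).
#' @examples
#' ppv(584, 617) # 94.7 (92.9, 96.4)
#' @export
ppv <- function(n_true, n_identified, conf_level = 0.95,
                ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (length(n_true) != length(n_identified)) {
    stop("n_true and n_identified must have equal length", call. = FALSE)
  }
  if (any(n_true < 0 | n_identified < 0 | n_true > n_identified)) {
    stop("need 0 <= n_true <= n_identified", call. = FALSE)
  }
  p <- ifelse(n_identified > 0, n_true / n_identified, NA_real_)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "wald") {
    se <- sqrt(p * (1 - p) / n_identified)
    lo <- p - z * se
    hi <- p + z * se
  } else {
    denom <- 1 + z^2 / n_identified
    centre <- (p + z^2 / (2 * n_identified)) / denom
    half <- z * sqrt(p * (1 - p) / n_identified + z^2 / (4 * n_identified^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  defined_ci <- !is.na(p) & n_true > 0
  tibble::tibble(
    n_true = as.integer(n_true),
    n_identified = as.integer(n_identified),
    ppv_percent = 100 * p,
    ci_low_percent = ifelse(defined_ci, pmax(0, 100 * lo), NA_real_),
    ci_high_percent = ifelse(defined_ci, pmin(100, 100 * hi), NA_real_)
  )
}

#' Format a PPV result like a validation-table cell
#'
#' Renders `"94.7 (92.9, 96.4)"` with half-up rounding to one decimal on the
#' percent scale, or `"N/A"` when the PPV or its interval is undefined.
#'
#' @param result A row set from [ppv()].
#' @return Character vector.
#' @export
format_ppv <- function(result) {
  ifelse(
    is.na(result$ppv_percent) | is.na(result$ci_low_percent),
    "N/A",
    sprintf(
      "%.1f (%.1f, %.1f)",
      round_half_up(result$ppv_percent),
      round_half_up(result$ci_low_percent),
      round_half_up(result$ci_high_percent)
    )
  )
}

#' Hospital-type stratum of an adjudicated event
#'
#' Multi-hospital episodes can be stratified by the first hospital visited
#' during the episode or by the highest-level hospital visited
#' (tertiary > secondary > primary).
#'
#' @param records Adjudication tibble with `hospital_type_first_visit` and
#'   `hospital_type_highest` columns.
#' @param rule `"first_visit"` or `"highest_level"`.
#' @return Character vector of hospital types.
#' @export
assign_stratum <- function(records, rule = c("first_visit", "highest_level")) {
  rule <- match.arg(rule)
  if (rule == "first_visit") {
    records$hospital_type_first_visit
  } else {
    records$hospital_type_highest
  }
}

#' Stratified PPVs from adjudication records
#'
#' Tabulates adjudicated-true and identified counts per
#' (disease, kind, hospital type) stratum and computes each stratum's PPV.
#'
#' @param records Adjudication tibble: `patient_id, disease, kind,
#'   episode_index, hospital_type_first_visit, hospital_type_highest,
#'   adjudicated_true`.
#' @param rule Stratum assignment rule, see [assign_stratum()].
#' @inheritParams ppv
#' @return Tibble with `disease, kind, hospital_type` and the [ppv()]
#'   columns, one row per observed stratum.
#' @export
ppv_by_stratum <- function(records, rule = c("first_visit", "highest_level"),
                           conf_level = 0.95, ci_method = c("wald", "wilson")) {
  rule <- match.arg(rule)
  ci_method <- match.arg(ci_method)
  records$hospital_type <- assign_stratum(records, rule)
  counts <- records |>
    dplyr::group_by(.data$disease, .data$kind, .data$hospital_type) |>
    dplyr::summarise(
      n_true = sum(.data$adjudicated_true),
      n_identified = dplyr::n(),
      .groups = "drop"
    )
  dplyr::bind_cols(
    counts[c("disease", "kind", "hospital_type")],
    ppv(counts$n_true, counts$n_identified,
      conf_level = conf_level, ci_method = ci_method
    )
  )
}

#' Unweighted pooled PPV
#'
#' Simple aggregation: the PPV of the summed counts,
#' `100 * sum(n_true) / sum(n_identified)` across strata.
#'
#' @param strata Tibble with `n_true` and `n_identified` per stratum (e.g.
#'   from [ppv_by_stratum()]).
#' @inheritParams ppv
#' @return One-row [ppv()] tibble.
#' @export
unweighted_pooled_ppv <- function(strata, conf_level = 0.95,
                                  ci_method = c("wald", "wilson")) {
  ppv(sum(strata$n_true), sum(strata$n_identified),
    conf_level = conf_level, ci_method = match.arg(ci_method)
  )
}

#' Weighted pooled PPV
#'
#' Combines stratum PPVs with external weights (case counts per hospital
#' type): `pooled = sum(w_t * ppv_t) / sum(w_t)`. The interval is a Wald
#' combination of the stratum binomial variances,
#' `var = sum(w_t^2 * p_t * (1 - p_t) / n_t) / sum(w_t)^2`. A stratum with a
#' positive weight but no defined PPV is dropped with a warning.
#'
#' @param strata Tibble with `hospital_type`, `n_true`, `n_identified`,
#'   `ppv_percent` per stratum.
#' @param weights Named numeric vector, `hospital_type -> nonnegative
#'   weight`; at least one weight matching a stratum must be positive.
#' @inheritParams ppv
#' @return One-row tibble with `ppv_percent`, `ci_low_percent`,
#'   `ci_high_percent` (counts are `NA`: pooled counts are not meaningful
#'   under external weighting).
#' @export
weighted_pooled_ppv <- function(strata, weights, conf_level = 0.95) {
  if (any(weights < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  w <- unname(weights[strata$hospital_type])
  w[is.na(w)] <- 0
  undefined <- w > 0 & is.na(strata$ppv_percent)
  if (any(undefined)) {
    warning("dropping stratum/strata with undefined PPV from weighted pool: ",
      paste(strata$hospital_type[undefined], collapse = ", "),
      call. = FALSE
    )
    w[undefined] <- 0
  }
  if (sum(w) <= 0) {
    stop("no positive-weight stratum with a defined PPV", call. = FALSE)
  }
  keep <- w > 0
  w <- w[keep]
  p <- strata$ppv_percent[keep] / 100
  n <- strata$n_identified[keep]
  pooled <- sum(w * p) / sum(w)
  pooled_var <- sum(w^2 * p * (1 - p) / n) / sum(w)^2
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    n_true = NA_integer_,
    n_identified = NA_integer_,
    ppv_percent = 100 * pooled,
    ci_low_percent = max(0, 100 * (pooled - z * sqrt(pooled_var))),
    ci_high_percent = min(100, 100 * (pooled + z * sqrt(pooled_var)))
  )
}

#' Full validation report over adjudication records
#'
#' One row per (disease, kind, hospital type) stratum plus pooled rows:
#' `pooled_unweighted` always, and `pooled_weighted` per (disease, kind)
#' when `weights` are supplied. A `display` column renders each row as a
#' validation-table cell.
#'
#' @inheritParams ppv_by_stratum
#' @param weights Optional named numeric vector (`hospital_type -> case
#'   count`) used for every (disease, kind) group, or a list of such vectors
#'   keyed `"<disease>_<kind>"` (e.g. `"AMI_FIRST"`).
#' @return Report tibble.
#' @export
validation_report <- function(records, weights = NULL,
                              rule = c("first_visit", "highest_level"),
                              conf_level = 0.95,
                              ci_method = c("wald", "wilson")) {
  rule <- match.arg(rule)
  ci_method <- match.arg(ci_method)
  strata <- ppv_by_stratum(records,
    rule = rule, conf_level = conf_level, ci_method = ci_method
  )
  groups <- split(
    strata, list(strata$disease, strata$kind),
    drop = TRUE
  )
  rows <- lapply(groups, function(g) {
    pooled_u <- dplyr::bind_cols(
      tibble::tibble(
        disease = g$disease[1], kind = g$kind[1],
        hospital_type = "pooled_unweighted"
      ),
      unweighted_pooled_ppv(g, conf_level = conf_level, ci_method = ci_method)
    )
    out <- dplyr::bind_rows(g, pooled_u)
    if (!is.null(weights)) {
      w <- if (is.list(weights)) {
        weights[[paste(g$disease[1], g$kind[1], sep = "_")]]
      } else {
        weights
      }
      if (!is.null(w)) {
        pooled_w <- dplyr::bind_cols(
          tibble::tibble(
            disease = g$disease[1], kind = g$kind[1],
            hospital_type = "pooled_weighted"
          ),
          weighted_pooled_ppv(g, w, conf_level = conf_level)
        )
        out <- dplyr::bind_rows(out, pooled_w)
      }
    }
    out
  })
  report <- dplyr::bind_rows(rows)
  report$display <- format_ppv(report)
  dplyr::arrange(report, .data$disease, .data$kind)
}

#' Read adjudication records from CSV
#'
#' Schema: `patient_id, disease, kind, episode_index,
#' hospital_type_first_visit, hospital_type_highest, adjudicated_true` (0/1).
#'
#' @param path CSV file path.
#' @return Adjudication tibble (see [ppv_by_stratum()]).
#' @export
read_adjudications <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c(
    "patient_id", "disease", "kind", "episode_index",
    "hospital_type_first_visit", "hospital_type_highest", "adjudicated_true"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("adjudications CSV is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    patient_id = raw$patient_id,
    disease = raw$disease,
    kind = raw$kind,
    episode_index = as.integer(raw$episode_index),
    hospital_type_first_visit = raw$hospital_type_first_visit,
    hospital_type_highest = raw$hospital_type_highest,
    adjudicated_true = as.integer(raw$adjudicated_true) == 1L
  )
}
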