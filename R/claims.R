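# Claims data model and tabular I/O.
#
# A claims table is a tibble with one row per insurance claim:
#   claim_id, patient_id, hospital_id, hospital_type, start_date, end_date,
#   dx (list of ICD-10 code character vectors; list position = diagnosis
#   position, 1 = primary), evidence (list of evidence-flag character
#   vectors).
# Rows are kept sorted by (patient_id, start_date, end_date, claim_id);
# the date/claim_id key makes the ordering total and deterministic.

claims_columns <- c(
  "claim_id", "patient_id", "hospital_id", "hospital_type",
  "start_date", "end_date", "dx", "evidence"
)

#' Construct a claims table from vectors
#'
#' Low-level constructor used by [read_claims()] and the synthetic
#' generator. Validates the schema and returns claims sorted by
#' `(patient_id, start_date, end_date, claim_id)`.
#'
#' @param claim_id,patient_id,hospital_id Character vectors.
#' @param hospital_type Character vector with values in
#'   `"tertiary"`, `"secondary"`, `"primary"`.
#' @param start_date,end_date `Date` vectors; `start_date <= end_date`
#'   row-wise.
#' @param dx List of character vectors of ICD-10 codes; element order is the
#'   diagnosis position (1 = primary diagnosis). Must be non-empty per claim.
#' @param evidence List of character vectors, each a subset of
#'   [evidence_flags].
#' @return A tibble of claims (see module description).
#' @export
new_claims <- function(claim_id, patient_id, hospital_id, hospital_type,
                       start_date, end_date, dx, evidence) {
  x <- tibble::tibble(
    claim_id = as.character(claim_id),
    patient_id = as.character(patient_id),
    hospital_id = as.character(hospital_id),
    hospital_type = as.character(hospital_type),
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    dx = dx,
    evidence = evidence
  )
  validate_claims(x)
  sort_claims(x)
}

#' Validate a claims table
#'
#' Checks the schema invariants: required columns, valid hospital types,
#' `start_date <= end_date`, non-empty well-formed diagnosis codes (a letter
#' followed by digits with an optional dot-subcode), and evidence flags drawn
#' from [evidence_flags]. Errors on the first violation; returns the input
#' invisibly when valid.
#'
#' @param claims A claims tibble.
#' @return `claims`, invisibly.
#' @export
validate_claims <- function(claims) {
  missing <- setdiff(claims_columns, names(claims))
  if (length(missing) > 0) {
    stop("claims table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(claims) == 0) {
    return(invisible(claims))
  }
  bad_type <- setdiff(unique(claims$hospital_type), hospital_type_levels)
  if (length(bad_type) > 0) {
    stop("unknown hospital_type value(s): ", paste(bad_type, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(claims$start_date) || anyNA(claims$end_date)) {
    stop("claims contain missing dates", call. = FALSE)
  }
  if (any(claims$start_date > claims$end_date)) {
    bad <- claims$claim_id[claims$start_date > claims$end_date]
    stop("start_date after end_date for claim(s): ",
      paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  n_dx <- vapply(claims$dx, length, integer(1))
  if (any(n_dx == 0)) {
    stop("claim(s) without diagnosis codes: ",
      paste(head(claims$claim_id[n_dx == 0], 5), collapse = ", "),
      call. = FALSE
    )
  }
  all_codes <- unlist(claims$dx, use.names = FALSE)
  bad_code <- all_codes[!grepl("^[A-Za-z][0-9]{2}(\\.?[0-9A-Za-z]*)?$", all_codes)]
  if (length(bad_code) > 0) {
    stop("malformed ICD-10 code(s): ", paste(unique(head(bad_code, 5)), collapse = ", "),
      call. = FALSE
    )
  }
  all_ev <- unlist(claims$evidence, use.names = FALSE)
  bad_ev <- setdiff(all_ev, evidence_flags)
  if (length(bad_ev) > 0) {
    stop("unknown evidence flag(s): ", paste(unique(bad_ev), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(claims$claim_id)) {
    stop("duplicated claim_id values", call. = FALSE)
  }
  invisible(claims)
}

sort_claims <- function(claims) {
  dplyr::arrange(
    claims, .data$patient_id, .data$start_date, .data$end_date, .data$claim_id
  )
}

#' 3-character ICD-10 prefix of a code
#'
#' @param code Character vector of ICD-10 codes (e.g. `"I21.0"`, `"I639"`).
#' @return Uppercased 3-character prefixes (`"I21"`, `"I63"`).
#' @export
dx_prefix <- function(code) {
  toupper(substr(code, 1L, 3L))
}

#' Test whether diagnosis codes match a code group at a position scope
#'
#' A diagnosis matches when the first three characters of its code are in
#' `group`; subcodes therefore match by prefix ("I21.9" matches I21).
#' `scope` restricts which positions count: `primary_only` (position 1),
#' `secondary_or_lower` (position >= 2), or `any`.
#'
#' @param codes Character vector of ICD-10 codes on one claim.
#' @param group Character vector of 3-character prefixes (non-empty).
#' @param scope Position scope; one of `"any"`, `"primary_only"`,
#'   `"secondary_or_lower"`.
#' @param positions Integer positions of `codes`; defaults to their order.
#' @return Logical scalar.
#' @examples
#' matches_code_group(c("I50", "I639"), code_group("STROKE"),
#'   scope = "secondary_or_lower"
#' )
#' @export
matches_code_group <- function(codes, group,
                               scope = c("any", "primary_only", "secondary_or_lower"),
                               positions = seq_along(codes)) {
  scope <- match.arg(scope)
  if (length(group) == 0) {
    stop("code group must be non-empty", call. = FALSE)
  }
  if (length(positions) != length(codes)) {
    stop("positions must parallel codes", call. = FALSE)
  }
  in_group <- dx_prefix(codes) %in% group
  keep <- switch(scope,
    any = rep(TRUE, length(codes)),
    primary_only = positions == 1L,
    secondary_or_lower = positions >= 2L
  )
  any(in_group & keep)
}

split_field <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_field <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

#' Read claims from CSV
#'
#' Expects one row per claim with columns `claim_id, patient_id, hospital_id,
#' hospital_type, start_date, end_date, dx_codes, evidence`. `dx_codes` is a
#' semicolon-separated list whose order encodes the diagnosis position
#' (first = primary); `evidence` is a semicolon-separated list of
#' [evidence_flags] names or raw service codes translated through
#' `evidence_map`.
#'
#' @param path CSV file path.
#' @param evidence_map Optional two-column data frame (`raw_code`, `flag`)
#'   mapping local service codes to evidence flags; see
#'   [read_evidence_map()]. Tokens already naming a flag pass through.
#' @param strict If `TRUE` (default), an evidence token that is neither a
#'   flag nor in the mapping is an ingest error; if `FALSE` such tokens are
#'   dropped with a warning.
#' @return A validated, sorted claims tibble.
#' @export
read_claims <- function(path, evidence_map = NULL, strict = TRUE) {
  if (!file.exists(path)) {
    stop("claims file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c(
    "claim_id", "patient_id", "hospital_id", "hospital_type",
    "start_date", "end_date", "dx_codes", "evidence"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("claims CSV is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) {
    return(empty_claims())
  }
  parse_date_col <- function(x, col) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(d)) {
      # +1 for the header row so the message points at the file line
      rows <- which(is.na(d)) + 1L
      stop("unparseable ", col, " at line(s): ",
        paste(head(rows, 5), collapse = ", "),
        call. = FALSE
      )
    }
    d
  }
  new_claims(
    claim_id = raw$claim_id,
    patient_id = raw$patient_id,
    hospital_id = raw$hospital_id,
    hospital_type = raw$hospital_type,
    start_date = parse_date_col(raw$start_date, "start_date"),
    end_date = parse_date_col(raw$end_date, "end_date"),
    dx = split_field(raw$dx_codes),
    evidence = map_evidence(split_field(raw$evidence), evidence_map, strict)
  )
}

map_evidence <- function(tokens, evidence_map, strict) {
  lookup <- character(0)
  if (!is.null(evidence_map)) {
    if (!all(c("raw_code", "flag") %in% names(evidence_map))) {
      stop("evidence_map needs columns raw_code and flag", call. = FALSE)
    }
    bad <- setdiff(evidence_map$flag, evidence_flags)
    if (length(bad) > 0) {
      stop("evidence_map targets unknown flag(s): ",
        paste(unique(bad), collapse = ", "),
        call. = FALSE
      )
    }
    lookup <- stats::setNames(evidence_map$flag, evidence_map$raw_code)
  }
  lapply(tokens, function(v) {
    if (length(v) == 0) {
      return(character(0))
    }
    mapped <- ifelse(v %in% evidence_flags, v, unname(lookup[v]))
    if (anyNA(mapped)) {
      unknown <- unique(v[is.na(mapped)])
      if (strict) {
        stop("unmapped service code(s): ", paste(unknown, collapse = ", "),
          call. = FALSE
        )
      }
      warning("dropping unmapped service code(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
      mapped <- mapped[!is.na(mapped)]
    }
    unique(mapped)
  })
}

#' Write claims to CSV
#'
#' Inverse of [read_claims()]: diagnosis and evidence lists are collapsed to
#' semicolon-separated fields, so `read_claims(write_claims(x, f))` round-trips
#' the logical records.
#'
#' @param claims A claims tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  validate_claims(claims)
  out <- tibble::tibble(
    claim_id = claims$claim_id,
    patient_id = claims$patient_id,
    hospital_id = claims$hospital_id,
    hospital_type = claims$hospital_type,
    start_date = format(claims$start_date, "%Y-%m-%d"),
    end_date = format(claims$end_date, "%Y-%m-%d"),
    dx_codes = join_field(claims$dx),
    evidence = join_field(claims$evidence)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

empty_claims <- function() {
  tibble::tibble(
    claim_id = character(0), patient_id = character(0),
    hospital_id = character(0), hospital_type = character(0),
    start_date = as.Date(character(0)), end_date = as.Date(character(0)),
    dx = list(), evidence = list()
  )
}

#' Read patient death dates from CSV
#'
#' Schema: `patient_id, death_date` (ISO-8601). Death is patient-level, not a
#' claim field: in-episode death is evaluated against the episode span after
#' episode construction.
#'
#' @param path CSV file path.
#' @return Tibble with `patient_id` and `death_date` (`Date`).
#' @export
read_deaths <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("patient_id", "death_date"), names(raw))
  if (length(missing) > 0) {
    stop("deaths CSV is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  d <- as.Date(raw$death_date, format = "%Y-%m-%d")
  if (anyNA(d) && nrow(raw) > 0) {
    stop("unparseable death_date at line(s): ",
      paste(head(which(is.na(d)) + 1L, 5), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(patient_id = as.character(raw$patient_id), death_date = d)
}

#' Write patient death dates to CSV
#'
#' @param deaths Tibble with `patient_id` and `death_date`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deaths <- function(deaths, path) {
  out <- tibble::tibble(
    patient_id = deaths$patient_id,
    death_date = format(as.Date(deaths$death_date), "%Y-%m-%d")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a service-code-to-evidence-flag mapping file
#'
#' Two-column CSV `raw_code, flag` translating local procedure/service codes
#' (e.g. national EDI codes) to the closed [evidence_flags] set. The mapping
#' is configuration because local code systems vary by payer.
#'
#' @param path CSV file path.
#' @return Tibble with `raw_code` and `flag`.
#' @export
read_evidence_map <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("raw_code", "flag"), names(raw))
  if (length(missing) > 0) {
    stop("evidence map is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw[c("raw_code", "flag")]
}

#' Check patient-level consistency of claims and deaths
#'
#' Asserts that no claim starts after its patient's recorded death date.
#'
#' @param claims A claims tibble.
#' @param deaths A deaths tibble, or `NULL`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
check_death_consistency <- function(claims, deaths) {
  if (is.null(deaths) || nrow(deaths) == 0 || nrow(claims) == 0) {
    return(invisible(TRUE))
  }
  dd <- stats::setNames(deaths$death_date, deaths$patient_id)
  d <- dd[claims$patient_id]
  bad <- !is.na(d) & claims$start_date > d
  if (any(bad)) {
    stop("claim(s) starting after patient death: ",
      paste(head(claims$claim_id[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
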