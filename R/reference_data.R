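# Published counts from the multicentre chart-review validation of the
# identification algorithms. Kept as code-constructed tibbles so the
# validation machinery can be exercised, and its output checked, without any
# claims-database access.

#' Chart-review validation counts by stratum
#'
#' Adjudicated-true and identified event counts from the retrospective
#' medical-record review of algorithm-identified events, per disease, event
#' kind and hospital type. Feeding these counts to [ppv()] reproduces the
#' published stratum PPVs and 95% CIs (e.g. first AMI, tertiary: 584/617 ->
#' 94.7 (92.9, 96.4)); the recurrent-AMI primary-hospital stratum is the 0/1
#' cell reported as N/A.
#'
#' @return Tibble with `disease, kind, hospital_type, n_true, n_identified`.
#' @examples
#' counts <- validation_counts()
#' cbind(counts[1:3], display = format_ppv(ppv(counts$n_true, counts$n_identified)))
#' @export
validation_counts <- function() {
  tibble::tribble(
    ~disease, ~kind, ~hospital_type, ~n_true, ~n_identified,
    "AMI", "FIRST", "tertiary", 584L, 617L,
    "AMI", "FIRST", "secondary", 339L, 368L,
    "AMI", "FIRST", "primary", 51L, 121L,
    "AMI", "RECURRENT", "tertiary", 88L, 108L,
    "AMI", "RECURRENT", "secondary", 138L, 184L,
    "AMI", "RECURRENT", "primary", 0L, 1L,
    "STROKE", "FIRST", "tertiary", 458L, 549L,
    "STROKE", "FIRST", "secondary", 335L, 356L,
    "STROKE", "FIRST", "primary", 275L, 392L,
    "STROKE", "RECURRENT", "tertiary", 137L, 181L,
    "STROKE", "RECURRENT", "secondary", 154L, 173L,
    "STROKE", "RECURRENT", "primary", 57L, 90L
  )
}

#' Chart-review case counts by review centre
#'
#' Number of AMI and stroke cases reviewed at each of the 24 participating
#' hospitals (5 tertiary, 10 secondary, 9 primary), anonymised A-X. Subtotals
#' by hospital tier are 725/552/122 for AMI and 730/529/482 for stroke
#' (totals 1,399 and 1,741; grand total 3,140).
#'
#' @return Tibble with `hospital_type, centre, n_ami, n_stroke`.
#' @export
review_centre_counts <- function() {
  tibble::tribble(
    ~hospital_type, ~centre, ~n_ami, ~n_stroke,
    "tertiary", "A", 421L, 428L,
    "tertiary", "B", 20L, 20L,
    "tertiary", "C", 108L, 103L,
    "tertiary", "D", 86L, 89L,
    "tertiary", "E", 90L, 90L,
    "secondary", "F", 90L, 99L,
    "secondary", "G", 40L, 36L,
    "secondary", "H", 39L, 41L,
    "secondary", "I", 41L, 33L,
    "secondary", "J", 40L, 40L,
    "secondary", "K", 120L, 118L,
    "secondary", "L", 30L, 28L,
    "secondary", "M", 49L, 45L,
    "secondary", "N", 70L, 59L,
    "secondary", "O", 33L, 30L,
    "primary", "P", 3L, 17L,
    "primary", "Q", 17L, 140L,
    "primary", "R", 23L, 36L,
    "primary", "S", 31L, 18L,
    "primary", "T", 12L, 168L,
    "primary", "U", 17L, 22L,
    "primary", "V", 7L, 32L,
    "primary", "W", 2L, 21L,
    "primary", "X", 10L, 28L
  )
}
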