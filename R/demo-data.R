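#' Six-record worked example
#'
#' A tiny cleaned record set — six records, all "DAVID WILSON" — illustrating
#' both strengths and hazards of exact-match linkage: common names recur
#' across genuinely different people, identifiers are patchy, and records of
#' one person must be pulled together through different identifier chains.
#' Records 3 and 5 share an NHS number, 3 and 6 a hospital number, and 3-6 a
#' composite identifier, so full linkage yields three clusters:
#' `{1}`, `{2}`, `{3,4,5,6}`.
#'
#' The identifier values are fabricated demonstration values and are used
#' verbatim (the NHS numbers are not check-digit valid, as is usual for
#' published example data).
#'
#' @return cleaned record data.frame of six rows, composite identifier
#'   included, with `record_id` 1..6 serving as start cluster ids.
#' @examples
#' link_records(demo_records())$assignment
#' @export
demo_records <- function() {
  rec <- data.frame(
    record_id = 1:6,
    source = "PAS",
    surname = "WILSON",
    forename = "DAVID",
    sex = "M",
    birthdate = as.Date(c("1940-06-14", "1939-05-01", "1969-01-20",
                          "1969-01-20", "1969-01-20", "1969-01-20")),
    deathdate = as.Date(NA),
    nhs_number = c(NA, "5170231111", "3319004037", NA, "3319004037", NA),
    hospital_number = c("4496644", NA, "4118890", NA, NA, "4118890"),
    suppressed = FALSE,
    stringsAsFactors = FALSE
  )
  add_composite_id(rec)
}
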