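#' Build the high-cardinality composite identifier
#'
#' Concatenates surname, the first three letters of the forename (all of them
#' when the cleaned forename has only two), and the date of birth as
#' `"SURNAME|FFF|YYYY-MM-DD"`. The `|` separator cannot occur in cleaned
#' names, so the encoding is unambiguous. The composite is `NA` whenever any
#' component is missing: a partial composite would link records on too little
#' evidence.
#'
#' @param surname,forename cleaned name vectors.
#' @param birthdate `Date` vector.
#' @return character vector of composite identifiers (or `NA`).
#' @examples
#' build_composite("WILSON", "DAVID", as.Date("1969-01-20"))
#' @export
build_composite <- function(surname, forename, birthdate) {
  out <- paste(surname, substr(forename, 1L, 3L),
               format(birthdate, "%Y-%m-%d"), sep = "|")
  out[is.na(surname) | is.na(forename) | is.na(birthdate)] <- NA_character_
  out
}

#' Add the composite identifier column to a cleaned record table
#'
#' @param records cleaned records (from [clean_records()]).
#' @return `records` with a `composite_id` column.
#' @export
add_composite_id <- function(records) {
  records$composite_id <- build_composite(records$surname, records$forename,
                                          records$birthdate)
  records
}

#' Cardinality report for candidate identifiers
#'
#' For each candidate identifier (a column, or a combination of columns
#' concatenated with `|`), counts the number of distinct values and the mean
#' number of distinct reference-identifier values (e.g. NHS numbers) mapped
#' to each candidate value. A mean close to 1 marks a combination with enough
#' cardinality to act as a near-unique person key.
#'
#' Only records with a non-null reference identifier and a fully non-null
#' candidate value enter each row of the report.
#'
#' @param records cleaned record table.
#' @param candidate_fields a named list; each element is a character vector of
#'   column names forming one candidate identifier.
#' @param reference_field column holding the reference identifier.
#' @return data.frame: identifier, cardinality, mean_reference_ids_per_value.
#' @examples
#' recs <- data.frame(record_id = 1:3, key = c("A", "A", "B"),
#'                    nhs_number = c("1", "2", "3"))
#' cardinality_report(recs, list(key = "key"), "nhs_number")
#' @export
cardinality_report <- function(records, candidate_fields,
                               reference_field = "nhs_number") {
  stopifnot(is.list(candidate_fields))
  if (is.null(names(candidate_fields))) {
    names(candidate_fields) <- vapply(candidate_fields, paste, "", collapse = "+")
  }
  ref <- as.character(records[[reference_field]])
  out <- lapply(names(candidate_fields), function(nm) {
    cols <- candidate_fields[[nm]]
    vals <- do.call(paste, c(lapply(cols, function(cl) {
      v <- records[[cl]]
      if (inherits(v, "Date")) format(v, "%Y-%m-%d") else as.character(v)
    }), sep = "|"))
    complete <- !is.na(ref) &
      Reduce(`&`, lapply(cols, function(cl) !is.na(records[[cl]])))
    vals <- vals[complete]
    refs <- ref[complete]
    if (!length(vals)) {
      return(data.frame(identifier = nm, cardinality = 0L,
                        mean_reference_ids_per_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    per_value <- tapply(refs, vals, function(r) length(unique(r)))
    data.frame(identifier = nm,
               cardinality = length(per_value),
               mean_reference_ids_per_value = mean(per_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
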