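#' Cleaning configuration
#'
#' Collects the tunable parts of the identifier quality-control rules. All
#' failures at cleaning null the offending value; cleaning never invents one.
#'
#' @param placeholder_tokens substrings that invalidate a forename (newborn
#'   placeholders and synonyms). Matching is by substring on the cleaned,
#'   uppercased forename.
#' @param sex_synonyms named character vector mapping common free-text sex
#'   values to the canonical M/F/U codes.
#' @param suppressed_clinics clinic/department codes whose records must have
#'   every identifier suppressed (genito-urinary medicine and occupational
#'   health, where identifiers are withheld by policy).
#' @param test_patient_surnames cleaned surnames marking internal test
#'   patients; their name fields are nulled.
#' @param hospital_number_range inclusive numeric bounds for a plausible
#'   hospital number.
#' @param strip_hospital_check_digit if `TRUE`, the last character of the
#'   hospital number is treated as a check digit and removed before range
#'   validation (off by default; most sites do not append one).
#' @param nhs_blacklist NHS numbers deleted even if the check digit passes
#'   (defaults to the ten all-same-digit values).
#' @param date_floor earliest credible birth/death date.
#' @param date_format either `"ddmmyyyy"` (default) or `"iso"`; ISO-8601 input
#'   is always accepted as a fallback so cleaned output re-cleans to itself.
#' @param reference_forenames character vector of known forenames used by the
#'   forename/surname swap rule; if `NULL`, the set is built from the
#'   dataset's own forename column (values seen at least
#'   `reference_forename_min_count` times).
#' @param reference_forename_min_count frequency threshold used when the
#'   reference forename set is derived from the data.
#' @return a list of class `cleaning_config`.
#' @export
cleaning_config <- function(placeholder_tokens = c("BABY", "INFANT", "TWIN"),
                            sex_synonyms = c(MALE = "M", FEMALE = "F",
                                             UNKNOWN = "U", INDETERMINATE = "U"),
                            suppressed_clinics = c("GUM", "OCCHEALTH", "OCCH"),
                            test_patient_surnames = c("TEST", "XXTEST", "ZZTEST", "DONOTUSE"),
                            hospital_number_range = c(1, 1e7),
                            strip_hospital_check_digit = FALSE,
                            nhs_blacklist = vapply(0:9, function(d) strrep(d, 10), ""),
                            date_floor = as.Date("1860-01-01"),
                            date_format = c("ddmmyyyy", "iso"),
                            reference_forenames = NULL,
                            reference_forename_min_count = 2L) {
  structure(list(
    placeholder_tokens = toupper(placeholder_tokens),
    sex_synonyms = sex_synonyms,
    suppressed_clinics = toupper(suppressed_clinics),
    test_patient_surnames = toupper(test_patient_surnames),
    hospital_number_range = hospital_number_range,
    strip_hospital_check_digit = strip_hospital_check_digit,
    nhs_blacklist = nhs_blacklist,
    date_floor = date_floor,
    date_format = match.arg(date_format),
    reference_forenames = reference_forenames,
    reference_forename_min_count = reference_forename_min_count
  ), class = "cleaning_config")
}

#' Clean a single name field
#'
#' Uppercases, strips whitespace and every non-alphabetic symbol, and nulls
#' values left with fewer than two letters. Forenames containing a newborn
#' placeholder token (BABY, INFANT, TWIN or configured synonyms) are nulled,
#' since they describe a situation, not a person.
#'
#' @param value character vector of raw names.
#' @param is_forename apply the placeholder-token rule.
#' @param placeholder_tokens uppercase substrings that invalidate a forename.
#' @return character vector; `NA` where the value failed quality control.
#' @examples
#' clean_name("De Souza")            # "DESOUZA"
#' clean_name("Baby", is_forename = TRUE) # NA
#' @export
clean_name <- function(value, is_forename = FALSE,
                       placeholder_tokens = c("BABY", "INFANT", "TWIN")) {
  x <- toupper(as.character(value))
  x <- gsub("[^A-Z]", "", x)
  x[is.na(x) | nchar(x) < 2L] <- NA_character_
  if (is_forename && length(placeholder_tokens)) {
    pat <- paste(placeholder_tokens, collapse = "|")
    x[!is.na(x) & grepl(pat, x)] <- NA_character_
  }
  x
}

#' Swap forename and surname when they look reversed
#'
#' If the stated forename is not a known forename but the stated surname is,
#' the two are assumed transposed and returned swapped. Both names must be
#' non-null (already cleaned); otherwise the pair is returned unchanged.
#'
#' @param forename,surname cleaned name vectors of equal length.
#' @param reference_forenames character vector of known forenames.
#' @return a list with elements `forename` and `surname`.
#' @export
maybe_swap_names <- function(forename, surname, reference_forenames) {
  swap <- !is.na(forename) & !is.na(surname) &
    !(forename %in% reference_forenames) &
    (surname %in% reference_forenames)
  new_f <- ifelse(swap, surname, forename)
  new_s <- ifelse(swap, forename, surname)
  list(forename = new_f, surname = new_s, swapped = swap)
}

#' Clean a sex code
#'
#' Maps configured synonyms (MALE, FEMALE, ...) to M/F/U, otherwise keeps the
#' uppercased first character when it is one of M, F or U; anything else is
#' nulled.
#'
#' @param value character vector.
#' @param synonyms named character vector of synonym mappings.
#' @return character vector with values in M/F/U or `NA`.
#' @export
clean_sex <- function(value, synonyms = c(MALE = "M", FEMALE = "F",
                                          UNKNOWN = "U", INDETERMINATE = "U")) {
  x <- toupper(trimws(as.character(value)))
  mapped <- unname(synonyms[x])
  x <- ifelse(!is.na(mapped), mapped, substr(x, 1L, 1L))
  x[!(x %in% c("M", "F", "U"))] <- NA_character_
  x
}

#' Validate an NHS number
#'
#' An NHS number is ten digits; the tenth is a Modulus-11 check digit over
#' the first nine (weights 10 down to 2; check digit = 11 minus the weighted
#' sum mod 11, with 11 mapping to 0 and 10 marking the number invalid).
#' Values on the blacklist (all-same-digit by default) are rejected even when
#' the arithmetic passes.
#'
#' @param value character vector of candidate numbers (whitespace tolerated).
#' @param blacklist values rejected outright.
#' @return the validated 10-digit string, or `NA` where invalid.
#' @examples
#' validate_nhs_number("4010232137") # passes the check digit
#' validate_nhs_number("123456789")  # NA: nine digits
#' @export
validate_nhs_number <- function(value,
                                blacklist = vapply(0:9, function(d) strrep(d, 10), "")) {
  x <- gsub("\\s", "", as.character(value))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]{10}$", x) & !(x %in% blacklist)
  for (i in which(ok)) {
    d <- as.integer(strsplit(x[i], "", fixed = TRUE)[[1L]])
    check <- 11L - sum(d[1:9] * (10:2)) %% 11L
    if (check == 11L) check <- 0L
    if (check != 10L && check == d[10L]) out[i] <- x[i]
  }
  out
}

#' Clean a hospital number
#'
#' Strips whitespace (and optionally a trailing check digit), requires an
#' all-digit value within the configured numeric range, and, when a hospital
#' code is supplied, prefixes it as `"CODE:number"` so numbers issued
#' independently by different hospitals cannot collide. Already-prefixed
#' values re-clean to themselves.
#'
#' @param value character vector of raw hospital numbers.
#' @param hospital_code optional short code of the issuing hospital (scalar or
#'   vector).
#' @param valid_range inclusive numeric bounds.
#' @param strip_check_digit drop the last character before validation.
#' @return character vector or `NA`.
#' @examples
#' clean_hospital_number("123456", hospital_code = "A") # "A:123456"
#' @export
clean_hospital_number <- function(value, hospital_code = NULL,
                                  valid_range = c(1, 1e7),
                                  strip_check_digit = FALSE) {
  x <- gsub("\\s", "", as.character(value))
  n <- length(x)
  code <- if (is.null(hospital_code)) rep(NA_character_, n)
          else rep_len(as.character(hospital_code), n)
  out <- rep(NA_character_, n)
  pre <- !is.na(x) & grepl("^[A-Z0-9]+:[0-9]+$", x)  # already prefixed
  num_part <- ifelse(pre, sub("^[A-Z0-9]+:", "", x), x)
  if (strip_check_digit) {
    long <- !is.na(num_part) & nchar(num_part) > 1L & !pre
    num_part[long] <- substr(num_part[long], 1L, nchar(num_part[long]) - 1L)
  }
  ok <- !is.na(num_part) & grepl("^[0-9]+$", num_part)
  v <- suppressWarnings(as.numeric(num_part))
  ok <- ok & !is.na(v) & v >= valid_range[1] & v <= valid_range[2]
  keep_prefix <- ok & pre
  out[keep_prefix] <- x[keep_prefix]
  new <- ok & !pre
  out[new] <- ifelse(is.na(code[new]) | !nzchar(code[new]),
                     num_part[new],
                     paste0(code[new], ":", num_part[new]))
  out
}

#' Clean a date field
#'
#' Parses `ddmmyyyy` (the common compact entry format) or ISO-8601, and nulls
#' dates before the floor (1860-01-01 by default: nobody in a live clinical
#' record set was born earlier) or in the future.
#'
#' @param value character or `Date` vector.
#' @param floor earliest acceptable date.
#' @param today latest acceptable date.
#' @param format `"ddmmyyyy"` or `"iso"`; the other form is tried as a
#'   fallback.
#' @return `Date` vector with `NA` where invalid.
#' @examples
#' clean_date("14061940") # 1940-06-14
#' @export
clean_date <- function(value, floor = as.Date("1860-01-01"),
                       today = Sys.Date(), format = "ddmmyyyy") {
  if (inherits(value, "Date")) {
    d <- value
  } else {
    x <- trimws(as.character(value))
    x[!nzchar(x)] <- NA_character_
    d <- rep(as.Date(NA), length(x))
    compact <- !is.na(x) & grepl("^[0-9]{8}$", x)
    iso <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
    if (format == "ddmmyyyy") {
      d[compact] <- as.Date(x[compact], format = "%d%m%Y")
    } else {
      d[compact] <- as.Date(x[compact], format = "%Y%m%d")
    }
    d[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  }
  d[!is.na(d) & (d < floor | d > today)] <- as.Date(NA)
  d
}

#' Apply all quality-control rules to a table of raw records
#'
#' Runs the field-level cleaners over a raw record table and returns the
#' cleaned table with the same `record_id` order. Records from suppressed
#' clinics have every identifier nulled and are flagged `suppressed`;
#' internal test patients have their name fields nulled. An audit log of the
#' values that were changed or nulled is attached as `attr(, "audit")`.
#'
#' Expected input columns (missing ones are treated as all-`NA`):
#' `record_id`, `source`, `surname`, `forename`, `sex`, `birthdate`,
#' `deathdate`, `nhs_number`, `hospital_number`, `hospital_code`,
#' `clinic_code`.
#'
#' @param records data.frame of raw records.
#' @param config a [cleaning_config()].
#' @return data.frame of cleaned records (one row per input row, same order)
#'   with a logical `suppressed` column, plus an `"audit"` attribute
#'   (data.frame: record_id, field, raw, action).
#' @export
clean_records <- function(records, config = cleaning_config()) {
  stopifnot(is.data.frame(records), "record_id" %in% names(records))
  if (anyDuplicated(records$record_id)) stop("record_id values must be unique")
  n <- nrow(records)
  col <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(NA_character_, n)
  }

  surname <- clean_name(col("surname"), is_forename = FALSE,
                        placeholder_tokens = config$placeholder_tokens)
  forename <- clean_name(col("forename"), is_forename = TRUE,
                         placeholder_tokens = config$placeholder_tokens)

  ref <- config$reference_forenames
  if (is.null(ref)) {
    tab <- table(forename)
    ref <- names(tab)[tab >= config$reference_forename_min_count]
  }
  ref <- toupper(ref)
  swapped <- maybe_swap_names(forename, surname, ref)
  forename <- swapped$forename
  surname <- swapped$surname

  sex <- clean_sex(col("sex"), synonyms = config$sex_synonyms)
  birthdate <- clean_date(col("birthdate"), floor = config$date_floor,
                          format = config$date_format)
  deathdate <- clean_date(col("deathdate"), floor = config$date_floor,
                          format = config$date_format)
  nhs_number <- validate_nhs_number(col("nhs_number"),
                                    blacklist = config$nhs_blacklist)
  hospital_number <- clean_hospital_number(
    col("hospital_number"),
    hospital_code = col("hospital_code"),
    valid_range = config$hospital_number_range,
    strip_check_digit = config$strip_hospital_check_digit
  )

  # internal test patients: null name fields
  test_pat <- !is.na(surname) & surname %in% config$test_patient_surnames
  forename[test_pat] <- NA_character_
  surname[test_pat] <- NA_character_

  clinic <- toupper(trimws(as.character(col("clinic_code"))))
  suppressed <- !is.na(clinic) & clinic %in% config$suppressed_clinics
  if (any(suppressed)) {
    surname[suppressed] <- NA_character_
    forename[suppressed] <- NA_character_
    sex[suppressed] <- NA_character_
    birthdate[suppressed] <- as.Date(NA)
    deathdate[suppressed] <- as.Date(NA)
    nhs_number[suppressed] <- NA_character_
    hospital_number[suppressed] <- NA_character_
  }

  out <- data.frame(
    record_id = records$record_id,
    source = as.character(col("source")),
    surname = surname,
    forename = forename,
    sex = sex,
    birthdate = birthdate,
    deathdate = deathdate,
    nhs_number = nhs_number,
    hospital_number = hospital_number,
    clinic_code = ifelse(is.na(clinic) | !nzchar(clinic), NA_character_, clinic),
    suppressed = suppressed,
    stringsAsFactors = FALSE
  )

  audit <- .cleaning_audit(records, out, swapped$swapped, test_pat)
  attr(out, "audit") <- audit
  out
}

# Build the audit log: one row per field whose value was nulled or altered.
.cleaning_audit <- function(raw, clean, swapped, test_pat) {
  fields <- c("surname", "forename", "sex", "birthdate", "deathdate",
              "nhs_number", "hospital_number")
  rows <- list()
  for (f in fields) {
    before <- if (f %in% names(raw)) as.character(raw[[f]]) else rep(NA_character_, nrow(raw))
    after <- as.character(clean[[f]])
    changed <- which((!is.na(before) & nzchar(trimws(before))) &
                       (is.na(after) | after != before))
    if (length(changed)) {
      rows[[f]] <- data.frame(
        record_id = raw$record_id[changed],
        field = f,
        raw = before[changed],
        action = ifelse(is.na(after[changed]), "nulled", "normalised"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (any(swapped)) {
    rows[["swap"]] <- data.frame(
      record_id = raw$record_id[swapped], field = "forename/surname",
      raw = "", action = "swapped", stringsAsFactors = FALSE
    )
  }
  if (any(test_pat)) {
    rows[["testpat"]] <- data.frame(
      record_id = raw$record_id[test_pat], field = "forename/surname",
      raw = "", action = "test-patient names nulled", stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(record_id = character(), field = character(),
                      raw = character(), action = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(rows))
}
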