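test_that("name cleaning uppercases, strips symbols and rejects short or placeholder values", {
  expect_equal(clean_name("De Souza"), "DESOUZA")
  expect_equal(clean_name("o'brien"), "OBRIEN")
  expect_true(is.na(clean_name("J.")))
  expect_true(is.na(clean_name("   ")))
  expect_true(is.na(clean_name(NA)))
  expect_true(is.na(clean_name("Baby", is_forename = TRUE)))
  expect_true(is.na(clean_name("BABYOF", is_forename = TRUE)))
  expect_true(is.na(clean_name("Twin 1", is_forename = TRUE)))
  # placeholder rule applies to forenames only
  expect_equal(clean_name("Baby", is_forename = FALSE), "BABY")
  expect_equal(clean_name("123David456"), "DAVID")
})

test_that("forename/surname swap fires only when surname is a known forename and forename is not", {
  ref <- c("DAVID", "MARY")
  sw <- maybe_swap_names("SMITH", "DAVID", ref)
  expect_equal(sw$forename, "DAVID")
  expect_equal(sw$surname, "SMITH")
  un <- maybe_swap_names("DAVID", "WILSON", ref)
  expect_equal(un$forename, "DAVID")
  expect_equal(un$surname, "WILSON")
  # neither name known: no swap
  nn <- maybe_swap_names("XQZR", "YTWP", ref)
  expect_equal(nn$forename, "XQZR")
  expect_equal(nn$surname, "YTWP")
  # null input: unchanged
  na <- maybe_swap_names(NA_character_, "DAVID", ref)
  expect_true(is.na(na$forename))
  expect_equal(na$surname, "DAVID")
})

test_that("sex cleaning maps synonyms and rejects anything outside M/F/U", {
  expect_equal(clean_sex("f"), "F")
  expect_equal(clean_sex("MALE"), "M")
  expect_equal(clean_sex("Female"), "F")
  expect_equal(clean_sex("unknown"), "U")
  expect_true(is.na(clean_sex("1")))
  expect_true(is.na(clean_sex("")))
})

test_that("NHS validation implements the Modulus-11 check digit", {
  # check digit oracle: 4010232137 -> weighted sum 92, 11 - 92 %% 11 = 7 = digit 10
  expect_equal(validate_nhs_number("4010232137"), "4010232137")
  expect_equal(validate_nhs_number(" 401 023 2137 "), "4010232137")
  # oracle verdicts: weighted sums 151 -> check 3 != 1; 150 -> check 4 != 7
  expect_true(is.na(validate_nhs_number("5170231111")))
  expect_true(is.na(validate_nhs_number("3319004037")))
  expect_true(is.na(validate_nhs_number("123456789")))   # nine digits
  expect_true(is.na(validate_nhs_number("1111111111"))) # blacklisted
  expect_true(is.na(validate_nhs_number(NA)))
})

test_that("hospital number cleaning enforces range and hospital prefixing", {
  expect_equal(clean_hospital_number("123456", hospital_code = "A"), "A:123456")
  expect_equal(clean_hospital_number("4496644"), "4496644")
  expect_true(is.na(clean_hospital_number("99999999")))  # out of range
  expect_true(is.na(clean_hospital_number("12AB34")))
  expect_equal(clean_hospital_number(" 44 96644 "), "4496644")
  # already-prefixed values re-clean to themselves (idempotence)
  expect_equal(clean_hospital_number("A:123456"), "A:123456")
  expect_equal(clean_hospital_number("1234567", strip_check_digit = TRUE), "123456")
})

test_that("date cleaning parses ddmmyyyy and applies floor and future rules", {
  expect_equal(clean_date("14061940"), as.Date("1940-06-14"))
  expect_equal(clean_date("1940-06-14"), as.Date("1940-06-14"))
  expect_true(is.na(clean_date("01011850")))  # before 1860 floor
  expect_true(is.na(clean_date("01013025")))  # future
  expect_true(is.na(clean_date("31022000")))  # impossible date
  expect_true(is.na(clean_date("garbage")))
})

test_that("record-level cleaning applies suppression and test-patient rules", {
  raw <- data.frame(
    record_id = 1:3,
    source = "PAS",
    surname = c("Wilson", "Wilson", "TEST"),
    forename = c("David", "David", "One"),
    sex = c("M", "M", "M"),
    birthdate = c("14061940", "14061940", "14061940"),
    nhs_number = c("4010232137", "4010232137", NA),
    hospital_number = c("4496644", "4496644", "123"),
    clinic_code = c(NA, "GUM", NA),
    stringsAsFactors = FALSE
  )
  cl <- clean_records(raw, cleaning_config(reference_forenames = "DAVID"))
  expect_equal(cl$surname[1], "WILSON")
  expect_equal(cl$nhs_number[1], "4010232137")
  # suppressed clinic: every identifier nulled
  expect_true(cl$suppressed[2])
  expect_true(all(is.na(cl[2, c("surname", "forename", "sex", "nhs_number",
                                "hospital_number")])))
  expect_true(is.na(cl$birthdate[2]))
  # test patient: names nulled, other identifiers kept
  expect_true(is.na(cl$surname[3]) && is.na(cl$forename[3]))
  expect_equal(cl$hospital_number[3], "123")
  # audit log names the suppressed fields
  audit <- attr(cl, "audit")
  expect_true(all(c("record_id", "field", "raw", "action") %in% names(audit)))
  expect_true(any(audit$record_id == 2))
})

test_that("cleaning is idempotent and never invents values", {
  set.seed(7)
  pats <- generate_patients(40)
  gen <- generate_records(pats, sim_config(typo_rate = 0.05))
  cfg <- cleaning_config(reference_forenames = "DAVID")
  once <- clean_records(gen$records, cfg)

  # every cleaned NHS number passes validation
  nhs <- once$nhs_number[!is.na(once$nhs_number)]
  expect_true(all(!is.na(validate_nhs_number(nhs))))

  # re-cleaning the serialised output is a fixed point
  reser <- once
  reser$birthdate <- ifelse(is.na(once$birthdate), NA,
                            format(once$birthdate, "%Y-%m-%d"))
  reser$deathdate <- ifelse(is.na(once$deathdate), NA,
                            format(once$deathdate, "%Y-%m-%d"))
  reser$suppressed <- NULL
  twice <- clean_records(reser, cfg)
  for (f in c("surname", "forename", "sex", "nhs_number", "hospital_number")) {
    expect_identical(twice[[f]], once[[f]])
  }
  expect_identical(twice$birthdate, once$birthdate)

  # no invention: every non-null cleaned name equals the normalised form of
  # one of the record's own raw name fields (swap included)
  strip <- function(x) gsub("[^A-Z]", "", toupper(x))
  ok <- vapply(seq_len(nrow(once)), function(i) {
    raw_pair <- strip(c(gen$records$surname[i], gen$records$forename[i]))
    for (f in c("surname", "forename")) {
      v <- once[[f]][i]
      if (!is.na(v) && !(v %in% raw_pair)) return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_true(all(ok))
})
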