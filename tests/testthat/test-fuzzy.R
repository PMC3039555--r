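test_that("trigram tokenisation follows the 3-consecutive-character definition", {
  idx <- build_index(data.frame(record_id = 1L, surname = "WILSON",
                                forename = NA_character_,
                                birthdate = as.Date(NA),
                                hospital_number = NA_character_,
                                nhs_number = NA_character_,
                                stringsAsFactors = FALSE))
  expect_setequal(names(idx$postings), c("WIL", "ILS", "LSO", "SON"))

  # a ddmmyyyy date contributes 8 - 3 + 1 = 6 trigrams
  idx_d <- build_index(data.frame(record_id = 1L, surname = NA_character_,
                                  forename = NA_character_,
                                  birthdate = as.Date("1969-01-20"),
                                  hospital_number = NA_character_,
                                  nhs_number = NA_character_,
                                  stringsAsFactors = FALSE))
  expect_equal(length(idx_d$postings), 6L)

  # short fields contribute themselves as a single token
  idx_s <- build_index(data.frame(record_id = 1L, surname = "LI",
                                  forename = NA_character_,
                                  birthdate = as.Date(NA),
                                  hospital_number = NA_character_,
                                  nhs_number = NA_character_,
                                  stringsAsFactors = FALSE))
  expect_equal(names(idx_s$postings), "LI")

  empty <- build_index(data.frame(record_id = integer(),
                                  surname = character(),
                                  forename = character(),
                                  birthdate = as.Date(character()),
                                  hospital_number = character(),
                                  nhs_number = character(),
                                  stringsAsFactors = FALSE))
  expect_equal(length(empty$postings), 0L)
})

test_that("top-k query ranks by shared trigrams with deterministic ties", {
  set.seed(41)
  pats <- generate_patients(60)
  gen <- generate_records(pats, sim_config(records_per_patient = c(1, 2)))
  recs <- clean_records(gen$records)
  idx <- build_index(recs)

  # a query identical to an indexed record ranks that record first
  q <- recs[5, ]
  q$record_id <- "QUERY"
  top <- query_top_k(idx, q, k = 10)
  oracle <- oracle_shared_trigrams(recs, q, idx$fields)
  # the copied record attains the maximal shared-trigram count (possibly tied
  # with exact duplicates of itself)
  expect_equal(top$shared_trigrams[1], max(oracle))
  expect_true(recs$record_id[5] %in%
                top$record_id[top$shared_trigrams == max(oracle)])

  # full ranking equals the brute-force oracle (count desc, record id asc)
  ord <- order(-oracle, recs$record_id)
  ord <- ord[oracle[ord] > 0]
  expect_equal(top$record_id, recs$record_id[utils::head(ord, 10)])
  expect_equal(top$shared_trigrams, oracle[utils::head(ord, 10)])

  # the query's own record is excluded when ids match
  top_self <- query_top_k(idx, recs[5, ], k = 10)
  expect_false(recs$record_id[5] %in% top_self$record_id)

  # nothing shared: empty result
  none <- data.frame(record_id = "Q2", surname = NA_character_,
                     forename = NA_character_, birthdate = as.Date(NA),
                     hospital_number = NA_character_,
                     nhs_number = NA_character_, stringsAsFactors = FALSE)
  expect_equal(nrow(query_top_k(idx, none)), 0L)
})

test_that("duplicates of an indexed record outrank non-duplicates", {
  set.seed(42)
  pats <- generate_patients(40)
  gen <- generate_records(pats, sim_config_consistent(records_per_patient = c(2, 3)))
  recs <- clean_records(gen$records)
  idx <- build_index(recs)
  truth <- gen$truth$true_id[match(recs$record_id, gen$truth$record_id)]
  # with fully identified records, same-person records share the most trigrams
  rich <- which(!is.na(recs$surname) & !is.na(recs$nhs_number) &
                  !is.na(recs$hospital_number))
  for (i in utils::head(rich, 5)) {
    oracle <- oracle_shared_trigrams(recs, recs[i, ], idx$fields)
    oracle[i] <- -1L
    dup <- truth == truth[i] & seq_along(truth) != i
    if (!any(dup)) next
    expect_gte(min(oracle[dup]), max(oracle[!dup]))
  }
})

test_that("exact-name search matches cleaned surname and forename", {
  r <- demo_records()
  hits <- exact_name_candidates(r, list(surname = "WILSON", forename = "DAVID"))
  expect_setequal(hits, 1:6)
  expect_equal(length(exact_name_candidates(r, list(surname = "SMITH",
                                                    forename = "DAVID"))), 0L)
  expect_equal(length(exact_name_candidates(r, list(surname = NA,
                                                    forename = "DAVID"))), 0L)
})
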