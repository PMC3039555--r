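test_that("edit and Jaro-Winkler distances match hand-computed oracles", {
  expect_equal(levenshtein("1969", "2007"), 4L)
  expect_equal(levenshtein("02", "02"), 0L)
  expect_equal(levenshtein("M", "F"), 1L)
  expect_equal(levenshtein(c("01", "1969"), c("11", "1970")), c(1L, 2L))

  expect_equal(jw_distance("WILSON", "WILSON"), 0)
  # JOHN/CHRIS: one match (H), no transpositions, no common prefix:
  # jaro = (1/4 + 1/5 + 1)/3 = 29/60, distance = 31/60
  expect_equal(jw_distance("JOHN", "CHRIS"), 31 / 60, tolerance = 1e-12)
  # classic reference values
  expect_equal(jaro_winkler("MARTHA", "MARHTA"), 0.9611111, tolerance = 1e-6)
  expect_equal(jaro_winkler("DWAYNE", "DUANE"), 0.84, tolerance = 1e-12)
  expect_equal(jw_distance("", "WILSON"), 1)
  expect_true(is.na(jw_distance(NA, "WILSON")))
})

test_that("complexity flag and good-cluster rules follow identifier cardinality", {
  mk <- function(nhs, hosp, comp, surname = "WILSON") {
    data.frame(record_id = seq_along(nhs), nhs_number = nhs,
               hospital_number = hosp, composite_id = comp,
               surname = surname, stringsAsFactors = FALSE)
  }
  expect_false(is_complex(mk("N1", "H1", "C1")))                    # singleton
  expect_true(is_complex(mk(c("N1", "N1"), c("H1", "H2"), c("C1", "C1"))))
  # a null alongside one value is not variation
  expect_false(is_complex(mk(c(NA, "N1"), c("H1", "H1"), c("C1", NA))))

  # rule 1 needs only one NHS + one hospital value; surnames may differ
  v <- rule_classify(mk(c("N1", "N1"), c("H1", "H1"), c("C1", "C2"),
                        surname = c("SMITH", "JONES")))
  expect_equal(v$label, "good")
  expect_equal(v$matched_rule, "nhs+hospital")
  # rule 3: one hospital + one composite despite two NHS numbers
  v3 <- rule_classify(mk(c("N1", "N2"), c("H1", "H1"), c("C1", "C1")))
  expect_equal(v3$label, "good")
  expect_equal(v3$matched_rule, "hospital+composite")
  # variation in every pair: uncertain
  vu <- rule_classify(mk(c("N1", "N2"), c("H1", "H2"), c("C1", "C2")))
  expect_equal(vu$label, "uncertain")
  expect_true(is.na(vu$matched_rule))
  # both fields must be present: all-null pairs do not fire a rule
  vn <- rule_classify(mk(c(NA, NA), c(NA, NA), c("C1", "C1")))
  expect_equal(vn$label, "uncertain")
})

test_that("feature extraction takes maximal pairwise distances and skips nulls", {
  cl <- data.frame(
    record_id = 1:2,
    surname = "WILSON", forename = "DAVID", sex = "M",
    birthdate = as.Date(c("1969-01-20", "2007-01-20")),
    nhs_number = c("N1", "N1"), hospital_number = NA_character_,
    composite_id = c("C1", "C2"),
    stringsAsFactors = FALSE
  )
  f <- extract_features(cl)
  expect_equal(f$dob_year, 4)
  expect_equal(f$dob_day, 0)
  expect_equal(f$dob_month, 0)
  expect_equal(f$forename, 0)
  expect_equal(f$hospital_number, 0)  # fewer than two non-null values
  expect_false(f$any_female)

  # identical records: all-zero features
  f0 <- extract_features(cl[c(1, 1), ])
  expect_true(all(as.numeric(f0[1, c("dob_day", "dob_month", "dob_year",
                                     "forename", "surname", "hospital_number",
                                     "sex")]) == 0))

  # three-way forename variation: the maximum pair wins
  cl3 <- cl[c(1, 1, 1), ]
  cl3$record_id <- 1:3
  cl3$forename <- c("DAVID", "DAVE", "JOHN")
  f3 <- extract_features(cl3)
  pairwise <- jw_distance(c("DAVID", "DAVID", "DAVE"), c("DAVE", "JOHN", "JOHN"))
  expect_equal(f3$forename, max(pairwise))

  # permutation invariance
  feat_cols <- c("dob_day", "dob_month", "dob_year", "forename", "surname",
                 "hospital_number", "sex")
  set.seed(3)
  f_perm <- extract_features(cl3[sample(3), ])
  expect_equal(f_perm[feat_cols], f3[feat_cols])
})

test_that("scoring applies the published coefficients with a strict cutoff", {
  zero <- data.frame(dob_day = 0, dob_month = 0, dob_year = 0, forename = 0,
                     surname = 0, hospital_number = 0, sex = 0,
                     any_female = FALSE)
  s0 <- score_cluster(zero)
  expect_equal(s0$score, -3.33)
  expect_equal(s0$label, "good")

  yr <- zero
  yr$dob_year <- 4
  s4 <- score_cluster(yr)
  expect_equal(s4$score, -3.33 + 4 * 5.12)
  expect_equal(s4$label, "bad")

  # a score exactly at the cutoff stays good (strict inequality)
  m <- published_models()
  m$no_female$coefficients <- c(dob_year = 1)
  m$no_female$intercept <- -2.5
  at_cut <- zero
  at_cut$dob_year <- 1
  expect_equal(score_cluster(at_cut, m)$score, -1.5)
  expect_equal(score_cluster(at_cut, m)$label, "good")

  # monotonicity: raising a positively weighted feature never lowers the score
  set.seed(5)
  for (i in 1:20) {
    base <- zero
    base[c("dob_day", "dob_month", "dob_year", "forename", "sex")] <-
      runif(5, 0, 2)
    bumped <- base
    f <- sample(c("dob_day", "dob_month", "dob_year", "forename", "sex"), 1)
    bumped[[f]] <- bumped[[f]] + runif(1)
    expect_gte(score_cluster(bumped)$score, score_cluster(base)$score)
  }

  expect_error(score_cluster(zero[, c("dob_day", "any_female")]), "missing")
})

test_that("random combination of good clusters yields complex, detectable bad clusters", {
  good <- generate_good_clusters(20, rng_seed = 31,
                                 config = sim_config_consistent())
  bad <- simulate_bad_by_combination(good, rng_seed = 1)
  expect_equal(length(bad), 10L)
  # same seed, same pairing
  bad2 <- simulate_bad_by_combination(good, rng_seed = 1)
  expect_identical(lapply(bad, function(x) x$record_id),
                   lapply(bad2, function(x) x$record_id))
  expect_true(all(vapply(bad, is_complex, logical(1))))
  expect_equal(simulate_bad_by_combination(good[1], rng_seed = 1), list())
})

test_that("backward-AIC logistic fitting recovers known coefficients and drops noise", {
  set.seed(17)
  n <- 5000
  X <- data.frame(
    dob_year = rpois(n, 0.8),
    forename = runif(n),
    noise = runif(n)
  )
  true_beta <- c(dob_year = 1.6, forename = 2.0, noise = 0)
  eta <- -2 + as.matrix(X) %*% true_beta
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_collision_model(X, y, include_fields = names(X))
  est <- stats::coef(attr(fit, "fit"))
  se <- sqrt(diag(stats::vcov(attr(fit, "fit"))))
  for (term in c("dob_year", "forename")) {
    expect_true(term %in% names(est))
    expect_lt(abs(est[[term]] - true_beta[[term]]), 3 * se[[term]])
  }
  expect_lt(abs(est[["(Intercept)"]] - (-2)), 3 * se[["(Intercept)"]])

  # labels independent of features: backward AIC keeps the intercept only
  set.seed(18)
  y_null <- rbinom(n, 1, 0.4)
  fit_null <- fit_collision_model(X, y_null, include_fields = names(X))
  expect_equal(length(fit_null$coefficients), 0L)

  expect_error(fit_collision_model(X, rep(TRUE, n), include_fields = names(X)),
               "both labels")
})
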