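# Bundled name pools for the synthetic generator. Sampling is Zipf-like
# (probability proportional to 1/rank) so common names repeat across
# patients, exercising the composite identifier: several distinct people
# named DAVID WILSON is the expected, not the pathological, case.
FORENAMES_M <- c(
  "DAVID", "JOHN", "MICHAEL", "JAMES", "ROBERT", "WILLIAM", "THOMAS",
  "CHRISTOPHER", "DANIEL", "PAUL", "MARK", "ANDREW", "GEORGE", "PETER",
  "RICHARD", "STEPHEN", "EDWARD", "ANTHONY", "KEVIN", "BRIAN", "MARTIN",
  "COLIN", "GRAHAM", "NIGEL", "TREVOR", "ALAN", "PHILIP", "SIMON", "IAN",
  "NEIL", "GARETH", "OWEN", "HUGH", "ROSS", "EWAN"
)
FORENAMES_F <- c(
  "MARY", "SUSAN", "MARGARET", "SARAH", "ELIZABETH", "PATRICIA", "KAREN",
  "HELEN", "ANNE", "JANET", "CATHERINE", "JOAN", "DOROTHY", "ALISON",
  "CLAIRE", "JOANNE", "LUCY", "EMMA", "HANNAH", "SOPHIE", "RACHEL",
  "REBECCA", "LAURA", "GILLIAN", "FIONA", "ANGELA", "DIANE", "PAULINE",
  "SHEILA", "WENDY", "CAROL", "JUDITH", "NICOLA", "TRACEY", "DAWN"
)
SURNAMES <- c(
  "SMITH", "JONES", "WILLIAMS", "TAYLOR", "BROWN", "DAVIES", "EVANS",
  "WILSON", "THOMAS", "JOHNSON", "ROBERTS", "ROBINSON", "THOMPSON",
  "WRIGHT", "WALKER", "WHITE", "EDWARDS", "HUGHES", "GREEN", "HALL",
  "LEWIS", "HARRIS", "CLARKE", "PATEL", "JACKSON", "WOOD", "TURNER",
  "MARTIN", "COOPER", "HILL", "WARD", "MORRIS", "MOORE", "CLARK", "LEE",
  "KING", "BAKER", "HARRISON", "MORGAN", "ALLEN", "JAMES", "SCOTT",
  "PHILLIPS", "WATSON", "DAVIS", "PARKER", "PRICE", "BENNETT", "YOUNG",
  "GRIFFITHS", "MITCHELL", "KELLY", "COOK", "CARTER", "RICHARDSON",
  "BAILEY", "COLLINS", "BELL", "SHAW", "MURPHY", "MILLER", "COX",
  "RICHARDS", "KHAN", "MARSHALL", "ANDERSON", "SIMPSON", "ELLIS",
  "ADAMS", "SINGH", "BEGUM", "WILKINSON", "FOSTER", "CHAPMAN", "POWELL",
  "WEBB", "ROGERS", "GRAY", "MASON", "ALI"
)

.zipf_sample <- function(pool, n) {
  w <- 1 / seq_along(pool)
  sample(pool, n, replace = TRUE, prob = w / sum(w))
}

#' Simulation configuration
#'
#' Study conditions for the synthetic record generator: a multi-source
#' hospital-like population with per-source identifier missingness, benign
#' within-person variation (surname change on marriage, repeated common
#' names) and optional typographic errors.
#'
#' The per-source missingness defaults qualitatively mirror a hospital
#' estate: an administration system (`pas`) nearly always carrying a hospital
#' number but an NHS number only for a fraction of entries; a laboratory
#' system (`lims`) dominated by name/date-of-birth-only records; a
#' microbiology system (`micro`) in between; an admissions tracker (`jonah`)
#' and an administrative-history source (`pashistory`) with nearly complete
#' identifiers. Each entry gives the probability that the record *keeps* the
#' hospital number, the NHS number, and the name/date-of-birth block.
#'
#' @param year_range birth years drawn uniformly over this inclusive range.
#' @param records_per_patient inclusive range for the number of records a
#'   patient generates (uniform).
#' @param sources source codes and their sampling weights.
#' @param missingness named list per source: `p_hosp`, `p_nhs`, `p_name`.
#' @param typo_rate per-field probability of a single-character substitution
#'   (applied to surname, forename, date of birth, NHS number, hospital
#'   number).
#' @param surname_change_rate probability that a female patient's later
#'   records carry a different (married) surname.
#' @param p_sex probability that the sex field is present.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(year_range = c(1920, 2005),
                       records_per_patient = c(1, 5),
                       sources = c(pas = 0.3, lims = 0.3, micro = 0.2,
                                   jonah = 0.1, pashistory = 0.1),
                       missingness = list(
                         pas = c(p_hosp = 0.99, p_nhs = 0.55, p_name = 0.95),
                         lims = c(p_hosp = 0.35, p_nhs = 0.05, p_name = 0.95),
                         micro = c(p_hosp = 0.50, p_nhs = 0.45, p_name = 0.85),
                         jonah = c(p_hosp = 0.999, p_nhs = 0.72, p_name = 0.99),
                         pashistory = c(p_hosp = 0.999, p_nhs = 0.83, p_name = 0.99)
                       ),
                       typo_rate = 0,
                       surname_change_rate = 0.1,
                       p_sex = 0.98) {
  structure(list(year_range = year_range,
                 records_per_patient = records_per_patient,
                 sources = sources,
                 missingness = missingness,
                 typo_rate = typo_rate,
                 surname_change_rate = surname_change_rate,
                 p_sex = p_sex),
            class = "sim_config")
}

#' @rdname sim_config
#' @details `sim_config_consistent()` is the configuration used by the
#'   collision experiments ([evaluate_resolution()],
#'   [evaluate_classifier_sensitivity()]): every record of a patient carries
#'   the full, agreeing identifier set (no missingness, no typos), each
#'   patient yielding 2-5 records. It isolates the behaviour of the
#'   splitting heuristic and the classifier from identifier missingness,
#'   which remains available through the ordinary [sim_config()] defaults.
#' @export
sim_config_consistent <- function(records_per_patient = c(2, 5)) {
  full <- c(p_hosp = 1, p_nhs = 1, p_name = 1)
  sim_config(
    records_per_patient = records_per_patient,
    missingness = list(pas = full, lims = full, micro = full,
                       jonah = full, pashistory = full),
    typo_rate = 0,
    p_sex = 1
  )
}

# Generate n unique NHS numbers with valid Modulus-11 check digits.
.generate_nhs_numbers <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    digits <- matrix(sample(0:9, 9L * need * 2L, replace = TRUE),
                     ncol = 9L)
    sums <- digits %*% (10:2)
    check <- 11L - (sums %% 11L)
    check[check == 11L] <- 0L
    ok <- check != 10L
    vals <- apply(cbind(digits[ok, , drop = FALSE], check[ok]), 1L,
                  paste, collapse = "")
    out <- unique(c(out, vals))
  }
  out[seq_len(n)]
}

#' Generate synthetic patients
#'
#' Each patient carries a true identity (`true_id`), sex, names drawn from
#' bundled pools with Zipf-like frequency skew, a birth date uniform over the
#' configured year range, a unique check-digit-valid NHS number and a unique
#' hospital number. Two patients may well share forename and surname; they
#' never share a unique identifier before error injection.
#'
#' @param n number of patients.
#' @param rng_seed integer seed; fixed seed gives identical output.
#' @param config a [sim_config()].
#' @return data.frame: true_id, forename, surname, sex, birthdate,
#'   nhs_number, hospital_number.
#' @export
generate_patients <- function(n, rng_seed = NULL, config = sim_config()) {
  stopifnot(n >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  forename <- character(n)
  forename[sex == "M"] <- .zipf_sample(FORENAMES_M, sum(sex == "M"))
  forename[sex == "F"] <- .zipf_sample(FORENAMES_F, sum(sex == "F"))
  y0 <- as.integer(as.Date(paste0(config$year_range[1], "-01-01")))
  y1 <- as.integer(as.Date(paste0(config$year_range[2], "-12-31")))
  data.frame(
    true_id = seq_len(n),
    forename = forename,
    surname = .zipf_sample(SURNAMES, n),
    sex = sex,
    birthdate = as.Date(sample(y0:y1, n, replace = TRUE),
                        origin = "1970-01-01"),
    nhs_number = .generate_nhs_numbers(n),
    hospital_number = as.character(sample(100000:9999999, n)),
    stringsAsFactors = FALSE
  )
}

# Introduce one random single-character substitution into a string.
.typo <- function(x) {
  n <- nchar(x)
  if (is.na(x) || n == 0L) return(x)
  i <- sample.int(n, 1L)
  old <- substr(x, i, i)
  repl <- if (grepl("[0-9]", old)) sample(as.character(0:9), 1L)
          else sample(LETTERS, 1L)
  substr(x, i, i) <- repl
  x
}

#' Generate raw records for synthetic patients
#'
#' Each patient yields a configurable number of records spread over the
#' sources; identifiers are dropped per the source's missingness pattern,
#' typos are applied as single-character substitutions at `typo_rate`, and a
#' fraction of female patients changes surname partway through their records
#' (marriage). Output rows are *raw* records — dates as `ddmmyyyy` strings —
#' ready for [clean_records()].
#'
#' @param patients data.frame from [generate_patients()].
#' @param config a [sim_config()].
#' @param rng_seed integer seed.
#' @return list with `records` (raw record data.frame) and `truth`
#'   (data.frame record_id, true_id).
#' @export
generate_records <- function(patients, config = sim_config(), rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- config$records_per_patient
  n_rec <- sample(k[1]:k[2], nrow(patients), replace = TRUE)
  rows <- vector("list", sum(n_rec))
  truth_ids <- integer(sum(n_rec))
  idx <- 0L
  for (p in seq_len(nrow(patients))) {
    pat <- patients[p, ]
    married <- pat$sex == "F" &&
      stats::runif(1) < config$surname_change_rate && n_rec[p] > 1L
    change_at <- if (married) sample(2:n_rec[p], 1L) else Inf
    married_surname <- if (married) .zipf_sample(SURNAMES, 1L) else NA_character_
    srcs <- sample(names(config$sources), n_rec[p], replace = TRUE,
                   prob = config$sources)
    for (r in seq_len(n_rec[p])) {
      mi <- config$missingness[[srcs[r]]]
      has_name <- stats::runif(1) < mi[["p_name"]]
      surname <- if (r >= change_at) married_surname else pat$surname
      rec <- list(
        source = srcs[r],
        surname = if (has_name) surname else NA_character_,
        forename = if (has_name) pat$forename else NA_character_,
        sex = if (stats::runif(1) < config$p_sex) pat$sex else NA_character_,
        birthdate = if (has_name) format(pat$birthdate, "%d%m%Y") else NA_character_,
        deathdate = NA_character_,
        nhs_number = if (stats::runif(1) < mi[["p_nhs"]]) pat$nhs_number else NA_character_,
        hospital_number = if (stats::runif(1) < mi[["p_hosp"]]) pat$hospital_number else NA_character_,
        clinic_code = NA_character_
      )
      if (config$typo_rate > 0) {
        for (f in c("surname", "forename", "birthdate", "nhs_number",
                    "hospital_number")) {
          if (!is.na(rec[[f]]) && stats::runif(1) < config$typo_rate) {
            rec[[f]] <- .typo(rec[[f]])
          }
        }
      }
      idx <- idx + 1L
      rows[[idx]] <- rec
      truth_ids[idx] <- pat$true_id
    }
  }
  records <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  records <- cbind(record_id = sprintf("R%06d", seq_len(nrow(records))),
                   records, stringsAsFactors = FALSE)
  list(records = records,
       truth = data.frame(record_id = records$record_id,
                          true_id = truth_ids, stringsAsFactors = FALSE))
}

#' Generate linked, rule-good synthetic clusters
#'
#' Convenience wrapper for the simulation experiments: generates patients and
#' typo-free records, cleans and links them, and returns clusters that (i)
#' pass the rule-based good screen, (ii) have the requested size range, (iii)
#' optionally carry at least one hospital number, keeping at most one cluster
#' per patient so any two returned clusters belong to distinct people.
#'
#' @param n_clusters how many good clusters to return.
#' @param rng_seed integer seed.
#' @param config a [sim_config()]; `typo_rate` is forced to 0 (good clusters
#'   are consistent by construction).
#' @param min_size,max_size cluster size bounds.
#' @param require_hospital require a non-null hospital number (needed by the
#'   collision-injection experiment).
#' @return list of cleaned cluster data.frames, each with a `true_id`
#'   attribute.
#' @export
generate_good_clusters <- function(n_clusters, rng_seed = NULL,
                                   config = sim_config(records_per_patient = c(2, 5)),
                                   min_size = 2L, max_size = 5L,
                                   require_hospital = TRUE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  config$typo_rate <- 0
  out <- list()
  guard <- 0L
  while (length(out) < n_clusters && guard < 50L) {
    guard <- guard + 1L
    need <- n_clusters - length(out)
    pats <- generate_patients(ceiling(need * 1.5), config = config)
    gen <- generate_records(pats, config = config)
    # keep record ids unique across generation batches
    gen$records$record_id <- paste0("b", guard, ".", gen$records$record_id)
    gen$truth$record_id <- gen$records$record_id
    cleaned <- add_composite_id(clean_records(gen$records))
    lr <- link_records(cleaned)
    truth <- gen$truth$true_id[match(cleaned$record_id, gen$truth$record_id)]
    seen_patients <- integer(0)
    for (ix in cluster_index(lr)) {
      if (length(ix) < min_size || length(ix) > max_size) next
      cl <- cleaned[ix, , drop = FALSE]
      tid <- unique(truth[ix])
      if (length(tid) != 1L || tid %in% seen_patients) next
      if (require_hospital && all(is.na(cl$hospital_number))) next
      if (rule_classify(cl)$label != "good") next
      seen_patients <- c(seen_patients, tid)
      attr(cl, "true_id") <- tid
      out[[length(out) + 1L]] <- cl
      if (length(out) >= n_clusters) break
    }
  }
  if (length(out) < n_clusters) {
    stop("could not generate enough good clusters; relax the filters")
  }
  out
}

#' Inject a single-identifier collision between two clusters
#'
#' Emulates the dominant real-world mislinkage mechanism: one randomly
#' selected hospital-number instance in cluster `a` is overwritten with the
#' maximal hospital number of cluster `b`, so the two otherwise-distinct
#' people now share one (forged) identifier value.
#'
#' @param cluster_a,cluster_b cleaned cluster data.frames, each with at least
#'   one non-null hospital number.
#' @param rng_seed optional integer seed.
#' @return list: `records` (the merged record set), `corrupted` (one-row
#'   data.frame record_id/field/value identifying the forged instance).
#' @export
inject_hospital_collision <- function(cluster_a, cluster_b, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  a_rows <- which(!is.na(cluster_a$hospital_number))
  b_vals <- na.omit(cluster_b$hospital_number)
  if (!length(a_rows) || !length(b_vals)) {
    stop("both clusters need at least one non-null hospital number")
  }
  nums <- suppressWarnings(as.numeric(b_vals))
  target <- if (!anyNA(nums)) b_vals[which.max(nums)] else max(b_vals)
  i <- if (length(a_rows) > 1L) a_rows[sample.int(length(a_rows), 1L)] else a_rows
  cluster_a$hospital_number[i] <- target
  list(
    records = rbind(cluster_a, cluster_b),
    corrupted = data.frame(record_id = cluster_a$record_id[i],
                           field = "hospital_number", value = target,
                           stringsAsFactors = FALSE)
  )
}

#' Splitting-recovery experiment
#'
#' End-to-end trial of the splitting heuristic on simulated collisions: good
#' clusters are paired, a hospital-number collision is injected into each
#' pair, the merged cluster is split by single-identifier deletion, and a
#' trial succeeds when the identifier instance chosen for deletion is exactly
#' the forged one.
#'
#' @param n_trials number of collision trials.
#' @param rng_seed integer seed governing generation, injection and
#'   tie-breaks.
#' @param config a [sim_config()] for the good-cluster generator.
#' @return list: `fraction` (successes / trials; `NA` for 0 trials) and
#'   `trials` (per-trial log with the injected and deleted instances).
#' @export
evaluate_resolution <- function(n_trials, rng_seed = 1L,
                                config = sim_config_consistent()) {
  empty <- data.frame(trial = integer(), success = logical(),
                      injected_record = character(), deleted_record = character(),
                      deleted_field = character(), n_parts = integer(),
                      tie_count = integer(), stringsAsFactors = FALSE)
  if (n_trials < 1L) return(list(fraction = NA_real_, trials = empty))
  set.seed(rng_seed)
  good <- generate_good_clusters(2L * n_trials, config = config)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    a <- good[[2L * t - 1L]]
    b <- good[[2L * t]]
    inj <- inject_hospital_collision(a, b)
    outcome <- split_cluster(inj$records)
    deleted <- outcome$deleted
    success <- !is.null(deleted) &&
      deleted$record_id == inj$corrupted$record_id &&
      deleted$field == inj$corrupted$field
    rows[[t]] <- data.frame(
      trial = t,
      success = success,
      injected_record = as.character(inj$corrupted$record_id),
      deleted_record = if (is.null(deleted)) NA_character_ else as.character(deleted$record_id),
      deleted_field = if (is.null(deleted)) NA_character_ else deleted$field,
      n_parts = outcome$n_parts,
      tie_count = outcome$tie_count,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  list(fraction = mean(trials$success), trials = trials)
}

#' Classifier-sensitivity experiment
#'
#' Simulates bad clusters by randomly pairing good clusters of distinct
#' synthetic patients, scores each combined cluster with the collision
#' classifier, and reports the detected fraction (score above the cutoff).
#'
#' @param n_clusters number of good clusters to generate (paired into
#'   `floor(n/2)` bad clusters).
#' @param rng_seed integer seed.
#' @param config a [sim_config()].
#' @param models classifier models (see [published_models()]).
#' @return list: `fraction` detected, `scores` (per-pair data.frame).
#' @export
evaluate_classifier_sensitivity <- function(n_clusters = 1000L, rng_seed = 1L,
                                            config = sim_config_consistent(),
                                            models = published_models()) {
  set.seed(rng_seed)
  good <- generate_good_clusters(n_clusters, config = config,
                                 require_hospital = FALSE)
  bad <- simulate_bad_by_combination(good)
  scores <- vapply(bad, function(cl) {
    score_cluster(extract_features(cl), models)$score
  }, numeric(1))
  list(fraction = mean(scores > models$no_female$cutoff),
       scores = data.frame(pair = seq_along(scores), score = scores))
}
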