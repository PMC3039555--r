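FEATURE_FIELDS <- c("dob_day", "dob_month", "dob_year", "forename",
                    "surname", "hospital_number", "sex")

#' Is a cluster complex?
#'
#' A cluster is complex when it shows any variation in a linkage identifier:
#' more than one distinct non-null value of the NHS number, hospital number
#' or composite identifier. Only complex clusters can harbour an identity
#' collision, so only they are scored by the classifier.
#'
#' @param cluster data.frame of one cluster's records.
#' @param identifier_fields identifier columns inspected.
#' @return logical flag.
#' @export
is_complex <- function(cluster, identifier_fields = LINKAGE_FIELDS) {
  any(vapply(identifier_fields, function(f) {
    length(unique(na.omit(as.character(cluster[[f]])))) > 1L
  }, logical(1)))
}

#' Rule-based screen for single-person clusters
#'
#' A cluster is provisionally labelled `good` (one person, with high
#' sensitivity) when it carries exactly one distinct non-null value in *both*
#' fields of any of these pairs:
#' one NHS number and one hospital number; one NHS number and one
#' name/date-of-birth composite; one hospital number and one composite.
#' Anything else is `uncertain` — not necessarily bad, just not provably
#' single-person by rule.
#'
#' @param cluster data.frame of one cluster's records.
#' @return list with `label` (`"good"` or `"uncertain"`) and `matched_rule`
#'   (`NA` or one of `"nhs+hospital"`, `"nhs+composite"`,
#'   `"hospital+composite"`).
#' @export
rule_classify <- function(cluster) {
  rules <- list(
    "nhs+hospital" = c("nhs_number", "hospital_number"),
    "nhs+composite" = c("nhs_number", "composite_id"),
    "hospital+composite" = c("hospital_number", "composite_id")
  )
  for (nm in names(rules)) {
    ok <- vapply(rules[[nm]], function(f) {
      length(unique(na.omit(as.character(cluster[[f]])))) == 1L
    }, logical(1))
    if (all(ok)) return(list(label = "good", matched_rule = nm))
  }
  list(label = "uncertain", matched_rule = NA_character_)
}

# Maximum pairwise distance over the distinct non-null values of a field.
# Fewer than two distinct values (including all-null) contributes 0:
# missingness must not mimic conflict.
.max_pair_dist <- function(values, dist_fun) {
  u <- unique(na.omit(as.character(values)))
  if (length(u) < 2L) return(0)
  pairs <- utils::combn(u, 2L)
  max(dist_fun(pairs[1L, ], pairs[2L, ]))
}

#' Extract collision features from a cluster
#'
#' For each field, the maximum distance over all pairs of records with both
#' values non-null: Levenshtein on zero-padded date-of-birth day, month and
#' 4-digit year components and on the single-character sex code; Jaro-Winkler
#' *dissimilarity* (1 - similarity) on forename, surname and hospital number.
#' Singleton clusters and fields with fewer than two non-null values score 0.
#' `any_female` is true when any record's sex is F and selects the classifier
#' variant without a surname term (surnames change on marriage).
#'
#' @param cluster data.frame of one cluster's records.
#' @param identifier_fields identifier columns used for the `is_complex`
#'   flag.
#' @return one-row data.frame: the seven feature columns, `any_female`,
#'   `is_complex`, `n_records`.
#' @export
extract_features <- function(cluster, identifier_fields = LINKAGE_FIELDS) {
  bd <- cluster$birthdate
  data.frame(
    dob_day = .max_pair_dist(format(bd, "%d"), levenshtein),
    dob_month = .max_pair_dist(format(bd, "%m"), levenshtein),
    dob_year = .max_pair_dist(format(bd, "%Y"), levenshtein),
    forename = .max_pair_dist(cluster$forename, jw_distance),
    surname = .max_pair_dist(cluster$surname, jw_distance),
    hospital_number = .max_pair_dist(cluster$hospital_number, jw_distance),
    sex = .max_pair_dist(cluster$sex, levenshtein),
    any_female = any(!is.na(cluster$sex) & cluster$sex == "F"),
    is_complex = is_complex(cluster, identifier_fields),
    n_records = nrow(cluster)
  )
}

#' The published collision classifier
#'
#' Logistic model scoring a cluster's odds of being bad (containing more than
#' one person) from its maximal within-cluster field distances. The default
#' coefficient set is the published one (intercept -3.33; date-of-birth day
#' 0.25, month 0.43, year 5.12; forename 2.45; hospital number -0.56; sex
#' 0.80; no surname term) with cutoff -1.5: a cluster is labelled bad when
#' its linear score strictly exceeds the cutoff. Two model slots are kept —
#' one applied to clusters containing a female record (never a surname term,
#' because surnames legitimately change on marriage) and one for clusters
#' without females — sharing the published coefficients by default.
#'
#' @param intercept model constant.
#' @param coefficients named numeric vector of feature coefficients.
#' @param cutoff score above which a cluster is labelled bad.
#' @param applies_when `"any_female"` or `"no_female"`.
#' @return object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coefficients, cutoff = -1.5,
                           applies_when = c("any_female", "no_female")) {
  stopifnot(is.numeric(intercept), is.numeric(coefficients),
            !is.null(names(coefficients)))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 cutoff = cutoff,
                 applies_when = match.arg(applies_when)),
            class = "logistic_model")
}

#' @rdname logistic_model
#' @param cutoff score cutoff shared by both models.
#' @export
published_models <- function(cutoff = -1.5) {
  coefs <- c(dob_day = 0.25, dob_month = 0.43, dob_year = 5.12,
             forename = 2.45, hospital_number = -0.56, sex = 0.80)
  list(
    any_female = logistic_model(-3.33, coefs, cutoff, "any_female"),
    no_female = logistic_model(-3.33, coefs, cutoff, "no_female")
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic collision model (", x$applies_when, "), cutoff ", x$cutoff,
      "\n  intercept: ", x$intercept, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Score a cluster's features against the collision classifier
#'
#' The model is selected by the cluster's `any_female` flag; the score is the
#' linear predictor `intercept + sum(coef * feature)`; the label is `bad`
#' when the score strictly exceeds the cutoff (a score exactly at the cutoff
#' is good).
#'
#' @param features one-row data.frame from [extract_features()].
#' @param models list with elements `any_female` and `no_female`
#'   (see [published_models()]).
#' @return list with `score` and `label` (`"good"`/`"bad"`).
#' @export
score_cluster <- function(features, models = published_models()) {
  model <- if (isTRUE(features$any_female[1L])) models$any_female else models$no_female
  needed <- names(model$coefficients)
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("features missing for model coefficient(s): ",
         paste(missing, collapse = ", "))
  }
  x <- as.numeric(features[1L, needed])
  score <- model$intercept + sum(model$coefficients * x)
  list(score = score, label = if (score > model$cutoff) "bad" else "good")
}

#' Feature-extract and score every cluster of a linkage result
#'
#' Clusters without identifier variation (`is_complex` false, including all
#' singletons) cannot be collisions and are labelled good without scoring
#' (score `NA`).
#'
#' @param result a `linkage_result`.
#' @param models classifier models (see [published_models()]).
#' @return data.frame with one row per cluster: `cluster_id`, `n_records`,
#'   `is_complex`, the feature columns, `any_female`, `score`, `label`.
#' @export
classify_clusters <- function(result, models = published_models()) {
  idx <- cluster_index(result)
  rows <- lapply(names(idx), function(cid) {
    cl <- result$records[idx[[cid]], , drop = FALSE]
    feats <- extract_features(cl, result$identifier_fields)
    if (feats$is_complex) {
      sc <- score_cluster(feats, models)
      feats$score <- sc$score
      feats$label <- sc$label
    } else {
      feats$score <- NA_real_
      feats$label <- "good"
    }
    cbind(data.frame(cluster_id = as.integer(cid)), feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate bad clusters by random combination of good clusters
#'
#' Pairs distinct good clusters uniformly at random (disjointly) and returns
#' the unions, each of which by construction contains records of more than
#' one person. These simulated collisions supply the `bad` class when fitting
#' or validating the classifier.
#'
#' @param good_clusters list of data.frames, one per good cluster.
#' @param rng_seed integer seed making the pairing reproducible.
#' @return list of combined data.frames (length `floor(n/2)`), each with
#'   attribute `"pair"` giving the two source indices; empty list when fewer
#'   than two inputs.
#' @export
simulate_bad_by_combination <- function(good_clusters, rng_seed = NULL) {
  n <- length(good_clusters)
  if (n < 2L) return(list())
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perm <- sample.int(n)
  n_pairs <- n %/% 2L
  lapply(seq_len(n_pairs), function(k) {
    i <- perm[2L * k - 1L]
    j <- perm[2L * k]
    out <- rbind(good_clusters[[i]], good_clusters[[j]])
    attr(out, "pair") <- c(i, j)
    out
  })
}

#' Fit a collision classifier by backward-AIC logistic regression
#'
#' Fits a maximum-likelihood logistic regression of bad-cluster status on the
#' supplied features, then removes terms by backward stepwise elimination
#' under AIC ([MASS::stepAIC()]). Under complete or quasi-complete separation
#' the fit is reported with a warning and coefficients clipped to
#' `± clip_bound`.
#'
#' @param features data.frame of feature columns.
#' @param labels logical (or 0/1) vector: `TRUE` = bad.
#' @param include_fields feature columns offered to the model.
#' @param cutoff score cutoff stored in the returned model.
#' @param applies_when which cluster stratum the model is meant for.
#' @param clip_bound absolute coefficient bound applied under separation.
#' @return a [logistic_model()] with attributes `"fit"` (the glm) and
#'   `"dropped"` (terms eliminated by AIC).
#' @export
fit_collision_model <- function(features, labels,
                                include_fields = setdiff(FEATURE_FIELDS, "surname"),
                                cutoff = -1.5,
                                applies_when = c("any_female", "no_female"),
                                clip_bound = 15) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(features))
  if (!any(labels) || all(labels)) stop("both labels must be present")
  if (nrow(features) <= length(include_fields) + 1L) {
    stop("need more observations than model terms")
  }
  dat <- features[, include_fields, drop = FALSE]
  dat$.bad <- labels
  warned <- FALSE
  full <- withCallingHandlers(
    stats::glm(.bad ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  reduced <- MASS::stepAIC(full, direction = "backward", trace = 0)
  cf <- stats::coef(reduced)
  intercept <- unname(cf["(Intercept)"])
  coefs <- cf[setdiff(names(cf), "(Intercept)")]
  separated <- warned || !reduced$converged || any(abs(cf) > clip_bound)
  if (separated) {
    warning("possible separation: coefficients clipped to +/-", clip_bound)
    intercept <- max(min(intercept, clip_bound), -clip_bound)
    coefs <- pmax(pmin(coefs, clip_bound), -clip_bound)
  }
  if (!length(coefs)) coefs <- stats::setNames(numeric(0), character(0))
  model <- logistic_model(intercept, coefs, cutoff, match.arg(applies_when))
  attr(model, "fit") <- reduced
  attr(model, "dropped") <- setdiff(include_fields, names(coefs))
  model
}
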