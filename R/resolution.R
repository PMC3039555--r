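#' Count invariant identifiers in a cluster
#'
#' An identifier field is invariant within a cluster when its non-null values
#' have cardinality exactly 1. The splitting heuristic maximises the increase
#' in this count, summed over the clusters a split produces: a correct split
#' separates two people whose identifiers then stop conflicting.
#'
#' @param cluster data.frame of one cluster's records.
#' @param identifier_fields identifier columns counted.
#' @return integer count in `0..length(identifier_fields)`.
#' @export
invariant_count <- function(cluster, identifier_fields = LINKAGE_FIELDS) {
  sum(vapply(identifier_fields, function(f) {
    length(unique(na.omit(as.character(cluster[[f]])))) == 1L
  }, logical(1)))
}

#' Enumerate candidate erroneous identifiers in a cluster
#'
#' Only identifier instances that form edges can hold a cluster together, so
#' the candidates for deletion are exactly the (record, field, value) triples
#' whose value occurs in at least two records of the cluster. They are
#' enumerated deterministically (field order, then row order).
#'
#' @param cluster data.frame of one cluster's records.
#' @param identifier_fields identifier columns searched.
#' @return data.frame: `row` (index into `cluster`), `record_id`, `field`,
#'   `value`; zero rows for singleton clusters.
#' @export
candidate_identifiers <- function(cluster, identifier_fields = LINKAGE_FIELDS) {
  empty <- data.frame(row = integer(), record_id = cluster$record_id[0],
                      field = character(), value = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cluster) < 2L) return(empty)
  out <- lapply(identifier_fields, function(f) {
    v <- as.character(cluster[[f]])
    tab <- table(v[!is.na(v)])
    shared <- names(tab)[tab >= 2L]
    rows <- which(!is.na(v) & v %in% shared)
    if (!length(rows)) return(NULL)
    data.frame(row = rows, record_id = cluster$record_id[rows],
               field = f, value = v[rows], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Split a bad cluster by single-identifier deletion
#'
#' Generates one variant per candidate identifier instance, nulling just that
#' one field of that one record, re-links the variant, and keeps the variant
#' that divides the cluster while maximising the gain in invariant
#' identifiers. Ties are broken uniformly at random (seeded via `rng_seed`,
#' or the current RNG stream when `NULL`). If no deletion both divides the
#' cluster and improves quality, no split is performed.
#'
#' Deletion granularity is a single identifier *instance*: the typical
#' collision is one record carrying another person's number, so only that
#' occurrence is wrong. `value_level = TRUE` instead nulls every occurrence
#' of the candidate value.
#'
#' @param cluster data.frame of one (flagged bad) cluster's records.
#' @param identifier_fields identifier columns used for re-linkage and
#'   quality.
#' @param rng_seed optional integer seed for the tie-break.
#' @param value_level null all occurrences of the value rather than one
#'   instance.
#' @return list of class `split_outcome`: `deleted` (one-row data.frame
#'   record_id/field/value, or `NULL`), `clusters` (list of record-id
#'   vectors partitioning the cluster), `quality_gain`, `n_parts`,
#'   `tie_count`, `records` (the cluster with the deletion applied).
#' @export
split_cluster <- function(cluster, identifier_fields = LINKAGE_FIELDS,
                          rng_seed = NULL, value_level = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  no_split <- list(deleted = NULL,
                   clusters = list(cluster$record_id),
                   quality_gain = 0L, n_parts = 1L, tie_count = 0L,
                   records = cluster)
  class(no_split) <- "split_outcome"
  cands <- candidate_identifiers(cluster, identifier_fields)
  if (!nrow(cands)) return(no_split)

  base_q <- invariant_count(cluster, identifier_fields)
  gains <- rep(NA_real_, nrow(cands))
  variants <- vector("list", nrow(cands))
  for (k in seq_len(nrow(cands))) {
    rec <- cluster
    if (value_level) {
      v <- as.character(rec[[cands$field[k]]])
      rec[[cands$field[k]]][!is.na(v) & v == cands$value[k]] <- NA
    } else {
      rec[[cands$field[k]]][cands$row[k]] <- NA
    }
    lr <- link_records(rec, identifier_fields)
    parts <- split(seq_len(nrow(rec)), lr$cluster_id)
    if (length(parts) < 2L) next
    q <- sum(vapply(parts, function(ix) {
      invariant_count(rec[ix, , drop = FALSE], identifier_fields)
    }, integer(1)))
    gains[k] <- q - base_q
    variants[[k]] <- list(rec = rec, parts = parts)
  }
  ok <- which(!is.na(gains) & gains > 0)
  if (!length(ok)) return(no_split)
  best_gain <- max(gains[ok])
  best <- ok[gains[ok] == best_gain]
  tie_count <- length(best)
  chosen <- if (tie_count > 1L) best[sample.int(tie_count, 1L)] else best
  var <- variants[[chosen]]
  out <- list(
    deleted = cands[chosen, c("record_id", "field", "value"), drop = FALSE],
    clusters = lapply(var$parts, function(ix) var$rec$record_id[ix]),
    quality_gain = as.integer(best_gain),
    n_parts = length(var$parts),
    tie_count = tie_count,
    records = var$rec
  )
  class(out) <- "split_outcome"
  out
}

#' Detect and resolve identity collisions across a whole linkage
#'
#' Scores every complex cluster with the collision classifier, splits the
#' clusters labelled bad by single-identifier deletion, and re-scores the
#' resulting clusters. With `max_passes = 1` (default) splitting happens
#' once and the final classification reports how many clusters remain bad;
#' larger values repeat the split/re-score cycle.
#'
#' Splitting only ever refines the partition (a deletion cannot merge
#' clusters) and never loses records. New cluster ids follow the minimum
#' start-id rule. Deleted identifier instances are nulled in the returned
#' records.
#'
#' @param result a `linkage_result`.
#' @param models classifier models (see [published_models()]).
#' @param rng_seed integer seed for split tie-breaks.
#' @param max_passes number of split passes.
#' @return list of class `resolution_result`: `result` (the refined
#'   `linkage_result`), `splits` (data.frame log: cluster_id, record_id,
#'   field, value, quality_gain, n_parts, tie_count), `n_complex`,
#'   `n_flagged_bad`, `n_splits`, `n_bad_after`, `classification` (final
#'   [classify_clusters()] table).
#' @export
resolve_all <- function(result, models = published_models(), rng_seed = 1L,
                        max_passes = 1L) {
  stopifnot(inherits(result, "linkage_result"))
  set.seed(rng_seed)
  records <- result$records
  start_id <- result$start_id
  fields <- result$identifier_fields
  cluster_id <- result$cluster_id

  splits_log <- list()
  n_complex <- NA_integer_
  n_flagged <- 0L
  n_splits <- 0L

  for (pass in seq_len(max_passes)) {
    res <- .linkage_result(records, cluster_id, start_id, result$iterations, fields)
    cls <- classify_clusters(res, models)
    if (pass == 1L) n_complex <- sum(cls$is_complex)
    bad_ids <- cls$cluster_id[cls$label == "bad"]
    n_flagged <- n_flagged + length(bad_ids)
    if (!length(bad_ids)) break
    did_split <- FALSE
    for (cid in bad_ids) {
      rows <- which(cluster_id == cid)
      outcome <- split_cluster(records[rows, , drop = FALSE], fields)
      if (is.null(outcome$deleted)) next
      did_split <- TRUE
      n_splits <- n_splits + 1L
      records[rows, ] <- outcome$records
      # new ids: minimum start id within each part
      for (part in outcome$clusters) {
        part_rows <- rows[match(part, records$record_id[rows])]
        cluster_id[part_rows] <- min(start_id[part_rows])
      }
      splits_log[[length(splits_log) + 1L]] <- data.frame(
        cluster_id = cid,
        record_id = outcome$deleted$record_id,
        field = outcome$deleted$field,
        value = outcome$deleted$value,
        quality_gain = outcome$quality_gain,
        n_parts = outcome$n_parts,
        tie_count = outcome$tie_count,
        stringsAsFactors = FALSE
      )
    }
    if (!did_split) break
  }

  final <- .linkage_result(records, cluster_id, start_id, result$iterations, fields)
  final_cls <- classify_clusters(final, models)
  splits <- if (length(splits_log)) do.call(rbind, splits_log) else
    data.frame(cluster_id = integer(), record_id = records$record_id[0],
               field = character(), value = character(),
               quality_gain = integer(), n_parts = integer(),
               tie_count = integer(), stringsAsFactors = FALSE)
  structure(list(
    result = final,
    splits = splits,
    n_complex = n_complex,
    n_flagged_bad = n_flagged,
    n_splits = n_splits,
    n_bad_after = sum(final_cls$label == "bad"),
    classification = final_cls
  ), class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("Collision resolution:\n")
  cat("  clusters:", length(unique(x$result$cluster_id)),
      " complex:", x$n_complex,
      " flagged bad:", x$n_flagged_bad,
      " splits:", x$n_splits,
      " bad after re-score:", x$n_bad_after, "\n")
  invisible(x)
}
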