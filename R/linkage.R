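#' Exact-match record linkage by iterated set union
#'
#' Records are joined whenever they share a non-null value of any linkage
#' identifier (NHS number, hospital number, composite identifier by default).
#' The clusters are the connected components of the identifier-sharing graph:
#' vertices are records, with an edge between two records sharing any
#' identifier value. The result is deterministic and independent of record
#' and field order. Null values never link.
#'
#' `single_pass_join()` performs one join on a single identifier field:
#' records sharing a non-null value of that field (or already co-clustered)
#' are merged, and a merged cluster adopts the minimum incoming cluster id.
#' `link_records()` iterates joins over all fields to the fixed point.
#'
#' Records with every linkage identifier null cannot link to anything; they
#' are kept as singleton clusters and listed in `$unidentified` so callers can
#' report them separately.
#'
#' @param records cleaned record table containing `record_id` and the
#'   identifier columns.
#' @param identifier_fields character vector of identifier column names.
#' @param identifier_field a single identifier column name.
#' @param start_ids integer start cluster ids (default `seq_len(nrow)`); a
#'   cluster's id is the minimum start id among its members.
#' @param dedupe collapse rows with identical identifier combinations before
#'   linking (they are re-expanded in the assignment); linkage is unaffected,
#'   only the work is reduced.
#' @return an object of class `linkage_result`: a list with `records`,
#'   `cluster_id` (per row), `start_id`, `assignment` (data.frame record_id,
#'   cluster_id), `iterations`, `n`, `m`, `identifier_fields`,
#'   `unidentified` (record ids with all identifiers null).
#' @examples
#' r <- demo_records()
#' link_records(r)$assignment
#' @export
link_records <- function(records, identifier_fields = LINKAGE_FIELDS,
                         start_ids = NULL, dedupe = FALSE) {
  .check_fields(records, identifier_fields)
  if (length(identifier_fields) == 0L) stop("identifier_fields must be non-empty")
  n <- nrow(records)
  if (is.null(start_ids)) start_ids <- seq_len(n)
  stopifnot(length(start_ids) == n)

  if (dedupe && n > 0L) {
    key <- do.call(paste, c(records[identifier_fields], sep = "\r"))
    first <- !duplicated(key)
    map <- match(key, key[first])  # row -> representative row index
    sub <- records[first, , drop = FALSE]
    sub_start <- tapply(start_ids, map, min)[as.character(seq_len(sum(first)))]
    linked <- .link_ids(sub, identifier_fields, as.integer(sub_start))
    ids <- linked$ids[map]
    iterations <- linked$iterations
  } else {
    linked <- .link_ids(records, identifier_fields, start_ids)
    ids <- linked$ids
    iterations <- linked$iterations
  }

  .linkage_result(records, ids, start_ids, iterations, identifier_fields)
}

#' @rdname link_records
#' @export
single_pass_join <- function(records, identifier_field, start_ids = NULL) {
  .check_fields(records, identifier_field)
  stopifnot(length(identifier_field) == 1L)
  n <- nrow(records)
  if (is.null(start_ids)) start_ids <- seq_len(n)
  ids <- .join_once(records, identifier_field, start_ids)
  .linkage_result(records, ids, start_ids, 1L, identifier_field)
}

#' Add records incrementally to an existing linkage
#'
#' Equivalent to re-linking the union of old and new records: new records may
#' join existing clusters or bridge them, in which case the merged cluster
#' takes the minimum start id.
#'
#' @param result a `linkage_result`.
#' @param new_records cleaned records with the same identifier columns;
#'   `record_id` values must not collide with existing ones.
#' @return a new `linkage_result` over the combined records.
#' @export
incremental_add <- function(result, new_records) {
  stopifnot(inherits(result, "linkage_result"))
  .check_fields(new_records, result$identifier_fields)
  if (any(new_records$record_id %in% result$records$record_id)) {
    stop("duplicate record_id in new_records")
  }
  common <- intersect(names(result$records), names(new_records))
  combined <- rbind(result$records[common], new_records[common])
  n_old <- nrow(result$records)
  start <- c(result$start_id, n_old + seq_len(nrow(new_records)))
  # seed with the existing partition so old unions are already in place
  seed <- c(result$cluster_id, n_old + seq_len(nrow(new_records)))
  linked <- .link_ids(combined, result$identifier_fields, seed)
  # cluster id must be min *start* id of members, not min seeded id
  ids <- .relabel_min(linked$ids, start)
  .linkage_result(combined, ids, start, linked$iterations,
                  result$identifier_fields)
}

#' Extract the member rows of one cluster
#'
#' @param result a `linkage_result`.
#' @param cluster_id a cluster id present in the result.
#' @return data.frame of the cluster's records.
#' @export
cluster_records <- function(result, cluster_id) {
  result$records[result$cluster_id == cluster_id, , drop = FALSE]
}

#' List clusters as row-index groups
#'
#' @param result a `linkage_result`.
#' @return named list mapping cluster id to integer row indices.
#' @export
cluster_index <- function(result) {
  split(seq_len(result$n), result$cluster_id)
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Linkage of", x$n, "records on", x$m, "identifier field(s):",
      paste(x$identifier_fields, collapse = ", "), "\n")
  cat("  clusters:", length(unique(x$cluster_id)),
      " iterations:", x$iterations,
      " unidentified:", length(x$unidentified), "\n")
  invisible(x)
}

# ---- internals -------------------------------------------------------------

.check_fields <- function(records, fields) {
  stopifnot(is.data.frame(records), "record_id" %in% names(records))
  missing <- setdiff(fields, names(records))
  if (length(missing)) {
    stop("unknown identifier field(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Union-find connected components over the given groups of row indices.
# Returns a representative row index per row.
.uf_components <- function(n, groups) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (g in groups) {
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# One join on one field: merge rows sharing a non-null value or already
# sharing a cluster id; each component takes its minimum incoming id.
.join_once <- function(records, field, ids) {
  n <- nrow(records)
  if (n == 0L) return(ids)
  v <- as.character(records[[field]])
  keep <- !is.na(v)
  groups <- c(
    split(seq_len(n)[keep], v[keep]),
    split(seq_len(n), ids)
  )
  comp <- .uf_components(n, groups)
  .relabel_min(comp, ids)
}

# Relabel components by the minimum of `ids` within each component.
.relabel_min <- function(comp, ids) {
  mins <- tapply(ids, comp, min)
  as.vector(mins[as.character(comp)])
}

# Iterate single joins over all fields until the partition is stable.
.link_ids <- function(records, fields, ids) {
  iterations <- 0L
  repeat {
    prev <- ids
    for (f in fields) ids <- .join_once(records, f, ids)
    iterations <- iterations + 1L
    if (identical(ids, prev)) break
  }
  list(ids = ids, iterations = iterations)
}

.linkage_result <- function(records, ids, start_ids, iterations, fields) {
  ids <- as.integer(ids)
  all_null <- if (nrow(records) == 0L) logical(0) else
    Reduce(`&`, lapply(fields, function(f) is.na(records[[f]])))
  structure(list(
    records = records,
    cluster_id = ids,
    start_id = as.integer(start_ids),
    assignment = data.frame(record_id = records$record_id, cluster_id = ids,
                            stringsAsFactors = FALSE),
    iterations = max(iterations, 1L),
    n = nrow(records),
    m = length(fields),
    identifier_fields = fields,
    unidentified = records$record_id[all_null]
  ), class = "linkage_result")
}
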