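FUZZY_FIELDS <- c("surname", "forename", "birthdate", "hospital_number",
                  "nhs_number")

# Distinct trigrams (3-consecutive-character substrings) of one string;
# values shorter than three characters contribute themselves as one token.
.trigrams <- function(x) {
  if (is.na(x)) return(character(0))
  n <- nchar(x)
  if (n < 3L) return(x)
  unique(substring(x, 1:(n - 2L), 3:n))
}

# Pooled distinct trigrams of one record over the indexed fields; dates are
# tokenised in their compact ddmmyyyy entry form.
.record_trigrams <- function(record, fields) {
  vals <- unlist(lapply(fields, function(f) {
    v <- record[[f]]
    if (inherits(v, "Date")) format(v, "%d%m%Y") else as.character(v)
  }))
  unique(unlist(lapply(vals, .trigrams)))
}

#' Build a trigram index over cleaned records
#'
#' Indexes every distinct trigram of surname, forename, date of birth (as its
#' compact `ddmmyyyy` string), hospital number and NHS number. The index
#' drives a fuzzy candidate search for records that look like a query despite
#' typos — used for sensitivity auditing, not for automatic merging.
#'
#' @param records cleaned record table.
#' @param fields columns to index.
#' @return object of class `trigram_index`: `postings` (trigram -> integer
#'   row vector), `record_ids`, `fields`.
#' @export
build_index <- function(records, fields = FUZZY_FIELDS) {
  n <- nrow(records)
  per_record <- lapply(seq_len(n), function(i) {
    .record_trigrams(records[i, , drop = FALSE], fields)
  })
  tg <- unlist(per_record)
  rows <- rep.int(seq_len(n), lengths(per_record))
  structure(list(
    postings = split(rows, tg),
    record_ids = records$record_id,
    fields = fields
  ), class = "trigram_index")
}

#' Rank fuzzy-match candidates for a query record
#'
#' Candidates are ranked by the number of distinct trigrams they share with
#' the query, pooled across all indexed fields, descending; ties are broken
#' by ascending record id. A record with the query's own `record_id` is
#' excluded.
#'
#' @param index a `trigram_index`.
#' @param query_record one-row data.frame (or list) with the indexed fields.
#' @param k maximum number of candidates returned.
#' @return data.frame: rank, record_id, shared_trigrams; zero rows when
#'   nothing is shared.
#' @export
query_top_k <- function(index, query_record, k = 10L) {
  q <- .record_trigrams(query_record, index$fields)
  empty <- data.frame(rank = integer(), record_id = index$record_ids[0],
                      shared_trigrams = integer(), stringsAsFactors = FALSE)
  if (!length(q)) return(empty)
  hits <- unlist(index$postings[intersect(q, names(index$postings))],
                 use.names = FALSE)
  if (!length(hits)) return(empty)
  counts <- table(hits)
  rows <- as.integer(names(counts))
  shared <- as.integer(counts)
  ids <- index$record_ids[rows]
  if (!is.null(query_record$record_id)) {
    keep <- ids != query_record$record_id
    ids <- ids[keep]
    shared <- shared[keep]
  }
  if (!length(ids)) return(empty)
  ord <- order(-shared, ids)
  top <- utils::head(ord, k)
  data.frame(rank = seq_along(top), record_id = ids[top],
             shared_trigrams = shared[top], stringsAsFactors = FALSE)
}

#' Records with identical cleaned surname and forename
#'
#' The exact-name companion to the trigram search: all records whose cleaned
#' surname and forename equal the query's. Returns an empty set when the
#' query lacks either name.
#'
#' @param records cleaned record table.
#' @param query_record one-row data.frame (or list) with `surname` and
#'   `forename`.
#' @return vector of record ids.
#' @export
exact_name_candidates <- function(records, query_record) {
  s <- query_record$surname
  f <- query_record$forename
  if (is.null(s) || is.null(f) || is.na(s) || is.na(f)) {
    return(records$record_id[0])
  }
  hit <- !is.na(records$surname) & !is.na(records$forename) &
    records$surname == s & records$forename == f
  records$record_id[hit]
}
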