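# Independent oracles used across the suite.

# Brute-force connected components over the pairwise identifier-sharing
# relation, via igraph: O(n^2) pair enumeration, no union-find.
oracle_partition <- function(records, fields) {
  n <- nrow(records)
  edges <- integer(0)
  for (f in fields) {
    v <- as.character(records[[f]])
    for (i in seq_len(n - 1L)) {
      if (is.na(v[i])) next
      hits <- which(!is.na(v[(i + 1L):n]) & v[(i + 1L):n] == v[i]) + i
      if (length(hits)) edges <- c(edges, rbind(i, hits))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Two cluster labellings describe the same partition?
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# Brute-force shared-trigram counts between a query and every record.
oracle_shared_trigrams <- function(records, query, fields) {
  tri <- function(x) {
    if (is.na(x)) return(character(0))
    n <- nchar(x)
    if (n < 3L) return(x)
    unique(substring(x, 1:(n - 2L), 3:n))
  }
  rec_tri <- function(row) {
    vals <- unlist(lapply(fields, function(f) {
      v <- row[[f]]
      if (inherits(v, "Date")) format(v, "%d%m%Y") else as.character(v)
    }))
    unique(unlist(lapply(vals, tri)))
  }
  q <- rec_tri(query)
  vapply(seq_len(nrow(records)), function(i) {
    length(intersect(q, rec_tri(records[i, , drop = FALSE])))
  }, integer(1))
}

# Small synthetic clean-record table with controllable sharing structure.
random_clean_records <- function(n, seed, n_values = max(3L, n %/% 3L),
                                 p_null = 0.3) {
  set.seed(seed)
  draw <- function(prefix) {
    v <- paste0(prefix, sample.int(n_values, n, replace = TRUE))
    v[runif(n) < p_null] <- NA_character_
    v
  }
  data.frame(
    record_id = seq_len(n),
    nhs_number = draw("N"),
    hospital_number = draw("H"),
    composite_id = draw("C"),
    stringsAsFactors = FALSE
  )
}
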