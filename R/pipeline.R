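#' Pipeline configuration
#'
#' Bundles everything a full linkage run needs so that a run is reproducible
#' from configuration plus input: the raw-column mapping, the identifier
#' fields used for linkage, cleaning options, classifier models and seed.
#'
#' @param columns named character vector mapping canonical field names
#'   (names) to the input file's column names (values); only present entries
#'   are renamed.
#' @param identifier_fields identifier columns used for exact linkage.
#' @param cleaning a [cleaning_config()].
#' @param models classifier models (see [published_models()]).
#' @param cutoff collision-score cutoff applied to both models.
#' @param seed integer seed for split tie-breaks.
#' @param max_passes split/re-score passes in [resolve_all()].
#' @param dedupe collapse duplicate identifier combinations before linkage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(columns = character(0),
                            identifier_fields = LINKAGE_FIELDS,
                            cleaning = cleaning_config(),
                            models = NULL,
                            cutoff = -1.5,
                            seed = 1L,
                            max_passes = 1L,
                            dedupe = FALSE) {
  if (is.null(models)) models <- published_models(cutoff = cutoff)
  structure(list(columns = columns, identifier_fields = identifier_fields,
                 cleaning = cleaning, models = models, cutoff = cutoff,
                 seed = as.integer(seed), max_passes = as.integer(max_passes),
                 dedupe = dedupe),
            class = "pipeline_config")
}

#' Run the full linkage pipeline
#'
#' Clean, build the composite identifier, link by iterated exact matching,
#' score complex clusters for identity collisions, split the clusters
#' flagged bad, and re-score. When `output_dir` is given, all artifacts are
#' written there as plain-text tables: `cleaned.csv`, `audit.tsv`,
#' `assignment.csv`, `features.tsv`, `splits.tsv`,
#' `multi_identifier_report.tsv` and `run_report.tsv`. Runs are deterministic
#' given the configuration seed.
#'
#' @param input path to a CSV/TSV file of raw records, or a data.frame.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for the output files.
#' @return list of class `run_report`: per-stage counts (`n_records`,
#'   `n_suppressed`, `n_unidentified`, `n_clusters_initial`, `n_complex`,
#'   `n_flagged_bad`, `n_splits`, `n_clusters_final`, `n_bad_after_rescore`),
#'   stage timings, and the component objects (`clean_records`, `linkage`,
#'   `resolution`, `multi_id_before`, `multi_id_after`).
#' @export
run_pipeline <- function(input, config = pipeline_config(), output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  raw <- if (is.data.frame(input)) input else .read_table(input)
  if (length(config$columns)) {
    for (canonical in names(config$columns)) {
      src <- config$columns[[canonical]]
      if (!src %in% names(raw)) stop("mapped column not in input: ", src)
      names(raw)[names(raw) == src] <- canonical
    }
  }
  if (!"record_id" %in% names(raw)) stop("input must have a record_id column")

  timing <- numeric(0)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[stage] <<- t1 - t0
    t0 <<- t1
  }

  cleaned <- add_composite_id(clean_records(raw, config$cleaning))
  tick("cleaning")

  linkage <- link_records(cleaned, config$identifier_fields,
                          dedupe = config$dedupe)
  tick("linkage")

  multi_before <- multi_identifier_report(linkage)
  resolution <- resolve_all(linkage, config$models, rng_seed = config$seed,
                            max_passes = config$max_passes)
  multi_after <- multi_identifier_report(resolution$result)
  tick("resolution")

  report <- structure(list(
    n_records = nrow(cleaned),
    n_suppressed = sum(cleaned$suppressed),
    n_unidentified = length(linkage$unidentified),
    n_clusters_initial = length(unique(linkage$cluster_id)),
    n_complex = resolution$n_complex,
    n_flagged_bad = resolution$n_flagged_bad,
    n_splits = resolution$n_splits,
    n_clusters_final = length(unique(resolution$result$cluster_id)),
    n_bad_after_rescore = resolution$n_bad_after,
    timing = timing,
    clean_records = cleaned,
    linkage = linkage,
    resolution = resolution,
    multi_id_before = multi_before,
    multi_id_after = multi_after
  ), class = "run_report")

  if (!is.null(output_dir)) .write_outputs(report, output_dir)
  report
}

#' Clusters with multiple values of theoretically unique fields
#'
#' For each field, counts the clusters whose non-null distinct value count
#' exceeds one. Computed before and after collision resolution, the drop per
#' field quantifies how much conflict the resolution removed; deletion-only
#' splitting guarantees no count increases.
#'
#' @param result a `linkage_result`.
#' @param fields fields to audit.
#' @return data.frame: field, n_clusters_multiple.
#' @export
multi_identifier_report <- function(result,
                                    fields = c("nhs_number", "hospital_number",
                                               "birthdate", "deathdate", "sex",
                                               "forename", "surname")) {
  fields <- intersect(fields, names(result$records))
  idx <- cluster_index(result)
  counts <- vapply(fields, function(f) {
    v <- result$records[[f]]
    if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
    v <- as.character(v)
    sum(vapply(idx, function(ix) {
      length(unique(na.omit(v[ix]))) > 1L
    }, logical(1)))
  }, integer(1))
  data.frame(field = fields, n_clusters_multiple = unname(counts),
             stringsAsFactors = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Linkage pipeline run\n")
  cat(sprintf("  records in:            %d (suppressed: %d, no identifiers: %d)\n",
              x$n_records, x$n_suppressed, x$n_unidentified))
  cat(sprintf("  clusters after linkage: %d\n", x$n_clusters_initial))
  cat(sprintf("  complex clusters:       %d (%.1f%%)\n", x$n_complex,
              100 * x$n_complex / max(x$n_clusters_initial, 1L)))
  cat(sprintf("  flagged bad:            %d\n", x$n_flagged_bad))
  cat(sprintf("  splits performed:       %d\n", x$n_splits))
  cat(sprintf("  clusters after resolve: %d\n", x$n_clusters_final))
  cat(sprintf("  bad after re-score:     %d\n", x$n_bad_after_rescore))
  invisible(x)
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("input not readable: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("", "NA", "NULL"))
}

.write_outputs <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  utils::write.csv(report$clean_records, out("cleaned.csv"), row.names = FALSE)
  audit <- attr(report$clean_records, "audit")
  if (!is.null(audit)) {
    utils::write.table(audit, out("audit.tsv"), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  utils::write.csv(report$resolution$result$assignment, out("assignment.csv"),
                   row.names = FALSE)
  utils::write.table(report$resolution$classification, out("features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$resolution$splits, out("splits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  multi <- rbind(cbind(stage = "before", report$multi_id_before),
                 cbind(stage = "after", report$multi_id_after))
  utils::write.table(multi, out("multi_identifier_report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  counts <- data.frame(
    quantity = c("records", "suppressed", "unidentified", "clusters_initial",
                 "complex", "flagged_bad", "splits", "clusters_final",
                 "bad_after_rescore"),
    value = c(report$n_records, report$n_suppressed, report$n_unidentified,
              report$n_clusters_initial, report$n_complex,
              report$n_flagged_bad, report$n_splits, report$n_clusters_final,
              report$n_bad_after_rescore)
  )
  utils::write.table(counts, out("run_report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(report)
}
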