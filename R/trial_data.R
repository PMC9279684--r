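# Arm-level trial data: reading, validation, per-outcome datasets with the
# double-zero exclusion rule, pooled group totals, and the evidence network.

.required_cols <- c("study_id", "treatment", "outcome", "n", "events")

#' Read arm-level trial data from CSV
#'
#' The expected layout is long format: one row per trial arm per outcome,
#' with columns `study_id`, `treatment`, `outcome`, `n` (patients
#' randomized) and `events` (patients with the outcome). A `schema` map
#' can rename non-standard columns, e.g.
#' `c(study_id = "trial", events = "r")`.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required)
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names
#' @return a `trial_arms` data frame with canonical columns
#' @export
read_trials <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_trinet("input file does not exist: %s", path, class = "trinet_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(.required_cols, names(raw))
  if (length(missing)) {
    stop_trinet("missing required column(s): %s",
                paste(missing, collapse = ", "), class = "trinet_schema_error")
  }
  arms <- raw[.required_cols]
  arms$study_id  <- as.character(arms$study_id)
  arms$treatment <- as.character(arms$treatment)
  arms$outcome   <- as.character(arms$outcome)
  suppressWarnings({
    arms$n      <- as.integer(arms$n)
    arms$events <- as.integer(arms$events)
  })
  validate_trials(arms)
}

#' Validate arm-level trial data
#'
#' Checks the per-arm invariants: integer counts, `n >= 1`, and
#' `0 <= events <= n` for every outcome row.
#'
#' @param arms a data frame in the canonical long layout
#' @return the validated `trial_arms` data frame (invisibly classed)
#' @export
validate_trials <- function(arms) {
  stopifnot(is.data.frame(arms))
  missing <- setdiff(.required_cols, names(arms))
  if (length(missing)) {
    stop_trinet("missing required column(s): %s",
                paste(missing, collapse = ", "), class = "trinet_schema_error")
  }
  if (anyNA(arms$n) || anyNA(arms$events)) {
    stop_trinet("non-numeric or missing counts in 'n'/'events'",
                class = "trinet_validation_error")
  }
  if (any(arms$n < 1L)) {
    bad <- arms$study_id[arms$n < 1L][1]
    stop_trinet("study %s has an arm with n < 1", bad,
                class = "trinet_validation_error")
  }
  if (any(arms$events < 0L)) {
    bad <- arms$study_id[arms$events < 0L][1]
    stop_trinet("study %s has a negative event count", bad,
                class = "trinet_validation_error")
  }
  over <- arms$events > arms$n
  if (any(over)) {
    i <- which(over)[1]
    stop_trinet("study %s, outcome %s: events (%d) exceed n (%d)",
                arms$study_id[i], arms$outcome[i], arms$events[i], arms$n[i],
                class = "trinet_validation_error")
  }
  class(arms) <- unique(c("trial_arms", class(arms)))
  arms
}

#' Write arm-level trial data to CSV
#'
#' @param arms a `trial_arms` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trials <- function(arms, path) {
  write.csv(as.data.frame(arms)[.required_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Build a per-outcome dataset with the double-zero exclusion rule
#'
#' Extracts the rows for one outcome and applies the exclusion rule used
#' for sparse binary meta-analysis: a study with zero events in every arm
#' carries no information about the odds ratio and is moved to
#' `excluded_studies`. Applying the constructor to its own output is a
#' no-op (the rule is idempotent).
#'
#' @param arms a `trial_arms` data frame or an existing `outcome_dataset`
#' @param outcome outcome label to extract
#' @return an `outcome_dataset`: list with `outcome`, `rows`
#'   (study_id, treatment, n, r) and `excluded_studies`
#' @export
build_outcome_dataset <- function(arms, outcome) {
  prior_excluded <- character()
  if (inherits(arms, "outcome_dataset")) {
    prior_excluded <- arms$excluded_studies
    outcome <- arms$outcome
    rows <- arms$rows
  } else {
    arms <- validate_trials(as.data.frame(arms))
    rows <- arms[arms$outcome == outcome, c("study_id", "treatment", "n", "events")]
    names(rows)[names(rows) == "events"] <- "r"
  }
  if (!nrow(rows)) {
    stop_trinet("no rows recorded for outcome '%s'", outcome,
                class = "trinet_validation_error")
  }
  key <- paste(rows$study_id, rows$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    stop_trinet("duplicate (study, treatment) rows for outcome '%s': %s",
                outcome, rows$study_id[duplicated(key)][1],
                class = "trinet_validation_error")
  }
  n_arms <- table(rows$study_id)
  single <- names(n_arms)[n_arms < 2]
  if (length(single)) {
    stop_trinet("outcome '%s' recorded for only one arm of study %s",
                outcome, single[1], class = "trinet_validation_error")
  }
  tot <- tapply(rows$r, rows$study_id, sum)
  zz <- names(tot)[tot == 0]
  keep <- !(rows$study_id %in% zz)
  structure(list(
    outcome = outcome,
    rows = rows[keep, , drop = FALSE],
    excluded_studies = sort(unique(c(prior_excluded, zz)))
  ), class = "outcome_dataset")
}

#' @export
print.outcome_dataset <- function(x, ...) {
  cat(sprintf("<outcome_dataset: %s>\n", x$outcome))
  cat(sprintf("  %d arms in %d studies; %d excluded (double-zero)\n",
              nrow(x$rows), length(unique(x$rows$study_id)),
              length(x$excluded_studies)))
  invisible(x)
}

#' Pool events and patients by treatment group
#'
#' Exact integer sums of events and patients over the retained arms of an
#' outcome dataset, with the event proportion as a percentage rounded
#' half-up to two decimals (the convention used in printed results
#' tables).
#'
#' @param ds an `outcome_dataset`
#' @return data frame with columns `treatment`, `n`, `events`, `pct`
#' @export
pool_by_treatment <- function(ds) {
  stopifnot(inherits(ds, "outcome_dataset"))
  if (!nrow(ds$rows)) {
    stop_trinet("outcome dataset '%s' has no retained rows", ds$outcome,
                class = "trinet_validation_error")
  }
  trt <- sort(unique(ds$rows$treatment))
  n <- vapply(trt, function(t) sum(as.numeric(ds$rows$n[ds$rows$treatment == t])), 0)
  ev <- vapply(trt, function(t) sum(as.numeric(ds$rows$r[ds$rows$treatment == t])), 0)
  data.frame(treatment = trt, n = as.integer(n), events = as.integer(ev),
             pct = round_half_up(100 * ev / n, 2), row.names = NULL)
}

#' Build the evidence-network summary
#'
#' Nodes are treatments with pooled patient counts; edges are observed
#' treatment pairs with the number of trials (`k`) and the number of
#' patients (`n`, summed over both arms of the trials on the edge).
#'
#' @param ds an `outcome_dataset`
#' @return an `evidence_network`: list with `nodes` and `edges` data frames
#' @export
build_network <- function(ds) {
  stopifnot(inherits(ds, "outcome_dataset"))
  pool <- pool_by_treatment(ds)
  nodes <- data.frame(treatment = pool$treatment, n = pool$n,
                      trials = vapply(pool$treatment, function(t)
                        length(unique(ds$rows$study_id[ds$rows$treatment == t])), 0L),
                      row.names = NULL)
  edges <- list()
  for (sid in unique(ds$rows$study_id)) {
    sub <- ds$rows[ds$rows$study_id == sid, ]
    trts <- sort(unique(sub$treatment))
    if (length(trts) < 2) next
    pairs <- utils::combn(trts, 2)
    for (j in seq_len(ncol(pairs))) {
      key <- paste(pairs[1, j], pairs[2, j], sep = " vs ")
      np <- sum(sub$n[sub$treatment %in% pairs[, j]])
      if (is.null(edges[[key]])) {
        edges[[key]] <- list(t1 = pairs[1, j], t2 = pairs[2, j], k = 1L, n = np)
      } else {
        edges[[key]]$k <- edges[[key]]$k + 1L
        edges[[key]]$n <- edges[[key]]$n + np
      }
    }
  }
  ed <- do.call(rbind, lapply(edges, function(e)
    data.frame(t1 = e$t1, t2 = e$t2, k = e$k, n = e$n)))
  if (is.null(ed)) ed <- data.frame(t1 = character(), t2 = character(),
                                    k = integer(), n = integer())
  ed <- ed[order(ed$t1, ed$t2), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(outcome = ds$outcome, nodes = nodes, edges = ed),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat(sprintf("<evidence_network: %s> %d nodes, %d edges\n",
              x$outcome, nrow(x$nodes), nrow(x$edges)))
  print(x$edges)
  invisible(x)
}

#' Serialize an evidence network to JSON
#'
#' @param net an `evidence_network`
#' @param path optional output path; when `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
network_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "evidence_network"))
  js <- jsonlite::toJSON(list(outcome = net$outcome, nodes = net$nodes,
                              edges = net$edges),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
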