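#' Read patient response records
#'
#' Reads a long-format CSV (`patient_id, item_id, severity_rank`, optional
#' `assessment_date`) into response sets, one per patient (and date, when
#' present). Rows are validated against the configuration: unknown item ids
#' and out-of-range ranks are reported with their line numbers.
#'
#' @param path CSV path (comma-separated, UTF-8, header row mandatory).
#' @param config The [instrument_config()] the responses target.
#' @return List of [response_set()] objects. An empty file yields an empty
#'   list with a warning.
#' @export
read_responses <- function(path, config) {
  stopifnot(inherits(config, "hmt_instrument"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "item_id", "severity_rank")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("response file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(sprintf("response file '%s' is empty", path), call. = FALSE)
    return(list())
  }
  items <- config_items(config)
  bad <- which(!df$item_id %in% names(items))
  if (length(bad) > 0L) {
    stop(sprintf("unknown item id(s) in '%s': %s (row %s)", path,
                 paste(unique(df$item_id[bad]), collapse = ", "),
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  kmax <- vapply(items[df$item_id], function(it) it$scale_size - 1L, integer(1))
  badrank <- which(is.na(df$severity_rank) | df$severity_rank < 0 |
                     df$severity_rank > kmax |
                     df$severity_rank != round(df$severity_rank))
  if (length(badrank) > 0L) {
    stop(sprintf("invalid severity rank(s) in '%s' at row %s", path,
                 paste(badrank + 1L, collapse = ", ")), call. = FALSE)
  }
  has_date <- "assessment_date" %in% names(df)
  key <- if (has_date) paste(df$patient_id, df$assessment_date, sep = "\r") else
    df$patient_id
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    response_set(
      patient_id = df$patient_id[idx[1]],
      disease = config$disease, setting = config$setting,
      answers = stats::setNames(as.integer(df$severity_rank[idx]),
                                df$item_id[idx]),
      assessment_date = if (has_date) df$assessment_date[idx[1]] else NULL
    )
  })
}

#' Write patient response records
#'
#' Writes response sets to the long CSV format read by [read_responses()];
#' writing then reading a cohort round-trips it losslessly.
#'
#' @param responses List of [response_set()] (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  if (inherits(responses, "hmt_responses")) responses <- list(responses)
  rows <- lapply(responses, function(r) {
    out <- data.frame(
      patient_id = r$patient_id,
      item_id = names(r$answers),
      severity_rank = unname(r$answers),
      stringsAsFactors = FALSE
    )
    if (!is.null(r$assessment_date)) out$assessment_date <- r$assessment_date
    out
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read expert rating records
#'
#' Reads a long-format ratings CSV (`rater_id, round, scope, slot_id, value`,
#' optional `justification`) into allocations grouped by rater, round and
#' scope.
#'
#' @param path CSV path.
#' @return List of [allocation()] objects.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("rater_id", "round", "scope", "slot_id", "value")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("ratings file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(sprintf("ratings file '%s' is empty", path), call. = FALSE)
    return(list())
  }
  if (any(is.na(df$value))) {
    stop(sprintf("non-numeric value(s) in '%s' at row %s", path,
                 paste(which(is.na(df$value)) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(df$rater_id, df$round, df$scope, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(unname(groups), function(idx) {
    just <- NULL
    if ("justification" %in% names(df)) {
      j <- df$justification[idx]
      keep <- !is.na(j) & nzchar(j)
      if (any(keep)) just <- stats::setNames(j[keep], df$slot_id[idx][keep])
    }
    allocation(
      rater_id = df$rater_id[idx[1]], round = df$round[idx[1]],
      scope = df$scope[idx[1]],
      values = stats::setNames(df$value[idx], df$slot_id[idx]),
      justifications = just
    )
  })
}

#' Write expert rating records
#'
#' Inverse of [read_ratings()].
#'
#' @param allocations List of [allocation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(allocations, path) {
  if (inherits(allocations, "hmt_allocation")) allocations <- list(allocations)
  rows <- lapply(allocations, function(a) {
    j <- vapply(names(a$values), function(slot) {
      if (!is.null(a$justifications) && slot %in% names(a$justifications)) {
        a$justifications[[slot]]
      } else ""
    }, character(1))
    data.frame(
      rater_id = a$rater_id, round = a$round, scope = a$scope,
      slot_id = names(a$values), value = unname(a$values),
      justification = unname(j), stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a score report
#'
#' Emits one or more score results as structured JSON: composite, category,
#' per-domain and per-item points, drivers, and the partial flag.
#'
#' @param results A single `hmt_score` or a list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(results, path) {
  if (inherits(results, "hmt_score")) results <- list(results)
  out <- lapply(unname(results), function(s) {
    list(
      patient_id = s$patient_id,
      assessment_date = if (is.null(s$assessment_date)) NA else s$assessment_date,
      composite = s$composite,
      category = s$category,
      domain_points = as.list(s$domain_points),
      item_points = as.list(s$item_points),
      drivers = s$drivers,
      partial = s$partial
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a consensus table
#'
#' Writes a [summarize_round()] table as CSV, mirroring the published table
#' layout (slot, median %, IQR, consensus).
#'
#' @param stats Data frame from [summarize_round()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus_table <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
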