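#' Construct a response set
#'
#' One patient's chosen answer (as a severity rank) for each item of an
#' instrument configuration.
#'
#' @param patient_id Opaque patient identifier.
#' @param disease `"A"` or `"B"`.
#' @param setting `"prophylaxis"` or `"on_demand"`.
#' @param answers Named integer vector (or named list), item id -> severity
#'   rank.
#' @param assessment_date Optional ISO-8601 date string.
#' @return An object of class `hmt_responses`.
#' @export
response_set <- function(patient_id, disease, setting, answers,
                         assessment_date = NULL) {
  disease <- match.arg(disease, c("A", "B"))
  setting <- match.arg(setting, c("prophylaxis", "on_demand"))
  answers <- unlist(answers)
  if (is.null(names(answers)) || any(!nzchar(names(answers)))) {
    stop("answers must be named by item id", call. = FALSE)
  }
  if (anyDuplicated(names(answers))) {
    stop("duplicated item ids in answers", call. = FALSE)
  }
  storage.mode(answers) <- "integer"
  if (any(is.na(answers)) || any(answers < 0L)) {
    stop("severity ranks must be non-negative integers", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id), disease = disease,
         setting = setting, answers = answers,
         assessment_date = assessment_date),
    class = "hmt_responses"
  )
}

#' Standardised response value of an answer
#'
#' Returns the standardised value r in \[0, 1\] of the option at the given
#' severity rank. For the bundled configurations these are exactly the printed
#' grids: 0, 0.33, 0.67, 1 on four-point scales and 0, 0.5, 1 on three-point
#' scales (0 = clinically optimal, 1 = worst).
#'
#' @param item An [instrument_item()].
#' @param severity_rank Integer rank, 0..scale_size-1.
#' @return The option's value r.
#' @export
response_value <- function(item, severity_rank) {
  stopifnot(inherits(item, "hmt_item"))
  severity_rank <- as.integer(severity_rank)
  ranks <- vapply(item$options, function(o) o$severity_rank, integer(1))
  idx <- match(severity_rank, ranks)
  if (is.na(idx)) {
    stop(sprintf("severity rank %d is not valid for item '%s' (%d-point scale)",
                 severity_rank, item$id, item$scale_size), call. = FALSE)
  }
  item$options[[idx]]$value
}

#' Map a composite score to its interpretive category
#'
#' The printed integer bands 0-25 (Excellent), 26-50 (Suboptimal), 51-75
#' (Poor) and 76-100 (Critical) are extended to the continuum as
#' left-open/right-closed intervals above 25, 50 and 75, so every real score
#' has exactly one category. Categories signal the need for treatment
#' reassessment, not disease severity.
#'
#' @param composite Numeric score(s) in \[0, 100\].
#' @return Factor with levels Excellent, Suboptimal, Poor, Critical.
#' @examples
#' categorize(c(0, 25, 25.5, 26, 50, 51, 75, 76, 100))
#' @export
categorize <- function(composite) {
  if (any(!is.finite(composite)) || any(composite < 0) || any(composite > 100)) {
    stop("composite scores must lie in [0, 100]", call. = FALSE)
  }
  cut(composite, breaks = c(0, 25, 50, 75, 100),
      labels = c("Excellent", "Suboptimal", "Poor", "Critical"),
      include.lowest = TRUE, right = TRUE)
}

#' Compute the composite monitoring score
#'
#' Each answered item contributes `(W/100) * (w/100) * r * 100` points, where W
#' is its domain's section weight, w the item weight within the domain, and r
#' the standardised value of the chosen option. The composite is the sum of
#' all item contributions, lies on a 0-100 scale (0 = fully aligned with the
#' consensus-optimal profile, 100 = worst possible on every item) and is
#' mapped to the four interpretive categories by [categorize()].
#'
#' By default every item must be answered. With `allow_missing = TRUE`, item
#' weights are renormalised over the answered items within each domain; a
#' domain with no answered item is dropped and the remaining domain weights
#' renormalised; the result is flagged `partial`.
#'
#' @param config An [instrument_config()].
#' @param responses A [response_set()] for the same disease and setting.
#' @param allow_missing Permit unanswered items (see Details).
#' @return An object of class `hmt_score`: a list with `composite`,
#'   `category`, `domain_points` (named numeric), `item_points` (named
#'   numeric), `drivers` (item ids by descending contribution), `partial`,
#'   `patient_id`, `assessment_date`.
#' @examples
#' cfg <- load_instrument("B", "prophylaxis")
#' ids <- names(all_best_profile(cfg)$answers)
#' worst_abr <- all_best_profile(cfg)
#' worst_abr$answers["abr"] <- 3L
#' composite_score(cfg, worst_abr)
#' @export
composite_score <- function(config, responses, allow_missing = FALSE) {
  stopifnot(inherits(config, "hmt_instrument"), inherits(responses, "hmt_responses"))
  if (!identical(responses$disease, config$disease) ||
      !identical(responses$setting, config$setting)) {
    stop(sprintf(
      "response set targets %s/%s but configuration is %s/%s",
      responses$disease, responses$setting, config$disease, config$setting),
      call. = FALSE)
  }
  items <- config_items(config)
  unknown <- setdiff(names(responses$answers), names(items))
  if (length(unknown) > 0L) {
    stop(sprintf("answers for unknown item(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(names(items), names(responses$answers))
  if (length(missing) > 0L && !allow_missing) {
    stop(sprintf("incomplete response set; missing item(s): %s (use allow_missing = TRUE to renormalise)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  # per-domain effective weights over answered items
  answered_domains <- Filter(function(d) {
    any(vapply(d$items, function(it) it$id %in% names(responses$answers), logical(1)))
  }, config$domains)
  if (length(answered_domains) == 0L) {
    stop("no answered items", call. = FALSE)
  }
  W_raw <- vapply(answered_domains, function(d) d$weight_pct, numeric(1))
  W <- W_raw * 100 / sum(W_raw)  # identity when nothing is missing

  item_points <- numeric(0)
  domain_points <- numeric(length(answered_domains))
  names(domain_points) <- vapply(answered_domains, function(d) d$id, character(1))
  for (k in seq_along(answered_domains)) {
    d <- answered_domains[[k]]
    ans_items <- Filter(function(it) it$id %in% names(responses$answers), d$items)
    w_raw <- vapply(ans_items, function(it) it$weight_pct, numeric(1))
    w <- w_raw * 100 / sum(w_raw)
    pts <- vapply(seq_along(ans_items), function(j) {
      it <- ans_items[[j]]
      r <- response_value(it, responses$answers[[it$id]])
      (W[k] / 100) * (w[j] / 100) * r * 100
    }, numeric(1))
    names(pts) <- vapply(ans_items, function(it) it$id, character(1))
    item_points <- c(item_points, pts)
    domain_points[k] <- sum(pts)
  }
  composite <- sum(item_points)
  drivers <- names(item_points)[order(-item_points)]
  structure(
    list(
      composite = composite,
      category = as.character(categorize(min(max(composite, 0), 100))),
      domain_points = domain_points,
      item_points = item_points,
      drivers = drivers,
      partial = length(missing) > 0L,
      patient_id = responses$patient_id,
      assessment_date = responses$assessment_date
    ),
    class = "hmt_score"
  )
}

#' @export
print.hmt_score <- function(x, ...) {
  cat(sprintf("<monitoring score> patient %s%s\n", x$patient_id,
              if (x$partial) " (partial)" else ""))
  cat(sprintf("  composite: %.2f / 100  ->  %s\n", x$composite, x$category))
  cat("  domain points:\n")
  for (d in names(x$domain_points)) {
    cat(sprintf("    %-18s %6.2f\n", d, x$domain_points[[d]]))
  }
  cat(sprintf("  top drivers: %s\n",
              paste(utils::head(x$drivers, 3), collapse = ", ")))
  invisible(x)
}

#' All-best / all-worst reference profiles
#'
#' Convenience constructors for the two anchor profiles of a configuration:
#' severity rank 0 on every item (scores exactly 0, Excellent) and the highest
#' severity rank on every item (scores exactly 100, Critical).
#'
#' @param config An [instrument_config()].
#' @param patient_id Patient identifier for the profile.
#' @return A [response_set()].
#' @export
all_best_profile <- function(config, patient_id = "reference_best") {
  items <- config_items(config)
  answers <- vapply(items, function(it) 0L, integer(1))
  response_set(patient_id, config$disease, config$setting, answers)
}

#' @rdname all_best_profile
#' @export
all_worst_profile <- function(config, patient_id = "reference_worst") {
  items <- config_items(config)
  answers <- vapply(items, function(it) it$scale_size - 1L, integer(1))
  response_set(patient_id, config$disease, config$setting, answers)
}

#' Score a longitudinal series of visits
#'
#' Scores each visit of one patient in order and reports the change in the
#' composite since the previous visit, supporting structured periodic
#' evaluation over follow-up.
#'
#' @param config An [instrument_config()].
#' @param responses_list Ordered list of [response_set()] for the same patient
#'   and configuration.
#' @param allow_missing Passed to [composite_score()].
#' @return A list with `scores` (list of `hmt_score`) and `deltas` (numeric;
#'   `NA` for the first visit).
#' @export
score_longitudinal <- function(config, responses_list, allow_missing = FALSE) {
  stopifnot(length(responses_list) >= 1L)
  pids <- vapply(responses_list, function(r) r$patient_id, character(1))
  if (length(unique(pids)) != 1L) {
    stop("longitudinal scoring expects a single patient", call. = FALSE)
  }
  scores <- lapply(responses_list, function(r) {
    composite_score(config, r, allow_missing = allow_missing)
  })
  comps <- vapply(scores, function(s) s$composite, numeric(1))
  deltas <- c(NA_real_, diff(comps))
  list(scores = scores, deltas = deltas)
}
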