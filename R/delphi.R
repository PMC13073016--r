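#' Construct a constant-sum allocation
#'
#' One expert's weight allocation in one Delphi round: 100 points distributed
#' across the slots of a scope (the clinical domains of an instrument, or the
#' items of one domain).
#'
#' @param rater_id Rater identifier.
#' @param round 1 or 2.
#' @param scope Scope label, e.g. `"domain"` or `"items:joint_health"`.
#' @param values Named numeric vector, slot id -> allocated points (>= 0,
#'   summing to 100).
#' @param justifications Optional named character vector, slot id -> free-text
#'   justification (round 2, for values kept outside the round-1 bounds).
#' @return An object of class `hmt_allocation`.
#' @export
allocation <- function(rater_id, round, scope, values, justifications = NULL) {
  round <- as.integer(round)
  if (!round %in% c(1L, 2L)) stop("round must be 1 or 2", call. = FALSE)
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by slot id", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (!is.null(justifications)) justifications <- unlist(justifications)
  structure(
    list(rater_id = as.character(rater_id), round = round,
         scope = as.character(scope), values = values,
         justifications = justifications),
    class = "hmt_allocation"
  )
}

#' Validate a constant-sum allocation
#'
#' @param a An [allocation()].
#' @param tolerance Tolerance on the 100-point sum (default `1e-9`).
#' @return A data frame of violations (`location`, `message`); zero rows means
#'   the allocation is valid.
#' @export
validate_allocation <- function(a, tolerance = 1e-9) {
  stopifnot(inherits(a, "hmt_allocation"))
  loc <- character(); msg <- character()
  s <- sum(a$values)
  if (abs(s - 100) > tolerance) {
    loc <- c(loc, "sum"); msg <- c(msg, sprintf("sum is %g, must be 100", s))
  }
  neg <- names(a$values)[a$values < 0]
  for (slot in neg) {
    loc <- c(loc, slot)
    msg <- c(msg, sprintf("negative allocation %g", a$values[[slot]]))
  }
  data.frame(location = loc, message = msg, stringsAsFactors = FALSE)
}

#' Delphi analysis options
#'
#' @param consensus_threshold Consensus is declared when the interquartile
#'   range of a slot's allocations is strictly below this many points
#'   (default 8, the pre-specified rule on the 0-100 constant-sum scale).
#' @param quantile_method `"linear"` (interpolation between order statistics at
#'   h = (n-1)p, the default), `"nearest"` (nearest order statistic), or
#'   `"tukey"` (Tukey hinges) — alternatives for sensitivity checks.
#' @param strict_bounds If `TRUE`, round-2 values outside the round-1
#'   interquartile interval without justification abort weight derivation.
#' @return An object of class `hmt_delphi_config`.
#' @export
delphi_config <- function(consensus_threshold = 8,
                          quantile_method = c("linear", "nearest", "tukey"),
                          strict_bounds = TRUE) {
  if (!is.numeric(consensus_threshold) || consensus_threshold <= 0) {
    stop("consensus_threshold must be > 0", call. = FALSE)
  }
  structure(
    list(consensus_threshold = consensus_threshold,
         quantile_method = match.arg(quantile_method),
         rounds = 2L, strict_bounds = isTRUE(strict_bounds)),
    class = "hmt_delphi_config"
  )
}

delphi_quartiles <- function(values, method) {
  switch(method,
    linear = stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                             names = FALSE),
    nearest = stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 3,
                              names = FALSE),
    tukey = stats::fivenum(values)[2:4],
    stop(sprintf("unknown quantile method '%s'", method), call. = FALSE)
  )
}

#' Quartile summary and consensus flag for one weighting slot
#'
#' Computes the first quartile, median, third quartile and interquartile range
#' of a panel's allocations to one slot, and flags consensus when the IQR is
#' strictly below the configured threshold.
#'
#' @param values Numeric allocations from at least two raters.
#' @param config A [delphi_config()].
#' @param slot_id Optional slot label carried through to the result.
#' @return An object of class `hmt_consensus`: list with `slot_id`, `n`, `q1`,
#'   `median`, `q3`, `iqr`, `consensus`.
#' @examples
#' quartile_summary(c(10, 20, 30, 40))  # q1 17.5, q3 32.5, iqr 15, no consensus
#' @export
quartile_summary <- function(values, config = delphi_config(), slot_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("at least two raters are required for a quartile summary", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("allocations must be finite", call. = FALSE)
  q <- delphi_quartiles(values, config$quantile_method)
  iqr <- q[3] - q[1]
  structure(
    list(slot_id = slot_id, n = length(values), q1 = q[1], median = q[2],
         q3 = q[3], iqr = iqr, consensus = iqr < config$consensus_threshold),
    class = "hmt_consensus"
  )
}

#' Summarise one Delphi round
#'
#' Computes per-slot consensus statistics over a panel of allocations sharing
#' one scope and round, mirroring the published consensus tables (median %,
#' IQR, consensus flag per slot).
#'
#' @param allocations List of [allocation()] with identical `scope` and
#'   `round`, one per rater, all covering the same slots.
#' @param config A [delphi_config()].
#' @return A data frame with one row per slot: `slot_id`, `n`, `q1`, `median`,
#'   `q3`, `iqr`, `consensus`, in the slot order of the first allocation.
#' @export
summarize_round <- function(allocations, config = delphi_config()) {
  stopifnot(length(allocations) >= 2L)
  lapply(allocations, function(a) stopifnot(inherits(a, "hmt_allocation")))
  scopes <- unique(vapply(allocations, function(a) a$scope, character(1)))
  rounds <- unique(vapply(allocations, function(a) a$round, integer(1)))
  if (length(scopes) != 1L || length(rounds) != 1L) {
    stop("allocations mix scopes or rounds; summarise one scope and round at a time",
         call. = FALSE)
  }
  slots <- names(allocations[[1]]$values)
  for (a in allocations) {
    if (!setequal(names(a$values), slots)) {
      stop(sprintf("rater '%s' covers different slots than the rest of the panel",
                   a$rater_id), call. = FALSE)
    }
  }
  rows <- lapply(slots, function(slot) {
    vals <- vapply(allocations, function(a) a$values[[slot]], numeric(1))
    s <- quartile_summary(vals, config, slot_id = slot)
    data.frame(slot_id = slot, n = s$n, q1 = s$q1, median = s$median,
               q3 = s$q3, iqr = s$iqr, consensus = s$consensus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scope") <- scopes
  attr(out, "round") <- rounds
  out
}

#' Round-2 rating bounds from round-1 statistics
#'
#' In round two each expert is asked to re-rate within the interquartile
#' interval of the first round; this returns the closed interval
#' \[q1, q3\] per slot.
#'
#' @param round1_stats A data frame from [summarize_round()] on round-1
#'   allocations.
#' @return Named list, slot id -> numeric `c(lower, upper)`.
#' @export
round2_bounds <- function(round1_stats) {
  stopifnot(is.data.frame(round1_stats))
  if (nrow(round1_stats) == 0L) return(stats::setNames(list(), character(0)))
  b <- lapply(seq_len(nrow(round1_stats)), function(i) {
    c(round1_stats$q1[i], round1_stats$q3[i])
  })
  stats::setNames(b, round1_stats$slot_id)
}

#' Check round-2 allocations against round-1 bounds
#'
#' Flags every round-2 value lying outside its slot's round-1 interquartile
#' interval; such values require a written justification, and an out-of-bounds
#' value without one is a violation.
#'
#' @param allocations List of round-2 [allocation()].
#' @param bounds Named list from [round2_bounds()], covering every slot used.
#' @return A data frame with one row per (rater, slot): `rater_id`, `slot_id`,
#'   `value`, `lower`, `upper`, `in_bounds`, `justification_present`,
#'   `violation`.
#' @export
check_round2 <- function(allocations, bounds) {
  lapply(allocations, function(a) stopifnot(inherits(a, "hmt_allocation")))
  rows <- list()
  for (a in allocations) {
    missing_bounds <- setdiff(names(a$values), names(bounds))
    if (length(missing_bounds) > 0L) {
      stop(sprintf("no round-1 bounds for slot(s): %s",
                   paste(missing_bounds, collapse = ", ")), call. = FALSE)
    }
    for (slot in names(a$values)) {
      v <- a$values[[slot]]
      b <- bounds[[slot]]
      inside <- v >= b[1] && v <= b[2]
      just <- !is.null(a$justifications) && slot %in% names(a$justifications) &&
        nzchar(a$justifications[[slot]])
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = a$rater_id, slot_id = slot, value = v,
        lower = b[1], upper = b[2], in_bounds = inside,
        justification_present = just,
        violation = !inside && !just,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(rater_id = character(), slot_id = character(),
                      value = numeric(), lower = numeric(), upper = numeric(),
                      in_bounds = logical(), justification_present = logical(),
                      violation = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Derive consensus weights from round-2 allocations
#'
#' The consensus weight of each slot is the median of the panel's round-2
#' allocations. If the medians do not sum to 100, they are proportionally
#' renormalised (recorded via the `renormalised` flag, with the raw sum
#' retained). In strict mode, unjustified out-of-bounds round-2 values (see
#' [check_round2()]) abort derivation when `bounds` are supplied.
#'
#' @param allocations List of round-2 [allocation()].
#' @param config A [delphi_config()].
#' @param bounds Optional named list from [round2_bounds()] for the strict
#'   bound check.
#' @return An object of class `hmt_weightset`: list with `scope`, `weights`
#'   (named numeric summing to 100), `renormalised`, `sum_raw`, `stats` (the
#'   [summarize_round()] table).
#' @export
derive_weights <- function(allocations, config = delphi_config(), bounds = NULL) {
  if (!is.null(bounds) && config$strict_bounds) {
    findings <- check_round2(allocations, bounds)
    if (any(findings$violation)) {
      bad <- findings[findings$violation, , drop = FALSE]
      stop(sprintf(
        "unjustified out-of-bounds round-2 value(s): %s",
        paste(sprintf("%s@%s=%g", bad$rater_id, bad$slot_id, bad$value),
              collapse = "; ")), call. = FALSE)
    }
  }
  stats_tab <- summarize_round(allocations, config)
  weights <- stats::setNames(stats_tab$median, stats_tab$slot_id)
  sum_raw <- sum(weights)
  renorm <- abs(sum_raw - 100) > 1e-9
  if (renorm) weights <- weights * 100 / sum_raw
  structure(
    list(scope = attr(stats_tab, "scope"), weights = weights,
         renormalised = renorm, sum_raw = sum_raw, stats = stats_tab),
    class = "hmt_weightset"
  )
}

#' @export
print.hmt_weightset <- function(x, ...) {
  cat(sprintf("<delphi weight set> scope '%s'%s\n", x$scope,
              if (x$renormalised)
                sprintf(" (renormalised from raw sum %g)", x$sum_raw) else ""))
  for (slot in names(x$weights)) {
    cat(sprintf("  %-18s %6.2f%%\n", slot, x$weights[[slot]]))
  }
  invisible(x)
}
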