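#' Simulate a constant-sum expert panel (round 1)
#'
#' Draws each rater's allocation from a Dirichlet distribution centred on the
#' target (shape = concentration x target proportion), scaled to 100 points,
#' so the constant-sum constraint holds by construction. Larger concentration
#' means tighter agreement: the per-slot standard deviation is approximately
#' `100 * sqrt(p (1 - p) / (concentration + 1))` for target proportion p. In
#' integer mode, draws are apportioned to integers summing exactly to 100 by
#' the largest-remainder method (ties broken by slot order).
#'
#' @param n_raters Number of raters (>= 2).
#' @param target Named numeric vector of target allocations summing to 100.
#' @param concentration Dispersion control, > 0; larger = tighter.
#' @param integer_mode Apportion each allocation to integers.
#' @param seed Integer seed; identical seeds give identical panels.
#' @param scope Scope label stamped on the allocations.
#' @return List of round-1 [allocation()] objects.
#' @examples
#' panel <- simulate_panel(16, c(pk = 18, bleed = 32, joint = 27, adhqol = 23),
#'                         concentration = 500, seed = 1)
#' summarize_round(panel)
#' @export
simulate_panel <- function(n_raters, target, concentration = 100,
                           integer_mode = FALSE, seed = 1L, scope = "domain") {
  if (n_raters < 2L) stop("n_raters must be >= 2", call. = FALSE)
  target <- unlist(target)
  if (is.null(names(target))) stop("target must be named by slot id", call. = FALSE)
  if (any(target < 0) || abs(sum(target) - 100) > 1e-9) {
    stop("target allocations must be non-negative and sum to 100", call. = FALSE)
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0", call. = FALSE)
  }
  shape <- concentration * target / 100
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_raters), function(i) {
    g <- stats::rgamma(length(shape), shape = shape, rate = 1)
    g[shape == 0] <- 0
    vals <- 100 * g / sum(g)
    if (integer_mode) vals <- largest_remainder(vals, 100L)
    allocation(sprintf("rater_%02d", i), round = 1L, scope = scope,
               values = stats::setNames(vals, names(target)))
  })
}

# largest-remainder apportionment of non-negative values to integers summing
# to `total`; ties broken deterministically by slot order
largest_remainder <- function(values, total = 100L) {
  fl <- floor(values)
  rem <- values - fl
  left <- total - sum(fl)
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    fl[take] <- fl[take] + 1
  }
  fl
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate round-2 re-rating behaviour
#'
#' Emulates how experts revise their allocations in the second round: with
#' probability `compliance` an out-of-bounds round-1 value is projected into
#' its slot's round-1 interquartile interval; otherwise it is kept outside
#' with an auto-generated justification. The allocation is then re-balanced
#' to sum to 100 by proportional adjustment: a common scale factor is applied
#' to all slots, complying slots are clamped to their intervals while
#' kept-outside slots float freely, and the factor is chosen by root-finding
#' so the allocation sums to 100. When no such factor exists (the interval
#' floors alone exceed the budget), generation fails rather than silently
#' fixing the allocation.
#'
#' @param round1 List of round-1 [allocation()] (e.g. from [simulate_panel()]).
#' @param bounds Named list from [round2_bounds()].
#' @param compliance Probability in \[0, 1\] of complying with the bounds.
#' @param seed Integer seed.
#' @return List of round-2 [allocation()] objects.
#' @export
simulate_round2 <- function(round1, bounds, compliance = 1, seed = 1L) {
  stopifnot(compliance >= 0, compliance <= 1)
  slots_needed <- unique(unlist(lapply(round1, function(a) names(a$values))))
  missing_bounds <- setdiff(slots_needed, names(bounds))
  if (length(missing_bounds) > 0L) {
    stop(sprintf("no bounds for slot(s): %s",
                 paste(missing_bounds, collapse = ", ")), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(round1, function(a) {
    slots <- names(a$values)
    v <- a$values
    kept <- character(0)
    for (slot in slots) {
      b <- bounds[[slot]]
      if ((v[[slot]] < b[1] || v[[slot]] > b[2]) && stats::runif(1) >= compliance) {
        kept <- c(kept, slot)
      }
    }
    # all slots are scaled by a common factor t; complying slots are clamped
    # into [q1, q3] while kept-outside slots are unconstrained. The clamped
    # sum is monotone non-decreasing in t, so a t balancing the allocation to
    # 100 exists (and is found by root-finding) unless the interval floors
    # alone already exceed the budget.
    lo <- vapply(slots, function(s) if (s %in% kept) 0 else bounds[[s]][1],
                 numeric(1))
    hi <- vapply(slots, function(s) if (s %in% kept) Inf else bounds[[s]][2],
                 numeric(1))
    clamped_sum <- function(t) sum(pmin(pmax(v * t, lo), hi))
    if (sum(lo) > 100 + 1e-9 || clamped_sum(1e12) < 100 - 1e-9) {
      stop(sprintf(
        "cannot re-balance rater '%s' to 100: round-1 intervals pin the sum away from the budget",
        a$rater_id), call. = FALSE)
    }
    t_hi <- 1
    while (clamped_sum(t_hi) < 100 && t_hi < 1e12) t_hi <- t_hi * 2
    t <- stats::uniroot(function(t) clamped_sum(t) - 100,
                        lower = 0, upper = t_hi, tol = 1e-12)$root
    v <- pmin(pmax(v * t, lo), hi)
    # absorb root-finding residue in the slot with most interior slack
    resid <- 100 - sum(v)
    if (abs(resid) > 0) {
      slack <- if (resid > 0) hi - v else v - lo
      k <- which.max(slack)
      if (slack[k] >= abs(resid)) v[k] <- v[k] + resid
    }
    just <- stats::setNames(vapply(kept, function(slot) {
      sprintf("rater %s maintains %0.1f for %s based on clinical experience",
              a$rater_id, v[[slot]], slot)
    }, character(1)), kept)
    allocation(a$rater_id, round = 2L, scope = a$scope, values = v,
               justifications = if (length(just) > 0) just else NULL)
  })
}

#' Simulate a patient cohort of instrument responses
#'
#' Generates complete response sets for an instrument. For an item with k
#' options the severity rank is drawn as Binomial(k - 1, severity), so the
#' response mass shifts monotonically toward the worst option as `severity`
#' grows: severity 0 forces the all-best profile (composite 0), severity 1 the
#' all-worst profile (composite 100).
#'
#' @param n_patients Number of patients (>= 1).
#' @param severity Number in \[0, 1\].
#' @param config An [instrument_config()].
#' @param seed Integer seed.
#' @return List of [response_set()] objects.
#' @export
simulate_cohort <- function(n_patients, severity, config, seed = 1L) {
  stopifnot(n_patients >= 1L, severity >= 0, severity <= 1,
            inherits(config, "hmt_instrument"))
  items <- config_items(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_patients), function(i) {
    answers <- vapply(items, function(it) {
      as.integer(stats::rbinom(1, size = it$scale_size - 1L, prob = severity))
    }, integer(1))
    response_set(sprintf("patient_%04d", i), config$disease, config$setting,
                 answers)
  })
}

#' Simulate raw clinical measurement records
#'
#' Generates per-patient measurement records exercising the raw-measure
#' pipeline end to end. Bleed counts are Poisson with mean
#' `bleed_rate_per_year * follow_up_days / 365.25`, so the annualised bleeding
#' rate recovered via [annualized_rate()] equals `bleed_rate_per_year` in
#' expectation; joint bleeds are a Binomial thinning of total bleeds;
#' infusions given are Binomial around `adherence_mean` percent of those
#' expected (a twice-weekly regimen), so `adherence_mean = 100` yields full
#' adherence deterministically. Joint-status and patient-reported fields are
#' driven by `severity` as in [simulate_cohort()].
#'
#' @param n Number of records.
#' @param bleed_rate_per_year True annual bleeding rate (>= 0).
#' @param follow_up_days Follow-up window in days (> 0).
#' @param adherence_mean Mean adherence percent (0..100).
#' @param seed Integer seed.
#' @param severity Severity in \[0, 1\] for joint/PRO fields (default 0.2).
#' @param joint_share Probability a bleed is a joint bleed (default 0.5).
#' @return A data frame, one row per record, with the `RawMeasurements`
#'   columns consumed by [responses_from_raw()].
#' @export
simulate_raw_records <- function(n, bleed_rate_per_year, follow_up_days,
                                 adherence_mean = 90, seed = 1L,
                                 severity = 0.2, joint_share = 0.5) {
  stopifnot(n >= 1L, bleed_rate_per_year >= 0, follow_up_days > 0,
            adherence_mean >= 0, adherence_mean <= 100,
            severity >= 0, severity <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  expected <- max(1L, as.integer(round(follow_up_days * 2 / 7)))
  bleed <- stats::rpois(n, bleed_rate_per_year * follow_up_days / 365.25)
  joint <- stats::rbinom(n, size = bleed, prob = joint_share)
  given <- stats::rbinom(n, size = expected, prob = adherence_mean / 100)
  lev <- function() 1L + stats::rbinom(n, 4L, severity)
  lev_b <- function() 1L + stats::rbinom(n, 4L, severity)
  data.frame(
    record_id = sprintf("rec_%04d", seq_len(n)),
    bleed_count = bleed,
    joint_bleed_count = joint,
    follow_up_days = follow_up_days,
    infusions_given = given,
    infusions_expected = expected,
    eq5d_mobility = lev(), eq5d_selfcare = lev(), eq5d_activities = lev(),
    eq5d_pain = lev(), eq5d_anxiety = lev(),
    eq5d_baseline_mobility = lev_b(), eq5d_baseline_selfcare = lev_b(),
    eq5d_baseline_activities = lev_b(), eq5d_baseline_pain = lev_b(),
    eq5d_baseline_anxiety = lev_b(),
    hjhs_delta = stats::rbinom(n, 5L, severity) - 1L,
    headus_delta = stats::rbinom(n, 3L, severity) - 1L,
    pj_count = stats::rbinom(n, 5L, severity),
    tj_count = stats::rbinom(n, 3L, severity),
    pj_trend = trend_levels[1L + stats::rbinom(n, 2L, severity)],
    tj_trend = trend_levels[1L + stats::rbinom(n, 2L, severity)],
    trough_satisfaction = trough_levels[1L + stats::rbinom(n, 3L, severity)],
    stringsAsFactors = FALSE
  )
}
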