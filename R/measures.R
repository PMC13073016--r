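#' Annualised event rate
#'
#' Computes an annualised bleeding rate: events divided by the follow-up
#' duration in days and multiplied by 365.25. Used for both the total
#' annualised bleeding rate (ABR) and the annualised joint bleeding rate
#' (AJBR).
#'
#' @param events Non-negative event count.
#' @param follow_up_days Follow-up duration in days, > 0.
#' @return Events per year.
#' @examples
#' annualized_rate(3, 365.25)  # 3 bleeds over one year -> ABR 3
#' @export
annualized_rate <- function(events, follow_up_days) {
  if (any(!is.finite(events)) || any(events < 0)) {
    stop("events must be a non-negative count", call. = FALSE)
  }
  if (any(!is.finite(follow_up_days)) || any(follow_up_days <= 0)) {
    stop("follow_up_days must be > 0", call. = FALSE)
  }
  events / follow_up_days * 365.25
}

#' Adherence percentage
#'
#' Administered prophylactic infusions as a percentage of the number expected
#' under the prescribed regimen over the same period.
#'
#' @param given Infusions administered (>= 0).
#' @param expected Infusions expected (> 0).
#' @return `100 * given / expected`.
#' @export
adherence_pct <- function(given, expected) {
  if (any(!is.finite(given)) || any(given < 0)) {
    stop("given must be a non-negative count", call. = FALSE)
  }
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop("expected must be > 0", call. = FALSE)
  }
  100 * given / expected
}

#' EQ-5D-5L Level Sum Score
#'
#' Sums the five dimension levels (mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression) of the EQ-5D-5L questionnaire. Each
#' level is an integer 1 (no problems) to 5 (extreme problems); the Level Sum
#' Score therefore ranges from 5 (best health) to 25 (worst health).
#'
#' @param levels Exactly five integers, each in 1..5.
#' @return Integer in \[5, 25\].
#' @export
level_sum_score <- function(levels) {
  levels <- as.numeric(levels)
  if (length(levels) != 5L) {
    stop("EQ-5D-5L has exactly five dimensions", call. = FALSE)
  }
  if (any(is.na(levels)) || any(levels != round(levels)) ||
      any(levels < 1) || any(levels > 5)) {
    stop("each EQ-5D-5L level must be an integer in 1..5", call. = FALSE)
  }
  as.integer(sum(levels))
}

#' Convert months of follow-up to days
#'
#' Convenience converter so follow-up recorded in months is made explicit
#' rather than silently mixed with days (one month = 365.25/12 = 30.4375 days).
#'
#' @param months Duration in months.
#' @return Duration in days.
#' @export
months_to_days <- function(months) {
  months * 30.4375
}

# Banding rules mapping a raw clinical value onto an item's severity ranks.
# Continuous annualised rates are rounded half-up to the nearest integer first,
# so the printed integer bands (e.g. "1-2", "3-4") give a total, monotone
# mapping; values in (0, 0.5) fall in the "0" band.
round_half_up <- function(x) floor(x + 0.5)

check_count <- function(x, what) {
  if (!is.finite(x) || x < 0 || x != round(x)) {
    stop(sprintf("%s must be a non-negative integer, got %s", what, format(x)),
         call. = FALSE)
  }
  as.integer(x)
}

check_enum <- function(x, levels, what) {
  x <- as.character(x)
  if (length(x) != 1L || !x %in% levels) {
    stop(sprintf("%s must be one of: %s", what, paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  x
}

trend_levels <- c("absent_or_decreased", "stable", "increased")
trough_levels <- c("very_satisfactory", "quite_satisfactory",
                   "not_very_satisfactory", "not_at_all_satisfactory")

bucketing_rules <- list(
  abr = function(x) {
    if (!is.finite(x) || x < 0) stop("ABR must be >= 0", call. = FALSE)
    v <- round_half_up(x)
    if (v == 0) 0L else if (v <= 2) 1L else if (v <= 4) 2L else 3L
  },
  ajbr = function(x) {
    if (!is.finite(x) || x < 0) stop("AJBR must be >= 0", call. = FALSE)
    v <- round_half_up(x)
    if (v == 0) 0L else if (v == 1) 1L else if (v == 2) 2L else 3L
  },
  pj_count = function(x) {
    v <- check_count(x, "problem-joint count")
    if (v == 0) 0L else if (v == 1) 1L else if (v <= 3) 2L else 3L
  },
  tj_count = function(x) {
    v <- check_count(x, "target-joint count")
    if (v == 0) 0L else if (v == 1) 1L else 2L
  },
  pj_trend = function(x) {
    match(check_enum(x, trend_levels, "problem-joint trend"), trend_levels) - 1L
  },
  tj_trend = function(x) {
    match(check_enum(x, trend_levels, "target-joint trend"), trend_levels) - 1L
  },
  hjhs_delta = function(x) {
    if (!is.finite(x) || x != round(x)) {
      stop("HJHS change must be an integer", call. = FALSE)
    }
    if (x <= 1) 0L else if (x <= 3) 1L else 2L
  },
  headus_delta = function(x) {
    if (!is.finite(x) || x != round(x)) {
      stop("HEAD-US change must be an integer", call. = FALSE)
    }
    if (x <= 0) 0L else if (x == 1) 1L else 2L
  },
  adherence = function(x) {
    if (!is.finite(x) || x < 0) stop("adherence %% must be >= 0", call. = FALSE)
    # printed inequalities read literally: >90 best; [80, 90] middle; <80 worst
    if (x > 90) 0L else if (x >= 80) 1L else 2L
  },
  lss_current = function(x) {
    if (!is.finite(x) || x != round(x) || x < 5 || x > 25) {
      stop("EQ-5D-5L level sum score must be an integer in 5..25", call. = FALSE)
    }
    if (x <= 6) 0L else if (x <= 11) 1L else if (x <= 18) 2L else 3L
  },
  lss_change = function(x) {
    if (!is.finite(x) || x != round(x)) {
      stop("level-sum-score change must be an integer", call. = FALSE)
    }
    if (x <= 0) 0L else if (x <= 2) 1L else 2L
  },
  trough_satisfaction = function(x) {
    match(check_enum(x, trough_levels, "trough satisfaction"), trough_levels) - 1L
  }
)

#' Bucket a raw clinical value into an item's answer bands
#'
#' Maps a raw measurement (annualised rate, count, score change, adherence
#' percentage, or a categorical level) onto the severity rank of the answer
#' band containing it, using the item's named banding rule. Continuous
#' annualised rates are rounded half-up to the nearest integer before banding.
#'
#' @param item An [instrument_item()] with a `bucketing_rule`.
#' @param raw_value The raw measurement (numeric, or a character level for the
#'   trend and trough-satisfaction items).
#' @return The severity rank (integer, 0 = optimal band).
#' @examples
#' cfg <- load_instrument("B", "prophylaxis")
#' abr_item <- config_item(cfg, "abr")
#' bucket(abr_item, 2.4)  # rounds to 2 -> band "1-2" -> rank 1
#' @export
bucket <- function(item, raw_value) {
  stopifnot(inherits(item, "hmt_item"))
  if (is.null(item$bucketing_rule)) {
    stop(sprintf("item '%s' has no bucketing rule; answer it directly", item$id),
         call. = FALSE)
  }
  rule <- bucketing_rules[[item$bucketing_rule]]
  if (is.null(rule)) {
    stop(sprintf("unknown bucketing rule '%s'", item$bucketing_rule), call. = FALSE)
  }
  rank <- rule(raw_value)
  if (rank >= item$scale_size) {
    stop(sprintf("rule '%s' produced rank %d for a %d-point item",
                 item$bucketing_rule, rank, item$scale_size), call. = FALSE)
  }
  rank
}

#' Look up an item of a configuration by id
#'
#' @param config An [instrument_config()].
#' @param id Item identifier.
#' @return The [instrument_item()].
#' @export
config_item <- function(config, id) {
  items <- config_items(config)
  if (!id %in% names(items)) {
    stop(sprintf("no item '%s' in the %s %s configuration", id,
                 config$disease, config$setting), call. = FALSE)
  }
  items[[id]]
}

# derive the raw value each bucketing rule consumes from a one-row
# measurement record (named list or one-row data frame)
raw_value_for_rule <- function(rule, rec) {
  get <- function(field) {
    v <- rec[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      stop(sprintf("measurement field '%s' is required but missing", field),
           call. = FALSE)
    }
    v
  }
  eq5d <- function(prefix) {
    dims <- c("mobility", "selfcare", "activities", "pain", "anxiety")
    vapply(paste0(prefix, dims), get, numeric(1))
  }
  switch(rule,
    abr = annualized_rate(get("bleed_count"), get("follow_up_days")),
    ajbr = {
      jb <- get("joint_bleed_count")
      if (!is.null(rec$bleed_count) && !is.na(rec$bleed_count) &&
          jb > rec$bleed_count) {
        stop("joint_bleed_count exceeds bleed_count", call. = FALSE)
      }
      annualized_rate(jb, get("follow_up_days"))
    },
    adherence = {
      given <- get("infusions_given")
      expected <- get("infusions_expected")
      if (given > 2 * expected) {
        warning(sprintf("infusions_given (%g) far exceeds infusions_expected (%g)",
                        given, expected), call. = FALSE)
      }
      adherence_pct(given, expected)
    },
    lss_current = level_sum_score(eq5d("eq5d_")),
    lss_change = level_sum_score(eq5d("eq5d_")) -
      level_sum_score(eq5d("eq5d_baseline_")),
    hjhs_delta = get("hjhs_delta"),
    headus_delta = get("headus_delta"),
    pj_count = get("pj_count"),
    tj_count = get("tj_count"),
    pj_trend = get("pj_trend"),
    tj_trend = get("tj_trend"),
    trough_satisfaction = get("trough_satisfaction"),
    stop(sprintf("unknown bucketing rule '%s'", rule), call. = FALSE)
  )
}

#' Build a response set from raw clinical measurements
#'
#' Computes the raw quantities every bucketed item of the configuration needs
#' (ABR and AJBR via [annualized_rate()], adherence via [adherence_pct()],
#' EQ-5D-5L level sum scores and their change) from one patient's measurement
#' record, buckets each into the item's answer bands, and returns a complete
#' [response_set()].
#'
#' @param config An [instrument_config()].
#' @param record Named list or one-row data frame with `RawMeasurements`
#'   fields: `bleed_count`, `joint_bleed_count`, `follow_up_days`,
#'   `infusions_given`, `infusions_expected`, `eq5d_<dim>` (and
#'   `eq5d_baseline_<dim>` where the configuration scores QoL change, with
#'   dimensions `mobility`, `selfcare`, `activities`, `pain`, `anxiety`),
#'   `hjhs_delta`, `headus_delta`, `pj_count`, `tj_count`, `pj_trend`,
#'   `tj_trend`, `trough_satisfaction`. Only the fields the configuration's
#'   items consume are required.
#' @param patient_id Patient identifier for the resulting response set.
#' @param assessment_date Optional ISO-8601 date string.
#' @return A [response_set()].
#' @export
responses_from_raw <- function(config, record, patient_id = "patient",
                               assessment_date = NULL) {
  stopifnot(inherits(config, "hmt_instrument"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  items <- config_items(config)
  answers <- vapply(items, function(it) {
    if (is.null(it$bucketing_rule)) {
      stop(sprintf("item '%s' has no bucketing rule; supply its answer directly",
                   it$id), call. = FALSE)
    }
    bucket(it, raw_value_for_rule(it$bucketing_rule, record))
  }, integer(1))
  response_set(patient_id, config$disease, config$setting, answers,
               assessment_date = assessment_date)
}
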