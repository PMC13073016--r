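#' Construct a response option
#'
#' A response option is one answer band of a single-choice item. Options are
#' ordered by clinical severity: `severity_rank` 0 is the clinically optimal
#' answer and the highest rank is the worst. `value` is the standardised
#' response value r on a 0-1 scale used by the scoring engine; it must be 0 at
#' rank 0 and 1 at the highest rank of the item.
#'
#' @param label Free-text answer label as shown to the clinician.
#' @param severity_rank Integer >= 0; 0 = clinically optimal.
#' @param value Number in \[0, 1\]; the standardised response value.
#' @return An object of class `hmt_option`.
#' @export
response_option <- function(label, severity_rank, value) {
  stopifnot(is.character(label), length(label) == 1L)
  severity_rank <- as.integer(severity_rank)
  if (is.na(severity_rank) || severity_rank < 0L) {
    stop("severity_rank must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop("value must be a number in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, severity_rank = severity_rank, value = as.numeric(value)),
    class = "hmt_option"
  )
}

#' Construct an instrument item
#'
#' An item is a single-choice question on a three- or four-point ordinal scale,
#' carrying an item weight w expressed as a percentage of its clinical domain.
#' Items that can be answered from raw clinical measurements name a
#' `bucketing_rule` (see [bucket()]).
#'
#' @param id Short stable identifier (snake_case), shared across configurations
#'   so longitudinal records are comparable.
#' @param text Question text.
#' @param scale_size 3 or 4.
#' @param weight_pct Item weight w in percent of the domain, > 0.
#' @param options List of [response_option()] in severity order (rank 0 first).
#' @param bucketing_rule Optional name of a raw-measure banding rule.
#' @return An object of class `hmt_item`.
#' @export
instrument_item <- function(id, text, scale_size, weight_pct, options,
                            bucketing_rule = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  scale_size <- as.integer(scale_size)
  if (!scale_size %in% c(3L, 4L)) {
    stop("scale_size must be 3 or 4", call. = FALSE)
  }
  if (!is.numeric(weight_pct) || weight_pct <= 0 || weight_pct > 100) {
    stop("weight_pct must be in (0, 100]", call. = FALSE)
  }
  options <- lapply(options, function(o) {
    if (inherits(o, "hmt_option")) o else do.call(response_option, o)
  })
  structure(
    list(
      id = id, text = text, scale_size = scale_size,
      weight_pct = as.numeric(weight_pct), options = options,
      bucketing_rule = bucketing_rule
    ),
    class = "hmt_item"
  )
}

#' Construct a clinical domain
#'
#' @param id Short stable identifier.
#' @param name One of `"pharmacokinetics"`, `"bleeding_episodes"`,
#'   `"joint_health"`, `"adherence_qol"`.
#' @param weight_pct Section weight W in percent of the instrument.
#' @param items Non-empty list of [instrument_item()].
#' @return An object of class `hmt_domain`.
#' @export
instrument_domain <- function(id, name, weight_pct, items) {
  name <- match.arg(name, c("pharmacokinetics", "bleeding_episodes",
                            "joint_health", "adherence_qol"))
  if (length(items) == 0L) stop("a domain needs at least one item", call. = FALSE)
  items <- lapply(items, function(it) {
    if (inherits(it, "hmt_item")) it else do.call(instrument_item, it)
  })
  structure(
    list(id = id, name = name, weight_pct = as.numeric(weight_pct), items = items),
    class = "hmt_domain"
  )
}

#' Construct an instrument configuration
#'
#' A configuration is one disease x treatment-setting questionnaire: an ordered
#' list of weighted clinical domains, each holding weighted items. Prophylaxis
#' configurations carry four domains (including pharmacokinetics); on-demand
#' configurations carry three, the pharmacokinetics domain being clinically
#' inapplicable under episodic treatment.
#'
#' @param disease `"A"` or `"B"`.
#' @param setting `"prophylaxis"` or `"on_demand"`.
#' @param domains Non-empty list of [instrument_domain()].
#' @param provenance Free text recording where the weights come from.
#' @return An object of class `hmt_instrument`.
#' @seealso [load_instrument()], [validate_instrument()]
#' @export
instrument_config <- function(disease, setting, domains, provenance = "") {
  disease <- match.arg(disease, c("A", "B"))
  setting <- match.arg(setting, c("prophylaxis", "on_demand"))
  if (length(domains) == 0L) stop("domains must be non-empty", call. = FALSE)
  domains <- lapply(domains, function(d) {
    if (inherits(d, "hmt_domain")) d else do.call(instrument_domain, d)
  })
  structure(
    list(disease = disease, setting = setting, domains = domains,
         provenance = provenance),
    class = "hmt_instrument"
  )
}

#' Validate an instrument configuration
#'
#' Checks every structural invariant of the instrument model and returns a
#' report of violations rather than throwing: domain weights summing to 100,
#' item weights summing to 100 within each domain, option counts matching the
#' scale size, severity ranks forming a gap-free 0..k-1 sequence, and
#' standardised values anchored at 0 (optimal) and 1 (worst) and non-decreasing
#' in severity. Setting-specific structure is checked too: on-demand
#' configurations must not contain a pharmacokinetics domain and carry exactly
#' three domains; prophylaxis configurations carry exactly four.
#'
#' @param config An [instrument_config()].
#' @param tolerance Numeric tolerance on the weight sums (default `1e-6`).
#' @return A data frame with columns `location` and `message`; zero rows means
#'   the configuration is valid.
#' @export
validate_instrument <- function(config, tolerance = 1e-6) {
  stopifnot(inherits(config, "hmt_instrument"))
  loc <- character()
  msg <- character()
  note <- function(where, what) {
    loc <<- c(loc, where)
    msg <<- c(msg, what)
  }

  dsum <- sum(vapply(config$domains, function(d) d$weight_pct, numeric(1)))
  if (abs(dsum - 100) > tolerance) {
    note("config", sprintf("domain weights sum to %g, expected 100", dsum))
  }
  dnames <- vapply(config$domains, function(d) d$name, character(1))
  if (anyDuplicated(dnames)) {
    note("config", "duplicated domain names")
  }
  if (config$setting == "on_demand") {
    if ("pharmacokinetics" %in% dnames) {
      note("config", "on-demand configurations must not contain a pharmacokinetics domain")
    }
    if (length(config$domains) != 3L) {
      note("config", sprintf("on-demand configurations carry 3 domains, found %d",
                             length(config$domains)))
    }
  } else {
    if (length(config$domains) != 4L) {
      note("config", sprintf("prophylaxis configurations carry 4 domains, found %d",
                             length(config$domains)))
    }
  }

  all_ids <- character()
  for (d in config$domains) {
    dloc <- paste0("domain:", d$id)
    isum <- sum(vapply(d$items, function(it) it$weight_pct, numeric(1)))
    if (abs(isum - 100) > tolerance) {
      note(dloc, sprintf("item weights sum to %g, expected 100", isum))
    }
    if (length(d$items) == 1L && abs(d$items[[1]]$weight_pct - 100) > tolerance) {
      note(dloc, "single-item domains must carry item weight 100")
    }
    for (it in d$items) {
      iloc <- paste0(dloc, "/item:", it$id)
      all_ids <- c(all_ids, it$id)
      k <- length(it$options)
      if (k != it$scale_size) {
        note(iloc, sprintf("%d options but scale_size %d", k, it$scale_size))
        next
      }
      ranks <- vapply(it$options, function(o) o$severity_rank, integer(1))
      vals <- vapply(it$options, function(o) o$value, numeric(1))
      if (!identical(sort(ranks), 0:(k - 1L))) {
        note(iloc, "severity ranks must be 0..k-1 with no gaps")
        next
      }
      ord <- order(ranks)
      vals <- vals[ord]
      if (vals[1] != 0) note(iloc, "value at severity rank 0 must be 0")
      if (vals[k] != 1) note(iloc, "value at the highest severity rank must be 1")
      if (any(diff(vals) < 0)) note(iloc, "values must be non-decreasing in severity rank")
    }
  }
  if (anyDuplicated(all_ids)) {
    note("config", sprintf("duplicated item ids: %s",
                           paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  data.frame(location = loc, message = msg, stringsAsFactors = FALSE)
}

# flat list of all items of a config, names = item ids
config_items <- function(config) {
  items <- unlist(lapply(config$domains, function(d) d$items), recursive = FALSE)
  names(items) <- vapply(items, function(it) it$id, character(1))
  items
}

#' @export
print.hmt_instrument <- function(x, ...) {
  cat(sprintf("<haemophilia monitoring instrument: haemophilia %s, %s>\n",
              x$disease, sub("_", "-", x$setting)))
  for (d in x$domains) {
    cat(sprintf("  %-18s W = %3g%%  (%d item%s)\n", d$name, d$weight_pct,
                length(d$items), if (length(d$items) > 1) "s" else ""))
    for (it in d$items) {
      cat(sprintf("    %-14s w = %3g%%  %d-point\n", it$id, it$weight_pct,
                  it$scale_size))
    }
  }
  invisible(x)
}
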