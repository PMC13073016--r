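#' Load a bundled or user-supplied instrument configuration
#'
#' The package ships the four published configurations (haemophilia A and B,
#' each for prophylaxis and on-demand treatment) with the consensus-derived
#' section and item weights. `load_instrument("B", "prophylaxis")` returns the
#' haemophilia B prophylaxis instrument; alternatively `path` loads a
#' user-supplied configuration file in the same JSON format, validated before
#' use (validation violations for user files are reported as an error unless
#' `renormalise = TRUE` rescales near-100 weight sums first).
#'
#' @param disease `"A"` or `"B"` (ignored when `path` is given).
#' @param setting `"prophylaxis"` or `"on_demand"` (ignored when `path` is given).
#' @param path Optional path to a user-supplied configuration file.
#' @param renormalise If `TRUE`, rescale domain and item weight sums to exactly
#'   100 before validating a user-supplied file (user-derived medians need not
#'   sum to 100).
#' @return A validated [instrument_config()].
#' @examples
#' cfg <- load_instrument("B", "prophylaxis")
#' cfg
#' @export
load_instrument <- function(disease = c("A", "B"),
                            setting = c("prophylaxis", "on_demand"),
                            path = NULL, renormalise = FALSE) {
  if (is.null(path)) {
    disease <- as.character(disease)[1]
    setting <- as.character(setting)[1]
    if (!disease %in% c("A", "B") || !setting %in% c("prophylaxis", "on_demand")) {
      stop(sprintf(
        "no bundled configuration for disease '%s', setting '%s'; available: A/B x prophylaxis/on_demand",
        disease, setting), call. = FALSE)
    }
    path <- system.file("extdata", "instruments",
                        sprintf("haemophilia_%s_%s.json", disease, setting),
                        package = "haemoscore")
    if (!nzchar(path)) {
      stop("bundled configuration file not found; broken installation", call. = FALSE)
    }
    cfg <- read_instrument(path)
  } else {
    if (!file.exists(path)) {
      stop(sprintf("configuration file not found: %s", path), call. = FALSE)
    }
    cfg <- read_instrument(path)
    if (renormalise) cfg <- renormalise_weights(cfg)
  }
  report <- validate_instrument(cfg)
  if (nrow(report) > 0L) {
    stop(sprintf("invalid instrument configuration (%s):\n%s", path,
                 paste0("  ", report$location, ": ", report$message, collapse = "\n")),
         call. = FALSE)
  }
  cfg
}

#' Read an instrument configuration file
#'
#' Parses the JSON instrument format (see the schema shipped at
#' `system.file("extdata", "instrument-schema.json", package = "haemoscore")`).
#' No validation beyond structural parsing is performed; use
#' [validate_instrument()] or [load_instrument()].
#'
#' @param path Path to a JSON configuration file.
#' @return An [instrument_config()].
#' @export
read_instrument <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse instrument file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop(sprintf("instrument file '%s': missing field '%s' in %s",
                   path, field, where), call. = FALSE)
    }
    x[[field]]
  }
  domains <- lapply(need(raw, "domains", "top level"), function(d) {
    items <- lapply(need(d, "items", paste0("domain '", d$id, "'")), function(it) {
      opts <- lapply(need(it, "options", paste0("item '", it$id, "'")), function(o) {
        response_option(
          label = need(o, "label", paste0("an option of item '", it$id, "'")),
          severity_rank = need(o, "severity_rank", paste0("an option of item '", it$id, "'")),
          value = need(o, "value", paste0("an option of item '", it$id, "'"))
        )
      })
      instrument_item(
        id = need(it, "id", "an item"), text = need(it, "text", "an item"),
        scale_size = need(it, "scale_size", paste0("item '", it$id, "'")),
        weight_pct = need(it, "weight_pct", paste0("item '", it$id, "'")),
        options = opts, bucketing_rule = it$bucketing_rule
      )
    })
    instrument_domain(
      id = need(d, "id", "a domain"), name = need(d, "name", "a domain"),
      weight_pct = need(d, "weight_pct", paste0("domain '", d$id, "'")),
      items = items
    )
  })
  instrument_config(
    disease = need(raw, "disease", "top level"),
    setting = need(raw, "setting", "top level"),
    domains = domains,
    provenance = if (is.null(raw$provenance)) "" else raw$provenance
  )
}

#' Write an instrument configuration file
#'
#' Serialises a configuration to the package's JSON format; reading the file
#' back with [read_instrument()] reproduces the configuration field-for-field.
#'
#' @param config An [instrument_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(config, path) {
  stopifnot(inherits(config, "hmt_instrument"))
  out <- list(
    disease = config$disease,
    setting = config$setting,
    provenance = config$provenance,
    domains = lapply(config$domains, function(d) {
      list(
        id = d$id, name = d$name, weight_pct = d$weight_pct,
        items = lapply(d$items, function(it) {
          x <- list(
            id = it$id, text = it$text, scale_size = it$scale_size,
            weight_pct = it$weight_pct,
            options = lapply(it$options, function(o) {
              list(label = o$label, severity_rank = o$severity_rank, value = o$value)
            })
          )
          if (!is.null(it$bucketing_rule)) x$bucketing_rule <- it$bucketing_rule
          x
        })
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# rescale domain weights and per-domain item weights so each sums to 100
renormalise_weights <- function(config) {
  dsum <- sum(vapply(config$domains, function(d) d$weight_pct, numeric(1)))
  config$domains <- lapply(config$domains, function(d) {
    d$weight_pct <- d$weight_pct * 100 / dsum
    isum <- sum(vapply(d$items, function(it) it$weight_pct, numeric(1)))
    d$items <- lapply(d$items, function(it) {
      it$weight_pct <- it$weight_pct * 100 / isum
      it
    })
    d
  })
  config
}

#' Published consensus medians and IQRs
#'
#' Returns the published per-slot consensus statistics for all four instrument
#' configurations: the median weight (in percent) and the interquartile range
#' of the expert panel's round-two constant-sum allocations, at domain level
#' and, for multi-item domains, at item level. These are the weights the
#' bundled configurations carry; all 44 entries reached consensus (IQR below
#' the pre-specified threshold of 8 points).
#'
#' @return A data frame with columns `disease`, `setting`, `scope`
#'   (`"domain"` or `"items:<domain id>"`), `slot_id`, `median_pct`, `iqr`.
#' @export
published_consensus <- function() {
  path <- system.file("extdata", "published_consensus.csv", package = "haemoscore")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
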