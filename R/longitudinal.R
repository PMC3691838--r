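#' Corneal zone and follow-up time vocabularies
#'
#' The cornea is divided into thirds by distance from the episcleral
#' plaque: the applicator zone (directly beneath the plaque), the central
#' zone, and the distal zone. Follow-up examinations are at baseline
#' (pre-irradiation), 3 days, and 1, 4 and 7 months.
#'
#' @return character vector of the closed vocabulary, in order.
#' @export
cornealZones <- function() c("applicator", "central", "distal")

#' @rdname cornealZones
#' @export
timePoints <- function() c("baseline", "day3", "month1", "month4", "month7")

assertZone <- function(zone) {
  if (!zone %in% cornealZones())
    stop("unknown zone: ", zone, " (expected one of ",
         paste(cornealZones(), collapse = ", "), ")")
  zone
}

#' Percent-of-baseline trajectory for one metric in one zone
#'
#' Longitudinal degeneration/regeneration expressed as a percentage of the
#' pre-irradiation level, computed from group means:
#' \code{percent(t) = 100 * value(t) / value(baseline)}, rounded half away
#' from zero to the nearest integer. Baseline maps to 100 by construction.
#' The computation is scale-invariant: rescaling all values by a positive
#' constant leaves the percentages unchanged.
#'
#' @param series data.frame with columns \code{metric}, \code{zone},
#'   \code{timepoint}, \code{value} (e.g. \code{\link{snpStudyMorphometry}}).
#' @param metric metric name to select.
#' @param zone corneal zone to select.
#' @return data.frame with columns \code{timepoint}, \code{percent}
#'   (integer), ordered baseline first.
#' @export
percentOfBaseline <- function(series, metric, zone) {
  assertZone(zone)
  s <- series[series$metric == metric & series$zone == zone, , drop = FALSE]
  if (nrow(s) == 0L) stop("no rows for metric '", metric, "' in zone '",
                          zone, "'")
  if (anyDuplicated(s$timepoint))
    stop("more than one aggregate value per timepoint")
  base <- s$value[s$timepoint == "baseline"]
  if (length(base) != 1L || !is.finite(base) || base <= 0)
    stop("baseline value missing or not positive")
  s <- s[order(match(s$timepoint, timePoints())), , drop = FALSE]
  data.frame(timepoint = s$timepoint,
             percent = as.integer(roundHalfAway(100 * s$value / base)))
}

#' Aggregate replicate scans
#'
#' At least three scans are acquired per zone and visit; replicates are
#' combined as arithmetic mean with sample standard deviation (n - 1
#' denominator; SD 0 for a single value).
#'
#' @param values numeric vector of replicate measurements (>= 1 value).
#' @return named list: \code{mean}, \code{sd}, \code{n}.
#' @export
aggregateReplicates <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("at least one finite value required")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values))
}

#' @rdname aggregateReplicates
#' @param probs quantile probabilities (default 0.5, the median).
#' @export
replicateQuantile <- function(values, probs = 0.5) {
  if (length(values) == 0L) stop("at least one value required")
  stats::quantile(values, probs, names = FALSE, type = 7)
}

#' Corneal sensation as percent of baseline
#'
#' Cochet-Bonnet aesthesiometry: a 60 mm nylon monofilament is applied at
#' full length and shortened in 5 mm steps until the touch is felt, so
#' readings are multiples of 5 in [0, 60] mm (longer = better sensation).
#' The percentage is \code{100 * filament / baseline}, rounded half away
#' from zero to the nearest integer.
#'
#' @param filamentMm filament length at response, mm.
#' @param baselineMm pre-irradiation filament length, mm (0 < x <= 60).
#' @return integer percent.
#' @export
sensationPercent <- function(filamentMm, baselineMm) {
  if (any(baselineMm <= 0) || any(baselineMm > 60))
    stop("baseline must be in (0, 60] mm")
  if (any(filamentMm < 0) || any(filamentMm > 60))
    stop("filament length must be in [0, 60] mm")
  as.integer(roundHalfAway(100 * filamentMm / baselineMm))
}

#' Classify corneal sensation as normal
#'
#' Normal sensation is defined as a Cochet-Bonnet reading between 50 and
#' 60 mm.
#'
#' @param filamentMm filament length, mm.
#' @return logical vector.
#' @export
isNormalSensation <- function(filamentMm)
  filamentMm >= 50 & filamentMm <= 60

#' Percent-of-baseline table for every (zone, metric) series
#'
#' Applies \code{\link{percentOfBaseline}} to each zone x metric
#' combination present in the input; series without a positive baseline
#' are skipped with a warning.
#'
#' @param series long data.frame (\code{metric}, \code{zone},
#'   \code{timepoint}, \code{value}).
#' @return data.frame: metric, zone, timepoint, percent.
#' @export
percentOfBaselineTable <- function(series) {
  combos <- unique(series[, c("metric", "zone")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch(
      percentOfBaseline(series, combos$metric[i], combos$zone[i]),
      error = function(e) {
        warning("skipping ", combos$metric[i], "/", combos$zone[i], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res))
      out[[length(out) + 1L]] <- cbind(metric = combos$metric[i],
                                       zone = combos$zone[i], res)
  }
  if (!length(out))
    return(data.frame(metric = character(), zone = character(),
                      timepoint = character(), percent = integer()))
  do.call(rbind, out)
}
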