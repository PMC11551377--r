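#' Define an analysis period
#'
#' Periods are half-open intervals `[start, end)` so every flux step belongs
#' to exactly one of two adjacent periods.
#'
#' @param label Period label (e.g. "baseline", "heatwave").
#' @param start,end Interval boundaries (POSIXct or parseable character,
#'   `start < end`).
#' @return A list of class `"flux_period"`.
#' @export
period <- function(label, start, end) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(start < end)) stop("period start must be before end", call. = FALSE)
  structure(list(label = label, start = start, end = end),
            class = "flux_period")
}

#' Heat-wave and baseline periods recorded on a simulated series
#'
#' Convenience accessor for the heat-wave boundaries that
#' [gen_met_series()] and [simulate_flux_series()] attach to their output.
#'
#' @param x A met or flux series carrying `heatwave_start` / `heatwave_end`
#'   attributes.
#' @return A list with elements `baseline` and `heatwave`, each a
#'   [period()].
#' @export
default_periods <- function(x) {
  hs <- attr(x, "heatwave_start")
  he <- attr(x, "heatwave_end")
  if (is.null(hs) || is.null(he))
    stop("series carries no heat-wave attributes; supply periods explicitly",
         call. = FALSE)
  list(baseline = period("baseline", min(x$timestamp), hs),
       heatwave = period("heatwave", hs, he))
}

#' Summarise a flux series over a period
#'
#' Arithmetic mean and maximum of the flux over all steps with
#' `start <= timestamp < end` (half-open rule: a step on the boundary belongs
#' to the period starting there).
#'
#' @param flux Data frame with columns `timestamp` and `flux` (and
#'   optionally `ppfd` when `daytime_only` is used).
#' @param prd A [period()].
#' @param daytime_only Restrict to daytime steps (`ppfd > 0`)? Default FALSE
#'   (all steps, day and night).
#' @return A list of class `"period_summary"` with `label`, `mean_flux`,
#'   `max_flux` (nmol m-2 s-1) and `n_steps`.
#' @examples
#' fx <- data.frame(timestamp = as.POSIXct("2022-08-15", tz = "UTC") +
#'                    0:2 * 3600, flux = c(0, 4, 8))
#' summarize_period(fx, period("all", "2022-08-15", "2022-08-16"))
#' @export
summarize_period <- function(flux, prd, daytime_only = FALSE) {
  stopifnot(inherits(prd, "flux_period"))
  inside <- flux$timestamp >= prd$start & flux$timestamp < prd$end
  if (daytime_only) {
    if (is.null(flux$ppfd))
      stop("daytime_only requires a ppfd column", call. = FALSE)
    inside <- inside & flux$ppfd > 0
  }
  if (!any(inside))
    stop(sprintf("period '%s' contains no flux steps", prd$label),
         call. = FALSE)
  f <- flux$flux[inside]
  structure(list(label = prd$label, mean_flux = mean(f), max_flux = max(f),
                 n_steps = sum(inside)), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.3g, max %.3g nmol m-2 s-1 over %d steps\n",
              x$label, x$mean_flux, x$max_flux, x$n_steps))
  invisible(x)
}

#' Percent change in mean flux between two periods
#'
#' `100 * (during - before) / before` on the period mean fluxes; e.g. a rise
#' from 2.5 to 10.5 nmol m-2 s-1 is +320%.
#'
#' @param before,during [summarize_period()] results.
#' @return Percent change (positive for an increase).
#' @export
percent_change <- function(before, during) {
  stopifnot(inherits(before, "period_summary"),
            inherits(during, "period_summary"))
  if (before$mean_flux <= 0)
    stop("percent change undefined: baseline mean flux is not positive",
         call. = FALSE)
  100 * (during$mean_flux - before$mean_flux) / before$mean_flux
}

#' Compare two species' flux series over a common period
#'
#' Computes `mean_ratio_pct = 100 * mean_a / mean_b` (how much of species b's
#' emission species a accounts for) and
#' `peak_excess_pct = 100 * (max_a - max_b) / max_b` (by how much species a's
#' peak exceeds species b's) over steps inside the period. The two series
#' must share identical timestamps.
#'
#' @param a,b Flux series data frames (`timestamp`, `flux`).
#' @param prd A [period()].
#' @return A list with `mean_ratio_pct` and `peak_excess_pct`.
#' @export
species_comparison <- function(a, b, prd) {
  stopifnot(inherits(prd, "flux_period"))
  if (nrow(a) != nrow(b) || !all(a$timestamp == b$timestamp))
    stop("flux series are not aligned on identical timestamps", call. = FALSE)
  sa <- summarize_period(a, prd)
  sb <- summarize_period(b, prd)
  if (sb$mean_flux <= 0 || sb$max_flux <= 0)
    stop("comparison undefined: reference species has non-positive flux",
         call. = FALSE)
  list(mean_ratio_pct = 100 * sa$mean_flux / sb$mean_flux,
       peak_excess_pct = 100 * (sa$max_flux - sb$max_flux) / sb$max_flux)
}
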