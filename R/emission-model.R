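#' Coefficients of the MEGANv2.1 leaf-level activity factors
#'
#' Default parameter set of the temperature and light activity factors of the
#' Model of Emissions of Gases and Aerosols from Nature, version 2.1
#' (isoprene, sun leaves). `c_t1` and `c_t2` (kJ mol-1) shape the rising and
#' falling limbs of the temperature response; `eopt_base`, `topt_base` (K)
#' and `topt_slope` set the optimum and its acclimation to the trailing
#' 240-h temperature; `p0_sun` (umol m-2 s-1), `alpha_base`, `alpha_slope`
#' and `cp_base` parameterise the saturating light response and its
#' acclimation to trailing 24-h/240-h daytime PPFD. The activity factors
#' equal 1 at MEGAN standard conditions (leaf temperature 303 K,
#' T24 = T240 = 297 K, PPFD 1000 umol m-2 s-1 with P24 = P240 = 200).
#'
#' @param ... Named overrides of individual coefficients.
#' @return A validated list of class `"megan_coefficients"`.
#' @export
megan_coefficients <- function(...) {
  coef <- list(c_t1 = 95, c_t2 = 230, gas_const = 0.00831,
               eopt_base = 2.034, topt_base = 313, topt_slope = 0.6,
               p0_sun = 200, alpha_base = 0.004, alpha_slope = 0.0005,
               cp_base = 0.0468)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(coef))
  if (length(unknown))
    stop("unknown MEGAN coefficient(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  coef[names(dots)] <- dots
  if (any(vapply(coef, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all MEGAN coefficients must be positive numbers", call. = FALSE)
  if (coef$c_t2 <= coef$c_t1)
    stop("MEGAN coefficients require c_t2 > c_t1", call. = FALSE)
  structure(coef, class = "megan_coefficients")
}

# trailing mean over a window of w steps; shorter-than-nominal windows at the
# start of the series use all available data (expanding window)
trailing_mean <- function(x, w) {
  n <- seq_along(x)
  cs <- c(0, cumsum(x))
  from <- pmax(n - w, 0L)
  (cs[n + 1L] - cs[from + 1L]) / (n - from)
}

# trailing mean of x restricted to steps where flag is TRUE; 0 where the
# window contains no flagged step
trailing_mean_flagged <- function(x, flag, w) {
  n <- seq_along(x)
  csx <- c(0, cumsum(x * flag))
  csf <- c(0, cumsum(as.numeric(flag)))
  from <- pmax(n - w, 0L)
  num <- csx[n + 1L] - csx[from + 1L]
  den <- csf[n + 1L] - csf[from + 1L]
  ifelse(den > 0, num / den, 0)
}

#' Add trailing acclimation averages to a meteorological series
#'
#' Computes the acclimation drivers of the MEGAN activity factors: `t24` and
#' `t240`, the trailing 24-h and 240-h mean air temperatures, and `p24` and
#' `p240`, the trailing mean PPFD over daytime steps (`ppfd > 0`) within the
#' same windows. At the start of the series, windows shorter than nominal use
#' all available data (expanding window); where a window contains no daytime
#' step the daytime PPFD mean is 0 (and the light activity factor is 0).
#'
#' @param met Data frame with columns `timestamp` (regular, strictly
#'   increasing), `t_air` (K) and `ppfd` (umol m-2 s-1).
#' @return The input with columns `t24`, `t240` (K), `p24`, `p240`
#'   (umol m-2 s-1) appended.
#' @export
rolling_acclimation <- function(met) {
  needed <- c("timestamp", "t_air", "ppfd")
  missing <- setdiff(needed, names(met))
  if (length(missing))
    stop("met series lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(met)
  if (n < 1L) stop("met series is empty", call. = FALSE)
  if (n > 1L) {
    dt <- diff(as.numeric(met$timestamp))
    if (any(dt <= 0))
      stop("met timestamps must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-6 * dt[1])
      stop("met timestamps must have a uniform step; run gap filling first",
           call. = FALSE)
    step_min <- dt[1] / 60
  } else {
    step_min <- attr(met, "timestep_min") %||% 60
  }
  w24 <- max(1L, as.integer(round(24 * 60 / step_min)))
  w240 <- 10L * w24
  day <- met$ppfd > 0
  met$t24 <- trailing_mean(met$t_air, w24)
  met$t240 <- trailing_mean(met$t_air, w240)
  met$p24 <- trailing_mean_flagged(met$ppfd, day, w24)
  met$p240 <- trailing_mean_flagged(met$ppfd, day, w240)
  met
}

#' MEGAN default temperature activity factor
#'
#' The MEGANv2.1 temperature response with acclimation: with
#' `Topt = topt_base + topt_slope * (t240 - 297)` and
#' `Eopt = eopt_base * exp(0.05 (t24 - 297)) * exp(0.05 (t240 - 297))`,
#' \deqn{\gamma_T = E_{opt} \frac{C_{T2} e^{C_{T1} x}}
#'   {C_{T2} - C_{T1} (1 - e^{C_{T2} x})}, \quad
#'   x = \frac{1/T_{opt} - 1/T}{R}.}
#' At the optimum (`x = 0`) the quotient is 1 and the value is `Eopt`; at
#' standard conditions (leaf temperature 303 K, `t24 = t240 = 297` K) the
#' value is 1. Over 20-35 degrees C at standard acclimation the response is
#' roughly equivalent to an exponential with Q10 near 3.
#'
#' @param t_leaf Leaf temperature (K); vectorised.
#' @param t24,t240 Trailing 24-h / 240-h mean air temperature (K).
#' @param coef A [megan_coefficients()] set.
#' @return Dimensionless activity factor(s).
#' @examples
#' gamma_t_megan(303, 297, 297)  # standard conditions: 1
#' @export
gamma_t_megan <- function(t_leaf, t24, t240, coef = megan_coefficients()) {
  if (any(t_leaf <= 0) || any(t24 <= 0) || any(t240 <= 0))
    stop("temperatures must be in kelvin and > 0", call. = FALSE)
  topt <- coef$topt_base + coef$topt_slope * (t240 - 297)
  eopt <- coef$eopt_base * exp(0.05 * (t24 - 297)) * exp(0.05 * (t240 - 297))
  x <- (1 / topt - 1 / t_leaf) / coef$gas_const
  # cap the exponent arguments: for t_leaf far above Topt, exp(c_t2 * x)
  # overflows double precision while the ratio itself tends to 0
  e1 <- exp(pmin(coef$c_t1 * x, 700))
  e2 <- exp(pmin(coef$c_t2 * x, 700))
  eopt * coef$c_t2 * e1 / (coef$c_t2 - coef$c_t1 * (1 - e2))
}

#' MEGAN light activity factor
#'
#' Saturating light response with acclimation to the trailing daytime PPFD:
#' `alpha = alpha_base - alpha_slope * ln(p240)`,
#' `C_P = cp_base * exp(alpha_slope * (p24 - p0_sun)) * p240^0.6`, and
#' \deqn{\gamma_P = C_P \frac{\alpha \, PPFD}{\sqrt{1 + \alpha^2 PPFD^2}}.}
#' Zero light gives exactly zero activity (isoprene synthesis is
#' light-dependent, with no storage pool); very high light saturates at
#' `C_P`. A series with no daylight history (`p240 = 0`) returns 0 rather
#' than evaluating `ln(0)`.
#'
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1); vectorised.
#' @param p24,p240 Trailing 24-h / 240-h daytime-mean PPFD (umol m-2 s-1).
#' @param coef A [megan_coefficients()] set.
#' @return Dimensionless activity factor(s).
#' @examples
#' gamma_p(1000, 200, 200)  # about 0.90
#' gamma_p(0, 200, 200)     # exactly 0: light off, emission off
#' @export
gamma_p <- function(ppfd, p24, p240, coef = megan_coefficients()) {
  if (any(ppfd < 0) || any(p24 < 0) || any(p240 < 0))
    stop("PPFD inputs must be >= 0", call. = FALSE)
  out <- numeric(length(ppfd))
  p24 <- rep_len(p24, length(ppfd))
  p240 <- rep_len(p240, length(ppfd))
  ok <- p240 > 0
  if (any(!ok & ppfd > 0))
    message("gamma_p: p240 = 0 (no daylight history) for ",
            sum(!ok & ppfd > 0), " step(s); returning 0")
  alpha <- coef$alpha_base - coef$alpha_slope * log(p240[ok])
  c_p <- coef$cp_base * exp(coef$alpha_slope * (p24[ok] - coef$p0_sun)) *
    p240[ok]^0.6
  out[ok] <- c_p * alpha * ppfd[ok] / sqrt(1 + alpha^2 * ppfd[ok]^2)
  out
}

#' Species parameters for the leaf emission model
#'
#' @param name Species label.
#' @param emission_factor Emission at standard conditions on a leaf-area
#'   basis (nmol m-2 s-1).
#' @param lai Leaf area index (m2 leaf per m2 ground); scales leaf-area flux
#'   to ground area.
#' @param response Temperature-response specification: either
#'   `list(kind = "exponential", q10 = ..., t_ref = 30)` for a fitted
#'   exponential response, or `list(kind = "megan_default")` for the MEGAN
#'   response with acclimation.
#' @return A validated list of class `"species_params"`.
#' @examples
#' species_params("C. praegracilis", 2, 2,
#'                list(kind = "exponential", q10 = 7.2))
#' @export
species_params <- function(name, emission_factor, lai,
                           response = list(kind = "megan_default")) {
  check_scalar(emission_factor, "emission_factor", nonneg = TRUE)
  check_scalar(lai, "lai", nonneg = TRUE)
  if (is.null(response$kind) ||
      !response$kind %in% c("exponential", "megan_default"))
    stop("response$kind must be 'exponential' or 'megan_default'",
         call. = FALSE)
  if (response$kind == "exponential") {
    if (is.null(response$q10)) stop("exponential response needs q10",
                                    call. = FALSE)
    check_scalar(response$q10, "q10", positive = TRUE)
    response$t_ref <- response$t_ref %||% 30
  }
  structure(list(name = name, emission_factor = emission_factor, lai = lai,
                 response = response), class = "species_params")
}

#' Leaf-scale emission flux for one or more meteorological steps
#'
#' Single-layer leaf model: ground-area flux is
#' `emission_factor * lai * gamma_p * gamma_t`, with `gamma_t` either the
#' MEGAN default response ([gamma_t_megan()]) or a fitted exponential
#' response ([gamma_exponential()], leaf temperature converted to degrees C).
#' Leaf temperature is taken equal to air temperature (met stations measure
#' air temperature only; this is an explicit model assumption).
#'
#' @param species A [species_params()] object.
#' @param t_air Air temperature (K); vectorised.
#' @param ppfd PPFD (umol m-2 s-1).
#' @param t24,t240,p24,p240 Acclimation averages (see [rolling_acclimation()]).
#' @param coef A [megan_coefficients()] set.
#' @return Flux in nmol m-2 s-1 (ground-area basis).
#' @export
leaf_flux <- function(species, t_air, ppfd, t24, t240, p24, p240,
                      coef = megan_coefficients()) {
  stopifnot(inherits(species, "species_params"))
  g_p <- gamma_p(ppfd, p24, p240, coef)
  g_t <- switch(species$response$kind,
    megan_default = gamma_t_megan(t_air, t24, t240, coef),
    exponential = gamma_exponential(t_air - 273.15, species$response$q10,
                                    species$response$t_ref))
  species$emission_factor * species$lai * g_p * g_t
}

#' Simulate an emission flux series over a meteorological series
#'
#' Applies [leaf_flux()] at every step of an acclimation-augmented
#' meteorological series. Deterministic: output rows align 1:1 with the met
#' timestamps.
#'
#' @param species A [species_params()] object.
#' @param met Met series with acclimation columns (from
#'   [rolling_acclimation()]).
#' @param coef A [megan_coefficients()] set.
#' @return Data frame with `timestamp`, `species`, `flux` (nmol m-2 s-1,
#'   ground-area) and `ppfd` (carried through for daytime filtering),
#'   carrying the met series' heat-wave attributes if present.
#' @export
simulate_flux_series <- function(species, met, coef = megan_coefficients()) {
  stopifnot(inherits(species, "species_params"))
  acc <- c("t24", "t240", "p24", "p240")
  if (!all(acc %in% names(met)))
    stop("met series lacks acclimation columns (",
         paste(setdiff(acc, names(met)), collapse = ", "),
         "); run rolling_acclimation() first", call. = FALSE)
  flux <- leaf_flux(species, met$t_air, met$ppfd, met$t24, met$t240,
                    met$p24, met$p240, coef)
  out <- data.frame(timestamp = met$timestamp, species = species$name,
                    flux = flux, ppfd = met$ppfd)
  attr(out, "heatwave_start") <- attr(met, "heatwave_start")
  attr(out, "heatwave_end") <- attr(met, "heatwave_end")
  attr(out, "response_kind") <- species$response$kind
  out
}
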