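#' Convert leaf-chamber records to area-based emission rates
#'
#' Standard dynamic-chamber mass balance: the emission rate per unit leaf area
#' is the mixing-ratio enhancement across the chamber times the molar flow of
#' air through it,
#' \deqn{F = (\chi_{out} - \chi_{in}) \cdot 10^{-9} \; \dot n / A,}
#' with the molar flow from the ideal gas law at the gas temperature and
#' pressure at which the flow was metered, \eqn{\dot n = P \dot V / (R T)}.
#' Because ppbv is a mole fraction of 1e-9, the result in mol m-2 s-1 times
#' 1e9 is numerically `delta_chi_ppbv * n_dot / leaf_area` in nmol m-2 s-1.
#'
#' A negative enhancement (`chi_out < chi_in`) yields a valid negative flux
#' (uptake or depletion) and a warning; it is retained, not clamped, so that
#' downstream fitting can decide how to treat it.
#'
#' @param chi_in,chi_out Isoprene mixing ratio at chamber inlet/outlet (ppbv).
#' @param flow Chamber flow rate (L min-1, metered at `t_gas`, `pressure`).
#' @param leaf_area Enclosed leaf area (m2).
#' @param t_gas Gas temperature at the flow meter (K). Default 298.15.
#' @param pressure Pressure at the flow meter (Pa). Default 101325.
#' @param background Optional per-record background offset (ppbv) subtracted
#'   from the enhancement, e.g. an empty-chamber blank. Default 0.
#' @return Emission rate(s) in nmol m-2 s-1 (vectorised over all arguments).
#' @examples
#' compute_emission_rate(chi_in = 0, chi_out = 10, flow = 1, leaf_area = 0.01)
#' @export
compute_emission_rate <- function(chi_in, chi_out, flow, leaf_area,
                                  t_gas = 298.15, pressure = 101325,
                                  background = 0) {
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("chamber record invalid: flow must be > 0", call. = FALSE)
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0))
    stop("chamber record invalid: leaf_area must be > 0", call. = FALSE)
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("chamber record invalid: pressure must be > 0", call. = FALSE)
  if (any(!is.finite(t_gas)) || any(t_gas <= 0))
    stop("chamber record invalid: t_gas must be > 0", call. = FALSE)
  delta_chi <- chi_out - chi_in - background
  if (any(delta_chi < 0))
    warning(sprintf(
      "%d record(s) with chi_out < chi_in: negative flux retained (uptake/depletion)",
      sum(delta_chi < 0)), call. = FALSE)
  v_dot <- flow * 1e-3 / 60                       # L min-1 -> m3 s-1
  n_dot <- pressure * v_dot / (GAS_CONSTANT_SI * t_gas)  # mol s-1
  delta_chi * n_dot / leaf_area                   # nmol m-2 s-1 (see above)
}

GAS_CONSTANT_SI <- 8.314462618  # J mol-1 K-1

#' Convert a table of chamber records to emission observations
#'
#' @param records Data frame with columns `chi_in`, `chi_out`, `flow`,
#'   `leaf_area`, plus `t_leaf` and `ppfd` carried through. Optional columns
#'   `t_gas` (K), `pressure` (Pa), `background` (ppbv) and `timestamp`
#'   override the defaults of [compute_emission_rate()].
#' @return Data frame of emission observations (`t_leaf`, `ppfd`, `flux`,
#'   plus `timestamp` if present) ready for [fit_q10()].
#' @export
chamber_to_flux <- function(records) {
  needed <- c("t_leaf", "ppfd", "chi_in", "chi_out", "flow", "leaf_area")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("chamber table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  flux <- compute_emission_rate(
    chi_in = records$chi_in, chi_out = records$chi_out,
    flow = records$flow, leaf_area = records$leaf_area,
    t_gas = records$t_gas %||% 298.15,
    pressure = records$pressure %||% 101325,
    background = records$background %||% 0)
  out <- data.frame(t_leaf = records$t_leaf, ppfd = records$ppfd, flux = flux)
  if ("timestamp" %in% names(records))
    out <- cbind(timestamp = records$timestamp, out)
  out
}

#' Read a chamber-record CSV
#'
#' One record per row with header-named columns (`t_leaf`, `ppfd`, `chi_in`,
#' `chi_out`, `flow`, `leaf_area`, optionally `timestamp`, `t_gas`,
#' `pressure`, `background`). Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return Data frame of chamber records.
#' @export
read_chamber_csv <- function(path) {
  if (!file.exists(path))
    stop("chamber CSV not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
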