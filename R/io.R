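#' Read a meteorological CSV
#'
#' Tolerant of station-export dialects (e.g. MesoWest downloads): lines
#' starting with `#` are skipped, column names are configurable, and units
#' must be declared — temperature in degrees C or K, light as PPFD or as
#' shortwave radiation converted with a configurable quantum yield
#' (default 2.1 umol J-1). Rows with missing values in the used columns are
#' dropped and counted; gaps larger than the modal timestep are reported.
#'
#' @param path Path to the CSV file.
#' @param timestamp_col,temp_col Column names. Defaults `"timestamp"`,
#'   `"t_air"`.
#' @param temp_unit `"K"` or `"C"`.
#' @param light_col Column holding the light variable. Default `"ppfd"`.
#' @param light_unit `"ppfd"` (umol m-2 s-1) or `"shortwave"` (W m-2,
#'   converted to PPFD).
#' @param sw_to_ppfd Conversion factor for shortwave radiation
#'   (umol photons per J). Default 2.1.
#' @param tz Time zone of the timestamps. Default `"UTC"`.
#' @return Data frame with `timestamp` (POSIXct), `t_air` (K), `ppfd`
#'   (umol m-2 s-1); attribute `n_dropped` counts removed rows.
#' @export
read_met_csv <- function(path, timestamp_col = "timestamp",
                         temp_col = "t_air", temp_unit = c("K", "C"),
                         light_col = "ppfd",
                         light_unit = c("ppfd", "shortwave"),
                         sw_to_ppfd = 2.1, tz = "UTC") {
  temp_unit <- match.arg(temp_unit)
  light_unit <- match.arg(light_unit)
  if (!file.exists(path)) stop("met CSV not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c(timestamp_col, temp_col, light_col))
    if (!col %in% names(raw))
      stop("met CSV lacks declared column '", col, "'", call. = FALSE)
  ts <- as.POSIXct(raw[[timestamp_col]], tz = tz)
  t_air <- as.numeric(raw[[temp_col]])
  light <- as.numeric(raw[[light_col]])

  ok <- !is.na(ts) & !is.na(t_air) & !is.na(light)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_met_csv: dropped ", n_dropped, " row(s) with missing values")
  ts <- ts[ok]; t_air <- t_air[ok]; light <- light[ok]
  if (length(ts) == 0) stop("met CSV contains no usable rows", call. = FALSE)

  dup <- duplicated(ts)
  if (any(dup))
    stop("duplicated timestamp in met CSV: ",
         format(ts[dup][1], "%Y-%m-%d %H:%M:%S %Z"), call. = FALSE)
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("met timestamps are not strictly increasing", call. = FALSE)
  if (length(ts) > 2) {
    dt <- diff(as.numeric(ts))
    step <- as.numeric(names(sort(table(dt), decreasing = TRUE))[1])
    n_gaps <- sum(dt > step * 1.5)
    if (n_gaps > 0)
      message("read_met_csv: ", n_gaps, " gap(s) larger than the ",
              step / 60, "-min modal step")
  }

  if (temp_unit == "C") t_air <- t_air + 273.15
  ppfd <- if (light_unit == "shortwave") pmax(0, light) * sw_to_ppfd
          else pmax(0, light)
  out <- data.frame(timestamp = ts, t_air = t_air, ppfd = ppfd)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a meteorological or flux series to CSV
#'
#' Plain CSV with ISO timestamps; round-trips through [read_met_csv()] (for
#' met series) at full precision.
#'
#' @param x Data frame with a `timestamp` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  out <- x
  out$timestamp <- format(x$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Q10 fit report as JSON
#'
#' Emits the fitted parameters, confidence interval, exclusion counts and
#' the normalised response sampled on a temperature grid, for plotting and
#' provenance.
#'
#' @param fit A [fit_q10()] result.
#' @param path Output path.
#' @param t_grid Temperature grid for the sampled curve (degrees C).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, t_grid = seq(15, 45, by = 0.5)) {
  stopifnot(inherits(fit, "q10_fit"))
  report <- list(
    q10 = fit$q10, e_ref = fit$e_ref, t_ref = fit$t_ref,
    t_fit_max = fit$t_fit_max,
    q10_ci = c(fit$q10_ci_low, fit$q10_ci_high),
    n_used = fit$n_used, n_excluded_temp = fit$n_excluded_temp,
    n_excluded_nonpos = fit$n_excluded_nonpos,
    ci_method = fit$ci_method, method = fit$method,
    normalized_curve = normalized_response(fit, t_grid))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order, the stages `chamber` (chamber records to emission
#' rates), `fit` (Q10 estimation), `met` (read or simulate forcing and add
#' acclimation averages), `flux` (emission simulation per species) and
#' `analysis` (period summaries, percent change, species comparison). Any
#' stage absent from the configuration is skipped; e.g. a config with only
#' simulated met, species entries carrying a supplied Q10, and periods needs
#' no chamber inputs. All outputs, a YAML echo of the configuration and a
#' run log (package version, seed, filter counts) are written to
#' `config$output_dir`. Re-running with an identical configuration is
#' reproducible.
#'
#' @param config A named list or a path to a YAML file. Recognised entries:
#'   \describe{
#'     \item{seed}{Top-level seed from which all stage seeds derive.}
#'     \item{output_dir}{Directory for outputs (created if needed).}
#'     \item{chamber}{`list(path=)` CSV of chamber records, or
#'       `list(simulate=)` arguments for [chamber_sim_config()].}
#'     \item{fit}{Options for [fit_q10()] (`t_ref`, `t_fit_max`,
#'       `ci_method`, `n_boot`).}
#'     \item{met}{`list(path=, temp_unit=, light_unit=, ...)` for
#'       [read_met_csv()], or `list(simulate=)` arguments for
#'       [met_sim_config()].}
#'     \item{species}{List of species entries, each with `name`,
#'       `emission_factor`, `lai` and `response` (a supplied `q10`, the
#'       string `"megan_default"`, or `"fitted"` to use the fit stage's
#'       Q10).}
#'     \item{periods}{List of `list(label=, start=, end=)`; omitted for
#'       simulated met, whose heat-wave block defines baseline/heatwave.}
#'     \item{analysis}{`list(daytime_only=, compare=c(a, b))`.}
#'   }
#' @return A list with elements `fit`, `flux` (named list of flux series),
#'   `summaries`, `percent_change`, `comparison` and `paths` of written
#'   files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("pipeline config not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% stop("config needs output_dir",
                                         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- c(
    sprintf("sedgeflux %s pipeline run",
            as.character(utils::packageVersion("sedgeflux"))),
    sprintf("seed: %d", seed))

  # fail fast on declared input files before any computation
  for (stage in c("chamber", "met")) {
    p <- config[[stage]]$path
    if (!is.null(p) && !file.exists(p))
      stop("pipeline stage '", stage, "': input file not found: ", p,
           call. = FALSE)
  }

  # -- chamber stage --------------------------------------------------------
  obs <- NULL
  if (!is.null(config$chamber)) {
    obs <- with_stage("chamber", {
      if (!is.null(config$chamber$path)) {
        chamber_to_flux(read_chamber_csv(config$chamber$path))
      } else if (!is.null(config$chamber$simulate)) {
        args <- config$chamber$simulate
        args$seed <- args$seed %||% seed
        gen_chamber_series(do.call(chamber_sim_config, args))
      } else stop("chamber stage needs 'path' or 'simulate'", call. = FALSE)
    })
    paths$observations <- file.path(out_dir, "emission_observations.csv")
    utils::write.csv(obs, paths$observations, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("chamber: %d observations", nrow(obs)))
  }

  # -- fit stage ------------------------------------------------------------
  fit <- NULL
  if (!is.null(config$fit)) {
    if (is.null(obs))
      stop("pipeline stage 'fit': no emission observations; configure the ",
           "chamber stage", call. = FALSE)
    fo <- config$fit
    fit <- with_stage("fit", fit_q10(
      obs, t_ref = fo$t_ref %||% 30, t_fit_max = fo$t_fit_max %||% 35,
      ci_method = fo$ci_method %||% "normal",
      n_boot = fo$n_boot %||% 1000L, seed = seed))
    paths$fit_report <- file.path(out_dir, "fit_report.json")
    write_fit_report(fit, paths$fit_report)
    log_lines <- c(log_lines, sprintf(
      "fit: q10 %.4g [%.4g, %.4g], n_used %d, excluded %d above %g degC, %d non-positive",
      fit$q10, fit$q10_ci_low, fit$q10_ci_high, fit$n_used,
      fit$n_excluded_temp, fit$t_fit_max, fit$n_excluded_nonpos))
  }

  # -- met stage ------------------------------------------------------------
  met <- NULL
  if (!is.null(config$met)) {
    met <- with_stage("met", {
      if (!is.null(config$met$path)) {
        args <- config$met
        args$path <- NULL
        do.call(read_met_csv, c(list(path = config$met$path), args))
      } else if (!is.null(config$met$simulate)) {
        args <- config$met$simulate
        args$seed <- args$seed %||% seed
        gen_met_series(do.call(met_sim_config, args))
      } else stop("met stage needs 'path' or 'simulate'", call. = FALSE)
    })
    met <- rolling_acclimation(met)
    log_lines <- c(log_lines, sprintf(
      "met: %d steps, %d dropped rows", nrow(met),
      attr(met, "n_dropped") %||% 0L))
  }

  # -- flux stage -----------------------------------------------------------
  flux <- list()
  coef <- do.call(megan_coefficients, config$megan %||% list())
  if (!is.null(config$species)) {
    if (is.null(met))
      stop("pipeline stage 'flux': no met series; configure the met stage",
           call. = FALSE)
    for (sp in config$species) {
      resp <- sp$response %||% "megan_default"
      if (identical(resp, "fitted")) {
        if (is.null(fit))
          stop("species '", sp$name, "' requests the fitted response but no ",
               "fit stage ran", call. = FALSE)
        resp <- list(kind = "exponential", q10 = fit$q10, t_ref = fit$t_ref)
      } else if (identical(resp, "megan_default")) {
        resp <- list(kind = "megan_default")
      } else if (is.numeric(resp)) {
        resp <- list(kind = "exponential", q10 = resp, t_ref = 30)
      }
      params <- species_params(sp$name, sp$emission_factor, sp$lai, resp)
      fx <- with_stage(paste0("flux:", sp$name),
                       simulate_flux_series(params, met, coef))
      flux[[sp$name]] <- fx
      p <- file.path(out_dir, paste0(
        "flux_", gsub("[^A-Za-z0-9]+", "_", sp$name), ".csv"))
      write_series_csv(fx, p)
      paths[[paste0("flux_", sp$name)]] <- p
    }
  }

  # -- analysis stage -------------------------------------------------------
  summaries <- NULL; pct <- NULL; comparison <- NULL
  if (length(flux) && !isFALSE(config$analysis %||% TRUE)) {
    prds <- if (!is.null(config$periods)) {
      lapply(config$periods, function(p) period(p$label, p$start, p$end))
    } else {
      default_periods(flux[[1]])
    }
    daytime <- isTRUE(config$analysis$daytime_only)
    rows <- list()
    pct <- list()
    for (nm in names(flux)) {
      per_sp <- lapply(prds, function(p)
        with_stage("analysis", summarize_period(flux[[nm]], p, daytime)))
      for (s in per_sp)
        rows[[length(rows) + 1L]] <- data.frame(
          species = nm, period = s$label, mean_flux = s$mean_flux,
          max_flux = s$max_flux, n_steps = s$n_steps)
      if (length(per_sp) >= 2L)
        pct[[nm]] <- percent_change(per_sp[[1]], per_sp[[2]])
    }
    summaries <- do.call(rbind, rows)
    paths$summaries <- file.path(out_dir, "period_summaries.csv")
    utils::write.csv(summaries, paths$summaries, row.names = FALSE)
    cmp <- config$analysis$compare
    if (!is.null(cmp) && all(cmp %in% names(flux)) && length(prds) >= 2L)
      comparison <- species_comparison(flux[[cmp[1]]], flux[[cmp[2]]],
                                       prds[[2]])
  }

  # -- provenance -----------------------------------------------------------
  paths$config_echo <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(config, paths$config_echo)
  paths$run_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$run_log)

  list(fit = fit, flux = flux, summaries = summaries, percent_change = pct,
       comparison = comparison, paths = paths)
}

# wrap a stage so failures carry the stage name
with_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
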