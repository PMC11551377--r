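#' Fit an exponential Q10 temperature response to emission observations
#'
#' Fits \eqn{E(T) = E_{ref} \cdot Q_{10}^{(T - T_{ref})/10}} by ordinary
#' least squares in log space: `ln(flux)` is regressed on
#' `(t_leaf - t_ref) / 10`, so `q10 = exp(slope)` and `e_ref = exp(intercept)`.
#' The log-linear form is closed-form, matches the multiplicative error
#' structure of chamber flux data, and recovers noiseless synthetic data
#' exactly. Nonlinear least squares on the untransformed fluxes is available
#' via `method = "nls"` for sensitivity analysis.
#'
#' Observations with `t_leaf` above `t_fit_max` are excluded before fitting
#' (emission is less stable at high leaf temperature, where activity can
#' decline or become erratic); the boundary is inclusive by default
#' (`t_leaf <= t_fit_max` is kept) and controlled by `inclusive`.
#' Non-positive fluxes are excluded before the log transform. Both exclusion
#' counts are reported.
#'
#' The 95% CI on Q10 is, by default, the normal-theory (t-based) interval on
#' the log-slope mapped through `exp`. `ci_method = "bootstrap"` resamples
#' observations with replacement (`n_boot` replicates, seeded) and takes
#' percentile limits.
#'
#' @param obs Data frame of emission observations with columns `t_leaf`
#'   (degrees C) and `flux` (nmol m-2 s-1).
#' @param t_ref Reference temperature (degrees C) at which `e_ref` is
#'   reported and the normalised response equals 1. Default 30.
#' @param t_fit_max Upper leaf-temperature limit for fitting (degrees C).
#'   Default 35.
#' @param inclusive Keep points with `t_leaf == t_fit_max`? Default TRUE.
#' @param ci_method `"normal"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @param method `"ols"` (log-space least squares, default) or `"nls"`.
#' @return An object of class `"q10_fit"`: a list with `q10`, `e_ref`,
#'   `t_ref`, `t_fit_max`, `q10_ci_low`, `q10_ci_high`, `n_used`,
#'   `n_excluded_temp`, `n_excluded_nonpos`, `ci_method`, `method` and the
#'   underlying `fit` object.
#' @examples
#' obs <- gen_chamber_series(chamber_sim_config(true_q10 = 8, e_ref = 2,
#'                                              t_min = 20, t_max = 35,
#'                                              noise_cv = 0))
#' fit_q10(obs)  # recovers q10 = 8, e_ref = 2 exactly
#' @export
fit_q10 <- function(obs, t_ref = 30, t_fit_max = 35, inclusive = TRUE,
                    ci_method = c("normal", "bootstrap"), n_boot = 1000L,
                    seed = 1L, method = c("ols", "nls")) {
  ci_method <- match.arg(ci_method)
  method <- match.arg(method)
  if (!all(c("t_leaf", "flux") %in% names(obs)))
    stop("observations need columns t_leaf and flux", call. = FALSE)

  in_temp <- if (inclusive) obs$t_leaf <= t_fit_max else obs$t_leaf < t_fit_max
  pos <- obs$flux > 0
  n_excluded_temp <- sum(!in_temp)
  n_excluded_nonpos <- sum(in_temp & !pos)
  keep <- obs[in_temp & pos, , drop = FALSE]

  if (nrow(keep) < 2L)
    stop("cannot fit Q10: fewer than 2 usable observations after filtering ",
         sprintf("(%d excluded above %g degC, %d non-positive)",
                 n_excluded_temp, t_fit_max, n_excluded_nonpos),
         call. = FALSE)
  if (length(unique(keep$t_leaf)) < 2L)
    stop("cannot fit Q10: degenerate design, all leaf temperatures identical",
         call. = FALSE)

  dat <- data.frame(x = (keep$t_leaf - t_ref) / 10, flux = keep$flux)
  x <- dat$x
  if (method == "ols") {
    fit <- stats::lm(log(flux) ~ x, data = dat)
    co <- stats::coef(fit)
    q10 <- exp(unname(co["x"]))
    e_ref <- exp(unname(co["(Intercept)"]))
  } else {
    # start from the closed-form log-space solution; scaleOffset keeps the
    # convergence test meaningful for (near-)zero-residual data
    ols <- stats::lm.fit(cbind(1, x), log(dat$flux))$coefficients
    start <- list(log_e_ref = ols[[1]], log_q10 = ols[[2]])
    fit <- stats::nls(flux ~ exp(log_e_ref) * exp(log_q10 * x),
                      data = dat, start = start,
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    co <- stats::coef(fit)
    q10 <- exp(unname(co["log_q10"]))
    e_ref <- exp(unname(co["log_e_ref"]))
  }

  if (ci_method == "normal") {
    # t-based Wald interval on the log slope, mapped through exp; a
    # zero-residual (noiseless) fit legitimately collapses it to the estimate
    slope_row <- if (method == "ols") "x" else "log_q10"
    smry <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    est <- smry$coefficients[slope_row, "Estimate"]
    se <- smry$coefficients[slope_row, "Std. Error"]
    df_resid <- nrow(dat) - 2L
    if (!is.finite(se)) se <- 0
    q10_ci <- exp(est + c(-1, 1) * stats::qt(0.975, df_resid) * se)
  } else {
    n <- nrow(keep)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(keep$t_leaf[idx])) < 2L) return(NA_real_)
        b <- stats::lm.fit(cbind(1, x[idx]), log(keep$flux[idx]))
        exp(b$coefficients[2L])
      }, numeric(1))
    })
    q10_ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(q10 = q10, e_ref = e_ref, t_ref = t_ref,
                 t_fit_max = t_fit_max,
                 q10_ci_low = min(q10_ci), q10_ci_high = max(q10_ci),
                 n_used = nrow(keep), n_excluded_temp = n_excluded_temp,
                 n_excluded_nonpos = n_excluded_nonpos,
                 ci_method = ci_method, method = method, fit = fit),
            class = "q10_fit")
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf("Q10 temperature-response fit (%s, %s CI)\n", x$method,
              x$ci_method))
  cat(sprintf("  Q10   = %.3g  [95%% CI %.3g - %.3g]\n",
              x$q10, x$q10_ci_low, x$q10_ci_high))
  cat(sprintf("  E_ref = %.3g nmol m-2 s-1 at %g degC\n", x$e_ref, x$t_ref))
  cat(sprintf("  n = %d used; %d above %g degC and %d non-positive excluded\n",
              x$n_used, x$n_excluded_temp, x$t_fit_max, x$n_excluded_nonpos))
  invisible(x)
}

#' Exponential temperature activity factor
#'
#' The normalised exponential response `q10^((t_leaf - t_ref) / 10)`: 1 at
#' the reference temperature, multiplied by `q10` for every 10 degrees C rise.
#'
#' @param t_leaf Leaf temperature (degrees C); vectorised.
#' @param q10 Q10 of the response (> 0).
#' @param t_ref Reference temperature (degrees C). Default 30.
#' @return Dimensionless activity factor(s).
#' @examples
#' gamma_exponential(40, q10 = 7.2)  # one decade step: 7.2
#' @export
gamma_exponential <- function(t_leaf, q10, t_ref = 30) {
  if (any(!is.finite(q10)) || any(q10 <= 0))
    stop("q10 must be > 0", call. = FALSE)
  q10^((t_leaf - t_ref) / 10)
}

#' Effective Q10 of an arbitrary temperature-activity function
#'
#' Summarises any temperature response as the equivalent exponential Q10 over
#' an interval: `(gamma(t_high) / gamma(t_low))^(10 / (t_high - t_low))`.
#' For an exponential response this returns its Q10 regardless of interval;
#' for the default MEGAN response it gives the interval-dependent effective
#' value commonly quoted as "about 3".
#'
#' @param gamma A function of leaf temperature in degrees C returning a
#'   dimensionless activity.
#' @param t_low,t_high Interval endpoints (degrees C, `t_low < t_high`).
#' @return Dimensionless effective Q10.
#' @examples
#' effective_q10(function(t) gamma_exponential(t, q10 = 5), 18, 33)  # 5
#' @export
effective_q10 <- function(gamma, t_low, t_high) {
  if (t_low >= t_high)
    stop("t_low must be < t_high", call. = FALSE)
  g_low <- gamma(t_low)
  g_high <- gamma(t_high)
  if (!is.finite(g_low) || g_low <= 0)
    stop("gamma(t_low) must be positive for an effective Q10", call. = FALSE)
  (g_high / g_low)^(10 / (t_high - t_low))
}

#' Sample a fitted, normalised response on a temperature grid
#'
#' @param fit A [fit_q10()] result.
#' @param t_grid Leaf temperatures (degrees C) at which to evaluate.
#' @return Data frame with `t_leaf` and `gamma` (activity normalised to 1 at
#'   the fit's reference temperature).
#' @export
normalized_response <- function(fit, t_grid = seq(15, 45, by = 0.5)) {
  stopifnot(inherits(fit, "q10_fit"))
  data.frame(t_leaf = t_grid,
             gamma = gamma_exponential(t_grid, fit$q10, fit$t_ref))
}
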