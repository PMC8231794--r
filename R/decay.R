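#' Fit a first-order degradation model to a concentration-time series
#'
#' Estimates `(C0, k)` in `C(t) = C0 * exp(-k t)` by unweighted nonlinear
#' least squares on the linear concentration scale, with all replicates
#' entering as independent observations. Start values come from a log-linear
#' regression of `log(C)` on `t`; the nonlinear refinement uses
#' [stats::nls()] (port algorithm, `k` bounded to `[0, 10]`/h). The standard
#' error of `k` is taken from the curvature of the least-squares objective at
#' the optimum.
#'
#' @param series a `concentration_series` data.frame (see
#'   [sim_decay_series()]) or any data.frame with columns `time_h`,
#'   `analyte`, `conc_mg_L`; only rows with `analyte == analyte_name` are
#'   fitted.
#' @param analyte_name analyte to fit, default `"meropenem"`.
#' @param scale `"linear"` (default) fits on the concentration scale;
#'   `"log"` performs the log-linear least-squares fit instead (exact on
#'   noise-free data, used as a cross-check).
#' @return An object of class `decay_fit`: a list with elements `k`,
#'   `c0_hat`, `se_k`, `residual_sd`, `half_life`, `r_squared`, `n_obs`,
#'   `scale`.
#' @examples
#' s <- sim_decay_series(k = 0.025, c0 = 50, noise = assay_noise(cv = 0),
#'                       seed = 1, matrix = "serum")
#' fit_first_order_decay(s)
#' @export
fit_first_order_decay <- function(series, analyte_name = "meropenem",
                                  scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.data.frame(series) ||
      !all(c("time_h", "conc_mg_L") %in% names(series))) {
    stop("`series` must have columns time_h and conc_mg_L", call. = FALSE)
  }
  d <- series
  if ("analyte" %in% names(d)) d <- d[d$analyte == analyte_name, , drop = FALSE]
  t <- d$time_h
  y <- d$conc_mg_L
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop("non-finite values in series", call. = FALSE)
  }
  if (length(unique(t)) < 3L) {
    stop("need >= 3 distinct time points to fit a decay curve", call. = FALSE)
  }
  if (all(y <= 0)) stop("all concentrations are zero; cannot fit", call. = FALSE)

  # log-linear start (and the log-scale fit itself)
  pos <- y > 0
  ll <- stats::lm(log(y[pos]) ~ t[pos])
  k0 <- max(0, -unname(stats::coef(ll)[2]))
  c00 <- exp(unname(stats::coef(ll)[1]))

  if (scale == "log") {
    k_hat <- k0
    c0_hat <- c00
    fitted <- c0_hat * exp(-k_hat * t)
    # a noise-free series fits the log-linear model exactly; summary.lm warns
    # about the zero residual variance, which is expected here
    se_k <- suppressWarnings(summary(ll)$coefficients[2, 2])
  } else {
    fit <- stats::nls(
      y ~ c0 * exp(-k * t),
      start = list(c0 = c00, k = max(k0, 1e-6)),
      lower = c(c0 = 0, k = 0), upper = c(c0 = Inf, k = 10),
      algorithm = "port",
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
    )
    cf <- stats::coef(fit)
    k_hat <- unname(cf["k"])
    c0_hat <- unname(cf["c0"])
    if (k_hat > 10 - 1e-8) {
      stop("decay fit diverged: k at upper bound (10/h)", call. = FALSE)
    }
    fitted <- c0_hat * exp(-k_hat * t)
    se_k <- tryCatch(sqrt(stats::vcov(fit)["k", "k"]), error = function(e) NA_real_)
  }

  res <- y - fitted
  p <- 2L
  rsd <- if (length(y) > p) sqrt(sum(res^2) / (length(y) - p)) else NA_real_
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_

  structure(
    list(k = k_hat, c0_hat = c0_hat, se_k = se_k, residual_sd = rsd,
         half_life = if (k_hat > 0) log(2) / k_hat else Inf,
         r_squared = r2, n_obs = length(y), scale = scale),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order decay fit (", x$scale, " scale, n = ", x$n_obs, ")\n",
      sep = "")
  cat(sprintf("  k        = %.6g /h (SE %.3g)\n", x$k, x$se_k))
  cat(sprintf("  C0       = %.6g mg/L\n", x$c0_hat))
  cat(sprintf("  t1/2     = %.4g h\n", x$half_life))
  cat(sprintf("  R^2      = %.4f, residual SD %.3g mg/L\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' Relative recovery after a given time under first-order decay
#'
#' @param k first-order rate constant, per hour (>= 0).
#' @param t time in hours (>= 0); vectorised.
#' @return Recovery as a percent of the initial concentration,
#'   `100 * exp(-k t)`.
#' @examples
#' recovery_at(0.006, 24)  # ~86.6 % in saline at 22 C
#' recovery_at(0.025, 24)  # ~54.9 % in serum at 37 C
#' @export
recovery_at <- function(k, t) {
  stopifnot_scalar(k, "k", lower = 0)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative", call. = FALSE)
  }
  100 * exp(-k * t)
}

#' Pharmacopoeial stability window
#'
#' Time until the relative recovery of a first-order-decaying drug crosses a
#' threshold (pharmacopoeially 90 percent of the initial concentration):
#' `-log(threshold) / k`.
#'
#' @param k first-order rate constant, per hour (> 0; `k = 0` returns `Inf`,
#'   an indefinitely stable solution).
#' @param threshold retained fraction, in `(0, 1]`. Default 0.90.
#' @return Stability window in hours (`Inf` when `k = 0`).
#' @examples
#' stability_window(0.006)  # ~17.56 h for 2 % meropenem in saline
#' @export
stability_window <- function(k, threshold = 0.90) {
  stopifnot_scalar(k, "k", lower = 0)
  stopifnot_scalar(threshold, "threshold", lower = 0, upper = 1,
                   strict_lower = TRUE)
  if (k == 0) return(Inf)
  -log(threshold) / k
}

#' First-order half-life
#'
#' @param k first-order rate constant, per hour (> 0).
#' @return `log(2) / k`, hours.
#' @examples
#' half_life(0.025)  # ~27.7 h in buffered serum at 37 C
#' @export
half_life <- function(k) {
  stopifnot_scalar(k, "k", lower = 0, strict_lower = TRUE)
  log(2) / k
}

#' Theoretical (equimolar-conversion) metabolite curve
#'
#' The metabolite concentration that full molar conversion of degraded parent
#' would produce: `(C0 - C0 exp(-k t)) * MM_metabolite / MM_parent`. Observed
#' ORM falls short of this curve because the ORM is itself further converted.
#'
#' @param c0 initial parent concentration, mg/L (> 0).
#' @param k first-order rate constant, per hour (>= 0).
#' @param times times in hours; vectorised.
#' @param mm_parent,mm_metabolite molar masses, g/mol (> 0).
#' @return Theoretical metabolite concentrations, mg/L.
#' @examples
#' theoretical_metabolite_curve(20000, 0.006, 24)
#' @export
theoretical_metabolite_curve <- function(c0, k, times,
                                         mm_parent = meropk_constants$mm_meropenem,
                                         mm_metabolite = meropk_constants$mm_orm) {
  stopifnot_scalar(c0, "c0", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(k, "k", lower = 0)
  stopifnot_scalar(mm_parent, "mm_parent", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(mm_metabolite, "mm_metabolite", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be non-negative", call. = FALSE)
  }
  (c0 - c0 * exp(-k * times)) * mm_metabolite / mm_parent
}

#' Metabolite mass-balance deficit per time point
#'
#' Fraction of the theoretical (equimolar-conversion) metabolite that is
#' missing from the observed metabolite signal:
#' `1 - observed / theoretical` at each sampled time. At times where the
#' theoretical metabolite is zero (t = 0 for any k, or k = 0) the deficit is
#' undefined and returned as `NA` with `defined = FALSE`.
#'
#' @param series a `concentration_series` containing `"orm"` rows.
#' @param fit a `decay_fit` for the parent in the same series.
#' @param mm_parent,mm_metabolite molar masses, g/mol.
#' @return A data.frame with columns `time_h`, `observed_mg_L` (replicate
#'   mean), `theoretical_mg_L`, `deficit`, `defined`.
#' @examples
#' s <- sim_decay_series(k = 0.025, c0 = 50, noise = assay_noise(cv = 0),
#'                       metabolite_yield = 0.8, seed = 1, matrix = "serum")
#' f <- fit_first_order_decay(s)
#' mass_balance_deficit(s, f)
#' @export
mass_balance_deficit <- function(series, fit,
                                 mm_parent = meropk_constants$mm_meropenem,
                                 mm_metabolite = meropk_constants$mm_orm) {
  if (!inherits(fit, "decay_fit")) stop("`fit` must be a decay_fit", call. = FALSE)
  m <- series[series$analyte == "orm", , drop = FALSE]
  if (nrow(m) == 0) stop("series contains no metabolite observations", call. = FALSE)
  obs <- tapply(m$conc_mg_L, m$time_h, mean)
  tt <- as.numeric(names(obs))
  theo <- theoretical_metabolite_curve(fit$c0_hat, fit$k, tt,
                                       mm_parent, mm_metabolite)
  defined <- theo > 0
  deficit <- ifelse(defined, 1 - as.numeric(obs) / theo, NA_real_)
  data.frame(time_h = tt, observed_mg_L = as.numeric(obs),
             theoretical_mg_L = theo, deficit = deficit, defined = defined,
             row.names = NULL)
}

#' Stability report for a fitted degradation curve
#'
#' Summarises a [fit_first_order_decay()] result against the pharmacopoeial
#' stability criterion: rate constant and its standard error, half-life,
#' stability window, recovery after 24 h, and a per-time-point verdict
#' (retained fraction >= threshold, inclusive). Report numbers are rounded
#' half-up to one decimal, matching typical printed precision; the unrounded
#' values are kept alongside.
#'
#' @param fit a `decay_fit`.
#' @param threshold retained fraction defining stability. Default 0.90.
#' @param times time points to issue verdicts for; defaults to the stability
#'   sampling schedule.
#' @return An object of class `stability_report` (a list), convertible to
#'   JSON via [write_stability_report()].
#' @examples
#' s <- sim_decay_series(k = 0.006, c0 = 20000, noise = assay_noise(cv = 0),
#'                       seed = 1)
#' stability_report(fit_first_order_decay(s))
#' @export
stability_report <- function(fit, threshold = 0.90,
                             times = meropk_constants$stability_times) {
  if (!inherits(fit, "decay_fit")) stop("`fit` must be a decay_fit", call. = FALSE)
  rec <- recovery_at(fit$k, times)
  win <- stability_window(fit$k, threshold)
  structure(
    list(
      k_per_h = fit$k,
      se_k = fit$se_k,
      c0_mg_L = fit$c0_hat,
      half_life_h = fit$half_life,
      threshold = threshold,
      stability_window_h = win,
      recovery_24h_percent = recovery_at(fit$k, 24),
      rounded = list(
        k_per_h = round_half_up(fit$k, 3),
        half_life_h = round_half_up(fit$half_life, 1),
        stability_window_h = round_half_up(win, 1),
        recovery_24h_percent = round_half_up(recovery_at(fit$k, 24), 1)
      ),
      verdict = data.frame(
        time_h = times,
        recovery_percent = rec,
        stable = rec >= 100 * threshold
      )
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report (threshold %.0f%%)\n", 100 * x$threshold))
  cat(sprintf("  k = %.4g /h, t1/2 = %.4g h\n", x$k_per_h, x$half_life_h))
  cat(sprintf("  stability window = %.4g h, recovery at 24 h = %.1f%%\n",
              x$stability_window_h, x$recovery_24h_percent))
  n_stable <- sum(x$verdict$stable)
  cat(sprintf("  %d/%d scheduled time points within specification\n",
              n_stable, nrow(x$verdict)))
  invisible(x)
}
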