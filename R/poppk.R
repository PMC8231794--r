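#' Fixed parameters of the steady-state population PK model
#'
#' The model fixes the central volume of distribution to a literature value
#' (steady-state sampling carries no information on V), fixes the
#' spontaneous-decay clearance to the in-vitro serum degradation rate times
#' that volume (`CL_decay = k_serum * V`), and fixes the renal clearance of
#' each patient to their measured GFR (converted from mL/min to L/h).
#'
#' @param v central volume of distribution, L. Default 26.2.
#' @param k_serum in-vitro first-order degradation rate in buffered serum at
#'   37 degrees C, per hour. Default 0.025.
#' @param gfr_factor unit bridge (L/h) per (mL/min). Default 0.06.
#' @return An object of class `fixed_params` with elements `v`, `k_serum`,
#'   `cl_decay` (`= k_serum * v`), `gfr_factor`.
#' @examples
#' fixed_params()            # cl_decay = 0.655 L/h
#' @export
fixed_params <- function(v = 26.2, k_serum = meropk_constants$k_serum,
                         gfr_factor = meropk_constants$gfr_factor) {
  stopifnot_scalar(v, "v", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(k_serum, "k_serum", lower = 0)
  stopifnot_scalar(gfr_factor, "gfr_factor", lower = 0, strict_lower = TRUE)
  structure(
    list(v = v, k_serum = k_serum, cl_decay = cl_decay_from_invitro(k_serum, v),
         gfr_factor = gfr_factor),
    class = "fixed_params"
  )
}

#' @export
print.fixed_params <- function(x, ...) {
  cat(sprintf(
    "Fixed PK parameters: V = %.1f L, k_serum = %.3g /h, CL_decay = %.3g L/h, GFR factor = %.2f\n",
    x$v, x$k_serum, x$cl_decay, x$gfr_factor))
  invisible(x)
}

#' Spontaneous-decay clearance from in-vitro kinetics
#'
#' Converts the in-vitro first-order degradation rate constant measured in
#' buffered serum into an apparent clearance, `CL_decay = k * V`.
#'
#' @param k_serum degradation rate constant, per hour (>= 0).
#' @param v volume of distribution, L (> 0).
#' @return Clearance in L/h.
#' @examples
#' cl_decay_from_invitro(0.025, 26.2)  # 0.655 L/h
#' @export
cl_decay_from_invitro <- function(k_serum, v) {
  stopifnot_scalar(k_serum, "k_serum", lower = 0)
  stopifnot_scalar(v, "v", lower = 0, strict_lower = TRUE)
  k_serum * v
}

#' Individual total clearance under the partitioned-clearance model
#'
#' `CL_i = (GFR_i * gfr_factor + theta_cl_nongfr + CL_decay) * exp(eta)`:
#' one lognormal random effect multiplies the whole clearance sum
#' (inter-individual variability on total clearance). An alternative
#' placement, the random effect on the non-GFR component only, is available
#' via `iiv = "nongfr"`.
#'
#' @param fixed a [fixed_params()] object.
#' @param theta_cl_nongfr typical non-GFR clearance, L/h (>= 0).
#' @param gfr glomerular filtration rate, mL/min (> 0); vectorised.
#' @param eta random effect on the log scale; vectorised with `gfr`.
#' @param iiv placement of the random effect, `"total"` (default) or
#'   `"nongfr"`.
#' @return Clearance(s), L/h.
#' @examples
#' individual_clearance(fixed_params(v = 26.4), 3.6, gfr = 139, eta = 0)
#' @export
individual_clearance <- function(fixed, theta_cl_nongfr, gfr, eta = 0,
                                 iiv = c("total", "nongfr")) {
  iiv <- match.arg(iiv)
  if (!inherits(fixed, "fixed_params")) {
    stop("`fixed` must be a fixed_params() object", call. = FALSE)
  }
  stopifnot_scalar(theta_cl_nongfr, "theta_cl_nongfr", lower = 0)
  if (any(!is.finite(gfr)) || any(gfr <= 0)) stop("`gfr` must be > 0", call. = FALSE)
  if (any(!is.finite(eta))) stop("`eta` must be finite", call. = FALSE)
  if (iiv == "total") {
    (gfr * fixed$gfr_factor + theta_cl_nongfr + fixed$cl_decay) * exp(eta)
  } else {
    gfr * fixed$gfr_factor + theta_cl_nongfr * exp(eta) + fixed$cl_decay
  }
}

#' Steady-state concentration under constant-rate infusion
#'
#' For a one-compartment model with zero-order input and first-order
#' elimination, the steady-state concentration is `Css = rate / CL`,
#' independent of the volume of distribution.
#'
#' @param infusion_rate constant infusion rate, mg/h (>= 0); vectorised.
#' @param cl clearance, L/h (> 0); vectorised.
#' @return Css in mg/L.
#' @examples
#' predict_css(250, 11.4)
#' @export
predict_css <- function(infusion_rate, cl) {
  if (any(!is.finite(infusion_rate)) || any(infusion_rate < 0)) {
    stop("`infusion_rate` must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(cl)) || any(cl <= 0)) stop("`cl` must be > 0", call. = FALSE)
  infusion_rate / cl
}

# ---------------------------------------------------------------------------
# internal likelihood machinery
#
# For the proportional-error steady-state model each patient's data enter the
# likelihood only through (n_i, sum y, sum y^2), and with C(eta) = C0*exp(-eta)
# the negative log joint is
#   g(eta) = K_i - n_i*eta + a_i*e^{2 eta} - b_i*e^{eta}
#            + 0.5*log(2*pi) + log(omega) + eta^2/(2 omega^2),
# with analytic first and second derivatives, so the inner (empirical Bayes)
# mode is found by a vectorised, safeguarded Newton iteration across patients.

prep_patients <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("id", "dv_mg_L", "rate_mg_h", "gfr_ml_min") %in% names(data))) {
    stop("cohort data must have columns id, dv_mg_L, rate_mg_h, gfr_ml_min",
         call. = FALSE)
  }
  d <- data
  if ("analyte" %in% names(d)) d <- d[d$analyte == "meropenem", , drop = FALSE]
  if (nrow(d) == 0) stop("no meropenem observations in data", call. = FALSE)
  if (any(!is.finite(d$dv_mg_L)) || any(d$dv_mg_L < 0)) {
    stop("observed concentrations must be finite and >= 0", call. = FALSE)
  }
  ids <- unique(d$id)
  out <- data.frame(
    id = ids,
    rate = vapply(ids, function(i) d$rate_mg_h[d$id == i][1], numeric(1)),
    gfr = vapply(ids, function(i) d$gfr_ml_min[d$id == i][1], numeric(1)),
    n = vapply(ids, function(i) sum(d$id == i), numeric(1)),
    sumy = vapply(ids, function(i) sum(d$dv_mg_L[d$id == i]), numeric(1)),
    sumy2 = vapply(ids, function(i) sum(d$dv_mg_L[d$id == i]^2), numeric(1))
  )
  if (any(out$gfr <= 0)) stop("GFR must be positive for every patient", call. = FALSE)
  if (any(out$rate < 0)) stop("infusion rate must be >= 0", call. = FALSE)
  out
}

# marginal -2LL and EBEs; pat is the prep_patients() summary
neg2ll_core <- function(theta, omega, sigma, pat, fixed,
                        method = "laplace", nodes = 21) {
  cl_typ <- pat$gfr * fixed$gfr_factor + theta + fixed$cl_decay
  c0 <- pat$rate / cl_typ
  if (any(c0 <= 0)) return(list(value = Inf, eta = rep(NA_real_, nrow(pat))))
  n <- pat$n
  a <- pat$sumy2 / (2 * sigma^2 * c0^2)
  b <- pat$sumy / (sigma^2 * c0)
  K <- n / 2 * log(2 * pi) + n * log(sigma) + n * log(c0) + n / (2 * sigma^2)

  ell <- function(eta) {           # data part; eta vector or matrix (np rows)
    e1 <- exp(eta)
    K - n * eta + a * e1^2 - b * e1
  }

  if (omega == 0) {
    logm <- -ell(rep(0, nrow(pat)))
    return(list(value = -2 * sum(logm), eta = rep(0, nrow(pat)),
                loglik_i = logm))
  }

  gfun <- function(eta) {
    ell(eta) + 0.5 * log(2 * pi) + log(omega) + eta^2 / (2 * omega^2)
  }

  # vectorised safeguarded Newton for the per-patient posterior mode
  eta <- rep(0, nrow(pat))
  conv <- FALSE
  for (it in 1:100) {
    e1 <- exp(eta)
    gp <- -n + 2 * a * e1^2 - b * e1 + eta / omega^2
    gpp <- 4 * a * e1^2 - b * e1 + 1 / omega^2
    gpp_safe <- pmax(gpp, 1e-8)
    step <- gp / gpp_safe
    step <- pmax(pmin(step, 1), -1)
    eta <- eta - step
    if (max(abs(gp)) < 1e-10) { conv <- TRUE; break }
  }
  if (!conv) {                       # per-patient golden-section fallback
    e1 <- exp(eta)
    gp <- -n + 2 * a * e1^2 - b * e1 + eta / omega^2
    bad <- which(abs(gp) > 1e-6)
    for (i in bad) {
      gi <- function(x) {
        e <- exp(x)
        K[i] - n[i] * x + a[i] * e^2 - b[i] * e +
          0.5 * log(2 * pi) + log(omega) + x^2 / (2 * omega^2)
      }
      eta[i] <- stats::optimize(gi, c(-10, 10), tol = 1e-12)$minimum
    }
  }

  e1 <- exp(eta)
  gpp <- pmax(4 * a * e1^2 - b * e1 + 1 / omega^2, 1e-8)

  if (method == "laplace") {
    logm <- -gfun(eta) + 0.5 * log(2 * pi) - 0.5 * log(gpp)
  } else {
    gh <- pracma::gaussHermite(nodes)
    tau <- 1 / sqrt(gpp)
    etas <- eta + sqrt(2) * tau %o% gh$x      # np x nodes
    term <- -gfun(etas)
    term <- sweep(term, 2, log(gh$w) + gh$x^2, `+`)
    m <- apply(term, 1, max)
    logm <- log(sqrt(2) * tau) + m + log(rowSums(exp(term - m)))
  }
  list(value = -2 * sum(logm), eta = eta, loglik_i = logm)
}

#' Marginal -2 log-likelihood of the steady-state population PK model
#'
#' Computes `-2 * sum_i log integral prod_j N(y_ij; Css_i(eta),
#' (sigma * Css_i(eta))^2) N(eta; 0, omega^2) d eta`, the marginal
#' likelihood of the one-compartment steady-state model with exponential
#' inter-individual variability on total clearance and proportional residual
#' error. The per-patient integral is evaluated by the Laplace approximation
#' (default) or by adaptive Gauss-Hermite quadrature centred and scaled at
#' the per-patient posterior mode. `omega = 0` is handled as the degenerate
#' fixed-effects limit (no integral). The value includes all `2*pi`
#' normalising constants; subtract `n_obs * log(2*pi)` for the
#' NONMEM-comparable objective.
#'
#' @param theta typical non-GFR clearance, L/h (>= 0).
#' @param omega SD of log-clearance (>= 0).
#' @param sigma proportional residual SD as a fraction (> 0).
#' @param data a `poppk_dataset` (see [sim_cohort()] or [read_cohort()]).
#' @param fixed a [fixed_params()] object.
#' @param method `"laplace"` or `"quadrature"`.
#' @param nodes number of Gauss-Hermite nodes (>= 5) for
#'   `method = "quadrature"`. Default 21.
#' @return The -2 log-likelihood (a single number).
#' @examples
#' cohort <- sim_cohort(cohort_spec(seed = 3))
#' poppk_neg2ll(3.6, 0.15, 0.135, cohort)
#' @export
poppk_neg2ll <- function(theta, omega, sigma, data, fixed = fixed_params(),
                         method = c("laplace", "quadrature"), nodes = 21) {
  method <- match.arg(method)
  stopifnot_scalar(theta, "theta", lower = 0)
  stopifnot_scalar(omega, "omega", lower = 0)
  stopifnot_scalar(sigma, "sigma", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(nodes, "nodes", lower = 5)
  pat <- if (is.data.frame(data) && all(c("sumy", "sumy2") %in% names(data))) {
    data
  } else {
    prep_patients(data)
  }
  neg2ll_core(theta, omega, sigma, pat, fixed, method, nodes)$value
}

# deterministic jittered multi-start grid (log-scale offsets)
start_grid <- function(s0, n_starts) {
  offsets <- rbind(
    c(0, 0, 0),
    c(0.4, -0.4, 0.4),
    c(-0.4, 0.4, -0.4),
    c(0.8, 0.8, -0.8),
    c(-0.8, -0.8, 0.8),
    c(0.3, -0.8, 0),
    c(-0.3, 0.8, 0)
  )
  offsets <- offsets[seq_len(min(n_starts, nrow(offsets))), , drop = FALSE]
  sweep(offsets, 2, log(s0), `+`)
}

#' Fit the steady-state population PK model by maximum marginal likelihood
#'
#' Estimates the typical non-GFR clearance, the inter-individual variability
#' of total clearance (exponential model) and the proportional residual
#' error by maximising the Laplace (or adaptive Gauss-Hermite) marginal
#' likelihood over `(theta, omega, sigma)`, from several deterministic
#' jittered starting points. Standard errors come from the central
#' finite-difference Hessian of the -2 log-likelihood at the optimum;
#' empirical Bayes estimates (EBEs) are the per-patient posterior modes, and
#' eta-/epsilon-shrinkage are reported as
#' `100 * (1 - SD(EBE)/omega_hat)` and `100 * (1 - SD(IWRES))`.
#'
#' @param data a `poppk_dataset` with at least 2 patients.
#' @param fixed a [fixed_params()] object.
#' @param method integral approximation, `"laplace"` (default) or
#'   `"quadrature"`.
#' @param nodes Gauss-Hermite nodes for `method = "quadrature"`.
#' @param n_starts number of jittered starts (1-7). Default 5.
#' @param start optional numeric length-3 `(theta, omega, sigma)` overriding
#'   the moment-based default start.
#' @return An object of class `poppk_fit`: a list with elements
#'   `theta_cl_nongfr`, `omega_cl`, `omega_cv_percent`, `sigma_prop`,
#'   `sigma_cv_percent`, `se`, `rse_percent`, `eta_shrinkage_percent`,
#'   `eps_shrinkage_percent`, `minus2ll`, `ofv_nonmem`, `ebe`, `convergence`,
#'   `n_patients`, `n_obs`, `fixed`, `method`.
#' @examples
#' cohort <- sim_cohort(cohort_spec(n_patients = 30, seed = 11))
#' fit <- fit_poppk(cohort)
#' fit
#' @export
fit_poppk <- function(data, fixed = fixed_params(),
                      method = c("laplace", "quadrature"), nodes = 21,
                      n_starts = 5, start = NULL) {
  method <- match.arg(method)
  pat <- prep_patients(data)
  if (nrow(pat) < 2) stop("need at least 2 patients", call. = FALSE)
  if (any(pat$n < 1)) stop("every patient needs >= 1 observation", call. = FALSE)

  # moment-based start: per-patient implied clearance -> theta, omega, sigma
  ybar <- pat$sumy / pat$n
  cl_impl <- pat$rate / pmax(ybar, 1e-6)
  th0 <- stats::median(pmax(cl_impl - pat$gfr * fixed$gfr_factor - fixed$cl_decay,
                            0.1))
  om0 <- max(0.05, stats::sd(log(pmax(
    cl_impl / (pat$gfr * fixed$gfr_factor + th0 + fixed$cl_decay), 1e-3))),
    na.rm = TRUE)
  within_cv <- sqrt(pmax(pat$sumy2 / pat$n - ybar^2, 0)) / pmax(ybar, 1e-6)
  sg0 <- max(0.05, stats::median(within_cv[pat$n > 1]), na.rm = TRUE)
  s0 <- if (is.null(start)) c(th0, om0, sg0) else start
  s0 <- pmax(s0, 1e-3)

  obj <- function(p) {
    v <- neg2ll_core(exp(p[1]), exp(p[2]), exp(p[3]), pat, fixed,
                     method, nodes)$value
    if (!is.finite(v)) 1e10 else v
  }

  grid <- start_grid(s0, n_starts)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    o <- tryCatch(
      stats::optim(grid[r, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("estimation failed from every starting point", call. = FALSE)

  est <- exp(best$par)             # (theta, omega, sigma) on natural scale
  names(est) <- c("theta_cl_nongfr", "omega_cl", "sigma_prop")

  # central finite-difference Hessian of -2LL on the natural scale
  f <- function(p) neg2ll_core(p[1], p[2], p[3], pat, fixed, method, nodes)$value
  h <- 1e-4 * pmax(abs(est), 1e-3)
  H <- matrix(NA_real_, 3, 3)
  f0 <- best$value
  for (i in 1:3) {
    for (j in i:3) {
      ei <- ej <- rep(0, 3); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(est + ei) - 2 * f0 + f(est - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(est + ei + ej) - f(est + ei - ej) -
             f(est - ei + ej) + f(est - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  se <- rep(NA_real_, 3)
  status <- "converged"
  covm <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(covm) || any(!is.finite(diag(covm))) || any(diag(covm) <= 0)) {
    status <- "hessian-not-positive-definite"
    warning("Hessian not positive definite; standard errors unavailable",
            call. = FALSE)
  } else {
    se <- sqrt(diag(covm))
  }
  names(se) <- names(est)
  rse <- 100 * se / est

  final <- neg2ll_core(est[1], est[2], est[3], pat, fixed, method, nodes)
  ebe <- data.frame(id = pat$id, eta = final$eta)
  eta_shr <- if (est[2] > 0 && nrow(ebe) > 1) {
    100 * (1 - stats::sd(ebe$eta) / est[2])
  } else NA_real_

  # IWRES on the observation rows
  d <- data
  if ("analyte" %in% names(d)) d <- d[d$analyte == "meropenem", , drop = FALSE]
  cl_typ <- d$gfr_ml_min * fixed$gfr_factor + est[1] + fixed$cl_decay
  eta_row <- ebe$eta[match(d$id, ebe$id)]
  ipred <- d$rate_mg_h / (cl_typ * exp(eta_row))
  iwres <- (d$dv_mg_L - ipred) / (est[3] * ipred)
  eps_shr <- 100 * (1 - stats::sd(iwres))

  n_obs <- nrow(d)
  structure(
    list(
      theta_cl_nongfr = unname(est[1]),
      omega_cl = unname(est[2]),
      omega_cv_percent = omega_to_cv(unname(est[2])),
      sigma_prop = unname(est[3]),
      sigma_cv_percent = 100 * unname(est[3]),
      se = se, rse_percent = rse,
      eta_shrinkage_percent = eta_shr,
      eps_shrinkage_percent = eps_shr,
      minus2ll = best$value,
      ofv_nonmem = best$value - n_obs * log(2 * pi),
      ebe = ebe,
      convergence = status,
      n_patients = nrow(pat), n_obs = n_obs,
      fixed = fixed, method = method
    ),
    class = "poppk_fit"
  )
}

#' @export
print.poppk_fit <- function(x, ...) {
  cat(sprintf("Steady-state population PK fit (%s; %d patients, %d observations)\n",
              x$method, x$n_patients, x$n_obs))
  cat(sprintf("  CL_nonGFR  = %.3g L/h (RSE %.0f%%)\n",
              x$theta_cl_nongfr, x$rse_percent[1]))
  cat(sprintf("  omega CL   = %.1f CV%% (RSE %.0f%%) [eta-shrinkage %.0f%%]\n",
              x$omega_cv_percent, x$rse_percent[2], x$eta_shrinkage_percent))
  cat(sprintf("  sigma prop = %.1f CV%% (RSE %.0f%%) [eps-shrinkage %.0f%%]\n",
              x$sigma_cv_percent, x$rse_percent[3], x$eps_shrinkage_percent))
  cat(sprintf("  -2LL = %.2f (NONMEM-comparable OFV %.2f); status: %s\n",
              x$minus2ll, x$ofv_nonmem, x$convergence))
  invisible(x)
}

#' Partition total clearance into its three components
#'
#' Total clearance is `CL = CL_GFR + CL_nonGFR + CL_decay`: a renal
#' component fixed to the cohort GFR, an estimated residual component, and
#' the in-vitro-fixed spontaneous-decay component. Fractions are percents of
#' the component sum (computed before any rounding).
#'
#' @param cl_gfr GFR-attributable clearance, L/h. Either supply directly or
#'   via `result`/`fixed`/`gfr_summary`.
#' @param cl_nongfr non-GFR clearance, L/h.
#' @param cl_decay spontaneous-decay clearance, L/h.
#' @param result optionally a `poppk_fit`; supplies `cl_nongfr` and, with
#'   `gfr_summary` and its `fixed` slot, the other components.
#' @param gfr_summary cohort GFR summary (e.g. the median), mL/min; used
#'   with `result`.
#' @return An object of class `clearance_partition`: list with `cl_gfr`,
#'   `cl_nongfr`, `cl_decay`, `cl_total` and `fraction_percent` (length 3,
#'   sums to 100 before rounding).
#' @examples
#' partition_clearance(cl_gfr = 7.1, cl_nongfr = 3.6, cl_decay = 0.66)
#' @export
partition_clearance <- function(cl_gfr = NULL, cl_nongfr = NULL,
                                cl_decay = NULL, result = NULL,
                                gfr_summary = NULL) {
  if (!is.null(result)) {
    if (!inherits(result, "poppk_fit")) {
      stop("`result` must be a poppk_fit", call. = FALSE)
    }
    if (is.null(cl_nongfr)) cl_nongfr <- result$theta_cl_nongfr
    if (is.null(cl_decay)) cl_decay <- result$fixed$cl_decay
    if (is.null(cl_gfr)) {
      if (is.null(gfr_summary)) {
        stop("supply `gfr_summary` (mL/min) to derive cl_gfr from a fit",
             call. = FALSE)
      }
      cl_gfr <- gfr_summary * result$fixed$gfr_factor
    }
  }
  for (nm in c("cl_gfr", "cl_nongfr", "cl_decay")) {
    stopifnot_scalar(get(nm), nm, lower = 0)
  }
  total <- cl_gfr + cl_nongfr + cl_decay
  if (total <= 0) stop("total clearance is zero; cannot form fractions", call. = FALSE)
  frac <- 100 * c(cl_gfr, cl_nongfr, cl_decay) / total
  names(frac) <- c("gfr", "nongfr", "decay")
  structure(
    list(cl_gfr = cl_gfr, cl_nongfr = cl_nongfr, cl_decay = cl_decay,
         cl_total = total, fraction_percent = frac),
    class = "clearance_partition"
  )
}

#' @export
print.clearance_partition <- function(x, ...) {
  cat("Clearance partition (L/h):\n")
  cat(sprintf("  CL_GFR    %6.2f  (%2.0f%%)\n", x$cl_gfr, x$fraction_percent[1]))
  cat(sprintf("  CL_nonGFR %6.2f  (%2.0f%%)\n", x$cl_nongfr, x$fraction_percent[2]))
  cat(sprintf("  CL_decay  %6.2f  (%2.0f%%)\n", x$cl_decay, x$fraction_percent[3]))
  cat(sprintf("  total     %6.2f\n", x$cl_total))
  invisible(x)
}

#' Goodness-of-fit table for a fitted population PK model
#'
#' Per-observation population predictions (random effect at zero),
#' individual predictions (random effect at the empirical Bayes estimate),
#' residuals and individual weighted residuals, in a tidy table suitable for
#' predicted-versus-observed and residual diagnostics.
#'
#' @param result a `poppk_fit`.
#' @param data the `poppk_dataset` the model was fitted to.
#' @return A data.frame with columns `id`, `time_h`, `observed`, `pred`
#'   (population), `ipred` (individual), `res`, `ires`, `iwres`, `eta`.
#' @examples
#' cohort <- sim_cohort(cohort_spec(n_patients = 12, seed = 5))
#' fit <- fit_poppk(cohort)
#' head(gof_tables(fit, cohort))
#' @export
gof_tables <- function(result, data) {
  if (!inherits(result, "poppk_fit")) stop("`result` must be a poppk_fit", call. = FALSE)
  d <- data
  if ("analyte" %in% names(d)) d <- d[d$analyte == "meropenem", , drop = FALSE]
  fixed <- result$fixed
  cl_typ <- d$gfr_ml_min * fixed$gfr_factor + result$theta_cl_nongfr + fixed$cl_decay
  eta <- result$ebe$eta[match(d$id, result$ebe$id)]
  pred <- d$rate_mg_h / cl_typ
  ipred <- d$rate_mg_h / (cl_typ * exp(eta))
  data.frame(
    id = d$id,
    time_h = if ("time_h" %in% names(d)) d$time_h else NA_real_,
    observed = d$dv_mg_L,
    pred = pred, ipred = ipred,
    res = d$dv_mg_L - pred,
    ires = d$dv_mg_L - ipred,
    iwres = (d$dv_mg_L - ipred) / (result$sigma_prop * ipred),
    eta = eta,
    row.names = NULL
  )
}
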