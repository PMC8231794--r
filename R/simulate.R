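#' Assay noise model
#'
#' Describes the measurement-error structure of the quantitative assay:
#' proportional (multiplicative Gaussian) noise with a given coefficient of
#' variation, a number of technical replicates per time point, and lower
#' limits of quantification for parent and metabolite. The assay used for the
#' stability experiments had imprecision and inaccuracy of at most 8 percent
#' (typically below 5 percent), which is what the default emulates.
#'
#' @param cv proportional coefficient of variation of the assay, as a
#'   fraction in `[0, 1)`. Default 0.05.
#' @param replicates number of technical replicates per time point (>= 1).
#'   Default 2 (the stability experiments were run in duplicate).
#' @param lloq_meropenem lower limit of quantification for meropenem, mg/L.
#' @param lloq_orm lower limit of quantification for the open-ring
#'   metabolite, mg/L.
#' @return An object of class `assay_noise`.
#' @examples
#' assay_noise(cv = 0.05, replicates = 2)
#' @export
assay_noise <- function(cv = 0.05, replicates = 2L,
                        lloq_meropenem = 1.0, lloq_orm = 0.62) {
  stopifnot_scalar(cv, "cv", lower = 0)
  if (cv >= 1) stop("`cv` must be < 1 (a fraction, not a percent)", call. = FALSE)
  stopifnot_scalar(replicates, "replicates", lower = 1)
  if (replicates != as.integer(replicates)) {
    stop("`replicates` must be an integer", call. = FALSE)
  }
  stopifnot_scalar(lloq_meropenem, "lloq_meropenem", lower = 0)
  stopifnot_scalar(lloq_orm, "lloq_orm", lower = 0)
  structure(
    list(cv = cv, replicates = as.integer(replicates),
         lloq_meropenem = lloq_meropenem, lloq_orm = lloq_orm),
    class = "assay_noise"
  )
}

#' @export
print.assay_noise <- function(x, ...) {
  cat(sprintf(
    "Assay noise model: proportional CV %.1f%%, %d replicate(s), LLOQ %.2f/%.2f mg/L\n",
    100 * x$cv, x$replicates, x$lloq_meropenem, x$lloq_orm))
  invisible(x)
}

#' Cohort specification for steady-state TDM simulation
#'
#' Describes a cohort of critically ill patients on continuous meropenem
#' infusion with once-daily steady-state therapeutic drug monitoring (TDM)
#' samples. Defaults emulate the study cohort: GFR spanning 28-307 mL/min,
#' daily doses of 3-6 g/24 h (125-250 mg/h), and four daily samples per
#' patient.
#'
#' @param n_patients number of patients (>= 1). Default 6.
#' @param gfr_range numeric length-2, lower/upper glomerular filtration rate
#'   in mL/min. Default `c(28, 307)`.
#' @param dose_range numeric length-2, lower/upper constant infusion rate in
#'   mg/h. Default `c(125, 250)` (3-6 g per 24 h).
#' @param samples_per_patient steady-state samples per patient, one per day
#'   (>= 1). Default 4.
#' @param seed integer seed driving all randomness of the cohort.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_patients = 6, seed = 1)
#' @export
cohort_spec <- function(n_patients = 6L, gfr_range = c(28, 307),
                        dose_range = c(125, 250), samples_per_patient = 4L,
                        seed = 1L) {
  stopifnot_scalar(n_patients, "n_patients", lower = 1)
  stopifnot_scalar(samples_per_patient, "samples_per_patient", lower = 1)
  check_range <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be an ordered numeric pair low <= high", name),
           call. = FALSE)
    }
    if (any(r <= 0)) stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  check_range(gfr_range, "gfr_range")
  check_range(dose_range, "dose_range")
  stopifnot_scalar(seed, "seed")
  structure(
    list(n_patients = as.integer(n_patients), gfr_range = gfr_range,
         dose_range = dose_range,
         samples_per_patient = as.integer(samples_per_patient),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: %d patients, GFR %g-%g mL/min, rate %g-%g mg/h, %d samples each (seed %d)\n",
    x$n_patients, x$gfr_range[1], x$gfr_range[2], x$dose_range[1],
    x$dose_range[2], x$samples_per_patient, x$seed))
  invisible(x)
}

#' Simulate a first-order degradation concentration-time series
#'
#' Generates parent (meropenem) and metabolite (ORM) concentrations under
#' first-order decay `C(t) = C0 * exp(-k t)` with proportional assay noise.
#' The metabolite follows the molar conversion of degraded parent, scaled by
#' a constant `metabolite_yield` to represent the incomplete ORM recovery
#' seen experimentally (the ORM is itself further converted, e.g. by
#' decarboxylation):
#' `C_orm(t) = yield * (C0 - C0 exp(-k t)) * MM_orm / MM_parent`.
#'
#' @param k first-order degradation rate constant, per hour (>= 0).
#' @param c0 initial parent concentration, mg/L (> 0).
#' @param times sampling times in hours; defaults to the stability-testing
#'   schedule `meropk_constants$stability_times`.
#' @param noise an [assay_noise()] object.
#' @param mm_parent,mm_metabolite molar masses, g/mol.
#' @param metabolite_yield fraction of degraded parent recovered as
#'   metabolite, in `[0, 1]`. Default 0.8.
#' @param seed integer seed; identical seeds give identical series.
#' @param matrix label for the matrix, `"saline"` or `"serum"`.
#' @param temperature nominal temperature in degrees C (bookkeeping only).
#' @return A `concentration_series` data.frame with columns `time_h`,
#'   `analyte` (`"meropenem"` or `"orm"`), `conc_mg_L`, `replicate`,
#'   `matrix`, `temperature`.
#' @examples
#' s <- sim_decay_series(k = 0.006, c0 = 20000, seed = 42)
#' head(s)
#' @export
sim_decay_series <- function(k, c0, times = meropk_constants$stability_times,
                             noise = assay_noise(),
                             mm_parent = meropk_constants$mm_meropenem,
                             mm_metabolite = meropk_constants$mm_orm,
                             metabolite_yield = 0.8, seed = 1L,
                             matrix = c("saline", "serum"),
                             temperature = NULL) {
  matrix <- match.arg(matrix)
  if (is.null(temperature)) temperature <- if (matrix == "saline") 22 else 37
  stopifnot_scalar(k, "k", lower = 0)
  stopifnot_scalar(c0, "c0", lower = 0, strict_lower = TRUE)
  if (length(times) == 0 || any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be non-empty, finite and non-negative", call. = FALSE)
  }
  stopifnot_scalar(mm_parent, "mm_parent", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(mm_metabolite, "mm_metabolite", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(metabolite_yield, "metabolite_yield", lower = 0, upper = 1)
  if (!inherits(noise, "assay_noise")) {
    stop("`noise` must be an assay_noise() object", call. = FALSE)
  }

  times <- sort(times)
  parent_true <- c0 * exp(-k * times)
  metab_true <- metabolite_yield * (c0 - parent_true) * mm_metabolite / mm_parent
  nrep <- noise$replicates
  nt <- length(times)

  df <- with_seed(seed, {
    mk <- function(true_conc, analyte) {
      true_rep <- rep(true_conc, each = nrep)
      eps <- stats::rnorm(nt * nrep, mean = 0, sd = noise$cv)
      data.frame(
        time_h = rep(times, each = nrep),
        analyte = analyte,
        conc_mg_L = pmax(0, true_rep * (1 + eps)),
        replicate = rep(seq_len(nrep), times = nt),
        matrix = matrix,
        temperature = temperature,
        stringsAsFactors = FALSE
      )
    }
    rbind(mk(parent_true, "meropenem"), mk(metab_true, "orm"))
  })
  class(df) <- c("concentration_series", "data.frame")
  df
}

# lognormal CV <-> SD-of-log conversions (exact, not the small-omega
# approximation) -------------------------------------------------------------

#' Convert between lognormal CV and SD of the log
#'
#' Inter-individual variability of clearance follows an exponential
#' (lognormal) model `CL_i = CL_typ * exp(eta)`, `eta ~ N(0, omega^2)`, and
#' is conventionally reported as a coefficient of variation in percent. The
#' exact relations are `CV = sqrt(exp(omega^2) - 1)` and its inverse.
#'
#' @param cv_percent CV in percent.
#' @param omega standard deviation of the log.
#' @return `cv_to_omega()` returns omega; `omega_to_cv()` returns CV %.
#' @examples
#' omega_to_cv(cv_to_omega(14.9))  # round trip
#' @export
cv_to_omega <- function(cv_percent) {
  stopifnot_scalar(cv_percent, "cv_percent", lower = 0)
  sqrt(log(1 + (cv_percent / 100)^2))
}

#' @rdname cv_to_omega
#' @export
omega_to_cv <- function(omega) {
  stopifnot_scalar(omega, "omega", lower = 0)
  100 * sqrt(exp(omega^2) - 1)
}

#' Simulate a steady-state TDM cohort from the population PK model
#'
#' Draws a cohort per a [cohort_spec()]: each patient receives a GFR uniform
#' over `gfr_range`, a constant infusion rate uniform over `dose_range`, and
#' a clearance `CL_i = (GFR_i * 0.06 + theta_cl_nongfr + CL_decay) * exp(eta_i)`
#' with `eta_i ~ N(0, omega_cl^2)`. Steady-state observations are
#' `y = Css_i * (1 + eps)`, `eps ~ N(0, sigma_prop^2)`, truncated at zero,
#' once daily. ORM observations are generated alongside from the patient's
#' non-renal clearance fraction so that metabolic-ratio analyses have
#' realistic structure (the ORM does not enter the PK likelihood).
#'
#' @param spec a [cohort_spec()].
#' @param fixed a [fixed_params()] object (fixed volume, decay clearance and
#'   GFR unit factor).
#' @param theta_cl_nongfr typical non-GFR clearance, L/h. Default 3.6.
#' @param omega_cl SD of log-clearance. Default `cv_to_omega(14.9)`.
#' @param sigma_prop proportional residual error (fraction). Default 0.135.
#' @return A `poppk_dataset` data.frame with columns `id`, `time_h`,
#'   `analyte`, `dv_mg_L`, `rate_mg_h`, `gfr_ml_min`, plus per-row `eta`
#'   and `cl_true` attributes columns kept in `attr(, "truth")` for
#'   simulation studies.
#' @examples
#' cohort <- sim_cohort(cohort_spec(seed = 7))
#' head(cohort)
#' @export
sim_cohort <- function(spec = cohort_spec(),
                       fixed = fixed_params(),
                       theta_cl_nongfr = 3.6,
                       omega_cl = cv_to_omega(14.9),
                       sigma_prop = 0.135) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec() object", call. = FALSE)
  }
  if (!inherits(fixed, "fixed_params")) {
    stop("`fixed` must be a fixed_params() object", call. = FALSE)
  }
  stopifnot_scalar(theta_cl_nongfr, "theta_cl_nongfr", lower = 0)
  stopifnot_scalar(omega_cl, "omega_cl", lower = 0)
  stopifnot_scalar(sigma_prop, "sigma_prop", lower = 0)

  n <- spec$n_patients
  nobs <- spec$samples_per_patient

  with_seed(spec$seed, {
    gfr <- stats::runif(n, spec$gfr_range[1], spec$gfr_range[2])
    rate <- stats::runif(n, spec$dose_range[1], spec$dose_range[2])
    eta <- stats::rnorm(n, 0, omega_cl)
    cl_typ <- gfr * fixed$gfr_factor + theta_cl_nongfr + fixed$cl_decay
    cl_i <- cl_typ * exp(eta)
    css <- rate / cl_i

    id <- rep(seq_len(n), each = nobs)
    time_h <- rep(48 + 24 * (seq_len(nobs) - 1), times = n)  # steady state: >48 h
    eps <- stats::rnorm(n * nobs, 0, sigma_prop)
    y <- pmax(0, css[id] * (1 + eps))

    # companion ORM level: proportional to the patient's non-renal clearance
    # share, with the same relative noise structure
    nonrenal_frac <- (theta_cl_nongfr + fixed$cl_decay) / cl_typ
    orm_true <- css * nonrenal_frac / (1 - nonrenal_frac)
    eps_orm <- stats::rnorm(n * nobs, 0, sigma_prop)
    y_orm <- pmax(0, orm_true[id] * (1 + eps_orm))

    df <- data.frame(
      id = rep(id, 2),
      time_h = rep(time_h, 2),
      analyte = rep(c("meropenem", "orm"), each = n * nobs),
      dv_mg_L = c(y, y_orm),
      rate_mg_h = rate[rep(id, 2)],
      gfr_ml_min = gfr[rep(id, 2)],
      stringsAsFactors = FALSE
    )
    attr(df, "truth") <- data.frame(
      id = seq_len(n), gfr = gfr, rate = rate, eta = eta,
      cl_typ = cl_typ, cl_true = cl_i, css = css
    )
    class(df) <- c("poppk_dataset", "data.frame")
    df
  })
}
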