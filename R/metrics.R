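#' Open-ring-metabolite metabolic ratio
#'
#' `Ratio = C_ORM / (C_ORM + C_meropenem)`, the fraction of total measured
#' drug present as the inactive open-ring metabolite. The mass basis applies
#' the formula to concentrations in mg/L as measured; the molar basis first
#' divides each concentration by its molar mass (383.46 g/mol for meropenem,
#' 401.16 g/mol for the ORM).
#'
#' @param c_orm ORM concentration, mg/L (>= 0); vectorised.
#' @param c_mero meropenem concentration, mg/L (>= 0); vectorised.
#' @param basis `"mass"` (default) or `"molar"`.
#' @param mm_mero,mm_orm molar masses used for the molar basis.
#' @return Ratio in `[0, 1]`; `NA` (with a warning) where both
#'   concentrations are zero.
#' @examples
#' orm_ratio(7.73, 19.74)                  # ~0.28
#' orm_ratio(7.73, 19.74, basis = "molar")
#' @export
orm_ratio <- function(c_orm, c_mero, basis = c("mass", "molar"),
                      mm_mero = meropk_constants$mm_meropenem,
                      mm_orm = meropk_constants$mm_orm) {
  basis <- match.arg(basis)
  if (any(!is.finite(c_orm)) || any(c_orm < 0) ||
      any(!is.finite(c_mero)) || any(c_mero < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (basis == "molar") {
    c_orm <- c_orm / mm_orm
    c_mero <- c_mero / mm_mero
  }
  both_zero <- c_orm + c_mero == 0
  if (any(both_zero)) {
    warning("ratio undefined where both concentrations are zero; returning NA",
            call. = FALSE)
  }
  ifelse(both_zero, NA_real_, c_orm / (c_orm + c_mero))
}

#' Creatinine clearance from a timed urine collection
#'
#' `CrCl = (crea_urine * urine_volume) / (collection_time * crea_plasma)`,
#' in mL/min, used as the estimate of the glomerular filtration rate.
#' Urine and plasma creatinine must be in identical concentration units.
#'
#' @param crea_urine urine creatinine concentration (> 0).
#' @param urine_volume collected urine volume, mL (> 0).
#' @param collection_time collection duration, minutes (> 0).
#' @param crea_plasma plasma creatinine concentration, same units as
#'   `crea_urine` (> 0).
#' @return Creatinine clearance, mL/min.
#' @examples
#' creatinine_clearance(100, 1500, 1440, 1)
#' @export
creatinine_clearance <- function(crea_urine, urine_volume, collection_time,
                                 crea_plasma) {
  stopifnot_scalar(crea_urine, "crea_urine", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(urine_volume, "urine_volume", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(collection_time, "collection_time", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(crea_plasma, "crea_plasma", lower = 0, strict_lower = TRUE)
  (crea_urine * urine_volume) / (collection_time * crea_plasma)
}

#' Convert a GFR in mL/min to a clearance in L/h
#'
#' @param gfr glomerular filtration rate, mL/min (>= 0); vectorised.
#' @return Clearance in L/h (`gfr * 60 / 1000`).
#' @examples
#' gfr_to_clearance(139)  # 8.34 L/h
#' @export
gfr_to_clearance <- function(gfr) {
  if (any(!is.finite(gfr)) || any(gfr < 0)) {
    stop("`gfr` must be finite and >= 0", call. = FALSE)
  }
  gfr * 60 / 1000
}

#' Per-sample and per-patient ORM ratio tables for a cohort
#'
#' Computes the metabolic ratio for every steady-state sample of a cohort on
#' both the mass and molar basis, together with per-patient medians and the
#' cohort ranges on both summaries.
#'
#' @param cohort a `poppk_dataset` with paired `"meropenem"` and `"orm"`
#'   rows per `(id, time_h)`.
#' @param basis default basis for the headline summary.
#' @return A list with `samples` (data.frame: id, time_h, c_mero, c_orm,
#'   ratio_mass, ratio_molar, gfr_ml_min), `patients` (per-patient median
#'   ratios and GFR) and `summary` (cohort median and range on both the
#'   per-sample and per-patient-median level, on the chosen basis).
#' @examples
#' cohort <- sim_cohort(cohort_spec(seed = 2))
#' ratio_table(cohort)$summary
#' @export
ratio_table <- function(cohort, basis = c("mass", "molar")) {
  basis <- match.arg(basis)
  need <- c("id", "time_h", "analyte", "dv_mg_L")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  mero <- cohort[cohort$analyte == "meropenem", ]
  orm <- cohort[cohort$analyte == "orm", ]
  key <- function(d) paste(d$id, d$time_h)
  m <- match(key(mero), key(orm))
  if (any(is.na(m))) stop("unpaired meropenem/orm samples in cohort", call. = FALSE)
  samples <- data.frame(
    id = mero$id, time_h = mero$time_h,
    c_mero = mero$dv_mg_L, c_orm = orm$dv_mg_L[m],
    gfr_ml_min = if ("gfr_ml_min" %in% names(mero)) mero$gfr_ml_min else NA_real_
  )
  samples$ratio_mass <- orm_ratio(samples$c_orm, samples$c_mero, "mass")
  samples$ratio_molar <- orm_ratio(samples$c_orm, samples$c_mero, "molar")

  col <- paste0("ratio_", basis)
  ids <- unique(samples$id)
  patients <- data.frame(
    id = ids,
    median_ratio = vapply(ids, function(i)
      stats::median(samples[[col]][samples$id == i]), numeric(1)),
    gfr_ml_min = vapply(ids, function(i)
      samples$gfr_ml_min[samples$id == i][1], numeric(1))
  )
  list(
    samples = samples,
    patients = patients,
    summary = list(
      basis = basis,
      per_sample_median = stats::median(samples[[col]]),
      per_sample_range = range(samples[[col]]),
      per_patient_median = stats::median(patients$median_ratio),
      per_patient_range = range(patients$median_ratio)
    )
  )
}

#' Association between the ORM metabolic ratio and the GFR
#'
#' Squared Pearson correlation between per-sample metabolic ratios and the
#' corresponding GFR values, with a seeded permutation p-value (GFR labels
#' permuted across samples).
#'
#' @param ratio per-sample metabolic ratios.
#' @param gfr matching GFR values, mL/min.
#' @param n_perm number of permutations (>= 100). Default 10000.
#' @param seed integer seed for the permutations.
#' @return A list with `r_squared`, `p_value`, `n`, `n_perm`.
#' @examples
#' cohort <- sim_cohort(cohort_spec(n_patients = 20, seed = 4))
#' rt <- ratio_table(cohort)
#' ratio_gfr_association(rt$samples$ratio_mass, rt$samples$gfr_ml_min, seed = 1)
#' @export
ratio_gfr_association <- function(ratio, gfr, n_perm = 10000, seed = 1L) {
  if (length(ratio) != length(gfr)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(ratio) & is.finite(gfr)
  ratio <- ratio[ok]; gfr <- gfr[ok]
  if (length(ratio) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(ratio) == 0 || stats::sd(gfr) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stopifnot_scalar(n_perm, "n_perm", lower = 100)
  r_obs <- stats::cor(ratio, gfr)
  r2 <- r_obs^2
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      r_b <- stats::cor(ratio, sample(gfr))
      if (r_b^2 >= r2) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(r_squared = r2, p_value = p, n = length(ratio), n_perm = as.integer(n_perm))
}
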