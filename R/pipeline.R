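#' Configuration for a full bottle-to-body pipeline run
#'
#' Bundles every tunable of the end-to-end analysis - simulation seeds,
#' in-vitro rate constants, cohort design, fixed PK parameters, the
#' stability threshold and the estimation method - into one object that
#' round-trips losslessly through JSON, so that a run is fully described by
#' its configuration.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param k_saline,k_serum in-vitro degradation rates, per hour.
#' @param c0_saline initial infusate concentration, mg/L. Default 20000
#'   (a 2 percent solution).
#' @param c0_serum initial serum-spike concentration, mg/L. Default 10.
#' @param assay_cv proportional assay CV (fraction). Default 0.05.
#' @param metabolite_yield fraction of degraded parent recovered as ORM.
#' @param threshold stability threshold (retained fraction). Default 0.90.
#' @param n_patients,samples_per_patient cohort design.
#' @param theta_cl_nongfr,omega_cv,sigma_cv simulation truth for the cohort:
#'   typical non-GFR clearance (L/h) and variability terms (CV percent).
#' @param v volume of distribution, L.
#' @param method estimation method, `"laplace"` or `"quadrature"`.
#' @param out_dir output directory for artifacts.
#' @return An object of class `run_config` (a list).
#' @examples
#' run_config(seed = 1, out_dir = tempdir())
#' @export
run_config <- function(seed = 1L,
                       k_saline = meropk_constants$k_saline,
                       k_serum = meropk_constants$k_serum,
                       c0_saline = 20000, c0_serum = 10,
                       assay_cv = 0.05, metabolite_yield = 0.8,
                       threshold = 0.90,
                       n_patients = 6L, samples_per_patient = 4L,
                       theta_cl_nongfr = 3.6, omega_cv = 14.9,
                       sigma_cv = 13.5, v = 26.2,
                       method = c("laplace", "quadrature"),
                       out_dir = "meropk-run") {
  method <- match.arg(method)
  cfg <- list(seed = as.integer(seed), k_saline = k_saline, k_serum = k_serum,
              c0_saline = c0_saline, c0_serum = c0_serum, assay_cv = assay_cv,
              metabolite_yield = metabolite_yield, threshold = threshold,
              n_patients = as.integer(n_patients),
              samples_per_patient = as.integer(samples_per_patient),
              theta_cl_nongfr = theta_cl_nongfr, omega_cv = omega_cv,
              sigma_cv = sigma_cv, v = v, method = method,
              out_dir = out_dir,
              version = as.character(utils::packageVersion("meropk")))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON path to write to / read from.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$samples_per_patient <- as.integer(cfg$samples_per_patient)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full bottle-to-body pipeline
#'
#' Executes, in order: simulation and first-order fitting of the saline
#' infusate series and of the buffered-serum series; derivation of the
#' spontaneous-decay clearance from the fitted serum rate; simulation and
#' mixed-effects fitting of a steady-state patient cohort; partition of the
#' total clearance into its GFR, non-GFR and decay components; and the
#' metabolic-ratio/GFR metrics. Every artifact is written under
#' `cfg$out_dir` and listed, with its MD5 checksum, in the returned
#' manifest; identical configurations (including the seed) give identical
#' manifests.
#'
#' @param cfg a [run_config()].
#' @return An object of class `run_manifest`: a list with `config`,
#'   `artifacts` (data.frame of file, md5), and `headline` (named list of
#'   the key numbers of the run).
#' @examples
#' \donttest{
#' m <- run_full_pipeline(run_config(seed = 1, out_dir = tempfile()))
#' m$headline$cl_total
#' }
#' @export
run_full_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) stop("`cfg` must be a run_config", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  cfg_disk <- cfg
  cfg_disk$out_dir <- "."   # artifact paths are relative to the run directory
  keep(write_run_config(cfg_disk, p("config.json")))
  noise <- assay_noise(cv = cfg$assay_cv)

  # stage 1: infusate stability at room temperature
  saline <- sim_decay_series(cfg$k_saline, cfg$c0_saline, noise = noise,
                             metabolite_yield = cfg$metabolite_yield,
                             seed = cfg$seed + 101L, matrix = "saline")
  keep(write_decay_series(saline, p("saline_series.csv")))
  fit_saline <- fit_first_order_decay(saline)
  rep_saline <- stability_report(fit_saline, cfg$threshold)
  keep(write_stability_report(rep_saline, p("saline_stability.json")))

  # stage 2: stability in buffered serum at body temperature
  serum <- sim_decay_series(cfg$k_serum, cfg$c0_serum, noise = noise,
                            metabolite_yield = cfg$metabolite_yield,
                            seed = cfg$seed + 202L, matrix = "serum")
  keep(write_decay_series(serum, p("serum_series.csv")))
  fit_serum <- fit_first_order_decay(serum)
  rep_serum <- stability_report(fit_serum, cfg$threshold)
  keep(write_stability_report(rep_serum, p("serum_stability.json")))

  # stage 3: decay clearance bridge and population PK
  fixed <- fixed_params(v = cfg$v, k_serum = fit_serum$k)
  spec <- cohort_spec(n_patients = cfg$n_patients,
                      samples_per_patient = cfg$samples_per_patient,
                      seed = cfg$seed + 303L)
  cohort <- sim_cohort(spec, fixed, theta_cl_nongfr = cfg$theta_cl_nongfr,
                       omega_cl = cv_to_omega(cfg$omega_cv),
                       sigma_prop = cfg$sigma_cv / 100)
  keep(write_cohort(cohort, p("cohort.csv")))
  fit <- fit_poppk(cohort, fixed, method = cfg$method)
  keep(write_poppk_fit(fit, p("poppk_fit.json")))
  gof <- gof_tables(fit, cohort)
  utils::write.csv(gof, keep(p("gof.csv")), row.names = FALSE)

  gfr_med <- stats::median(unique(cohort[c("id", "gfr_ml_min")])$gfr_ml_min)
  part <- partition_clearance(result = fit, gfr_summary = gfr_med)

  # stage 4: metabolic-ratio metrics
  rt <- ratio_table(cohort)
  utils::write.csv(rt$samples, keep(p("ratio_samples.csv")), row.names = FALSE)
  utils::write.csv(rt$patients, keep(p("ratio_patients.csv")), row.names = FALSE)
  assoc <- ratio_gfr_association(rt$samples$ratio_mass, rt$samples$gfr_ml_min,
                                 seed = cfg$seed + 404L)

  headline <- list(
    k_saline = fit_saline$k,
    k_serum = fit_serum$k,
    stability_window_h = rep_saline$stability_window_h,
    recovery_saline_24h = rep_saline$recovery_24h_percent,
    recovery_serum_24h = rep_serum$recovery_24h_percent,
    half_life_serum_h = fit_serum$half_life,
    cl_decay = fixed$cl_decay,
    cl_nongfr = fit$theta_cl_nongfr,
    cl_gfr = part$cl_gfr,
    cl_total = part$cl_total,
    fraction_percent = as.list(part$fraction_percent),
    omega_cv_percent = fit$omega_cv_percent,
    sigma_cv_percent = fit$sigma_cv_percent,
    minus2ll = fit$minus2ll,
    ofv_nonmem = fit$ofv_nonmem,
    ratio_median = rt$summary$per_patient_median,
    ratio_range = rt$summary$per_patient_range,
    ratio_gfr_r2 = assoc$r_squared,
    ratio_gfr_p = assoc$p_value
  )
  jsonlite::write_json(headline, keep(p("headline.json")), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- structure(
    list(
      config = cfg,
      artifacts = data.frame(
        file = basename(artifacts),
        md5 = unname(tools::md5sum(artifacts)),
        stringsAsFactors = FALSE
      ),
      headline = headline
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(config = unclass(cfg), artifacts = manifest$artifacts,
         headline = headline),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest (seed ", x$config$seed, ")\n", sep = "")
  cat("  artifacts:\n")
  for (i in seq_len(nrow(x$artifacts))) {
    cat(sprintf("    %-24s %s\n", x$artifacts$file[i], x$artifacts$md5[i]))
  }
  cat(sprintf("  headline: CL total %.2f L/h, stability window %.1f h\n",
              x$headline$cl_total, x$headline$stability_window_h))
  invisible(x)
}

#' Render a human-readable summary of a pipeline run
#'
#' Produces a plain-text report with the stability table, the clearance
#' partition, the metabolic-ratio summary, and both objective-function
#' conventions, with headline numbers rounded half-up to one decimal.
#'
#' @param manifest a `run_manifest` from [run_full_pipeline()].
#' @param path optional file to write the report to.
#' @return The report as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
render_report <- function(manifest, path = NULL) {
  if (!inherits(manifest, "run_manifest")) {
    stop("`manifest` must be a run_manifest", call. = FALSE)
  }
  h <- manifest$headline
  r1 <- function(x) sprintf("%.1f", round_half_up(x, 1))
  lines <- c(
    "Meropenem bottle-to-body analysis",
    sprintf("package version %s, seed %d", manifest$config$version,
            manifest$config$seed),
    "",
    "In-vitro stability",
    sprintf("  saline 22 C : k = %.4g /h, recovery at 24 h %s%%, 90%% window %s h",
            h$k_saline, r1(h$recovery_saline_24h), r1(h$stability_window_h)),
    sprintf("  serum  37 C : k = %.4g /h, recovery at 24 h %s%%, half-life %s h",
            h$k_serum, r1(h$recovery_serum_24h), r1(h$half_life_serum_h)),
    "",
    "Clearance partition (L/h)",
    sprintf("  CL_GFR    %s (%.0f%%)", r1(h$cl_gfr), h$fraction_percent$gfr),
    sprintf("  CL_nonGFR %s (%.0f%%)", r1(h$cl_nongfr), h$fraction_percent$nongfr),
    sprintf("  CL_decay  %s (%.0f%%)", r1(h$cl_decay), h$fraction_percent$decay),
    sprintf("  total     %s", r1(h$cl_total)),
    "",
    "Variability",
    sprintf("  omega CL  %s CV%%", r1(h$omega_cv_percent)),
    sprintf("  sigma prop %s CV%%", r1(h$sigma_cv_percent)),
    sprintf("  -2LL %.2f (full) / %.2f (NONMEM-comparable)",
            h$minus2ll, h$ofv_nonmem),
    "",
    "ORM metabolic ratio",
    sprintf("  per-patient median %.2f (range %.2f-%.2f)", h$ratio_median,
            h$ratio_range[1], h$ratio_range[2]),
    sprintf("  ratio~GFR: R^2 %.2f, permutation p %.3g", h$ratio_gfr_r2,
            h$ratio_gfr_p)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
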