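#' Analysis configuration for the two-step workflow
#'
#' The analysis proceeds in two steps: a drug-only two-compartment fit
#' (step 1) whose estimates seed the simultaneous drug + target QSS TMDD
#' fit (step 2). Exactly one data source is allowed: a dataset (path or
#' tibble), or a synthetic-cohort block (`design` plus the generating
#' `sim_spec`).
#'
#' @param data A `study_dataset` tibble or a CSV path, or NULL to
#'   generate a synthetic cohort.
#' @param design [cohort_design()] used when `data` is NULL.
#' @param sim_spec Generating [pop_model_spec()] used when `data` is
#'   NULL.
#' @param seed Seed for every stochastic stage (mandatory).
#' @param step1_init,step2_init Named lists (`theta`, `omega2`, `sigma`)
#'   of initial estimates; step 2 defaults pull the disposition
#'   parameters from the step-1 fit.
#' @param settings [estimation_settings()] shared by the fits.
#' @param n_sim_vpc Simulated datasets for the predictive check.
#' @param scm_candidates Optional candidate list for [scm()].
#' @param randtest Optional list `(covariate =, n_perm =)` requesting a
#'   randomization test of the first SCM candidate.
#' @param out_dir Output directory for [run_all()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(data = NULL, design = cohort_design(),
                            sim_spec = NULL, seed,
                            step1_init = NULL, step2_init = NULL,
                            settings = estimation_settings(),
                            n_sim_vpc = 1000,
                            scm_candidates = NULL, randtest = NULL,
                            out_dir = NULL) {
  if (is.null(data) && is.null(sim_spec)) {
    stop("Provide `data` or a synthetic block (`design` + `sim_spec`).",
         call. = FALSE)
  }
  if (!is.null(data) && !is.null(sim_spec)) {
    stop("Exactly one data source: `data` or `sim_spec`.", call. = FALSE)
  }
  structure(list(data = data, design = design, sim_spec = sim_spec,
                 seed = seed, step1_init = step1_init,
                 step2_init = step2_init, settings = settings,
                 n_sim_vpc = n_sim_vpc, scm_candidates = scm_candidates,
                 randtest = randtest, out_dir = out_dir),
            class = "analysis_config")
}

resolve_data <- function(config) {
  if (!is.null(config$data)) {
    if (is.character(config$data)) return(read_study_csv(config$data))
    return(study_dataset(config$data))
  }
  skeleton <- generate_cohort(config$design, seed = config$seed)
  simulate_observations(skeleton, config$sim_spec,
                        seed = config$seed + 1)$data
}

#' Step 1: drug-only population PK fit
#'
#' Fits the two-compartment linear model with proportional residual
#' error to the total-drug observations only, with fixed allometric
#' body-weight scaling on all clearance and volume parameters and
#' log-normal variability on `CL` and `V1`.
#'
#' @param config An [analysis_config()].
#' @param data Optional pre-resolved dataset (otherwise taken from the
#'   config).
#' @return An `nlme_fit`.
#' @export
run_step1 <- function(config, data = NULL) {
  if (is.null(data)) data <- resolve_data(config)
  pk_data <- dplyr::filter(tibble::as_tibble(data),
                           .data$EVID == 1 | .data$DVID == 1)
  if (!any(pk_data$EVID == 0 & pk_data$MDV == 0)) {
    stop("Step 1 requires total-drug observation rows.", call. = FALSE)
  }
  theta0 <- c(CL = 0.25, V1 = 4, Q = 0.5, V2 = 4)
  spec <- pop_model_spec(
    "linear_pk", theta = theta0,
    omega2 = c(CL = 0.09, V1 = 0.09),
    sigma = c(total_drug = 0.2),
    covariates = allometric_weight_relations()
  )
  fit_nlme(spec, study_dataset(pk_data), init = config$step1_init,
           settings = config$settings)
}

#' Step 2: simultaneous drug + target QSS TMDD fit
#'
#' Fits the QSS TMDD model to both analytes simultaneously with
#' additive-log residual error per analyte, complex clearance tied to
#' drug clearance, allometric weight scaling on all disposition
#' parameters, and log-normal variability on `CL`, `V1` and the target
#' baseline. Disposition initials default to the step-1 estimates.
#'
#' @param config An [analysis_config()].
#' @param step1 The step-1 `nlme_fit` (run if missing).
#' @param data Optional pre-resolved dataset.
#' @return An `nlme_fit`.
#' @export
run_step2 <- function(config, step1 = NULL, data = NULL) {
  if (is.null(data)) data <- resolve_data(config)
  tb <- tibble::as_tibble(data)
  has_drug <- any(tb$EVID == 0 & tb$MDV == 0 & tb$DVID == 1)
  has_target <- any(tb$EVID == 0 & tb$MDV == 0 & tb$DVID == 2)
  if (!has_drug || !has_target) {
    stop("Step 2 requires observations of both analytes.", call. = FALSE)
  }
  if (is.null(step1)) step1 <- run_step1(config, data = data)
  pk <- step1$spec$theta
  theta0 <- c(CL = unname(pk[["CL"]]), V1 = unname(pk[["V1"]]),
              Q = unname(pk[["Q"]]), V2 = unname(pk[["V2"]]),
              BM0 = 0.004, kout = 0.3, Kss = 150)
  spec <- pop_model_spec(
    "qss_tmdd", theta = theta0,
    omega2 = c(CL = 0.04, V1 = 0.04, BM0 = 0.09),
    sigma = c(total_drug = 0.3, free_target = 0.3),
    covariates = allometric_weight_relations()
  )
  fit_nlme(spec, data, init = config$step2_init,
           settings = config$settings)
}

#' Run the full analysis pipeline
#'
#' Resolves the data once, runs both estimation steps, then (as
#' requested) stepwise covariate search, a randomization test, the
#' predictive check and typical-patient profiles, writing every
#' artifact plus a manifest of MD5 hashes under `out_dir`.
#'
#' @param config An [analysis_config()] with a non-NULL `out_dir`.
#' @return A list with the fitted objects, report paths and the
#'   manifest tibble.
#' @export
run_all <- function(config) {
  if (is.null(config$out_dir)) {
    stop("run_all needs `out_dir`.", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  data <- resolve_data(config)
  write_study_csv(data, out("dataset.csv"))
  step1 <- run_step1(config, data = data)
  readr::write_csv(tidy(step1), out("step1_estimates.csv"))
  step2 <- run_step2(config, step1 = step1, data = data)
  readr::write_csv(tidy(step2), out("step2_estimates.csv"))
  results <- list(step1 = step1, step2 = step2)
  if (!is.null(config$scm_candidates)) {
    scm_res <- scm(step2$spec, data, config$scm_candidates,
                   settings = config$settings)
    readr::write_csv(scm_res$log, out("scm_log.csv"))
    results$scm <- scm_res
  }
  if (!is.null(config$randtest)) {
    rt_args <- config$randtest
    cand <- as_candidate(config$scm_candidates[[1]])
    rt <- randomization_test(step2$spec, add_candidate(step2$spec, cand),
                             data, covariate = rt_args$covariate,
                             n_perm = rt_args$n_perm,
                             seed = config$seed + 2,
                             settings = config$settings)
    readr::write_csv(tibble::tibble(observed = rt$observed,
                                    critical_drop = rt$critical_drop,
                                    p_value = rt$p_value,
                                    n_failed = rt$n_failed),
                     out("randomization_test.csv"))
    results$randtest <- rt
  }
  vpc <- pcvpc(step2, n_sim = config$n_sim_vpc, seed = config$seed + 3)
  readr::write_csv(tibble::as_tibble(vpc), out("pcvpc.csv"))
  results$vpc <- vpc
  profiles <- typical_profiles(step2$spec$theta)
  readr::write_csv(profiles$summary, out("typical_profiles_summary.csv"))
  readr::write_csv(profiles$trajectories, out("typical_profiles.csv"))
  results$profiles <- profiles
  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  readr::write_csv(manifest, out("manifest.csv"))
  results$manifest <- manifest
  results
}
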