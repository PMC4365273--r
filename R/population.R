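#' Covariate-parameter relation
#'
#' One multiplicative covariate factor on a structural parameter, in one
#' of three forms: centered linear for continuous covariates
#' (`1 + theta * (Cov - ref)`), power (`(Cov / ref)^k`, with `k` fixed to
#' 0.75 for clearances and 1 for volumes under the allometric convention,
#' or estimated), and linear in an indicator for categorical covariates
#' (`1 + theta * 1[Cov == level]`).
#'
#' @param parameter Structural parameter name (e.g. `"CL"`).
#' @param covariate Covariate name: one of `weight`, `age`, `sex`,
#'   `snp_2578`, `snp_1154`, `snp_634`.
#' @param form `"linear_centered"`, `"power"` or `"linear_categorical"`.
#' @param value Coefficient `theta` (linear forms) or exponent `k`
#'   (power form).
#' @param ref Reference (median) covariate value; required and positive
#'   for the power form.
#' @param level Covariate level the indicator tests (categorical form).
#' @param fixed If `FALSE` the coefficient/exponent is estimated during
#'   fitting; if `TRUE` (default) it is held at `value`.
#' @return A `covariate_relation` list.
#' @examples
#' covariate_relation("CL", "weight", "power", value = 0.75, ref = 70)
#' @export
covariate_relation <- function(parameter, covariate,
                               form = c("linear_centered", "power",
                                        "linear_categorical"),
                               value, ref = NULL, level = NULL,
                               fixed = TRUE) {
  form <- match.arg(form)
  if (form == "power" && (is.null(ref) || ref <= 0)) {
    stop("Power form requires a positive reference value.", call. = FALSE)
  }
  if (form == "linear_centered" && is.null(ref)) {
    stop("Centered linear form requires a reference value.", call. = FALSE)
  }
  if (form == "linear_categorical" && is.null(level)) {
    stop("Categorical form requires `level`.", call. = FALSE)
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 value = value, ref = ref, level = level, fixed = fixed),
            class = "covariate_relation")
}

# id used for estimated coefficients and reporting
relation_label <- function(rel) {
  lvl <- if (!is.null(rel$level)) paste0(".", rel$level) else ""
  paste0("cov_", rel$parameter, "_", rel$covariate, lvl)
}

#' Allometric body-weight relations
#'
#' Standard fixed-exponent allometry on all clearance and volume
#' parameters: exponent 0.75 on `CL`, `Q` (and the complex clearance tied
#' to `CL`), exponent 1 on `V1`, `V2`, referenced to 70 kg.
#'
#' @param clearances,volumes Character vectors of parameter names.
#' @param ref Reference body weight, kg.
#' @return A list of [covariate_relation()]s.
#' @export
allometric_weight_relations <- function(clearances = c("CL", "Q"),
                                        volumes = c("V1", "V2"),
                                        ref = 70) {
  c(
    purrr::map(clearances, covariate_relation, covariate = "weight",
               form = "power", value = 0.75, ref = ref),
    purrr::map(volumes, covariate_relation, covariate = "weight",
               form = "power", value = 1, ref = ref)
  )
}

#' Population model specification
#'
#' Bundles everything that maps population quantities to an individual's
#' structural parameters and observation distributions: the structural
#' model, typical values `theta` (natural scale), diagonal log-normal
#' random-effect variances `omega2` (named subset of `theta`), residual
#' error models and magnitudes per analyte, and covariate relations.
#' Individual parameters follow
#' `P_i = P_pop * (covariate factors) * exp(eta_i)`.
#'
#' @param structural `"linear_pk"`, `"qss_tmdd"`, or a function
#'   `f(params, subject)` returning predictions (nM) at
#'   `subject$obs_times` (an escape hatch for custom models; used mostly
#'   for testing the estimation machinery on analytically tractable
#'   cases).
#' @param theta Named numeric vector of typical values. For
#'   `"qss_tmdd"`: `CL, V1, Q, V2, BM0, kout, Kss` (BM0 in nM); the
#'   complex clearance is tied to `CL`. For `"linear_pk"`:
#'   `CL, V1, Q, V2`.
#' @param omega2 Named numeric vector of random-effect variances
#'   (may be empty).
#' @param sigma Named numeric vector of residual-error magnitudes, one
#'   per analyte present (`total_drug`, `free_target`).
#' @param error_model Named character vector per analyte:
#'   `"proportional"`, `"additive"` or `"additive_log"`.
#' @param covariates List of [covariate_relation()]s.
#' @param iiv_form `"exponential"` (log-normal, default) or `"additive"`
#'   random effects.
#' @param constants [molar_constants()].
#' @return A `pop_model_spec` list.
#' @export
pop_model_spec <- function(structural, theta, omega2 = numeric(),
                           sigma, error_model = NULL, covariates = list(),
                           iiv_form = c("exponential", "additive"),
                           constants = molar_constants()) {
  iiv_form <- match.arg(iiv_form)
  if (is.character(structural)) {
    structural <- match.arg(structural, c("linear_pk", "qss_tmdd"))
    needed <- switch(structural,
                     linear_pk = c("CL", "V1", "Q", "V2"),
                     qss_tmdd = c("CL", "V1", "Q", "V2", "BM0", "kout", "Kss"))
    if (!all(needed %in% names(theta))) {
      stop("`theta` must contain: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
  } else if (!is.function(structural)) {
    stop("`structural` must be a model name or a prediction function.",
         call. = FALSE)
  }
  if (is.null(error_model)) {
    error_model <- if (identical(structural, "linear_pk")) {
      c(total_drug = "proportional")
    } else {
      c(total_drug = "additive_log", free_target = "additive_log")
    }
  }
  stopifnot(all(error_model %in% c("proportional", "additive",
                                   "additive_log")))
  if (!all(names(error_model) %in% c("total_drug", "free_target"))) {
    stop("Analytes must be 'total_drug' and/or 'free_target'.",
         call. = FALSE)
  }
  if (!setequal(names(sigma), names(error_model))) {
    stop("`sigma` must be named per analyte in `error_model`.",
         call. = FALSE)
  }
  if (any(omega2 < 0)) stop("omega2 must be non-negative.", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive.", call. = FALSE)
  if (length(omega2) > 0 && !all(names(omega2) %in% names(theta))) {
    stop("omega2 names must be a subset of theta names.", call. = FALSE)
  }
  for (rel in covariates) {
    if (!rel$parameter %in% names(theta)) {
      stop("Covariate relation references unknown parameter ",
           rel$parameter, call. = FALSE)
    }
  }
  structure(list(structural = structural, theta = theta, omega2 = omega2,
                 sigma = sigma, error_model = error_model,
                 covariates = covariates, iiv_form = iiv_form,
                 constants = constants),
            class = "pop_model_spec")
}

# multiplicative covariate factor for one parameter and one subject
covariate_factor <- function(rel, covs) {
  x <- covs[[rel$covariate]]
  if (is.null(x)) {
    stop("Subject lacks covariate ", rel$covariate, call. = FALSE)
  }
  switch(rel$form,
    linear_centered = 1 + rel$value * (x - rel$ref),
    power = (x / rel$ref)^rel$value,
    linear_categorical = 1 + rel$value * as.numeric(identical(x, rel$level))
  )
}

#' Resolve individual structural parameters
#'
#' Applies covariate factors and random effects to the typical values:
#' `P_i = P_pop * prod(factors) * exp(eta)` (or `+ eta` under the
#' additive form). Linear covariate forms that drive a parameter
#' non-positive raise an error rather than being clipped.
#'
#' @param spec A [pop_model_spec()].
#' @param eta Named numeric vector of random effects (parameters not
#'   named are treated as 0).
#' @param covariates Named list of subject covariates (`weight`, `age`,
#'   `sex`, `snp_*`).
#' @param theta Optional override of `spec$theta`.
#' @return Named numeric vector of individual parameters; for the
#'   `qss_tmdd` structural model this includes `CL_RC = CL`.
#' @examples
#' spec <- pop_model_spec("linear_pk",
#'   theta = c(CL = 0.17, V1 = 3.14, Q = 0.36, V2 = 2.63),
#'   omega2 = c(CL = 0.053), sigma = c(total_drug = 0.24),
#'   covariates = allometric_weight_relations())
#' individual_parameters(spec, eta = c(CL = 0), covariates = list(weight = 94))
#' @export
individual_parameters <- function(spec, eta = numeric(),
                                  covariates = list(), theta = NULL) {
  th <- if (is.null(theta)) spec$theta else theta
  p <- th
  for (rel in spec$covariates) {
    f <- covariate_factor(rel, covariates)
    p[rel$parameter] <- p[rel$parameter] * f
  }
  if (any(p <= 0)) {
    stop("Covariate relation yields non-positive parameter(s): ",
         paste(names(p)[p <= 0], collapse = ", "), call. = FALSE)
  }
  if (length(eta) > 0) {
    idx <- names(eta)[names(eta) %in% names(p)]
    if (spec$iiv_form == "exponential") {
      p[idx] <- p[idx] * exp(eta[idx])
    } else {
      p[idx] <- p[idx] + eta[idx]
    }
  }
  if (identical(spec$structural, "qss_tmdd")) {
    p <- c(p, CL_RC = unname(p[["CL"]]))
  }
  p
}

#' Residual-error distribution for one prediction
#'
#' Returns the mean and variance of the (possibly transformed)
#' observation for a model prediction `f`: proportional error gives mean
#' `f`, variance `(sigma * f)^2` on the natural scale; additive gives
#' variance `sigma^2`; additive-log gives mean `log f`, variance
#' `sigma^2` on the log scale (so `sigma` is approximately the CV for
#' small `sigma`).
#'
#' @param spec A [pop_model_spec()].
#' @param analyte `"total_drug"` or `"free_target"`.
#' @param prediction Model prediction(s), must be positive for the
#'   log-scale model.
#' @return Tibble with columns `mean`, `variance`, `scale` (`"natural"`
#'   or `"log"`).
#' @export
residual_distribution <- function(spec, analyte, prediction) {
  model <- spec$error_model[[analyte]]
  sigma <- spec$sigma[[analyte]]
  if (is.null(model) || is.null(sigma) || sigma <= 0) {
    stop("No valid residual model for analyte ", analyte, call. = FALSE)
  }
  if (model == "additive_log" && any(prediction <= 0)) {
    stop("Log-scale residual model needs positive predictions.",
         call. = FALSE)
  }
  switch(model,
    proportional = tibble::tibble(mean = prediction,
                                  variance = (sigma * prediction)^2,
                                  scale = "natural"),
    additive = tibble::tibble(mean = prediction, variance = sigma^2,
                              scale = "natural"),
    additive_log = tibble::tibble(mean = log(prediction), variance = sigma^2,
                                  scale = "log")
  )
}

#' Inter-individual variability as a CV percentage
#'
#' Converts a log-normal random-effect variance `omega2` to a coefficient
#' of variation in percent. By default small variances are reported as
#' `100 * omega` (the convention most parameter tables use, and
#' indistinguishable from the exact value below about 30 % CV); set
#' `exact = TRUE` for the exact log-normal CV
#' `100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 Non-negative variance(s).
#' @param exact Use the exact log-normal formula regardless of magnitude.
#' @return CV in percent.
#' @examples
#' iiv_cv_percent(0.04) # ~20
#' iiv_cv_percent(0.04, exact = TRUE) # 20.2
#' @export
iiv_cv_percent <- function(omega2, exact = FALSE) {
  stopifnot(all(omega2 >= 0))
  omega <- sqrt(omega2)
  exact_cv <- 100 * sqrt(exp(omega2) - 1)
  if (exact) exact_cv else ifelse(omega < 0.3, 100 * omega, exact_cv)
}
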