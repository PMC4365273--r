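#' Estimation settings
#'
#' Numerical controls for the marginal-likelihood engine. The objective
#' is a Laplace approximation of the marginal likelihood with interaction
#' (residual variance evaluated at the individual prediction), minimized
#' over log-transformed population quantities. Random-effect modes are
#' found per subject by damped Gauss-Newton with a Fisher-scoring
#' Hessian, which is exact for models linear in the random effects with
#' constant residual variance.
#'
#' @param inner_maxit Maximum inner (per-subject) iterations.
#' @param inner_tol Convergence tolerance on the inner step norm.
#' @param fd_step Forward-difference step for random-effect Jacobians.
#' @param interaction Evaluate residual variance at the individual
#'   prediction (TRUE, default) or the population prediction.
#' @param outer_rel_tol Relative objective-change tolerance of the outer
#'   optimizer.
#' @param outer_fd_step Central-difference step (transformed scale) of
#'   the outer gradient.
#' @param outer_maxit,outer_maxeval Outer iteration/evaluation budget.
#' @param covariance_step Compute the covariance matrix and relative
#'   standard errors after fitting.
#' @param rtol,atol Integrator tolerances passed to the TMDD solver.
#' @return A list of settings.
#' @export
estimation_settings <- function(inner_maxit = 50, inner_tol = 1e-6,
                                fd_step = 1e-4, interaction = TRUE,
                                outer_rel_tol = 1e-6, outer_maxit = 400,
                                outer_maxeval = 2000, outer_fd_step = 1e-3,
                                covariance_step = TRUE,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inner_tol > 0, outer_rel_tol > 0, fd_step > 0)
  list(inner_maxit = inner_maxit, inner_tol = inner_tol, fd_step = fd_step,
       interaction = interaction, outer_rel_tol = outer_rel_tol,
       outer_maxit = outer_maxit, outer_maxeval = outer_maxeval,
       outer_fd_step = outer_fd_step,
       covariance_step = covariance_step, rtol = rtol, atol = atol)
}

# ---- structural predictions (hot path: plain numeric vectors) ----

pred_natural <- function(spec, params, subject, settings) {
  if (is.function(spec$structural)) {
    return(spec$structural(params, subject))
  }
  if (identical(spec$structural, "linear_pk")) {
    if (any(subject$obs_dvid != 1)) {
      stop("linear_pk model supports total-drug observations only ",
           "(subject ", subject$id, ")", call. = FALSE)
    }
    return(linear_pk_conc(params, subject))
  }
  states <- tmdd_solve_cpp(params, subject$dose_times, subject$dose_nmol,
                           subject$dose_durations, subject$obs_times,
                           settings$rtol, settings$atol)
  out <- states[, "Ctot"]
  i2 <- subject$obs_dvid == 2
  if (any(i2)) {
    Ctot <- pmax(states[i2, "Ctot"], 0)
    Rtot <- pmax(states[i2, "Rtot"], 0)
    C <- qss_free_drug(Ctot, Rtot, params[["Kss"]])
    out[i2] <- Rtot * params[["Kss"]] / (params[["Kss"]] + C)
  }
  out
}

# closed-form two-compartment central concentration at subject obs times
linear_pk_conc <- function(params, subject) {
  d <- normalize_doses(subject$dose_times, subject$dose_nmol,
                       subject$dose_durations)
  CL <- params[["CL"]]; V1 <- params[["V1"]]
  Q <- params[["Q"]]; V2 <- params[["V2"]]
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  times <- subject$obs_times
  conc <- numeric(length(times))
  for (i in seq_along(d$times)) {
    k0 <- d$nmol[i] / d$durations[i]
    tt <- times - d$times[i]
    te <- pmax(pmin(tt, d$durations[i]), 0)
    dec <- pmax(tt - te, 0)
    conc <- conc + (k0 / V1) * (
      (A / alpha) * (1 - exp(-alpha * te)) * exp(-alpha * dec) +
      (B / beta) * (1 - exp(-beta * te)) * exp(-beta * dec)
    )
  }
  conc
}

# per-observation residual machinery: given natural predictions f, return
# transformed prediction fstar, variance v and (optionally) dv/df factor
obs_layers <- function(spec, subject) {
  analyte <- ifelse(subject$obs_dvid == 1, "total_drug", "free_target")
  model <- unname(spec$error_model[analyte])
  if (any(is.na(model))) {
    stop("Dataset has analytes the spec declares no error model for.",
         call. = FALSE)
  }
  sigma <- unname(spec$sigma[analyte])
  ystar <- ifelse(model == "additive_log", log(subject$obs_nM),
                  subject$obs_nM)
  list(analyte = analyte, model = model, sigma = sigma, ystar = ystar)
}

# transformed predictions + variance at natural predictions f
obs_eval <- function(layers, f, f_var = NULL) {
  islog <- layers$model == "additive_log"
  if (any(islog & f <= 0)) {
    return(NULL)  # infeasible parameters for log-scale residuals
  }
  fv <- if (is.null(f_var)) f else f_var  # predictions used in the variance
  fstar <- ifelse(islog, log(f), f)
  v <- ifelse(layers$model == "proportional", (layers$sigma * fv)^2,
              layers$sigma^2)
  if (any(v <= 0)) return(NULL)
  list(fstar = fstar, v = v, f = f)
}

obs_neg2ll <- function(layers, ev) {
  r <- layers$ystar - ev$fstar
  sum(log(2 * pi * ev$v) + r * r / ev$v)
}

BAD_OFV <- 1e10

# ---- inner problem: random-effect mode and Laplace contribution ----

inner_laplace <- function(spec, subject, settings, eta0 = NULL) {
  eff <- names(spec$omega2)[spec$omega2 > 0]
  d <- length(eff)
  layers <- obs_layers(spec, subject)
  omega2 <- spec$omega2[eff]

  # covariate factors do not depend on eta: resolve them once, then apply
  # eta multiplicatively (or additively) in the hot loop
  p_base <- individual_parameters(spec, covariates = subject$covariates)
  iiv_idx <- match(eff, names(p_base))
  expform <- spec$iiv_form == "exponential"
  tie_clrc <- identical(spec$structural, "qss_tmdd")
  clrc_idx <- if (tie_clrc) match(c("CL_RC", "CL"), names(p_base)) else NULL
  islog <- layers$model == "additive_log"
  isprop <- layers$model == "proportional"
  sig2 <- layers$sigma^2
  v_const <- sig2  # variance for the additive/additive-log observations

  f_pop <- NULL
  if (!settings$interaction && d > 0) {
    f_pop <- pred_natural(spec, p_base, subject, settings)
  }
  eval_g <- function(eta) {
    p <- p_base
    if (d > 0) {
      if (expform) p[iiv_idx] <- p[iiv_idx] * exp(eta)
      else p[iiv_idx] <- p[iiv_idx] + eta
      if (tie_clrc) p[clrc_idx[1]] <- p[clrc_idx[2]]
    }
    f <- tryCatch(pred_natural(spec, p, subject, settings),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(NULL)
    if (any(islog) && any(f[islog] <= 0)) return(NULL)
    fstar <- f
    if (any(islog)) fstar[islog] <- log(f[islog])
    fv <- if (is.null(f_pop)) f else f_pop
    v <- v_const
    if (any(isprop)) v[isprop] <- sig2[isprop] * fv[isprop]^2
    if (any(v <= 0)) return(NULL)
    r <- layers$ystar - fstar
    g <- sum(log(2 * pi * v) + r * r / v)
    if (d > 0) g <- g + sum(log(2 * pi * omega2) + eta^2 / omega2)
    list(g = g, ev = list(fstar = fstar, v = v, f = f))
  }

  if (d == 0) {
    base <- eval_g(setNames(numeric(0), character(0)))
    if (is.null(base)) {
      return(list(contribution = BAD_OFV, eta = numeric(0), ok = FALSE))
    }
    return(list(contribution = base$g, eta = numeric(0),
                hessian = matrix(0, 0, 0), ok = TRUE))
  }

  eta <- if (is.null(eta0)) setNames(numeric(d), eff) else eta0[eff]
  base <- eval_g(eta)
  if (is.null(base)) {
    eta <- setNames(numeric(d), eff)
    base <- eval_g(eta)
    if (is.null(base)) {
      return(list(contribution = BAD_OFV, eta = eta, ok = FALSE))
    }
  }
  h <- settings$fd_step
  converged <- FALSE
  H <- NULL
  for (iter in seq_len(settings$inner_maxit)) {
    # Jacobian of transformed predictions wrt eta (forward differences)
    J <- matrix(0, length(base$ev$fstar), d)
    for (k in seq_len(d)) {
      ek <- eta; ek[k] <- ek[k] + h
      pk <- eval_g(ek)
      if (is.null(pk)) { ek[k] <- eta[k] - h; pk <- eval_g(ek) }
      if (is.null(pk)) {
        return(list(contribution = base$g, eta = eta, ok = FALSE))
      }
      J[, k] <- (pk$ev$fstar - base$ev$fstar) / (ek[k] - eta[k])
    }
    r <- layers$ystar - base$ev$fstar
    v <- base$ev$v
    prop_int <- settings$interaction & layers$model == "proportional"
    # dv/deta_k = 2 sigma^2 f J_k for proportional-with-interaction
    dvfac <- ifelse(prop_int, 2 * layers$sigma^2 * base$ev$f, 0)
    grad <- numeric(d)
    H <- matrix(0, d, d)
    for (k in seq_len(d)) {
      dv_k <- dvfac * J[, k]
      grad[k] <- sum(dv_k / v - 2 * r * J[, k] / v - r^2 * dv_k / v^2) +
        2 * eta[k] / omega2[k]
      for (l in seq_len(k)) {
        dv_l <- dvfac * J[, l]
        H[k, l] <- sum(2 * J[, k] * J[, l] / v + dv_k * dv_l / v^2)
        H[l, k] <- H[k, l]
      }
    }
    diag(H) <- diag(H) + 2 / omega2
    delta <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      return(list(contribution = base$g, eta = eta, hessian = H, ok = FALSE))
    }
    if (sqrt(sum(delta^2)) < settings$inner_tol) {
      converged <- TRUE
      break
    }
    step <- 1
    improved <- FALSE
    for (ls in 1:6) {
      cand <- eta + step * delta
      trial <- eval_g(cand)
      if (!is.null(trial) && trial$g <= base$g + 1e-12) {
        gain <- base$g - trial$g
        eta <- cand; base <- trial; improved <- TRUE
        # at the finite-difference noise floor further steps are noise
        if (gain < 1e-9 * (1 + abs(base$g))) improved <- FALSE
        break
      }
      step <- step / 2
    }
    if (!improved || sqrt(sum((step * delta)^2)) < settings$inner_tol) {
      converged <- TRUE
      break
    }
  }
  ld <- determinant(H / 2, logarithm = TRUE)
  if (ld$sign <= 0) {
    return(list(contribution = base$g, eta = eta, hessian = H, ok = FALSE))
  }
  contribution <- base$g + as.numeric(ld$modulus) - d * log(2 * pi)
  list(contribution = contribution, eta = eta, hessian = H, ok = converged)
}

# ---- exported likelihood pieces ----

as_subjects <- function(data, constants) {
  if (is.data.frame(data)) prep_subjects(data, constants) else data
}

#' Joint -2 log-likelihood of one subject at fixed random effects
#'
#' The sum of the observation terms (Gaussian on the error-model scale)
#' and the random-effect prior terms, i.e. the function whose minimizer
#' over `eta` is the empirical Bayes mode.
#'
#' @param spec A [pop_model_spec()].
#' @param data A study dataset (or prepped subject list).
#' @param id Subject id.
#' @param eta Named random-effect vector.
#' @param settings [estimation_settings()].
#' @return Scalar -2 log joint likelihood.
#' @export
subject_joint_neg2ll <- function(spec, data, id, eta,
                                 settings = estimation_settings()) {
  subjects <- as_subjects(data, spec$constants)
  subject <- subjects[[as.character(id)]]
  if (is.null(subject)) stop("Unknown subject id ", id, call. = FALSE)
  eff <- names(spec$omega2)[spec$omega2 > 0]
  layers <- obs_layers(spec, subject)
  p <- individual_parameters(spec, eta = eta, covariates = subject$covariates)
  f <- pred_natural(spec, p, subject, settings)
  f_pop <- NULL
  if (!settings$interaction && length(eff) > 0) {
    p0 <- individual_parameters(spec, covariates = subject$covariates)
    f_pop <- pred_natural(spec, p0, subject, settings)
  }
  ev <- obs_eval(layers, f, f_var = f_pop)
  if (is.null(ev)) return(BAD_OFV)
  g <- obs_neg2ll(layers, ev)
  if (length(eff) > 0) {
    om <- spec$omega2[eff]
    g <- g + sum(log(2 * pi * om) + eta[eff]^2 / om)
  }
  g
}

#' Laplace contribution of one subject to the objective function
#'
#' Minimizes the joint -2 log-likelihood over the subject's random
#' effects and returns the Laplace-approximate marginal contribution
#' (mode value plus the log-determinant correction, 2-pi terms
#' included), together with the mode and the inner Hessian.
#'
#' @inheritParams subject_joint_neg2ll
#' @return A list with `contribution`, `eta` (the empirical Bayes mode),
#'   `hessian` and `ok`.
#' @export
subject_laplace_contribution <- function(spec, data, id,
                                         settings = estimation_settings()) {
  subjects <- as_subjects(data, spec$constants)
  subject <- subjects[[as.character(id)]]
  if (is.null(subject)) stop("Unknown subject id ", id, call. = FALSE)
  inner_laplace(spec, subject, settings)
}

#' Objective function value (OFV) of a population model on a dataset
#'
#' `-2 *` the Laplace-approximate marginal log-likelihood: the sum of
#' per-subject contributions, hence additive over subjects and invariant
#' to their order.
#'
#' @inheritParams subject_joint_neg2ll
#' @param warm Internal environment for warm-started random-effect modes.
#' @return Scalar OFV.
#' @export
ofv <- function(spec, data, settings = estimation_settings(), warm = NULL) {
  subjects <- as_subjects(data, spec$constants)
  total <- 0
  failed <- character()
  for (id in names(subjects)) {
    eta0 <- if (!is.null(warm)) warm$eta[[id]] else NULL
    res <- inner_laplace(spec, subjects[[id]], settings, eta0 = eta0)
    if (!is.null(warm)) warm$eta[[id]] <- res$eta
    if (!res$ok && res$contribution >= BAD_OFV) failed <- c(failed, id)
    total <- total + res$contribution
  }
  if (length(failed) > 0) {
    attr(total, "failed_subjects") <- failed
  }
  total
}

# ---- outer parameter bookkeeping ----

# table of estimated quantities: term, type, transform
par_map <- function(spec, fix = character()) {
  fixed <- function(nm, type) {
    nm %in% fix || paste(type, nm, sep = ".") %in% fix
  }
  rows <- list()
  for (nm in names(spec$theta)) {
    if (!fixed(nm, "theta")) {
      rows[[length(rows) + 1]] <-
        list(term = nm, type = "theta", transform = "log")
    }
  }
  for (rel in spec$covariates) {
    if (!isTRUE(rel$fixed)) {
      rows[[length(rows) + 1]] <-
        list(term = relation_label(rel), type = "cov", transform = "identity")
    }
  }
  for (nm in names(spec$omega2)) {
    if (spec$omega2[nm] > 0 && !fixed(nm, "omega2")) {
      rows[[length(rows) + 1]] <-
        list(term = nm, type = "omega2", transform = "log")
    }
  }
  for (nm in names(spec$sigma)) {
    rows[[length(rows) + 1]] <-
      list(term = nm, type = "sigma", transform = "log")
  }
  dplyr::bind_rows(rows)
}

spec_values <- function(spec, map) {
  purrr::map2_dbl(map$term, map$type, function(term, type) {
    switch(type,
      theta = spec$theta[[term]],
      omega2 = spec$omega2[[term]],
      sigma = spec$sigma[[term]],
      cov = {
        idx <- which(purrr::map_chr(spec$covariates, relation_label) == term)
        spec$covariates[[idx]]$value
      }
    )
  })
}

to_transformed <- function(values, map) {
  ifelse(map$transform == "log", log(values), values)
}

apply_values <- function(spec, map, x) {
  values <- ifelse(map$transform == "log", exp(x), x)
  for (i in seq_len(nrow(map))) {
    term <- map$term[i]
    switch(map$type[i],
      theta = spec$theta[term] <- values[i],
      omega2 = spec$omega2[term] <- values[i],
      sigma = spec$sigma[term] <- values[i],
      cov = {
        idx <- which(purrr::map_chr(spec$covariates, relation_label) == term)
        spec$covariates[[idx]]$value <- values[i]
      }
    )
  }
  spec
}

#' Fit a population model by Laplace-approximate marginal likelihood
#'
#' Minimizes [ofv()] over the log-transformed typical values,
#' random-effect variances and residual magnitudes (estimated covariate
#' coefficients enter untransformed). Deterministic given data, initial
#' values and settings: no random numbers are used anywhere in
#' estimation. After convergence the empirical Bayes modes, shrinkage
#' and (optionally) the covariance step are computed.
#'
#' @param spec A [pop_model_spec()]; its parameter values are the
#'   initial estimates unless overridden by `init`.
#' @param data A study dataset tibble.
#' @param init Optional named list with elements `theta`, `omega2`,
#'   `sigma` overriding starting values.
#' @param settings [estimation_settings()].
#' @param fix Character vector of parameter names to hold fixed at
#'   their initial values. A bare name fixes both the typical value and
#'   its variance; `"theta.CL"` / `"omega2.CL"` fix one of the two.
#' @return An `nlme_fit` object; see [tidy.nlme_fit()] and
#'   [glance.nlme_fit()].
#' @export
fit_nlme <- function(spec, data, init = NULL,
                     settings = estimation_settings(), fix = character()) {
  if (!is.null(init)) {
    for (slot in c("theta", "omega2", "sigma")) {
      if (!is.null(init[[slot]])) {
        common <- intersect(names(init[[slot]]), names(spec[[slot]]))
        spec[[slot]][common] <- init[[slot]][common]
      }
    }
  }
  subjects <- as_subjects(data, spec$constants)
  map <- par_map(spec, fix = fix)
  x0 <- to_transformed(spec_values(spec, map), map)
  warm <- new.env(parent = emptyenv())
  warm$eta <- list()
  n_eval <- 0L
  obj <- function(x) {
    n_eval <<- n_eval + 1L
    sp <- apply_values(spec, map, x)
    val <- ofv(sp, subjects, settings, warm = warm)
    as.numeric(val)
  }
  # Central-difference outer gradient with a step large enough to sit
  # well above the solver/inner-optimization noise floor of the OFV.
  hg <- settings$outer_fd_step
  grad <- function(x) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + hg
      xm <- x; xm[i] <- x[i] - hg
      g[i] <- (obj(xp) - obj(xm)) / (2 * hg)
    }
    g
  }
  # box constraints on the transformed scale keep log-variances away
  # from degenerate collapse (omega2 ~ exp(-16) is numerically zero IIV)
  lower <- ifelse(map$transform == "log", -16, -Inf)
  upper <- ifelse(map$transform == "log", 16, Inf)
  opt <- stats::nlminb(x0, obj, gradient = grad,
                       lower = lower, upper = upper,
                       control = list(rel.tol = settings$outer_rel_tol,
                                      iter.max = settings$outer_maxit,
                                      eval.max = settings$outer_maxeval))
  final <- apply_values(spec, map, opt$par)
  # empirical Bayes modes and per-subject contributions at the optimum
  ebe <- list()
  contributions <- numeric(length(subjects))
  failed <- character()
  for (i in seq_along(subjects)) {
    id <- names(subjects)[i]
    res <- inner_laplace(final, subjects[[id]], settings,
                         eta0 = warm$eta[[id]])
    ebe[[id]] <- res$eta
    contributions[i] <- res$contribution
    if (!res$ok) failed <- c(failed, id)
  }
  eff <- names(final$omega2)[final$omega2 > 0]
  eta_tbl <- if (length(eff) > 0) {
    dplyr::bind_cols(
      tibble::tibble(ID = names(subjects)),
      purrr::map_dfr(ebe, ~ tibble::as_tibble(as.list(.x[eff])))
    )
  } else {
    tibble::tibble(ID = names(subjects))
  }
  fit <- structure(list(
    spec = final, map = map, data = data, subjects = subjects,
    estimate = setNames(ifelse(map$transform == "log", exp(opt$par),
                               opt$par), map$term),
    par = opt$par,
    ofv = opt$objective, contributions = setNames(contributions,
                                                  names(subjects)),
    eta = eta_tbl, failed_subjects = failed,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations, n_eval = n_eval),
    settings = settings,
    n_obs = sum(purrr::map_int(subjects, ~ length(.x$obs_times)))
  ), class = "nlme_fit")
  fit$shrinkage <- shrinkage(fit)
  if (settings$covariance_step) {
    fit <- add_covariance(fit)
  }
  fit
}

#' @export
print.nlme_fit <- function(x, ...) {
  cat("Population model fit (Laplace marginal likelihood)\n")
  cat(sprintf("  structural model: %s\n",
              if (is.function(x$spec$structural)) "custom"
              else x$spec$structural))
  cat(sprintf("  subjects: %d   observations: %d   OFV: %.3f\n",
              length(x$subjects), x$n_obs, x$ofv))
  cat(sprintf("  outer convergence code %d after %d evaluations\n",
              x$convergence$code, x$convergence$n_eval))
  if (length(x$failed_subjects) > 0) {
    cat("  inner step flagged for subjects:",
        paste(x$failed_subjects, collapse = ", "), "\n")
  }
  print(tidy(x))
  invisible(x)
}

#' Empirical Bayes random-effect estimates
#'
#' Per-subject posterior modes of the random effects at the final
#' population estimates (already computed during fitting; re-derived
#' here on request for a possibly different dataset).
#'
#' @param fit An `nlme_fit`.
#' @param data Optional dataset; defaults to the fitted one.
#' @return Tibble with `ID` and one column per random effect.
#' @export
empirical_bayes <- function(fit, data = NULL) {
  if (is.null(data)) return(fit$eta)
  subjects <- as_subjects(data, fit$spec$constants)
  eff <- names(fit$spec$omega2)[fit$spec$omega2 > 0]
  rows <- purrr::map(subjects, function(s) {
    res <- inner_laplace(fit$spec, s, fit$settings)
    tibble::as_tibble(as.list(res$eta[eff]))
  })
  dplyr::bind_cols(tibble::tibble(ID = names(subjects)),
                   dplyr::bind_rows(rows))
}

#' Shrinkage diagnostics
#'
#' Random-effect shrinkage `100 * (1 - sd(eta_hat) / omega)` per effect,
#' and residual shrinkage `100 * (1 - sd(IWRES))` per analyte, where
#' IWRES is the individual weighted residual at the empirical Bayes
#' mode. Values near 100 % flag uninformative individual data.
#'
#' @param fit An `nlme_fit`.
#' @return List with elements `eta` (named numeric, %) and `eps`
#'   (named numeric, %).
#' @export
shrinkage <- function(fit) {
  spec <- fit$spec
  eff <- names(spec$omega2)[spec$omega2 > 0]
  eta_shr <- setNames(rep(NA_real_, length(eff)), eff)
  for (k in eff) {
    est <- fit$eta[[k]]
    if (!is.null(est) && length(est) > 1) {
      eta_shr[k] <- 100 * (1 - sd(est) / sqrt(spec$omega2[[k]]))
    }
  }
  iwres <- gof_residuals(fit)
  eps_shr <- iwres |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(shr = 100 * (1 - sd(.data$iwres)), .groups = "drop")
  list(eta = eta_shr, eps = setNames(eps_shr$shr, eps_shr$analyte))
}

# covariance step: central finite-difference Hessian of the OFV on the
# transformed scale; covariance = 2 * inverse Hessian; delta method back
# to the natural scale.
add_covariance <- function(fit) {
  map <- fit$map
  spec <- fit$spec
  subjects <- fit$subjects
  settings <- fit$settings
  warm <- new.env(parent = emptyenv())
  warm$eta <- as.list(setNames(purrr::map(names(subjects), function(id) {
    eff <- names(spec$omega2)[spec$omega2 > 0]
    e <- fit$eta[fit$eta$ID == id, eff, drop = FALSE]
    setNames(as.numeric(unlist(e[1, ])), eff)
  }), names(subjects)))
  f <- function(x) as.numeric(ofv(apply_values(spec, map, x), subjects,
                                  settings, warm = warm))
  x <- fit$par
  p <- length(x)
  # step large enough that h^2 * curvature clears the OFV noise floor
  # even for weakly identified variance components
  hstep <- rep(1e-2, p)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      hi <- hstep[i]; hj <- hstep[j]
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hi
        xm <- x; xm[i] <- x[i] - hi
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hi^2
      } else {
        xpp <- x; xpp[i] <- x[i] + hi; xpp[j] <- x[j] + hj
        xpm <- x; xpm[i] <- x[i] + hi; xpm[j] <- x[j] - hj
        xmp <- x; xmp[i] <- x[i] - hi; xmp[j] <- x[j] + hj
        xmm <- x; xmm[i] <- x[i] - hi; xmm[j] <- x[j] - hj
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hi * hj)
      }
    }
  }
  vcov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
  ok <- !is.null(vcov_t) && all(diag(vcov_t) > 0)
  if (ok) {
    est_nat <- fit$estimate
    scale <- ifelse(map$transform == "log", est_nat, 1)
    vcov_nat <- vcov_t * tcrossprod(scale)
    se <- sqrt(diag(vcov_nat))
    fit$vcov <- vcov_nat
    fit$se <- setNames(se, map$term)
    fit$rse_pct <- setNames(100 * se / abs(est_nat), map$term)
    fit$covariance_ok <- TRUE
  } else {
    fit$vcov <- NULL
    fit$se <- setNames(rep(NA_real_, nrow(map)), map$term)
    fit$rse_pct <- fit$se
    fit$covariance_ok <- FALSE
  }
  fit
}

#' Covariance step results
#'
#' @param fit An `nlme_fit`.
#' @return List with the natural-scale covariance matrix (`vcov`),
#'   standard errors and RSE percentages; computed on demand if the fit
#'   skipped the covariance step.
#' @export
standard_errors <- function(fit) {
  if (is.null(fit[["se"]]) || all(is.na(fit[["se"]]))) {
    fit <- add_covariance(fit)
  }
  list(vcov = fit[["vcov"]], se = fit[["se"]], rse_pct = fit[["rse_pct"]],
       ok = isTRUE(fit[["covariance_ok"]]))
}

#' Likelihood-ratio test between nested fits
#'
#' Compares the OFV drop to the upper tail of a chi-square with `df`
#' degrees of freedom. A negative drop (full model worse) yields p = 1
#' with a warning.
#'
#' @param ofv_reduced,ofv_full OFVs of the nested models.
#' @param df Number of additional parameters in the full model.
#' @return Tibble with `delta_ofv` (reduced - full), `df`, `p_value`.
#' @examples
#' lrt(105.2, 100.0, df = 1)
#' @export
lrt <- function(ofv_reduced, ofv_full, df) {
  stopifnot(df >= 1)
  delta <- ofv_reduced - ofv_full
  if (delta < 0) {
    warning("Full model has higher OFV than reduced model; p set to 1.")
    p <- 1
  } else {
    p <- pchisq(delta, df = df, lower.tail = FALSE)
  }
  tibble::tibble(delta_ofv = delta, df = df, p_value = p)
}

#' Critical OFV drop for a given significance level
#'
#' The chi-square quantile used as the inclusion/deletion threshold in
#' covariate model building: 3.84 at p = 0.05 and 6.64 at p = 0.01 for
#' one parameter.
#'
#' @param p Confidence level (e.g. 0.95).
#' @param df Degrees of freedom.
#' @return Critical delta-OFV.
#' @examples
#' chi2_quantile(0.95, 1) # 3.84
#' chi2_quantile(0.99, 1) # 6.64
#' @export
chi2_quantile <- function(p, df = 1) {
  qchisq(p, df = df)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy estimates of a population fit
#'
#' One row per estimated quantity with its type (`theta`, `omega2`,
#' `sigma`, `cov`), natural-scale estimate, standard error and RSE.
#' Random-effect variances additionally carry the CV% convention used in
#' parameter tables.
#'
#' @param x An `nlme_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nlme_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = x$map$term, type = x$map$type,
    estimate = unname(x$estimate),
    se = if (is.null(x[["se"]])) NA_real_ else unname(x[["se"]][x$map$term]),
    rse_pct = if (is.null(x[["rse_pct"]])) NA_real_
              else unname(x[["rse_pct"]][x$map$term])
  )
  out$cv_pct <- ifelse(out$type == "omega2",
                       iiv_cv_percent(pmax(out$estimate, 0)), NA_real_)
  out
}

#' One-line summary of a population fit
#'
#' @param x An `nlme_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the OFV, data size, convergence code
#'   and evaluation count.
#' @export
glance.nlme_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv, n_subjects = length(x$subjects), n_obs = x$n_obs,
    convergence = x$convergence$code,
    n_eval = x$convergence$n_eval,
    n_failed_subjects = length(x$failed_subjects),
    covariance_ok = isTRUE(x$covariance_ok)
  )
}
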