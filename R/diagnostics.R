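#' Goodness-of-fit residual table
#'
#' Per-observation population and individual predictions with weighted
#' residuals: IWRES is the transformed-scale residual at the empirical
#' Bayes mode divided by the individual residual standard deviation;
#' PWRES is the analogous population residual at zero random effects.
#' Deterministic given the fit.
#'
#' @param fit An `nlme_fit`.
#' @return Tibble with columns `ID`, `time`, `analyte`, `dv` (nM),
#'   `pred`, `ipred` (nM), `iwres`, `pwres`.
#' @export
gof_residuals <- function(fit) {
  spec <- fit$spec
  settings <- fit$settings
  eff <- names(spec$omega2)[spec$omega2 > 0]
  rows <- purrr::map(names(fit$subjects), function(id) {
    s <- fit$subjects[[id]]
    layers <- obs_layers(spec, s)
    p0 <- individual_parameters(spec, covariates = s$covariates)
    f0 <- pred_natural(spec, p0, s, settings)
    eta <- setNames(rep(0, length(eff)), eff)
    if (length(eff) > 0 && id %in% fit$eta$ID) {
      eta[eff] <- as.numeric(fit$eta[fit$eta$ID == id, eff])
    }
    pi <- individual_parameters(spec, eta = eta, covariates = s$covariates)
    fi <- pred_natural(spec, pi, s, settings)
    ev0 <- obs_eval(layers, f0)
    evi <- obs_eval(layers, fi)
    tibble::tibble(
      ID = id, time = s$obs_times, analyte = layers$analyte,
      dv = s$obs_nM, pred = f0, ipred = fi,
      iwres = (layers$ystar - evi$fstar) / sqrt(evi$v),
      pwres = (layers$ystar - ev0$fstar) / sqrt(ev0$v)
    )
  })
  dplyr::bind_rows(rows)
}

# assign bins on a time axis: exact unique values when few, quantile
# bins otherwise
assign_bins <- function(x, bins = NULL, max_unique = 12) {
  if (!is.null(bins)) {
    return(cut(x, breaks = bins, include.lowest = TRUE))
  }
  ux <- sort(unique(round(x, 6)))
  if (length(ux) <= max_unique) {
    return(factor(round(x, 6), levels = ux))
  }
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = 9)))
  cut(x, breaks = breaks, include.lowest = TRUE)
}

#' Prediction-corrected visual predictive check
#'
#' Observations (and their simulated counterparts) are multiplied by
#' `bin-median population prediction / own population prediction` on the
#' natural concentration scale, removing dose- and covariate-driven
#' level differences so sparse heterogeneous designs can be pooled. Per
#' bin and analyte the 10th/50th/90th percentiles of the corrected
#' observations are compared with 95 % confidence bands of the same
#' percentiles across `n_sim` datasets simulated from the fitted model
#' (new random effects and residuals on the original design).
#'
#' @param fit An `nlme_fit`.
#' @param n_sim Number of simulated datasets.
#' @param seed RNG seed for the simulations.
#' @param bins Optional numeric break points for time binning; default
#'   bins by nominal sample time (or time-quantiles when the design has
#'   many distinct times).
#' @param time_var `"time"` (time since first dose) or `"tad"` (time
#'   since most recent dose).
#' @return A `pcvpc` tibble: one row per analyte and bin with observed
#'   percentiles and simulation confidence bands.
#' @export
pcvpc <- function(fit, n_sim = 1000, seed = 1, bins = NULL,
                  time_var = c("time", "tad")) {
  time_var <- match.arg(time_var)
  if (n_sim < 50) {
    warning("n_sim < 50 gives unreliable confidence bands.")
  }
  spec <- fit$spec
  settings <- fit$settings
  eff <- names(spec$omega2)[spec$omega2 > 0]
  # per-observation population predictions and bin assignment
  obs_tbl <- purrr::map(names(fit$subjects), function(id) {
    s <- fit$subjects[[id]]
    layers <- obs_layers(spec, s)
    p0 <- individual_parameters(spec, covariates = s$covariates)
    f0 <- pred_natural(spec, p0, s, settings)
    tad <- purrr::map_dbl(s$obs_times, function(t) {
      past <- s$dose_times[s$dose_times <= t]
      if (length(past) == 0) t else t - max(past)
    })
    tibble::tibble(ID = id, time = s$obs_times, tad = tad,
                   analyte = layers$analyte, dv = s$obs_nM, pred = f0)
  }) |>
    dplyr::bind_rows()
  obs_tbl$axis <- obs_tbl[[time_var]]
  obs_tbl <- obs_tbl |>
    dplyr::group_by(.data$analyte) |>
    dplyr::mutate(bin = assign_bins(.data$axis, bins)) |>
    dplyr::group_by(.data$analyte, .data$bin) |>
    dplyr::mutate(pc_factor = median(.data$pred) / .data$pred) |>
    dplyr::ungroup()
  pctl <- function(y) {
    obs_tbl |>
      dplyr::mutate(y = y) |>
      dplyr::group_by(.data$analyte, .data$bin) |>
      dplyr::summarise(mid = median(.data$axis),
                       p10 = quantile(.data$y, 0.1),
                       p50 = quantile(.data$y, 0.5),
                       p90 = quantile(.data$y, 0.9), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::arrange(.data$analyte, .data$bin)
  }
  observed <- pctl(obs_tbl$dv * obs_tbl$pc_factor)
  # simulate replicates of the design
  set.seed(seed)
  sims <- array(NA_real_, dim = c(nrow(observed), 3, n_sim))
  for (b in seq_len(n_sim)) {
    ysim <- numeric(nrow(obs_tbl))
    for (id in names(fit$subjects)) {
      s <- fit$subjects[[id]]
      layers <- obs_layers(spec, s)
      eta <- setNames(rnorm(length(eff), 0, sqrt(spec$omega2[eff])), eff)
      p <- individual_parameters(spec, eta = eta, covariates = s$covariates)
      f <- pred_natural(spec, p, s, settings)
      eps <- rnorm(length(f))
      y <- ifelse(layers$model == "additive_log",
                  exp(log(pmax(f, 1e-300)) + layers$sigma * eps),
                  f * (1 + layers$sigma * eps))
      ysim[obs_tbl$ID == id] <- y
    }
    sm <- pctl(ysim * obs_tbl$pc_factor)
    sims[, 1, b] <- sm$p10
    sims[, 2, b] <- sm$p50
    sims[, 3, b] <- sm$p90
  }
  band <- function(j, q) apply(sims[, j, , drop = FALSE], 1, quantile, q)
  out <- tibble::tibble(
    analyte = observed$analyte,
    bin = as.character(observed$bin),
    bin_mid = observed$mid,
    n = observed$n,
    obs_p10 = observed$p10, obs_p50 = observed$p50, obs_p90 = observed$p90,
    sim_p10_lo = band(1, 0.025), sim_p10_hi = band(1, 0.975),
    sim_p50_lo = band(2, 0.025), sim_p50_hi = band(2, 0.975),
    sim_p90_lo = band(3, 0.025), sim_p90_hi = band(3, 0.975)
  )
  structure(out, class = c("pcvpc", class(out)),
            n_sim = n_sim, time_var = time_var, seed = seed)
}

#' Fraction of pcVPC percentile points inside their confidence bands
#'
#' Summary used for self-consistency calibration: for data simulated
#' from the fitted model itself, roughly 95 % of (bin x percentile)
#' points should fall inside their bands.
#'
#' @param x A [pcvpc()] result.
#' @return Fraction in `[0, 1]`.
#' @export
pcvpc_coverage <- function(x) {
  inside <- c(
    x$obs_p10 >= x$sim_p10_lo & x$obs_p10 <= x$sim_p10_hi,
    x$obs_p50 >= x$sim_p50_lo & x$obs_p50 <= x$sim_p50_hi,
    x$obs_p90 >= x$sim_p90_lo & x$obs_p90 <= x$sim_p90_hi
  )
  mean(inside)
}

#' Typical-patient simulation summary
#'
#' Simulates the QSS TMDD model for a typical patient (reference
#' covariates, zero random effects) under each requested regimen and
#' summarises first-dose target suppression and long-run total-target
#' accumulation.
#'
#' @param theta Named typical values (`CL, V1, Q, V2, BM0, kout, Kss`;
#'   `BM0` in nM).
#' @param regimens Tibble with columns `label`, `dose_mg_per_kg`,
#'   `interval` (days); defaults to the two study regimens.
#' @param weight Body weight of the typical patient, kg.
#' @param n_cycles Number of dosing cycles simulated.
#' @param infusion_min Infusion durations (minutes) for dose 1, 2, 3+.
#' @param points_per_day Output grid resolution.
#' @return A list with `trajectories` (long tibble: regimen, time,
#'   series, value) and `summary` (per regimen: first-dose suppression
#'   %, end-of-horizon suppression %, total-target accumulation ratio).
#' @export
typical_profiles <- function(theta,
                             regimens = tibble::tibble(
                               label = c("5 mg/kg q2w", "7.5 mg/kg q3w"),
                               dose_mg_per_kg = c(5, 7.5),
                               interval = c(14, 21)),
                             weight = 70, n_cycles = 10,
                             infusion_min = c(90, 60, 30),
                             points_per_day = 4) {
  params <- tmdd_parameters(CL = theta[["CL"]], V1 = theta[["V1"]],
                            Q = theta[["Q"]], V2 = theta[["V2"]],
                            BM0 = theta[["BM0"]], kout = theta[["kout"]],
                            Kss = theta[["Kss"]])
  traj_rows <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(regimens))) {
    reg <- regimens[i, ]
    dose_times <- (seq_len(n_cycles) - 1) * reg$interval
    doses <- tibble::tibble(
      time = dose_times,
      amount = reg$dose_mg_per_kg * weight,
      duration = infusion_days(seq_len(n_cycles), infusion_min))
    horizon <- n_cycles * reg$interval
    times <- sort(unique(c(seq(0, horizon, by = 1 / points_per_day),
                           doses$time + doses$duration)))
    traj <- simulate_tmdd(params, doses, times)
    traj_rows[[i]] <- traj |>
      tidyr::pivot_longer(cols = c("Ctot", "Rtot", "C", "R", "RC"),
                          names_to = "series", values_to = "value") |>
      dplyr::mutate(regimen = reg$label)
    acc <- target_accumulation_profile(params, doses, horizon)
    summary_rows[[i]] <- tibble::tibble(
      regimen = reg$label,
      first_dose_suppression_pct =
        first_dose_suppression(params, doses$amount[1], doses$duration[1]),
      horizon_suppression_pct =
        100 * (1 - traj$R[nrow(traj)] / params[["BM0"]]),
      target_accumulation_ratio = acc$asymptote / params[["BM0"]]
    )
  }
  list(trajectories = dplyr::bind_rows(traj_rows),
       summary = dplyr::bind_rows(summary_rows))
}

#' @export
autoplot.tmdd_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("Ctot", "Rtot", "R"),
                              names_to = "series", values_to = "value")
  labels <- c(Ctot = "total drug", Rtot = "total target",
              R = "free target")
  long$series <- factor(labels[long$series], levels = unname(labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "concentration (nM)")
}

#' @export
autoplot.pcvpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p10_lo,
                                      ymax = .data$sim_p10_hi),
                         alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p90_lo,
                                      ymax = .data$sim_p90_hi),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p10), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p90), linetype = 2) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "prediction-corrected conc. (nM)")
}

#' Goodness-of-fit panel
#'
#' Observed versus population/individual predictions and IWRES over
#' time, from a [gof_residuals()] table.
#'
#' @param residuals A [gof_residuals()] tibble.
#' @return A ggplot object.
#' @export
plot_gof <- function(residuals) {
  ggplot2::ggplot(residuals,
                  ggplot2::aes(x = .data$time, y = .data$iwres)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~analyte) +
    ggplot2::labs(x = "time (days)", y = "IWRES")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
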