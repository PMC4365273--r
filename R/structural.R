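#' Parameter constructors for the structural models
#'
#' `pk_parameters()` holds the two-compartment linear disposition
#' parameters; `tmdd_parameters()` adds the target-related quantities of
#' the quasi-steady-state (QSS) TMDD system: complex clearance `CL_RC`
#' (defaults to `CL`, the identifiability constraint used for fitting),
#' baseline free target `BM0` (nM), target turnover rate `kout` (/day) and
#' the steady-state binding constant `Kss` (nM). The target production
#' rate is tied to baseline stationarity, `kin = BM0 * kout` (nM/day).
#'
#' @param CL Linear clearance of free drug, L/day.
#' @param V1,V2 Central and peripheral volumes, L.
#' @param Q Inter-compartmental clearance, L/day.
#' @param CL_RC Elimination clearance of the drug-target complex, L/day.
#' @param BM0 Baseline free-target concentration, nM.
#' @param kout First-order target elimination rate, /day.
#' @param Kss QSS binding constant, nM.
#' @return A named numeric vector (class `pk_parameters` /
#'   `tmdd_parameters`); `tmdd_parameters` carries `kin` as an attribute.
#' @examples
#' p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
#'                      BM0 = 0.0053, kout = 0.401, Kss = 267)
#' attr(p, "kin") # nM/day
#' @export
tmdd_parameters <- function(CL, V1, Q, V2, BM0, kout, Kss, CL_RC = CL) {
  p <- c(CL = CL, V1 = V1, Q = Q, V2 = V2, CL_RC = CL_RC,
         BM0 = BM0, kout = kout, Kss = Kss)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("All TMDD parameters must be positive and finite.", call. = FALSE)
  }
  structure(p, kin = unname(BM0 * kout), class = "tmdd_parameters")
}

#' @rdname tmdd_parameters
#' @export
pk_parameters <- function(CL, V1, Q, V2) {
  p <- c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("All PK parameters must be positive and finite.", call. = FALSE)
  }
  structure(p, class = "pk_parameters")
}

#' Steady-state binding constant from binding micro-constants
#'
#' `Kss = (kint + koff)/kon`: the QSS approximation collapses complex
#' internalization (`kint`), dissociation (`koff`) and association (`kon`)
#' into one constant, the in vivo analogue of the dissociation constant.
#'
#' @param kon Second-order association rate, /nM/day. Must be positive.
#' @param koff First-order dissociation rate, /day (non-negative).
#' @param kint First-order complex elimination rate, /day (non-negative).
#' @return `Kss` in nM.
#' @examples
#' kss_from_micro(kon = 5, koff = 10, kint = 2) # 2.4 nM
#' @export
kss_from_micro <- function(kon, koff, kint) {
  if (!is.numeric(kon) || any(kon <= 0)) {
    stop("`kon` must be positive.", call. = FALSE)
  }
  if (any(koff < 0) || any(kint < 0)) {
    stop("`koff` and `kint` must be non-negative.", call. = FALSE)
  }
  (kint + koff) / kon
}

#' Free-drug concentration under the QSS approximation
#'
#' Solves the QSS quadratic for free drug given total drug, total target
#' and `Kss`, using a cancellation-safe root (important here because total
#' drug typically exceeds total target by about five orders of magnitude).
#' The root satisfies `C + Rtot * C / (Kss + C) = Ctot`.
#'
#' @param Ctot Total drug concentration, nM (non-negative).
#' @param Rtot Total target concentration, nM (non-negative).
#' @param Kss QSS constant, nM (positive).
#' @return Free-drug concentration `C` in nM (vectorized).
#' @examples
#' qss_free_drug(727, 0.0053, 267)
#' @export
qss_free_drug <- function(Ctot, Rtot, Kss) {
  if (any(Ctot < 0) || any(Rtot < 0) || any(Kss <= 0)) {
    stop("Require Ctot >= 0, Rtot >= 0, Kss > 0.", call. = FALSE)
  }
  b <- Ctot - Rtot - Kss
  disc <- sqrt(b * b + 4 * Kss * Ctot)
  ifelse(Ctot == 0, 0,
         ifelse(b >= 0, 0.5 * (b + disc), 2 * Kss * Ctot / (disc - b)))
}

#' Complex and free-target concentrations under QSS
#'
#' Given the algebraic free-drug root, the complex is
#' `RC = Rtot * C / (Kss + C)` and free target is `R = Rtot - RC`
#' (equivalently `R = Rtot * Kss / (Kss + C)`).
#'
#' @inheritParams qss_free_drug
#' @return A tibble with columns `C`, `RC`, `R` (nM).
#' @export
qss_complex_and_target <- function(Ctot, Rtot, Kss) {
  C <- qss_free_drug(Ctot, Rtot, Kss)
  RC <- Rtot * C / (Kss + C)
  tibble::tibble(C = C, RC = RC, R = Rtot - RC)
}

#' Right-hand side of the QSS TMDD differential system
#'
#' State is `(Ctot, Rtot, A2)`: total drug in the central compartment
#' (nM), total target (nM) and free drug amount in the peripheral
#' compartment (nmol). Free drug distributes peripherally; the complex
#' stays central and is cleared with `CL_RC`. Target turnover is zero
#' order in, first order out, with `kin = BM0 * kout` so the drug-free
#' system is stationary at `Rtot = BM0`.
#'
#' @param state Named numeric vector `c(Ctot =, Rtot =, A2 =)`.
#' @param params A [tmdd_parameters()] vector.
#' @param infusion_rate Drug input rate in nmol/day (0 when no infusion is
#'   running).
#' @return Named vector of derivatives `(dCtot, dRtot, dA2)`.
#' @export
tmdd_rhs <- function(state, params, infusion_rate = 0) {
  Ctot <- state[["Ctot"]]; Rtot <- state[["Rtot"]]; A2 <- state[["A2"]]
  CL <- params[["CL"]]; V1 <- params[["V1"]]; Q <- params[["Q"]]
  V2 <- params[["V2"]]; CL_RC <- params[["CL_RC"]]
  kout <- params[["kout"]]; Kss <- params[["Kss"]]
  kin <- params[["BM0"]] * kout
  C <- qss_free_drug(max(Ctot, 0), max(Rtot, 0), Kss)
  occ <- C / (Kss + C)
  c(
    dCtot = infusion_rate / V1 - (CL / V1 + Q / V1) * C -
      Rtot * (CL_RC / V1) * occ + (Q / V2) * A2 / V1,
    dRtot = kin - kout * Rtot - (CL_RC / V1 - kout) * Rtot * occ,
    dA2 = Q * C - (Q / V2) * A2
  )
}

# normalize a dose table: tibble(time, amount_mg = NULL, amount_nmol,
# duration). Zero-amount doses are dropped.
normalize_doses <- function(dose_times, dose_nmol, dose_durations) {
  stopifnot(length(dose_times) == length(dose_nmol),
            length(dose_nmol) == length(dose_durations))
  if (any(dose_durations <= 0 & dose_nmol > 0)) {
    stop("Infusion durations must be positive.", call. = FALSE)
  }
  keep <- dose_nmol > 0
  list(times = dose_times[keep], nmol = dose_nmol[keep],
       durations = dose_durations[keep])
}

#' Simulate the QSS TMDD system over a dosing regimen
#'
#' Integrates the system from the drug-free steady state
#' (`Ctot = 0, Rtot = BM0, A2 = 0`) with a compiled adaptive Runge-Kutta
#' integrator (relative tolerance `1e-8`, absolute `1e-10` nM),
#' restarting at every infusion start/stop. Derived series (`C`, `R`,
#' `RC`) come from the QSS algebra at the output times.
#'
#' @param params A [tmdd_parameters()] vector.
#' @param doses A data frame with columns `time` (days), `amount` (mg) and
#'   `duration` (days), or NULL for no dosing.
#' @param times Output time grid (days, sorted, non-negative).
#' @param constants [molar_constants()] used to convert dose mg to nmol.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble (class `tmdd_trajectory`) with columns `time`, `Ctot`,
#'   `Rtot`, `C`, `R`, `RC` (all concentrations in nM) and `A2` (nmol).
#' @examples
#' p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
#'                      BM0 = 0.0053, kout = 0.401, Kss = 267)
#' traj <- simulate_tmdd(p, tibble::tibble(time = 0, amount = 350,
#'                                         duration = 90 / 1440),
#'                       times = seq(0, 14, by = 0.5))
#' @export
simulate_tmdd <- function(params, doses, times, constants = molar_constants(),
                          rtol = 1e-8, atol = 1e-10) {
  if (is.null(doses) || nrow(doses) == 0) {
    doses <- tibble::tibble(time = numeric(), amount = numeric(),
                            duration = numeric())
  }
  if (is.unsorted(times)) stop("`times` must be sorted.", call. = FALSE)
  d <- normalize_doses(doses$time, dose_mg_to_nmol(doses$amount,
                                                   constants$mw_drug),
                       doses$duration)
  states <- tmdd_solve_cpp(unclass(params), d$times, d$nmol, d$durations,
                           as.numeric(times), rtol, atol)
  derived <- qss_complex_and_target(pmax(states[, "Ctot"], 0),
                                    pmax(states[, "Rtot"], 0),
                                    params[["Kss"]])
  structure(
    tibble::tibble(time = as.numeric(times),
                   Ctot = states[, "Ctot"], Rtot = states[, "Rtot"],
                   C = derived$C, R = derived$R, RC = derived$RC,
                   A2 = states[, "A2"]),
    class = c("tmdd_trajectory", class(tibble::tibble()))
  )
}

#' Closed-form two-compartment concentration profile
#'
#' Evaluates the standard bi-exponential solution of the two-compartment
#' model with first-order elimination under superposed constant-rate
#' infusions. Exact (no ODE integration); times before the first dose
#' return 0.
#'
#' @param params A [pk_parameters()] vector.
#' @param doses Data frame with `time` (days), `amount` (mg), `duration`
#'   (days); may be empty.
#' @param times Output times (days).
#' @param constants [molar_constants()] for the mg-to-nmol conversion.
#' @return Tibble with columns `time` and `conc` (central concentration of
#'   drug, nM).
#' @export
linear_pk_profile <- function(params, doses, times,
                              constants = molar_constants()) {
  CL <- params[["CL"]]; V1 <- params[["V1"]]
  Q <- params[["Q"]]; V2 <- params[["V2"]]
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  conc <- numeric(length(times))
  if (!is.null(doses) && nrow(doses) > 0) {
    d <- normalize_doses(doses$time, dose_mg_to_nmol(doses$amount,
                                                     constants$mw_drug),
                         doses$duration)
    for (i in seq_along(d$times)) {
      k0 <- d$nmol[i] / d$durations[i]  # nmol/day
      tt <- times - d$times[i]
      te <- pmax(pmin(tt, d$durations[i]), 0)  # elapsed infusion time
      on <- tt > 0
      contrib <- (k0 / V1) * (
        (A / alpha) * (1 - exp(-alpha * te)) * exp(-alpha * pmax(tt - te, 0)) +
        (B / beta) * (1 - exp(-beta * te)) * exp(-beta * pmax(tt - te, 0))
      )
      conc <- conc + ifelse(on, contrib, 0)
    }
  }
  tibble::tibble(time = as.numeric(times), conc = conc)
}

#' Free-target suppression after the first dose
#'
#' Simulates a single infusion from baseline and reports the percent drop
#' in free target at the end of the infusion,
#' `100 * (1 - R(t_end) / BM0)`. With typical parameters this is the
#' figure quoted for first-dose ligand suppression.
#'
#' @param params A [tmdd_parameters()] vector.
#' @param dose_mg Dose in mg.
#' @param infusion_duration Infusion length in days (default 90 min).
#' @param constants [molar_constants()].
#' @return Percent suppression (scalar, 0 for a zero dose).
#' @examples
#' p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
#'                      BM0 = 0.0053, kout = 0.401, Kss = 267)
#' first_dose_suppression(p, 350) # about 73
#' @export
first_dose_suppression <- function(params, dose_mg,
                                   infusion_duration = 90 / 1440,
                                   constants = molar_constants()) {
  if (dose_mg == 0) return(0)
  traj <- simulate_tmdd(
    params,
    tibble::tibble(time = 0, amount = dose_mg, duration = infusion_duration),
    times = c(0, infusion_duration), constants = constants
  )
  100 * (1 - traj$R[2] / params[["BM0"]])
}

#' Free-target suppression at an arbitrary time
#'
#' Generic suppression query relative to baseline,
#' `100 * (1 - R(t) / BM0)`, for any regimen and evaluation time. Useful
#' for steady-state or end-of-horizon summaries, whose definition is
#' regimen- and convention-dependent.
#'
#' @inheritParams simulate_tmdd
#' @param at Evaluation time(s), days.
#' @return Tibble with columns `time` and `suppression_pct`.
#' @export
suppression_at <- function(params, doses, at, constants = molar_constants()) {
  at <- sort(as.numeric(at))
  traj <- simulate_tmdd(params, doses, at, constants = constants)
  tibble::tibble(time = at,
                 suppression_pct = 100 * (1 - traj$R / params[["BM0"]]))
}

#' Total-target accumulation under sustained dosing
#'
#' Returns the total-target trajectory over the regimen plus the
#' constant-exposure asymptote implied by setting the target balance to
#' zero at a fixed free-drug concentration `C`:
#' `Rtot_ss = kin / (kout * (1 - b) + (CL_RC / V1) * b)` with occupancy
#' `b = C / (Kss + C)`. The asymptote is evaluated at the average
#' steady-state drug concentration of the regimen
#' (`dose rate / CL`), a standard exposure summary.
#'
#' @inheritParams simulate_tmdd
#' @param horizon Simulation horizon in days.
#' @param n_grid Number of output points.
#' @return A list with `trajectory` (tibble `time`, `Rtot`) and
#'   `asymptote` (nM), plus `css` (the average drug concentration used).
#' @export
target_accumulation_profile <- function(params, doses, horizon,
                                        n_grid = 200,
                                        constants = molar_constants()) {
  times <- seq(0, horizon, length.out = n_grid)
  traj <- simulate_tmdd(params, doses, times, constants = constants)
  if (is.null(doses) || nrow(doses) == 0 || sum(doses$amount) == 0) {
    css <- 0
  } else {
    interval <- if (nrow(doses) > 1) mean(diff(doses$time)) else horizon
    dose_nmol <- dose_mg_to_nmol(mean(doses$amount), constants$mw_drug)
    css <- dose_nmol / (params[["CL"]] * interval)
  }
  asymptote <- rtot_asymptote(params, css)
  list(trajectory = tibble::tibble(time = times, Rtot = traj$Rtot),
       asymptote = asymptote, css = css)
}

# steady-state total target at a fixed free-drug concentration C
rtot_asymptote <- function(params, C) {
  b <- C / (params[["Kss"]] + C)
  kin <- params[["BM0"]] * params[["kout"]]
  kin / (params[["kout"]] * (1 - b) + (params[["CL_RC"]] / params[["V1"]]) * b)
}
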