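test_that("QSS free-drug root matches fixed-point and bisection oracles", {
  # fixed-point iteration of C = Ctot - Rtot*C/(Kss+C)
  fp_oracle <- function(Ctot, Rtot, Kss) {
    C <- Ctot
    for (i in 1:200) C <- Ctot - Rtot * C / (Kss + C)
    C
  }
  expect_equal(qss_free_drug(727, 0.0053, 267),
               fp_oracle(727, 0.0053, 267), tolerance = 1e-10)
  # bisection on the defining equation over random triples
  bisect_oracle <- function(Ctot, Rtot, Kss) {
    f <- function(C) C + Rtot * C / (Kss + C) - Ctot
    uniroot(f, c(0, Ctot), tol = 1e-14)$root
  }
  set.seed(1)
  for (i in 1:40) {
    Ctot <- 10^runif(1, -3, 3.5)
    Rtot <- 10^runif(1, -3, 2)
    Kss <- 10^runif(1, -2, 3)
    expect_equal(qss_free_drug(Ctot, Rtot, Kss),
                 bisect_oracle(Ctot, Rtot, Kss),
                 tolerance = 1e-9)
  }
  # trivial cases
  expect_equal(qss_free_drug(10, 0, 267), 10)
  expect_equal(qss_free_drug(0, 0.0053, 267), 0)
  # the root satisfies the mass balance in the cancellation-prone regime
  C <- qss_free_drug(1e3, 1e-3, 267)
  expect_equal(C + 1e-3 * C / (267 + C), 1e3, tolerance = 1e-10)
  expect_error(qss_free_drug(-1, 0, 267), "Require")
})

test_that("complex and free target follow the QSS algebra", {
  out <- qss_complex_and_target(727, 0.0053, 267)
  expect_equal(out$RC + out$R, 0.0053, tolerance = 1e-12)
  expect_equal(out$R, 0.0053 * 267 / (267 + out$C), tolerance = 1e-12)
  # half-saturation: choose Ctot so that C = Kss exactly
  Kss <- 50; Rtot <- 2
  Ctot <- Kss + Rtot * Kss / (Kss + Kss)
  half <- qss_complex_and_target(Ctot, Rtot, Kss)
  expect_equal(half$R, Rtot / 2, tolerance = 1e-10)
  # no target
  none <- qss_complex_and_target(10, 0, 50)
  expect_equal(none$RC, 0)
  expect_equal(none$R, 0)
})

test_that("kss_from_micro reduces correctly in limiting cases", {
  expect_equal(kss_from_micro(kon = 5, koff = 10, kint = 0), 2)
  expect_equal(kss_from_micro(kon = 5, koff = 10, kint = 2), 2.4)
  expect_equal(kss_from_micro(kon = 1, koff = 0, kint = 0), 0)
  expect_error(kss_from_micro(kon = 0, koff = 1, kint = 1), "positive")
})

test_that("the TMDD right-hand side is stationary at the drug-free state", {
  p <- tmdd_typical_params()
  d0 <- tmdd_rhs(c(Ctot = 0, Rtot = p[["BM0"]], A2 = 0), p)
  expect_equal(unname(d0), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the RHS reduces to the linear model as the target vanishes", {
  p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
                       BM0 = 1e-12, kout = 0.401, Kss = 267)
  state <- c(Ctot = 100, Rtot = 1e-12, A2 = 50)
  d <- tmdd_rhs(state, p, infusion_rate = 0)
  # linear two-compartment derivatives at the same free concentration
  C <- 100
  expect_equal(d[["dCtot"]],
               -(0.18 / 3.23 + 1.38 / 3.23) * C + (1.38 / 3.1) * 50 / 3.23,
               tolerance = 1e-10)
  expect_equal(d[["dA2"]], 1.38 * C - (1.38 / 3.1) * 50, tolerance = 1e-10)
})

test_that("compiled trajectories match an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  p <- tmdd_typical_params()
  dur <- 90 / 1440
  rate_nmol <- (350e6 / 149000) / dur
  rhs <- function(t, y, parms) {
    rate <- if (t > 0 && t <= dur) rate_nmol else 0
    list(qsstmdd::tmdd_rhs(c(Ctot = y[1], Rtot = y[2], A2 = y[3]), p, rate))
  }
  times <- c(0, dur, 0.5, 2, 7, 14, 28)
  oracle <- deSolve::lsoda(c(0, p[["BM0"]], 0), times, rhs,
                           rtol = 1e-10, atol = 1e-12)
  traj <- simulate_tmdd(p, tibble::tibble(time = 0, amount = 350,
                                          duration = dur), times)
  expect_equal(traj$Ctot, unname(oracle[, 2]), tolerance = 1e-6)
  expect_equal(traj$Rtot, unname(oracle[, 3]), tolerance = 1e-6)
  expect_equal(traj$A2, unname(oracle[, 4]), tolerance = 1e-6)
})

test_that("trajectories conserve mass and stay non-negative", {
  p <- tmdd_typical_params()
  doses <- tibble::tibble(time = c(0, 14, 28), amount = 350,
                          duration = c(90, 60, 30) / 1440)
  traj <- simulate_tmdd(p, doses, seq(0, 42, by = 0.25))
  expect_true(all(traj$Ctot >= 0 & traj$Rtot >= 0 & traj$C >= 0 &
                    traj$R >= 0 & traj$RC >= 0))
  expect_equal(traj$C + traj$RC, traj$Ctot, tolerance = 1e-7)
  expect_equal(traj$R + traj$RC, traj$Rtot, tolerance = 1e-7)
})

test_that("with no dosing the target stays at baseline for 100 days", {
  p <- tmdd_typical_params()
  traj <- simulate_tmdd(p, NULL, seq(0, 100, by = 1))
  expect_true(max(abs(traj$Rtot - p[["BM0"]])) / p[["BM0"]] < 1e-8)
  expect_true(all(traj$Ctot == 0))
})

test_that("total drug reduces to the linear PK profile as BM0 -> 0", {
  p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
                       BM0 = 1e-9, kout = 0.401, Kss = 267)
  doses <- tibble::tibble(time = 0, amount = 350, duration = 90 / 1440)
  times <- seq(90 / 1440, 28, length.out = 60)
  traj <- simulate_tmdd(p, doses, times)
  lin <- linear_pk_profile(pk_parameters(0.18, 3.23, 1.38, 3.1), doses,
                           times)
  expect_lt(max(abs(traj$Ctot - lin$conc) / lin$conc), 1e-3)
})

test_that("closed-form linear profile matches limits and an ODE oracle", {
  skip_if_not_installed("deSolve")
  # empty regimen
  p <- pk_parameters(CL = 0.17, V1 = 3.14, Q = 0.36, V2 = 2.63)
  expect_true(all(linear_pk_profile(
    p, NULL, seq(0, 10, by = 1))$conc == 0))
  # one-compartment limit: Q -> 0, during a 1-day infusion
  p1 <- pk_parameters(CL = 0.2, V1 = 3, Q = 1e-10, V2 = 1)
  doses <- tibble::tibble(time = 0, amount = 149, duration = 1)
  tt <- c(0.1, 0.5, 0.9)
  prof <- linear_pk_profile(p1, doses, tt)
  k0 <- (149e6 / 149000) / 1  # nmol/day
  oracle1 <- k0 / 0.2 * (1 - exp(-(0.2 / 3) * tt))
  expect_equal(prof$conc, oracle1, tolerance = 1e-6)
  # two-compartment vs numeric integration, end of 90-min infusion
  dur <- 90 / 1440
  k0 <- (350e6 / 149000) / dur
  rhs <- function(t, y, parms) {
    rate <- if (t <= dur) k0 else 0
    with(as.list(parms), list(c(
      rate / V1 - (CL / V1 + Q / V1) * y[1] + (Q / V2) * y[2] / V1,
      Q * y[1] - (Q / V2) * y[2]
    )))
  }
  times <- c(0, dur, 1, 5, 14)
  oracle <- deSolve::lsoda(c(0, 0), times, rhs,
                           parms = c(CL = 0.17, V1 = 3.14, Q = 0.36,
                                     V2 = 2.63),
                           rtol = 1e-10, atol = 1e-12)
  prof2 <- linear_pk_profile(p, tibble::tibble(time = 0, amount = 350,
                                               duration = dur), times)
  expect_equal(prof2$conc, unname(oracle[, 2]), tolerance = 1e-7)
  # end-of-infusion concentration is close to dose/V1
  expect_equal(prof2$conc[2], (350e6 / 149000) / 3.14, tolerance = 0.03)
})

test_that("first-dose target suppression reproduces the typical values", {
  p <- tmdd_typical_params()
  expect_equal(first_dose_suppression(p, 0), 0)
  # 5 mg/kg x 70 kg and 7.5 mg/kg x 70 kg, 90-min infusions
  s350 <- first_dose_suppression(p, 350)
  s525 <- first_dose_suppression(p, 525)
  expect_equal(round(s350), 73)
  expect_equal(round(s525), 80)
  # analytic shortcut: occupancy at C ~ dose/V1
  shortcut <- function(dose_mg) {
    C <- (dose_mg * 1e6 / 149000) / 3.23
    100 * C / (267 + C)
  }
  expect_lt(abs(s350 - shortcut(350)), 1)
  expect_lt(abs(s525 - shortcut(525)), 1)
})

test_that("suppression increases with dose and decreases with Kss", {
  doses <- c(100, 250, 400, 600)
  kss_grid <- c(100, 267, 500)
  prev <- -Inf
  for (dose in doses) {
    s <- first_dose_suppression(tmdd_typical_params(), dose)
    expect_gt(s, prev)
    prev <- s
  }
  prev <- Inf
  for (kss in kss_grid) {
    p <- tmdd_parameters(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
                         BM0 = 0.0053, kout = 0.401, Kss = kss)
    s <- first_dose_suppression(p, 350)
    expect_lt(s, prev)
    prev <- s
  }
})

test_that("target accumulation matches the algebraic steady state", {
  p <- tmdd_typical_params()
  # no drug: asymptote is the baseline
  acc0 <- target_accumulation_profile(p, NULL, horizon = 50)
  expect_equal(acc0$asymptote, p[["BM0"]])
  # CL_RC/V1 = kout: binding term vanishes, asymptote stays at baseline
  peq <- tmdd_parameters(CL = 0.401 * 3.23, V1 = 3.23, Q = 1.38, V2 = 3.1,
                         BM0 = 0.0053, kout = 0.401, Kss = 267)
  doses <- tibble::tibble(time = seq(0, 126, by = 14), amount = 350,
                          duration = 90 / 1440)
  acc_eq <- target_accumulation_profile(peq, doses, horizon = 140)
  expect_equal(acc_eq$asymptote, 0.0053, tolerance = 1e-12)
  # algebraic oracle: solve dRtot/dt = 0 at fixed C
  C <- 932
  b <- C / (267 + C)
  kin <- 0.0053 * 0.401
  oracle <- kin / (0.401 * (1 - b) + (0.18 / 3.23) * b)
  expect_equal(qsstmdd:::rtot_asymptote(p, C), oracle)
  expect_equal(oracle / 0.0053, 3.0, tolerance = 0.02)
  # under sustained dosing Rtot approaches a level within the
  # baseline-to-asymptote band
  acc <- target_accumulation_profile(p, doses, horizon = 140)
  expect_gt(dplyr::last(acc$trajectory$Rtot), 2 * p[["BM0"]])
})
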