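# Shared fixtures: typical parameter sets and small builders.

# final-model typical values (BM0 in nM)
TMDD_TYPICAL <- c(CL = 0.18, V1 = 3.23, Q = 1.38, V2 = 3.1,
                  BM0 = 0.0053, kout = 0.401, Kss = 267)
PK_TYPICAL <- c(CL = 0.17, V1 = 3.14, Q = 0.36, V2 = 2.63)

tmdd_typical_params <- function() {
  tmdd_parameters(CL = TMDD_TYPICAL[["CL"]], V1 = TMDD_TYPICAL[["V1"]],
                  Q = TMDD_TYPICAL[["Q"]], V2 = TMDD_TYPICAL[["V2"]],
                  BM0 = TMDD_TYPICAL[["BM0"]], kout = TMDD_TYPICAL[["kout"]],
                  Kss = TMDD_TYPICAL[["Kss"]])
}

tmdd_truth_spec <- function(omega2 = c(CL = 0.04, V1 = 0.0484,
                                       BM0 = 0.1089),
                            sigma = c(total_drug = 0.28,
                                      free_target = 0.32)) {
  pop_model_spec("qss_tmdd", theta = TMDD_TYPICAL, omega2 = omega2,
                 sigma = sigma,
                 covariates = allometric_weight_relations())
}

pk_truth_spec <- function(omega2 = c(CL = 0.0529, V1 = 0.0225),
                          sigma = c(total_drug = 0.24)) {
  pop_model_spec("linear_pk", theta = PK_TYPICAL, omega2 = omega2,
                 sigma = sigma,
                 covariates = allometric_weight_relations())
}

# minimal valid two-subject dataset built by hand
two_subject_data <- function() {
  study_dataset(tibble::tibble(
    ID = c("A", "A", "A", "B", "B", "B"),
    TIME = c(0, 0.0625, 14, 0, 0.0625, 14),
    AMT = c(350, NA, NA, 400, NA, NA),
    RATE = c(350 / 0.0625, NA, NA, 400 / 0.0625, NA, NA),
    EVID = c(1L, 0L, 0L, 1L, 0L, 0L),
    DVID = c(1L, 1L, 2L, 1L, 1L, 2L),
    DV = c(NA, 150, 100, NA, 180, 90),
    MDV = c(1L, 0L, 0L, 1L, 0L, 0L),
    WT = c(70, 70, 70, 80, 80, 80),
    AGE = c(60, 60, 60, 55, 55, 55),
    SEX = c(1L, 1L, 1L, 0L, 0L, 0L),
    SNP2578 = "CA", SNP1154 = "GG", SNP634 = "GG"
  ))
}

# subjects with a single shared-mean observation model, linear in eta:
# y_ij = mu + eta_i + eps_ij, an LMM with a closed-form marginal.
lmm_spec <- function(mu, omega2, sigma) {
  pop_model_spec(
    structural = function(params, subject) {
      rep(params[["mu"]], length(subject$obs_times))
    },
    theta = c(mu = mu), omega2 = c(mu = omega2),
    sigma = c(total_drug = sigma),
    error_model = c(total_drug = "additive"),
    iiv_form = "additive"
  )
}

# dataset for the LMM case: y values given in nM, stored as mg/L
lmm_data <- function(y_by_subject) {
  mw <- molar_constants()$mw_drug
  rows <- purrr::imap(y_by_subject, function(y, id) {
    tibble::tibble(
      ID = id,
      TIME = c(0, seq_along(y)),
      AMT = c(1, rep(NA, length(y))),
      RATE = c(1 / 0.01, rep(NA, length(y))),
      EVID = c(1L, rep(0L, length(y))),
      DVID = 1L,
      DV = c(NA, molar_to_mass(y, mw, to = "mg/L")),
      MDV = c(1L, rep(0L, length(y))),
      WT = 70, AGE = 60, SEX = 1L,
      SNP2578 = "CC", SNP1154 = "GG", SNP634 = "GG"
    )
  })
  study_dataset(dplyr::bind_rows(rows))
}

# exact -2 log marginal likelihood of the shared-mean LMM
lmm_neg2ll <- function(y_by_subject, mu, omega2, sigma) {
  -2 * sum(purrr::map_dbl(y_by_subject, function(y) {
    n <- length(y)
    Sigma <- diag(sigma^2, n) + matrix(omega2, n, n)
    -0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus +
              drop(t(y - mu) %*% solve(Sigma, y - mu)))
  }))
}
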