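# SCM and randomization tests run on a deliberately cheap structural
# model (constant prediction per subject) so that dozens of refits cost
# milliseconds; the machinery is model-agnostic.

# subjects whose level depends (or not) on a binary sex covariate
scm_fixture <- function(n = 16, effect = 0, seed = 1, sigma = 0.1) {
  set.seed(seed)
  sexes <- rep(c(1L, 0L), length.out = n)
  mw <- molar_constants()$mw_drug
  rows <- purrr::map(seq_len(n), function(i) {
    mu <- 10 * (1 + effect * sexes[i])
    y <- mu * exp(rnorm(3, 0, sigma))
    tibble::tibble(
      ID = sprintf("S%02d", i), TIME = c(0, 1, 2, 3),
      AMT = c(1, NA, NA, NA), RATE = c(1 / 0.01, NA, NA, NA),
      EVID = c(1L, 0L, 0L, 0L), DVID = 1L,
      DV = c(NA, molar_to_mass(y, mw, to = "mg/L")), MDV = c(1L, 0L, 0L, 0L),
      WT = 70, AGE = 60, SEX = sexes[i],
      SNP2578 = "CC", SNP1154 = "GG", SNP634 = "GG")
  })
  study_dataset(dplyr::bind_rows(rows))
}

const_spec <- function(sigma = 0.1) {
  pop_model_spec(
    structural = function(params, subject) {
      rep(params[["mu"]], length(subject$obs_times))
    },
    theta = c(mu = 8), omega2 = c(mu = 0.01),
    sigma = c(total_drug = sigma),
    error_model = c(total_drug = "additive_log")
  )
}

sex_candidate <- function() {
  covariate_relation("mu", "sex", "linear_categorical", value = 0,
                     level = "M", fixed = FALSE)
}

age_candidate <- function() {
  covariate_relation("mu", "age", "linear_centered", value = 0, ref = 60,
                     fixed = FALSE)
}

fast <- estimation_settings(covariance_step = FALSE)

test_that("a strong true covariate is selected first and survives", {
  d <- scm_fixture(effect = 0.5, seed = 5)
  res <- scm(const_spec(), d, list(sex = sex_candidate(),
                                   age = age_candidate()),
             settings = fast)
  expect_true("cov_mu_sex.M" %in% res$included)
  first_inclusion <- res$log[res$log$decision == "included", ][1, ]
  expect_equal(first_inclusion$candidate, "cov_mu_sex.M")
  # the selected effect is estimated near its true size
  sel <- purrr::keep(res$final_spec$covariates,
                     ~ relation_label(.x) == "cov_mu_sex.M")[[1]]
  expect_equal(sel$value, 0.5, tolerance = 0.15)
})

test_that("with no real effects the base model survives unchanged", {
  d <- scm_fixture(effect = 0, seed = 6)
  res <- scm(const_spec(), d, list(sex = sex_candidate(),
                                   age = age_candidate()),
             settings = fast)
  expect_equal(res$included, character(0))
  expect_false(any(res$log$decision == "included"))
  expect_equal(length(res$final_spec$covariates), 0)
})

test_that("SCM is reproducible: identical inputs give identical logs", {
  d <- scm_fixture(effect = 0.4, seed = 7)
  r1 <- scm(const_spec(), d, list(sex = sex_candidate()), settings = fast)
  r2 <- scm(const_spec(), d, list(sex = sex_candidate()), settings = fast)
  expect_identical(r1$log, r2$log)
  expect_equal(r1$final_fit$ofv, r2$final_fit$ofv)
})

test_that("backward elimination removes borderline forward inclusions", {
  # effect sized so the OFV drop lands between 3.84 and 6.64
  found <- FALSE
  grid <- expand.grid(seed = c(3, 8, 12, 17, 21, 29, 35, 41),
                      effect = c(0.06, 0.08, 0.1, 0.12))
  for (gi in seq_len(nrow(grid))) {
    seed <- grid$seed[gi]
    d <- scm_fixture(n = 12, effect = grid$effect[gi], seed = seed,
                     sigma = 0.1)
    base_fit <- fit_nlme(const_spec(), d, settings = fast)
    full_spec <- const_spec()
    full_spec$covariates <- list(sex_candidate())
    full_fit <- fit_nlme(full_spec, d, settings = fast)
    drop <- base_fit$ofv - full_fit$ofv
    if (drop > 3.84 && drop < 6.64) {
      res <- scm(const_spec(), d, list(sex = sex_candidate()),
                 settings = fast)
      expect_true(any(res$log$decision == "included"))
      expect_true(any(res$log$decision == "removed"))
      expect_equal(res$included, character(0))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("randomization test is seeded, reproducible and calibrated", {
  d <- scm_fixture(n = 12, effect = 0, seed = 9)
  base <- const_spec()
  full <- const_spec()
  full$covariates <- list(sex_candidate())
  r1 <- randomization_test(base, full, d, covariate = "sex", n_perm = 30,
                           seed = 123, settings = fast)
  r2 <- randomization_test(base, full, d, covariate = "sex", n_perm = 30,
                           seed = 123, settings = fast)
  expect_identical(r1$permuted, r2$permuted)
  # null covariate: the observed drop sits inside the permutation spread
  expect_gt(r1$observed, min(r1$permuted) - 1e-8)
  expect_gt(r1$p_value, 0.05)
  expect_equal(r1$n_failed, 0)
})

test_that("permuting a constant covariate leaves the OFV unchanged", {
  d <- scm_fixture(n = 8, effect = 0, seed = 10)
  d2 <- tibble::as_tibble(d)
  d2$SEX <- 1L  # constant column
  d2 <- study_dataset(d2)
  base <- const_spec()
  full <- const_spec()
  full$covariates <- list(sex_candidate())
  r <- randomization_test(base, full, d2, covariate = "sex", n_perm = 5,
                          seed = 99, settings = fast)
  expect_true(all(abs(r$permuted - r$observed) < 1e-6))
})

test_that("the empirical critical drop approximates the chi-square rule", {
  # well-behaved null with enough subjects: 5th percentile of permuted
  # delta-OFV should sit in the vicinity of -3.84 (wide tolerance)
  d <- scm_fixture(n = 24, effect = 0, seed = 30, sigma = 0.15)
  base <- const_spec()
  full <- const_spec()
  full$covariates <- list(sex_candidate())
  r <- randomization_test(base, full, d, covariate = "sex", n_perm = 60,
                          seed = 7, settings = fast)
  expect_lt(r$critical_drop, -1)
  expect_gt(r$critical_drop, -9)
})

test_that("forward inclusion keeps its nominal type-I error on null data", {
  # repeated null datasets: the fraction of spurious inclusions at the
  # 3.84 threshold should be near 5 % (coarse check)
  set.seed(44)
  seeds <- sample.int(1e6, 40)
  hits <- purrr::map_lgl(seeds, function(s) {
    d <- scm_fixture(n = 10, effect = 0, seed = s, sigma = 0.12)
    base_fit <- fit_nlme(const_spec(sigma = 0.12), d, settings = fast)
    full_spec <- const_spec(sigma = 0.12)
    full_spec$covariates <- list(sex_candidate())
    full_fit <- fit_nlme(full_spec, d, settings = fast)
    (base_fit$ofv - full_fit$ofv) > chi2_quantile(0.95, 1)
  })
  expect_lte(mean(hits), 0.2)
  expect_gte(mean(hits), 0)
})
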