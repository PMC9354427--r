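qc_params <- function(...) {
  p <- list(mu_x = 3, mu_y = 1, a_x = 0.7, c_x = 0.4, e_x = 0.5,
            b_P = -0.3, b_A = -0.2, b_C = 0.1,
            a_u = 0.6, c_u = 0.3, e_u = 0.5)
  utils::modifyList(p, list(...))
}

test_that("implied pair moments: structural zeroes and zygosity contrast", {
  p0 <- qc_params(b_A = 0, b_C = 0)
  for (z in c("MZ", "DZ")) {
    m <- implied_pair_moments(p0, z)
    vx <- p0$a_x^2 + p0$c_x^2 + p0$e_x^2
    expect_equal(m$cov["X1", "Y1"], p0$b_P * vx, tolerance = 1e-12)
  }
  # cross-twin X-Y covariances differ between zygosities only through A terms
  p <- qc_params()
  mz <- implied_pair_moments(p, "MZ")$cov
  dz <- implied_pair_moments(p, "DZ")$cov
  diff_xy <- mz["X1", "Y2"] - dz["X1", "Y2"]
  expect_equal(diff_xy, 0.5 * (p$b_P * p$a_x^2 + p$b_A * p$a_x),
               tolerance = 1e-12)
  expect_equal(mz["X1", "X2"] - dz["X1", "X2"], 0.5 * p$a_x^2,
               tolerance = 1e-12)
})

test_that("implied pair moments agree with a simulation oracle", {
  # independent structural simulation of one million pairs at fixed params
  set.seed(321)
  p <- qc_params()
  n <- 1e6
  for (z in c("MZ", "DZ")) {
    rbar <- if (z == "MZ") 1 else 0.5
    Ax1 <- rnorm(n); Ax2 <- rbar * Ax1 + sqrt(1 - rbar^2) * rnorm(n)
    Cx <- rnorm(n)
    Au1 <- rnorm(n); Au2 <- rbar * Au1 + sqrt(1 - rbar^2) * rnorm(n)
    Cu <- rnorm(n)
    X1 <- p$mu_x + p$a_x * Ax1 + p$c_x * Cx + p$e_x * rnorm(n)
    X2 <- p$mu_x + p$a_x * Ax2 + p$c_x * Cx + p$e_x * rnorm(n)
    Y1 <- p$mu_y + p$b_P * X1 + p$b_A * Ax1 + p$b_C * Cx +
      p$a_u * Au1 + p$c_u * Cu + p$e_u * rnorm(n)
    Y2 <- p$mu_y + p$b_P * X2 + p$b_A * Ax2 + p$b_C * Cx +
      p$a_u * Au2 + p$c_u * Cu + p$e_u * rnorm(n)
    emp <- cov(cbind(X1, Y1, X2, Y2))
    mom <- implied_pair_moments(p, z)
    expect_equal(unname(mom$cov), unname(emp), tolerance = 0.01)
    expect_equal(unname(mom$mean), unname(colMeans(cbind(X1, Y1, X2, Y2))),
                 tolerance = 0.01)
  }
})

test_that("percent-change conversion from log-scale slopes", {
  expect_equal(round(percent_change_per_pillar(-0.026), 1), 2.6)
  expect_equal(round(exp(-0.026), 2), 0.97)
  expect_equal(round(percent_change_per_pillar(-0.052), 1), 5.1)
  expect_equal(round(exp(-0.052), 2), 0.95)
  expect_equal(round(exp(-0.006), 2), 0.99)
  expect_equal(percent_change_per_pillar(0), 0)
})

make_two_sex_data <- function(n_per, seed, b_P = -0.05, b_F = 0) {
  cfg <- registry_config(
    n_mz_pairs = n_per, n_dz_pairs = n_per,
    outcomes = list(
      log_bmi = outcome_spec(mu = 3.23, residual_sd = 0.2,
                             residual_ace = c(0.6, 0.1, 0.3),
                             b_P = b_P, b_A = b_F, b_C = b_F),
      sqrt_phq = outcome_spec(mu = 0.65, residual_sd = 0.55,
                              residual_ace = c(0.35, 0.05, 0.6))),
    missing_rates = c(bmi = 0, phq = 0, pillars = 0))
  code_pillars(generate_registry(cfg, seed = seed))
}

test_that("Wald test identities: z-squared and satisfied constraints", {
  dat <- make_two_sex_data(350, seed = 61)
  fit <- fit_quasicausal(dat, "log_bmi", model = 2,
                         predictor_mode = "observed_count")
  # single-parameter restriction equals the squared z statistic
  R <- matrix(0, 1, length(fit$theta),
              dimnames = list(NULL, names(fit$theta)))
  R[1, "male.b_P"] <- 1
  w <- wald_test(fit, R)
  est <- fit$groups$male$estimates["b_P"]
  se <- fit$groups$male$se["b_P"]
  expect_equal(w$statistic, unname((est / se)^2), tolerance = 1e-10)
  expect_equal(w$df, 1)
  # a constraint satisfied exactly by the estimate gives W = 0, p = 1
  w0 <- wald_test(fit, R, rhs = unname(est))
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$p, 1)
  # the two-group equality shortcut matches the explicit matrix
  R2 <- matrix(0, 1, length(fit$theta),
               dimnames = list(NULL, names(fit$theta)))
  R2[1, "male.b_P"] <- 1; R2[1, "female.b_P"] <- -1
  expect_equal(wald_test(fit, "b_P_equal")$statistic,
               wald_test(fit, R2)$statistic, tolerance = 1e-12)
})

test_that("observed-count fit recovers the generating slope", {
  dat <- make_two_sex_data(1200, seed = 62, b_P = -0.10)
  gen <- attr(generate_registry(registry_config(
    n_mz_pairs = 10, n_dz_pairs = 10), seed = 1), "generator")
  fit <- fit_quasicausal(dat, "log_bmi", model = 2,
                         predictor_mode = "observed_count",
                         groups = "pooled")
  bP <- fit$groups$pooled$estimates["b_P"]
  se <- fit$groups$pooled$se["b_P"]
  # generator slope is per standardized count unit; fit is per raw count
  expect_lt(abs(bP - (-0.10) / gen$sd_X), 2.5 * se)
  expect_true(fit$converged)
})

test_that("constraint sequence is properly nested in -2LL", {
  dat <- make_two_sex_data(350, seed = 63, b_P = -0.08, b_F = -0.04)
  f1 <- fit_quasicausal(dat, "log_bmi", model = 1,
                        predictor_mode = "observed_count", se = FALSE)
  f2 <- fit_quasicausal(dat, "log_bmi", model = 2,
                        predictor_mode = "observed_count", se = FALSE)
  f3 <- fit_quasicausal(dat, "log_bmi", model = 3,
                        predictor_mode = "observed_count", se = FALSE)
  # Model 1 (b_F = 0) and Model 3 (shared b_P) are both restrictions of 2
  expect_gte(f1$minus2LL, f2$minus2LL - 1e-4)
  expect_gte(f3$minus2LL, f2$minus2LL - 1e-4)
})

test_that("covariate slopes are recovered", {
  cfg <- registry_config(
    n_mz_pairs = 900, n_dz_pairs = 900,
    outcomes = list(
      log_bmi = outcome_spec(mu = 3.23, residual_sd = 0.2,
                             residual_ace = c(0.6, 0.1, 0.3),
                             b_P = -0.05, b_A = 0, b_C = 0,
                             covariate_effects = c(age_decade = 0.03,
                                                   race = 0, income = -0.01,
                                                   education = 0)),
      sqrt_phq = outcome_spec(mu = 0.65, residual_sd = 0.55,
                              residual_ace = c(0.35, 0.05, 0.6))),
    missing_rates = c(bmi = 0, phq = 0, pillars = 0))
  dat <- code_pillars(generate_registry(cfg, seed = 64))
  fit <- fit_quasicausal(dat, "log_bmi", model = 2,
                         covariates = c("age", "income"),
                         predictor_mode = "observed_count",
                         groups = "pooled")
  ct <- fit$groups$pooled$covariate_table
  expect_lt(abs(ct$estimate[ct$covariate == "age"] - 0.03),
            2 * ct$se[ct$covariate == "age"] + 1e-6)
  expect_lt(abs(ct$estimate[ct$covariate == "income"] - (-0.01)),
            2 * ct$se[ct$covariate == "income"] + 1e-6)
})

test_that("liability likelihood factorizes when all cross paths are zero", {
  set.seed(71)
  tau <- c(-1, 0.2, 1.1)
  n <- 30
  k <- cbind(sample(1:4, n, TRUE), sample(1:4, n, TRUE))
  y <- cbind(rnorm(n, 1, 0.5), rnorm(n, 1, 0.5))
  zyg <- sample(c("MZ", "DZ"), n, TRUE)
  p <- list(mu_y = 1, b_P = 0, b_A = 0, b_C = 0,
            a_x = sqrt(0.4), c_x = sqrt(0.2), e_x = sqrt(0.4),
            a_u = 0.4, c_u = 0.2, e_u = 0.3, mu_x = 0, thresholds = tau)
  got <- liability_predictor_loglik(k, y, zyg, p, gl_order = 16)
  want <- pair_loglik_ordinal(k, zyg, tau, 0.4, 0.2) +
    pair_loglik_continuous(y, zyg, list(
      mu = 1, var = 0.4^2 + 0.2^2 + 0.3^2,
      a2 = 0.4^2 / 0.29, c2 = 0.2^2 / 0.29))
  expect_equal(got, want, tolerance = 1e-8)
  # missing outcomes reduce to the pure rectangle probability
  y2 <- y; y2[] <- NA
  got2 <- liability_predictor_loglik(k, y2, zyg, p)
  expect_equal(got2, pair_loglik_ordinal(k, zyg, tau, 0.4, 0.2),
               tolerance = 1e-9)
})

test_that("liability and observed-count modes agree on the association", {
  dat <- make_two_sex_data(400, seed = 72, b_P = -0.12)
  fo <- fit_quasicausal(dat, "log_bmi", model = 2,
                        predictor_mode = "observed_count",
                        groups = "pooled")
  fl <- fit_quasicausal(dat, "log_bmi", model = 2,
                        predictor_mode = "liability_ordinal",
                        groups = "pooled", gl_order = 6)
  bo <- fo$groups$pooled$estimates["b_P"]
  so <- fo$groups$pooled$se["b_P"]
  sdx <- sqrt(fo$groups$pooled$predictor_shares[["var_x"]])
  bl <- fl$groups$pooled$estimates["b_P"]
  sl <- fl$groups$pooled$se["b_P"]
  expect_equal(sign(bo), sign(bl))
  # 95% intervals on the per-SD scale overlap
  lo_o <- (bo - 1.96 * so) * sdx; hi_o <- (bo + 1.96 * so) * sdx
  lo_l <- bl - 1.96 * sl; hi_l <- bl + 1.96 * sl
  expect_true(max(lo_o, lo_l) <= min(hi_o, hi_l))
})
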