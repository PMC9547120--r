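test_that("parameters are recovered on complete data at moderate n", {
  d <- sim_uni_lcsm(5, 2000, worked_model(), worked_x_param(), seed = 101)
  fit <- fit_uni_lcsm(d, var = paste0("x", 1:5), model = worked_model(),
                      fit_stats = FALSE)
  expect_true(fit$converged)
  truth <- unlist(worked_x_param())
  est <- fit$estimates[names(truth)]
  # generous bands: a few sampling standard errors at n = 2000
  expect_equal(unname(est["gamma_lx1"]), 29, tolerance = 0.005)
  expect_lt(abs(est["alpha_g2"] - (-.3)), .25)
  expect_lt(abs(est["beta_x"] - (-.1)), .01)
  expect_lt(abs(est["phi_x"] - .1), .03)
  expect_lt(abs(est["sigma2_ux"] - .2), .02)
  expect_lt(abs(est["sigma2_g2"] - .6), .08)
})

test_that("nested models never lose log-likelihood by adding parameters", {
  d <- sim_uni_lcsm(5, 300, worked_model(), worked_x_param(), na_pct = .1,
                    seed = 55)
  f_small <- fit_uni_lcsm(d, paste0("x", 1:5),
                          list(alpha_constant = TRUE), fit_stats = FALSE,
                          se = FALSE)
  f_mid <- fit_uni_lcsm(d, paste0("x", 1:5),
                        list(alpha_constant = TRUE, beta = TRUE),
                        fit_stats = FALSE, se = FALSE)
  f_big <- fit_uni_lcsm(d, paste0("x", 1:5), worked_model(),
                        fit_stats = FALSE, se = FALSE)
  expect_gte(f_mid$loglik, f_small$loglik - 1e-6)
  expect_gte(f_big$loglik, f_mid$loglik - 1e-6)
})

test_that("refitting from the solution is stationary", {
  fit <- small_uni_fit()
  refit <- fit_lcsm(fit$model, fit$data_matrix, start = fit$estimates,
                    se = FALSE, fit_stats = FALSE)
  expect_true(refit$converged)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(unname(refit$estimates), unname(fit$estimates),
               tolerance = 1e-4)
})

test_that("listwise ML equals FIML when the data are complete", {
  d <- sim_uni_lcsm(5, 200, worked_model(), worked_x_param(), seed = 77)
  f1 <- fit_uni_lcsm(d, paste0("x", 1:5), worked_model(), estimator = "fiml",
                     se = FALSE, fit_stats = FALSE)
  f2 <- fit_uni_lcsm(d, paste0("x", 1:5), worked_model(),
                     estimator = "listwise_ml", se = FALSE, fit_stats = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$n_used, f2$n_used)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  d1 <- sim_uni_lcsm(5, 500, worked_model(), worked_x_param(), seed = 21)
  d2 <- sim_uni_lcsm(5, 4500, worked_model(), worked_x_param(), seed = 22)
  f1 <- fit_uni_lcsm(d1, paste0("x", 1:5), worked_model(), fit_stats = FALSE)
  f2 <- fit_uni_lcsm(d2, paste0("x", 1:5), worked_model(), fit_stats = FALSE)
  ratio <- f1$se / f2$se  # expected sqrt(4500/500) = 3
  expect_true(all(ratio > 2.2 & ratio < 4.1))
})

test_that("degenerate inputs raise data errors, not crashes", {
  m <- compile_lcsm(uni_spec(alpha_constant = TRUE), 3)
  expect_error(fit_lcsm(m, data.frame(x1 = 1, x2 = 2, x3 = 3)),
               "fewer than 2 rows")
  expect_error(fit_lcsm(m, data.frame(a = 1:5)), "lacks observed variable")
})

test_that("fit statistics satisfy their structural identities", {
  fit <- small_uni_fit()
  fs <- fit_statistics(fit)
  p <- 5
  expect_equal(fs$npar, 8)
  expect_equal(fs$df, p * (p + 3) / 2 - 8)  # 20 moments - 8 parameters = 12
  expect_equal(fs$df, 12)
  expect_equal(fs$bic - fs$aic, 8 * (log(fit$n_used) - 2), tolerance = 1e-10)
  expect_equal(fs$aic, -2 * fit$loglik + 2 * 8, tolerance = 1e-10)
  expect_gte(fs$chisq, 0)
  expect_true(fs$cfi >= 0 && fs$cfi <= 1)
  expect_gte(fs$rmsea, 0)
  expect_gte(fs$srmr, 0)
})

test_that("a candidate that attains the saturated likelihood is a perfect fit", {
  fit <- small_uni_fit()
  sat <- lcsmr:::em_saturated(fit$data_matrix)
  at_sat <- fit
  at_sat$loglik <- sat$loglik
  fs <- lcsmr:::compute_fit_statistics(at_sat, fit$data_matrix)
  expect_equal(fs$chisq, 0)
  expect_equal(fs$cfi, 1)
  expect_equal(fs$rmsea, 0)
})

test_that("wrong start-value labels are rejected", {
  fit <- small_uni_fit()
  expect_error(fit_lcsm(fit$model, fit$data_matrix,
                        start = c(nonsense = 1)), "nonsense")
})
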