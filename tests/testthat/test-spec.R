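test_that("conflicting or incomplete change-factor options are rejected", {
  expect_error(uni_spec(alpha_constant = TRUE, alpha_linear = TRUE),
               "alpha_constant.*alpha_linear")
  expect_error(uni_spec(alpha_constant = TRUE, alpha_piecewise = TRUE,
                        alpha_piecewise_num = 3),
               "alpha_constant.*alpha_piecewise")
  expect_error(uni_spec(alpha_piecewise = TRUE), "alpha_piecewise_num")
  expect_error(
    build_parameter_table(uni_spec(alpha_piecewise = TRUE,
                                   alpha_piecewise_num = 5), 5),
    "2\\.\\.T-1")
  expect_error(build_parameter_table(uni_spec(phi = TRUE), 2),
               "at least 3 timepoints")
  expect_error(as_uni_spec(list(alpha_constnt = TRUE)), "alpha_constnt")
})

test_that("lagged coupling and piecewise coupling respect timepoint limits", {
  spec <- bi_spec(list(alpha_constant = TRUE), list(alpha_constant = TRUE),
                  list(xi_lag_yx = TRUE))
  expect_error(build_parameter_table(spec, 2), "at least 3 timepoints")
  expect_silent(build_parameter_table(spec, 3))
  spec2 <- bi_spec(list(alpha_constant = TRUE), list(alpha_constant = TRUE),
                   list(delta_lag_yx = TRUE))
  expect_error(build_parameter_table(spec2, 2), "at least 3 timepoints")
  spec3 <- bi_spec(list(alpha_constant = TRUE), list(alpha_constant = TRUE),
                   list(xi_con_yx = TRUE, coupling_piecewise = TRUE,
                        coupling_piecewise_num = 9))
  expect_error(build_parameter_table(spec3, 5), "2\\.\\.T-1")
})

test_that("the worked univariate model implies exactly its 8 parameters", {
  tab <- build_parameter_table(as_uni_spec(worked_model()), 5)
  expect_identical(tab$label,
                   c("gamma_lx1", "sigma2_lx1", "sigma2_ux", "alpha_g2",
                     "sigma2_g2", "sigma_g2lx1", "beta_x", "phi_x"))
  tab2 <- build_parameter_table(uni_spec(alpha_constant = TRUE), 5)
  expect_identical(tab2$label,
                   c("gamma_lx1", "sigma2_lx1", "sigma2_ux", "alpha_g2",
                     "sigma2_g2", "sigma_g2lx1"))
})

test_that("the worked bivariate model implies exactly 22 parameters", {
  spec <- bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE))
  tab <- build_parameter_table(spec, 5)
  expect_equal(nrow(tab), 22)
  expect_setequal(tab$label,
                  c(names(worked_x_param()), names(worked_y_param()),
                    names(worked_coupling_param())))
})

test_that("parameter set does not depend on T once options are admissible", {
  spec <- bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE))
  expect_identical(build_parameter_table(spec, 5)$label,
                   build_parameter_table(spec, 10)$label)
  pw <- uni_spec(alpha_piecewise = TRUE, alpha_piecewise_num = 3, beta = TRUE)
  expect_identical(build_parameter_table(pw, 5)$label,
                   build_parameter_table(pw, 8)$label)
})

test_that("piecewise options add the second change factor block", {
  tab <- build_parameter_table(
    uni_spec(alpha_piecewise = TRUE, alpha_piecewise_num = 3), 5)
  expect_setequal(tab$label,
                  c("gamma_lx1", "sigma2_lx1", "sigma2_ux",
                    "alpha_g2", "sigma2_g2", "sigma_g2lx1",
                    "alpha_g3", "sigma2_g3", "sigma_g3lx1", "sigma_g2g3"))
  spec <- bi_spec(worked_model(), worked_model(),
                  list(xi_lag_yx = TRUE, delta_con_xy = TRUE,
                       coupling_piecewise = TRUE,
                       coupling_piecewise_num = 3))
  labs <- build_parameter_table(spec, 5)$label
  expect_true(all(c("xi_lag_yx_p1", "xi_lag_yx_p2",
                    "delta_con_xy_p1", "delta_con_xy_p2") %in% labs))
  expect_false(any(c("xi_lag_yx", "delta_con_xy") %in% labs))
})

test_that("every label has a unique role drawn from the inventory", {
  inv <- lcsm_parameters()
  expect_false(anyDuplicated(inv$label) > 0)
  expect_true(all(inv$role %in%
                    c("mean", "variance", "covariance", "regression")))
  tab <- build_parameter_table(
    bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE)), 5)
  expect_identical(tab$role[tab$label == "beta_x"], "regression")
  expect_identical(tab$role[tab$label == "sigma2_g2"], "variance")
  expect_identical(tab$role[tab$label == "alpha_g2"], "mean")
  expect_identical(tab$role[tab$label == "sigma_g2lx1"], "covariance")
})
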