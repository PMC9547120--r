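test_that("zero-variance simulation reproduces the deterministic recursion", {
  th <- list(gamma_lx1 = 29, sigma2_lx1 = 0, sigma2_ux = 0, alpha_g2 = -.3,
             sigma2_g2 = 0, sigma_g2lx1 = 0, beta_x = -.1, phi_x = .1)
  d <- sim_uni_lcsm(5, 10, worked_model(), th, seed = 1)
  expected <- recursion_means(29, -.3, -.1, .1, 5)
  for (t in 1:5) {
    expect_equal(d[[paste0("x", t)]], rep(expected[t], 10), tolerance = 1e-10)
  }
})

test_that("missingness injection hits the requested rates", {
  d <- sim_worked_example(n = 2000, seed = 10)
  x_cells <- as.matrix(d[, paste0("x", 1:5)])
  y_cells <- as.matrix(d[, paste0("y", 1:5)])
  # 10000 cells per construct: binomial SD ~ 0.0036 at p = .15
  expect_lt(abs(mean(is.na(x_cells)) - .15), .015)
  expect_lt(abs(mean(is.na(y_cells)) - .10), .015)
  expect_false(anyNA(d$id))
})

test_that("simulation is seed-deterministic", {
  d1 <- sim_worked_example(n = 50, seed = 123)
  d2 <- sim_worked_example(n = 50, seed = 123)
  d3 <- sim_worked_example(n = 50, seed = 124)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("theta/spec mismatches are reported by label", {
  expect_error(
    sim_uni_lcsm(5, 10, list(alpha_constant = TRUE),
                 list(gamma_lx1 = 10, beta_x = -.1), seed = 1),
    "beta_x")
  expect_message(
    sim_uni_lcsm(5, 10, list(alpha_constant = TRUE),
                 list(gamma_lx1 = 10), seed = 1),
    "set to 0.*sigma2_lx1")
})

test_that("simulated moments track the implied moments (bivariate)", {
  spec <- bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE))
  m <- compile_lcsm(spec, 5)
  th <- c(unlist(worked_x_param()), unlist(worked_y_param()),
          unlist(worked_coupling_param()))
  mom <- implied_moments(m, th)
  n <- 4e4
  d <- sim_bi_lcsm(5, n, worked_model(), worked_x_param(),
                   worked_model(), worked_y_param(),
                   list(xi_lag_yx = TRUE), worked_coupling_param(),
                   seed = 271)
  Y <- as.matrix(d[, -1])[, m$obs]
  se_mean <- sqrt(diag(mom$cov) / n)
  expect_true(all(abs(colMeans(Y) - mom$mean) < 4 * se_mean))
  S <- stats::cov(Y) * (n - 1) / n
  se_cov <- sqrt((tcrossprod(diag(mom$cov)) + mom$cov^2) / n)
  expect_true(all(abs(S - mom$cov) < 4 * se_cov))
})

test_that("latent debug scores satisfy the measurement decomposition", {
  d <- sim_uni_lcsm(4, 30, list(alpha_constant = TRUE),
                    list(gamma_lx1 = 10, sigma2_lx1 = .5, sigma2_ux = .2,
                         alpha_g2 = -.4, sigma2_g2 = .3, sigma_g2lx1 = .1),
                    seed = 17, return_latent = TRUE)
  lat <- attr(d, "latent_scores")
  expect_true(all(c("lx1", "lx2", "dx2", "g2") %in% names(lat)))
  # lx2 = lx1 + dx2 and dx2 = g2 exactly, by construction
  expect_equal(lat$lx2, lat$lx1 + lat$dx2, tolerance = 1e-10)
  expect_equal(lat$dx2, lat$g2, tolerance = 1e-10)
})

test_that("inject_missingness masks cells MCAR and never the id", {
  d <- tibble::tibble(id = 1:1000, x1 = rnorm(1000), x2 = rnorm(1000),
                      x3 = rnorm(1000), x4 = rnorm(1000), x5 = rnorm(1000))
  d0 <- inject_missingness(d, 0, seed = 3)
  expect_identical(d0, d)
  d1 <- inject_missingness(d, .1, seed = 3)
  d2 <- inject_missingness(d, .1, seed = 3)
  expect_identical(d1, d2)
  n_masked <- sum(is.na(d1[, -1]))
  expect_lt(abs(n_masked - 500), 45)   # binomial(5000, .1)
  expect_false(anyNA(d1$id))
  expect_error(inject_missingness(d, 1), "\\[0, 1\\)")
})
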