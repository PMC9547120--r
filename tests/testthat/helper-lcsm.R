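# Shared fixtures: the worked-example generating values, small simulated
# datasets, and independent oracles (deterministic change recursion,
# case-wise multivariate-normal log-likelihood).

worked_model <- function() list(alpha_constant = TRUE, beta = TRUE, phi = TRUE)

worked_x_param <- function() {
  list(gamma_lx1 = 29, sigma2_lx1 = .5, sigma2_ux = .2, alpha_g2 = -.3,
       sigma2_g2 = .6, sigma_g2lx1 = .2, beta_x = -.1, phi_x = .1)
}

worked_y_param <- function() {
  list(gamma_ly1 = 15, sigma2_ly1 = .2, sigma2_uy = .2, alpha_j2 = -.4,
       sigma2_j2 = .1, sigma_j2ly1 = .02, beta_y = -.2, phi_y = .1)
}

worked_coupling_param <- function() {
  list(sigma_su = .01, sigma_ly1lx1 = .2, sigma_g2ly1 = .1,
       sigma_j2lx1 = .1, sigma_j2g2 = .01, xi_lag_yx = .5)
}

sim_worked_example <- function(n = 500, seed = 1234, na_x = .15, na_y = .1) {
  sim_bi_lcsm(timepoints = 5, sample_nobs = n,
              na_x_pct = na_x, na_y_pct = na_y,
              model_x = worked_model(), model_x_param = worked_x_param(),
              model_y = worked_model(), model_y_param = worked_y_param(),
              coupling = list(xi_lag_yx = TRUE),
              coupling_param = worked_coupling_param(),
              seed = seed)
}

# deterministic change recursion (the change equation with zero variances):
# x[1] = gamma; dx[t] = alpha + beta x[t-1] + phi dx[t-1]
recursion_means <- function(gamma, alpha, beta, phi, timepoints) {
  x <- numeric(timepoints)
  x[1] <- gamma
  d_prev <- 0
  for (t in 2:timepoints) {
    d <- alpha + beta * x[t - 1] + if (t >= 3) phi * d_prev else 0
    x[t] <- x[t - 1] + d
    d_prev <- d
  }
  x
}

# brute-force case-wise FIML log-likelihood: one multivariate-normal
# log-density per row, restricted to the row's observed variables
casewise_loglik <- function(mu, Sigma, Y) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    x <- Y[i, o]
    So <- Sigma[o, o, drop = FALSE]
    R <- chol(So)
    d <- backsolve(R, x - mu[o], transpose = TRUE)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(d^2))
  }
  ll
}

# one small converged univariate fit, computed once and reused across tests
small_fit_cache <- new.env(parent = emptyenv())
small_uni_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    d <- sim_uni_lcsm(timepoints = 5, sample_nobs = 400,
                      model = worked_model(), model_param = worked_x_param(),
                      na_pct = .1, seed = 2024)
    small_fit_cache$fit <- fit_uni_lcsm(d, var = paste0("x", 1:5),
                                        model = worked_model())
  }
  small_fit_cache$fit
}
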