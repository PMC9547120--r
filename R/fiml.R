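# Full-information maximum likelihood under missing data.
#
# The sample is grouped by missingness pattern; within a pattern the summed
# log-density depends on the data only through (n_g, mean_g, scatter_g), so
# each likelihood evaluation costs O(#patterns * p^3) independent of n:
#   sum_i log phi(x_i; mu_o, Sigma_oo)
#     = -n_g/2 [ p_g log(2*pi) + log|Sigma_oo|
#                + tr(Sigma_oo^{-1} S_g) + d' Sigma_oo^{-1} d ]
# with d = mean_g - mu_o and S_g the ML scatter about the pattern mean.

pattern_stats <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  p <- ncol(Y)
  miss <- is.na(Y)
  all_missing <- rowSums(miss) == p
  n_excluded <- sum(all_missing)
  Y <- Y[!all_missing, , drop = FALSE]
  miss <- miss[!all_missing, , drop = FALSE]
  if (nrow(Y) == 0) {
    return(list(patterns = list(), n_used = 0L, n_excluded = n_excluded, p = p))
  }
  key <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  patterns <- lapply(groups, function(rows) {
    obs <- which(!miss[rows[1], ])
    Xo <- Y[rows, obs, drop = FALSE]
    n_g <- length(rows)
    mean_g <- colMeans(Xo)
    dev <- sweep(Xo, 2L, mean_g)
    scatter <- crossprod(dev) / n_g
    list(obs = obs, n = n_g, mean = mean_g, scatter = scatter)
  })
  list(patterns = patterns, n_used = nrow(Y), n_excluded = n_excluded, p = p)
}

# log-likelihood of N(mu, Sigma) for pattern-grouped data; -Inf when any
# pattern's covariance block is not positive definite
fiml_loglik_moments <- function(mu, Sigma, stats) {
  if (!all(is.finite(Sigma)) || !all(is.finite(mu))) return(-Inf)
  ll <- 0
  for (pt in stats$patterns) {
    o <- pt$obs
    So <- Sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    dd <- diag(R)
    # numerically untrustworthy factorisations (near-singular at huge scale)
    # are treated as outside the admissible region
    if (any(dd <= 0) || max(dd) / min(dd) > 1e10) return(-Inf)
    logdet <- 2 * sum(log(dd))
    Sinv <- chol2inv(R)
    d <- pt$mean - mu[o]
    quad <- sum(Sinv * pt$scatter) + drop(crossprod(d, Sinv %*% d))
    if (!is.finite(quad) || quad < 0) return(-Inf)
    ll <- ll - pt$n / 2 * (length(o) * log(2 * pi) + logdet + quad)
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Full-information maximum likelihood log-likelihood
#'
#' Sum over individuals of the multivariate-normal log-density of each
#' individual's observed subset of variables, at the model-implied moments.
#' Rows with all values missing contribute nothing and are excluded from the
#' effective sample size. Evaluation is grouped by missingness pattern but is
#' numerically identical to case-by-case evaluation.
#'
#' @inheritParams implied_moments
#' @param data Data frame (or matrix) containing the model's observed
#'   variables; `NA` marks missing values.
#' @return The log-likelihood (scalar); `-Inf` if the implied covariance is
#'   not positive definite on some observed subset.
#' @export
fiml_loglik <- function(model, theta, data) {
  Y <- extract_observed(model, data)
  stats <- pattern_stats(Y)
  mom <- implied_moments(model, theta)
  fiml_loglik_moments(mom$mean, mom$cov, stats)
}

extract_observed <- function(model, data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  missing_cols <- setdiff(model$obs, names(data))
  if (length(missing_cols)) {
    stop_data("data lacks observed variable(s): ",
              paste(missing_cols, collapse = ", "))
  }
  Y <- as.matrix(data[, model$obs, drop = FALSE])
  if (!is.numeric(Y)) stop_data("observed variables must be numeric")
  Y
}

# ---- saturated model under missingness (EM) -------------------------------

closed_form_saturated <- function(stats) {
  # only valid when every pattern is complete
  pt <- stats$patterns[[1]]
  n <- pt$n
  list(mean = pt$mean, cov = pt$scatter)
}

# EM for the unstructured multivariate normal with MCAR/MAR missingness.
# E-step sufficient statistics are accumulated pattern-by-pattern.
em_saturated <- function(Y, max_iter = 1000L, tol = 1e-8) {
  stats <- pattern_stats(Y)
  p <- stats$p
  if (stats$n_used < 2L) stop_data("fewer than 2 usable rows")
  complete <- length(stats$patterns) == 1L &&
    length(stats$patterns[[1]]$obs) == p
  if (complete) {
    est <- closed_form_saturated(stats)
    ll <- fiml_loglik_moments(est$mean, est$cov, stats)
    return(list(mean = est$mean, cov = est$cov, loglik = ll,
                iterations = 0L, converged = TRUE, n_used = stats$n_used))
  }
  # keep raw rows for the E-step
  Y <- as.matrix(Y)
  miss <- is.na(Y)
  keep <- rowSums(miss) < p
  Y <- Y[keep, , drop = FALSE]
  miss <- miss[keep, , drop = FALSE]
  n <- nrow(Y)
  key <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), key)
  # initial values: available-case means/variances, zero covariances
  mu <- vapply(seq_len(p), function(j) mean(Y[, j], na.rm = TRUE), numeric(1))
  v0 <- vapply(seq_len(p), function(j) {
    v <- stats::var(Y[, j], na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1))
  Sigma <- diag(v0, p)
  ll_old <- fiml_loglik_moments(mu, Sigma, stats)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sum1 <- numeric(p)
    sum2 <- matrix(0, p, p)
    for (rows in groups) {
      o <- which(!miss[rows[1], ])
      m_ <- which(miss[rows[1], ])
      Xo <- Y[rows, o, drop = FALSE]
      n_g <- length(rows)
      Z <- matrix(0, n_g, p)
      Z[, o] <- Xo
      if (length(m_)) {
        Soo <- Sigma[o, o, drop = FALSE]
        R <- chol(Soo)
        B <- Sigma[m_, o, drop = FALSE] %*% chol2inv(R)
        dev <- sweep(Xo, 2L, mu[o])
        Z[, m_] <- matrix(mu[m_], n_g, length(m_), byrow = TRUE) +
          dev %*% t(B)
        Cg <- Sigma[m_, m_, drop = FALSE] - B %*% Sigma[o, m_, drop = FALSE]
        sum2[m_, m_] <- sum2[m_, m_] + n_g * Cg
      }
      sum1 <- sum1 + colSums(Z)
      sum2 <- sum2 + crossprod(Z)
    }
    mu <- sum1 / n
    Sigma <- sum2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- fiml_loglik_moments(mu, Sigma, stats)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mean = stats::setNames(mu, colnames(Y)), cov = Sigma, loglik = ll_old,
       iterations = iter, converged = converged, n_used = n)
}

# independence baseline: free means and variances, zero covariances.
# With a diagonal covariance the likelihood factorises per variable, so the
# MLE is available in closed form from each variable's observed values.
baseline_saturated <- function(Y) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  ll <- 0
  for (j in seq_len(p)) {
    v <- Y[, j]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop_data("variable ", j, " has fewer than 2 values")
    mu_j <- mean(v)
    s2_j <- mean((v - mu_j)^2)
    ll <- ll + sum(stats::dnorm(v, mu_j, sqrt(s2_j), log = TRUE))
  }
  list(loglik = ll, npar = 2L * p)
}
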