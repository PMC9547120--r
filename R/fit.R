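# Fitting: quasi-Newton maximisation of the FIML log-likelihood on the
# natural parameter scale, with a finite penalty replacing -Inf where the
# implied covariance is not positive definite. Standard errors come from the
# inverse of the numerically differentiated observed information.

default_control <- function(control = list()) {
  utils::modifyList(list(maxit = 500L, reltol = 1e-9, grad_tol = 1e-6,
                         restarts = 2L, penalty = 1e10), control)
}

# data-driven start values: initial-status mean from the first occasion,
# half the first occasion's variance for true-score and unique variances,
# mean successive difference for change-factor means, half the variance of
# successive differences for change-factor variances, zero for regressions
# and covariances
start_values <- function(model, Y) {
  tab <- model$param_table
  theta <- stats::setNames(tab$start, tab$label)
  theta[tab$role %in% c("regression", "covariance")] <- 0
  side_start <- function(obs_names) {
    first <- Y[, obs_names[1]]
    mu1 <- mean(first, na.rm = TRUE)
    v1 <- stats::var(first, na.rm = TRUE)
    if (!is.finite(v1) || v1 <= 0) v1 <- 1
    D <- Y[, obs_names[-1], drop = FALSE] - Y[, obs_names[-length(obs_names)],
                                              drop = FALSE]
    md <- mean(D, na.rm = TRUE)
    vd <- stats::var(as.vector(D), na.rm = TRUE)
    if (!is.finite(md)) md <- 0
    if (!is.finite(vd) || vd <= 0) vd <- 1
    list(mu1 = mu1, v1 = v1, md = md, vd = vd)
  }
  sx <- side_start(model$names_x$obs)
  put <- function(lab, val) {
    if (lab %in% names(theta)) theta[lab] <<- val
  }
  put("gamma_lx1", sx$mu1)
  put("sigma2_lx1", sx$v1 / 2)
  put("sigma2_ux", sx$v1 / 2)
  for (lab in c("alpha_g2", "alpha_g3")) put(lab, sx$md)
  for (lab in c("sigma2_g2", "sigma2_g3")) put(lab, sx$vd / 2)
  if (!is.null(model$names_y)) {
    sy <- side_start(model$names_y$obs)
    put("gamma_ly1", sy$mu1)
    put("sigma2_ly1", sy$v1 / 2)
    put("sigma2_uy", sy$v1 / 2)
    for (lab in c("alpha_j2", "alpha_j3")) put(lab, sy$md)
    for (lab in c("sigma2_j2", "sigma2_j3")) put(lab, sy$vd / 2)
  }
  theta
}

num_gradient <- function(fn, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(1e-6 * abs(x), 1e-7)
  g <- numeric(k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    g[i] <- (fn(x + e) - fn(x - e)) / (2 * h[i])
  }
  g
}

num_hessian <- function(gr, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(1e-5 * abs(x), 1e-6)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    H[i, ] <- (gr(x + e) - gr(x - e)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

# negative FIML log-likelihood with the label -> cell fills precomputed,
# avoiding per-evaluation validation and name matching
make_negll <- function(model, stats_, penalty) {
  labs <- model$param_table$label
  A0 <- model$A; S0 <- model$S; m0 <- model$m
  ia <- which(model$A_lab != "")
  a_pos <- match(model$A_lab[ia], labs)
  is_ <- which(model$S_lab != "")
  s_pos <- match(model$S_lab[is_], labs)
  im <- which(model$m_lab != "")
  m_pos <- match(model$m_lab[im], labs)
  oi <- match(model$obs, model$vars)
  Ieye <- diag(length(model$vars))
  function(par) {
    A <- A0; A[ia] <- par[a_pos]
    S <- S0; S[is_] <- par[s_pos]
    m <- m0; m[im] <- par[m_pos]
    B <- tryCatch(solve(Ieye - A), error = function(e) NULL)
    if (is.null(B)) return(penalty)
    mu <- drop(B %*% m)[oi]
    Sig <- (B %*% S %*% t(B))[oi, oi, drop = FALSE]
    Sig <- (Sig + t(Sig)) / 2
    ll <- fiml_loglik_moments(mu, Sig, stats_)
    if (!is.finite(ll)) return(penalty)
    -ll
  }
}

#' Fit a latent change score model
#'
#' Maximises the full-information maximum likelihood of a compiled model by
#' quasi-Newton (BFGS) iteration. Under `estimator = "fiml"` every row with
#' at least one observed value contributes its observed subset; under
#' `"listwise_ml"` incomplete rows are dropped first. Standard errors are
#' computed from the inverse of the numerically differentiated observed
#' information of the negative log-likelihood. Non-convergence is reported
#' through the `converged` flag (with optimizer diagnostics), not an error.
#'
#' @param model An `lcsm_model` from [compile_lcsm()].
#' @param data Data frame containing the model's observed variables.
#' @param estimator `"fiml"` (default) or `"listwise_ml"`.
#' @param start Optional named vector of start values (overrides the
#'   data-driven defaults label by label).
#' @param se Compute standard errors (default `TRUE`).
#' @param fit_stats Compute fit statistics (chi-square against an EM-estimated
#'   saturated model, AIC, BIC, CFI, RMSEA, SRMR); default `TRUE`.
#' @param control List overriding optimisation controls: `maxit` (500),
#'   `reltol` (1e-9), `grad_tol` (1e-6, relative to `max(1, |loglik|)`),
#'   `restarts` (2).
#' @return An object of class `lcsm_fit`.
#' @seealso [fit_uni_lcsm()], [fit_bi_lcsm()], [extract_param()],
#'   [extract_fit()]
#' @export
fit_lcsm <- function(model, data, estimator = c("fiml", "listwise_ml"),
                     start = NULL, se = TRUE, fit_stats = TRUE,
                     control = list()) {
  stopifnot(inherits(model, "lcsm_model"))
  estimator <- match.arg(estimator)
  ctrl <- default_control(control)
  Y <- extract_observed(model, data)
  if (estimator == "listwise_ml") {
    Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  }
  stats_ <- pattern_stats(Y)
  if (stats_$n_used < 2L) {
    stop_data("fewer than 2 rows with observed values")
  }
  labs <- model$param_table$label
  theta0 <- start_values(model, Y)
  if (!is.null(start)) {
    if (is.list(start)) start <- unlist(start)
    bad <- setdiff(names(start), labs)
    if (length(bad)) {
      stop_spec("start values for unknown label(s): ",
                paste(bad, collapse = ", "))
    }
    theta0[names(start)] <- start
  }
  negll <- make_negll(model, stats_, ctrl$penalty)
  negll_grad <- function(par) num_gradient(negll, par)
  par <- unname(theta0[labs])
  pscale <- pmax(abs(par), 0.1)
  # derivative-free pre-stage: moves cautiously off poor start values (a
  # quasi-Newton line search can overshoot into numerically degenerate
  # territory when the start misfit is large)
  pre <- stats::optim(par, negll, method = "Nelder-Mead",
                      control = list(maxit = 500L, parscale = pscale))
  iterations <- pre$counts
  opt <- stats::optim(pre$par, negll, gr = negll_grad, method = "BFGS",
                      control = list(maxit = ctrl$maxit,
                                     reltol = ctrl$reltol,
                                     parscale = pscale))
  if (opt$value > pre$value) opt <- pre
  iterations <- iterations + opt$counts
  par <- opt$par
  value <- opt$value
  grad <- negll_grad(par)
  gtol <- ctrl$grad_tol * max(1, abs(value))
  # Newton polish: quasi-Newton line searches satisfy the relative-change
  # criterion before the gradient max-norm one; a few damped Newton steps on
  # the numeric Hessian finish the job, and the final Hessian is reused as
  # the observed information for standard errors
  H <- NULL
  polish <- 0L
  while (max(abs(grad)) > gtol && polish < 10L) {
    polish <- polish + 1L
    H <- num_hessian(negll_grad, par)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    damp <- 1
    for (half in 1:8) {
      cand <- par - damp * step
      v_cand <- negll(cand)
      if (is.finite(v_cand) && v_cand <= value + 1e-10 * abs(value)) {
        g_cand <- negll_grad(cand)
        if (max(abs(g_cand)) < max(abs(grad)) || v_cand < value) {
          par <- cand; value <- v_cand; grad <- g_cand
          improved <- TRUE
          break
        }
      }
      damp <- damp / 2
    }
    if (!improved) break
  }
  if (max(abs(grad)) > gtol) {
    # final fallback: restart BFGS from the current point
    tries <- 0L
    while (max(abs(grad)) > gtol && tries < ctrl$restarts) {
      tries <- tries + 1L
      opt2 <- stats::optim(par, negll, gr = negll_grad, method = "BFGS",
                           control = list(maxit = ctrl$maxit,
                                          reltol = ctrl$reltol))
      iterations <- iterations + opt2$counts
      if (opt2$value <= value) {
        par <- opt2$par; value <- opt2$value
        H <- NULL
      }
      grad <- negll_grad(par)
    }
  }
  loglik <- -value
  converged <- is.finite(loglik) && max(abs(grad)) <= gtol
  estimates <- stats::setNames(par, labs)
  se_vec <- stats::setNames(rep(NA_real_, length(labs)), labs)
  vcov_mat <- NULL
  if (se && converged) {
    if (is.null(H)) H <- num_hessian(negll_grad, par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se_vec[] <- sqrt(diag(V))
      dimnames(V) <- list(labs, labs)
      vcov_mat <- V
    }
  }
  out <- structure(list(model = model, estimates = estimates, se = se_vec,
                        vcov = vcov_mat, loglik = loglik,
                        n_used = stats_$n_used,
                        n_excluded = stats_$n_excluded,
                        converged = converged, estimator = estimator,
                        iterations = iterations,
                        gradient_max = max(abs(grad)),
                        data_stats = stats_, fit = NULL),
                   class = "lcsm_fit")
  if (fit_stats && converged) {
    out$fit <- tryCatch(compute_fit_statistics(out, Y),
                        error = function(e) NULL)
  }
  out$data_matrix <- Y
  out
}

#' Fit a univariate LCSM from data and an option list
#'
#' Mirrors the option-list workflow: the model options are compiled against
#' the supplied variable names and fitted by FIML.
#'
#' @param data Wide-format data frame (one row per individual).
#' @param var Character vector of the repeated-measure column names, in
#'   temporal order.
#' @param model Option list (e.g. `list(alpha_constant = TRUE, beta = TRUE)`)
#'   or a [uni_spec()].
#' @param ... Passed on to [fit_lcsm()].
#' @return An `lcsm_fit`.
#' @examples
#' \donttest{
#' d <- sim_uni_lcsm(timepoints = 5, sample_nobs = 200,
#'                   model = list(alpha_constant = TRUE),
#'                   model_param = list(gamma_lx1 = 20, sigma2_lx1 = .5,
#'                                      sigma2_ux = .2, alpha_g2 = -.4,
#'                                      sigma2_g2 = .3, sigma_g2lx1 = .1),
#'                   seed = 7)
#' fit <- fit_uni_lcsm(d, var = paste0("x", 1:5),
#'                     model = list(alpha_constant = TRUE))
#' extract_param(fit)
#' }
#' @export
fit_uni_lcsm <- function(data, var, model, ...) {
  spec <- as_uni_spec(model)
  mod <- compile_lcsm(spec, timepoints = length(var), var_x = var)
  fit_lcsm(mod, data, ...)
}

#' Fit a bivariate LCSM from data and option lists
#'
#' @inheritParams fit_uni_lcsm
#' @param var_x,var_y Column names of the two constructs' repeated measures.
#' @param model_x,model_y Option lists or [uni_spec()] objects.
#' @param coupling Option list or [coupling_spec()].
#' @return An `lcsm_fit`.
#' @export
fit_bi_lcsm <- function(data, var_x, var_y, model_x, model_y,
                        coupling = list(), ...) {
  spec <- bi_spec(model_x, model_y, coupling)
  mod <- compile_lcsm(spec, timepoints = length(var_x),
                      var_x = var_x, var_y = var_y)
  fit_lcsm(mod, data, ...)
}

#' @export
print.lcsm_fit <- function(x, ...) {
  kind <- if (inherits(x$model$spec, "bi_spec")) "bivariate" else "univariate"
  cat(sprintf("%s LCSM fit (%s), %d parameters\n", kind, x$estimator,
              length(x$estimates)))
  cat(sprintf("log-likelihood %.3f on n = %d (%d excluded), converged: %s\n",
              x$loglik, x$n_used, x$n_excluded, x$converged))
  if (!is.null(x$fit)) {
    cat(sprintf("chisq %.3f (df %d), aic %.1f, bic %.1f, cfi %.3f, rmsea %.3f, srmr %.4f\n",
                x$fit$chisq, x$fit$df, x$fit$aic, x$fit$bic, x$fit$cfi,
                x$fit$rmsea, x$fit$srmr))
  }
  print(extract_param(x), n = length(x$estimates))
  invisible(x)
}

#' Log-likelihood of a fitted LCSM
#' @param object An `lcsm_fit`.
#' @param ... Unused.
#' @export
logLik.lcsm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_used, class = "logLik")
}

#' Parameter estimates of a fitted LCSM
#' @param object An `lcsm_fit`.
#' @param ... Unused.
#' @export
coef.lcsm_fit <- function(object, ...) object$estimates
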