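# Simulation follows the structural path: exogenous latents (initial true
# scores, change factors, occasion-specific unique scores) are drawn from the
# multivariate normal defined by theta's means and (co)variances, then the
# structural recursions build change scores, true scores and observed scores.
# This is distributionally identical to sampling the implied MVN directly,
# and additionally yields the latent scores for diagnostics.

# symmetric square root of a PSD matrix (tolerates zero variances)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- max(abs(vals)) * 1e-10
  if (any(vals < -max(tol, 1e-12))) {
    stop_spec("latent covariance structure is not positive semidefinite ",
              "at the supplied parameter values")
  }
  vals[vals < 0] <- 0
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

resolve_theta <- function(model, theta) {
  labs <- model$param_table$label
  if (is.list(theta)) theta <- unlist(theta)
  if (length(theta) && (is.null(names(theta)) || any(!nzchar(names(theta))))) {
    stop_spec("simulation parameters must be named")
  }
  extra <- setdiff(names(theta), labs)
  if (length(extra)) {
    stop_spec("parameter(s) not in this specification: ",
              paste(extra, collapse = ", "),
              "; expected labels: ", paste(labs, collapse = ", "))
  }
  full <- stats::setNames(rep(0, length(labs)), labs)
  full[names(theta)] <- theta
  omitted <- setdiff(labs, names(theta))
  if (length(omitted)) {
    message("Parameters not specified are set to 0: ",
            paste(omitted, collapse = ", "))
  }
  full
}

#' Simulate wide-format data from an LCSM specification
#'
#' Draws `sample_nobs` individuals from the distribution a specification and
#' parameter vector imply, then (optionally) masks cells completely at random.
#' Parameters omitted from `theta` default to 0 with a message; parameters
#' not in the specification are an error.
#'
#' @param spec A [uni_spec()] or [bi_spec()].
#' @param timepoints Number of repeated measures per construct.
#' @param sample_nobs Number of individuals.
#' @param theta Named list/vector of generating parameter values.
#' @param na_pct Probability that an observed cell is set missing, per
#'   construct: a single value, or a vector named `x`/`y`. Must be in
#'   `[0, 1)`.
#' @param seed Optional integer seed; identical seeds give identical output.
#'   Reproducing a dataset bit-for-bit requires this implementation — the
#'   same seed in a different program draws different numbers.
#' @param var_x,var_y Observed variable names.
#' @param return_latent Attach the latent true/change/factor scores as
#'   attribute `"latent_scores"` (a tibble).
#' @return A tibble with columns `id` and the observed variables.
#' @export
sim_lcsm <- function(spec, timepoints, sample_nobs, theta = list(),
                     na_pct = 0, seed = NULL,
                     var_x = paste0("x", seq_len(timepoints)),
                     var_y = paste0("y", seq_len(timepoints)),
                     return_latent = FALSE) {
  model <- compile_lcsm(spec, timepoints, var_x = var_x, var_y = var_y)
  theta <- resolve_theta(model, theta)
  n <- as.integer(sample_nobs)
  if (is.na(n) || n < 1L) stop_spec("`sample_nobs` must be a positive integer")
  if (is.null(names(na_pct))) {
    na_pct <- stats::setNames(rep(na_pct[1], 2), c("x", "y"))
  }
  if (any(na_pct < 0 | na_pct >= 1)) {
    stop_spec("missingness proportions must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  mats <- fill_matrices(model, theta)
  B <- solve_structure(mats$A)
  p_all <- length(model$vars)
  Rt <- psd_sqrt(mats$S)
  E <- matrix(stats::rnorm(n * p_all), n, p_all) %*% Rt
  mu_all <- drop(B %*% mats$m)
  V <- E %*% t(B)
  V <- sweep(V, 2L, mu_all, "+")
  colnames(V) <- model$vars
  obs <- V[, model$obs, drop = FALSE]
  # MCAR masking, cellwise and independent; the id column is never masked
  mask_cols <- function(M, cols, pct) {
    if (pct <= 0 || !length(cols)) return(M)
    sel <- matrix(stats::runif(nrow(M) * length(cols)) < pct,
                  nrow(M), length(cols))
    M[, cols][sel] <- NA
    M
  }
  obs <- mask_cols(obs, intersect(var_x, colnames(obs)), na_pct[["x"]])
  if (inherits(spec, "bi_spec")) {
    obs <- mask_cols(obs, intersect(var_y, colnames(obs)), na_pct[["y"]])
  }
  out <- tibble::as_tibble(as.data.frame(obs))
  out <- tibble::add_column(out, id = seq_len(n), .before = 1)
  if (return_latent) {
    latent <- V[, setdiff(model$vars, model$obs), drop = FALSE]
    attr(out, "latent_scores") <-
      tibble::add_column(tibble::as_tibble(as.data.frame(latent)),
                         id = seq_len(n), .before = 1)
  }
  out
}

#' Simulate data from a univariate LCSM
#'
#' @inheritParams sim_lcsm
#' @param model Option list or [uni_spec()].
#' @param model_param Named list of generating parameter values.
#' @param var Observed variable names.
#' @return A tibble with columns `id`, `x1..xT` (or `var`).
#' @examples
#' sim_uni_lcsm(timepoints = 4, sample_nobs = 5,
#'              model = list(alpha_constant = TRUE),
#'              model_param = list(gamma_lx1 = 20, sigma2_lx1 = .5,
#'                                 sigma2_ux = .2, alpha_g2 = -.4,
#'                                 sigma2_g2 = .3, sigma_g2lx1 = .1),
#'              seed = 1)
#' @export
sim_uni_lcsm <- function(timepoints, sample_nobs, model, model_param = list(),
                         na_pct = 0, seed = NULL,
                         var = paste0("x", seq_len(timepoints)),
                         return_latent = FALSE) {
  sim_lcsm(as_uni_spec(model), timepoints, sample_nobs, theta = model_param,
           na_pct = c(x = na_pct, y = 0), seed = seed, var_x = var,
           return_latent = return_latent)
}

#' Simulate data from a bivariate LCSM
#'
#' @inheritParams sim_lcsm
#' @param model_x,model_y Option lists or [uni_spec()] objects.
#' @param model_x_param,model_y_param Named lists of generating values for
#'   the two constructs.
#' @param coupling Option list or [coupling_spec()].
#' @param coupling_param Named list of coupling parameter values (covariances
#'   between the constructs and coupling regressions).
#' @param na_x_pct,na_y_pct Cellwise MCAR missingness probability per
#'   construct.
#' @return A tibble with columns `id`, `x1..xT`, `y1..yT`.
#' @export
sim_bi_lcsm <- function(timepoints, sample_nobs,
                        model_x, model_x_param = list(),
                        model_y, model_y_param = list(),
                        coupling = list(), coupling_param = list(),
                        na_x_pct = 0, na_y_pct = 0, seed = NULL,
                        var_x = paste0("x", seq_len(timepoints)),
                        var_y = paste0("y", seq_len(timepoints)),
                        return_latent = FALSE) {
  spec <- bi_spec(model_x, model_y, coupling)
  theta <- c(unlist(model_x_param), unlist(model_y_param),
             unlist(coupling_param))
  sim_lcsm(spec, timepoints, sample_nobs, theta = theta,
           na_pct = c(x = na_x_pct, y = na_y_pct), seed = seed,
           var_x = var_x, var_y = var_y, return_latent = return_latent)
}

#' Inject MCAR missingness into wide data
#'
#' Masks cells of the given columns independently with the stated
#' probability. The `id` column is never masked.
#'
#' @param data A data frame.
#' @param pct Missingness probability in `[0, 1)`: a single value applied to
#'   all `vars`, or a named vector whose names are column names.
#' @param vars Columns to mask; defaults to every column except `id`.
#' @param seed Optional integer seed (identical seed, identical mask).
#' @return The data with cells set to `NA`.
#' @export
inject_missingness <- function(data, pct, vars = setdiff(names(data), "id"),
                               seed = NULL) {
  if (any(pct < 0 | pct >= 1)) {
    stop_spec("missingness proportions must lie in [0, 1)")
  }
  vars <- setdiff(vars, "id")
  stopifnot(all(vars %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(names(pct))) {
    stopifnot(all(names(pct) %in% names(data)))
    for (v in setdiff(names(pct), "id")) {
      sel <- stats::runif(nrow(data)) < pct[[v]]
      data[[v]][sel] <- NA
    }
  } else {
    for (v in vars) {
      sel <- stats::runif(nrow(data)) < pct
      data[[v]][sel] <- NA
    }
  }
  data
}
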