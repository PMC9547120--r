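# Model-implied moments via RAM algebra:
#   mu    = F (I - A)^{-1} m
#   Sigma = F (I - A)^{-1} S (I - A)^{-T} F'
# where F filters the observed variables.

check_theta <- function(model, theta) {
  labs <- model$param_table$label
  if (is.list(theta)) theta <- unlist(theta)
  if (is.null(names(theta)) || any(!nzchar(names(theta)))) {
    stop_spec("`theta` must be a fully named numeric vector")
  }
  missing <- setdiff(labs, names(theta))
  extra <- setdiff(names(theta), labs)
  if (length(missing) || length(extra)) {
    stop_spec("parameter vector does not match the model's labels",
              if (length(missing)) paste0("; missing: ",
                                          paste(missing, collapse = ", ")),
              if (length(extra)) paste0("; extra: ",
                                        paste(extra, collapse = ", ")))
  }
  theta[labs]
}

fill_matrices <- function(model, theta) {
  A <- model$A; S <- model$S; m <- model$m
  ia <- model$A_lab != ""
  A[ia] <- theta[model$A_lab[ia]]
  is_ <- model$S_lab != ""
  S[is_] <- theta[model$S_lab[is_]]
  im <- model$m_lab != ""
  m[im] <- theta[model$m_lab[im]]
  list(A = A, S = S, m = m)
}

solve_structure <- function(A) {
  B <- tryCatch(solve(diag(nrow(A)) - A),
                error = function(e) NULL)
  if (is.null(B)) {
    stop_spec("structural cycle: (I - A) is singular for this model/theta")
  }
  B
}

#' Model-implied mean vector and covariance matrix
#'
#' Evaluates the moments of the observed variables implied by the structural
#' model at a given parameter vector, using the reduced-form algebra
#' `mu = F (I - A)^{-1} m`, `Sigma = F (I - A)^{-1} S (I - A)^{-T} F'`.
#'
#' @param model An `lcsm_model`.
#' @param theta Named numeric vector covering exactly the model's parameter
#'   labels.
#' @return List with `mean` (named vector over observed variables) and
#'   `cov` (symmetric matrix).
#' @examples
#' m <- compile_lcsm(uni_spec(alpha_constant = TRUE), 3)
#' implied_moments(m, c(gamma_lx1 = 10, sigma2_lx1 = 1, sigma2_ux = .5,
#'                      alpha_g2 = -1, sigma2_g2 = .2, sigma_g2lx1 = 0))
#' @export
implied_moments <- function(model, theta) {
  stopifnot(inherits(model, "lcsm_model"))
  theta <- check_theta(model, theta)
  mats <- fill_matrices(model, theta)
  B <- solve_structure(mats$A)
  mu_all <- drop(B %*% mats$m)
  Sig_all <- B %*% mats$S %*% t(B)
  Sig_all <- (Sig_all + t(Sig_all)) / 2
  oi <- match(model$obs, model$vars)
  list(mean = stats::setNames(mu_all[oi], model$obs),
       cov = Sig_all[oi, oi, drop = FALSE])
}
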