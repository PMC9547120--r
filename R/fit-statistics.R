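# Likelihood-ratio fit statistics against an EM-estimated saturated model
# (unstructured mean vector and covariance matrix) and an independence
# baseline (free means and variances, zero covariances):
#   chisq = 2 (ll_sat - ll_model),  df = p(p+3)/2 - npar
#   aic   = -2 ll + 2 npar,         bic = -2 ll + npar log(n_used)
#   cfi   = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)
#   rmsea = sqrt(max(chisq - df, 0) / (df * n_used))
#   srmr  = RMS of covariance residuals standardised by saturated variances
#           (classic covariance-only definition)

compute_fit_statistics <- function(fit, Y) {
  p <- length(fit$model$obs)
  npar <- length(fit$estimates)
  n <- fit$n_used
  moments <- p * (p + 3) / 2
  df <- as.integer(moments - npar)
  ll <- fit$loglik
  aic <- -2 * ll + 2 * npar
  bic <- -2 * ll + npar * log(n)
  sat <- tryCatch(em_saturated(Y), error = function(e) NULL)
  base <- tryCatch(baseline_saturated(Y), error = function(e) NULL)
  out <- list(chisq = NA_real_, df = df, npar = npar, p.value = NA_real_,
              aic = aic, bic = bic, cfi = NA_real_, rmsea = NA_real_,
              srmr = NA_real_, loglik = ll, loglik_sat = NA_real_,
              loglik_baseline = NA_real_, n = n)
  if (is.null(sat) || !sat$converged) return(out)
  out$loglik_sat <- sat$loglik
  chisq <- max(2 * (sat$loglik - ll), 0)
  out$chisq <- chisq
  out$p.value <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  out$rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * n)) else 0
  if (!is.null(base)) {
    out$loglik_baseline <- base$loglik
    chisq_b <- max(2 * (sat$loglik - base$loglik), 0)
    df_b <- as.integer(moments - base$npar)
    denom <- max(chisq_b - df_b, chisq - df, 0)
    out$cfi <- if (denom <= 0) 1 else 1 - max(chisq - df, 0) / denom
  }
  mom <- implied_moments(fit$model, fit$estimates)
  sd_sat <- sqrt(diag(sat$cov))
  Rmat <- (sat$cov - mom$cov) / tcrossprod(sd_sat)
  resid <- Rmat[upper.tri(Rmat, diag = TRUE)]
  out$srmr <- sqrt(mean(resid^2))
  out
}

#' Fit statistics of a fitted LCSM
#'
#' Returns (computing if necessary) the likelihood-ratio fit statistics of a
#' converged fit: chi-square against the saturated model estimated by FIML on
#' the same data, degrees of freedom (observed moments minus free
#' parameters), AIC, BIC, CFI against an independence baseline, RMSEA and
#' SRMR. When the saturated or baseline estimation fails the dependent
#' indices are `NA` while AIC and BIC are still returned.
#'
#' @param fitted An `lcsm_fit`.
#' @return A list with elements `chisq`, `df`, `npar`, `p.value`, `aic`,
#'   `bic`, `cfi`, `rmsea`, `srmr`, `loglik`, `loglik_sat`,
#'   `loglik_baseline`, `n`.
#' @export
fit_statistics <- function(fitted) {
  stopifnot(inherits(fitted, "lcsm_fit"))
  if (!fitted$converged) {
    stop_data("fit statistics require a converged model")
  }
  if (!is.null(fitted$fit)) return(fitted$fit)
  compute_fit_statistics(fitted, fitted$data_matrix)
}
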