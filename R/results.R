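format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("< .001")
    sub("^0", "", sprintf("%.3f", pi))
  }, character(1))
}

#' Extract fit statistics from one or more fitted models
#'
#' One row per model, in the order passed. The compact table carries the
#' commonly reported indices; `details = TRUE` appends degrees of freedom,
#' the chi-square p-value, the log-likelihood and the effective sample size.
#' A non-converged model yields a row of missing indices.
#'
#' @param ... One or more `lcsm_fit` objects (or a single list of them).
#' @param details Append the extended columns.
#' @return A tibble with columns `model`, `chisq`, `npar`, `aic`, `bic`,
#'   `cfi`, `rmsea`, `srmr` (plus `df`, `p.value`, `loglik`, `n` when
#'   `details = TRUE`).
#' @export
extract_fit <- function(..., details = FALSE) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1]]) &&
      !inherits(models[[1]], "lcsm_fit")) {
    models <- models[[1]]
  }
  cols <- c("model", "chisq", "npar", "aic", "bic", "cfi", "rmsea", "srmr")
  ext <- c("df", "p.value", "loglik", "n")
  if (!length(models)) {
    empty <- stats::setNames(rep(list(numeric(0)),
                                 length(cols) + if (details) length(ext) else 0),
                             c(cols, if (details) ext))
    empty$model <- character(0)
    return(tibble::as_tibble(empty))
  }
  rows <- lapply(seq_along(models), function(i) {
    f <- models[[i]]
    stopifnot(inherits(f, "lcsm_fit"))
    fs <- if (f$converged) tryCatch(fit_statistics(f), error = function(e) NULL)
          else NULL
    row <- tibble::tibble(
      model = as.character(i),
      chisq = fs$chisq %||% NA_real_,
      npar = length(f$estimates),
      aic = fs$aic %||% NA_real_,
      bic = fs$bic %||% NA_real_,
      cfi = fs$cfi %||% NA_real_,
      rmsea = fs$rmsea %||% NA_real_,
      srmr = fs$srmr %||% NA_real_)
    if (details) {
      row$df <- fs$df %||% NA_integer_
      row$p.value <- fs$p.value %||% NA_real_
      row$loglik <- f$loglik
      row$n <- f$n_used
    }
    row
  })
  do.call(rbind, rows)
}

#' Extract parameter estimates from a fitted model
#'
#' One row per free parameter, in the canonical parameter-table order, with
#' the estimate, standard error, Wald z statistic (`estimate / std.error`)
#' and its two-sided p-value. With `printp = TRUE` the p-value is formatted
#' as text: `"< .001"` below 0.001, otherwise three decimals without the
#' leading zero (e.g. `".571"`). Missing standard errors give rows with
#' missing `std.error`, `statistic` and `p.value`.
#'
#' @param model An `lcsm_fit`.
#' @param printp Format p-values as text.
#' @return A tibble with columns `label`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
extract_param <- function(model, printp = FALSE) {
  stopifnot(inherits(model, "lcsm_fit"))
  est <- model$estimates
  se <- model$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(label = names(est),
                        estimate = unname(est),
                        std.error = unname(se),
                        statistic = unname(z),
                        p.value = unname(p))
  if (printp) out$p.value <- format_p(out$p.value)
  out
}

#' Serialise a fitted model to JSON
#'
#' Writes labels, estimates, standard errors, the fit-statistics block and
#' convergence diagnostics; full numeric precision is kept.
#'
#' @param fit An `lcsm_fit`.
#' @param path File to write (UTF-8).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lcsm_fit"))
  fs <- if (fit$converged) tryCatch(fit_statistics(fit),
                                    error = function(e) NULL) else NULL
  payload <- list(
    kind = if (inherits(fit$model$spec, "bi_spec")) "bivariate" else "univariate",
    timepoints = fit$model$timepoints,
    observed = fit$model$obs,
    estimator = fit$estimator,
    converged = fit$converged,
    loglik = fit$loglik,
    n_used = fit$n_used,
    n_excluded = fit$n_excluded,
    gradient_max = fit$gradient_max,
    parameters = extract_param(fit),
    fit = fs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted-model JSON back into tables
#'
#' Returns the parameter and fit tables written by [write_fit_json()]; used
#' by the command-line `extract` subcommand.
#'
#' @param path JSON file written by [write_fit_json()].
#' @return A list with `parameters` (tibble) and `fit` (list or `NULL`),
#'   plus the stored metadata.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$parameters <- tibble::as_tibble(x$parameters)
  x
}
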