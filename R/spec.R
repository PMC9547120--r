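#' Specify a univariate latent change score model
#'
#' A univariate LCSM decomposes each observed score into a latent true score
#' plus an occasion-specific unique score, and models the latent change
#' between adjacent occasions. The change equation can combine a constant
#' change factor (acting like a linear slope), a piecewise or linear change
#' factor, proportional change (regression of each change score on the
#' previous true score), and an autoregression of the change scores.
#'
#' At most one of `alpha_constant`, `alpha_piecewise` and `alpha_linear` may
#' be active; they are alternative parameterisations of the systematic change
#' component.
#'
#' @param alpha_constant Constant change factor: a latent factor with unit
#'   loadings on every change score, estimated mean and variance, and a
#'   covariance with the initial true score.
#' @param alpha_piecewise Piecewise constant change factor: one factor loads
#'   on the change scores up to `alpha_piecewise_num`, a second factor on the
#'   remaining change scores.
#' @param alpha_piecewise_num Change point (occasion index `k`) of the
#'   piecewise change factor; the first factor covers change scores
#'   `2..k`, the second `k+1..T`. Must satisfy `2 <= k <= T - 1`.
#' @param alpha_linear Linear change factor: fixed loadings `t - 1` on the
#'   change score at occasion `t`, yielding quadratic observed trajectories.
#' @param beta Proportional change: regression of each change score on the
#'   previous occasion's true score (equal over time).
#' @param phi Autoregression of change scores: regression of each change
#'   score on the previous change score (equal over time); requires at least
#'   three occasions.
#'
#' @return An object of class `uni_spec`.
#' @seealso [bi_spec()], [build_parameter_table()], [compile_lcsm()]
#' @examples
#' uni_spec(alpha_constant = TRUE, beta = TRUE, phi = TRUE)
#' @export
uni_spec <- function(alpha_constant = FALSE, alpha_piecewise = FALSE,
                     alpha_piecewise_num = NULL, alpha_linear = FALSE,
                     beta = FALSE, phi = FALSE) {
  for (nm in c("alpha_constant", "alpha_piecewise", "alpha_linear",
               "beta", "phi")) {
    if (!is_flag(get(nm))) stop_spec("`", nm, "` must be TRUE or FALSE")
  }
  alpha_flags <- c(alpha_constant = alpha_constant,
                   alpha_piecewise = alpha_piecewise,
                   alpha_linear = alpha_linear)
  if (sum(alpha_flags) > 1L) {
    stop_spec("conflicting change-factor options: ",
              paste(names(alpha_flags)[alpha_flags], collapse = ", "),
              " (at most one may be TRUE)")
  }
  if (alpha_piecewise) {
    if (is.null(alpha_piecewise_num) || !is.numeric(alpha_piecewise_num) ||
        length(alpha_piecewise_num) != 1L ||
        alpha_piecewise_num != round(alpha_piecewise_num)) {
      stop_spec("alpha_piecewise requires an integer `alpha_piecewise_num`")
    }
    alpha_piecewise_num <- as.integer(alpha_piecewise_num)
  } else {
    alpha_piecewise_num <- NULL
  }
  structure(list(alpha_constant = alpha_constant,
                 alpha_piecewise = alpha_piecewise,
                 alpha_piecewise_num = alpha_piecewise_num,
                 alpha_linear = alpha_linear,
                 beta = beta, phi = phi),
            class = "uni_spec")
}

#' Coerce a list of model options to a univariate specification
#'
#' Accepts the option-list idiom `list(alpha_constant = TRUE, beta = TRUE)`
#' where omitted options default to `FALSE`.
#'
#' @param x A `uni_spec`, or a named list of option flags.
#' @return A `uni_spec`.
#' @export
as_uni_spec <- function(x) {
  if (inherits(x, "uni_spec")) return(x)
  if (!is.list(x)) stop_spec("model options must be a list or a `uni_spec`")
  known <- c("alpha_constant", "alpha_piecewise", "alpha_piecewise_num",
             "alpha_linear", "beta", "phi")
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop_spec("unknown univariate model option(s): ",
              paste(bad, collapse = ", "),
              "; valid options are: ", paste(known, collapse = ", "))
  }
  do.call(uni_spec, x)
}

#' Specify coupling between two constructs
#'
#' Coupling options regress one construct's change scores on the other
#' construct's true scores (`delta_*`) or change scores (`xi_*`), either
#' concurrently (`*_con_*`, same occasion) or with a one-occasion lag
#' (`*_lag_*`). The suffix gives the direction: `_yx` means the change score
#' of construct y is determined by construct x, `_xy` the reverse.
#'
#' @param delta_con_xy,delta_con_yx,delta_lag_xy,delta_lag_yx True-score
#'   coupling flags (concurrent / lagged).
#' @param xi_con_xy,xi_con_yx,xi_lag_xy,xi_lag_yx Change-score coupling
#'   flags (concurrent / lagged).
#' @param coupling_piecewise Split every active coupling coefficient at a
#'   change point so it is equal within but free between phases.
#' @param coupling_piecewise_num Change point of the piecewise coupling;
#'   paths into change scores at occasions `<= k` get the pre-phase label,
#'   later ones the post-phase label.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(delta_con_xy = FALSE, delta_con_yx = FALSE,
                          delta_lag_xy = FALSE, delta_lag_yx = FALSE,
                          xi_con_xy = FALSE, xi_con_yx = FALSE,
                          xi_lag_xy = FALSE, xi_lag_yx = FALSE,
                          coupling_piecewise = FALSE,
                          coupling_piecewise_num = NULL) {
  flags <- c("delta_con_xy", "delta_con_yx", "delta_lag_xy", "delta_lag_yx",
             "xi_con_xy", "xi_con_yx", "xi_lag_xy", "xi_lag_yx",
             "coupling_piecewise")
  for (nm in flags) {
    if (!is_flag(get(nm))) stop_spec("`", nm, "` must be TRUE or FALSE")
  }
  if (coupling_piecewise) {
    if (is.null(coupling_piecewise_num) ||
        !is.numeric(coupling_piecewise_num) ||
        length(coupling_piecewise_num) != 1L ||
        coupling_piecewise_num != round(coupling_piecewise_num)) {
      stop_spec("coupling_piecewise requires an integer `coupling_piecewise_num`")
    }
    coupling_piecewise_num <- as.integer(coupling_piecewise_num)
  } else {
    coupling_piecewise_num <- NULL
  }
  structure(list(delta_con_xy = delta_con_xy, delta_con_yx = delta_con_yx,
                 delta_lag_xy = delta_lag_xy, delta_lag_yx = delta_lag_yx,
                 xi_con_xy = xi_con_xy, xi_con_yx = xi_con_yx,
                 xi_lag_xy = xi_lag_xy, xi_lag_yx = xi_lag_yx,
                 coupling_piecewise = coupling_piecewise,
                 coupling_piecewise_num = coupling_piecewise_num),
            class = "coupling_spec")
}

#' @rdname coupling_spec
#' @param x A `coupling_spec`, or a named list of coupling option flags.
#' @export
as_coupling_spec <- function(x) {
  if (inherits(x, "coupling_spec")) return(x)
  if (is.null(x)) return(coupling_spec())
  if (!is.list(x)) stop_spec("coupling options must be a list or a `coupling_spec`")
  known <- names(formals(coupling_spec))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop_spec("unknown coupling option(s): ", paste(bad, collapse = ", "),
              "; valid options are: ", paste(known, collapse = ", "))
  }
  do.call(coupling_spec, x)
}

#' Specify a bivariate latent change score model
#'
#' Combines two univariate specifications (constructs x and y) with a set of
#' cross-construct coupling options.
#'
#' @param model_x,model_y Univariate specifications (or option lists) for
#'   the two constructs.
#' @param coupling A [coupling_spec()] or option list; defaults to no
#'   coupling regressions (the bivariate base covariances are always free).
#' @return An object of class `bi_spec`.
#' @export
bi_spec <- function(model_x, model_y, coupling = coupling_spec()) {
  structure(list(model_x = as_uni_spec(model_x),
                 model_y = as_uni_spec(model_y),
                 coupling = as_coupling_spec(coupling)),
            class = "bi_spec")
}

active_coupling <- function(cpl) {
  opts <- c("delta_con_xy", "delta_con_yx", "delta_lag_xy", "delta_lag_yx",
            "xi_con_xy", "xi_con_yx", "xi_lag_xy", "xi_lag_yx")
  opts[vapply(opts, function(o) isTRUE(cpl[[o]]), logical(1))]
}

has_g2 <- function(spec) spec$alpha_constant || spec$alpha_piecewise || spec$alpha_linear
has_g3 <- function(spec) isTRUE(spec$alpha_piecewise)

# validate a spec against a number of occasions
validate_spec <- function(spec, timepoints) {
  timepoints <- assert_timepoints(timepoints)
  if (inherits(spec, "uni_spec")) {
    if (spec$alpha_piecewise) {
      k <- spec$alpha_piecewise_num
      if (k < 2L || k > timepoints - 1L) {
        stop_spec("alpha_piecewise_num must lie in 2..T-1 (got ", k,
                  " with T = ", timepoints, ")")
      }
    }
    if (spec$phi && timepoints < 3L) {
      stop_spec("phi requires at least 3 timepoints ",
                "(two successive change scores)")
    }
    return(invisible(timepoints))
  }
  if (inherits(spec, "bi_spec")) {
    validate_spec(spec$model_x, timepoints)
    validate_spec(spec$model_y, timepoints)
    cpl <- spec$coupling
    lagged <- intersect(active_coupling(cpl),
                        c("delta_lag_xy", "delta_lag_yx",
                          "xi_lag_xy", "xi_lag_yx"))
    if (length(lagged) && timepoints < 3L) {
      stop_spec("lagged coupling (", paste(lagged, collapse = ", "),
                ") requires at least 3 timepoints")
    }
    if (cpl$coupling_piecewise) {
      k <- cpl$coupling_piecewise_num
      if (k < 2L || k > timepoints - 1L) {
        stop_spec("coupling_piecewise_num must lie in 2..T-1 (got ", k,
                  " with T = ", timepoints, ")")
      }
      if (!length(active_coupling(cpl))) {
        stop_spec("coupling_piecewise set but no coupling option is active")
      }
    }
    return(invisible(timepoints))
  }
  stop_spec("`spec` must be a `uni_spec` or `bi_spec`")
}
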