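# RAM-style structural model: directed paths A, symmetric (co)variances S,
# mean/intercept vector m, and an observed-variable filter. Free cells carry
# a parameter label; cells sharing a label are constrained equal. Fixed
# structural paths (unit loadings, true-score autoregressions, change-score
# definitions) have value 1 and no label.

new_structural_model <- function(vars, obs) {
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  list(vars = vars, obs = obs,
       A = A, A_lab = matrix("", p, p, dimnames = dimnames(A)),
       S = A, S_lab = matrix("", p, p, dimnames = dimnames(A)),
       m = stats::setNames(numeric(p), vars),
       m_lab = stats::setNames(character(p), vars))
}

# path target <- source
set_path <- function(mod, target, source, value = 0, label = "") {
  mod$A[target, source] <- value
  mod$A_lab[target, source] <- label
  mod
}

set_cov <- function(mod, a, b, value = 0, label = "") {
  mod$S[a, b] <- value; mod$S[b, a] <- value
  mod$S_lab[a, b] <- label; mod$S_lab[b, a] <- label
  mod
}

set_mean <- function(mod, var, value = 0, label = "") {
  mod$m[var] <- value
  mod$m_lab[var] <- label
  mod
}

construct_names <- function(obs, factor_prefix) {
  list(obs = obs,
       true = paste0("l", obs),
       change = paste0("d", obs[-1]),
       f2 = paste0(factor_prefix, 2),
       f3 = paste0(factor_prefix, 3))
}

# piecewise phase of the change score at occasion t for change point k:
# phase 1 covers t in 2..k, phase 2 covers k+1..T
phase_of <- function(t, k) if (t <= k) 1L else 2L

add_construct <- function(mod, nm, spec, timepoints, side = c("x", "y")) {
  side <- match.arg(side)
  T <- timepoints
  lab <- function(base) base  # labels already side-specific via uni_labels
  L <- if (side == "x") {
    list(gamma = "gamma_lx1", s2l = "sigma2_lx1", s2u = "sigma2_ux",
         a2 = "alpha_g2", a3 = "alpha_g3", s2f2 = "sigma2_g2",
         s2f3 = "sigma2_g3", f2l = "sigma_g2lx1", f3l = "sigma_g3lx1",
         f2f3 = "sigma_g2g3", beta = "beta_x", phi = "phi_x")
  } else {
    list(gamma = "gamma_ly1", s2l = "sigma2_ly1", s2u = "sigma2_uy",
         a2 = "alpha_j2", a3 = "alpha_j3", s2f2 = "sigma2_j2",
         s2f3 = "sigma2_j3", f2l = "sigma_j2ly1", f3l = "sigma_j3ly1",
         f2f3 = "sigma_j2j3", beta = "beta_y", phi = "phi_y")
  }
  # measurement: observed[t] <- 1 * true[t], unique variance shared over t
  for (t in seq_len(T)) {
    mod <- set_path(mod, nm$obs[t], nm$true[t], 1)
    mod <- set_cov(mod, nm$obs[t], nm$obs[t], label = L$s2u)
    # observed intercepts fixed at 0 (already zero, no label)
  }
  # true-score autoregressions and change-score definitions (all fixed 1)
  for (t in 2:T) {
    mod <- set_path(mod, nm$true[t], nm$true[t - 1], 1)
    mod <- set_path(mod, nm$true[t], nm$change[t - 1], 1)
  }
  # initial true score: free mean and variance
  mod <- set_mean(mod, nm$true[1], label = L$gamma)
  mod <- set_cov(mod, nm$true[1], nm$true[1], label = L$s2l)
  # change factors
  if (has_g2(spec)) {
    mod <- set_mean(mod, nm$f2, label = L$a2)
    mod <- set_cov(mod, nm$f2, nm$f2, label = L$s2f2)
    mod <- set_cov(mod, nm$f2, nm$true[1], label = L$f2l)
    if (spec$alpha_constant) {
      for (t in 2:T) mod <- set_path(mod, nm$change[t - 1], nm$f2, 1)
    } else if (spec$alpha_linear) {
      for (t in 2:T) mod <- set_path(mod, nm$change[t - 1], nm$f2, t - 1)
    } else {
      k <- spec$alpha_piecewise_num
      for (t in 2:k) mod <- set_path(mod, nm$change[t - 1], nm$f2, 1)
    }
  }
  if (has_g3(spec)) {
    k <- spec$alpha_piecewise_num
    mod <- set_mean(mod, nm$f3, label = L$a3)
    mod <- set_cov(mod, nm$f3, nm$f3, label = L$s2f3)
    mod <- set_cov(mod, nm$f3, nm$true[1], label = L$f3l)
    mod <- set_cov(mod, nm$f3, nm$f2, label = L$f2f3)
    for (t in (k + 1):T) mod <- set_path(mod, nm$change[t - 1], nm$f3, 1)
  }
  # proportional change: dx[t] <- lx[t-1], t = 2..T
  if (spec$beta) {
    for (t in 2:T) {
      mod <- set_path(mod, nm$change[t - 1], nm$true[t - 1], label = L$beta)
    }
  }
  # autoregression of change scores: dx[t] <- dx[t-1], t = 3..T
  if (spec$phi) {
    for (t in 3:T) {
      mod <- set_path(mod, nm$change[t - 1], nm$change[t - 2], label = L$phi)
    }
  }
  mod
}

coupling_label_at <- function(base, t, cpl) {
  if (cpl$coupling_piecewise) {
    paste0(base, "_p", phase_of(t, cpl$coupling_piecewise_num))
  } else {
    base
  }
}

add_coupling <- function(mod, nmx, nmy, spec, timepoints) {
  T <- timepoints
  cpl <- spec$coupling
  # unique-score covariance at equal occasions, shared label
  for (t in seq_len(T)) {
    mod <- set_cov(mod, nmy$obs[t], nmx$obs[t], label = "sigma_su")
  }
  mod <- set_cov(mod, nmy$true[1], nmx$true[1], label = "sigma_ly1lx1")
  gx2 <- has_g2(spec$model_x); gx3 <- has_g3(spec$model_x)
  jy2 <- has_g2(spec$model_y); jy3 <- has_g3(spec$model_y)
  if (gx2) mod <- set_cov(mod, nmx$f2, nmy$true[1], label = "sigma_g2ly1")
  if (gx3) mod <- set_cov(mod, nmx$f3, nmy$true[1], label = "sigma_g3ly1")
  if (jy2) mod <- set_cov(mod, nmy$f2, nmx$true[1], label = "sigma_j2lx1")
  if (jy3) mod <- set_cov(mod, nmy$f3, nmx$true[1], label = "sigma_j3lx1")
  if (jy2 && gx2) mod <- set_cov(mod, nmy$f2, nmx$f2, label = "sigma_j2g2")
  if (jy2 && gx3) mod <- set_cov(mod, nmy$f2, nmx$f3, label = "sigma_j2g3")
  if (jy3 && gx2) mod <- set_cov(mod, nmy$f3, nmx$f2, label = "sigma_j3g2")
  # coupling regressions; concurrent paths run t = 2..T, lagged t = 3..T
  con_t <- 2:T
  lag_t <- if (T >= 3) 3:T else integer(0)
  paths <- list(
    delta_con_xy = list(t = con_t, tgt = function(t) nmx$change[t - 1], src = function(t) nmy$true[t]),
    delta_con_yx = list(t = con_t, tgt = function(t) nmy$change[t - 1], src = function(t) nmx$true[t]),
    delta_lag_xy = list(t = lag_t, tgt = function(t) nmx$change[t - 1], src = function(t) nmy$true[t - 1]),
    delta_lag_yx = list(t = lag_t, tgt = function(t) nmy$change[t - 1], src = function(t) nmx$true[t - 1]),
    xi_con_xy    = list(t = con_t, tgt = function(t) nmx$change[t - 1], src = function(t) nmy$change[t - 1]),
    xi_con_yx    = list(t = con_t, tgt = function(t) nmy$change[t - 1], src = function(t) nmx$change[t - 1]),
    xi_lag_xy    = list(t = lag_t, tgt = function(t) nmx$change[t - 1], src = function(t) nmy$change[t - 2]),
    xi_lag_yx    = list(t = lag_t, tgt = function(t) nmy$change[t - 1], src = function(t) nmx$change[t - 2])
  )
  for (opt in active_coupling(cpl)) {
    pp <- paths[[opt]]
    for (t in pp$t) {
      mod <- set_path(mod, pp$tgt(t), pp$src(t),
                      label = coupling_label_at(opt, t, cpl))
    }
  }
  mod
}

build_label_map <- function(mod) {
  cells <- list()
  collect <- function(labmat, mat_name) {
    idx <- which(labmat != "", arr.ind = TRUE)
    if (!length(idx)) return(NULL)
    data.frame(matrix = mat_name, row = rownames(labmat)[idx[, 1]],
               col = colnames(labmat)[idx[, 2]],
               label = labmat[idx], stringsAsFactors = FALSE)
  }
  a <- collect(mod$A_lab, "A")
  su <- mod$S_lab
  su[lower.tri(su)] <- ""  # upper triangle only; S is symmetric
  s <- collect(su, "S")
  midx <- which(mod$m_lab != "")
  mm <- if (length(midx)) {
    data.frame(matrix = "m", row = mod$vars[midx], col = "1",
               label = mod$m_lab[midx], stringsAsFactors = FALSE)
  } else NULL
  all_cells <- rbind(a, s, mm)
  split(all_cells[, c("matrix", "row", "col")], all_cells$label)
}

#' Compile a specification into structural model matrices
#'
#' Builds the RAM-style representation of an LCSM: a directed-path matrix
#' `A`, a symmetric covariance matrix `S`, a mean vector `m` — each with a
#' companion label matrix marking free cells — plus the observed-variable
#' filter and a map from parameter labels to the matrix cells sharing them
#' (the equality constraints over time).
#'
#' The layout realises the LCSM structure: each observed score loads 1 on
#' its latent true score with an occasion-invariant unique variance; each
#' true score is the previous true score plus a latent change score (both
#' paths fixed at 1); change factors point at the change scores with fixed
#' loadings (1 for constant and piecewise factors, `t - 1` for the linear
#' factor); proportional change, change-score autoregression and the
#' coupling options add labelled regressions among true and change scores.
#'
#' @inheritParams build_parameter_table
#' @param var_x,var_y Observed variable names (length `timepoints`);
#'   defaults `x1..xT` and `y1..yT`. Latent true and change scores take the
#'   prefixes `l` and `d`; change factors are named `g2`/`g3` (construct x)
#'   and `j2`/`j3` (construct y).
#' @return An object of class `lcsm_model`.
#' @examples
#' m <- compile_lcsm(uni_spec(alpha_constant = TRUE), timepoints = 5)
#' m$param_table$label
#' @export
compile_lcsm <- function(spec, timepoints,
                         var_x = paste0("x", seq_len(timepoints)),
                         var_y = paste0("y", seq_len(timepoints))) {
  if (is.list(spec) && !inherits(spec, c("uni_spec", "bi_spec"))) {
    spec <- as_uni_spec(spec)
  }
  timepoints <- assert_timepoints(timepoints)
  validate_spec(spec, timepoints)
  bivariate <- inherits(spec, "bi_spec")
  if (length(var_x) != timepoints) {
    stop_spec("`var_x` must have length ", timepoints)
  }
  nmx <- construct_names(var_x, "g")
  spec_x <- if (bivariate) spec$model_x else spec
  vars <- c(nmx$obs, nmx$true, nmx$change,
            if (has_g2(spec_x)) nmx$f2, if (has_g3(spec_x)) nmx$f3)
  obs <- nmx$obs
  nmy <- NULL
  if (bivariate) {
    if (length(var_y) != timepoints) {
      stop_spec("`var_y` must have length ", timepoints)
    }
    nmy <- construct_names(var_y, "j")
    vars <- c(vars, nmy$obs, nmy$true, nmy$change,
              if (has_g2(spec$model_y)) nmy$f2,
              if (has_g3(spec$model_y)) nmy$f3)
    obs <- c(obs, nmy$obs)
  }
  if (anyDuplicated(vars)) {
    stop_spec("variable names must be distinct (clashes: ",
              paste(unique(vars[duplicated(vars)]), collapse = ", "), ")")
  }
  mod <- new_structural_model(vars, obs)
  mod <- add_construct(mod, nmx, spec_x, timepoints, "x")
  if (bivariate) {
    mod <- add_construct(mod, nmy, spec$model_y, timepoints, "y")
    mod <- add_coupling(mod, nmx, nmy, spec, timepoints)
  }
  mod$label_map <- build_label_map(mod)
  mod$param_table <- build_parameter_table(spec, timepoints)
  stopifnot(setequal(names(mod$label_map), mod$param_table$label))
  mod$spec <- spec
  mod$timepoints <- timepoints
  mod$names_x <- nmx
  mod$names_y <- nmy
  class(mod) <- "lcsm_model"
  mod
}

#' @export
print.lcsm_model <- function(x, ...) {
  kind <- if (inherits(x$spec, "bi_spec")) "bivariate" else "univariate"
  cat(sprintf("%s latent change score model, %d timepoints\n",
              kind, x$timepoints))
  cat(sprintf("variables: %d observed, %d latent\n",
              length(x$obs), length(x$vars) - length(x$obs)))
  cat(sprintf("free parameters: %d (%s)\n", nrow(x$param_table),
              paste(x$param_table$label, collapse = ", ")))
  invisible(x)
}
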