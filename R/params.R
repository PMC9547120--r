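# Full inventory of estimable LCSM parameters: construct x, construct y,
# and the bivariate coupling block. Order here fixes the reporting order of
# parameter tables and extracted estimates.
label_inventory <- function() {
  inv <- rbind(
    # construct x
    c("gamma_lx1",   "gamma(lx1)",     "mean",       "Mean of latent true scores x (intercept)"),
    c("sigma2_lx1",  "sigma^2(lx1)",   "variance",   "Variance of latent true scores x"),
    c("sigma2_ux",   "sigma^2(ux)",    "variance",   "Variance of observed scores x (unique)"),
    c("alpha_g2",    "alpha(g2)",      "mean",       "Mean of change factor (g2)"),
    c("alpha_g3",    "alpha(g3)",      "mean",       "Mean of change factor (g3)"),
    c("sigma2_g2",   "sigma^2(g2)",    "variance",   "Variance of change factor (g2)"),
    c("sigma2_g3",   "sigma^2(g3)",    "variance",   "Variance of change factor (g3)"),
    c("sigma_g2lx1", "sigma(g2,lx1)",  "covariance", "Covariance: change factor (g2) with initial true score x (lx1)"),
    c("sigma_g3lx1", "sigma(g3,lx1)",  "covariance", "Covariance: change factor (g3) with initial true score x (lx1)"),
    c("sigma_g2g3",  "sigma(g2,g3)",   "covariance", "Covariance: change factors within construct x"),
    c("beta_x",      "beta(x)",        "regression", "Proportional change factor of construct x"),
    c("phi_x",       "phi(x)",         "regression", "Autoregression of change scores x"),
    # construct y
    c("gamma_ly1",   "gamma(ly1)",     "mean",       "Mean of latent true scores y (intercept)"),
    c("sigma2_ly1",  "sigma^2(ly1)",   "variance",   "Variance of latent true scores y"),
    c("sigma2_uy",   "sigma^2(uy)",    "variance",   "Variance of observed scores y (unique)"),
    c("alpha_j2",    "alpha(j2)",      "mean",       "Mean of change factor (j2)"),
    c("alpha_j3",    "alpha(j3)",      "mean",       "Mean of change factor (j3)"),
    c("sigma2_j2",   "sigma^2(j2)",    "variance",   "Variance of change factor (j2)"),
    c("sigma2_j3",   "sigma^2(j3)",    "variance",   "Variance of change factor (j3)"),
    c("sigma_j2ly1", "sigma(j2,ly1)",  "covariance", "Covariance: change factor (j2) with initial true score y (ly1)"),
    c("sigma_j3ly1", "sigma(j3,ly1)",  "covariance", "Covariance: change factor (j3) with initial true score y (ly1)"),
    c("sigma_j2j3",  "sigma(j2,j3)",   "covariance", "Covariance: change factors within construct y"),
    c("beta_y",      "beta(y)",        "regression", "Proportional change factor of construct y"),
    c("phi_y",       "phi(y)",         "regression", "Autoregression of change scores y"),
    # coupling
    c("sigma_su",    "sigma(su)",      "covariance", "Covariance: unique scores x with y (same occasion)"),
    c("sigma_ly1lx1","sigma(ly1,lx1)", "covariance", "Covariance: initial true scores x with y"),
    c("sigma_g2ly1", "sigma(g2,ly1)",  "covariance", "Covariance: change factor x (g2) with initial true score y (ly1)"),
    c("sigma_g3ly1", "sigma(g3,ly1)",  "covariance", "Covariance: change factor x (g3) with initial true score y (ly1)"),
    c("sigma_j2lx1", "sigma(j2,lx1)",  "covariance", "Covariance: change factor y (j2) with initial true score x (lx1)"),
    c("sigma_j3lx1", "sigma(j3,lx1)",  "covariance", "Covariance: change factor y (j3) with initial true score x (lx1)"),
    c("sigma_j2g2",  "sigma(j2,g2)",   "covariance", "Covariance: change factors y (j2) with x (g2)"),
    c("sigma_j2g3",  "sigma(j2,g3)",   "covariance", "Covariance: change factors y (j2) with x (g3)"),
    c("sigma_j3g2",  "sigma(j3,g2)",   "covariance", "Covariance: change factors y (j3) with x (g2)"),
    c("delta_con_xy","delta(con,xy)",  "regression", "Change score x (t) determined by true score y (t)"),
    c("delta_con_yx","delta(con,yx)",  "regression", "Change score y (t) determined by true score x (t)"),
    c("delta_lag_xy","delta(lag,xy)",  "regression", "Change score x (t) determined by true score y (t-1)"),
    c("delta_lag_yx","delta(lag,yx)",  "regression", "Change score y (t) determined by true score x (t-1)"),
    c("xi_con_xy",   "xi(con,xy)",     "regression", "Change score x (t) determined by change score y (t)"),
    c("xi_con_yx",   "xi(con,yx)",     "regression", "Change score y (t) determined by change score x (t)"),
    c("xi_lag_xy",   "xi(lag,xy)",     "regression", "Change score x (t) determined by change score y (t-1)"),
    c("xi_lag_yx",   "xi(lag,yx)",     "regression", "Change score y (t) determined by change score x (t-1)")
  )
  data.frame(label = inv[, 1], symbol = inv[, 2], role = inv[, 3],
             description = inv[, 4], stringsAsFactors = FALSE)
}

#' Inventory of LCSM parameter labels
#'
#' Returns the complete catalogue of parameter labels available across
#' univariate and bivariate specifications, with the symbol, role
#' (mean, variance, covariance or regression) and a description.
#'
#' @return A tibble with columns `label`, `symbol`, `role`, `description`.
#' @export
lcsm_parameters <- function() {
  tibble::as_tibble(label_inventory())
}

uni_labels <- function(spec, construct = c("x", "y")) {
  construct <- match.arg(construct)
  if (construct == "x") {
    base <- c("gamma_lx1", "sigma2_lx1", "sigma2_ux")
    g2 <- c("alpha_g2", "sigma2_g2", "sigma_g2lx1")
    g3 <- c("alpha_g3", "sigma2_g3", "sigma_g3lx1", "sigma_g2g3")
    bp <- c("beta_x", "phi_x")
  } else {
    base <- c("gamma_ly1", "sigma2_ly1", "sigma2_uy")
    g2 <- c("alpha_j2", "sigma2_j2", "sigma_j2ly1")
    g3 <- c("alpha_j3", "sigma2_j3", "sigma_j3ly1", "sigma_j2j3")
    bp <- c("beta_y", "phi_y")
  }
  labs <- base
  if (has_g2(spec)) labs <- c(labs, g2)
  if (has_g3(spec)) labs <- c(labs, g3)
  if (spec$beta) labs <- c(labs, bp[1])
  if (spec$phi) labs <- c(labs, bp[2])
  labs
}

coupling_labels <- function(spec) {
  cpl <- spec$coupling
  labs <- c("sigma_su", "sigma_ly1lx1")
  gx2 <- has_g2(spec$model_x); gx3 <- has_g3(spec$model_x)
  jy2 <- has_g2(spec$model_y); jy3 <- has_g3(spec$model_y)
  if (gx2) labs <- c(labs, "sigma_g2ly1")
  if (gx3) labs <- c(labs, "sigma_g3ly1")
  if (jy2) labs <- c(labs, "sigma_j2lx1")
  if (jy3) labs <- c(labs, "sigma_j3lx1")
  if (jy2 && gx2) labs <- c(labs, "sigma_j2g2")
  if (jy2 && gx3) labs <- c(labs, "sigma_j2g3")
  if (jy3 && gx2) labs <- c(labs, "sigma_j3g2")
  coup <- active_coupling(cpl)
  if (cpl$coupling_piecewise && length(coup)) {
    coup <- as.vector(rbind(paste0(coup, "_p1"), paste0(coup, "_p2")))
  }
  c(labs, coup)
}

inventory_row <- function(label) {
  inv <- label_inventory()
  parent <- sub("_p[12]$", "", label)
  i <- match(parent, inv$label)
  out <- inv[i, , drop = FALSE]
  out$label <- label
  if (label != parent) {
    phase <- if (grepl("_p1$", label)) "pre" else "post"
    out$symbol <- paste0(out$symbol, ",", phase)
    out$description <- paste0(out$description, " [", phase, " change point]")
  }
  out
}

#' Free parameters implied by a model specification
#'
#' Enumerates the free parameters that a univariate or bivariate LCSM
#' specification implies: the base parameters (initial true-score mean and
#' variance, unique variance), the parameters each active model option adds,
#' and — for bivariate specifications — the cross-construct covariances and
#' one regression coefficient per active coupling option. Equality
#' constraints over time mean the set does not depend on the number of
#' occasions (beyond the minimum the options require).
#'
#' @param spec A [uni_spec()] or [bi_spec()] (or option list coercible to a
#'   `uni_spec`).
#' @param timepoints Number of repeated measures per construct.
#' @return A tibble with one row per free parameter: `label`, `symbol`,
#'   `role`, `description`, `start` (generic default start value; data-driven
#'   starts are chosen at fitting time).
#' @examples
#' build_parameter_table(
#'   uni_spec(alpha_constant = TRUE, beta = TRUE, phi = TRUE), timepoints = 5)
#' @export
build_parameter_table <- function(spec, timepoints) {
  if (is.list(spec) && !inherits(spec, c("uni_spec", "bi_spec", "coupling_spec"))) {
    spec <- as_uni_spec(spec)
  }
  validate_spec(spec, timepoints)
  labs <- if (inherits(spec, "uni_spec")) {
    uni_labels(spec, "x")
  } else {
    c(uni_labels(spec$model_x, "x"), uni_labels(spec$model_y, "y"),
      coupling_labels(spec))
  }
  tab <- do.call(rbind, lapply(labs, inventory_row))
  tab$start <- ifelse(tab$role == "variance", 1,
               ifelse(tab$role == "mean", 0, 0))
  rownames(tab) <- NULL
  tibble::as_tibble(tab)
}
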