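# Render a compiled model as human-readable lavaan-dialect syntax.
# The text is organised in commented sections; every free parameter appears
# through its label, so equality constraints over time are explicit and the
# set of distinct labels in the text equals the parameter table.

fmt_num <- function(x) {
  if (x == round(x)) format(as.integer(x)) else format(x)
}

# coefficient prefix for a cell: label if free, fixed value otherwise
coef_of <- function(value, label) {
  if (nzchar(label)) label else fmt_num(value)
}

render_construct <- function(mod, nm, spec, cname) {
  T <- mod$timepoints
  out <- character(0)
  add <- function(...) out <<- c(out, ...)
  sec <- function(txt) add(paste0("# ", txt))

  sec(sprintf("Construct %s: latent true scores", cname))
  for (t in seq_len(T)) {
    add(sprintf("%s =~ 1 * %s", nm$true[t], nm$obs[t]))
  }
  sec(sprintf("Construct %s: mean of latent true scores", cname))
  for (t in seq_len(T)) {
    add(sprintf("%s ~ %s * 1", nm$true[t],
                coef_of(mod$m[nm$true[t]], mod$m_lab[nm$true[t]])))
  }
  sec(sprintf("Construct %s: variance of latent true scores", cname))
  for (t in seq_len(T)) {
    v <- nm$true[t]
    add(sprintf("%s ~~ %s * %s", v, coef_of(mod$S[v, v], mod$S_lab[v, v]), v))
  }
  sec(sprintf("Construct %s: intercept of observed scores", cname))
  for (t in seq_len(T)) add(sprintf("%s ~ 0 * 1", nm$obs[t]))
  sec(sprintf("Construct %s: variance of observed scores", cname))
  for (t in seq_len(T)) {
    v <- nm$obs[t]
    add(sprintf("%s ~~ %s * %s", v, coef_of(mod$S[v, v], mod$S_lab[v, v]), v))
  }
  sec(sprintf("Construct %s: autoregressions of latent true scores", cname))
  for (t in 2:T) add(sprintf("%s ~ 1 * %s", nm$true[t], nm$true[t - 1]))
  sec(sprintf("Construct %s: latent change scores", cname))
  for (t in 2:T) add(sprintf("%s =~ 1 * %s", nm$change[t - 1], nm$true[t]))
  sec(sprintf("Construct %s: latent change score means", cname))
  for (t in 2:T) add(sprintf("%s ~ 0 * 1", nm$change[t - 1]))
  sec(sprintf("Construct %s: latent change score variances", cname))
  for (t in 2:T) add(sprintf("%s ~~ 0 * %s", nm$change[t - 1], nm$change[t - 1]))

  for (f in c("f2", "f3")) {
    fv <- nm[[f]]
    if (!fv %in% mod$vars) next
    loads <- which(mod$A[, fv] != 0)
    if (!length(loads)) next
    sec(sprintf("Construct %s: change factor %s", cname, fv))
    add(paste0(fv, " =~ ",
               paste(sprintf("%s * %s", vapply(loads, function(i)
                 fmt_num(mod$A[i, fv]), character(1)),
                 mod$vars[loads]), collapse = " + ")))
    add(sprintf("%s ~ %s * 1", fv, coef_of(mod$m[fv], mod$m_lab[fv])))
    add(sprintf("%s ~~ %s * %s", fv,
                coef_of(mod$S[fv, fv], mod$S_lab[fv, fv]), fv))
    if (nzchar(mod$S_lab[fv, nm$true[1]])) {
      add(sprintf("%s ~~ %s * %s", fv, mod$S_lab[fv, nm$true[1]], nm$true[1]))
    }
    if (f == "f3" && nzchar(mod$S_lab[nm$f3, nm$f2])) {
      add(sprintf("%s ~~ %s * %s", nm$f3, mod$S_lab[nm$f3, nm$f2], nm$f2))
    }
  }
  if (spec$beta) {
    sec(sprintf("Construct %s: proportional change", cname))
    for (t in 2:T) {
      add(sprintf("%s ~ %s * %s", nm$change[t - 1],
                  mod$A_lab[nm$change[t - 1], nm$true[t - 1]], nm$true[t - 1]))
    }
  }
  if (spec$phi) {
    sec(sprintf("Construct %s: autoregression of change scores", cname))
    for (t in 3:T) {
      add(sprintf("%s ~ %s * %s", nm$change[t - 1],
                  mod$A_lab[nm$change[t - 1], nm$change[t - 2]],
                  nm$change[t - 2]))
    }
  }
  out
}

render_coupling <- function(mod) {
  spec <- mod$spec
  nmx <- mod$names_x; nmy <- mod$names_y
  T <- mod$timepoints
  out <- character(0)
  add <- function(...) out <<- c(out, ...)
  add("# Coupling: covariance of unique scores (same occasion)")
  for (t in seq_len(T)) {
    add(sprintf("%s ~~ %s * %s", nmy$obs[t],
                mod$S_lab[nmy$obs[t], nmx$obs[t]], nmx$obs[t]))
  }
  add("# Coupling: covariances of initial true scores and change factors")
  pairs <- list(c(nmy$true[1], nmx$true[1]),
                c(nmx$f2, nmy$true[1]), c(nmx$f3, nmy$true[1]),
                c(nmy$f2, nmx$true[1]), c(nmy$f3, nmx$true[1]),
                c(nmy$f2, nmx$f2), c(nmy$f2, nmx$f3), c(nmy$f3, nmx$f2))
  for (pr in pairs) {
    if (!all(pr %in% mod$vars)) next
    if (nzchar(mod$S_lab[pr[1], pr[2]])) {
      add(sprintf("%s ~~ %s * %s", pr[1], mod$S_lab[pr[1], pr[2]], pr[2]))
    }
  }
  reg <- character(0)
  for (tgt in c(nmx$change, nmy$change)) {
    srcs <- which(nzchar(mod$A_lab[tgt, ]) &
                  grepl("^(delta|xi)_", mod$A_lab[tgt, ]))
    for (s in srcs) {
      reg <- c(reg, sprintf("%s ~ %s * %s", tgt, mod$A_lab[tgt, s],
                            mod$vars[s]))
    }
  }
  if (length(reg)) {
    add("# Coupling: regressions on the other construct", reg)
  }
  out
}

#' Render lavaan-dialect model syntax
#'
#' Emits the compiled model as lavaan-dialect text (`=~`, `~`, `~~`, `~ 1`
#' statements), with one section comment per block and every equality
#' constraint expressed through a shared label. The output is deterministic:
#' rendering the same model twice gives byte-identical text.
#'
#' @param model An `lcsm_model` from [compile_lcsm()].
#' @return A single character scalar (LF line endings).
#' @examples
#' cat(render_syntax(compile_lcsm(uni_spec(alpha_constant = TRUE), 5)))
#' @export
render_syntax <- function(model) {
  stopifnot(inherits(model, "lcsm_model"))
  bivariate <- inherits(model$spec, "bi_spec")
  spec_x <- if (bivariate) model$spec$model_x else model$spec
  lines <- render_construct(model, model$names_x, spec_x, "x")
  if (bivariate) {
    lines <- c(lines,
               render_construct(model, model$names_y, model$spec$model_y, "y"),
               render_coupling(model))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Generate univariate LCSM syntax directly from options
#'
#' Convenience wrapper: builds the specification, compiles it, and returns
#' the rendered syntax.
#'
#' @param timepoints Number of repeated measures.
#' @param model Option list or [uni_spec()].
#' @param var Observed variable names (default `x1..xT`).
#' @return Character scalar of model syntax.
#' @export
specify_uni_lcsm <- function(timepoints, model,
                             var = paste0("x", seq_len(timepoints))) {
  render_syntax(compile_lcsm(as_uni_spec(model), timepoints, var_x = var))
}

#' Generate bivariate LCSM syntax directly from options
#'
#' @inheritParams specify_uni_lcsm
#' @param model_x,model_y Option lists or [uni_spec()] objects.
#' @param coupling Option list or [coupling_spec()].
#' @param var_x,var_y Observed variable names for the two constructs.
#' @return Character scalar of model syntax.
#' @export
specify_bi_lcsm <- function(timepoints, model_x, model_y,
                            coupling = list(),
                            var_x = paste0("x", seq_len(timepoints)),
                            var_y = paste0("y", seq_len(timepoints))) {
  spec <- bi_spec(model_x, model_y, coupling)
  render_syntax(compile_lcsm(spec, timepoints, var_x = var_x, var_y = var_y))
}

#' Distinct parameter labels appearing in rendered syntax
#'
#' Parses rendered model syntax and returns the distinct free-parameter
#' labels it uses (coefficients that are names rather than numbers).
#'
#' @param syntax Character scalar as returned by [render_syntax()].
#' @return Character vector of labels in order of first appearance.
#' @export
syntax_labels <- function(syntax) {
  lines <- strsplit(syntax, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hits <- regmatches(lines,
                     gregexpr("[A-Za-z][A-Za-z0-9_]*(?=\\s*\\*)", lines,
                              perl = TRUE))
  unique(unlist(hits))
}
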