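# Simplified path-diagram layout: nodes layered by role (observed squares,
# latent circles), positioned left-to-right by occasion; edges are exactly
# the nonzero pattern of A plus the free off-diagonal pattern of S over the
# shown nodes. The layout is the tested artifact; the ggplot rendering is a
# thin layer over it.

construct_layers <- function(mod, nm, spec, base_y, direction) {
  T <- mod$timepoints
  layer_y <- function(k) base_y + direction * k
  nodes <- rbind(
    data.frame(name = nm$obs, shape = "square", layer = "observed",
               x = seq_len(T), y = layer_y(0)),
    data.frame(name = nm$true, shape = "circle", layer = "true",
               x = seq_len(T), y = layer_y(1)),
    data.frame(name = nm$change, shape = "circle", layer = "change",
               x = 2:T, y = layer_y(2))
  )
  fac <- character(0)
  if (has_g2(spec)) fac <- nm$f2
  if (has_g3(spec)) fac <- c(fac, nm$f3)
  if (length(fac)) {
    xs <- seq(1, T, length.out = length(fac) + 2)[-c(1, length(fac) + 2)]
    nodes <- rbind(nodes, data.frame(name = fac, shape = "circle",
                                     layer = "factor", x = xs,
                                     y = layer_y(3)))
  }
  nodes
}

#' Diagram layout of a compiled LCSM
#'
#' Builds a layered node/edge description of the model: observed scores as
#' squares on the outer layer, latent true scores, latent change scores and
#' change factors as circles on successive layers, positioned left-to-right
#' by occasion (construct y, when present, is mirrored above construct x).
#' Edges are the directed paths of `A` and the free off-diagonal covariances
#' of `S`; equality-constrained paths share one label. Unique-score
#' (residual) nodes are hidden unless requested.
#'
#' @param model An `lcsm_model`.
#' @param show_residuals Add one unique-score node (and its loading edge) per
#'   observed variable.
#' @return An object of class `lcsm_layout`: list with data frames `nodes`
#'   (`name`, `shape`, `layer`, `x`, `y`) and `edges` (`from`, `to`, `kind`,
#'   `label`).
#' @export
diagram_layout <- function(model, show_residuals = FALSE) {
  stopifnot(inherits(model, "lcsm_model"))
  bivariate <- inherits(model$spec, "bi_spec")
  spec_x <- if (bivariate) model$spec$model_x else model$spec
  nodes <- construct_layers(model, model$names_x, spec_x, 0, 1)
  if (bivariate) {
    nodes <- rbind(nodes,
                   construct_layers(model, model$names_y,
                                    model$spec$model_y, 7, -1))
  }
  if (show_residuals) {
    obs_nodes <- nodes[nodes$layer == "observed", , drop = FALSE]
    res <- data.frame(name = paste0("u_", obs_nodes$name), shape = "circle",
                      layer = "residual", x = obs_nodes$x,
                      y = obs_nodes$y + ifelse(obs_nodes$y <= 3, -1, 1))
    nodes <- rbind(nodes, res)
  }
  shown <- nodes$name
  lab_or_1 <- function(lab) if (nzchar(lab)) lab else "1"
  A_idx <- which(model$A != 0 | model$A_lab != "", arr.ind = TRUE)
  edges <- data.frame(from = character(0), to = character(0),
                      kind = character(0), label = character(0))
  if (nrow(A_idx)) {
    keep <- model$vars[A_idx[, 1]] %in% shown &
            model$vars[A_idx[, 2]] %in% shown
    A_idx <- A_idx[keep, , drop = FALSE]
    edges <- data.frame(
      from = model$vars[A_idx[, 2]],
      to = model$vars[A_idx[, 1]],
      kind = "directed",
      label = vapply(seq_len(nrow(A_idx)), function(i) {
        lab <- model$A_lab[A_idx[i, 1], A_idx[i, 2]]
        if (nzchar(lab)) lab else fmt_num(model$A[A_idx[i, 1], A_idx[i, 2]])
      }, character(1)))
  }
  # free off-diagonal covariances (upper triangle once)
  Su <- model$S_lab
  Su[lower.tri(Su, diag = TRUE)] <- ""
  S_idx <- which(Su != "", arr.ind = TRUE)
  if (nrow(S_idx)) {
    keep <- model$vars[S_idx[, 1]] %in% shown &
            model$vars[S_idx[, 2]] %in% shown
    S_idx <- S_idx[keep, , drop = FALSE]
    if (nrow(S_idx)) {
      edges <- rbind(edges, data.frame(
        from = model$vars[S_idx[, 1]],
        to = model$vars[S_idx[, 2]],
        kind = "bidirectional",
        label = Su[S_idx]))
    }
  }
  if (show_residuals) {
    obs_nodes <- nodes[nodes$layer == "observed", , drop = FALSE]
    edges <- rbind(edges, data.frame(from = paste0("u_", obs_nodes$name),
                                     to = obs_nodes$name,
                                     kind = "directed", label = "1"))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 show_residuals = show_residuals),
            class = "lcsm_layout")
}

#' @export
print.lcsm_layout <- function(x, ...) {
  cat(sprintf("LCSM diagram layout: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Plot a simplified LCSM path diagram
#'
#' Renders the [diagram_layout()] with ggplot2: squares for observed scores,
#' circles for latent variables, single-headed arrows for regressions and
#' dashed double-headed connectors for covariances, with one printed label
#' per equality-constrained parameter.
#'
#' @inheritParams diagram_layout
#' @param label_edges Print edge labels (free-parameter labels and fixed
#'   values).
#' @return A `ggplot` object with the layout attached as attribute
#'   `"layout"`.
#' @export
plot_lcsm <- function(model, show_residuals = FALSE, label_edges = TRUE) {
  lay <- diagram_layout(model, show_residuals = show_residuals)
  nodes <- lay$nodes
  edges <- lay$edges
  pos <- nodes[, c("name", "x", "y")]
  ed <- merge(edges, stats::setNames(pos, c("from", "x0", "y0")), by = "from")
  ed <- merge(ed, stats::setNames(pos, c("to", "x1", "y1")), by = "to")
  # shorten segments a little so arrows stop at the node border
  shrink <- 0.12
  dx <- ed$x1 - ed$x0; dy <- ed$y1 - ed$y0
  len <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  ed$x0s <- ed$x0 + shrink * dx / len; ed$y0s <- ed$y0 + shrink * dy / len
  ed$x1s <- ed$x1 - shrink * dx / len; ed$y1s <- ed$y1 - shrink * dy / len
  dir <- ed[ed$kind == "directed", , drop = FALSE]
  cov <- ed[ed$kind == "bidirectional", , drop = FALSE]
  p <- ggplot2::ggplot()
  if (nrow(cov)) {
    p <- p + ggplot2::geom_curve(
      data = cov,
      ggplot2::aes(x = .data$x0s, y = .data$y0s,
                   xend = .data$x1s, yend = .data$y1s),
      curvature = 0.25, linetype = "dashed", colour = "grey40",
      arrow = grid::arrow(ends = "both", length = grid::unit(5, "pt")))
  }
  if (nrow(dir)) {
    p <- p + ggplot2::geom_segment(
      data = dir,
      ggplot2::aes(x = .data$x0s, y = .data$y0s,
                   xend = .data$x1s, yend = .data$y1s),
      arrow = grid::arrow(length = grid::unit(5, "pt")), colour = "grey25")
  }
  p <- p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   shape = .data$shape, fill = .data$layer),
      size = 10, colour = "black") +
    ggplot2::scale_shape_manual(values = c(square = 22, circle = 21)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name), size = 2.6)
  if (label_edges && nrow(ed)) {
    labelled <- ed[nzchar(ed$label) & ed$label != "1", , drop = FALSE]
    if (nrow(labelled)) {
      p <- p + ggplot2::geom_text(
        data = labelled,
        ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                     y = (.data$y0 + .data$y1) / 2, label = .data$label),
        size = 2.2, colour = "grey10", vjust = -0.4)
    }
  }
  p <- p + ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
  attr(p, "layout") <- lay
  p
}

#' Export a diagram layout as JSON
#'
#' @param layout An `lcsm_layout`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "lcsm_layout"))
  jsonlite::write_json(list(nodes = layout$nodes, edges = layout$edges),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
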