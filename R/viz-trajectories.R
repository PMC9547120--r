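# wide -> long reshape for one or more constructs; the long table is the
# tested artifact, the ggplot is a thin layer over it

#' Reshape wide longitudinal data to long format
#'
#' @param data Wide data frame.
#' @param vars Character vector of repeated-measure columns (one construct)
#'   or a named list of such vectors (one element per construct).
#' @param id Name of the identifier column.
#' @return A tibble with columns `id`, `construct`, `time` (occasion index),
#'   `variable`, `value`. Pivoting back reproduces the wide input.
#' @export
wide_to_long <- function(data, vars, id = "id") {
  if (!id %in% names(data)) stop_data("no `", id, "` column in data")
  if (!is.list(vars)) {
    prefix <- unique(sub("[0-9]+$", "", vars))
    nm <- if (length(prefix) == 1L && nzchar(prefix)) prefix else "construct1"
    vars <- stats::setNames(list(vars), nm)
  }
  blocks <- lapply(names(vars), function(cn) {
    vv <- vars[[cn]]
    missing_cols <- setdiff(vv, names(data))
    if (length(missing_cols)) {
      stop_data("variable(s) not in data: ", paste(missing_cols, collapse = ", "))
    }
    tibble::tibble(
      id = rep(data[[id]], times = length(vv)),
      construct = cn,
      time = rep(seq_along(vv), each = nrow(data)),
      variable = rep(vv, each = nrow(data)),
      value = unlist(lapply(vv, function(v) data[[v]]), use.names = FALSE))
  })
  do.call(rbind, blocks)
}

#' Plot individual longitudinal trajectories
#'
#' Reshapes the data to long format, optionally draws a seed-deterministic
#' random subset of individuals, and plots one line per individual per
#' construct, panelled by construct. By default a missing occasion breaks the
#' line; with `connect_missing = TRUE` the observed points of an individual
#' are joined across gaps.
#'
#' @param data Wide data frame.
#' @param var Repeated-measure columns: character vector or named list per
#'   construct.
#' @param id Identifier column name.
#' @param random_sample_frac Fraction of individuals to draw, in `(0, 1]`.
#' @param seed Optional seed for the individual subsample.
#' @param connect_missing Join observed points across missing occasions.
#' @return A `ggplot` object; its `$data` is the underlying long table.
#' @export
plot_trajectories <- function(data, var, id = "id", random_sample_frac = 1,
                              seed = NULL, connect_missing = FALSE) {
  if (random_sample_frac <= 0 || random_sample_frac > 1) {
    stop_data("`random_sample_frac` must be in (0, 1]")
  }
  long <- wide_to_long(data, var, id = id)
  ids <- unique(long$id)
  if (random_sample_frac < 1) {
    if (!is.null(seed)) set.seed(seed)
    ids <- sample(ids, size = round(length(ids) * random_sample_frac))
    long <- long[long$id %in% ids, , drop = FALSE]
  }
  if (!nrow(long) || all(is.na(long$value))) {
    stop_data("no observations left to plot after sampling")
  }
  if (connect_missing) {
    plotted <- long[!is.na(long$value), , drop = FALSE]
    plotted$series <- plotted$id
  } else {
    # split each individual's series into segments at missing occasions so
    # lines break rather than bridging the gap
    ord <- order(long$construct, long$id, long$time)
    long <- long[ord, , drop = FALSE]
    gap <- stats::ave(is.na(long$value), long$construct, long$id,
                      FUN = cumsum)
    long$series <- interaction(long$construct, long$id, gap, drop = TRUE)
    plotted <- long[!is.na(long$value), , drop = FALSE]
  }
  ggplot2::ggplot(plotted,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               group = .data$series)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~construct, scales = "free_y") +
    ggplot2::labs(x = "timepoint", y = "value") +
    ggplot2::theme_minimal()
}
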