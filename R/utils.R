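`%||%` <- function(a, b) if (is.null(a)) b else a

stop_spec <- function(...) {
  stop(structure(class = c("lcsm_spec_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("lcsm_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
assert_timepoints <- function(timepoints) {
  if (!is.numeric(timepoints) || length(timepoints) != 1L ||
      is.na(timepoints) || timepoints != round(timepoints) || timepoints < 2) {
    stop_spec("`timepoints` must be a single integer >= 2")
  }
  as.integer(timepoints)
}
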