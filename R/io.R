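#' Read wide-format longitudinal data from CSV
#'
#' Expects a header row with an `id` column and one column per
#' occasion-variable; empty cells are read as missing.
#'
#' @param path CSV file.
#' @param id Name of the identifier column (must be present).
#' @return A tibble.
#' @export
read_lcsm_data <- function(path, id = "id") {
  if (!file.exists(path)) stop_data("data file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, na.strings = c("", "NA"),
                    check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_data("malformed CSV (", path, "): ",
                                  conditionMessage(e)))
  if (!id %in% names(df)) {
    stop_data("CSV ", path, " lacks required `", id, "` column (found: ",
              paste(utils::head(names(df), 10), collapse = ", "), ")")
  }
  bad <- names(df)[vapply(df, function(col)
    !(is.numeric(col) || all(is.na(col))), logical(1))]
  bad <- setdiff(bad, id)
  if (length(bad)) {
    stop_data("non-numeric measurement column(s) in ", path, ": ",
              paste(bad, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write wide-format data to CSV
#'
#' Missing values are written as empty cells.
#'
#' @param data A data frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_lcsm_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
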