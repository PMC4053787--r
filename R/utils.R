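#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the fixture.
#' @keywords internal
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "substrain")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

# TSV fixtures carry '#'-prefixed header comments declaring their conventions.
read_fixture_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

# Consistent error for a bad fixture row: names the file and the 1-based data row.
fixture_row_error <- function(file, row, why) {
  stop(sprintf("corrupt fixture '%s', row %d: %s", file, row, why), call. = FALSE)
}
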