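#' Write a result table as CSV, losslessly
#'
#' Doubles are serialized with 17 significant digits so that
#' [read_table()] reproduces them bit-exact; all other columns round-trip at
#' their natural precision. Tables with coordinate-like numeric columns are
#' rejected if they contain non-finite values (`NA` is allowed — it encodes a
#' missing observation, e.g. a gap frame).
#'
#' @param records a data.frame.
#' @param path output CSV path (comma-separated, header row, UTF-8).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  out <- records
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      if (any(is.infinite(col) | is.nan(col))) {
        stop("column '", names(out)[j], "' contains non-finite values")
      }
      chr <- sprintf("%.17g", col)
      chr[is.na(col)] <- NA_character_
      out[[j]] <- chr
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' @param path CSV file.
#' @return a data.frame with types restored by `type.convert`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
}
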