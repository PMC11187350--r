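#' Write result tables to disk
#'
#' Writes each table of a named list to `out_dir` as TSV (default) or
#' JSON. Output is deterministic: fixed column order as supplied, rows as
#' supplied (operations in this package emit pre-sorted tables), UTF-8, LF
#' line endings, and undefined values rendered as `-` in TSV. Writing the
#' same tables twice yields byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param format `"tsv"` or `"json"`.
#' @return manifest data.frame with columns `table`, `path`, `n_rows`.
#' @export
write_results <- function(tables, out_dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop_input("output directory is not writable: ", out_dir)
  }
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) {
    stop_input("tables must be a named list")
  }
  paths <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "tsv") {
      con <- file(path, open = "wb")
      utils::write.table(tab, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "-", eol = "\n",
                         fileEncoding = "UTF-8")
      close(con)
    } else {
      jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    paths <- c(paths, path)
    rows <- c(rows, nrow(tab))
  }
  data.frame(table = names(tables) %||% character(0), path = paths,
             n_rows = rows, stringsAsFactors = FALSE)
}

#' Read back a TSV result table
#'
#' Companion to [write_results()]; `-` is read as missing.
#'
#' @param path path to a TSV written by [write_results()].
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, na.strings = "-", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
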