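#' Write a result table with a JSON manifest
#'
#' Writes a delimited text table with a header, fixed column order and
#' reproducible float formatting (10 significant digits), plus a JSON
#' manifest (`<path>.manifest.json`) recording the column schema and any
#' run metadata (config, seeds) supplied. Identical inputs produce
#' byte-identical files, so any table can be regenerated from its own
#' manifest.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param manifest Named list of metadata (config echo, seeds, ...).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv"),
                        manifest = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  sep <- if (format == "tsv") "\t" else ","
  fmt <- rows
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]]))
      fmt[[j]] <- trimws(formatC(fmt[[j]], digits = 10, format = "g"))
  write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  man <- c(list(columns = names(rows), nrow = nrow(rows), format = format,
                package_version = as.character(
                  utils::packageVersion("paradigmflow"))),
           manifest)
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to the table.
#' @return A data.frame (numeric columns restored).
#' @export
read_table <- function(path) {
  man_path <- paste0(path, ".manifest.json")
  sep <- "\t"
  if (file.exists(man_path)) {
    man <- jsonlite::fromJSON(man_path)
    if (identical(man$format, "csv")) sep <- ","
  }
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Flatten a sweep result for writing
#'
#' @param sweep A [alpha_sweep()] result.
#' @return Its per-cell table (data.frame).
#' @export
sweep_table <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  sweep$table
}
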