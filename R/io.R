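#' Write per-read calls as TSV
#'
#' Columns: `read_id`, `gene`, `status`, `orientation`, `polyA_len`,
#' `additions`, `addition_class`. `NA` fields are written empty.
#'
#' @param calls a [TailCallSet-class] or calls table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCallsTsv <- function(calls, path) {
  df <- as.data.frame(.callsTable(calls))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-read calls from TSV
#'
#' @param path calls TSV written by [writeCallsTsv()].
#' @return a [TailCallSet-class].
#' @export
readCallsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          colClasses = c(read_id = "character",
                                         gene = "character",
                                         status = "character",
                                         orientation = "character",
                                         polyA_len = "integer",
                                         additions = "character",
                                         addition_class = "character"))
  ## empty addition blocks of called reads are "", not missing
  fix <- df$status == "called" & is.na(df$additions)
  df$additions[fix] <- ""
  counters <- stats::setNames(integer(length(CALL_STATUSES)), CALL_STATUSES)
  tab <- table(df$status)
  counters[names(tab)] <- as.integer(tab)
  new("TailCallSet", calls = S4Vectors::DataFrame(df), counters = counters)
}

#' Write a uridylation summary (TSV and/or JSON)
#'
#' @param x a [UridylationSummary-class].
#' @param path output path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
writeSummary <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(condition = x@condition, gene = x@gene,
           total_called = x@totalCalled,
           counts = as.list(x@counts),
           frequencies_pct = as.list(x@frequencies),
           defined = x@defined),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
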