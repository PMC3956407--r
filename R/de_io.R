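#' Write differential-expression results to TSV
#'
#' Rows are ordered by descending \code{|log(Dif)|} (strongest
#' differential representation first; 0 and +Inf sort to the top), ties
#' broken by tag text. The \code{adjusted_p} column is left blank when
#' multiple-testing correction was disabled.
#'
#' @param results a \code{\link{sage_test}} fit or its \code{$results}
#'   data.frame.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_de_table <- function(results, path) {
  if (inherits(results, "sage_test")) results <- results$results
  if (NROW(results) == 0) stop("no results to write")
  key <- abs(log(results$dif))
  key[results$dif == 0] <- Inf
  ord <- order(-key, results$tag)
  out <- results[ord, c("tag", "count_A", "count_B", "dif", "bin",
                        "p_two_sided", "significant_by_test", "adjusted_p")]
  names(out)[names(out) == "significant_by_test"] <- "significant"
  out$dif <- ifelse(is.finite(out$dif), signif(out$dif, 6), out$dif)
  out$p_two_sided <- signif(out$p_two_sided, 6)
  out$adjusted_p <- ifelse(is.na(out$adjusted_p), "",
                           format(signif(out$adjusted_p, 6)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a differential-expression results table written by
#' \code{\link{write_de_table}}
#'
#' @param path file path.
#' @return data.frame with the written columns; \code{adjusted_p} is
#'   \code{NA} where blank.
#' @export
read_de_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(adjusted_p = "character"))
  df$adjusted_p <- suppressWarnings(as.numeric(df$adjusted_p))
  df$significant <- as.logical(df$significant)
  df
}
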