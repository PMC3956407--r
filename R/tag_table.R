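#' Construct a tag-count table for two SAGE libraries
#'
#' The central container of the pipeline: per-tag counts in two libraries
#' plus the library totals. Tags are canonicalized on entry; rows where
#' both counts are zero are rejected; both totals must be positive.
#'
#' @param tag character vector of 21-bp tags (any recordable orientation;
#'   canonicalized internally).
#' @param count_A,count_B non-negative integer counts per tag in each
#'   library.
#' @param labels length-2 character vector naming the libraries.
#' @return an object of class \code{"tag_count_table"}: a data.frame with
#'   columns \code{tag}, \code{count_A}, \code{count_B} and attributes
#'   \code{total_A}, \code{total_B}, \code{labels}.
#' @export
#' @examples
#' tag_count_table(c("CATGAAACCCGGGTTTAAACC", "CATGTTTGGGCCCAAATTTGG"),
#'                 c(3L, 1L), c(0L, 5L))
tag_count_table <- function(tag, count_A, count_B,
                            labels = c("library_A", "library_B")) {
  stopifnot(length(tag) == length(count_A), length(tag) == length(count_B),
            length(labels) == 2)
  if (length(tag) == 0) stop("tag table must contain at least one tag")
  count_A <- as.integer(count_A)
  count_B <- as.integer(count_B)
  if (anyNA(count_A) || anyNA(count_B) || any(count_A < 0) || any(count_B < 0)) {
    stop("counts must be non-negative integers")
  }
  tag <- canonical_tag(tag)
  if (anyDuplicated(tag)) {
    agg <- rowsum(cbind(count_A, count_B), tag)
    tag <- rownames(agg)
    count_A <- as.integer(agg[, 1])
    count_B <- as.integer(agg[, 2])
  }
  if (any(count_A == 0 & count_B == 0)) {
    stop("tags absent from both libraries are not allowed (count_A = count_B = 0)")
  }
  total_A <- sum(count_A)
  total_B <- sum(count_B)
  if (total_A <= 0 || total_B <= 0) {
    stop("both library totals must be positive (got ", total_A, ", ", total_B, ")")
  }
  out <- data.frame(tag = tag, count_A = count_A, count_B = count_B,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_A") <- total_A
  attr(out, "total_B") <- total_B
  attr(out, "labels") <- as.character(labels)
  class(out) <- c("tag_count_table", "data.frame")
  out
}

#' @export
print.tag_count_table <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("Tag-count table: ", nrow(x), " unique 21-bp tags\n", sep = "")
  cat(sprintf("  %s total: %d\n  %s total: %d\n",
              lab[1], attr(x, "total_A"), lab[2], attr(x, "total_B")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more tags\n", sep = "")
  invisible(x)
}

#' Read a two-library tag-count table from TSV
#'
#' Expects a tab-delimited file with a header. The column layout of
#' published tag lists varies, so the mapping is configurable; the default
#' expects columns \code{tag}, \code{count_A}, \code{count_B}.
#'
#' @param path file path.
#' @param columns named character vector mapping the roles \code{tag},
#'   \code{count_A}, \code{count_B} to column names in the file.
#' @param labels library names (defaults to the two count column names).
#' @return a \code{\link{tag_count_table}}.
#' @export
read_tag_table <- function(path,
                           columns = c(tag = "tag", count_A = "count_A",
                                       count_B = "count_B"),
                           labels = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- columns[c("tag", "count_A", "count_B")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("tag table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(labels)) labels <- unname(need[c("count_A", "count_B")])
  tag_count_table(df[[need["tag"]]], df[[need["count_A"]]], df[[need["count_B"]]],
                  labels = labels)
}

#' Write a tag-count table to TSV
#'
#' @param table a \code{\link{tag_count_table}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_tag_table <- function(table, path) {
  stopifnot(inherits(table, "tag_count_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
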