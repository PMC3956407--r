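# Ditag/tag extraction: the computational half of SAGE library construction.
# Concatemer inserts are runs of ~34-bp ditag cores separated by CATG
# anchoring-enzyme sites; each core yields one tag from each end.

#' Split a concatemer sequence into ditag cores
#'
#' Scans the clone sequence for occurrences of the CATG anchor and takes
#' every maximal segment strictly between consecutive anchors as a
#' candidate ditag core. Cores outside the length window or containing N
#' are rejected with a reason; partial segments before the first / after
#' the last anchor are never ditags and are ignored.
#'
#' @param sequence upper-case clone sequence (single string).
#' @param clone_id clone identifier carried into results and logs.
#' @param min_core,max_core accepted core length window. MmeI cuts 19-21
#'   bases from its recognition site, so cores run 34 +/- a few bases;
#'   the default window is \code{[32, 38]}.
#' @return list with \code{ditags}: data.frame(clone_id, index_in_clone,
#'   core) of accepted cores, and \code{rejected}: data.frame(clone_id,
#'   segment, reason) for everything else. Reasons are
#'   \code{"no_anchor"}, \code{"short_core"}, \code{"long_core"},
#'   \code{"contains_n"}.
#' @export
split_concatemer <- function(sequence, clone_id = "clone",
                             min_core = 32L, max_core = 38L) {
  stopifnot(length(sequence) == 1, min_core <= max_core)
  rej <- function(segment, reason) {
    data.frame(clone_id = rep_len(clone_id, length(segment)),
               segment = segment, reason = reason, stringsAsFactors = FALSE)
  }
  empty_d <- data.frame(clone_id = character(), index_in_clone = integer(),
                        core = character(), stringsAsFactors = FALSE)
  hits <- gregexpr(ANCHOR, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1 || length(hits) < 2) {
    return(list(ditags = empty_d, rejected = rej(sequence, "no_anchor")))
  }
  starts <- hits + 4L          # first base after each anchor
  ends <- hits[-1] - 1L        # last base before the next anchor
  cores <- substring(sequence, starts[-length(starts)], ends)
  len <- nchar(cores)
  reason <- rep(NA_character_, length(cores))
  reason[len < min_core] <- "short_core"
  reason[len > max_core] <- "long_core"
  reason[is.na(reason) & grepl("N", cores, fixed = TRUE)] <- "contains_n"
  keep <- is.na(reason)
  ditags <- data.frame(clone_id = rep_len(clone_id, sum(keep)),
                       index_in_clone = seq_along(cores)[keep],
                       core = cores[keep], stringsAsFactors = FALSE)
  rejected <- if (any(!keep)) rej(cores[!keep], reason[!keep]) else
    rej(character(), character())
  list(ditags = ditags, rejected = rejected)
}

#' Release the two 21-bp tags of a ditag core
#'
#' A ditag is two tags ligated tail-to-tail, so the first 17 bases of the
#' core belong to one transcript's tag read forward, and the last 17 bases
#' are the reverse complement of the other's. Cores of length 34-38 always
#' yield two 17-base tags from opposite ends; any middle overlap or gap
#' (MmeI cut-site variability) is ignored.
#'
#' @param core ditag core string(s), length >= 34.
#' @return character matrix with columns \code{tag1}, \code{tag2} of
#'   canonical 21-bp tags, one row per core.
#' @export
ditag_to_tags <- function(core) {
  n <- nchar(core)
  if (any(n < 34)) stop("ditag core shorter than 34 bp cannot yield two full tags")
  tag1 <- paste0(ANCHOR, substring(core, 1L, 17L))
  tag2 <- paste0(ANCHOR, revcomp(substring(core, n - 16L, n)))
  cbind(tag1 = canonical_tag(tag1), tag2 = canonical_tag(tag2))
}

#' Remove duplicate ditags
#'
#' PCR amplification during library construction can duplicate a ligation
#' product; classic SAGE discards repeated ditags. A ditag read from the
#' opposite strand is the same ligation product, so cores are compared up
#' to reverse complement. First occurrence wins. Off by default in the
#' pipeline because published tag totals are typically raw counts.
#'
#' @param ditags data.frame with a \code{core} column.
#' @param enabled if \code{FALSE}, returns the input unchanged.
#' @return the deduplicated (or original) data.frame.
#' @export
deduplicate_ditags <- function(ditags, enabled = TRUE) {
  if (!enabled || nrow(ditags) == 0) return(ditags)
  key <- pmin(ditags$core, revcomp(ditags$core))
  ditags[!duplicated(key), , drop = FALSE]
}

#' Count canonical tags from two libraries' tag lists
#'
#' @param tags_A,tags_B character vectors of canonical 21-bp tags (the
#'   flattened tag pairs from each library's accepted ditags).
#' @param labels library names.
#' @return a \code{\link{tag_count_table}} whose totals equal the input
#'   lengths.
#' @export
count_tags <- function(tags_A, tags_B, labels = c("library_A", "library_B")) {
  all_tags <- sort(unique(c(tags_A, tags_B)))
  if (length(all_tags) == 0) stop("no tags to count")
  cA <- table(factor(tags_A, levels = all_tags))
  cB <- table(factor(tags_B, levels = all_tags))
  tag_count_table(all_tags, as.integer(cA), as.integer(cB), labels = labels)
}

#' Extract a tag-count table from two concatemer FASTA libraries
#'
#' End-to-end extraction: split every clone into ditag cores, optionally
#' deduplicate ditags (per library), release two tags per core, count.
#'
#' @param records_A,records_B concatemer sets from
#'   \code{\link{read_concatemer_fasta}} (or paths to FASTA files).
#' @param min_core,max_core ditag core length window.
#' @param dedup drop duplicate ditags (up to reverse complement) before
#'   tag release.
#' @param labels library names.
#' @return list with \code{table} (a \code{\link{tag_count_table}}) and
#'   \code{rejection_log} (data.frame clone_id, segment, reason, library).
#' @export
extract_tag_table <- function(records_A, records_B, min_core = 32L,
                              max_core = 38L, dedup = FALSE,
                              labels = c("library_A", "library_B")) {
  one_library <- function(records) {
    if (is.character(records) && length(records) == 1) {
      records <- read_concatemer_fasta(records)
    }
    parts <- lapply(seq_len(nrow(records)), function(i) {
      split_concatemer(records$sequence[i], records$clone_id[i],
                       min_core = min_core, max_core = max_core)
    })
    ditags <- do.call(rbind, lapply(parts, `[[`, "ditags"))
    rejected <- do.call(rbind, lapply(parts, `[[`, "rejected"))
    ditags <- deduplicate_ditags(ditags, enabled = dedup)
    tags <- if (nrow(ditags)) as.vector(t(ditag_to_tags(ditags$core))) else character()
    list(tags = tags, rejected = rejected)
  }
  a <- one_library(records_A)
  b <- one_library(records_B)
  log <- rbind(
    if (nrow(a$rejected)) cbind(a$rejected, library = labels[1]) else NULL,
    if (nrow(b$rejected)) cbind(b$rejected, library = labels[2]) else NULL
  )
  if (is.null(log)) {
    log <- data.frame(clone_id = character(), segment = character(),
                      reason = character(), library = character(),
                      stringsAsFactors = FALSE)
  }
  list(table = count_tags(a$tags, b$tags, labels = labels),
       rejection_log = log)
}
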