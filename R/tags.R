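#' @keywords internal
"_PACKAGE"

TAG_LENGTH <- 21L
ANCHOR <- "CATG"

#' Reverse-complement a DNA string
#'
#' Plain-character helper used throughout tag handling; operates on
#' uppercase A/C/G/T(/N) strings and is vectorised.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CATGAAATTT")
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# positionwise complement, no reversal
complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Canonicalize a 21-bp SAGE tag
#'
#' SAGE tags are 21-bp sequences consisting of the CATG anchoring-enzyme
#' site followed by 17 informative bases. A tag can be recorded in three
#' orientations: as read (starts with \code{CATG}), as the opposite-strand
#' read (ends with \code{CATG}; the reverse complement restores it), or as
#' the in-place complementary strand (starts with \code{GTAC}, as tag
#' primer listings sometimes do; the positionwise complement restores it).
#' Canonicalization maps all three to the CATG-prefixed form and is
#' idempotent.
#'
#' @param tag character vector of 21-bp tag sequences (case-insensitive).
#' @return character vector of canonical tags, each starting with
#'   \code{CATG}.
#' @export
#' @examples
#' canonical_tag("catgAAACCCGGGTTTAAACC")
#' canonical_tag(revcomp("CATGAAACCCGGGTTTAAACC"))
canonical_tag <- function(tag) {
  tag <- toupper(tag)
  bad_len <- nchar(tag) != TAG_LENGTH
  if (any(bad_len)) {
    stop("tag length must be exactly ", TAG_LENGTH, " bp; offending tag(s): ",
         paste(utils::head(tag[bad_len], 3), collapse = ", "))
  }
  bad_chr <- grepl("[^ACGT]", tag)
  if (any(bad_chr)) {
    stop("tags must contain only A/C/G/T; offending tag(s): ",
         paste(utils::head(tag[bad_chr], 3), collapse = ", "))
  }
  out <- tag
  ends <- !startsWith(out, ANCHOR) & endsWith(out, ANCHOR)
  out[ends] <- revcomp(out[ends])
  gtac <- !startsWith(out, ANCHOR) & startsWith(out, "GTAC")
  out[gtac] <- complement(out[gtac])
  bad <- !startsWith(out, ANCHOR)
  if (any(bad)) {
    stop("cannot canonicalize tag(s) lacking a terminal CATG anchor or GTAC ",
         "complement prefix: ", paste(utils::head(tag[bad], 3), collapse = ", "))
  }
  out
}

is_canonical_tag <- function(tag) {
  nchar(tag) == TAG_LENGTH & startsWith(tag, ANCHOR) & !grepl("[^ACGT]", tag)
}
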