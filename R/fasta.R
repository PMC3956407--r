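#' Read concatemer clone sequences from a FASTA file
#'
#' Each record is one sequenced concatemer clone insert. Sequences are
#' upper-cased; record order is preserved; duplicate clone ids are an
#' error.
#'
#' @param path FASTA file path.
#' @return data.frame of class \code{"concatemer_set"} with columns
#'   \code{clone_id} and \code{sequence}.
#' @export
read_concatemer_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA at '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate clone id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(clone_id = ids,
                    sequence = toupper(as.character(seqs)),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sequence))) stop("empty sequence in FASTA: ", path)
  rownames(out) <- NULL
  class(out) <- c("concatemer_set", "data.frame")
  out
}

#' Write concatemer clones to FASTA
#'
#' @param records data.frame with columns \code{clone_id}, \code{sequence}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_concatemer_fasta <- function(records, path) {
  stopifnot(all(c("clone_id", "sequence") %in% names(records)))
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$clone_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}
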