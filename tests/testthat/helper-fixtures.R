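# Shared fixture builders. All randomness goes through explicit seeds.

# n distinct canonical tags whose 21-mers contain CATG only at the anchor
fixture_tags <- function(n, seed = 1) {
  set.seed(seed)
  tags <- character(0)
  while (length(tags) < n) {
    cand <- paste0("CATG", vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
    }, character(1)))
    ok <- !grepl("CATG", substring(cand, 2), fixed = TRUE)
    tags <- unique(c(tags, cand[ok]))
  }
  tags[seq_len(n)]
}

fixture_table <- function(n = 6, seed = 1, totals_scale = 10L) {
  tags <- fixture_tags(n, seed)
  set.seed(seed + 1000)
  cA <- rpois(n, totals_scale) + 1L
  cB <- rpois(n, totals_scale) + 1L
  tag_count_table(tags, cA, cB)
}

write_fasta_lines <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}
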