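# Ditag splitting, tag release, deduplication, counting, and the
# conservation/anchor bookkeeping properties.

core_for <- function(t1, t2) {
  paste0(substring(t1, 5, 21), revcomp(substring(t2, 5, 21)))
}

test_that("concatemers split into length-filtered anchor-free cores", {
  tags <- fixture_tags(4, seed = 21)
  c1 <- core_for(tags[1], tags[2])
  c2 <- core_for(tags[3], tags[4])
  seq <- paste0("CATG", c1, "CATG", c2, "CATG")
  out <- split_concatemer(seq, "cl1")
  expect_identical(out$ditags$core, c(c1, c2))
  expect_identical(out$ditags$index_in_clone, 1:2)
  expect_identical(nrow(out$rejected), 0L)

  # no anchor at all
  out2 <- split_concatemer("AAAATTTTGGGGCCCC", "cl2")
  expect_identical(nrow(out2$ditags), 0L)
  expect_identical(out2$rejected$reason, "no_anchor")

  # short segment between anchors is rejected with a reason
  out3 <- split_concatemer(paste0("CATG", "AAAATTTTGG", "CATG", c1, "CATG"), "cl3")
  expect_identical(out3$rejected$reason, "short_core")
  expect_identical(out3$ditags$core, c1)

  # N-containing and over-long cores are rejected too
  c_n <- sub("A", "N", c1)
  out4 <- split_concatemer(paste0("CATG", c_n, "CATG"), "cl4")
  expect_identical(out4$rejected$reason, "contains_n")
  long <- paste0(c1, "AAAAAAA")  # 41 bp
  out5 <- split_concatemer(paste0("CATG", long, "CATG"), "cl5")
  expect_identical(out5$rejected$reason, "long_core")
})

test_that("accepted plus rejected segments account for all anchor-delimited segments", {
  tags <- fixture_tags(6, seed = 22)
  cores <- c(core_for(tags[1], tags[2]), "AAAA",
             core_for(tags[3], tags[4]), core_for(tags[5], tags[6]))
  seq <- paste0("CATG", paste(cores, collapse = "CATG"), "CATG")
  out <- split_concatemer(seq, "cl")
  expect_identical(nrow(out$ditags) + nrow(out$rejected), length(cores))
})

test_that("a ditag core yields one forward and one reverse-complement tag", {
  tags <- fixture_tags(2, seed = 23)
  core <- core_for(tags[1], tags[2])
  pair <- ditag_to_tags(core)
  expect_identical(unname(pair[1, "tag1"]), tags[1])
  expect_identical(unname(pair[1, "tag2"]), tags[2])
  expect_true(all(startsWith(pair, "CATG")))

  # palindromic core: both ends read the same tag
  half <- substring(tags[1], 5, 21)
  pal <- paste0(half, revcomp(half))
  pp <- ditag_to_tags(pal)
  expect_identical(unname(pp[1, "tag1"]), unname(pp[1, "tag2"]))

  # a 36-bp core ignores its 2 middle bases
  core36 <- paste0(substring(core, 1, 17), "GG", substring(core, 18, 34))
  expect_identical(ditag_to_tags(core36), ditag_to_tags(core))

  expect_error(ditag_to_tags(substring(core, 1, 33)), "shorter than 34")
})

test_that("ditag deduplication honors reverse-complement identity", {
  tags <- fixture_tags(8, seed = 24)
  cores <- c(core_for(tags[1], tags[2]), core_for(tags[3], tags[4]),
             core_for(tags[1], tags[2]),            # exact duplicate
             revcomp(core_for(tags[3], tags[4])),   # opposite-strand read
             core_for(tags[5], tags[6]))
  d <- data.frame(clone_id = "c", index_in_clone = seq_along(cores),
                  core = cores, stringsAsFactors = FALSE)
  expect_identical(nrow(deduplicate_ditags(d, enabled = FALSE)), 5L)
  kept <- deduplicate_ditags(d, enabled = TRUE)
  expect_identical(nrow(kept), 3L)

  # brute-force pairwise oracle on random cores with planted rc-duplicates
  set.seed(42)
  base <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE), collapse = "")
  }, character(1))
  mix <- c(base, revcomp(base[1:10]), base[5:8])
  mix <- sample(mix)
  dd <- data.frame(clone_id = "c", index_in_clone = seq_along(mix),
                   core = mix, stringsAsFactors = FALSE)
  keep_oracle <- logical(length(mix))
  for (i in seq_along(mix)) {
    keep_oracle[i] <- !any(vapply(seq_len(i - 1), function(j) {
      mix[j] == mix[i] || mix[j] == revcomp(mix[i])
    }, logical(1)))
  }
  expect_identical(deduplicate_ditags(dd, enabled = TRUE)$core,
                   mix[keep_oracle])
})

test_that("tag counting preserves totals and merges orientations", {
  tags <- fixture_tags(2, seed = 25)
  t <- tags[1]; u <- tags[2]
  tab <- count_tags(c(t, t, u), u)
  expect_identical(attr(tab, "total_A"), 3L)
  expect_identical(attr(tab, "total_B"), 1L)
  expect_identical(tab$count_A[tab$tag == t], 2L)
  expect_identical(tab$count_B[tab$tag == u], 1L)
  expect_error(count_tags(character(0), u), "positive|no tags")
})

test_that("extraction conserves tags: two per accepted ditag, round-trips simulation", {
  cfg <- sim_config(n_transcripts = 120, de_fraction = 0.05, total_A = 400L,
                    total_B = 500L, seed = 31)
  truth <- simulate_truth(cfg)
  tab <- sample_libraries(truth)
  fa <- libraries_to_concatemers(tab, tags_per_clone = 8L, seed = 32)
  ext <- extract_tag_table(fa$A, fa$B)
  expect_identical(as.data.frame(ext$table)[c("tag", "count_A", "count_B")],
                   as.data.frame(tab)[c("tag", "count_A", "count_B")])
  expect_identical(nrow(ext$rejection_log), 0L)
  # conservation: counted tags = 2 x accepted ditags
  n_ditags <- sum(vapply(fa$A$sequence, function(s) {
    nrow(split_concatemer(s, "x")$ditags)
  }, 0L))
  expect_identical(attr(ext$table, "total_A"), 2L * n_ditags)
})
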