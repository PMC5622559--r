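test_that("center partitioning covers the sequence with a kept remainder", {
  p <- partition_center("ACGTACGT", 4)
  expect_equal(p$segment, c("ACGT", "ACGT"))
  expect_equal(p$center_offset, c(0L, 4L))
  p <- partition_center("ACGTA", 4)
  expect_equal(p$segment, c("ACGT", "A"))
  expect_equal(p$center_offset, c(0L, 4L))
  expect_error(partition_center("ACGT", 0), "seg_len")

  set.seed(2)
  for (t in 1:10) {
    m <- sample(5:60, 1); L <- sample(1:9, 1)
    s <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    p <- partition_center(s, L)
    expect_equal(nrow(p), ceiling(m / L))
    expect_equal(p$center_offset, seq(0L, m - 1L, by = L))
    expect_equal(paste(p$segment, collapse = ""), s)
  }
})

test_that("the keyword tree has one root, per-segment terminals and correct failure links", {
  tr <- build_keyword_tree("ACG")
  expect_equal(length(tr$children), 4L)  # root + 3
  expect_equal(sum(lengths(tr$terminal) > 0), 1L)

  # n distinct equal-length segments -> n terminal leaves
  segs <- partition_center("ACGTTGCAAAACCGGT", 4)
  tr <- build_keyword_tree(segs)
  expect_equal(sum(lengths(tr$terminal) > 0), 4L)
  expect_equal(tr$fail[1], 1L)
  expect_true(all(tr$depth[tr$fail] < pmax(tr$depth, 1L)))

  set.seed(31)
  for (t in 1:20) {
    k <- sample(1:8, 1)
    segs <- unique(replicate(k, paste(sample(c("A", "C"), sample(1:5, 1), TRUE),
                                      collapse = "")))
    tr <- build_keyword_tree(segs)
    expect_equal(tr$fail, oracle_failure_links(tr))
  }
  expect_error(build_keyword_tree(c("ACG", "")), "empty")
})

test_that("segment matching equals naive substring search", {
  center <- "ACGTACGTTTGCAC"
  segs <- partition_center(center, 4)
  tr <- build_keyword_tree(segs)
  self <- match_segments(tr, center)
  own <- self[self$query_offset == self$center_offset, ]
  expect_equal(sort(own$center_offset), segs$center_offset)

  expect_equal(nrow(match_segments(build_keyword_tree("ACGC"), "TTTT")), 0L)

  set.seed(37)
  for (t in 1:20) {
    c_ <- paste(sample(c("A", "C", "G"), sample(8:20, 1), TRUE), collapse = "")
    q <- paste(sample(c("A", "C", "G"), sample(8:25, 1), TRUE), collapse = "")
    segs <- partition_center(c_, sample(2:4, 1))
    tr <- build_keyword_tree(segs)
    got <- match_segments(tr, q)
    want <- naive_segment_search(segs, q)
    o1 <- order(got$segment_id, got$query_offset)
    o2 <- order(want$segment_id, want$query_offset)
    expect_equal(got[o1, c("segment_id", "query_offset", "length")],
                 want[o2, c("segment_id", "query_offset", "length")],
                 ignore_attr = TRUE)
  }
})

test_that("chaining keeps collinear matches and resolves crossings optimally", {
  m <- data.frame(segment_id = 1:2, center_offset = c(0L, 10L),
                  query_offset = c(0L, 12L), length = c(5L, 5L))
  ch <- chain_matches(m)
  expect_equal(nrow(ch), 2L)
  expect_equal(attr(ch, "total_length"), 10L)

  crossing <- data.frame(segment_id = 1:2, center_offset = c(0L, 5L),
                         query_offset = c(6L, 0L), length = c(4L, 6L))
  ch <- chain_matches(crossing)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$length, 6L)

  expect_equal(nrow(chain_matches(NULL)), 0L)

  set.seed(41)
  for (t in 1:40) {
    k <- sample(1:12, 1)
    m <- data.frame(segment_id = seq_len(k),
                    center_offset = sample(0:30, k, TRUE),
                    query_offset = sample(0:30, k, TRUE),
                    length = sample(1:6, k, TRUE))
    ch <- chain_matches(m)
    expect_equal(attr(ch, "total_length"), oracle_chain_best(m))
    # the selected chain is itself valid
    if (nrow(ch) > 1) {
      expect_true(all(diff(ch$center_offset) >= head(ch$length, -1)))
      expect_true(all(diff(ch$query_offset) >= head(ch$length, -1)))
    }
  }
})

test_that("anchored pairwise alignment copies anchors and degaps correctly", {
  sch <- scoring_scheme("dna")
  center <- "ACGTACGTTTGCACGGA"
  rec <- trie_pairwise(center, center, scheme = sch, seg_len = 4)
  expect_true(all(rec$center_ins == 0L))
  expect_true(all(rec$seq_ins == 0L))

  # one residue deleted between anchors -> exactly one space in the query side
  query <- paste0(substr(center, 1, 9), substr(center, 11, nchar(center)))
  rec <- trie_pairwise(center, query, scheme = sch, seg_len = 4)
  expect_equal(sum(rec$seq_ins), 1L)
  expect_equal(sum(rec$center_ins), 0L)
  expect_equal(gsub("-", "", rec$aligned_seq), query)

  # random similar pairs: round-trip plus exact anchors
  set.seed(43)
  for (t in 1:10) {
    fix <- generate_dna_family(2, 150, seed = 100 + t)
    c_ <- fix$members[[1]]; q <- fix$members[[2]]
    tr <- build_keyword_tree(partition_center(c_, 10))
    chain <- chain_matches(match_segments(tr, q))
    rec <- trie_pairwise(c_, q, chain = chain, scheme = sch)
    expect_equal(gsub("-", "", rec$aligned_center), c_)
    expect_equal(gsub("-", "", rec$aligned_seq), q)
    if (nrow(chain) > 0) {
      anch_c <- substring(c_, chain$center_offset + 1,
                          chain$center_offset + chain$length)
      anch_q <- substring(q, chain$query_offset + 1,
                          chain$query_offset + chain$length)
      expect_equal(anch_c, anch_q)
    }
  }
  bad <- data.frame(segment_id = 1L, center_offset = 0L, query_offset = 0L,
                    length = 4L)
  expect_error(trie_pairwise("ACGT", "TTTT", chain = bad, scheme = sch),
               "inconsistent chain")
})

test_that("keyword-tree MSA recovers ground truth on clean single indels", {
  expect_true(all(!grepl("-", trie_center_star_msa(
    c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"),
    seg_len = 4)$rows)))

  fix <- generate_dna_family(8, 400, sub_rate = 0.002, indel_rate = 0.002,
                             max_indel_len = 2, seed = 47)
  aln <- trie_center_star_msa(fix$members, seg_len = 15)
  expect_equal(unname(gsub("-", "", aln$rows)), unname(fix$members))
  expect_gte(sps(aln, fix$truth)$sps, 0.95)
})

test_that("small-input invariants agree with the plain center-star path", {
  fix <- generate_dna_family(5, 40, seed = 53)
  sch <- scoring_scheme("dna")
  ta <- trie_center_star_msa(fix$members, seg_len = 6, scheme = sch)
  ca <- center_star_msa(fix$members, scheme = sch, mode = "first")
  expect_equal(unname(gsub("-", "", ta$rows)), unname(fix$members))
  expect_equal(unname(gsub("-", "", ca$rows)), unname(fix$members))
  expect_equal(names(ta$rows), names(ca$rows))
})

test_that("a mitochondrial-scale similar family aligns with little dynamic programming", {
  fix <- generate_dna_family(50, 2000, sub_rate = 0.01, indel_rate = 0.0005,
                             seed = 59)
  aln <- trie_center_star_msa(fix$members, seg_len = 15)
  expect_equal(unname(gsub("-", "", aln$rows)), unname(fix$members))
  widths <- nchar(aln$rows)
  expect_true(all(widths == aln$ncol))
  cells <- attr(aln, "dp_cells")
  full <- sum(vapply(fix$members[-1],
                     function(s) nchar(fix$members[[1]]) * nchar(s),
                     numeric(1)))
  expect_lt(cells / full, 0.2)
})
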