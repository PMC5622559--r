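test_that("center selection follows the mode contract", {
  seqs <- c(a = "ACGT", b = "ACGG", c = "TTTT")
  expect_equal(select_center(seqs, mode = "first"), 1L)
  expect_equal(select_center(c(x = "ACGT"), mode = "kmer"), 1L)
  expect_error(select_center(character(0)), "empty")

  # the un-mutated ancestor wins the k-mer vote over its mutated offspring
  fix <- generate_protein_family(4, 60, sub_rate = 0.1, indel_rate = 0.01,
                                 seed = 21)
  seqs <- c(anc = fix$ancestor, fix$members)
  picked <- select_center(seqs, mode = "kmer", k = 3)
  # brute-force shared-k-mer vote
  km <- lapply(seqs, function(s)
    unique(substring(s, 1:(nchar(s) - 2), 3:nchar(s))))
  votes <- sapply(seq_along(seqs), function(i)
    sum(sapply(seq_along(seqs)[-i],
               function(j) length(intersect(km[[i]], km[[j]])))))
  expect_equal(picked, which.max(votes))
  expect_equal(names(seqs)[picked], "anc")
})

test_that("gap profiles merge as a commutative associative monoid", {
  p0 <- gap_profile("c", 10)
  p1 <- gap_profile("c", 10, c(0, 0, 0, 0, 2, rep(0, 6)))
  p2 <- gap_profile("c", 10, c(0, 0, 0, 0, 3, 0, 0, 0, 1, 0, 0))
  m12 <- starlign:::profile_merge2(p1, p2)
  expect_equal(m12$ins[5], 3L)
  expect_equal(m12$ins[9], 1L)
  expect_equal(profile_width(m12), 10 + 4)
  # identity, commutativity, associativity on random profiles
  set.seed(5)
  for (t in 1:20) {
    a <- gap_profile("c", 10, rpois(11, 0.5))
    b <- gap_profile("c", 10, rpois(11, 0.5))
    c_ <- gap_profile("c", 10, rpois(11, 0.5))
    expect_equal(starlign:::profile_merge2(a, p0), a)
    expect_equal(starlign:::profile_merge2(a, b), starlign:::profile_merge2(b, a))
    expect_equal(
      starlign:::profile_merge2(starlign:::profile_merge2(a, b), c_),
      starlign:::profile_merge2(a, starlign:::profile_merge2(b, c_)))
  }
})

test_that("merging records matches a naive pair-at-a-time merge", {
  sch <- scoring_scheme("dna")
  center <- "ACGTACGTAC"
  set.seed(9)
  for (t in 1:10) {
    others <- replicate(4, paste(sample(c("A", "C", "G", "T"),
                                        sample(6:14, 1), TRUE), collapse = ""))
    records <- lapply(others, function(s) sw_align_full(center, s, sch))
    prof <- merge_gap_profiles(records, center)
    # naive: fold records one at a time, in reversed order
    naive <- gap_profile("center", nchar(center))
    for (rec in rev(records))
      naive <- starlign:::profile_merge2(
        naive, gap_profile("center", nchar(center), rec$center_ins))
    expect_equal(prof$ins, naive$ins)
    # every projected row has exactly the profile width and degaps back
    for (k in seq_along(records)) {
      row <- project_row(records[[k]], prof)
      expect_equal(nchar(row), profile_width(prof))
      expect_equal(gsub("-", "", row), others[k])
    }
  }
  expect_error(merge_gap_profiles(list(sw_align_full("ACGT", "ACGT", sch)),
                                  center),
               "degap|positions")
})

test_that("projection handles the trivial and center cases", {
  sch <- scoring_scheme("dna")
  rec <- sw_align_full("ACGT", "ACGT", sch)
  prof <- merge_gap_profiles(list(rec), "ACGT")
  expect_equal(project_row(rec, prof), "ACGT")
  prof2 <- gap_profile("c", 5, c(0, 0, 0, 2, 0, 0))
  expect_equal(project_center("ACGTA", prof2), "ACG--TA")
})

test_that("center-star alignment satisfies its structural invariants", {
  seqs <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  aln <- center_star_msa(seqs, mode = "first")
  expect_equal(aln$ncol, 6L)
  expect_true(all(!grepl("-", aln$rows)))

  one <- center_star_msa(c(z = "MKVLA"))
  expect_equal(unname(one$rows), "MKVLA")

  fix <- generate_protein_family(8, 60, seed = 13)
  aln <- center_star_msa(fix$members, mode = "first")
  # column count = |center| + sum of max insertions
  sch <- scoring_scheme("protein")
  center <- fix$members[[1]]
  records <- lapply(fix$members[-1], function(s) sw_align_full(center, s, sch))
  prof <- merge_gap_profiles(records, center)
  expect_equal(aln$ncol, profile_width(prof))
  # degapping round-trip for every row
  expect_equal(unname(gsub("-", "", aln$rows)), unname(fix$members))
})

test_that("alignments are byte-identical across worker counts", {
  fix <- generate_protein_family(6, 40, seed = 17)
  a1 <- center_star_msa(fix$members, workers = 1)
  a4 <- center_star_msa(fix$members, workers = 4)
  expect_identical(a1$rows, a4$rows)

  dfix <- generate_dna_family(6, 120, seed = 19)
  t1 <- trie_center_star_msa(dfix$members, workers = 1)
  t4 <- trie_center_star_msa(dfix$members, workers = 4)
  expect_identical(t1$rows, t4$rows)
})

test_that("center-star alignment beats a random-gap alignment on truth SPS", {
  fix <- generate_protein_family(10, 50, seed = 23)
  aln <- center_star_msa(fix$members)
  got <- sps(aln, fix$truth)$sps
  set.seed(29)
  rand <- random_alignment(fix$members, aln$ncol)
  expect_gte(got, sps(rand, fix$truth)$sps)
  expect_equal(unname(gsub("-", "", aln$rows)), unname(fix$members))
})
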