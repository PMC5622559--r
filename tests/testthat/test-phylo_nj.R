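test_that("gapped p-distance counts one-sided gaps as mismatches", {
  expect_equal(msa_distance("ACGT", "ACGT"), 0)
  expect_equal(msa_distance("AAAA", "CCCC"), 1)
  expect_equal(msa_distance("A-C", "AGC"), 1 / 3)
  expect_equal(msa_distance("A--A", "A--C"), 0.5)  # dual gaps excluded
  expect_equal(msa_distance("--", "--"), 0)
  expect_error(msa_distance("AC", "ACG"), "unequal")

  set.seed(71)
  for (t in 1:15) {
    w <- sample(5:15, 1)
    a <- paste(sample(c("A", "C", "-"), w, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "-"), w, TRUE), collapse = "")
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    use <- !(ac == "-" & bc == "-")
    if (!any(use)) next
    expect_equal(msa_distance(a, b), sum(ac[use] != bc[use]) / sum(use))
  }
})

test_that("sampling for clustering is deterministic with the stated size", {
  ids <- paste0("s", 1:100)
  s <- sample_for_clustering(ids, 0.1, seed = 5)
  expect_length(s, 10)
  expect_identical(s, sample_for_clustering(ids, 0.1, seed = 5))
  expect_setequal(sample_for_clustering(ids, 1.0, seed = 5), ids)
  expect_length(sample_for_clustering(paste0("s", 1:4), 0.1, seed = 1), 2)
  expect_error(sample_for_clustering(ids, 0), "fraction")
  expect_error(sample_for_clustering(ids, 1.5), "fraction")
})

test_that("clustering recovers well-separated clades and respects size bounds", {
  fix <- generate_clades(1, 3, 50, seed = 1)
  cl <- cluster_sequences(fix$truth, seed = 2)
  expect_equal(unname(cl$assignment), rep(1L, 3))

  fix <- generate_clades(2, 10, 150, within_rate = 0.005,
                         between_rate = 0.2, seed = 73)
  cl <- cluster_sequences(fix$truth, fraction = 0.3, max_cluster_frac = 0.6,
                          seed = 7)
  # assignment refines to the generator's clades
  tab <- table(cl$assignment, fix$clade_labels)
  expect_true(all(rowSums(tab > 0) == 1))

  fix <- generate_clades(6, 50, 80, within_rate = 0.01, between_rate = 0.15,
                         seed = 79)
  cl <- cluster_sequences(fix$truth, fraction = 0.1, max_cluster_frac = 0.1,
                          seed = 11)
  n <- length(fix$members)
  expect_true(all(table(cl$assignment) <= floor(0.1 * n)))
  expect_true(all(names(fix$members) %in% names(cl$assignment)))
})

test_that("neighbor joining satisfies the small-n closed forms", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.5, 0.5))

  labs <- c("a", "b", "c")
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["c"]), (4 + 5 - 3) / 2)

  expect_error(nj_tree(matrix(0, 1, 1, dimnames = list("a", "a"))), "n >= 2")
})

test_that("additive matrices are recovered exactly", {
  # the worked 4-taxon case: ((a,b),(c,d)) with unit branches
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  D <- ape::cophenetic.phylo(tree)
  tr <- nj_tree(D)
  expect_equal(phangorn::RF.dist(ape::unroot(tree), tr), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  set.seed(83)
  for (t in 1:30) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n)
    D <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), tr), 0, info = t)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9, info = t)
  }
})

test_that("negative branch estimates are clamped without losing path length", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 2, 0.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                0.1, 2, 2, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_setequal(tr$tip.label, labs)
})

test_that("subtree merging grafts clusters at their representatives", {
  fix <- generate_clades(2, 2, 60, seed = 5)
  D <- msa_dist_matrix(fix$truth)
  single <- nj_tree(D)
  expect_identical(ape::write.tree(merge_subtrees(list(single), "s1", D)),
                   ape::write.tree(single))

  clA <- c("s1", "s2"); clB <- c("s3", "s4")
  sub <- list(nj_tree(D[clA, clA]), nj_tree(D[clB, clB]))
  reps <- c("s1", "s3")
  merged <- merge_subtrees(sub, reps, D[reps, reps])
  expect_setequal(merged$tip.label, c(clA, clB))
  expect_true(is_split(merged, clA))
  expect_true(is_split(merged, clB))

  expect_error(merge_subtrees(sub, c("s1", "s9"), D[reps, reps]), "missing")
})

test_that("cluster-and-merge preserves clade-level structure", {
  fix <- generate_clades(3, 5, 120, within_rate = 0.01, between_rate = 0.15,
                         seed = 89)
  D <- msa_dist_matrix(fix$truth)
  ids <- names(fix$members)
  member_sets <- split(ids, fix$clade_labels)
  reps <- vapply(member_sets, function(ms)
    ms[which.min(rowSums(D[ms, ms]))], character(1))
  merged <- merge_subtrees(lapply(member_sets, function(ms)
    nj_tree(D[ms, ms])), unname(reps), D)
  direct <- nj_tree(D)
  for (ms in member_sets) {
    expect_true(is_split(merged, ms))
    expect_true(is_split(direct, ms))
  }
})

test_that("the full tree pipeline is deterministic and conserves leaves", {
  ident <- multiple_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  star <- build_tree(ident)
  expect_equal(length(star$tip.label), 3)
  expect_true(all(star$edge.length == 0))

  fix <- generate_clades(3, 4, 80, seed = 97)
  direct <- nj_tree(msa_dist_matrix(fix$truth))
  bypass <- build_tree(fix$truth, single_cluster = TRUE)
  expect_identical(ape::write.tree(bypass), ape::write.tree(direct))

  for (frac in c(0.1, 0.5)) {
    tr <- build_tree(fix$truth, fraction = frac, max_cluster_frac = 0.5,
                     seed = 3)
    expect_setequal(tr$tip.label, names(fix$members))
  }
  t1 <- build_tree(fix$truth, fraction = 0.3, max_cluster_frac = 0.5,
                   seed = 3, workers = 1)
  t2 <- build_tree(fix$truth, fraction = 0.3, max_cluster_frac = 0.5,
                   seed = 3, workers = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})
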