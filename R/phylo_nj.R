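#' Gapped p-distance between two alignment rows
#'
#' Proportion of differing positions among the columns carrying a residue in
#' at least one row: residue-residue mismatches and one-sided gaps both count
#' as differences; columns gapped in both rows are excluded. Two all-gap rows
#' have distance 0 by convention.
#'
#' @param rowA,rowB equal-length gapped strings.
#' @return numeric in \[0, 1\].
#' @export
msa_distance <- function(rowA, rowB) {
  if (nchar(rowA) != nchar(rowB)) stop("rows have unequal lengths")
  a <- chars(rowA); b <- chars(rowB)
  ga <- a == "-"; gb <- b == "-"
  usable <- !(ga & gb)
  if (!any(usable)) {
    if (all(ga) && all(gb)) return(0)
    stop("no comparable columns")
  }
  mism <- sum((a[usable] != b[usable]))
  mism / sum(usable)
}

#' Pairwise distance matrix of an alignment
#'
#' @param msa a [multiple_alignment].
#' @param correction `"none"` (gapped p-distance, default) or `"JC"` for the
#'   Jukes-Cantor transform -3/4 log(1 - 4d/3) applied to each entry
#'   (distances >= 0.75 are capped below saturation first).
#' @return symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
msa_dist_matrix <- function(msa, correction = c("none", "JC")) {
  correction <- match.arg(correction)
  m <- aln_matrix(msa)
  n <- nrow(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      usable <- !(gap[i, ] & gap[j, ])
      d <- if (any(usable)) sum(m[i, usable] != m[j, usable]) / sum(usable)
           else 0
      D[i, j] <- D[j, i] <- d
    }
  }
  if (correction == "JC") {
    off <- row(D) != col(D)
    D[off] <- -0.75 * log(pmax(1 - 4 * pmin(D[off], 0.7499) / 3, 1e-12))
  }
  D
}

#' Random sample of ids for initial clustering
#'
#' Draws ceiling(fraction * n) ids without replacement (at least 2 when n >=
#' 2), deterministically for a given seed. The default fraction corresponds
#' to sampling roughly 10% of all alignment rows before clustering.
#'
#' @param ids character vector of ids.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return character subset of `ids`.
#' @export
sample_for_clustering <- function(ids, fraction = 0.1, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- length(ids)
  k <- min(n, max(ceiling(fraction * n), if (n >= 2) 2L else 1L))
  with_seed(seed, sample(ids, k))
}

# greedy leader clustering: ids joins the first center within `radius`,
# otherwise founds a new cluster; returns integer assignment
leader_cluster <- function(ids, D, radius) {
  centers <- character(0)
  assign <- integer(length(ids))
  names(assign) <- ids
  for (id in ids) {
    d <- if (length(centers)) D[id, centers] else numeric(0)
    hit <- which(d <= radius)
    if (length(hit) > 0) {
      assign[id] <- hit[1L]
    } else {
      centers <- c(centers, id)
      assign[id] <- length(centers)
    }
  }
  assign
}

# medoid: member minimizing summed distance to the rest of its cluster
cluster_medoid <- function(members, D) {
  if (length(members) == 1) return(members)
  sums <- rowSums(D[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' Cluster alignment rows by sampled leader clustering with rebalancing
#'
#' A sampled subset of rows seeds greedy leader clustering (joining radius =
#' median of the sampled pairwise distances); remaining rows join their
#' nearest seeded cluster. Rebalancing then merges undersized clusters into
#' their nearest cluster and splits oversized ones (more than
#' `max_cluster_frac` of all rows) by re-running leader clustering inside
#' them at half the within-cluster median radius, falling back to
#' deterministic chunking when a cluster of identical rows cannot be
#' separated. Everything is deterministic for a given seed.
#'
#' @param msa a [multiple_alignment].
#' @param fraction sampling fraction (default 0.1).
#' @param max_cluster_frac maximum cluster size as a fraction of n (default
#'   0.1).
#' @param min_cluster_size clusters smaller than this merge into their
#'   nearest cluster (default 2).
#' @param seed integer seed.
#' @param D optional precomputed distance matrix.
#' @return list with `assignment` (named integer vector, consecutive cluster
#'   indices) and `representatives` (medoid id per cluster).
#' @export
cluster_sequences <- function(msa, fraction = 0.1, max_cluster_frac = 0.1,
                              min_cluster_size = 2L, seed = 1L, D = NULL) {
  ids <- names(msa$rows)
  n <- length(ids)
  if (is.null(D)) D <- msa_dist_matrix(msa)
  single <- function() list(
    assignment = stats::setNames(rep(1L, n), ids),
    representatives = cluster_medoid(ids, D))
  if (n <= 3L) return(single())
  max_size <- max(2L, floor(max_cluster_frac * n))

  seeds <- sample_for_clustering(ids, fraction, seed)
  sampled_d <- D[seeds, seeds][upper.tri(D[seeds, seeds])]
  radius <- if (length(sampled_d)) stats::median(sampled_d) else 0
  seed_assign <- leader_cluster(seeds, D, radius)
  centers <- seeds[!duplicated(seed_assign)][order(unique(seed_assign))]
  rest <- setdiff(ids, seeds)
  assign <- integer(n); names(assign) <- ids
  assign[seeds] <- seed_assign
  if (length(rest))
    assign[rest] <- apply(D[rest, centers, drop = FALSE], 1, which.min)

  # merge undersized clusters into the nearest (by medoid distance) cluster
  repeat {
    sizes <- table(assign)
    small <- as.integer(names(sizes)[sizes < min_cluster_size])
    if (length(small) == 0 || length(sizes) == 1) break
    k <- small[1L]
    meds <- vapply(as.integer(names(sizes)),
                   function(cl) cluster_medoid(ids[assign == cl], D),
                   character(1))
    names(meds) <- names(sizes)
    other <- setdiff(names(sizes), as.character(k))
    target <- other[which.min(D[meds[as.character(k)], meds[other]])]
    assign[assign == k] <- as.integer(target)
  }

  # split oversized clusters
  next_id <- max(assign) + 1L
  repeat {
    sizes <- table(assign)
    big <- as.integer(names(sizes)[sizes > max_size])
    if (length(big) == 0) break
    k <- big[1L]
    members <- ids[assign == k]
    sub <- D[members, members][upper.tri(D[members, members])]
    r <- stats::median(sub) / 2
    sub_assign <- leader_cluster(members, D, r)
    while (length(unique(sub_assign)) == 1 && r > 1e-12) {
      r <- r / 2
      sub_assign <- leader_cluster(members, D, r)
    }
    if (length(unique(sub_assign)) == 1) {
      # identical rows: deterministic chunk split
      sub_assign <- ((seq_along(members) - 1L) %/% max_size) + 1L
      names(sub_assign) <- members
    }
    for (s in unique(sub_assign)[-1L]) {
      assign[members[sub_assign == s]] <- next_id
      next_id <- next_id + 1L
    }
  }

  # renumber consecutively in first-appearance order
  lev <- unique(unname(assign))
  assign <- stats::setNames(match(assign, lev), ids)
  reps <- vapply(seq_along(lev),
                 function(cl) cluster_medoid(ids[assign == cl], D),
                 character(1))
  list(assignment = assign, representatives = reps)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: repeatedly join the pair
#' minimizing Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with
#' branch lengths from the rate-corrected split. Ties pick the smallest
#' (i, j); negative branch estimates are clamped to zero with the deficit
#' moved to the sibling branch, so all branch lengths are non-negative.
#' The implementation is deterministic, for byte-identical Newick output
#' across worker configurations.
#'
#' @param D symmetric distance matrix with labels as dimnames (n >= 2).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  if (is.null(labels) || n < 2) stop("need a labelled matrix with n >= 2")
  if (any(D < 0) || any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(D[1, 2] / 2),
                   labels[2], fmt(D[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }
  nodes <- labels  # newick fragment per active node
  while (length(nodes) > 3) {
    k <- length(nodes)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- dij - li
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    du <- pmax((D[i, ] + D[j, ] - dij) / 2, 0)[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    nodes <- c(nodes[-c(i, j)], merged)
  }
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], fmt(x), nodes[2], fmt(y), nodes[3], fmt(z))
  ape::read.tree(text = nwk)
}

#' Merge per-cluster subtrees over a backbone of representatives
#'
#' Builds a neighbor-joining backbone on the cluster representatives and
#' replaces each representative leaf with its cluster's subtree, rooted at
#' the representative's attachment node, so the representative stays a leaf
#' inside the grafted subtree and the backbone branch length is kept as the
#' connecting edge.
#'
#' @param subtrees list of [ape::phylo] trees (or single-leaf clusters given
#'   as their label), one per cluster and each containing its representative
#'   leaf.
#' @param representatives character vector, one id per cluster.
#' @param D_rep distance matrix over the representatives.
#' @return an [ape::phylo] tree whose leaves are the union of all cluster
#'   members.
#' @export
merge_subtrees <- function(subtrees, representatives, D_rep) {
  stopifnot(length(subtrees) == length(representatives))
  for (ci in seq_along(subtrees)) {
    st <- subtrees[[ci]]
    if (inherits(st, "phylo") &&
        !(representatives[ci] %in% st$tip.label))
      stop("representative '", representatives[ci],
           "' missing from its subtree")
  }
  if (length(subtrees) == 1) {
    st <- subtrees[[1L]]
    if (!inherits(st, "phylo")) stop("single cluster must be a phylo tree")
    return(st)
  }
  backbone <- nj_tree(D_rep[representatives, representatives, drop = FALSE])
  nwk <- ape::write.tree(backbone)
  for (ci in seq_along(subtrees)) {
    st <- subtrees[[ci]]
    if (!inherits(st, "phylo")) next  # singleton cluster: tip stays as-is
    if (length(st$tip.label) == 1) next
    rep_id <- representatives[ci]
    # root the subtree at the representative's attachment node
    tip <- which(st$tip.label == rep_id)
    parent <- st$edge[st$edge[, 2] == tip, 1]
    rooted <- if (parent == length(st$tip.label) + 1L) st
              else ape::root(st, node = parent, resolve.root = FALSE)
    sub_nwk <- sub(";$", "", ape::write.tree(rooted))
    # splice the subtree over the representative tip in the backbone Newick
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", rep_id)
    m <- regexpr(paste0("[(,]", esc, ":"), nwk)
    if (m == -1L) stop("representative '", rep_id, "' not in backbone")
    at <- m + 1L  # keep the leading '(' or ','
    nwk <- paste0(substr(nwk, 1L, at - 1L), sub_nwk,
                  substr(nwk, at + nchar(rep_id), nchar(nwk)))
  }
  ape::read.tree(text = nwk)
}

#' Divide-and-conquer phylogeny from an alignment
#'
#' Pipeline: gapped p-distances over all rows, sampled clustering with
#' rebalancing, an independent neighbor-joining tree per cluster (a
#' parallelizable map over clusters), and a merge of the cluster subtrees
#' over a representative backbone. Deterministic for a given seed; the leaf
#' set always equals the alignment's row ids.
#'
#' @param msa a [multiple_alignment].
#' @param fraction sampling fraction for clustering (default 0.1).
#' @param max_cluster_frac maximum cluster size fraction (default 0.1).
#' @param seed integer seed for the sampling step.
#' @param single_cluster `TRUE` bypasses clustering and runs plain neighbor
#'   joining on the full matrix.
#' @param workers executor workers for the per-cluster tree map.
#' @return an [ape::phylo] tree.
#' @export
build_tree <- function(msa, fraction = 0.1, max_cluster_frac = 0.1,
                       seed = 1L, single_cluster = FALSE, workers = 1L) {
  D <- msa_dist_matrix(msa)
  ids <- names(msa$rows)
  if (single_cluster || length(ids) <= 3L)
    return(nj_tree(D))
  cl <- cluster_sequences(msa, fraction = fraction,
                          max_cluster_frac = max_cluster_frac,
                          seed = seed, D = D)
  ncl <- max(cl$assignment)
  if (ncl == 1L) return(nj_tree(D))
  backend <- if (workers > 1L) "workers" else "sequential"
  member_sets <- lapply(seq_len(ncl), function(k) ids[cl$assignment == k])
  subtrees <- pexec_run(plan_collect(plan_map(
    task_plan(member_sets, partitions = max(1L, workers), backend = backend),
    function(members) {
      if (length(members) == 1) members
      else nj_tree(D[members, members, drop = FALSE])
    })))
  merge_subtrees(subtrees, cl$representatives, D)
}
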