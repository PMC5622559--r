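# Independent oracles used by the property tests. These deliberately use
# naive, exhaustive formulations and share no code with the package paths
# they check.

# global (Needleman-Wunsch) alignment score with linear gap penalty
oracle_nw_score <- function(a, b, match = 2, mismatch = -1, gap = 2) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0) return(-gap * m)
  if (m == 0) return(-gap * n)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  prev <- -gap * (0:m)
  for (i in 1:n) {
    cur <- numeric(m + 1); cur[1] <- -gap * i
    for (j in 1:m) {
      s <- if (ac[i] == bc[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] - gap, cur[j] - gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

# best local alignment score by exhaustive enumeration of substring pairs
oracle_local_best <- function(a, b, match = 2, mismatch = -1, gap = 2) {
  subs <- function(s) {
    out <- ""
    n <- nchar(s)
    if (n > 0) for (st in 1:n) for (en in st:n) out <- c(out, substr(s, st, en))
    unique(out)
  }
  best <- 0
  for (sa in subs(a)) for (sb in subs(b))
    best <- max(best, oracle_nw_score(sa, sb, match, mismatch, gap))
  best
}

# score of an explicit gapped alignment pair under match/mismatch/linear gap
score_gapped_pair <- function(x, y, match = 2, mismatch = -1, gap = 2) {
  xc <- strsplit(x, "")[[1]]; yc <- strsplit(y, "")[[1]]
  s <- 0
  for (k in seq_along(xc)) {
    s <- s + if (xc[k] == "-" || yc[k] == "-") -gap
             else if (xc[k] == yc[k]) match else mismatch
  }
  s
}

all_strings <- function(alphabet, maxlen) {
  out <- ""
  for (L in seq_len(maxlen))
    out <- c(out, do.call(paste0, expand.grid(rep(list(alphabet), L))))
  out
}

# all occurrences of every segment in a query, by direct substring scan
naive_segment_search <- function(segments, query) {
  hits <- list()
  for (sid in seq_len(nrow(segments))) {
    seg <- segments$segment[sid]
    L <- nchar(seg)
    if (L > nchar(query)) next
    for (q in 0:(nchar(query) - L)) {
      if (substr(query, q + 1, q + L) == seg)
        hits[[length(hits) + 1]] <-
          data.frame(segment_id = sid,
                     center_offset = segments$center_offset[sid],
                     query_offset = q, length = L)
    }
  }
  if (length(hits) == 0)
    return(data.frame(segment_id = integer(0), center_offset = integer(0),
                      query_offset = integer(0), length = integer(0)))
  do.call(rbind, hits)
}

# root path string of every keyword-tree node, by BFS over child edges
keyword_tree_paths <- function(tree) {
  paths <- character(length(tree$children))
  paths[1] <- ""
  queue <- 1L
  while (length(queue) > 0) {
    node <- queue[1]; queue <- queue[-1]
    for (ch in names(tree$children[[node]])) {
      child <- tree$children[[node]][[ch]]
      paths[child] <- paste0(paths[node], ch)
      queue <- c(queue, child)
    }
  }
  paths
}

# brute-force failure link: longest proper suffix of the node path that is
# itself a node path (i.e. a prefix of some segment)
oracle_failure_links <- function(tree) {
  paths <- keyword_tree_paths(tree)
  vapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (nchar(p) == 0) return(1L)
    for (drop in 1:nchar(p)) {
      suf <- substr(p, drop + 1, nchar(p))
      hit <- which(paths == suf)
      if (length(hit) > 0) return(hit[1])
    }
    1L
  }, integer(1))
}

# best total anchored length over all valid chains, by exhaustive DFS
oracle_chain_best <- function(matches) {
  if (nrow(matches) == 0) return(0L)
  o <- order(matches$center_offset, matches$query_offset)
  m <- matches[o, , drop = FALSE]
  k <- nrow(m)
  best <- 0L
  rec <- function(last_c, last_q, i, tot) {
    if (tot > best) best <<- tot
    if (i > k) return(invisible())
    for (j in i:k) {
      if (m$center_offset[j] >= last_c && m$query_offset[j] >= last_q)
        rec(m$center_offset[j] + m$length[j],
            m$query_offset[j] + m$length[j], j + 1L, tot + m$length[j])
    }
  }
  rec(0L, 0L, 1L, 0L)
  best
}

# pair value computed directly from the column strings, independent of the
# package's residue-index machinery
oracle_pair_value <- function(test, ref, i, x, y) {
  cx <- substr(test$rows[[x]], i, i)
  cy <- substr(test$rows[[y]], i, i)
  if (cx == "-" && cy == "-") return(0L)
  if (cx == "-" || cy == "-") return(1L)
  ordinal <- function(row, col) {
    sum(strsplit(substr(row, 1, col), "")[[1]] != "-")
  }
  px <- ordinal(test$rows[[x]], i)
  py <- ordinal(test$rows[[y]], i)
  for (rc in ref$segment_columns) {
    rx <- substr(ref$rows[[x]], rc, rc)
    ry <- substr(ref$rows[[y]], rc, rc)
    if (rx != "-" && ry != "-" &&
        ordinal(ref$rows[[x]], rc) == px && ordinal(ref$rows[[y]], rc) == py)
      return(2L)
  }
  0L
}

# SPS by brute-force triple loop over (column, x, y)
oracle_sps <- function(test, ref) {
  ids <- names(test$rows)
  num <- 0L
  for (i in seq_len(test$ncol))
    for (x in ids) for (y in setdiff(ids, x))
      num <- num + oracle_pair_value(test, ref, i, x, y)
  den <- 0L
  for (i in ref$segment_columns)
    for (x in ids) for (y in setdiff(ids, x))
      den <- den + oracle_pair_value(ref, ref, i, x, y)
  num / den
}

# is the tip set a bipartition (split) of the unrooted tree?
is_split <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)
  if (length(out) == 0 || length(tips) <= 1) return(TRUE)
  rt <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  pp <- ape::prop.part(rt)
  labs <- attr(pp, "labels")
  any(vapply(pp, function(p) setequal(labs[p], tips), logical(1)))
}

# random gapped alignment of the given sequences at the given width
random_alignment <- function(seqs, width, segment_columns = NULL) {
  rows <- vapply(seqs, function(s) {
    res <- strsplit(s, "")[[1]]
    pos <- sort(sample(width, length(res)))
    row <- rep("-", width)
    row[pos] <- res
    paste(row, collapse = "")
  }, character(1))
  multiple_alignment(rows, segment_columns = segment_columns)
}
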