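#' Select the center sequence for center-star alignment
#'
#' The center should be the sequence most similar to all others. For highly
#' similar nucleotide data the first sequence is used as the center. For
#' divergent proteins the default is a k-mer vote: the sequence whose
#' distinct k-mers are shared with the other sequences the most; `"exact"`
#' scores every pair with Smith-Waterman and picks the sequence with the
#' largest score sum (quadratic, for small inputs).
#'
#' @param seqs named character vector of residue strings.
#' @param mode `"first"`, `"kmer"` or `"exact"`.
#' @param k k-mer length for the vote (default 3).
#' @param scheme [scoring_scheme] used by `"exact"` mode.
#' @return integer index of the center within `seqs` (ties: smallest index).
#' @export
select_center <- function(seqs, mode = c("first", "kmer", "exact"),
                          k = 3L, scheme = NULL) {
  mode <- match.arg(mode)
  if (length(seqs) == 0) stop("empty sequence list")
  if (mode == "first" || length(seqs) == 1) return(1L)
  if (mode == "kmer") {
    kmers <- lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, 1:(n - k + 1), k:n))
    })
    score <- vapply(seq_along(seqs), function(i) {
      sum(vapply(seq_along(seqs)[-i],
                 function(j) length(intersect(kmers[[i]], kmers[[j]])),
                 integer(1)))
    }, integer(1))
    return(which.max(score))  # which.max takes the first maximum
  }
  if (is.null(scheme)) stop("exact center selection needs a scoring scheme")
  score <- vapply(seq_along(seqs), function(i) {
    sum(vapply(seq_along(seqs)[-i],
               function(j) sw_matrix(seqs[[i]], seqs[[j]], scheme)$score,
               integer(1)))
  }, integer(1))
  which.max(score)
}

#' Gap profiles: the merged inserted-space record of a center-star alignment
#'
#' A gap profile stores, for every center position p (0 = before the first
#' residue), the maximum number of spaces any pairwise alignment inserted
#' after it. Profiles with `max` as the merge form a commutative, associative
#' monoid whose identity is the all-zero profile, so the merge can run as a
#' reduce in any order and partitioning.
#'
#' @param center_id id of the center sequence.
#' @param center_len number of center residues (m).
#' @param ins integer vector of length m+1: `ins[p+1]` = spaces after
#'   position p.
#' @return an object of class `gap_profile`; the final alignment width is
#'   `center_len + sum(ins)`.
#' @export
gap_profile <- function(center_id, center_len, ins = integer(center_len + 1L)) {
  stopifnot(length(ins) == center_len + 1L, all(ins >= 0L))
  structure(list(center_id = center_id, center_len = as.integer(center_len),
                 ins = as.integer(ins)),
            class = "gap_profile")
}

#' @rdname gap_profile
#' @param x a `gap_profile`.
#' @export
profile_width <- function(x) x$center_len + sum(x$ins)

# monoid operation: elementwise max of insertion counts
profile_merge2 <- function(p1, p2) {
  if (p1$center_len != p2$center_len || !identical(p1$center_id, p2$center_id))
    stop("cannot merge gap profiles of different centers")
  gap_profile(p1$center_id, p1$center_len, pmax(p1$ins, p2$ins))
}

#' Merge pairwise insertion records into a gap profile
#'
#' @param records list of [pairwise_record]s whose center side degaps to
#'   `center`.
#' @param center the center residue string.
#' @param center_id id of the center.
#' @return a [gap_profile] with per-position maxima over all records.
#' @export
merge_gap_profiles <- function(records, center, center_id = "center") {
  m <- nchar(center)
  prof <- gap_profile(center_id, m)
  for (rec in records) {
    if (length(rec$center_ins) != m + 1L)
      stop("pairwise record refers to positions outside the center")
    if (degap(rec$aligned_center) != center)
      stop("pairwise record center side does not degap to the center")
    prof <- profile_merge2(prof, gap_profile(center_id, m, rec$center_ins))
  }
  prof
}

# split a record's query row into the residue aligned at each center
# position and the inserted characters after each center position
record_groups <- function(record) {
  cc <- chars(record$aligned_center)
  qq <- chars(record$aligned_seq)
  m <- sum(cc != "-")
  res <- character(m)          # query character aligned to center residue p
  ins <- vector("list", m + 1L)  # query characters inserted after position p
  for (i in seq_along(ins)) ins[[i]] <- character(0)
  p <- 0L
  for (k in seq_along(cc)) {
    if (cc[k] == "-") {
      ins[[p + 1L]] <- c(ins[[p + 1L]], qq[k])
    } else {
      p <- p + 1L
      res[p] <- qq[k]
    }
  }
  list(res = res, ins = ins)
}

#' Project a pairwise record onto a gap profile
#'
#' Expands one sequence's pairwise alignment against the center into a row of
#' the final alignment: each insertion block is padded with gaps up to the
#' profile's count (insertions left-justified within their block).
#'
#' @param record a [pairwise_record] against the profile's center.
#' @param profile the merged [gap_profile].
#' @return a gapped string of width `profile_width(profile)` that degaps to
#'   the record's original sequence.
#' @export
project_row <- function(record, profile) {
  m <- profile$center_len
  if (length(record$center_ins) != m + 1L)
    stop("record inconsistent with profile center length")
  if (any(record$center_ins > profile$ins))
    stop("record inserts more spaces than the profile allows")
  gr <- record_groups(record)
  parts <- character(2L * m + 1L)
  parts[1L] <- paste0(paste(gr$ins[[1L]], collapse = ""),
                      strrep("-", profile$ins[1L] - length(gr$ins[[1L]])))
  for (p in seq_len(m)) {
    parts[2L * p] <- gr$res[p]
    parts[2L * p + 1L] <-
      paste0(paste(gr$ins[[p + 1L]], collapse = ""),
             strrep("-", profile$ins[p + 1L] - length(gr$ins[[p + 1L]])))
  }
  paste(parts, collapse = "")
}

#' Project the center itself under a gap profile
#'
#' @param center the center residue string.
#' @param profile a [gap_profile].
#' @return the center row: its residues with gap blocks exactly at the
#'   profile's insertion points.
#' @export
project_center <- function(center, profile) {
  m <- nchar(center)
  stopifnot(m == profile$center_len)
  cc <- if (m > 0) chars(center) else character(0)
  parts <- character(2L * m + 1L)
  parts[1L] <- strrep("-", profile$ins[1L])
  for (p in seq_len(m)) {
    parts[2L * p] <- cc[p]
    parts[2L * p + 1L] <- strrep("-", profile$ins[p + 1L])
  }
  paste(parts, collapse = "")
}

#' Center-star multiple sequence alignment
#'
#' Two-phase procedure: (1) map a full-length Smith-Waterman alignment of
#' every non-center sequence against the broadcast center and reduce the
#' per-pair inserted-space records into a master gap profile; (2) map each
#' record through [project_row()] under the merged profile. Both phases run
#' on the bundled executor, so the output is identical for any worker count.
#'
#' @param seqs named character vector of residue strings (>= 1).
#' @param scheme a [scoring_scheme]; default chosen from the inferred
#'   alphabet.
#' @param mode center-selection mode, see [select_center()].
#' @param workers number of workers (1 = sequential backend).
#' @param partitions partition count for the executor (defaults to
#'   `workers`).
#' @param pairwise_fun function `(center, seq) -> pairwise_record`; defaults
#'   to [sw_align_full()] with `scheme`. The keyword-tree aligner passes its
#'   own.
#' @return a [multiple_alignment] with rows in input order.
#' @export
center_star_msa <- function(seqs, scheme = NULL,
                            mode = c("kmer", "first", "exact"),
                            workers = 1L, partitions = workers,
                            pairwise_fun = NULL) {
  mode <- match.arg(mode)
  if (length(seqs) == 0) stop("no sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (is.null(scheme)) scheme <- scoring_scheme(infer_alphabet(seqs))
  ci <- select_center(seqs, mode = mode, scheme = scheme)
  center <- seqs[[ci]]
  center_id <- names(seqs)[ci]
  if (is.null(pairwise_fun))
    pairwise_fun <- function(center, s) sw_align_full(center, s, scheme)
  backend <- if (workers > 1L) "workers" else "sequential"
  partitions <- max(1L, as.integer(partitions))
  bc_center <- broadcast(center)

  others <- seqs[-ci]
  records <- pexec_run(plan_collect(plan_map(
    task_plan(unname(others), partitions, backend),
    function(s) pairwise_fun(bc_value(bc_center), s))))

  m <- nchar(center)
  profile <- pexec_run(plan_reduce(plan_map(
    task_plan(records, partitions, backend),
    function(rec) gap_profile(center_id, m, rec$center_ins)),
    profile_merge2, gap_profile(center_id, m)))

  bc_profile <- broadcast(profile)
  proj <- pexec_run(plan_collect(plan_map(
    task_plan(records, partitions, backend),
    function(rec) project_row(rec, bc_value(bc_profile)))))

  rows <- character(length(seqs))
  rows[ci] <- project_center(center, profile)
  if (length(proj) > 0) rows[-ci] <- unlist(proj)
  names(rows) <- names(seqs)
  multiple_alignment(rows)
}
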