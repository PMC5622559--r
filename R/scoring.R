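# residue indices per row: entry (r, col) = ordinal of the residue in row r
# at that column (NA at gaps); this makes "aligned to each other" independent
# of column coordinates
residue_index_matrix <- function(aln) {
  m <- aln_matrix(aln)
  idx <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (r in seq_len(nrow(m))) {
    nongap <- m[r, ] != "-"
    idx[r, nongap] <- seq_len(sum(nongap))
  }
  idx
}

# for each ordered row pair and each residue of row x: the residue ordinal of
# row y it is paired with in a *segment* column of the reference (NA if none)
ref_pair_maps <- function(ref) {
  if (is.null(ref$segment_columns) || length(ref$segment_columns) == 0)
    stop("reference alignment has no segment column annotation")
  idx <- residue_index_matrix(ref)
  n <- nrow(idx)
  segs <- ref$segment_columns
  maps <- vector("list", n)
  for (x in seq_len(n)) {
    maps[[x]] <- vector("list", n)
    for (y in seq_len(n)) {
      if (x == y) next
      map <- rep(NA_integer_, max(idx[x, ], 0L, na.rm = TRUE))
      both <- segs[!is.na(idx[x, segs]) & !is.na(idx[y, segs])]
      map[idx[x, both]] <- idx[y, both]
      maps[[x]][[y]] <- map
    }
    names(maps[[x]]) <- rownames(idx)
  }
  names(maps) <- rownames(idx)
  maps
}

check_same_ids <- function(test, ref) {
  if (!setequal(names(test$rows), names(ref$rows)))
    stop("test and reference alignments contain different sequence ids")
}

#' Pair value of two rows at one test column
#'
#' The elementary quantity of the sum-of-pairs score: for test column `i` and
#' sequences `x`, `y`, the value is 2 when both carry residues that the
#' reference alignment pairs with each other in an annotated segment column,
#' 1 when exactly one of the two test entries is a gap, and 0 otherwise.
#'
#' @param test,ref [multiple_alignment]s over the same sequence ids; `ref`
#'   must carry segment-column annotations.
#' @param i test column (1-based).
#' @param x,y sequence ids (or row indices).
#' @return integer 0, 1 or 2.
#' @export
pair_value <- function(test, ref, i, x, y) {
  check_same_ids(test, ref)
  if (i < 1L || i > test$ncol) stop("column out of range")
  if (is.numeric(x)) x <- names(test$rows)[x]
  if (is.numeric(y)) y <- names(test$rows)[y]
  cx <- substr(test$rows[[x]], i, i)
  cy <- substr(test$rows[[y]], i, i)
  if (xor(cx == "-", cy == "-")) return(1L)
  if (cx == "-" && cy == "-") return(0L)
  px <- sum(chars(substr(test$rows[[x]], 1L, i)) != "-")
  py <- sum(chars(substr(test$rows[[y]], 1L, i)) != "-")
  maps <- ref_pair_maps(ref)
  partner <- maps[[x]][[y]]
  if (px <= length(partner) && !is.na(partner[px]) && partner[px] == py)
    2L else 0L
}

#' Sum-of-pairs score against an annotated reference
#'
#' For every test column i, S_i sums the pair values over all ordered
#' sequence pairs; the score is the ratio of the test's column sum over all M
#' test columns to the reference's own column sum over its M_r segment
#' columns. 1 means the alignment is identical to the reference on the
#' annotated segments.
#'
#' @inheritParams pair_value
#' @return an object of class `sps_report`: list with `N`, `M`, `M_r`, the
#'   per-column scores `S` and `S_r`, and the scalar scores `sps` and `cs`.
#' @export
sps <- function(test, ref) {
  check_same_ids(test, ref)
  ord <- names(ref$rows)
  tidx <- residue_index_matrix(test)[ord, , drop = FALSE]
  maps <- ref_pair_maps(ref)
  n <- length(ord)
  S <- column_pair_sums(tidx, maps, seq_len(test$ncol))
  ridx <- residue_index_matrix(ref)[ord, , drop = FALSE]
  S_r <- column_pair_sums(ridx, maps, ref$segment_columns)
  denom <- sum(S_r)
  if (denom == 0) stop("undefined score: reference segment pair sum is zero")
  structure(list(N = n, M = test$ncol, M_r = length(ref$segment_columns),
                 S = S, S_r = S_r, sps = sum(S) / denom,
                 cs = cs(test, ref)),
            class = "sps_report")
}

# S_i for the given columns of an alignment described by its residue-index
# matrix, scored against the reference pair maps
column_pair_sums <- function(idx, maps, columns) {
  n <- nrow(idx)
  S <- numeric(length(columns))
  for (ci in seq_along(columns)) {
    i <- columns[ci]
    col <- idx[, i]
    tot <- 0L
    for (x in seq_len(n)) {
      for (y in seq_len(n)) {
        if (x == y) next
        if (is.na(col[x]) && is.na(col[y])) next
        if (is.na(col[x]) || is.na(col[y])) { tot <- tot + 1L; next }
        partner <- maps[[x]][[y]]
        if (col[x] <= length(partner) && !is.na(partner[col[x]]) &&
            partner[col[x]] == col[y]) tot <- tot + 2L
      }
    }
    S[ci] <- tot
  }
  S
}

#' @export
print.sps_report <- function(x, ...) {
  cat(sprintf("sps_report: N=%d M=%d M_r=%d  SPS=%.4f  CS=%.4f\n",
              x$N, x$M, x$M_r, x$sps, x$cs))
  invisible(x)
}

#' Column score against an annotated reference
#'
#' Fraction of the reference's segment columns that the test alignment
#' reproduces exactly across all sequences: some test column must pair the
#' very same residues (and gaps) in every row. One badly misaligned sequence
#' drives the score from 1 to 0, so it behaves almost binarily in practice.
#'
#' @inheritParams pair_value
#' @return numeric in \[0, 1\].
#' @export
cs <- function(test, ref) {
  check_same_ids(test, ref)
  if (is.null(ref$segment_columns) || length(ref$segment_columns) == 0)
    stop("reference alignment has no segment column annotation")
  ord <- names(ref$rows)
  tidx <- residue_index_matrix(test)[ord, , drop = FALSE]
  ridx <- residue_index_matrix(ref)[ord, , drop = FALSE]
  sig <- function(m) apply(m, 2, function(col)
    paste(ifelse(is.na(col), ".", col), collapse = "|"))
  test_sigs <- sig(tidx)
  ref_sigs <- sig(ridx[, ref$segment_columns, drop = FALSE])
  mean(ref_sigs %in% test_sigs)
}

#' Average sum-of-pairs score over alignment pairs
#'
#' @param pairs non-empty list of `list(test = , ref = )` alignment pairs.
#' @return arithmetic mean of the per-pair SPS values.
#' @export
avg_sps <- function(pairs) {
  if (length(pairs) == 0) stop("empty list of alignment pairs")
  mean(vapply(pairs, function(p) sps(p$test, p$ref)$sps, numeric(1)))
}
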