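#' Scoring schemes for pairwise alignment
#'
#' A scheme bundles a substitution function s(a,b), realized as a full lookup
#' matrix over the alphabet, and a linear gap penalty: a gap of length k costs
#' W_k = k * gap. Defaults are match +2 / mismatch -1 for nucleotides and
#' BLOSUM62 for proteins, with gap opening cost 2 per gap column in both
#' cases. Wildcards (`N`, `X`) score 0 against every residue.
#'
#' @param type `"dna"`, `"rna"` or `"protein"`.
#' @param match,mismatch integer scores used when `matrix` is `NULL` (ignored
#'   for the protein default, which loads BLOSUM62).
#' @param gap positive integer per-column gap penalty (the g in W_k = k*g).
#' @param matrix optional full substitution matrix with residue dimnames,
#'   overriding the defaults.
#' @return an object of class `scoring_scheme` with elements `type`, `submat`
#'   (integer lookup matrix) and `gap`.
#' @export
scoring_scheme <- function(type = c("dna", "rna", "protein"),
                           match = 2L, mismatch = -1L, gap = 2L,
                           matrix = NULL) {
  type <- match.arg(type)
  gap <- as.integer(gap)
  if (is.na(gap) || gap <= 0L) stop("gap penalty must be a positive integer")
  ab <- alphabet_chars(type)
  wildcard <- if (type == "protein") "X" else "N"
  if (is.null(matrix)) {
    if (type == "protein") {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      full <- e$BLOSUM62
      core <- setdiff(ab, wildcard)
      submat <- full[core, core]
    } else {
      core <- setdiff(ab, wildcard)
      submat <- matrix(as.integer(mismatch), length(core), length(core),
                       dimnames = list(core, core))
      diag(submat) <- as.integer(match)
    }
  } else {
    core <- setdiff(ab, wildcard)
    if (!all(core %in% rownames(matrix)) || !all(core %in% colnames(matrix)))
      stop("substitution matrix must cover the full ", type, " alphabet")
    submat <- matrix[core, core]
  }
  # add a zero-scoring wildcard row/column
  full <- matrix(0L, length(ab), length(ab), dimnames = list(ab, ab))
  full[rownames(submat), colnames(submat)] <- as.integer(submat)
  full[wildcard, ] <- 0L
  full[, wildcard] <- 0L
  structure(list(type = type, submat = full, gap = gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme:", x$type, "| linear gap penalty g =", x$gap, "\n")
  invisible(x)
}

# substitution score for two residue characters
sub_score <- function(scheme, a, b) scheme$submat[a, b]

#' Smith-Waterman scoring matrix
#'
#' Fills the (n+1) x (m+1) local-alignment matrix H with zero first row and
#' column and the zero-floored recurrence over match/mismatch and gap moves.
#' With the linear penalty W_k = k*g the maxima over all gap lengths collapse
#' to single-step moves: H itself already dominates longer gaps by induction.
#'
#' @param A,B residue strings over the scheme's alphabet.
#' @param scheme a [scoring_scheme].
#' @return an object of class `sw_matrix`: list with `H` (integer matrix,
#'   dimnames are "0" plus residue positions), `best` (the (i,j) cell of the
#'   maximum, smallest lexicographically among ties) and `score`.
#' @export
sw_matrix <- function(A, B, scheme) {
  a <- if (nzchar(A)) chars(A) else character(0)
  b <- if (nzchar(B)) chars(B) else character(0)
  bad <- setdiff(c(a, b), rownames(scheme$submat))
  if (length(bad) > 0)
    stop("residues outside scheme alphabet: ", paste(bad, collapse = ","))
  n <- length(a); m <- length(b)
  g <- scheme$gap
  H <- matrix(0L, n + 1L, m + 1L)
  if (n > 0 && m > 0) {
    for (i in seq_len(n)) {
      srow <- scheme$submat[a[i], b]
      prev <- H[i, ]
      cur <- integer(m + 1L)
      for (j in seq_len(m)) {
        v <- prev[j] + srow[j]
        u <- prev[j + 1L] - g
        if (u > v) v <- u
        l <- cur[j] - g
        if (l > v) v <- l
        if (v < 0L) v <- 0L
        cur[j + 1L] <- v
      }
      H[i + 1L, ] <- cur
    }
  }
  score <- max(H)
  cand <- which(H == score, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  best <- cand[1, ] - 1L  # 0-based: number of residues consumed
  structure(list(H = H, best = unname(best), score = score, n = n, m = m),
            class = "sw_matrix")
}

#' Traceback of a Smith-Waterman matrix
#'
#' Starts at the highest-scoring cell and walks back until a zero cell,
#' preferring diagonal, then vertical (gap in B), then horizontal (gap in A)
#' moves for determinism.
#'
#' @param M an [sw_matrix].
#' @param A,B the residue strings `M` was computed from.
#' @param scheme the [scoring_scheme] used.
#' @return list with the locally aligned gapped strings `aligned_A` and
#'   `aligned_B`, `score`, and the 1-based residue coordinate ranges
#'   `a_range`, `b_range` of the local core (`c(start, end)`, empty range
#'   `start > end` when the best score is 0).
#' @export
sw_traceback <- function(M, A, B, scheme) {
  a <- if (nzchar(A)) chars(A) else character(0)
  b <- if (nzchar(B)) chars(B) else character(0)
  H <- M$H; g <- scheme$gap
  i <- M$best[1]; j <- M$best[2]
  a_end <- i; b_end <- j
  ra <- character(0); rb <- character(0)
  while (i > 0 && j > 0 && H[i + 1L, j + 1L] > 0L) {
    h <- H[i + 1L, j + 1L]
    if (h == H[i, j] + scheme$submat[a[i], b[j]]) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1L] - g) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L
    } else if (h == H[i + 1L, j] - g) {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L
    } else {
      stop("inconsistent Smith-Waterman matrix")  # M not from (A, B, scheme)
    }
  }
  if (M$score == 0L) {
    a_start <- M$n + 1L; a_end <- M$n
    b_start <- M$m + 1L; b_end <- M$m
    ra <- rb <- character(0)
  } else {
    a_start <- i + 1L; b_start <- j + 1L
  }
  list(aligned_A = paste(ra, collapse = ""),
       aligned_B = paste(rb, collapse = ""),
       score = M$score,
       a_range = c(a_start, a_end), b_range = c(b_start, b_end))
}

# derive insertion-count vectors from a gapped pair: ins[p+1] = number of
# gap columns in this row immediately after its residue p (p = 0: before
# the first residue)
insertions_from_row <- function(gapped) {
  cc <- chars(gapped)
  nres <- sum(cc != "-")
  ins <- integer(nres + 1L)
  p <- 0L
  for (ch in cc) {
    if (ch == "-") ins[p + 1L] <- ins[p + 1L] + 1L else p <- p + 1L
  }
  ins
}

#' Construct a pairwise record
#'
#' A pairwise record holds one sequence aligned against the center: the two
#' equal-length gapped strings plus, for each side, the positions and counts
#' of inserted spaces (`ins[p+1]` = gaps after residue `p`; `p = 0` means
#' before the first residue). These per-pair records are what the center-star
#' reduce step merges into a gap profile.
#'
#' @param aligned_center,aligned_seq equal-length gapped strings.
#' @param score integer alignment score.
#' @param core optional list with the local-core coordinate ranges.
#' @return an object of class `pairwise_record`.
#' @export
pairwise_record <- function(aligned_center, aligned_seq, score, core = NULL) {
  if (nchar(aligned_center) != nchar(aligned_seq))
    stop("aligned strings must have equal length")
  structure(list(score = as.integer(score),
                 aligned_center = aligned_center,
                 aligned_seq = aligned_seq,
                 center_ins = insertions_from_row(aligned_center),
                 seq_ins = insertions_from_row(aligned_seq),
                 core = core),
            class = "pairwise_record")
}

#' Full-length pairwise alignment via a Smith-Waterman core
#'
#' Aligns the local Smith-Waterman core and completes it to a full-length
#' pairwise alignment by placing the unaligned flanks end-gap-free: the
#' shorter flank is padded with gaps at the outer edge, and flank residues
#' are not scored.
#'
#' @param A center-side residue string.
#' @param B other residue string.
#' @param scheme a [scoring_scheme].
#' @return a [pairwise_record]; degapping `aligned_center` recovers `A` and
#'   degapping `aligned_seq` recovers `B`.
#' @export
sw_align_full <- function(A, B, scheme) {
  if (!nzchar(A) && !nzchar(B)) stop("both sequences empty")
  M <- sw_matrix(A, B, scheme)
  tb <- sw_traceback(M, A, B, scheme)
  la <- tb$a_range[1] - 1L; lb <- tb$b_range[1] - 1L
  ra <- nchar(A) - tb$a_range[2]; rb <- nchar(B) - tb$b_range[2]
  wl <- max(la, lb); wr <- max(ra, rb)
  leftA <- paste0(strrep("-", wl - la), substr(A, 1L, la))
  leftB <- paste0(strrep("-", wl - lb), substr(B, 1L, lb))
  rightA <- paste0(substr(A, tb$a_range[2] + 1L, nchar(A)), strrep("-", wr - ra))
  rightB <- paste0(substr(B, tb$b_range[2] + 1L, nchar(B)), strrep("-", wr - rb))
  rec <- pairwise_record(paste0(leftA, tb$aligned_A, rightA),
                         paste0(leftB, tb$aligned_B, rightB),
                         score = tb$score,
                         core = list(a_range = tb$a_range,
                                     b_range = tb$b_range))
  stopifnot(degap(rec$aligned_center) == A, degap(rec$aligned_seq) == B)
  rec
}
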