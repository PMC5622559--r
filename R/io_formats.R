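#' Multiple sequence alignment container
#'
#' An alignment is a set of equal-length gapped rows (gap character `-`)
#' together with an optional annotation of *segment columns*: the columns of
#' a reference alignment that are considered reliably aligned and against
#' which the sum-of-pairs and column scores are computed.
#'
#' @param rows named character vector of gapped rows (names are sequence ids).
#' @param segment_columns optional integer vector of 1-based column indices
#'   annotated as reference segments.
#' @return an object of class `multiple_alignment` with elements `rows`,
#'   `ncol` and `segment_columns`.
#' @export
multiple_alignment <- function(rows, segment_columns = NULL) {
  rows <- unlist(rows)
  if (length(rows) == 0) stop("alignment must contain at least one row")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  if (anyDuplicated(names(rows)))
    stop("duplicate row ids: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ","))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1)
    stop("unequal row lengths: ", paste(unique(widths), collapse = ","))
  nc <- widths[[1]]
  if (!is.null(segment_columns)) {
    segment_columns <- sort(unique(as.integer(segment_columns)))
    if (any(segment_columns < 1L) || any(segment_columns > nc))
      stop("segment columns outside [1, ", nc, "]")
  }
  structure(list(rows = rows, ncol = nc, segment_columns = segment_columns),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment:", length(x$rows), "rows x", x$ncol, "columns")
  if (!is.null(x$segment_columns))
    cat(";", length(x$segment_columns), "segment columns")
  cat("\n")
  show <- utils::head(x$rows, 6)
  for (i in seq_along(show))
    cat(sprintf("  %-12s %s\n", names(show)[i],
                if (nchar(show[i]) > 60) paste0(substr(show[i], 1, 57), "...")
                else show[i]))
  if (length(x$rows) > 6) cat("  ...\n")
  invisible(x)
}

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  m
}

#' Read sequences from a FASTA file
#'
#' Reads unaligned sequences: residues are upcased, gap characters (`-`, `.`)
#' are stripped, and ids are required to be unique. The alphabet is validated
#' against the declared (or inferred) sequence type; `N`/`X` wildcards are
#' accepted.
#'
#' @param path FASTA file path.
#' @param alphabet `"auto"` (default) infers DNA/RNA/protein from content.
#' @return named character vector of residue strings, with a `descriptions`
#'   attribute carrying header text after the id, and an `alphabet` attribute.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "rna", "protein")) {
  alphabet <- match.arg(alphabet)
  seqs <- read_fasta_raw(path)
  seqs[] <- gsub("[-.]", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty record(s) after gap stripping: ",
         paste(names(seqs)[empty], collapse = ","))
  if (alphabet == "auto") alphabet <- infer_alphabet(seqs)
  check_alphabet(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  seqs
}

# shared low-level FASTA reader: upcase, '.'->'-', unique non-empty ids
read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("no FASTA records in '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids)))
    stop("record ", which(!nzchar(ids))[1], ": empty FASTA header")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings (gapped or not).
#' @param path output path.
#' @return invisibly, `path`. Lines are wrapped at 80 columns.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Gap characters are kept (`.` normalized to `-`); all rows must have equal
#' length.
#'
#' @inheritParams read_fasta
#' @param segment_columns optional 1-based segment column annotation to attach.
#' @return a [multiple_alignment].
#' @export
read_alignment_fasta <- function(path, segment_columns = NULL) {
  seqs <- read_fasta_raw(path)
  attr(seqs, "descriptions") <- NULL
  multiple_alignment(seqs, segment_columns = segment_columns)
}

#' Write a [multiple_alignment] to aligned FASTA
#'
#' @param aln a [multiple_alignment].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (any(nchar(aln$rows) != aln$ncol))
    stop("alignment invariant violated: unequal row lengths")
  write_fasta(aln$rows, path)
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ","))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("Newick parse error in '", path, "'")
  tr
}

#' Read segment-column annotations
#'
#' The `.seg` file format is one line of whitespace-separated 0-based column
#' indices; this converts to the 1-based indices used internally.
#'
#' @param path segment file path.
#' @return integer vector of 1-based column indices.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- scan(path, what = integer(), quiet = TRUE)
  if (length(x) == 0) stop("no segment columns in '", path, "'")
  x + 1L
}

#' Write segment-column annotations (0-based on disk)
#'
#' @param segment_columns integer vector of 1-based column indices.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segment_columns, path) {
  writeLines(paste(segment_columns - 1L, collapse = " "), path)
  invisible(path)
}
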