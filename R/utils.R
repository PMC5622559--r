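# internal helpers shared across modules

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Residue alphabets
#'
#' Character vectors of the residue symbols accepted for each sequence type,
#' including the wildcard (`N` for nucleotides, `X` for amino acids).
#'
#' @param type one of `"dna"`, `"rna"`, `"protein"`.
#' @return character vector of allowed residue symbols.
#' @export
alphabet_chars <- function(type = c("dna", "rna", "protein")) {
  type <- match.arg(type)
  switch(type,
    dna = c("A", "C", "G", "T", "N"),
    rna = c("A", "C", "G", "U", "N"),
    protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"))
}

# infer the alphabet of a set of residue strings
infer_alphabet <- function(seqs) {
  residues <- unique(chars(paste(seqs, collapse = "")))
  residues <- setdiff(residues, "-")
  if (all(residues %in% c("A", "C", "G", "T", "N"))) return("dna")
  if (all(residues %in% c("A", "C", "G", "U", "N"))) return("rna")
  if (all(residues %in% alphabet_chars("protein"))) return("protein")
  stop("cannot infer alphabet: residues ",
       paste(setdiff(residues, alphabet_chars("protein")), collapse = ","),
       " fit no supported alphabet")
}

check_alphabet <- function(seqs, type) {
  allowed <- c(alphabet_chars(type), "-")
  for (i in seq_along(seqs)) {
    res <- unique(chars(seqs[[i]]))
    bad <- setdiff(res, allowed)
    if (length(bad) > 0)
      stop("record '", names(seqs)[i], "': residues ",
           paste(bad, collapse = ","), " outside ", type, " alphabet")
  }
  invisible(TRUE)
}
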