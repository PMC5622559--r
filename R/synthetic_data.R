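# draw a substitute residue for `base`: uniform over the other nucleotides,
# or BLOSUM62-biased (prob ~ exp(score/2) over the 19 alternatives) for
# amino acids
draw_substitute <- function(base, type, submat = NULL) {
  if (type == "protein") {
    aas <- setdiff(alphabet_chars("protein"), c("X", base))
    w <- exp(submat[base, aas] / 2)
    sample(aas, 1L, prob = w / sum(w))
  } else {
    sample(setdiff(alphabet_chars(type)[1:4], base), 1L)
  }
}

# evolve one member from the ancestor; returns the member row laid out in
# ancestor coordinates plus its edit script
evolve_member <- function(anc, type, sub_rate, indel_rate, max_indel_len,
                          submat = NULL) {
  m <- length(anc)
  res <- anc                 # residue at each ancestor site ("-" if deleted)
  ins <- vector("list", m + 1L)  # insertion after each site (0 = before 1st)
  for (i in seq_len(m + 1L)) ins[[i]] <- character(0)
  script <- list()
  covered <- logical(m)      # sites consumed by an earlier deletion
  for (p in seq_len(m)) {
    if (covered[p]) next
    if (stats::runif(1) < sub_rate) {
      newb <- draw_substitute(anc[p], type, submat)
      res[p] <- newb
      script[[length(script) + 1L]] <- list(pos = p, op = "sub",
                                            payload = newb)
    }
    if (stats::runif(1) < indel_rate) {
      len <- sample.int(max_indel_len, 1L)
      if (stats::runif(1) < 0.5) {
        sites <- p:min(p + len - 1L, m)
        sites <- sites[!covered[sites]]
        res[sites] <- "-"
        covered[sites] <- TRUE
        script[[length(script) + 1L]] <- list(pos = p, op = "del",
                                              payload = as.character(length(sites)))
      } else {
        abc <- if (type == "protein") setdiff(alphabet_chars(type), "X")
               else alphabet_chars(type)[1:4]
        payload <- paste(sample(abc, len, replace = TRUE), collapse = "")
        ins[[p + 1L]] <- chars(payload)
        script[[length(script) + 1L]] <- list(pos = p, op = "ins",
                                              payload = payload)
      }
    }
  }
  script <- if (length(script))
    data.frame(pos = vapply(script, `[[`, integer(1), "pos"),
               op = vapply(script, `[[`, character(1), "op"),
               payload = vapply(script, `[[`, character(1), "payload"),
               stringsAsFactors = FALSE)
  else data.frame(pos = integer(0), op = character(0), payload = character(0))
  list(res = res, ins = ins, script = script)
}

#' Replay an edit script against an ancestor sequence
#'
#' @param ancestor residue string.
#' @param script data.frame with columns `pos` (1-based ancestor site), `op`
#'   (`sub`, `ins`, `del`) and `payload` (new residue, inserted string, or
#'   deletion length).
#' @return the derived residue string.
#' @export
apply_edits <- function(ancestor, script) {
  anc <- chars(ancestor)
  res <- anc
  ins <- rep("", length(anc) + 1L)
  for (r in seq_len(nrow(script))) {
    p <- script$pos[r]
    switch(script$op[r],
      sub = { res[p] <- script$payload[r] },
      del = { res[p:min(p + as.integer(script$payload[r]) - 1L,
                        length(anc))] <- "-" },
      ins = { ins[p + 1L] <- script$payload[r] },
      stop("unknown edit op: ", script$op[r]))
  }
  degap(paste0(paste0(ins[1L],
                      paste0(res, ins[-1L], collapse = "")), collapse = ""))
}

# assemble the ground-truth alignment from per-member layouts
build_truth <- function(members_layout, anc, ids) {
  m <- length(anc)
  ins_max <- integer(m + 1L)
  for (ml in members_layout)
    ins_max <- pmax(ins_max, lengths(ml$ins))
  rows <- vapply(members_layout, function(ml) {
    parts <- character(2L * m + 1L)
    parts[1L] <- paste0(paste(ml$ins[[1L]], collapse = ""),
                        strrep("-", ins_max[1L] - length(ml$ins[[1L]])))
    for (p in seq_len(m)) {
      parts[2L * p] <- ml$res[p]
      parts[2L * p + 1L] <-
        paste0(paste(ml$ins[[p + 1L]], collapse = ""),
               strrep("-", ins_max[p + 1L] - length(ml$ins[[p + 1L]])))
    }
    paste(parts, collapse = "")
  }, character(1))
  names(rows) <- ids
  multiple_alignment(rows, segment_columns = seq_len(nchar(rows[[1]])))
}

family_fixture <- function(ancestor, members, truth, edit_scripts,
                           clade_labels = NULL) {
  stopifnot(all(vapply(seq_along(members),
                       function(i) degap(truth$rows[[i]]) == members[[i]],
                       logical(1))))
  structure(list(ancestor = ancestor, members = members, truth = truth,
                 edit_scripts = edit_scripts, clade_labels = clade_labels),
            class = "family_fixture")
}

#' @export
print.family_fixture <- function(x, ...) {
  cat("family_fixture:", length(x$members), "members, ancestor length",
      nchar(x$ancestor), "| truth", x$truth$ncol, "columns\n")
  invisible(x)
}

#' Simulate a family of similar DNA sequences with known truth
#'
#' Emulates sets of highly similar long nucleotide sequences (mitochondrial
#' genome style): a uniform random ancestor, and members derived by per-site
#' substitution (probability `sub_rate`, uniform over the other bases) and
#' rare short indels (per-site probability `indel_rate`, length uniform on 1
#' to `max_indel_len`, never nested inside an earlier indel). The true
#' alignment and per-member edit scripts are returned alongside the
#' sequences; every truth column is annotated as a reference segment.
#'
#' @param n number of members.
#' @param m ancestor length.
#' @param sub_rate per-site substitution probability (default 0.01, the ~1%
#'   divergence regime of within-species genome data).
#' @param indel_rate per-site indel probability (default 0.001).
#' @param max_indel_len maximum indel length (default 3).
#' @param seed integer seed; the fixture is byte-identical across reruns.
#' @return an object of class `family_fixture` with `ancestor`, `members`,
#'   `truth` ([multiple_alignment]), `edit_scripts` and `clade_labels`.
#' @export
generate_dna_family <- function(n, m, sub_rate = 0.01, indel_rate = 0.001,
                                max_indel_len = 3L, seed = 1L) {
  generate_family(n, m, sub_rate, indel_rate, max_indel_len, seed,
                  type = "dna")
}

#' Simulate a protein family with known truth
#'
#' As [generate_dna_family()], over the 20-letter amino-acid alphabet, with
#' substitutions biased toward high-scoring BLOSUM62 exchanges. Defaults
#' emulate divergent protein families (higher substitution and indel rates
#' than the DNA regime).
#'
#' @inheritParams generate_dna_family
#' @param sub_rate per-site substitution probability (default 0.05).
#' @param indel_rate per-site indel probability (default 0.005).
#' @return a `family_fixture`.
#' @export
generate_protein_family <- function(n, m, sub_rate = 0.05,
                                    indel_rate = 0.005, max_indel_len = 3L,
                                    seed = 1L) {
  generate_family(n, m, sub_rate, indel_rate, max_indel_len, seed,
                  type = "protein")
}

generate_family <- function(n, m, sub_rate, indel_rate, max_indel_len, seed,
                            type) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)")
  with_seed(seed, {
    submat <- if (type == "protein") scoring_scheme("protein")$submat
              else NULL
    abc <- if (type == "protein") setdiff(alphabet_chars(type), "X")
           else alphabet_chars(type)[1:4]
    anc <- sample(abc, m, replace = TRUE)
    layouts <- lapply(seq_len(n), function(i)
      evolve_member(anc, type, sub_rate, indel_rate, max_indel_len, submat))
    ids <- paste0("s", seq_len(n))
    truth <- build_truth(layouts, anc, ids)
    members <- stats::setNames(degap(truth$rows), ids)
    scripts <- stats::setNames(lapply(layouts, `[[`, "script"), ids)
    family_fixture(paste(anc, collapse = ""), members, truth, scripts)
  })
}

#' Simulate clade-structured DNA families
#'
#' k clade ancestors diverge from a common root by per-site substitution at
#' `between_rate`; members diverge from their clade ancestor at
#' `within_rate`. Substitution-only, so all sequences share the root's
#' length and the ground-truth alignment is gap-free; `clade_labels` gives
#' the generating clade of each member.
#'
#' @param k number of clades.
#' @param per_clade members per clade.
#' @param m sequence length.
#' @param within_rate within-clade per-site substitution rate.
#' @param between_rate root-to-clade-ancestor rate; must exceed
#'   `within_rate`.
#' @param seed integer seed.
#' @return a `family_fixture` with `clade_labels` populated.
#' @export
generate_clades <- function(k, per_clade, m, within_rate = 0.01,
                            between_rate = 0.1, seed = 1L) {
  if (between_rate <= within_rate)
    stop("between_rate must exceed within_rate")
  if (k < 1 || per_clade < 1 || m < 1) stop("k, per_clade, m must be >= 1")
  with_seed(seed, {
    root <- sample(alphabet_chars("dna")[1:4], m, replace = TRUE)
    mutate <- function(x, rate) {
      hit <- stats::runif(length(x)) < rate
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      x
    }
    rows <- character(0); labels <- integer(0); scripts <- list()
    for (ci in seq_len(k)) {
      canc <- mutate(root, between_rate)
      for (j in seq_len(per_clade)) {
        mem <- mutate(canc, within_rate)
        rows <- c(rows, paste(mem, collapse = ""))
        labels <- c(labels, ci)
        diffs <- which(mem != root)
        scripts[[length(scripts) + 1L]] <-
          data.frame(pos = diffs, op = rep("sub", length(diffs)),
                     payload = mem[diffs], stringsAsFactors = FALSE)
      }
    }
    ids <- paste0("s", seq_along(rows))
    names(rows) <- ids
    truth <- multiple_alignment(rows, segment_columns = seq_len(m))
    family_fixture(paste(root, collapse = ""),
                   stats::setNames(rows, ids), truth,
                   stats::setNames(scripts, ids),
                   clade_labels = stats::setNames(labels, ids))
  })
}
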