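# Multiple sequence alignment handling: the alignment columns are the shared
# coordinate frame for interaction profiles. Columns are 1-based throughout.

#' Construct an MSA object
#'
#' @param ids sequence identifiers (unique).
#' @param seqs gapped sequences, all the same length; gaps are \code{"-"}
#'   (\code{"."} is accepted and normalized).
#' @return list of class \code{"MSA"} with \code{ids}, \code{seqs},
#'   \code{n_columns}.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("ragged alignment: row '", ids[which(lens != lens[1])[1]],
         "' has length ", lens[lens != lens[1]][1], ", expected ", lens[1])
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 n_columns = lens[1]), class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$ids), x$n_columns))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file.
#' @param format \code{"fasta"} (aligned FASTA) or \code{"clustal"}.
#' @return an \code{\link{msa}} object.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- if (format == "fasta") Biostrings::readAAStringSet(path)
  else Biostrings::unmasked(Biostrings::readAAMultipleAlignment(
    path, format = "clustal"))
  msa(names(seqs), as.character(seqs))
}

#' Map a structure chain onto an alignment row
#'
#' The k-th residue of the chain maps to the column of the k-th non-gap
#' character of the row. The ungapped row must equal the chain sequence
#' (\code{X} in either sequence matches anything).
#'
#' @param chain_seq one-letter chain sequence (single string).
#' @param row gapped alignment row (single string).
#' @return integer vector: 1-based column index per chain residue.
#' @export
map_structure_to_row <- function(chain_seq, row) {
  row <- toupper(gsub(".", "-", row, fixed = TRUE))
  cols <- which(strsplit(row, "")[[1]] != "-")
  if (!length(cols)) stop("alignment row is all gaps")
  ungapped <- strsplit(gsub("-", "", row), "")[[1]]
  cs <- strsplit(toupper(chain_seq), "")[[1]]
  if (length(cs) != length(ungapped))
    stop(sprintf("chain has %d residues but alignment row has %d non-gap characters",
                 length(cs), length(ungapped)))
  mism <- which(cs != ungapped & cs != "X" & ungapped != "X")
  if (length(mism))
    stop(sprintf("sequence mismatch at residue %d: chain '%s' vs row '%s'",
                 mism[1], cs[mism[1]], ungapped[mism[1]]))
  cols
}

#' Residue-to-column map for a complex
#'
#' Combines \code{\link{chain_sequence}} and
#' \code{\link{map_structure_to_row}} into a named lookup from residue keys to
#' alignment columns. Multi-chain pockets map each chain to its own row and
#' concatenate with a per-chain column offset.
#'
#' @param record a \code{ComplexRecord}.
#' @param aln an \code{\link{msa}} object.
#' @param row_id alignment row id(s), one per chain mapped.
#' @param chains chain ids to map; default first chain.
#' @return named integer vector (names = residue keys, values = columns), with
#'   attribute \code{n_columns}.
#' @export
column_map <- function(record, aln, row_id, chains = NULL) {
  if (is.null(chains)) chains <- record$protein$chain[1]
  stopifnot(length(row_id) == length(chains))
  out <- integer(0); offset <- 0L
  for (k in seq_along(chains)) {
    cs <- chain_sequence(record, chains[k])
    if (!row_id[k] %in% aln$ids)
      stop("alignment has no row '", row_id[k], "'")
    cols <- map_structure_to_row(cs$sequence, aln$seqs[[row_id[k]]]) + offset
    out <- c(out, stats::setNames(cols, cs$residues))
    offset <- offset + aln$n_columns
  }
  structure(out, n_columns = offset)
}

# ---- center-star aligner (fixture-scale substitute for a full MSA tool) -----

.pairwise_align <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  list(score = Biostrings::score(al),
       a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

#' Center-star progressive alignment
#'
#' Small deterministic multiple aligner used to build test fixtures: the
#' center sequence is the one maximizing the summed pairwise BLOSUM62
#' alignment score; the others are merged in input order under the
#' "once a gap, always a gap" rule. Not a replacement for a production MSA
#' tool; adequate for the near-identical pocket sequences the fixtures use.
#'
#' @param sequences named character vector of ungapped sequences (>= 2).
#' @return an \code{\link{msa}} object.
#' @export
center_star_align <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(sequences))) stop("empty sequence in input")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  scores <- matrix(0, n, n)
  cache <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- .pairwise_align(sequences[[i]], sequences[[j]])
    scores[i, j] <- scores[j, i] <- al$score
    cache[[paste(i, j)]] <- al
  }
  center <- which.max(rowSums(scores))
  aligned_center <- sequences[[center]]
  rows <- stats::setNames(as.list(rep(NA_character_, n)), NULL)
  rows[[center]] <- aligned_center
  others <- setdiff(seq_len(n), center)
  for (j in others) {
    i <- min(center, j); k <- max(center, j)
    al <- cache[[paste(i, k)]]
    pc <- if (center < j) al$a else al$b   # center side of the pairwise alignment
    po <- if (center < j) al$b else al$a
    # merge pairwise (pc, po) into the growing center row aligned_center
    gi <- 1L; pi_ <- 1L
    gchars <- strsplit(aligned_center, "")[[1]]
    pchars <- strsplit(pc, "")[[1]]; ochars <- strsplit(po, "")[[1]]
    new_center <- character(0); new_other <- character(0)
    ins_existing <- integer(0)   # per new column: source column in old rows, 0 = gap
    while (gi <= length(gchars) || pi_ <= length(pchars)) {
      gc <- if (gi <= length(gchars)) gchars[gi] else NULL
      pcch <- if (pi_ <= length(pchars)) pchars[pi_] else NULL
      if (!is.null(gc) && gc == "-" && (is.null(pcch) || pcch != "-")) {
        new_center <- c(new_center, "-"); new_other <- c(new_other, "-")
        ins_existing <- c(ins_existing, gi); gi <- gi + 1L
      } else if (!is.null(pcch) && pcch == "-" && (is.null(gc) || gc != "-")) {
        new_center <- c(new_center, "-"); new_other <- c(new_other, ochars[pi_])
        ins_existing <- c(ins_existing, 0L); pi_ <- pi_ + 1L
      } else {
        new_center <- c(new_center, gc); new_other <- c(new_other, ochars[pi_])
        ins_existing <- c(ins_existing, gi); gi <- gi + 1L; pi_ <- pi_ + 1L
      }
    }
    for (r in seq_len(n)) {
      if (r == j || is.na(rows[[r]][1])) next
      old <- strsplit(rows[[r]], "")[[1]]
      rows[[r]] <- paste(ifelse(ins_existing == 0L, "-", old[pmax(ins_existing, 1)]),
                         collapse = "")
    }
    aligned_center <- paste(new_center, collapse = "")
    rows[[center]] <- aligned_center
    rows[[j]] <- paste(new_other, collapse = "")
  }
  msa(ids, unlist(rows))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an \code{\link{msa}} object.
#' @param path output path.
#' @export
write_msa_fasta <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$ids))
    writeLines(c(paste0(">", aln$ids[i]), aln$seqs[[i]]), con)
  invisible(path)
}
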