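# Atom-pair (AP) topology descriptors and compound similarity.
#
# Atom type = (element, number of heavy-atom neighbours, pi-electron count),
# one descriptor per unordered pair of heavy atoms in the same connected
# component, keyed additionally by the bond-count (topological) distance.

#' Build a compound graph from SMILES or an SDF/MOL block
#'
#' Chemistry perception (SMILES parsing, kekulization) is delegated to
#' OpenBabel via ChemmineR/ChemmineOB; the graph keeps heavy atoms only.
#' Pi-electron counts are read off the kekulized bond orders: each double bond
#' contributes one pi electron to both ends, each triple bond two; atoms on
#' SDF "aromatic" (order 4) bonds contribute one.
#'
#' @param input a SMILES string, a path to an SDF/MOL file, or a
#'   \code{ChemmineR} \code{SDF} object.
#' @param id identifier stored on the graph.
#' @return a \code{CompoundGraph}: list with \code{id}, \code{atoms}
#'   (data.frame element / n_heavy_neighbors / n_pi_electrons) and
#'   \code{bonds} (data.frame i / j / order).
#' @export
parse_compound <- function(input, id = NULL) {
  sdf <- NULL
  if (inherits(input, "SDF")) {
    sdf <- input
  } else if (is.character(input) && length(input) == 1) {
    if (file.exists(input)) {
      set <- ChemmineR::read.SDFset(input)
      sdf <- set[[1]]
      if (is.null(id)) id <- ChemmineR::sdfid(set)[1]
    } else {
      sdf <- tryCatch(ChemmineR::smiles2sdf(input)[[1]],
                      error = function(e) stop("invalid SMILES '", input,
                                               "': ", conditionMessage(e),
                                               call. = FALSE))
    }
  } else stop("input must be a SMILES string, SDF path, or SDF object")
  if (is.null(id)) id <- if (is.character(input) && !file.exists(input))
    input else "compound"

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- toupper(gsub("_.*$", "", rownames(ab)))
  elements <- paste0(substr(elements, 1, 1),
                     tolower(substr(elements, 2, nchar(elements))))
  elements <- toupper(elements)
  n <- length(elements)
  bonds <- if (is.null(bb) || nrow(as.matrix(bb)) == 0)
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  else {
    bm <- matrix(as.numeric(as.matrix(bb)[, 1:3]), ncol = 3)
    data.frame(i = bm[, 1], j = bm[, 2], order = bm[, 3])
  }
  compound_graph(elements, bonds, id = id)
}

#' Construct a compound graph from explicit atoms and bonds
#'
#' Lower-level constructor used by \code{\link{parse_compound}} and the
#' fixture generators. Hydrogens are removed and indices remapped; neighbour
#' and pi counts are derived from the surviving bonds.
#'
#' @param elements character vector of element symbols (may include H).
#' @param bonds data.frame with columns i, j, order (1, 2, 3; 4 = aromatic).
#' @param id graph identifier.
#' @return a \code{CompoundGraph}.
#' @export
compound_graph <- function(elements, bonds, id = "compound") {
  elements <- toupper(elements)
  keep <- elements != "H"
  map <- cumsum(keep)
  if (nrow(bonds)) {
    ok <- keep[bonds$i] & keep[bonds$j]
    bonds <- bonds[ok, , drop = FALSE]
    bonds$i <- map[bonds$i]
    bonds$j <- map[bonds$j]
  }
  elements <- elements[keep]
  n <- length(elements)
  deg <- integer(n); pi <- numeric(n); arom <- logical(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      if (o == 2) { pi[i] <- pi[i] + 1; pi[j] <- pi[j] + 1 }
      if (o == 3) { pi[i] <- pi[i] + 2; pi[j] <- pi[j] + 2 }
      if (o == 4) { arom[i] <- TRUE; arom[j] <- TRUE }
    }
  }
  pi[arom & pi == 0] <- 1
  structure(list(
    id = id,
    atoms = data.frame(element = elements, n_heavy_neighbors = deg,
                       n_pi_electrons = as.integer(pi),
                       stringsAsFactors = FALSE),
    bonds = bonds), class = "CompoundGraph")
}

#' @export
print.CompoundGraph <- function(x, ...) {
  cat(sprintf("CompoundGraph %s: %d heavy atoms, %d bonds\n", x$id,
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# BFS topological distances from one atom; NA for unreachable atoms
.bfs_dist <- function(adj, start, n) {
  d <- rep(NA_integer_, n)
  d[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1L
    frontier <- nxt
  }
  d
}

#' Atom-pair fingerprint
#'
#' One multiset entry per unordered pair of heavy atoms connected in the
#' graph, keyed by the two (canonically ordered) atom types and the
#' shortest-path bond count. Pairs in different connected components are
#' omitted.
#'
#' @param g a \code{CompoundGraph}.
#' @return an \code{APFingerprint}: named integer vector of pair counts, key
#'   format \code{"el.deg.pi|el.deg.pi|dist"}.
#' @export
ap_fingerprint <- function(g) {
  n <- nrow(g$atoms)
  if (n < 2)
    stop(structure(class = c("empty_fingerprint", "error", "condition"),
                   list(message = sprintf(
                     "compound %s has %d heavy atoms; need >= 2", g$id, n),
                     call = sys.call())))
  types <- sprintf("%s.%d.%d", g$atoms$element, g$atoms$n_heavy_neighbors,
                   g$atoms$n_pi_electrons)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[r]; j <- g$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  keys <- character(0)
  for (s in seq_len(n - 1)) {
    d <- .bfs_dist(adj, s, n)
    for (t in seq(s + 1, n)) {
      if (is.na(d[t])) next
      ab <- sort(c(types[s], types[t]))
      keys <- c(keys, paste(ab[1], ab[2], d[t], sep = "|"))
    }
  }
  counts <- table(keys)
  fp <- as.integer(counts)
  names(fp) <- names(counts)
  structure(fp, n_heavy = n, id = g$id, class = "APFingerprint")
}

#' Multiset Tanimoto similarity of two atom-pair fingerprints
#'
#' \eqn{\sum_p \min(a_p, b_p) / \sum_p \max(a_p, b_p)} over the union of pair
#' keys; 0 when either fingerprint is empty.
#'
#' @param a,b \code{APFingerprint} objects (or named count vectors).
#' @return similarity in [0, 1].
#' @export
ap_tanimoto <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  keys <- union(names(a), names(b))
  av <- ifelse(is.na(a[keys]), 0L, a[keys])
  bv <- ifelse(is.na(b[keys]), 0L, b[keys])
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Atom-pair similarity between two compound graphs
#'
#' Convenience wrapper computing fingerprints and their similarity.
#' \code{method = "tanimoto"} is the multiset min/max form (package default);
#' \code{method = "dice"} is the matches-over-total form of the original
#' atom-pair formulation.
#'
#' @param g1,g2 \code{CompoundGraph} objects.
#' @param method \code{"tanimoto"} or \code{"dice"}.
#' @return similarity in [0, 1].
#' @export
ap_similarity <- function(g1, g2, method = c("tanimoto", "dice")) {
  method <- match.arg(method)
  a <- ap_fingerprint(g1); b <- ap_fingerprint(g2)
  if (method == "tanimoto") return(ap_tanimoto(a, b))
  keys <- union(names(a), names(b))
  av <- ifelse(is.na(a[keys]), 0L, a[keys])
  bv <- ifelse(is.na(b[keys]), 0L, b[keys])
  2 * sum(pmin(av, bv)) / (sum(av) + sum(bv))
}

#' Reserve candidates by compound topology similarity
#'
#' A candidate is reserved when its best atom-pair Tanimoto similarity over
#' the reference compounds reaches the threshold (default 0.6, the reservation
#' rule applied after pharma-interface candidates are found).
#'
#' @param candidates named list of \code{CompoundGraph} (names = complex ids),
#'   or a list of \code{list(id =, graph =)} pairs.
#' @param references list of \code{CompoundGraph}.
#' @param threshold reservation threshold in [0, 1].
#' @return list with \code{reserved} and \code{dropped} data.frames
#'   (complex_id, best_reference, score).
#' @export
reserve_by_similarity <- function(candidates, references, threshold = 0.6) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(references) == 0) stop("no reference compounds: filter undefined")
  ref_fp <- lapply(references, ap_fingerprint)
  ref_ids <- vapply(references, function(g) g$id, "")
  ids <- names(candidates)
  if (is.null(ids))
    ids <- vapply(candidates, function(g) g$id, "")
  rows <- lapply(seq_along(candidates), function(k) {
    fp <- tryCatch(ap_fingerprint(candidates[[k]]),
                   empty_fingerprint = function(e) NULL)
    if (is.null(fp))
      return(data.frame(complex_id = ids[k], best_reference = NA_character_,
                        score = 0, stringsAsFactors = FALSE))
    s <- vapply(ref_fp, function(r) ap_tanimoto(fp, r), 0)
    data.frame(complex_id = ids[k], best_reference = ref_ids[which.max(s)],
               score = max(s), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- tab$score >= threshold & !is.na(tab$best_reference)
  list(reserved = tab[keep, , drop = FALSE],
       dropped = tab[!keep, , drop = FALSE])
}

#' Read a SMILES file
#'
#' One compound per line, \code{SMILES<TAB>id}; the id defaults to the SMILES
#' string when absent.
#'
#' @param path file path.
#' @return named character vector of SMILES.
#' @export
read_smiles_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  stats::setNames(smi, ids)
}

#' Pairwise atom-pair similarity matrix
#'
#' @param graphs named list of \code{CompoundGraph}.
#' @return symmetric numeric matrix of Tanimoto similarities.
#' @export
compound_similarity_matrix <- function(graphs) {
  ids <- names(graphs)
  if (is.null(ids)) ids <- vapply(graphs, function(g) g$id, "")
  fps <- lapply(graphs, function(g)
    tryCatch(ap_fingerprint(g), empty_fingerprint = function(e) integer(0)))
  n <- length(fps)
  S <- diag(1, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    S[i, j] <- S[j, i] <- ap_tanimoto(fps[[i]], fps[[j]])
  dimnames(S) <- list(ids, ids)
  S
}
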