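# Rigid-body superposition (Kabsch, SVD with reflection correction) and the
# RMSD <= cutoff reservation filter applied to pharma-interface candidates.

#' Least-squares rigid superposition of two point sets
#'
#' Kabsch algorithm: the candidate set is rotated and translated onto the
#' query set minimizing RMSD, with the determinant sign corrected so the
#' transform is a proper rotation (no reflection).
#'
#' @param query_coords N x 3 matrix (Angstrom).
#' @param cand_coords N x 3 matrix, row-aligned with \code{query_coords}.
#' @return \code{SuperpositionResult}: list with \code{rotation} (3 x 3),
#'   \code{translation} (length 3), \code{rmsd}, \code{n_atoms}. The aligned
#'   candidate is \code{cand \%*\% rotation + translation} (rows).
#' @export
kabsch_superpose <- function(query_coords, cand_coords) {
  q <- as.matrix(query_coords); p <- as.matrix(cand_coords)
  if (!all(dim(q) == dim(p)) || ncol(q) != 3)
    stop("coordinate sets must be index-aligned N x 3 matrices")
  n <- nrow(q)
  if (n < 3) stop("need at least 3 points to superpose, got ", n)
  cq <- colMeans(q); cp <- colMeans(p)
  qc <- sweep(q, 2, cq); pc <- sweep(p, 2, cp)
  H <- crossprod(pc, qc)           # covariance: candidate -> query
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))   # rank < 2: collinear points
    warning("near-degenerate (collinear) point set; fit is still least-squares optimal")
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)      # right-multiplication rotation
  aligned <- pc %*% R
  rmsd <- sqrt(mean(rowSums((aligned - qc)^2)))
  if (rmsd < 1e-9) rmsd <- 0   # numerical floor: exact copies report 0
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd, n_atoms = n),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a \code{SuperpositionResult}.
#' @param coords N x 3 matrix in the candidate frame.
#' @return N x 3 matrix in the query frame.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, `+`)
}

#' Identity residue correspondence
#'
#' Pairs residues by identical (chain, number, insertion) keys; the shortcut
#' for candidates that share the query's numbering.
#'
#' @param query,candidate \code{ComplexRecord} objects.
#' @return data.frame with columns query_res, cand_res.
#' @export
identity_correspondence <- function(query, candidate) {
  shared <- intersect(unique(query$protein$residue),
                      unique(candidate$protein$residue))
  if (!length(shared)) stop("no shared residue keys between query and candidate")
  data.frame(query_res = shared, cand_res = shared, stringsAsFactors = FALSE)
}

#' Read a residue correspondence table
#'
#' @param path TSV with header columns \code{query_res} and \code{cand_res}
#'   (residue keys, see \code{\link{residue_key}}).
#' @return data.frame correspondence.
#' @export
read_correspondence <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("query_res", "cand_res") %in% names(df)))
    stop("correspondence file needs columns query_res, cand_res: ", path)
  df
}

# coordinates of the atom_set atoms for the listed residues, in order;
# errors listing residues missing from the structure
.corr_coords <- function(record, residues, atom_set) {
  p <- record$protein
  p <- switch(atom_set,
              "CA" = p[p$name == "CA", , drop = FALSE],
              "backbone" = p[p$is_mainchain, , drop = FALSE],
              "all-heavy" = p,
              stop("unknown atom_set: ", atom_set))
  missing <- setdiff(residues, unique(p$residue))
  if (length(missing))
    stop(sprintf("complex %s: correspondence references residues missing %s: %s",
                 record$complex_id,
                 if (atom_set == "CA") "a CA atom" else "atoms",
                 paste(missing, collapse = ", ")))
  do.call(rbind, lapply(residues, function(rk) {
    as.matrix(p[p$residue == rk, c("x", "y", "z"), drop = FALSE])
  }))
}

#' RMSD reservation filter
#'
#' Superposes every candidate onto the query over corresponding residues and
#' reserves those with RMSD at or below the cutoff (default 3 Angstrom, the
#' reservation rule for pharma-interface candidates). With
#' \code{atom_set = "all-heavy"} the per-residue atom counts must agree
#' between query and candidate.
#'
#' @param query a \code{ComplexRecord}.
#' @param candidates list; each element either a \code{ComplexRecord} (an
#'   identity correspondence is built) or \code{list(record =,
#'   correspondence =)}.
#' @param cutoff RMSD cutoff in Angstrom.
#' @param atom_set \code{"CA"}, \code{"backbone"} or \code{"all-heavy"}.
#' @return list with \code{table} (data.frame complex_id, rmsd, n_atoms,
#'   reserved) and \code{reserved} (named list of \code{list(record,
#'   superposition)}).
#' @export
rmsd_reserve <- function(query, candidates, cutoff = 3.0,
                         atom_set = c("CA", "backbone", "all-heavy")) {
  atom_set <- match.arg(atom_set)
  stopifnot(cutoff >= 0)
  rows <- list(); reserved <- list()
  for (k in seq_along(candidates)) {
    el <- candidates[[k]]
    if (inherits(el, "ComplexRecord"))
      el <- list(record = el, correspondence = identity_correspondence(query, el))
    rec <- el$record; corr <- el$correspondence
    qc <- .corr_coords(query, corr$query_res, atom_set)
    cc <- .corr_coords(rec, corr$cand_res, atom_set)
    if (nrow(qc) != nrow(cc))
      stop(sprintf("complex %s: atom count mismatch over correspondence (%d vs %d)",
                   rec$complex_id, nrow(qc), nrow(cc)))
    sup <- kabsch_superpose(qc, cc)
    ok <- sup$rmsd <= cutoff
    rows[[k]] <- data.frame(complex_id = rec$complex_id, rmsd = sup$rmsd,
                            n_atoms = sup$n_atoms, reserved = ok,
                            stringsAsFactors = FALSE)
    if (ok) reserved[[rec$complex_id]] <- list(record = rec, superposition = sup)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(complex_id = character(0), rmsd = numeric(0),
                  n_atoms = integer(0), reserved = logical(0),
                  stringsAsFactors = FALSE)
  list(table = tab, reserved = reserved)
}
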