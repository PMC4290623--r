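# Geometric protein-ligand interaction typing. Each contact is assigned one
# of three types by exclusive precedence (electrostatic > hydrogen bond >
# van der Waals), separately for main-chain and side-chain protein atoms,
# and accumulated per alignment column into a 6-channel interaction profile.

#' Interaction detection parameters
#'
#' Distance-only criteria (hydrogens are absent from most crystal structures,
#' so no angular term is used): electrostatic when formal charges are opposite
#' and the distance is at most \code{elec_cutoff}; hydrogen bond when one atom
#' is a donor and the other an acceptor within \code{hbond_cutoff}; van der
#' Waals contact within \code{vdw_cutoff}. One event at most per atom pair.
#'
#' @param elec_cutoff,hbond_cutoff,vdw_cutoff distances in Angstrom.
#' @return list of class \code{"interaction_params"}.
#' @export
interaction_params <- function(elec_cutoff = 4.0, hbond_cutoff = 3.5,
                               vdw_cutoff = 4.5) {
  stopifnot(elec_cutoff > 0, hbond_cutoff > 0, vdw_cutoff > 0)
  structure(list(elec_cutoff = elec_cutoff, hbond_cutoff = hbond_cutoff,
                 vdw_cutoff = vdw_cutoff), class = "interaction_params")
}

# per-residue side-chain role table: donor / acceptor / positive / negative
.SIDECHAIN_ROLES <- list(
  SER = list(donor = "OG",  acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  TYR = list(donor = "OH",  acceptor = "OH"),
  CYS = list(donor = "SG"),
  LYS = list(donor = "NZ",  positive = "NZ"),
  ARG = list(donor = c("NE", "NH1", "NH2"), positive = c("NH1", "NH2", "NE")),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  ASP = list(acceptor = c("OD1", "OD2"), negative = c("OD1", "OD2")),
  GLU = list(acceptor = c("OE1", "OE2"), negative = c("OE1", "OE2")),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  TRP = list(donor = "NE1"))

#' Assign physico-chemical roles to protein and ligand atoms
#'
#' Protein roles come from a shipped per-residue table (e.g. Lys NZ is a donor
#' and positively charged, Asp OD1/OD2 acceptors and negatively charged;
#' backbone N donor except proline, backbone O and OXT acceptors, OXT also
#' negative). Ligand roles are element/connectivity heuristics: O with at
#' most one heavy neighbour is donor+acceptor, ether O acceptor, carboxylate
#' O (terminal O on a carbon bearing two terminal oxygens) acceptor+negative;
#' N with at most two heavy neighbours donor+acceptor, three-coordinate N
#' acceptor, four-coordinate N positive. Everything else is nonpolar. Atoms of
#' unrecognized protein residues are treated as nonpolar (with a warning).
#'
#' @param record a \code{ComplexRecord}.
#' @return the record with logical columns donor, acceptor, positive,
#'   negative added to \code{protein} and \code{ligand$atoms}.
#' @export
assign_atom_roles <- function(record) {
  p <- record$protein
  n <- nrow(p)
  don <- acc <- pos <- neg <- logical(n)
  don[p$name == "N" & p$resid != "PRO"] <- TRUE
  acc[p$name %in% c("O", "OXT")] <- TRUE
  neg[p$name == "OXT"] <- TRUE
  unknown <- character(0)
  for (res in unique(p$resid)) {
    rules <- .SIDECHAIN_ROLES[[res]]
    sel <- p$resid == res
    if (is.null(rules)) {
      if (!res %in% c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET"))
        unknown <- c(unknown, res)
      next
    }
    if (!is.null(rules$donor))    don[sel & p$name %in% rules$donor] <- TRUE
    if (!is.null(rules$acceptor)) acc[sel & p$name %in% rules$acceptor] <- TRUE
    if (!is.null(rules$positive)) pos[sel & p$name %in% rules$positive] <- TRUE
    if (!is.null(rules$negative)) neg[sel & p$name %in% rules$negative] <- TRUE
  }
  if (length(unknown))
    warning("unrecognized residue(s) treated as nonpolar: ",
            paste(unique(unknown), collapse = ", "))
  p$donor <- don; p$acceptor <- acc; p$positive <- pos; p$negative <- neg
  record$protein <- p

  la <- record$ligand$atoms
  m <- nrow(la)
  deg <- integer(m)
  b <- record$ligand$bonds
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    deg[b$i[r]] <- deg[b$i[r]] + 1L; deg[b$j[r]] <- deg[b$j[r]] + 1L
  }
  ldon <- lacc <- lpos <- lneg <- logical(m)
  nbrs <- function(i) {
    c(b$j[b$i == i], b$i[b$j == i])
  }
  for (i in seq_len(m)) {
    el <- la$element[i]
    if (el == "O") {
      lacc[i] <- TRUE
      if (deg[i] <= 1) {
        ldon[i] <- TRUE
        cn <- nbrs(i)
        cn <- cn[la$element[cn] == "C"]
        if (length(cn) == 1) {
          oo <- nbrs(cn)
          oo <- oo[la$element[oo] == "O" & deg[oo] <= 1]
          if (length(oo) >= 2) { lneg[i] <- TRUE; ldon[i] <- FALSE }
        }
      }
    } else if (el == "N") {
      if (deg[i] <= 2) { ldon[i] <- TRUE; lacc[i] <- TRUE }
      else if (deg[i] == 3) lacc[i] <- TRUE
      else lpos[i] <- TRUE
    }
  }
  la$donor <- ldon; la$acceptor <- lacc; la$positive <- lpos; la$negative <- lneg
  record$ligand$atoms <- la
  record
}

#' Detect typed protein-ligand contacts
#'
#' Emits at most one event per (protein heavy atom, ligand heavy atom) pair,
#' typed by the exclusive precedence electrostatic > hydrogen bond > van der
#' Waals under the distance criteria in \code{params}.
#'
#' @param record a \code{ComplexRecord}; roles are assigned on the fly when
#'   absent.
#' @param params an \code{\link{interaction_params}}.
#' @return data.frame of events: residue, resid, name, chain_part, itype,
#'   distance, ligand_atom.
#' @export
detect_interactions <- function(record, params = interaction_params()) {
  if (is.null(record$protein$donor)) record <- assign_atom_roles(record)
  p <- record$protein
  la <- record$ligand$atoms
  la <- la[la$element != "H", , drop = FALSE]
  empty <- data.frame(residue = character(0), resid = character(0),
                      name = character(0), chain_part = character(0),
                      itype = character(0), distance = numeric(0),
                      ligand_atom = character(0), stringsAsFactors = FALSE)
  if (nrow(la) == 0 || nrow(p) == 0) return(empty)
  px <- as.matrix(p[, c("x", "y", "z")])
  lx <- as.matrix(la[, c("x", "y", "z")])
  maxcut <- max(params$elec_cutoff, params$hbond_cutoff, params$vdw_cutoff)
  d2 <- outer(rowSums(px^2), rowSums(lx^2), `+`) - 2 * px %*% t(lx)
  idx <- which(d2 <= maxcut^2, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  d <- sqrt(pmax(d2[idx], 0))
  elec <- ((p$positive[i] & la$negative[j]) | (p$negative[i] & la$positive[j])) &
    d <= params$elec_cutoff
  hb <- ((p$donor[i] & la$acceptor[j]) | (p$acceptor[i] & la$donor[j])) &
    d <= params$hbond_cutoff
  vdw <- d <= params$vdw_cutoff
  itype <- ifelse(elec, "electrostatic", ifelse(hb, "hbond",
                  ifelse(vdw, "vdw", NA)))
  keep <- !is.na(itype)
  data.frame(residue = p$residue[i][keep], resid = p$resid[i][keep],
             name = p$name[i][keep],
             chain_part = ifelse(p$is_mainchain[i][keep], "mainchain", "sidechain"),
             itype = itype[keep], distance = d[keep],
             ligand_atom = la$name[j][keep], stringsAsFactors = FALSE)
}

.CHANNELS <- c("electrostatic.mainchain", "electrostatic.sidechain",
               "hbond.mainchain", "hbond.sidechain",
               "vdw.mainchain", "vdw.sidechain")

#' Build an interaction profile over alignment columns
#'
#' Aggregates events into an (alignment column) x (3 interaction types x 2
#' chain parts) matrix. Binary mode records presence; count mode records the
#' number of events.
#'
#' @param events event table from \code{\link{detect_interactions}}.
#' @param cmap residue-to-column map from \code{\link{column_map}}; residues
#'   absent from the map raise an error. Events at residues of unmapped
#'   chains must be filtered by the caller beforehand.
#' @param mode \code{"binary"} or \code{"count"}.
#' @param complex_id identifier stored on the profile.
#' @return an \code{InteractionProfile}: list with \code{complex_id},
#'   \code{mat} (n_columns x 6), \code{mode}, \code{n_events}.
#' @export
build_profile <- function(events, cmap, mode = c("binary", "count"),
                          complex_id = "complex") {
  mode <- match.arg(mode)
  ncol_total <- attr(cmap, "n_columns")
  if (is.null(ncol_total)) ncol_total <- max(cmap)
  mat <- matrix(0, nrow = ncol_total, ncol = 6,
                dimnames = list(NULL, .CHANNELS))
  if (nrow(events)) {
    missing <- setdiff(unique(events$residue), names(cmap))
    if (length(missing))
      stop("events at residues absent from the alignment map: ",
           paste(missing, collapse = ", "))
    col <- cmap[events$residue]
    ch <- match(paste(events$itype, events$chain_part, sep = "."), .CHANNELS)
    for (r in seq_along(col)) mat[col[r], ch[r]] <- mat[col[r], ch[r]] + 1
    if (mode == "binary") mat[mat > 0] <- 1
  }
  structure(list(complex_id = complex_id, mat = mat, mode = mode,
                 n_events = nrow(events)), class = "InteractionProfile")
}

#' @export
print.InteractionProfile <- function(x, ...) {
  cat(sprintf("InteractionProfile %s: %d columns x 6 channels, %d events (%s mode)\n",
              x$complex_id, nrow(x$mat), x$n_events, x$mode))
  invisible(x)
}

#' Compute the interaction profile of one complex
#'
#' Convenience wrapper: role assignment, contact detection, column mapping,
#' profile construction. Events on chains that are not mapped to the
#' alignment are dropped.
#'
#' @param record a \code{ComplexRecord}.
#' @param aln an \code{\link{msa}}.
#' @param row_id alignment row id(s) for the mapped chain(s).
#' @param chains chains contacting the ligand; default first chain.
#' @param params \code{\link{interaction_params}}.
#' @param mode \code{"binary"} or \code{"count"}.
#' @return an \code{InteractionProfile}.
#' @export
interaction_profile <- function(record, aln, row_id, chains = NULL,
                                params = interaction_params(),
                                mode = "binary") {
  if (is.null(chains)) chains <- record$protein$chain[1]
  cmap <- column_map(record, aln, row_id, chains)
  ev <- detect_interactions(record, params)
  ev <- ev[ev$residue %in% names(cmap) |
             sub(":.*$", "", ev$residue) %in% chains, , drop = FALSE]
  build_profile(ev, cmap, mode = mode, complex_id = record$complex_id)
}

#' Write an interaction profile as TSV
#'
#' Long format: complex_id, column, itype, chain_part, value (nonzero cells
#' only).
#'
#' @param profile an \code{InteractionProfile}.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  nz <- which(profile$mat > 0, arr.ind = TRUE)
  parts <- strsplit(.CHANNELS[nz[, 2]], ".", fixed = TRUE)
  df <- data.frame(complex_id = profile$complex_id, column = nz[, 1],
                   itype = vapply(parts, `[`, "", 1),
                   chain_part = vapply(parts, `[`, "", 2),
                   value = profile$mat[nz], stringsAsFactors = FALSE)
  df <- df[order(df$column, df$itype, df$chain_part), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
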