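# ---- residue keys -----------------------------------------------------------

#' Canonical residue identifier
#'
#' Residues are identified throughout the package by chain id, author residue
#' number and insertion code, rendered as \code{"<chain>:<resno><icode>"}.
#'
#' @param chain chain identifier (single character).
#' @param resno author residue sequence number.
#' @param insert insertion code, \code{""} or \code{NA} when absent.
#' @return character vector of residue keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == "?", "", trimws(insert))
  chain <- ifelse(is.na(chain), "", trimws(chain))
  sprintf("%s:%s%s", chain, resno, insert)
}

# three-letter -> one-letter amino-acid code; nonstandard residues become X
aa3to1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

.WATER  <- c("HOH", "WAT", "DOD", "H2O", "DIS")
.METALS <- c("LI", "NA", "K", "RB", "CS", "BE", "MG", "CA", "SR", "BA",
             "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "GA",
             "PB", "PT", "PD", "AG", "AU", "MO", "W", "V", "CR", "TL")

#' Default cofactor component-id exclusion list
#'
#' Chemical component identifiers treated as cofactors by
#' \code{\link{classify_ligand}}. The set is configurable through
#' \code{\link{filter_config}}.
#'
#' @return character vector of component ids.
#' @export
hp_cofactors <- function() {
  c("HEM", "NAD", "NAP", "FAD", "FMN", "SAM", "SAH", "COA", "PLP", "TPP",
    "GSH", "ADP", "ATP", "AMP", "GDP", "GTP", "GMP")
}

#' Complex filtering configuration
#'
#' @param min_heavy ligands with fewer heavy atoms than this are "small".
#' @param surface_radius contact radius in Angstrom for the pocket-burial rule.
#' @param surface_min_residues minimum number of distinct protein residues with
#'   a heavy atom within \code{surface_radius} of the ligand for the ligand to
#'   count as buried; fewer means "surface".
#' @param cofactor_list component ids classified as cofactors.
#' @return a list of class \code{"filter_config"}.
#' @export
filter_config <- function(min_heavy = 6, surface_radius = 4.5,
                          surface_min_residues = 5,
                          cofactor_list = hp_cofactors()) {
  stopifnot(min_heavy >= 1, surface_radius > 0, surface_min_residues >= 0)
  structure(list(min_heavy = min_heavy, surface_radius = surface_radius,
                 surface_min_residues = surface_min_residues,
                 cofactor_list = toupper(cofactor_list)),
            class = "filter_config")
}

# element symbol from a PDB atom name when the element column is absent
.elem_from_name <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- c("FE", "ZN", "MG", "MN", "CU", "CO", "NI", "CL", "BR", "SE", "CD",
           "HG", "NA", "CA", "LI", "AL", "SI")
  out <- substr(nm, 1, 1)
  hit <- substr(nm, 1, 2) %in% two & nchar(nm) >= 2
  out[hit] <- substr(nm[hit], 1, 2)
  out
}

# resolve alternate locations: highest occupancy wins, ties go to label order
.resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$type, atom$chain, atom$resno, atom$insert, atom$resid,
               atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

# parse CONECT records from a PDB file: matrix of atom-serial pairs
.read_conect <- function(path) {
  ln <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(matrix(integer(0), ncol = 2))
  pairs <- lapply(ln, function(l) {
    f <- substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))
    f <- suppressWarnings(as.integer(trimws(f)))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  })
  m <- do.call(rbind, pairs)
  if (is.null(m)) return(matrix(integer(0), ncol = 2))
  m <- t(apply(m, 1, sort))
  unique(m)
}

# infer covalent bonds between heavy atoms from interatomic distances
.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  big <- atoms$element %in% c("S", "P", "SE", "CL", "BR", "I")
  cut <- outer(ifelse(big, 2.3, 1.9), ifelse(big, 2.3, 1.9), pmax)
  idx <- which(d > 0.4 & d <= cut & upper.tri(d), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], order = rep(1L, nrow(idx)))
}

.ligand <- function(component_id, atoms, bonds) {
  structure(list(component_id = component_id, atoms = atoms, bonds = bonds,
                 heavy_atom_count = sum(atoms$element != "H")),
            class = "Ligand")
}

.complex_record <- function(complex_id, protein, ligand, source) {
  stopifnot(nrow(protein) >= 1)
  structure(list(complex_id = complex_id, protein = protein, ligand = ligand,
                 source = source),
            class = "ComplexRecord")
}

#' @export
print.ComplexRecord <- function(x, ...) {
  cat(sprintf("ComplexRecord %s: %d protein atoms (%d chains), ligand %s (%d heavy atoms)\n",
              x$complex_id, nrow(x$protein), length(unique(x$protein$chain)),
              x$ligand$component_id, x$ligand$heavy_atom_count))
  invisible(x)
}

#' Read protein-ligand complexes from a structure file
#'
#' Parses a PDB or mmCIF file and emits one \code{ComplexRecord} per bound
#' non-water HETATM component instance; a file holding k ligand copies yields
#' k records sharing the same protein chains. Waters are always discarded,
#' hydrogens are dropped (all rules in this package operate on heavy atoms),
#' and alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by altloc label).
#'
#' @param path path to the structure file.
#' @param format \code{"pdb"} or \code{"mmcif"}.
#' @return list of \code{ComplexRecord}; empty list when the file contains no
#'   ligand.
#' @export
read_complexes <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop(sprintf("cannot parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  atom <- .resolve_altloc(parsed$atom)
  elem <- toupper(trimws(atom$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- .elem_from_name(atom$elety[miss])
  atom$element <- elem
  atom <- atom[!atom$element %in% c("H", "D"), , drop = FALSE]
  atom <- atom[!atom$resid %in% .WATER, , drop = FALSE]
  atom$insert[is.na(atom$insert) | atom$insert == "?"] <- ""
  atom$chain[is.na(atom$chain)] <- ""

  is_prot <- atom$type == "ATOM"
  prot <- atom[is_prot, , drop = FALSE]
  het <- atom[!is_prot, , drop = FALSE]
  if (nrow(prot) == 0) stop("no protein (ATOM) records in ", path)

  protein <- data.frame(
    name = trimws(prot$elety), element = prot$element,
    x = prot$x, y = prot$y, z = prot$z,
    chain = prot$chain, resno = prot$resno, insert = prot$insert,
    resid = prot$resid,
    is_mainchain = trimws(prot$elety) %in% c("N", "CA", "C", "O", "OXT"),
    stringsAsFactors = FALSE)
  protein$residue <- residue_key(protein$chain, protein$resno, protein$insert)

  if (nrow(het) == 0) return(list())

  conect <- if (format == "pdb") .read_conect(path) else matrix(integer(0), ncol = 2)
  base <- sub("\\.[^.]*$", "", basename(path))
  inst <- split(seq_len(nrow(het)),
                paste(het$resid, het$chain, het$resno, het$insert, sep = "\r"))
  inst <- inst[order(vapply(inst, min, 1L))]
  records <- lapply(inst, function(ii) {
    h <- het[ii, , drop = FALSE]
    latoms <- data.frame(name = trimws(h$elety), element = h$element,
                         x = h$x, y = h$y, z = h$z, stringsAsFactors = FALSE)
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    if (nrow(conect)) {
      local <- match(conect[, 1], h$eleno)
      local2 <- match(conect[, 2], h$eleno)
      ok <- !is.na(local) & !is.na(local2)
      if (any(ok)) bonds <- data.frame(i = local[ok], j = local2[ok], order = 1L)
    }
    if (nrow(bonds) == 0 && nrow(latoms) > 1) bonds <- .infer_bonds(latoms)
    lig <- .ligand(h$resid[1], latoms, bonds)
    cid <- sprintf("%s_%s_%s%s%s", base, lig$component_id, h$chain[1],
                   h$resno[1], h$insert[1])
    .complex_record(cid, protein, lig, list(path = path, format = format))
  })
  names(records) <- vapply(records, function(r) r$complex_id, "")
  records
}

#' One-letter sequence of a protein chain
#'
#' @param record a \code{ComplexRecord}.
#' @param chain chain id; default is the first chain in the record.
#' @return list with \code{sequence} (single string) and \code{residues}
#'   (residue keys in chain order).
#' @export
chain_sequence <- function(record, chain = NULL) {
  p <- record$protein
  if (is.null(chain)) chain <- p$chain[1]
  p <- p[p$chain == chain, , drop = FALSE]
  if (nrow(p) == 0) stop("no such chain: ", chain)
  keys <- unique(p$residue)
  resid <- p$resid[match(keys, p$residue)]
  list(sequence = paste(aa3to1(resid), collapse = ""), residues = keys)
}

#' Classify a bound ligand
#'
#' Applies the elimination rules for validation-set construction: metal ions,
#' cofactors, small compounds (fewer than \code{min_heavy} heavy atoms) and
#' surface-bound compounds are flagged for removal; everything else is
#' \code{"valid"}. Labels are assigned in the fixed precedence
#' metal_ion > cofactor > small > surface. The surface rule is a pocket-burial
#' proxy: a ligand is "surface" when fewer than \code{surface_min_residues}
#' distinct protein residues have any heavy atom within \code{surface_radius}
#' of any ligand heavy atom (the underlying notion is not otherwise defined;
#' both parameters are configurable).
#'
#' @param ligand a \code{Ligand}.
#' @param record the \code{ComplexRecord} the ligand belongs to.
#' @param cfg a \code{\link{filter_config}}.
#' @return list of class \code{"LigandClass"} with \code{label} and
#'   \code{evidence}.
#' @export
classify_ligand <- function(ligand, record, cfg = filter_config()) {
  mk <- function(label, evidence)
    structure(list(label = label, evidence = evidence), class = "LigandClass")
  if (ligand$heavy_atom_count == 1 && ligand$atoms$element[1] %in% .METALS)
    return(mk("metal_ion", sprintf("single %s ion", ligand$atoms$element[1])))
  if (toupper(ligand$component_id) %in% cfg$cofactor_list)
    return(mk("cofactor", sprintf("component %s in cofactor list",
                                  ligand$component_id)))
  if (ligand$heavy_atom_count < cfg$min_heavy)
    return(mk("small", sprintf("%d heavy atoms < %d",
                               ligand$heavy_atom_count, cfg$min_heavy)))
  lx <- as.matrix(ligand$atoms[ligand$atoms$element != "H", c("x", "y", "z")])
  p <- record$protein
  px <- as.matrix(p[, c("x", "y", "z")])
  d2 <- cfg$surface_radius^2
  near <- vapply(seq_len(nrow(px)), function(i) {
    min(colSums((t(lx) - px[i, ])^2)) <= d2
  }, TRUE)
  ncontact <- length(unique(p$residue[near]))
  if (ncontact < cfg$surface_min_residues)
    return(mk("surface", sprintf("%d contact residues < %d within %.1f A",
                                 ncontact, cfg$surface_min_residues,
                                 cfg$surface_radius)))
  mk("valid", sprintf("%d contact residues within %.1f A", ncontact,
                      cfg$surface_radius))
}

#' Filter complexes by ligand class
#'
#' Partitions records into kept (label \code{"valid"}) and dropped, with every
#' dropped record carrying its classification evidence.
#'
#' @param records list of \code{ComplexRecord}.
#' @param cfg a \code{\link{filter_config}}.
#' @return list with \code{kept} (records) and \code{dropped} (data.frame:
#'   complex_id, component_id, label, evidence).
#' @export
filter_complexes <- function(records, cfg = filter_config()) {
  dropped <- data.frame(complex_id = character(0), component_id = character(0),
                        label = character(0), evidence = character(0),
                        stringsAsFactors = FALSE)
  kept <- list()
  for (r in records) {
    cls <- classify_ligand(r$ligand, r, cfg)
    if (cls$label == "valid") {
      kept[[r$complex_id]] <- r
    } else {
      dropped <- rbind(dropped, data.frame(
        complex_id = r$complex_id, component_id = r$ligand$component_id,
        label = cls$label, evidence = cls$evidence, stringsAsFactors = FALSE))
    }
  }
  list(kept = kept, dropped = dropped)
}

#' Write a dropped-ligand report
#'
#' @param dropped the \code{dropped} table from \code{\link{filter_complexes}}.
#' @param path output TSV path.
#' @export
write_drop_report <- function(dropped, path) {
  utils::write.table(dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
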