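# Deterministic synthetic fixtures: idealized binding pockets with planted
# typed contacts, compound families with controlled topology similarity, and
# planted group-recovery scenarios. Pocket geometry uses a ring template
# (residues on circles of radius 12 A, 8 per ring, rings stacked every 8 A)
# with minimal atom sets; ligand probes are placed radially inward of their
# target residue at exactly the distance of the requested interaction type.
# Not physically relaxed: the fixtures exercise the detection rules, not
# physics.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# planted residue templates: residue name + minimal atoms; "probe" describes
# the ligand fragment placed inward of the functional atom
.PLANT_TEMPLATES <- list(
  "hbond.mainchain" = list(resid = "GLY", func = "N", func_offset = 2.4,
                           dist = 2.9, probe = "O", extra_atom = "CA"),
  "hbond.sidechain" = list(resid = "SER", func = "OG", func_offset = 2.4,
                           dist = 2.9, probe = "O", extra_atom = "CA"),
  "electrostatic.sidechain" = list(resid = "LYS", func = "NZ",
                                   func_offset = 2.4, dist = 3.8,
                                   probe = "carboxylate", extra_atom = "CA"),
  "vdw.mainchain" = list(resid = "GLY", func = "CA", func_offset = 0,
                         dist = 4.2, probe = "C", extra_atom = NULL),
  "vdw.sidechain" = list(resid = "ALA", func = "CB", func_offset = 2.4,
                         dist = 4.2, probe = "C", extra_atom = "CA"))

.ring_position <- function(p, radius = 12, per_ring = 8, spacing = 8) {
  ring <- (p - 1) %/% per_ring
  slot <- (p - 1) %% per_ring
  theta <- slot * 2 * pi / per_ring
  list(ca = c(radius * cos(theta), radius * sin(theta), ring * spacing),
       inward = c(-cos(theta), -sin(theta), 0))
}

#' Build a toy binding-pocket complex with planted typed contacts
#'
#' Residues sit on a ring template; each planted residue carries the minimal
#' side-chain (or backbone) atom set for its interaction type, with a ligand
#' probe placed at exactly the type's distance: hydrogen bonds at 2.9 A
#' (lone hydroxyl-like O probe), electrostatic contacts at 3.8 A (a real
#' three-atom carboxylate, anti-aligned so only the charged O is in range),
#' van der Waals contacts at 4.2 A (lone C probe). Hydrogen-bond and vdW
#' probes are deliberately single-atom ligand fragments: any covalently
#' attached neighbour of a probe within hydrogen-bond range would itself fall
#' inside the vdW cutoff and break the exactly-the-planted-events contract.
#' A far-away anchor carbon keeps the ligand non-empty for plant-free
#' pockets. Electrostatic main-chain plants are infeasible (backbone atoms
#' carry no formal charge) and raise an error.
#'
#' @param id complex identifier (also the PDB "file" stem).
#' @param plant data.frame with columns position (residue index), itype
#'   (electrostatic / hbond / vdw), chain_part (mainchain / sidechain).
#' @param pocket_size number of residues.
#' @param seed integer; controls the rigid reorientation and jitter.
#' @param jitter_sd per-coordinate Gaussian noise in Angstrom (0 = exact).
#' @param rigid apply a seeded random rigid rotation + translation.
#' @return list with \code{record} (\code{ComplexRecord}), \code{pdb}
#'   (character vector of PDB lines) and \code{plant}.
#' @export
make_pocket_complex <- function(id, plant = NULL, pocket_size = 15,
                                seed = 1, jitter_sd = 0, rigid = FALSE) {
  if (is.null(plant))
    plant <- data.frame(position = integer(0), itype = character(0),
                        chain_part = character(0))
  stopifnot(pocket_size >= 1)
  if (nrow(plant)) {
    if (any(plant$position < 1 | plant$position > pocket_size))
      stop("plant positions outside 1..", pocket_size)
    if (anyDuplicated(plant$position))
      stop("duplicate plant positions")
    keys <- paste(plant$itype, plant$chain_part, sep = ".")
    bad <- setdiff(keys, names(.PLANT_TEMPLATES))
    if (length(bad))
      stop("infeasible plant type(s): ", paste(unique(bad), collapse = ", "),
           " (electrostatic main-chain contacts cannot be realized: backbone",
           " atoms carry no formal charge)")
  }
  .with_seed(seed, {
    prot <- list(); lig <- list(); lig_bonds <- list()
    for (p in seq_len(pocket_size)) {
      geom <- .ring_position(p)
      k <- match(p, plant$position)
      if (is.na(k)) {
        prot[[length(prot) + 1]] <- data.frame(
          name = "CA", element = "C", x = geom$ca[1], y = geom$ca[2],
          z = geom$ca[3], resno = p, resid = "ALA",
          stringsAsFactors = FALSE)
        next
      }
      tpl <- .PLANT_TEMPLATES[[paste(plant$itype[k], plant$chain_part[k],
                                     sep = ".")]]
      func <- geom$ca + tpl$func_offset * geom$inward
      rows <- data.frame(name = tpl$func, element = substr(tpl$func, 1, 1),
                         x = func[1], y = func[2], z = func[3],
                         resno = p, resid = tpl$resid, stringsAsFactors = FALSE)
      if (!is.null(tpl$extra_atom))
        rows <- rbind(rows, data.frame(
          name = tpl$extra_atom, element = "C", x = geom$ca[1],
          y = geom$ca[2], z = geom$ca[3], resno = p, resid = tpl$resid,
          stringsAsFactors = FALSE))
      prot[[length(prot) + 1]] <- rows
      probe0 <- func + tpl$dist * geom$inward
      if (tpl$probe == "carboxylate") {
        cpos <- probe0 + 1.25 * geom$inward
        o2 <- cpos + 1.25 * geom$inward
        i0 <- length(lig)
        lig[[i0 + 1]] <- c(name = sprintf("O%d", i0 + 1), element = "O", probe0)
        lig[[i0 + 2]] <- c(name = sprintf("C%d", i0 + 2), element = "C", cpos)
        lig[[i0 + 3]] <- c(name = sprintf("O%d", i0 + 3), element = "O", o2)
        lig_bonds[[length(lig_bonds) + 1]] <- c(i0 + 1, i0 + 2)
        lig_bonds[[length(lig_bonds) + 1]] <- c(i0 + 2, i0 + 3)
      } else {
        lig[[length(lig) + 1]] <- c(name = sprintf("%s%d", tpl$probe,
                                                   length(lig) + 1),
                                    element = tpl$probe, probe0)
      }
    }
    # anchor keeps the ligand non-empty and never contacts the pocket
    top <- (pocket_size - 1) %/% 8 * 8
    lig[[length(lig) + 1]] <- c(name = "CAN", element = "C", c(0, 0, top + 25))

    protein <- do.call(rbind, prot)
    latoms <- data.frame(
      name = vapply(lig, `[[`, "", "name"),
      element = vapply(lig, `[[`, "", "element"),
      x = as.numeric(vapply(lig, `[`, "", 3)),
      y = as.numeric(vapply(lig, `[`, "", 4)),
      z = as.numeric(vapply(lig, `[`, "", 5)), stringsAsFactors = FALSE)
    bonds <- if (length(lig_bonds)) {
      bm <- do.call(rbind, lig_bonds)
      data.frame(i = bm[, 1], j = bm[, 2], order = 1L)
    } else data.frame(i = integer(0), j = integer(0), order = integer(0))

    coords <- rbind(as.matrix(protein[, c("x", "y", "z")]),
                    as.matrix(latoms[, c("x", "y", "z")]))
    if (rigid) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 0, 2 * pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      coords <- coords %*% t(R)
      coords <- sweep(coords, 2, stats::runif(3, -10, 10), `+`)
    }
    if (jitter_sd > 0) {
      coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                                ncol = 3)
      # re-impose exact planted pair distances: jitter models coordinate
      # noise but must not retype planted contacts (the plant contract)
      np0 <- nrow(protein)
      for (k in seq_len(nrow(plant))) {
        tpl <- .PLANT_TEMPLATES[[paste(plant$itype[k], plant$chain_part[k],
                                       sep = ".")]]
        fi <- which(protein$resno == plant$position[k] &
                      protein$name == tpl$func)
        pname <- if (tpl$probe == "carboxylate") "O" else tpl$probe
        # probe index: nearest ligand atom of the probe element to the
        # functional atom (unambiguous by construction: foreign probes are
        # kept beyond 5.5 A)
        cand <- which(latoms$element == substr(pname, 1, 1))
        dists <- sqrt(colSums((t(coords[np0 + cand, , drop = FALSE]) -
                                 coords[fi, ])^2))
        pi_ <- cand[which.min(dists)]
        dirv <- coords[np0 + pi_, ] - coords[fi, ]
        dirv <- dirv / sqrt(sum(dirv^2))
        shift <- (coords[fi, ] + tpl$dist * dirv) - coords[np0 + pi_, ]
        # carboxylate fragments move rigidly (C and second O follow)
        move <- pi_
        if (tpl$probe == "carboxylate") {
          nb <- unique(c(bonds$j[bonds$i == pi_], bonds$i[bonds$j == pi_]))
          nb2 <- unique(unlist(lapply(nb, function(x)
            c(bonds$j[bonds$i == x], bonds$i[bonds$j == x]))))
          move <- unique(c(pi_, nb, nb2))
        }
        coords[np0 + move, ] <- sweep(coords[np0 + move, , drop = FALSE],
                                      2, shift, `+`)
      }
    }
    np <- nrow(protein)
    protein[, c("x", "y", "z")] <- coords[seq_len(np), , drop = FALSE]
    latoms[, c("x", "y", "z")] <- coords[-seq_len(np), , drop = FALSE]

    protein$chain <- "A"; protein$insert <- ""
    protein$is_mainchain <- protein$name %in% c("N", "CA", "C", "O", "OXT")
    protein$residue <- residue_key(protein$chain, protein$resno, protein$insert)
    protein <- protein[, c("name", "element", "x", "y", "z", "chain", "resno",
                           "insert", "resid", "is_mainchain", "residue")]
    record <- .complex_record(id, protein, .ligand("LIG", latoms, bonds),
                              list(path = NA_character_, format = "synthetic"))
    list(record = record, pdb = .pocket_pdb(protein, latoms, bonds),
         plant = plant)
  })
}

# render ATOM / HETATM / CONECT lines
.pocket_pdb <- function(protein, latoms, bonds) {
  fmt <- function(type, serial, name, resid, chain, resno, x, y, z, element)
    sprintf("%-6s%5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, resid, chain, resno, x, y, z, 1, 0, element)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(protein))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, protein$name[i], protein$resid[i],
                          "A", protein$resno[i], protein$x[i], protein$y[i],
                          protein$z[i], protein$element[i]))
  }
  lig_serial <- serial + seq_len(nrow(latoms))
  for (i in seq_len(nrow(latoms)))
    lines <- c(lines, fmt("HETATM", lig_serial[i], latoms$name[i], "LIG",
                          "L", 900L, latoms$x[i], latoms$y[i], latoms$z[i],
                          latoms$element[i]))
  if (nrow(bonds))
    for (r in seq_len(nrow(bonds)))
      lines <- c(lines, sprintf("CONECT%5d%5d", lig_serial[bonds$i[r]],
                                lig_serial[bonds$j[r]]))
  c(lines, "END")
}

#' Write a pocket fixture as a PDB file
#'
#' @param pocket result of \code{\link{make_pocket_complex}}.
#' @param path output path; defaults to \code{<id>.pdb} in \code{dir}.
#' @param dir directory used when \code{path} is missing.
#' @return the path written.
#' @export
write_pocket_pdb <- function(pocket, path = NULL, dir = tempdir()) {
  if (is.null(path))
    path <- file.path(dir, paste0(pocket$record$complex_id, ".pdb"))
  writeLines(pocket$pdb, path)
  invisible(path)
}

#' Generate a compound family by seeded scaffold edits
#'
#' Variants are produced by point substitutions (C/N/O) at heavy-atom letter
#' positions of an acyclic chain-style scaffold SMILES; only uppercase
#' element letters are edited, so any branching or ring syntax in the
#' scaffold is preserved untouched. Within-family atom-pair similarity
#' decreases as \code{edit_rate} grows.
#'
#' @param seed integer seed.
#' @param scaffold scaffold SMILES (must parse).
#' @param n_variants number of variants to generate.
#' @param edit_rate per-position substitution probability in [0, 1].
#' @return character vector of SMILES, names v1..vn.
#' @export
make_compound_family <- function(seed, scaffold, n_variants, edit_rate = 0.05) {
  stopifnot(edit_rate >= 0, edit_rate <= 1, n_variants >= 1)
  parse_compound(scaffold)   # validates; errors on bad scaffold
  chars <- strsplit(scaffold, "")[[1]]
  editable <- which(chars %in% c("C", "N", "O"))
  .with_seed(seed, {
    out <- vapply(seq_len(n_variants), function(v) {
      cs <- chars
      for (p in editable) {
        if (stats::runif(1) < edit_rate)
          cs[p] <- sample(setdiff(c("C", "N", "O"), cs[p]), 1)
      }
      paste(cs, collapse = "")
    }, "")
    stats::setNames(out, paste0("v", seq_len(n_variants)))
  })
}

#' Scenario specification for planted group recovery
#'
#' @param seed master seed; all randomness in the scenario derives from it.
#' @param n_groups number of planted groups.
#' @param complexes_per_group complexes per group.
#' @param channel_flip_noise probability of flipping each pooled interaction
#'   channel per complex.
#' @param pocket_size residues per pocket (one candidate channel each).
#' @param rmsd_perturbation target RMS coordinate displacement in Angstrom;
#'   kept small so planted geometry stays inside its typing cutoff.
#' @param msa_gap_rate deletion probability per non-planted residue.
#' @return list of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(seed = 1, n_groups = 3, complexes_per_group = 8,
                          channel_flip_noise = 0.05, pocket_size = 15,
                          rmsd_perturbation = 0.1, msa_gap_rate = 0) {
  stopifnot(n_groups >= 1, complexes_per_group >= 1, pocket_size >= n_groups,
            channel_flip_noise >= 0, channel_flip_noise <= 1,
            msa_gap_rate >= 0, msa_gap_rate <= 1, rmsd_perturbation >= 0)
  structure(list(seed = seed, n_groups = n_groups,
                 complexes_per_group = complexes_per_group,
                 channel_flip_noise = channel_flip_noise,
                 pocket_size = pocket_size,
                 rmsd_perturbation = rmsd_perturbation,
                 msa_gap_rate = msa_gap_rate), class = "scenario_spec")
}

#' Generate a planted Homopharma scenario
#'
#' Each pocket position is a candidate interaction channel, assigned
#' round-robin to the groups so group channel sets are disjoint; every
#' complex realizes its group's channels, each flipped (dropped)
#' independently with probability \code{channel_flip_noise}. Flips are
#' confined to the complex's planted set: since group channel sets are
#' disjoint, injecting another group's channel would carry that group's full
#' conservation weight and the effective noise would far exceed the nominal
#' rate, destroying the intended within-group similarity of about 0.9 at the
#' default noise level. Complexes share
#' residue numbering (identity correspondences), carry compounds from one
#' edit family (so the topology filter keeps them), and an alignment row per
#' complex is emitted by construction, gapped at deleted residues.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param scaffold family scaffold SMILES. The default 20-heavy-atom chain is
#'   sized so that one or two point edits keep pairwise atom-pair similarity
#'   above the 0.6 reservation threshold (on an n-atom chain a single edit
#'   scales similarity by roughly (n-2)/(n+2), so short scaffolds would let
#'   the topology filter eject family members and break the scenario's
#'   contract).
#' @param compound_edit_rate edit rate of the compound family.
#' @return list with \code{complexes} (pocket fixtures), \code{query_id},
#'   \code{aln}, \code{compounds} (named \code{CompoundGraph} list),
#'   \code{smiles}, \code{ground_truth} (named integer vector) and
#'   \code{channels} (the per-group planted channel tables).
#' @export
make_homopharma_scenario <- function(spec = scenario_spec(),
                                     scaffold = "CCCNCCOCCCNCCCOCCNCC",
                                     compound_edit_rate = 0.02) {
  tcycle <- c("hbond.mainchain", "hbond.sidechain", "vdw.sidechain",
              "electrostatic.sidechain", "vdw.mainchain")
  pool <- data.frame(position = seq_len(spec$pocket_size),
                     group = rep(seq_len(spec$n_groups),
                                 length.out = spec$pocket_size),
                     type = tcycle[(seq_len(spec$pocket_size) - 1) %%
                                     length(tcycle) + 1],
                     stringsAsFactors = FALSE)
  n_total <- spec$n_groups * spec$complexes_per_group
  ids <- sprintf("cplx_g%d_%d", rep(seq_len(spec$n_groups),
                                    each = spec$complexes_per_group),
                 rep(seq_len(spec$complexes_per_group), spec$n_groups))
  truth <- stats::setNames(rep(seq_len(spec$n_groups),
                               each = spec$complexes_per_group), ids)
  .with_seed(spec$seed, {
    sub_seeds <- sample.int(1e6, n_total + 1)
    flips <- matrix(stats::runif(n_total * nrow(pool)) <
                      spec$channel_flip_noise, nrow = n_total)
    deld <- matrix(stats::runif(n_total * spec$pocket_size) <
                     spec$msa_gap_rate, nrow = n_total)
    complexes <- list(); rows <- character(n_total)
    for (k in seq_len(n_total)) {
      has <- (pool$group == truth[k]) & !flips[k, ]   # drop each planted channel w.p. p
      plant <- pool[has, c("position", "type")]
      parts <- strsplit(plant$type, ".", fixed = TRUE)
      plant <- data.frame(position = plant$position,
                          itype = vapply(parts, `[`, "", 1),
                          chain_part = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE)
      pocket <- make_pocket_complex(ids[k], plant,
                                    pocket_size = spec$pocket_size,
                                    seed = sub_seeds[k],
                                    jitter_sd = spec$rmsd_perturbation / sqrt(3),
                                    rigid = TRUE)
      # optionally delete non-planted residues (alignment gaps)
      drop_res <- which(deld[k, ] & !seq_len(spec$pocket_size) %in%
                          plant$position)
      if (length(drop_res)) {
        pr <- pocket$record$protein
        pocket$record$protein <- pr[!pr$resno %in% drop_res, , drop = FALSE]
        pocket$pdb <- .pocket_pdb(pocket$record$protein,
                                  pocket$record$ligand$atoms,
                                  pocket$record$ligand$bonds)
      }
      seq1 <- aa3to1(.pocket_residue_names(pool, plant, spec$pocket_size))
      seq1[drop_res] <- "-"
      rows[k] <- paste(seq1, collapse = "")
      complexes[[ids[k]]] <- pocket
    }
    aln <- msa(ids, rows)
    smiles <- make_compound_family(sub_seeds[n_total + 1], scaffold,
                                   n_variants = n_total,
                                   edit_rate = compound_edit_rate)
    names(smiles) <- ids
    compounds <- lapply(ids, function(i) parse_compound(smiles[[i]], id = i))
    names(compounds) <- ids
    list(complexes = complexes, query_id = ids[1], aln = aln,
         compounds = compounds, smiles = smiles, ground_truth = truth,
         channels = split(pool, pool$group))
  })
}

# residue names per position for a given plant (fillers are ALA)
.pocket_residue_names <- function(pool, plant, pocket_size) {
  res <- rep("ALA", pocket_size)
  if (nrow(plant)) {
    keys <- paste(plant$itype, plant$chain_part, sep = ".")
    res[plant$position] <- vapply(keys, function(k)
      .PLANT_TEMPLATES[[k]]$resid, "")
  }
  res
}

#' Run a planted scenario through the pipeline
#'
#' @param scen result of \code{\link{make_homopharma_scenario}}.
#' @param config pipeline configuration.
#' @return the \code{\link{homopharma}} result, with the ground truth
#'   attached as attribute \code{truth}.
#' @export
run_scenario <- function(scen, config = homopharma_config()) {
  query <- scen$complexes[[scen$query_id]]$record
  cands <- lapply(scen$complexes[setdiff(names(scen$complexes),
                                         scen$query_id)],
                  function(p) p$record)
  fit <- homopharma(query, cands, compounds = scen$compounds,
                    aln = scen$aln, config = config)
  attr(fit, "truth") <- scen$ground_truth
  fit
}
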