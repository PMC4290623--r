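mk_protein_atom <- function(name, resid, x, resno = 1, mainchain = FALSE) {
  data.frame(name = name, element = substr(name, 1, 1), x = x, y = 0, z = 0,
             chain = "A", resno = resno, insert = "", resid = resid,
             is_mainchain = mainchain,
             residue = sprintf("A:%d", resno), stringsAsFactors = FALSE)
}

mk_record <- function(protein, lig_atoms, lig_bonds = NULL) {
  if (is.null(lig_bonds))
    lig_bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  structure(list(complex_id = "toy", protein = protein,
                 ligand = structure(list(component_id = "LIG",
                                         atoms = lig_atoms, bonds = lig_bonds,
                                         heavy_atom_count = nrow(lig_atoms)),
                                    class = "Ligand"),
                 source = list(path = NA, format = "synthetic")),
            class = "ComplexRecord")
}

lig_atom <- function(name, element, x) {
  data.frame(name = name, element = element, x = x, y = 0, z = 0,
             stringsAsFactors = FALSE)
}

test_that("protein atom roles follow the residue rule table", {
  prot <- rbind(mk_protein_atom("OD1", "ASP", 0, 1),
                mk_protein_atom("OD2", "ASP", 1, 1),
                mk_protein_atom("O",   "ASP", 2, 1, mainchain = TRUE),
                mk_protein_atom("N",   "PRO", 3, 2, mainchain = TRUE),
                mk_protein_atom("NZ",  "LYS", 4, 3))
  rec <- assign_atom_roles(mk_record(prot, lig_atom("C1", "C", 50)))
  p <- rec$protein
  expect_true(all(p$acceptor[p$name %in% c("OD1", "OD2")]))
  expect_true(all(p$negative[p$name %in% c("OD1", "OD2")]))
  expect_true(p$acceptor[p$name == "O"])          # backbone O of any residue
  expect_false(p$donor[p$name == "N"])            # proline N has no H
  expect_true(p$donor[p$name == "NZ"] && p$positive[p$name == "NZ"])
})

test_that("ligand role heuristics cover hydroxyl, carboxylate and amines", {
  # quercetin-like hydroxyl: O bonded to one C -> donor and acceptor
  la <- rbind(lig_atom("O1", "O", 0), lig_atom("C1", "C", 1.4))
  rec <- assign_atom_roles(mk_record(mk_protein_atom("CA", "GLY", 50, 1, TRUE),
                                     la, data.frame(i = 1, j = 2, order = 1)))
  expect_true(rec$ligand$atoms$donor[1] && rec$ligand$atoms$acceptor[1])

  # carboxylate: both terminal O on the same C are negative, not donors
  la2 <- rbind(lig_atom("O1", "O", 0), lig_atom("C1", "C", 1.25),
               lig_atom("O2", "O", 2.5))
  rec2 <- assign_atom_roles(mk_record(mk_protein_atom("CA", "GLY", 50, 1, TRUE),
                                      la2, data.frame(i = c(1, 2), j = c(2, 3),
                                                      order = c(1, 2))))
  expect_true(all(rec2$ligand$atoms$negative[c(1, 3)]))
  expect_false(any(rec2$ligand$atoms$donor[c(1, 3)]))

  # quaternary N is positive
  la3 <- rbind(lig_atom("N1", "N", 0), lig_atom("C1", "C", 1.5),
               lig_atom("C2", "C", -1.5),
               data.frame(name = c("C3", "C4"), element = "C", x = 0,
                          y = c(1.5, -1.5), z = 0, stringsAsFactors = FALSE))
  rec3 <- assign_atom_roles(mk_record(mk_protein_atom("CA", "GLY", 50, 1, TRUE),
                                      la3, data.frame(i = 1, j = 2:5, order = 1)))
  expect_true(rec3$ligand$atoms$positive[1])
})

test_that("contacts are typed by exclusive precedence with one event per pair", {
  # far ligand: no events at all
  far <- mk_record(mk_protein_atom("N", "GLY", 0, 1, TRUE),
                   lig_atom("O1", "O", 10))
  expect_equal(nrow(detect_interactions(far)), 0)

  # backbone N donor at 2.9 A from a lone acceptor O: one main-chain hbond
  hb <- mk_record(mk_protein_atom("N", "GLY", 0, 1, TRUE),
                  lig_atom("O1", "O", 2.9))
  ev <- detect_interactions(hb)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$itype, "hbond")
  expect_equal(ev$chain_part, "mainchain")

  # Lys NZ(+) vs carboxylate O(-) inside both cutoffs: electrostatic wins,
  # the pair is not double-counted as hydrogen bond
  prot <- mk_protein_atom("NZ", "LYS", 0, 1)
  la <- rbind(lig_atom("O1", "O", 3.3), lig_atom("C1", "C", 4.55),
              lig_atom("O2", "O", 5.8))
  elec <- mk_record(prot, la, data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  ev2 <- detect_interactions(elec)
  ev2_o1 <- ev2[ev2$ligand_atom == "O1", ]
  expect_equal(nrow(ev2_o1), 1)
  expect_equal(ev2_o1$itype, "electrostatic")
  expect_equal(ev2_o1$chain_part, "sidechain")

  # beyond 4.0 A the same pair degrades to vdw (inside 4.5)
  la_far <- la; la_far$x <- la_far$x + 1
  elec2 <- mk_record(prot, la_far, data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  ev3 <- detect_interactions(elec2)
  expect_equal(ev3$itype[ev3$ligand_atom == "O1"], "vdw")
})

test_that("profiles aggregate events over alignment columns", {
  cmap <- structure(c("A:1" = 3L, "A:2" = 5L), n_columns = 6L)
  empty <- build_profile(data.frame(residue = character(0), itype = character(0),
                                    chain_part = character(0)), cmap)
  expect_equal(sum(empty$mat), 0)
  expect_equal(dim(empty$mat), c(6, 6))

  ev <- data.frame(residue = rep("A:1", 3), itype = "hbond",
                   chain_part = "sidechain", stringsAsFactors = FALSE)
  bin <- build_profile(ev, cmap, mode = "binary")
  expect_equal(unname(bin$mat[3, "hbond.sidechain"]), 1)
  expect_equal(sum(bin$mat), 1)
  cnt <- build_profile(ev, cmap, mode = "count")
  expect_equal(unname(cnt$mat[3, "hbond.sidechain"]), 3)
  expect_equal(sum(cnt$mat), cnt$n_events)

  ev_bad <- data.frame(residue = "A:9", itype = "vdw", chain_part = "mainchain")
  expect_error(build_profile(ev_bad, cmap), "A:9")
})

test_that("profiles are invariant under rigid transformation of the complex", {
  plant <- data.frame(position = c(2, 5, 8),
                      itype = c("hbond", "electrostatic", "vdw"),
                      chain_part = c("mainchain", "sidechain", "sidechain"))
  base <- make_pocket_complex("rigidA", plant, seed = 21)
  moved <- make_pocket_complex("rigidA", plant, seed = 99, rigid = TRUE)
  aln <- msa("rigidA", chain_sequence(base$record)$sequence)
  p1 <- interaction_profile(base$record, aln, "rigidA")
  p2 <- interaction_profile(moved$record, aln, "rigidA")
  expect_equal(p1$mat, p2$mat)
})

test_that("planted fixtures produce exactly the planted channels", {
  plant <- data.frame(position = c(1, 4, 7, 10, 13),
                      itype = c("hbond", "hbond", "electrostatic", "vdw", "vdw"),
                      chain_part = c("mainchain", "sidechain", "sidechain",
                                     "sidechain", "mainchain"))
  pk <- make_pocket_complex("plantck", plant, seed = 31)
  aln <- msa("plantck", chain_sequence(pk$record)$sequence)
  prof <- interaction_profile(pk$record, aln, "plantck")
  nz <- which(prof$mat > 0, arr.ind = TRUE)
  got <- data.frame(position = unname(nz[, 1]),
                    channel = colnames(prof$mat)[nz[, 2]])
  want <- data.frame(position = plant$position,
                     channel = paste(plant$itype, plant$chain_part, sep = "."))
  expect_equal(got[order(got$position), ], want[order(want$position), ],
               ignore_attr = TRUE)
})
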