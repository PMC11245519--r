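# Ligand-contact extraction and interaction labelling.

toy_complex <- function(nProt = 25L, nLig = 5L, spread = 8) {
  prot <- lapply(seq_len(nProt), function(i)
    pdb_line("ATOM", i, sample(c("CA", "CB", "N", "O", "CG"), 1L),
             sample(c("ALA", "SER", "ASP", "TRP"), 1L), "A",
             ceiling(i / 3), runif(1, -spread, spread),
             runif(1, -spread, spread), runif(1, -spread, spread),
             sample(c("C", "N", "O"), 1L)))
  lig <- lapply(seq_len(nLig), function(j)
    pdb_line("HETATM", nProt + j, paste0("X", j), "URC", "A", 900,
             runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 2), "C"))
  readStructure(write_pdb(unlist(c(prot, lig))))
}

test_that("contacts respect the distance cutoff", {
  atoms <- readStructure(write_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 10, 0, 0, 3.4, "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 11, 0, 0, 3.6, "C"),
    pdb_line("HETATM", 3, "C1", "URC", "A", 900, 0, 0, 0, "C"))))
  ct <- findLigandContacts(atoms, "URC")
  expect_identical(ct$residue_seq, 10L)
  expect_equal(ct$min_distance, 3.4)
  expect_identical(nrow(findLigandContacts(atoms, "URC", cutoff = 3.3)), 0L)
})

test_that("contact sets equal the all-pairs oracle on random complexes", {
  set.seed(11)
  for (rep in 1:10) {
    atoms <- toy_complex()
    got <- proposeBindingPositions(findLigandContacts(atoms, "URC"))
    expect_identical(got, contact_oracle(atoms, "URC"))
  }
})

test_that("contacts are invariant under rigid-body motion and monotone in cutoff", {
  set.seed(12)
  atoms <- toy_complex()
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L)
  xyz <- as.matrix(atoms[c("x", "y", "z")]) %*% R
  moved <- atoms
  moved$x <- xyz[, 1L] + 5; moved$y <- xyz[, 2L] - 3; moved$z <- xyz[, 3L]
  a <- findLigandContacts(atoms, "URC")
  b <- findLigandContacts(moved, "URC")
  expect_identical(a$residue_seq, b$residue_seq)
  expect_equal(a$min_distance, b$min_distance, tolerance = 1e-9)
  small <- findLigandContacts(atoms, "URC", cutoff = 3.0)
  expect_true(all(small$residue_seq %in% a$residue_seq))
})

test_that("hydrogens are ignored and duplicate residues collapse", {
  atoms <- readStructure(write_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 10, 0, 0, 3.4, "C"),
    pdb_line("ATOM", 2, "CB", "GLY", "A", 10, 0, 0, 3.2, "C"),
    pdb_line("ATOM", 3, "H", "GLY", "A", 11, 0, 0, 1.0, "H"),
    pdb_line("HETATM", 4, "C1", "URC", "A", 900, 0, 0, 0, "C"))))
  ct <- findLigandContacts(atoms, "URC")
  expect_identical(ct$residue_seq, 10L)       # one record per residue
  expect_equal(ct$min_distance, 3.2)          # min over atom pairs
})

test_that("interaction labels follow the N/O and aromatic-ring rules", {
  atoms <- readStructure(write_pdb(c(
    pdb_line("ATOM", 1, "OD1", "ASP", "A", 1, 0, 0, 2.9, "O"),
    pdb_line("ATOM", 2, "CB", "ALA", "A", 2, 3.4, 0, 0, "C"),
    pdb_line("ATOM", 3, "CZ2", "TRP", "A", 3, 0, 3.8, 0, "C"),
    pdb_line("HETATM", 4, "N1", "URC", "A", 900, 0, 0, 0, "N"))))
  ct <- labelContacts(findLigandContacts(atoms, "URC", cutoff = 4.0),
                      atoms, "URC", cutoff = 3.5)
  labs <- setNames(ct$label, ct$residue_seq)
  expect_identical(labs[["1"]], "hydrogen-bond-capable")  # O...N at 2.9
  expect_identical(labs[["2"]], "other")                  # C...N on ALA
  expect_identical(labs[["3"]], "aromatic-proximal")      # ring at 3.8
})

test_that("binding-position proposal sorts and de-duplicates", {
  ct <- data.frame(residue_seq = c(140L, 121L, 140L, 129L))
  expect_identical(proposeBindingPositions(ct), c(121L, 129L, 140L))
  expect_identical(proposeBindingPositions(data.frame(
    residue_seq = integer())), integer())
})

test_that("absent ligands and protein-free structures error", {
  atoms <- readStructure(write_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("HETATM", 2, "C1", "URC", "A", 900, 0, 0, 2, "C"))))
  expect_error(findLigandContacts(atoms, "ADE"), "no heavy atoms")
  expect_error(findLigandContacts(atoms, "URC", cutoff = -1), "positive")
})
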