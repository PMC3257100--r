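# hand-assembled PDB records, independent of the package's writer
pdb_line <- function(name, resn, chain, resno, x, y, z,
                     alt = " ", occ = 1, type = "ATOM  ", serial = 1,
                     ele = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, ele)
}

test_that("parsing keeps standard residues and drops water, ligands, hydrogens", {
  txt <- c(
    pdb_line("N",  "ALA", "A", 1, 0, 1, 0),
    pdb_line("CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("CB", "ALA", "A", 1, 1, 2, 3),
    pdb_line("HB1", "ALA", "A", 1, 9, 9, 9, ele = "H"),
    pdb_line("CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line("CA", "SER", "A", 3, 7.6, 0, 0),
    pdb_line("CB", "SER", "A", 3, 8, 0, 0),
    pdb_line("OG", "SER", "A", 3, 10, 0, 0),
    pdb_line("CA", "MSE", "A", 4, 11.4, 0, 0, type = "HETATM"),
    pdb_line("SE", "MSE", "A", 4, 12, 1, 0, type = "HETATM", ele = "SE"),
    pdb_line("CA", "LEU", "A", 5, 15.2, 0, 0),
    pdb_line("O",  "HOH", "A", 101, 50, 50, 50, type = "HETATM"),
    pdb_line("C1", "NAG", "A", 102, 60, 60, 60, type = "HETATM"),
    "END")
  s <- suppressMessages(read_structure(txt))
  expect_equal(nrow(s), 5)
  expect_identical(s$seq_index, 0:4)
  expect_identical(s$resname, c("ALA", "GLY", "SER", "MET", "LEU"))
  # ALA centre = its CB (hydrogen excluded), GLY centre = CA,
  # SER centre = midpoint of CB/OG, MET (from MSE) centre = SE atom
  expect_equal(unlist(s[1, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))
  expect_equal(unlist(s[2, c("x", "y", "z")]), c(x = 3.8, y = 0, z = 0))
  expect_equal(unlist(s[3, c("x", "y", "z")]), c(x = 9, y = 0, z = 0))
  expect_equal(unlist(s[4, c("x", "y", "z")]), c(x = 12, y = 1, z = 0))
  # LEU has no side-chain atoms in the file: CA fallback
  expect_equal(unlist(s[5, c("x", "y", "z")]), c(x = 15.2, y = 0, z = 0))
})

test_that("chains partition the nodes into contiguous 0-based ranges", {
  txt <- c(pdb_line("CA", "ALA", "A", 1, 0, 0, 0),
           pdb_line("CA", "GLY", "A", 2, 4, 0, 0),
           "TER",
           pdb_line("CA", "VAL", "B", 1, 20, 0, 0),
           pdb_line("CA", "TRP", "B", 2, 24, 0, 0),
           pdb_line("CA", "LYS", "B", 3, 28, 0, 0),
           "END")
  s <- read_structure(txt, quiet = TRUE)
  expect_identical(unique(s$chain), c("A", "B"))
  expect_identical(s$seq_index[s$chain == "A"], 0:1)
  expect_identical(s$seq_index[s$chain == "B"], 0:2)
})

test_that("altLoc picks the highest occupancy, first record on ties", {
  txt <- c(pdb_line("CA", "ALA", "A", 1, 0, 0, 0),
           pdb_line("CB", "ALA", "A", 1, 1, 0, 0, alt = "A", occ = 0.4),
           pdb_line("CB", "ALA", "A", 1, 2, 0, 0, alt = "B", occ = 0.6),
           pdb_line("CA", "SER", "A", 2, 4, 0, 0),
           pdb_line("CB", "SER", "A", 2, 5, 0, 0, alt = "A", occ = 0.5),
           pdb_line("CB", "SER", "A", 2, 6, 0, 0, alt = "B", occ = 0.5),
           "END")
  s <- read_structure(txt, quiet = TRUE)
  expect_equal(s$x[1], 2)   # occupancy 0.6 conformer
  expect_equal(s$x[2], 5)   # tie: first encountered
})

test_that("multi-MODEL files read a single selected model", {
  model <- function(k, x) c(sprintf("MODEL %8d", k),
                            pdb_line("CA", "GLY", "A", 1, x, 0, 0),
                            "ENDMDL")
  txt <- c(model(1, 1), model(2, 2))
  expect_equal(read_structure(txt, quiet = TRUE)$x, 1)
  expect_equal(read_structure(txt, model = 2, quiet = TRUE)$x, 2)
  expect_error(read_structure(txt, model = 3, quiet = TRUE), "model 3")
})

test_that("degenerate inputs raise informative errors", {
  expect_error(read_structure(c(pdb_line("O", "HOH", "A", 1, 0, 0, 0,
                                         type = "HETATM"), "END"),
                              quiet = TRUE),
               class = "wrndock_empty_structure")
  bad <- pdb_line("CA", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 32, 34) <- "abc"
  expect_error(read_structure(c(bad, "END"), quiet = TRUE),
               class = "wrndock_parse_error")
})

test_that("side-chain centres follow the documented conventions", {
  atoms <- function(nm, m) tibble::tibble(atom = nm, x = m[, 1], y = m[, 2], z = m[, 3])
  expect_equal(sidechain_center(atoms("CB", rbind(c(1, 2, 3))), "ALA"),
               c(1, 2, 3))
  expect_equal(sidechain_center(atoms("CA", rbind(c(0, 0, 0))), "GLY"),
               c(0, 0, 0))
  expect_equal(sidechain_center(atoms(c("CB", "OG"),
                                      rbind(c(0, 0, 0), c(2, 0, 0))), "SER"),
               c(1, 0, 0))
  # glycine keeps its CA even when stray non-backbone atoms are present
  expect_equal(sidechain_center(atoms(c("CA", "CB"),
                                      rbind(c(0, 0, 0), c(9, 9, 9))), "GLY"),
               c(0, 0, 0))
  expect_null(sidechain_center(atoms(c("N", "C"),
                                     rbind(c(0, 0, 0), c(1, 0, 0))), "ALA"))
})

test_that("centres and backbone transform equivariantly under rigid maps", {
  set.seed(42)
  rot <- random_rotation()
  tr <- c(3, -2, 7)
  # atom-level equivariance of the centre rule
  m <- matrix(rnorm(12), 4, 3)
  a <- tibble::tibble(atom = c("CA", "CB", "CG", "OD1"),
                      x = m[, 1], y = m[, 2], z = m[, 3])
  m2 <- sweep(m %*% t(rot), 2, tr, "+")
  a2 <- tibble::tibble(atom = a$atom, x = m2[, 1], y = m2[, 2], z = m2[, 3])
  expect_equal(sidechain_center(a2, "ASP"),
               drop(rot %*% sidechain_center(a, "ASP")) + tr,
               tolerance = 1e-12, ignore_attr = TRUE)
  # structure-level transform maps every coordinate by the same rigid map
  s <- make_polypeptide(12, "coil", seed = 2)
  s2 <- transform_structure(s, rot, tr)
  expect_equal(as.matrix(s2[, c("x", "y", "z")]),
               sweep(as.matrix(s[, c("x", "y", "z")]) %*% t(rot), 2, tr, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
  bb <- structure_backbone(s); bb2 <- structure_backbone(s2)
  expect_equal(as.matrix(bb2[, c("x", "y", "z")]),
               sweep(as.matrix(bb[, c("x", "y", "z")]) %*% t(rot), 2, tr, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("parsing the serialisation of a parsed model is idempotent", {
  s <- make_complex(8, 5, separation = 4, seed = 9)
  s1 <- read_structure(write_pdb(s), quiet = TRUE)
  s2 <- read_structure(write_pdb(s1), quiet = TRUE)
  expect_identical(nrow(s1), nrow(s))
  expect_equal(as.data.frame(s1[, names(s)]), as.data.frame(s2[, names(s)]))
  expect_equal(as.matrix(s1[, c("x", "y", "z")]),
               as.matrix(s[, c("x", "y", "z")]))
})
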