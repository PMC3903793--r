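test_that("a minimal two-chain PDB loads with both chains and all atoms", {
  s <- load_structure(mini_two_chain_pdb(), pdb_id = "MINI")
  expect_s3_class(s, "piface_structure")
  expect_identical(chain_ids(s), c("A", "B"))
  expect_identical(nrow(s$atoms), 12L)
  expect_identical(s$pdb_id, "MINI")
  expect_equal(s$atoms$x[2], 1.5)
})

test_that("a file with only water HETATM records yields zero protein chains", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "O", "HOH", "W", 1, 0, 0, 0, record = "HETATM",
                  element = "O"),
    pdb_atom_line(2, "O", "HOH", "W", 2, 5, 0, 0, record = "HETATM",
                  element = "O")))
  s <- filter_structure(load_structure(p))
  expect_length(chain_ids(s), 0L)
  expect_identical(nrow(s$atoms), 0L)
})

test_that("corrupt coordinate records raise a parse error naming the line", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ATOM      2  CA  ALA A   2      xx.xxx   0.000   0.000  1.00  0.00           C",
               "END"), p)
  expect_error(load_structure(p), "bad coordinate")
})

test_that("unknown elements fall back to the default radius with a warning", {
  p <- write_pdb_fixture(pdb_atom_line(1, "XX", "ALA", "A", 1, 0, 0, 0,
                                       element = "XQ"))
  expect_warning(s <- load_structure(p), "unknown element")
  expect_equal(s$atoms$radius, 1.70)
})

test_that("filtering removes nucleic-acid chains and keeps protein chains", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0, element = "C"),
    pdb_atom_line(4, "P",   "DA", "B", 1, 0, 9, 0, element = "P"),
    pdb_atom_line(5, "C1'", "DA", "B", 1, 1, 9, 0, element = "C"),
    pdb_atom_line(6, "P",   "DT", "B", 2, 2, 9, 0, element = "P")))
  s <- filter_structure(load_structure(p))
  expect_identical(chain_ids(s), "A")
})

test_that("chains containing a nonstandard residue (MSE) are dropped whole", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0, element = "C"),
    pdb_atom_line(4, "N",  "MSE", "A", 2, 3.5, 1.3, 0, record = "HETATM",
                  element = "N"),
    pdb_atom_line(5, "CA", "MSE", "A", 2, 4.3, 2.5, 0, record = "HETATM",
                  element = "C"),
    pdb_atom_line(6, "C",  "MSE", "A", 2, 5.7, 2.2, 0, record = "HETATM",
                  element = "C"),
    pdb_atom_line(7, "N",  "GLY", "B", 1, 0, 9, 0, element = "N"),
    pdb_atom_line(8, "CA", "GLY", "B", 1, 1.5, 9, 0, element = "C"),
    pdb_atom_line(9, "C",  "GLY", "B", 1, 2.2, 10.3, 0, element = "C")))
  s <- filter_structure(load_structure(p))
  expect_identical(chain_ids(s), "B")
})

test_that("only the first model of an NMR ensemble is retained", {
  one_model <- function(k, z) c(
    sprintf("MODEL     %4d", k),
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, z, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, z, element = "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.2, 1.3, z, element = "C"),
    "ENDMDL")
  p <- write_pdb_fixture(unlist(lapply(1:5, function(k) one_model(k, k * 10))))
  s <- filter_structure(load_structure(p))
  expect_identical(nrow(s$atoms), 3L)
  expect_true(all(s$atoms$z == 10))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, altloc = "A", occ = 0.4,
                  element = "C"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 2.0, 0, 0, altloc = "B", occ = 0.6,
                  element = "C"),
    pdb_atom_line(4, "C",  "ALA", "A", 1, 2.2, 1.3, 0, element = "C")))
  s <- filter_structure(load_structure(p))
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)
})

test_that("filter_structure is idempotent", {
  s <- load_structure(mini_two_chain_pdb())
  f1 <- filter_structure(s)
  f2 <- filter_structure(f1)
  expect_identical(f1$atoms, f2$atoms)
})

test_that("writing then re-loading a filtered structure preserves residues and atoms", {
  s <- filter_structure(load_structure(mini_two_chain_pdb(), pdb_id = "MINI"))
  p <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, p)
  s2 <- filter_structure(load_structure(p, pdb_id = "MINI"))
  expect_identical(s$atoms[, c("atom", "resname", "chain", "resno")],
                   s2$atoms[, c("atom", "resname", "chain", "resno")])
  expect_equal(s$atoms[, c("x", "y", "z")], s2$atoms[, c("x", "y", "z")],
               tolerance = 1e-6)
})

test_that("enumerate_chain_pairs gives all n(n-1)/2 pairs lexicographically", {
  s <- filter_structure(load_structure(mini_two_chain_pdb()))
  expect_identical(enumerate_chain_pairs(s),
                   matrix(c("A", "B"), 1, 2,
                          dimnames = list(NULL, c("chain_a", "chain_b"))))
  # synthetic 4-chain structure
  a <- s$atoms
  a4 <- do.call(rbind, lapply(1:4, function(k) {
    b <- a[a$chain == "A", ]; b$chain <- LETTERS[k]; b$y <- b$y + 20 * k; b
  }))
  s4 <- piface:::new_structure("FOUR", a4, filtered = TRUE)
  prs <- enumerate_chain_pairs(s4)
  expect_identical(nrow(prs), 6L)
  expect_false(any(duplicated(apply(prs, 1, paste, collapse = ""))))
  expect_true(all(prs[, 1] < prs[, 2]))
  # single chain -> empty
  s1 <- piface:::new_structure("ONE", a[a$chain == "A", ], filtered = TRUE)
  expect_identical(nrow(enumerate_chain_pairs(s1)), 0L)
})

test_that("the minimal mmCIF atom_site loop parses equivalently to PDB", {
  cif <- c("data_test", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
           "ATOM 1 N N . ALA A 1 ? 0.000 0.000 0.000 1.00 1",
           "ATOM 2 C CA . ALA A 1 ? 1.500 0.000 0.000 1.00 1",
           "ATOM 3 C C . ALA A 1 ? 2.200 1.300 0.000 1.00 1",
           "#")
  p <- tempfile(fileext = ".cif")
  writeLines(cif, p)
  s <- load_structure(p, format = "mmcif", pdb_id = "CIFT")
  expect_identical(nrow(s$atoms), 3L)
  expect_identical(s$atoms$atom, c("N", "CA", "C"))
  expect_equal(s$atoms$x, c(0, 1.5, 2.2))
})
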