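# In-code fixtures: minimal PDB texts and small atom tables.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", altloc = " ", icode = " ",
                          occ = 1.00, element = substr(trimws(name), 1, 1)) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# minimal 2-chain, 2-residue-per-chain protein fixture
mini_two_chain_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0.0, 0.0, 0.0, element = "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.5, 0.0, 0.0, element = "C"),
    pdb_atom_line(3, "C",  "GLY", "A", 1, 2.2, 1.3, 0.0, element = "C"),
    pdb_atom_line(4, "N",  "ALA", "A", 2, 3.5, 1.3, 0.0, element = "N"),
    pdb_atom_line(5, "CA", "ALA", "A", 2, 4.3, 2.5, 0.0, element = "C"),
    pdb_atom_line(6, "C",  "ALA", "A", 2, 5.7, 2.2, 0.0, element = "C"),
    pdb_atom_line(7, "N",  "SER", "B", 1, 0.0, 6.0, 0.0, element = "N"),
    pdb_atom_line(8, "CA", "SER", "B", 1, 1.5, 6.0, 0.0, element = "C"),
    pdb_atom_line(9, "C",  "SER", "B", 1, 2.2, 7.3, 0.0, element = "C"),
    pdb_atom_line(10, "N",  "VAL", "B", 2, 3.5, 7.3, 0.0, element = "N"),
    pdb_atom_line(11, "CA", "VAL", "B", 2, 4.3, 8.5, 0.0, element = "C"),
    pdb_atom_line(12, "C",  "VAL", "B", 2, 5.7, 8.2, 0.0, element = "C")))
}

# structure holding two single-atom-distinguished residues at a set distance
# (for exercising the contact rule arithmetic); backbone present so the
# residues survive filtering
two_residue_pair_structure <- function(gap_x) {
  mk <- function(chain, x0, y_away) {
    # CA sits on the x axis; N and C are pushed far off so the closest
    # inter-chain atom pair is always CA (carbon, r = 1.70) vs CA
    data.frame(model = 1L, record = "ATOM", serial = NA_integer_,
               atom = c("N", "CA", "C"), altloc = " ", resname = "ALA",
               chain = chain, resno = 1L, icode = "",
               x = x0 + c(-1.3, 0, 1.3), y = c(y_away, 0, y_away),
               z = 0, occ = 1, element = c("N", "C", "C"),
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk("A", 0, -8), mk("B", gap_x, 8))
  atoms$radius <- piface::vdw_radius(atoms$element)
  atoms$serial <- seq_len(nrow(atoms))
  piface:::new_structure("TEST", atoms, filtered = TRUE)
}

# a family of similar toy interfaces: perturbed copies of one parent
toy_interface_family <- function(n, pdb_ids, sigma = 0.25, fraction = 0.3,
                                 seed0 = 100, ...) {
  parent <- make_toy_complex(...)
  lapply(seq_len(n), function(k) {
    s <- perturb_interface(parent, sigma = if (k == 1) 0 else sigma,
                           fraction_displaced = fraction, seed = seed0 + k)
    s$pdb_id <- pdb_ids[k]
    s
  })
}

extract_first_interface <- function(s) {
  prs <- enumerate_chain_pairs(s)
  extract_interface(s, prs[1, 1], prs[1, 2])
}

# deterministic rigid motion applied to a structure
rigid_move_structure <- function(s, angle = 0.7, axis = c(1, 2, 2),
                                 shift = c(10, -5, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
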