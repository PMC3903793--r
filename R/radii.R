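#' Van der Waals radius tables
#'
#' Bondi-style van der Waals radii (Angstrom) used by the contact rule and
#' the Shrake-Rupley surface engine. The contact rule declares two residues
#' in contact when any inter-chain atom pair is closer than
#' `r_vdw(x) + r_vdw(y) + 0.5` A, so contact counts depend on this table;
#' it is therefore explicit and swappable everywhere it is consumed.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param table named numeric vector mapping element symbol to radius (A).
#' @param default radius (A) assigned to elements absent from `table`;
#'   a warning is emitted once per unknown element.
#' @return numeric vector of radii, same length as `element`.
#' @examples
#' vdw_radius(c("C", "N", "O", "S"))
#' @export
vdw_radius <- function(element, table = default_vdw_table(), default = 1.70) {
  el <- toupper(trimws(element))
  r <- unname(table[el])
  unknown <- is.na(r) & !is.na(el) & nzchar(el)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using default vdW radius ", default, " A", call. = FALSE)
    r[unknown] <- default
  }
  r[is.na(r)] <- default
  r
}

#' @rdname vdw_radius
#' @export
default_vdw_table <- function() {
  c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, FE = 1.40, MG = 1.73, CA = 2.31, MN = 1.97, CU = 1.40,
    "NA" = 2.27, K = 2.75, NI = 1.63, CO = 1.40, CD = 1.58, HG = 1.55)
}

#' Reference maximum accessible surface areas per residue type
#'
#' NACCESS-style maximum accessible surface areas (A^2) of residue X in an
#' extended Ala-X-Ala tripeptide, used to convert absolute residue ASA into
#' relative ASA (RASA, percent). The table is the denominator of
#' [relative_asa()]; swap it to match a different reference convention.
#'
#' @return named numeric vector over the 20 standard amino acids
#'   (three-letter codes).
#' @export
default_max_asa_table <- function() {
  c(ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39,
    CYS = 134.28, GLN = 178.50, GLU = 172.25, GLY = 80.10,
    HIS = 182.88, ILE = 175.12, LEU = 178.63, LYS = 200.78,
    MET = 194.15, PHE = 199.48, PRO = 136.13, SER = 116.50,
    THR = 139.27, TRP = 249.36, TYR = 187.24, VAL = 151.44)
}

# the 20 standard amino acids (three-letter codes)
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# residue names treated as nucleic-acid polymer components
NUCLEIC_RESNAMES <- c("A", "C", "G", "U", "T", "I",
                      "DA", "DC", "DG", "DT", "DU", "DI")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
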