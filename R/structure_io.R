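#' Read a coordinate file into a structure object
#'
#' Parses a PDB (fixed-column `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records) or a
#' minimal mmCIF (`atom_site` loop) file. No filtering is applied at load
#' time: all models, chains and heteroatoms are retained so that
#' [filter_structure()] owns every selection rule. Each atom is annotated
#' with a van der Waals radius from `radius_table` (unknown elements fall
#' back to `default_radius` with a warning).
#'
#' @param path file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @param pdb_id 4-character identifier; defaults to the upper-cased file
#'   base name (first 4 characters) unless a `HEADER` record supplies one.
#' @param radius_table,default_radius see [vdw_radius()].
#' @param keep_hydrogens retain hydrogen/deuterium atoms (default `FALSE`;
#'   typical X-ray depositions carry none and the contact rule in the
#'   literature operates on heavy atoms).
#' @return an object of class `piface_structure`: a list with elements
#'   `pdb_id`, `atoms` (one row per atom: `model`, `record`, `serial`,
#'   `atom`, `altloc`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`,
#'   `occ`, `element`, `radius`) and `filtered` (logical).
#' @seealso [filter_structure()], [enumerate_chain_pairs()],
#'   [write_structure_pdb()]
#' @export
load_structure <- function(path, format = c("pdb", "mmcif"), pdb_id = NULL,
                           radius_table = default_vdw_table(),
                           default_radius = 1.70, keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atoms <- switch(format,
                  pdb = parse_pdb_lines(lines, path),
                  mmcif = parse_mmcif_lines(lines, path))
  if (is.null(pdb_id)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    if (format == "pdb" && length(hdr) >= 1L && nchar(hdr[[1L]]) >= 66L) {
      pdb_id <- toupper(trimws(substr(hdr[[1L]], 63L, 66L)))
    }
    if (is.null(pdb_id) || !nzchar(pdb_id)) {
      pdb_id <- toupper(substr(sub("\\.(pdb|ent|cif)(\\.gz)?$", "",
                                   basename(path), ignore.case = TRUE), 1L, 4L))
    }
  }
  if (!keep_hydrogens && nrow(atoms) > 0L) {
    atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  }
  atoms$radius <- vdw_radius(atoms$element, radius_table, default_radius)
  new_structure(pdb_id, atoms, filtered = FALSE)
}

new_structure <- function(pdb_id, atoms, filtered = FALSE) {
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, atoms = atoms, filtered = filtered),
            class = "piface_structure")
}

parse_pdb_lines <- function(lines, path = "<text>") {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # ordinal model index per line (MODEL serial numbers are not trusted;
  # "first model" only needs ordering)
  model_no <- cumsum(rec == "MODEL ")
  model_no[model_no == 0L] <- 1L
  idx <- which(is_atom)
  if (length(idx) == 0L) {
    return(empty_atom_df())
  }
  al <- lines[idx]
  bad <- nchar(al) < 54L
  if (any(bad)) {
    stop("unparseable ", path, ": ATOM/HETATM record shorter than 54 columns at line ",
         idx[which(bad)[1L]], ": ", al[which(bad)[1L]])
  }
  num <- function(from, to) suppressWarnings(as.numeric(substr(al, from, to)))
  xyz <- cbind(num(31L, 38L), num(39L, 46L), num(47L, 54L))
  if (anyNA(xyz)) {
    i <- which(is.na(xyz[, 1L]) | is.na(xyz[, 2L]) | is.na(xyz[, 3L]))[1L]
    stop("unparseable ", path, ": bad coordinate field at line ", idx[i],
         ": ", al[i])
  }
  element <- toupper(trimws(substr(al, 77L, 78L)))
  name <- trimws(substr(al, 13L, 16L))
  # deduce element from the atom-name columns when the element field is blank
  blank <- !nzchar(element)
  if (any(blank)) {
    guess <- toupper(trimws(substr(al, 13L, 14L)))
    one <- !(guess %in% names(default_vdw_table())) | grepl("^[0-9]", guess)
    guess[one] <- substr(gsub("^[0-9]+", "", toupper(name[one])), 1L, 1L)
    element[blank] <- guess[blank]
  }
  occ <- num(55L, 60L)
  occ[is.na(occ)] <- 1
  data.frame(
    model = model_no[idx],
    record = trimws(substr(al, 1L, 6L)),
    serial = suppressWarnings(as.integer(substr(al, 7L, 11L))),
    atom = name,
    altloc = substr(al, 17L, 17L),
    resname = trimws(substr(al, 18L, 20L)),
    chain = substr(al, 22L, 22L),
    resno = suppressWarnings(as.integer(substr(al, 23L, 26L))),
    icode = trimws(substr(al, 27L, 27L)),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occ = occ,
    element = element,
    stringsAsFactors = FALSE
  )
}

# minimal mmCIF reader: first atom_site loop, whitespace-separated values
parse_mmcif_lines <- function(lines, path = "<text>") {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) stop("unparseable ", path, ": no atom_site loop")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_")) break
    body <- c(body, ln)
  }
  if (length(body) == 0L) return(empty_atom_df())
  fields <- strsplit(body, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != length(tags))) {
    stop("unparseable ", path, ": atom_site row with ", nf[nf != length(tags)][1L],
         " fields (expected ", length(tags), ")")
  }
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  get <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm] else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  clean <- function(v) { v[v %in% c(".", "?")] <- ""; v }
  model_v <- suppressWarnings(as.integer(clean(get("pdbx_PDB_model_num"))))
  model_v[is.na(model_v)] <- 1L
  icode <- clean(get("pdbx_PDB_ins_code"))
  resno <- suppressWarnings(as.integer(clean(get("auth_seq_id", "label_seq_id"))))
  data.frame(
    model = model_v,
    record = toupper(get("group_PDB")),
    serial = suppressWarnings(as.integer(get("id"))),
    atom = gsub('"', "", clean(get("auth_atom_id", "label_atom_id"))),
    altloc = ifelse(nzchar(clean(get("label_alt_id"))), clean(get("label_alt_id")), " "),
    resname = clean(get("auth_comp_id", "label_comp_id")),
    chain = clean(get("auth_asym_id", "label_asym_id")),
    resno = resno,
    icode = icode,
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = {o <- suppressWarnings(as.numeric(clean(get("occupancy")))); o[is.na(o)] <- 1; o},
    element = toupper(clean(get("type_symbol"))),
    stringsAsFactors = FALSE
  )
}

empty_atom_df <- function() {
  data.frame(model = integer(), record = character(), serial = integer(),
             atom = character(), altloc = character(), resname = character(),
             chain = character(), resno = integer(), icode = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

#' @export
print.piface_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("piface_structure ", x$pdb_id,
      if (x$filtered) " (filtered)" else " (raw)",
      ": ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s)",
      if (length(ch)) paste0(" [", paste(ch, collapse = ","), "]") else "",
      "\n", sep = "")
  invisible(x)
}

# residue unique id within a structure: chain:resno:icode
res_uid <- function(chain, resno, icode) {
  paste0(chain, ":", resno, ifelse(nzchar(icode), paste0(":", icode), ""))
}

atom_res_uid <- function(atoms) res_uid(atoms$chain, atoms$resno, atoms$icode)

#' Chain identifiers of a structure
#' @param s a `piface_structure`.
#' @return sorted character vector of chain ids present.
#' @export
chain_ids <- function(s) sort(unique(s$atoms$chain))

#' Atoms of one chain
#' @param s a `piface_structure`.
#' @param chain chain identifier.
#' @return the atom data frame restricted to `chain`.
#' @export
chain_atoms <- function(s, chain) {
  s$atoms[s$atoms$chain == chain, , drop = FALSE]
}

#' Apply the dataset filtering rules to a raw structure
#'
#' Reduces a freshly loaded structure to the protein content the pipeline
#' operates on, deterministically:
#'
#' * only the first model of an NMR ensemble is retained;
#' * alternate locations are resolved to the highest-occupancy conformer
#'   (ties broken by altloc letter order);
#' * waters and non-polymeric heteroatoms (residues lacking an N/CA/C
#'   backbone) are removed;
#' * nucleic-acid chains are removed;
#' * chains containing any polymeric residue outside the 20 standard amino
#'   acids (e.g. selenomethionine, MSE) are dropped whole.
#'
#' The operation is idempotent; a structure left with no protein chain is
#' returned empty rather than raising an error (downstream steps skip it).
#'
#' @param s a `piface_structure`.
#' @return the filtered `piface_structure`.
#' @export
filter_structure <- function(s) {
  stopifnot(inherits(s, "piface_structure"))
  a <- s$atoms
  if (nrow(a) == 0L) return(new_structure(s$pdb_id, a, filtered = TRUE))
  a <- a[a$model == min(a$model), , drop = FALSE]
  # altloc resolution: highest occupancy, then altloc letter order
  key <- paste(a$chain, a$resno, a$icode, a$atom, sep = "\r")
  ord <- order(key, -a$occ, a$altloc)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$icode, a$atom, sep = "\r")), , drop = FALSE]
  a <- a[order(a$chain, a$resno, a$icode, a$serial), , drop = FALSE]
  a <- a[!(a$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (nrow(a) == 0L) return(new_structure(s$pdb_id, a, filtered = TRUE))
  # classify residues: polymeric = has N, CA and C atoms
  uid <- atom_res_uid(a)
  has_bb <- function(nm) uid %in% unique(uid[a$atom == nm])
  polymeric <- has_bb("N") & has_bb("CA") & has_bb("C")
  nucleic <- a$resname %in% NUCLEIC_RESNAMES
  drop_chain <- unique(a$chain[nucleic])
  # drop ligands (non-polymeric, non-nucleic residues)
  keep <- polymeric & !nucleic
  a2 <- a[keep & !(a$chain %in% drop_chain), , drop = FALSE]
  if (nrow(a2) > 0L) {
    # chains with any nonstandard polymeric residue are dropped whole
    nonstd_chain <- unique(a2$chain[!(a2$resname %in% AA3)])
    a2 <- a2[!(a2$chain %in% nonstd_chain), , drop = FALSE]
  }
  new_structure(s$pdb_id, a2, filtered = TRUE)
}

#' Enumerate candidate chain pairs of a filtered structure
#'
#' All unordered chain pairs, in lexicographic order: `n*(n-1)/2` pairs for
#' `n` chains; structures with fewer than two chains yield an empty list.
#'
#' @param s a filtered `piface_structure`.
#' @return a two-column character matrix (`chain_a`, `chain_b`), possibly
#'   with zero rows.
#' @export
enumerate_chain_pairs <- function(s) {
  ch <- chain_ids(s)
  if (length(ch) < 2L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("chain_a", "chain_b"))))
  }
  m <- t(combn(ch, 2L))
  colnames(m) <- c("chain_a", "chain_b")
  m
}

#' Write a structure (or an atom table) as a PDB file
#'
#' @param s a `piface_structure` or an atom data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  atoms <- if (inherits(s, "piface_structure")) s$atoms else s
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(atoms) > 0L) {
    nm <- atoms$atom
    # column-13 alignment rule: 1-3 character names start in column 14
    nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
    rec <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$record, seq_len(nrow(atoms)) %% 100000L, nm4,
                   ifelse(nzchar(trimws(atoms$altloc)), atoms$altloc, " "),
                   atoms$resname, atoms$chain, atoms$resno,
                   ifelse(nzchar(atoms$icode), atoms$icode, " "),
                   atoms$x, atoms$y, atoms$z, atoms$occ, 0,
                   atoms$element)
    writeLines(rec, con)
  }
  writeLines("END", con)
  invisible(path)
}

# C-alpha table of a structure: one row per residue possessing a CA atom
ca_table <- function(s) {
  a <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  a <- a[!duplicated(atom_res_uid(a)), , drop = FALSE]
  data.frame(res_id = atom_res_uid(a), chain = a$chain, resno = a$resno,
             icode = a$icode, resname = a$resname,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}
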