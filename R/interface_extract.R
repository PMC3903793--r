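#' Contact residue pairs between two chains
#'
#' Residues `i` (chain a) and `j` (chain b) are in contact when any two of
#' their atoms are closer than the sum of the atoms' van der Waals radii
#' plus `slack` (0.5 A); the comparison is strict (`<`).
#'
#' @param s a filtered `piface_structure`.
#' @param chain_a,chain_b chain ids.
#' @param slack distance slack added to the vdW radius sum (A).
#' @return data frame with columns `res_a`, `res_b` (residue uids,
#'   `chain:resno[:icode]`), one row per contacting residue pair, ordered
#'   deterministically. Zero rows when the chains do not touch.
#' @export
contact_residues <- function(s, chain_a, chain_b, slack = 0.5) {
  a <- chain_atoms(s, chain_a)
  b <- chain_atoms(s, chain_b)
  if (nrow(a) == 0L) stop("chain ", chain_a, " absent from structure ", s$pdb_id)
  if (nrow(b) == 0L) stop("chain ", chain_b, " absent from structure ", s$pdb_id)
  # atom-pair distances vs per-pair thresholds, chunked over chain a atoms
  bx <- as.matrix(b[, c("x", "y", "z")])
  thr_b <- b$radius + slack
  pairs <- vector("list", 0L)
  uid_a <- atom_res_uid(a)
  uid_b <- atom_res_uid(b)
  chunk <- 512L
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    ax <- as.matrix(a[idx, c("x", "y", "z")])
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
    thr <- outer(a$radius[idx], thr_b, "+")
    hit <- which(d2 < thr^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      pairs[[length(pairs) + 1L]] <-
        unique(data.frame(res_a = uid_a[idx[hit[, 1L]]],
                          res_b = uid_b[hit[, 2L]],
                          stringsAsFactors = FALSE))
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(res_a = character(), res_b = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, pairs))
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

#' Nearby residues supporting a contact set
#'
#' Non-contact residues of the same chain whose C-alpha lies strictly
#' within `cutoff` (6 A) of the C-alpha of any contact residue of that
#' chain. Residues lacking a C-alpha atom are skipped with a warning.
#'
#' @param s a filtered `piface_structure`.
#' @param chain chain id.
#' @param contact_set character vector of contact residue uids on `chain`.
#' @param cutoff C-alpha distance cutoff (A).
#' @return sorted character vector of nearby residue uids.
#' @export
nearby_residues <- function(s, chain, contact_set, cutoff = 6) {
  if (length(contact_set) == 0L) return(character())
  ca <- ca_table(s)
  ca <- ca[ca$chain == chain, , drop = FALSE]
  at <- chain_atoms(s, chain)
  all_res <- unique(atom_res_uid(at))
  no_ca <- setdiff(all_res, ca$res_id)
  if (length(no_ca) > 0L) {
    warning("residue(s) without C-alpha skipped on chain ", chain, ": ",
            paste(no_ca, collapse = ", "), call. = FALSE)
  }
  is_contact <- ca$res_id %in% contact_set
  if (!any(is_contact) || all(is_contact)) return(character())
  cxyz <- as.matrix(ca[is_contact, c("x", "y", "z")])
  oxyz <- as.matrix(ca[!is_contact, c("x", "y", "z")])
  d2 <- outer(rowSums(oxyz^2), rowSums(cxyz^2), "+") - 2 * oxyz %*% t(cxyz)
  dmin2 <- pmax(apply(d2, 1L, min), 0)
  sort(ca$res_id[!is_contact][dmin2 < cutoff^2])
}

#' Extract the interface of a chain pair
#'
#' Builds the contact and nearby residue sets of both sides and applies the
#' minimum-size rule: the interface is kept only when each side has at
#' least `min_contacts` (5) contact residues. The interface is named
#' `<pdb_id><chain_a><chain_b>` (e.g. `1GQPAB`).
#'
#' @param s a filtered `piface_structure`.
#' @param chain_a,chain_b chain ids (the name uses this order).
#' @param min_contacts minimum contact residues per side.
#' @param slack contact-rule slack (A).
#' @param nearby_cutoff nearby-rule C-alpha cutoff (A).
#' @param min_rule which per-side count the minimum-size rule tests:
#'   `"contact"` (default) or `"total"` (contact + nearby).
#' @return a `piface_interface` (list with `name`, `pdb_id`, `chain_a`,
#'   `chain_b`, `side_a`/`side_b` each `list(contact=, nearby=)`,
#'   `n_contact`, `n_total`, `ca` table of interface residues, `atoms`), or
#'   `NULL` when the pair fails the minimum-size rule or has no contacts.
#' @export
extract_interface <- function(s, chain_a, chain_b, min_contacts = 5,
                              slack = 0.5, nearby_cutoff = 6,
                              min_rule = c("contact", "total")) {
  min_rule <- match.arg(min_rule)
  cp <- contact_residues(s, chain_a, chain_b, slack)
  if (nrow(cp) == 0L) return(NULL)
  contact_a <- sort(unique(cp$res_a))
  contact_b <- sort(unique(cp$res_b))
  nearby_a <- nearby_residues(s, chain_a, contact_a, nearby_cutoff)
  nearby_b <- nearby_residues(s, chain_b, contact_b, nearby_cutoff)
  n_contact <- c(a = length(contact_a), b = length(contact_b))
  n_total <- c(a = length(contact_a) + length(nearby_a),
               b = length(contact_b) + length(nearby_b))
  tested <- if (min_rule == "contact") n_contact else n_total
  if (any(tested < min_contacts)) return(NULL)
  keep <- c(contact_a, nearby_a, contact_b, nearby_b)
  ca <- ca_table(s)
  ca <- ca[ca$res_id %in% keep, , drop = FALSE]
  ca$side <- ifelse(ca$chain == chain_a, "a", "b")
  ca$role <- ifelse(ca$res_id %in% c(contact_a, contact_b), "contact", "nearby")
  ca <- ca[order(ca$side, ca$res_id), , drop = FALSE]
  rownames(ca) <- NULL
  at <- s$atoms[atom_res_uid(s$atoms) %in% keep &
                  s$atoms$chain %in% c(chain_a, chain_b), , drop = FALSE]
  structure(list(
    name = paste0(s$pdb_id, chain_a, chain_b),
    pdb_id = s$pdb_id, chain_a = chain_a, chain_b = chain_b,
    side_a = list(contact = contact_a, nearby = nearby_a),
    side_b = list(contact = contact_b, nearby = nearby_b),
    n_contact = n_contact, n_total = n_total,
    ca = ca, atoms = at), class = "piface_interface")
}

#' @export
print.piface_interface <- function(x, ...) {
  cat("piface_interface ", x$name, ": contacts ", x$n_contact[["a"]], "+",
      x$n_contact[["b"]], ", with nearby ", x$n_total[["a"]], "+",
      x$n_total[["b"]], "\n", sep = "")
  invisible(x)
}

#' Number of interface residues
#'
#' Size conventions used by the similarity denominator and the
#' size-compatibility gate. `"contact"` counts contact residues over both
#' sides (the Table-1-style "# of interface residues"); `"total"` adds
#' nearby residues.
#'
#' @param iface a `piface_interface`.
#' @param which `"contact"` or `"total"`.
#' @return integer count.
#' @export
n_interface_residues <- function(iface, which = c("total", "contact")) {
  which <- match.arg(which)
  if (which == "contact") sum(iface$n_contact) else sum(iface$n_total)
}

#' Write an interface as a PDB file (aligner input)
#'
#' Emits only the atoms of the interface residues (contact + nearby, both
#' chains) in PDB format, lossless for the retained residues; the companion
#' JSON sidecar (`<name>.json`) records the residue lists and counts.
#'
#' @param iface a `piface_interface`.
#' @param path output PDB path.
#' @param sidecar write the JSON sidecar next to `path` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_interface <- function(iface, path, sidecar = TRUE) {
  stopifnot(inherits(iface, "piface_interface"))
  if (length(iface$side_a$contact) == 0L || length(iface$side_b$contact) == 0L) {
    stop("invalid interface ", iface$name, ": empty contact side")
  }
  write_structure_pdb(iface$atoms, path)
  if (isTRUE(sidecar)) {
    meta <- list(name = iface$name, pdb_id = iface$pdb_id,
                 chain_a = iface$chain_a, chain_b = iface$chain_b,
                 side_a = iface$side_a, side_b = iface$side_b,
                 n_contact = as.list(iface$n_contact),
                 n_total = as.list(iface$n_total))
    jsonlite::write_json(meta, sub("\\.pdb$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
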