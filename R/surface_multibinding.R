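#' Surface residues of a monomer by RASA cutoff
#'
#' Residues of one chain, taken in isolation, whose relative accessible
#' surface area strictly exceeds `cutoff` percent. The default 40% cutoff
#' captures ~99% of average interface-residue exposure in representative
#' interface libraries; `cutoff = 5` reproduces the classical
#' exterior-residue convention (RASA > 5%).
#'
#' @param s a filtered `piface_structure`.
#' @param chain chain id.
#' @param cutoff RASA cutoff in percent (default 40).
#' @param rasa optional precomputed per-residue RASA table from
#'   [chain_rasa_table()] (computed on the isolated monomer when omitted).
#' @param ... passed to [chain_rasa_table()].
#' @return `piface_surface`: data frame of surface residues (`res_id`,
#'   `chain`, `resno`, `icode`, `resname`, `asa`, `rasa`) with attribute
#'   `cutoff`.
#' @export
surface_residues <- function(s, chain, cutoff = 40, rasa = NULL, ...) {
  if (is.null(rasa)) rasa <- chain_rasa_table(s, chain, ...)
  out <- rasa[rasa$rasa > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("piface_surface", class(out))
  out
}

#' RASA statistics of interface and nearby residues
#'
#' For each interface, the average monomer RASA of its contact residues
#' and of its nearby residues is computed; the statistics reported are the
#' mean and standard deviation of those per-interface averages across the
#' interface set (the convention behind "average RASA of each
#' representative interface").
#'
#' @param interfaces list of `piface_interface` objects.
#' @param rasa_tables named list: `pdb_id` -> per-residue RASA lookup, itself
#'   a named list `chain` -> data frame from [chain_rasa_table()].
#' @return named numeric vector `interface_mean`, `interface_sd`,
#'   `nearby_mean`, `nearby_sd` (percent). SDs are 0 for a single
#'   interface; nearby values are `NA` when no interface has nearby
#'   residues.
#' @export
rasa_statistics <- function(interfaces, rasa_tables) {
  stopifnot(length(interfaces) >= 1L)
  per_iface <- lapply(interfaces, function(iface) {
    tabs <- rasa_tables[[iface$pdb_id]]
    if (is.null(tabs)) stop("no RASA table for structure ", iface$pdb_id)
    lookup <- function(chain, res_ids) {
      tab <- tabs[[chain]]
      if (is.null(tab)) stop("no RASA table for chain ", chain, " of ", iface$pdb_id)
      v <- tab$rasa[match(res_ids, tab$res_id)]
      v[!is.na(v)]
    }
    contact <- c(lookup(iface$chain_a, iface$side_a$contact),
                 lookup(iface$chain_b, iface$side_b$contact))
    nearby <- c(lookup(iface$chain_a, iface$side_a$nearby),
                lookup(iface$chain_b, iface$side_b$nearby))
    c(contact = mean(contact),
      nearby = if (length(nearby)) mean(nearby) else NA_real_)
  })
  cm <- vapply(per_iface, `[[`, numeric(1L), "contact")
  nm <- vapply(per_iface, `[[`, numeric(1L), "nearby")
  nm <- nm[!is.na(nm)]
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  c(interface_mean = mean(cm), interface_sd = sd0(cm),
    nearby_mean = if (length(nm)) mean(nm) else NA_real_,
    nearby_sd = if (length(nm)) sd0(nm) else NA_real_)
}

#' Group chains by exact (100%) sequence identity
#'
#' Chains receive the same sequence-cluster id iff their one-letter
#' sequences are exactly identical strings; ids are assigned in first-seen
#' order of the input, so the grouping is deterministic.
#'
#' @param chains data frame with columns `id` (unique chain key, e.g.
#'   `"1VKG:A"`) and `sequence` (one-letter, 20-letter alphabet), or a
#'   named character vector of sequences.
#' @return named integer vector: chain id -> sequence cluster id.
#' @export
sequence_identity_clusters <- function(chains) {
  if (is.character(chains)) {
    chains <- data.frame(id = names(chains), sequence = unname(chains),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(chains)))
  if (any(!nzchar(chains$sequence))) {
    stop("empty sequence for chain(s): ",
         paste(chains$id[!nzchar(chains$sequence)], collapse = ", "))
  }
  cluster <- match(chains$sequence, unique(chains$sequence))
  setNames(as.integer(cluster), chains$id)
}

#' One-letter sequence of a chain
#'
#' @param s a filtered `piface_structure`.
#' @param chain chain id.
#' @return one-letter amino-acid string in residue order.
#' @export
chain_sequence <- function(s, chain) {
  at <- chain_atoms(s, chain)
  at <- at[order(at$resno, at$icode), , drop = FALSE]
  uid <- atom_res_uid(at)
  first <- !duplicated(uid)
  paste(AA3_TO_1[at$resname[first]], collapse = "")
}

#' Detect protein pairs binding through multiple interface architectures
#'
#' Interfaces are grouped by the unordered pair of sequence-cluster ids of
#' their two chains (`"<smaller>_<larger>"`, e.g. `"423_1002"`); a pair
#' binds through multiple interfaces when its interfaces span more than
#' one structural cluster.
#'
#' @param interfaces list of `piface_interface` objects.
#' @param seq_clusters named vector from [sequence_identity_clusters()],
#'   keyed `"<pdb_id>:<chain>"`.
#' @param structural_clusters named vector: interface name -> structural
#'   cluster id (see [cluster_membership()]).
#' @return list of `piface_pair_profile` objects: each a list with
#'   `pair_label`, `interfaces`, `structural_clusters` (set),
#'   `multi_interface` (logical).
#' @export
detect_multi_interface_pairs <- function(interfaces, seq_clusters,
                                         structural_clusters) {
  labels <- vapply(interfaces, function(iface) {
    ka <- paste0(iface$pdb_id, ":", iface$chain_a)
    kb <- paste0(iface$pdb_id, ":", iface$chain_b)
    ca <- seq_clusters[[ka]]; cb <- seq_clusters[[kb]]
    if (is.null(ca) || is.null(cb) || is.na(ca) || is.na(cb)) {
      stop("missing sequence-cluster assignment for ", ka, " or ", kb)
    }
    paste0(min(ca, cb), "_", max(ca, cb))
  }, character(1L))
  names(interfaces) <- vapply(interfaces, `[[`, character(1L), "name")
  out <- lapply(sort(unique(labels)), function(lab) {
    ifs <- sort(names(interfaces)[labels == lab])
    sc <- structural_clusters[ifs]
    if (anyNA(sc)) stop("missing structural cluster for interface(s): ",
                        paste(ifs[is.na(sc)], collapse = ", "))
    structure(list(pair_label = lab, interfaces = ifs,
                   structural_clusters = sort(unique(unname(sc))),
                   multi_interface = length(unique(sc)) > 1L),
              class = "piface_pair_profile")
  })
  out
}

#' Classify the binding sites of a multi-interface pair
#'
#' For every pair of interfaces in the profile, the contact-residue sets
#' on the common monomer (the side whose chain belongs to the same
#' sequence cluster) are mapped to sequence positions — valid because the
#' sequences are 100% identical — and their overlap is measured as the
#' fraction of the smaller set. Overlap `>= overlap_threshold` (0.5)
#' declares the two interfaces to use a shared site; binding sites are the
#' connected components of the shared-site relation, which therefore
#' partition the profile's interfaces.
#'
#' @param profile a `piface_pair_profile` with at least 2 structural
#'   clusters (or simply >= 2 interfaces).
#' @param interfaces named list of `piface_interface` objects covering the
#'   profile.
#' @param structures named list of filtered `piface_structure`s by pdb_id
#'   (for residue -> sequence-position mapping).
#' @param seq_clusters named vector from [sequence_identity_clusters()].
#' @param overlap_threshold shared-site overlap cutoff on the smaller
#'   contact set (default 0.5; the published shared/distinct split does
#'   not disclose its rule, so this is an explicit, tunable stand-in).
#' @return list with `site_of` (named integer: interface -> site id),
#'   `n_sites`, `shared_pairs` (data frame `iface1`, `iface2`, `overlap`,
#'   `class`).
#' @export
classify_binding_sites <- function(profile, interfaces, structures,
                                   seq_clusters, overlap_threshold = 0.5) {
  ifs <- profile$interfaces
  stopifnot(length(ifs) >= 2L)
  ref_cluster <- as.integer(strsplit(profile$pair_label, "_", fixed = TRUE)[[1L]][1L])
  # contact residues of each interface on the reference monomer, as
  # sequence positions
  pos_sets <- lapply(ifs, function(nm) {
    iface <- interfaces[[nm]]
    if (is.null(iface)) stop("interface ", nm, " not supplied")
    s <- structures[[iface$pdb_id]]
    if (is.null(s)) stop("structure ", iface$pdb_id, " not supplied")
    sides <- list(a = list(chain = iface$chain_a, contact = iface$side_a$contact),
                  b = list(chain = iface$chain_b, contact = iface$side_b$contact))
    use <- NULL
    for (side in sides) {
      key <- paste0(iface$pdb_id, ":", side$chain)
      sc <- seq_clusters[[key]]
      if (is.null(sc)) stop("no sequence cluster for ", key)
      if (sc == ref_cluster) { use <- side; break }
    }
    if (is.null(use)) stop("interface ", nm, " has no chain in sequence cluster ",
                           ref_cluster, " (no common monomer mapping)")
    residue_seq_positions(s, use$chain, use$contact)
  })
  names(pos_sets) <- ifs
  prs <- t(combn(ifs, 2L))
  overlap <- vapply(seq_len(nrow(prs)), function(r) {
    a <- pos_sets[[prs[r, 1L]]]; b <- pos_sets[[prs[r, 2L]]]
    length(intersect(a, b)) / min(length(a), length(b))
  }, numeric(1L))
  shared <- overlap >= overlap_threshold
  rel <- igraph::graph_from_data_frame(
    data.frame(from = prs[shared, 1L], to = prs[shared, 2L]),
    directed = FALSE, vertices = data.frame(name = ifs))
  comp <- igraph::components(rel)$membership
  list(site_of = setNames(as.integer(comp[ifs]), ifs),
       n_sites = as.integer(max(comp)),
       shared_pairs = data.frame(iface1 = prs[, 1L], iface2 = prs[, 2L],
                                 overlap = overlap,
                                 class = ifelse(shared, "shared", "distinct"),
                                 stringsAsFactors = FALSE))
}

# map residue uids of a chain to 1-based sequence positions (rank order of
# residues in author numbering)
residue_seq_positions <- function(s, chain, res_ids) {
  at <- chain_atoms(s, chain)
  at <- at[order(at$resno, at$icode), , drop = FALSE]
  uid <- unique(atom_res_uid(at))
  pos <- match(res_ids, uid)
  if (anyNA(pos)) stop("residue(s) absent from chain ", chain, ": ",
                       paste(res_ids[is.na(pos)], collapse = ", "))
  sort(pos)
}
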