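#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the published
#' defaults: contact slack 0.5 A, nearby cutoff 6 A, minimum 5 contact
#' residues per side, 1 A^2 buried-area prefilter, probe 1.4 A, 3 A
#' alignment threshold, size-gate factors 1.25 (contacts) / 1.50
#' (contacts + nearby), 0.75 edge threshold, grouping steps
#' 0.80..1.00, clustering-coefficient stop 1.0, max merge mode, minimum
#' cluster size 5, 40% RASA surface cutoff.
#'
#' @param ... overrides of the defaults listed above (see
#'   `piface_config()$` names).
#' @return a `piface_config` list.
#' @export
piface_config <- function(...) {
  cfg <- list(
    probe = 1.4, n_points = 960,
    contact_slack = 0.5, nearby_cutoff = 6, min_contacts = 5,
    asa_prefilter = 1,
    rmsd_threshold = 3.0, contact_factor = 1.25, total_factor = 1.50,
    edge_threshold = 0.75,
    grouping_steps = c(0.80, 0.85, 0.90, 0.95, 1.00),
    cc_stop = 1.0, merge_mode = "max", min_cluster_size = 5,
    rasa_cutoff = 40, seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stop("unknown config option(s): ",
                                 paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$probe > 0, cfg$contact_slack >= 0, cfg$nearby_cutoff > 0,
            cfg$min_contacts >= 1, cfg$rmsd_threshold > 0,
            cfg$edge_threshold >= 0, cfg$edge_threshold <= 1)
  structure(cfg, class = "piface_config")
}

#' Run the full interface pipeline
#'
#' Executes extraction, comparison, clustering, evaluation and downstream
#' products on a set of coordinate files, persisting every stage under
#' `out_dir`:
#'
#' * `interfaces/<name>.pdb` + `.json` — extracted interfaces;
#' * `similarity.tsv` — pairwise similarity table;
#' * `network.graphml` — the similarity network;
#' * `clusters.tsv` — cluster id, representative, members;
#' * `silhouette.tsv` — per-interface a, b, s (when >= 2 clusters);
#' * `surface/<pdb>_<chain>.tsv` — per-residue ASA/RASA with surface flag;
#' * `profiles.json` — multi-interface pair profiles;
#' * `manifest.json` — configuration, counts and package version.
#'
#' Outputs are deterministic: interfaces are processed in sorted name
#' order, so re-running with identical inputs and configuration
#' reproduces identical files. An empty input set is not an error; the
#' run directory is created with empty products and a warning.
#'
#' @param paths character vector of PDB files.
#' @param out_dir output directory (created if needed).
#' @param cfg a [piface_config()].
#' @param format input format for [load_structure()].
#' @param verbose log per-stage counts.
#' @return invisibly, a list with the in-memory stage products
#'   (`structures`, `interfaces`, `similarity`, `network`, `clusters`,
#'   `silhouette`, `profiles`, `counts`, `out_dir`).
#' @export
run_pipeline <- function(paths, out_dir, cfg = piface_config(),
                         format = "pdb", verbose = TRUE) {
  stopifnot(inherits(cfg, "piface_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "interfaces"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "surface"), showWarnings = FALSE)
  say <- function(...) if (verbose) message("piface: ", ...)
  if (length(paths) == 0L) {
    warning("no input structures; writing empty outputs", call. = FALSE)
  }

  # stage 1: load + filter
  structures <- list()
  for (p in sort(paths)) {
    s <- filter_structure(load_structure(p, format))
    if (length(chain_ids(s)) == 0L) { say("skipping ", p, ": no protein chain"); next }
    structures[[s$pdb_id]] <- s
  }
  say(length(structures), " structure(s) loaded")

  # stage 2: candidate pairs -> interfaces
  interfaces <- list()
  n_pairs <- 0L; n_prefilter <- 0L
  for (s in structures) {
    prs <- enumerate_chain_pairs(s)
    n_pairs <- n_pairs + nrow(prs)
    for (r in seq_len(nrow(prs))) {
      a <- chain_atoms(s, prs[r, 1L]); b <- chain_atoms(s, prs[r, 2L])
      if (!candidate_prefilter(a, b, cfg$asa_prefilter, cfg$probe, cfg$n_points)) next
      n_prefilter <- n_prefilter + 1L
      iface <- extract_interface(s, prs[r, 1L], prs[r, 2L], cfg$min_contacts,
                                 cfg$contact_slack, cfg$nearby_cutoff)
      if (!is.null(iface)) interfaces[[iface$name]] <- iface
    }
  }
  interfaces <- interfaces[sort(names(interfaces))]
  for (iface in interfaces) {
    write_interface(iface, file.path(out_dir, "interfaces",
                                     paste0(iface$name, ".pdb")))
  }
  say(n_pairs, " chain pair(s), ", n_prefilter, " past the ",
      cfg$asa_prefilter, " A^2 prefilter, ", length(interfaces),
      " interface(s) extracted")

  # stage 3: pairwise similarity
  simtab <- pairwise_similarity_matrix(
    unname(interfaces), rmsd_threshold = cfg$rmsd_threshold,
    contact_factor = cfg$contact_factor, total_factor = cfg$total_factor,
    verbose = verbose)
  write_similarity_tsv(simtab, file.path(out_dir, "similarity.tsv"))

  # stage 4: network
  net <- build_network(simtab, cfg$edge_threshold)
  # graphml cannot carry list attributes; members == name at this stage
  igraph::write_graph(igraph::delete_vertex_attr(net, "members"),
                      file.path(out_dir, "network.graphml"),
                      format = "graphml")

  # stage 5: clustering
  clusters <- NULL
  if (length(interfaces) > 0L) {
    clusters <- cluster_interfaces(net, cc_stop = cfg$cc_stop,
                                   grouping_steps = cfg$grouping_steps,
                                   merge_mode = cfg$merge_mode,
                                   min_size = cfg$min_cluster_size,
                                   sim = simtab)
    write_clusters_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    say(length(clusters$clusters), " cluster(s) [", clusters$params$tag, "]")
  } else {
    writeLines("cluster_id\trepresentative\tmembers",
               file.path(out_dir, "clusters.tsv"))
  }

  # stage 6: silhouette
  sil <- NULL
  if (!is.null(clusters) && length(clusters$clusters) >= 2L) {
    sil <- silhouette_index(clusters, simtab)
    memb <- cluster_membership(clusters)
    df <- data.frame(interface = names(sil$per_interface_s),
                     cluster = unname(memb[names(sil$per_interface_s)]),
                     a = unname(sil$a_values), b = unname(sil$b_values),
                     s = unname(sil$per_interface_s))
    write.table(df, file.path(out_dir, "silhouette.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("overall silhouette ", formatC(sil$overall, digits = 3, format = "f"))
  }

  # stage 7: monomer surfaces
  for (s in structures) {
    for (ch in chain_ids(s)) {
      tab <- chain_rasa_table(s, ch, cfg$probe, cfg$n_points)
      tab$surface <- tab$rasa > cfg$rasa_cutoff
      write.table(tab, file.path(out_dir, "surface",
                                 paste0(s$pdb_id, "_", ch, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # stage 8: sequence clusters + multi-interface profiles
  profiles <- list()
  if (length(interfaces) > 0L && !is.null(clusters)) {
    seqs <- do.call(c, unname(lapply(structures, function(s) {
      setNames(vapply(chain_ids(s), function(ch) chain_sequence(s, ch),
                      character(1L)),
               paste0(s$pdb_id, ":", chain_ids(s)))
    })))
    seq_cl <- sequence_identity_clusters(seqs)
    memb <- cluster_membership(clusters)
    profiles <- detect_multi_interface_pairs(unname(interfaces), seq_cl, memb)
    jsonlite::write_json(
      lapply(profiles, function(p) p[c("pair_label", "interfaces",
                                       "structural_clusters",
                                       "multi_interface")]),
      file.path(out_dir, "profiles.json"), auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(list(), file.path(out_dir, "profiles.json"))
  }

  counts <- list(structures = length(structures), chain_pairs = n_pairs,
                 past_prefilter = n_prefilter, interfaces = length(interfaces),
                 clusters = if (is.null(clusters)) 0L else length(clusters$clusters))
  manifest <- list(package = "piface",
                   version = as.character(utils::packageVersion("piface")),
                   config = unclass(cfg), counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(structures = structures, interfaces = interfaces,
                 similarity = simtab, network = net, clusters = clusters,
                 silhouette = sil, profiles = profiles, counts = counts,
                 out_dir = out_dir))
}
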