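# run code under a fixed seed without touching the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy two-chain complex
#'
#' Two backbone-only (N, CA, C, O) poly-alanine chains laid out as extended
#' strands: chain A runs along x; chain B runs antiparallel-facing at a
#' `gap` offset in y, with its carbonyl oxygens pointing back toward A so
#' that residues inside `contact_span` satisfy the vdW + 0.5 A contact
#' rule at the default gap, while residues outside the span curve away in
#' z (4 A per residue) and become nearby or remote. Small gaps give dense
#' contacts; very large gaps (e.g. 100 A) are legal and simply yield no
#' interface. Geometry is deterministic; optional Gaussian jitter
#' (`perturbation_sigma`) is driven entirely by `seed`.
#'
#' @param n_residues residues per chain.
#' @param gap inter-chain offset in y (A), must be positive.
#' @param contact_span integer range of chain-B residues held at the gap
#'   distance (must lie within the chain).
#' @param perturbation_sigma sd (A) of coordinate jitter on all atoms.
#' @param seed integer seed for the jitter.
#' @param pdb_id identifier for the generated structure.
#' @return a filtered-equivalent `piface_structure` with chains A and B.
#' @export
make_toy_complex <- function(n_residues = 20, gap = 6.4, contact_span = 6:15,
                             perturbation_sigma = 0, seed = 1,
                             pdb_id = "TOYC") {
  stopifnot(n_residues >= 2, perturbation_sigma >= 0)
  if (gap <= 0) stop("infeasible geometry: gap must be positive")
  if (min(contact_span) < 1 || max(contact_span) > n_residues) {
    stop("infeasible geometry: contact_span outside the chain")
  }
  spacing <- 3.8
  bb <- function(i, flip) {
    # backbone offsets relative to CA; `flip` mirrors y so chain B's
    # carbonyl oxygen points back toward chain A
    ca <- c(spacing * (i - 1), 0, 0)
    f <- if (flip) -1 else 1
    rbind(N = ca + c(-1.25, f * 0.70, 0),
          CA = ca,
          C = ca + c(1.25, f * 0.70, 0),
          O = ca + c(1.40, f * 1.90, 0))
  }
  mk_chain <- function(chain, flip, y_off, x_off, curve) {
    rows <- lapply(seq_len(n_residues), function(i) {
      m <- bb(i, flip)
      m[, 1L] <- m[, 1L] + x_off
      m[, 2L] <- m[, 2L] + y_off
      if (curve) {
        dist_out <- max(0, min(contact_span) - i, i - max(contact_span))
        m[, 3L] <- m[, 3L] + 4 * dist_out
      }
      data.frame(model = 1L, record = "ATOM", serial = NA_integer_,
                 atom = rownames(m), altloc = " ", resname = "ALA",
                 chain = chain, resno = i, icode = "",
                 x = m[, 1L], y = m[, 2L], z = m[, 3L], occ = 1,
                 element = substr(rownames(m), 1L, 1L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  atoms <- rbind(mk_chain("A", flip = FALSE, y_off = 0, x_off = 0, curve = FALSE),
                 mk_chain("B", flip = TRUE, y_off = gap, x_off = 1.9, curve = TRUE))
  atoms$element[atoms$atom %in% c("N", "CA", "C")] <-
    c(N = "N", CA = "C", C = "C")[atoms$atom[atoms$atom %in% c("N", "CA", "C")]]
  atoms$element[atoms$atom == "O"] <- "O"
  atoms$radius <- vdw_radius(atoms$element)
  atoms$serial <- seq_len(nrow(atoms))
  if (perturbation_sigma > 0) {
    noise <- with_local_seed(seed, matrix(rnorm(3L * nrow(atoms),
                                                sd = perturbation_sigma),
                                          ncol = 3L))
    atoms$x <- atoms$x + noise[, 1L]
    atoms$y <- atoms$y + noise[, 2L]
    atoms$z <- atoms$z + noise[, 3L]
  }
  new_structure(pdb_id, atoms, filtered = FALSE)
}

#' Displace part of an interface to create similar-but-distinct copies
#'
#' Adds Gaussian noise (sd `sigma`) to every atom of a deterministic,
#' seed-chosen fraction of the given residues (by default the interface
#' residues of the structure's first chain pair). `sigma = 0` or
#' `fraction_displaced = 0` return the structure unchanged, so families of
#' decreasingly similar interfaces can be generated from one parent.
#'
#' @param s a `piface_structure`.
#' @param sigma displacement sd (A), >= 0.
#' @param fraction_displaced fraction of the target residues displaced.
#' @param seed integer seed (residue choice and noise).
#' @param residues residue uids to draw from; default: contact + nearby
#'   residues of the first chain pair's interface.
#' @return the perturbed `piface_structure`.
#' @export
perturb_interface <- function(s, sigma, fraction_displaced = 1, seed = 1,
                              residues = NULL) {
  stopifnot(sigma >= 0, fraction_displaced >= 0, fraction_displaced <= 1)
  if (is.null(residues)) {
    prs <- enumerate_chain_pairs(s)
    if (nrow(prs) == 0L) stop("structure has fewer than 2 chains")
    iface <- extract_interface(s, prs[1L, 1L], prs[1L, 2L])
    if (is.null(iface)) stop("no interface found to perturb")
    residues <- iface$ca$res_id
  }
  if (sigma == 0 || fraction_displaced == 0 || length(residues) == 0L) return(s)
  residues <- sort(residues)
  n_pick <- max(1L, floor(fraction_displaced * length(residues)))
  a <- s$atoms
  with_local_seed(seed, {
    picked <- sort(sample(residues, n_pick))
    hit <- atom_res_uid(a) %in% picked
    noise <- matrix(rnorm(3L * sum(hit), sd = sigma), ncol = 3L)
    a$x[hit] <- a$x[hit] + noise[, 1L]
    a$y[hit] <- a$y[hit] + noise[, 2L]
    a$z[hit] <- a$z[hit] + noise[, 3L]
  })
  new_structure(s$pdb_id, a, filtered = s$filtered)
}

#' Planted-partition similarity network
#'
#' Random graph with known community structure: within-block edges appear
#' with probability `p_in` and weights uniform in `w_in`; between-block
#' edges with probability `p_out` and weights uniform in `w_out`. Node
#' names are `B<block>N<index>`. All randomness is driven by `seed`; the
#' true labels are returned for recovery tests.
#'
#' @param block_sizes integer vector of community sizes.
#' @param p_in,p_out edge probabilities (`0 <= p_out < p_in <= 1` for a
#'   meaningful planted structure; not enforced beyond range checks).
#' @param w_in,w_out length-2 weight ranges within `[0, 1]`.
#' @param seed integer seed.
#' @return list with `network` (an `igraph` as from [build_network()]) and
#'   `membership` (named integer vector of true block labels).
#' @export
planted_partition_graph <- function(block_sizes, p_in, p_out,
                                    w_in = c(0.85, 1.0), w_out = c(0.75, 0.80),
                                    seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            length(w_in) == 2L, length(w_out) == 2L,
            all(c(w_in, w_out) >= 0), all(c(w_in, w_out) <= 1))
  blocks <- rep(seq_along(block_sizes), block_sizes)
  nodes <- sprintf("B%dN%02d", blocks,
                   unlist(lapply(block_sizes, seq_len)))
  n <- length(nodes)
  tab <- with_local_seed(seed, {
    prs <- t(combn(seq_len(n), 2L))
    same <- blocks[prs[, 1L]] == blocks[prs[, 2L]]
    keep <- runif(nrow(prs)) < ifelse(same, p_in, p_out)
    w <- ifelse(same[keep],
                runif(sum(keep), w_in[1L], w_in[2L]),
                runif(sum(keep), w_out[1L], w_out[2L]))
    data.frame(iface1 = nodes[prs[keep, 1L]], iface2 = nodes[prs[keep, 2L]],
               similarity = w, stringsAsFactors = FALSE)
  })
  net <- build_network(tab, edge_threshold = 0, nodes = nodes)
  list(network = net, membership = setNames(blocks, nodes))
}
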