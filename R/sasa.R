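#' Deterministic unit sphere points (golden-section spiral)
#'
#' @param n number of points (>= 2).
#' @return an `n x 3` matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley accessible surface area
#'
#' Numerical solvent-accessible surface area: each atom's solvent-extended
#' sphere (radius `r_vdw + probe`) is sampled at `n_points` deterministic
#' golden-spiral points, and the accessible fraction is the fraction of
#' points outside every neighbouring atom's extended sphere. With a fixed
#' point generator the result is fully reproducible and converges to the
#' analytic area as `n_points` grows. The contract is NACCESS-equivalent
#' (same probe, per-residue totals), not bit-compatible.
#'
#' Exactly coincident atoms of equal radius mutually occlude each other
#' (both receive zero area), the conservative convention for duplicated
#' coordinates.
#'
#' @param atoms atom data frame (needs `x`, `y`, `z`, `radius`; residue
#'   aggregation uses `chain`, `resno`, `icode`, `resname` when present), or
#'   a `piface_structure`.
#' @param probe probe sphere radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return an object of class `piface_asa`: list with `per_atom` (numeric
#'   vector, A^2, one per input atom), `per_residue` (data frame `res_id`,
#'   `chain`, `resno`, `icode`, `resname`, `asa`) and `total` (A^2).
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
#' compute_asa(a)$total        # ~ 4*pi*(1.7+1.4)^2
#' @export
compute_asa <- function(atoms, probe = 1.4, n_points = 960) {
  if (inherits(atoms, "piface_structure")) atoms <- atoms$atoms
  stopifnot(nrow(atoms) >= 1L, probe > 0, n_points >= 2)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  re <- atoms$radius + probe
  if (any(!is.finite(re) | re <= probe)) stop("invalid vdW radii")
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  tol <- 1e-9
  # neighbour candidates via squared-distance threshold per atom pair
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * re[i]^2
      next
    }
    sp <- pts * re[i]
    sp <- sweep(sp, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    # nearest neighbours first prune fastest
    for (j in nb[order(d2[nb])]) {
      if (!any(acc)) break
      k <- which(acc)
      dj2 <- (sp[k, 1L] - xyz[j, 1L])^2 + (sp[k, 2L] - xyz[j, 2L])^2 +
        (sp[k, 3L] - xyz[j, 3L])^2
      acc[k[dj2 <= re[j]^2 + tol]] <- FALSE
    }
    per_atom[i] <- 4 * pi * re[i]^2 * sum(acc) / n_points
  }
  per_residue <- NULL
  if (all(c("chain", "resno", "icode", "resname") %in% names(atoms))) {
    uid <- atom_res_uid(atoms)
    sums <- rowsum(per_atom, uid, reorder = FALSE)
    first <- !duplicated(uid)
    per_residue <- data.frame(
      res_id = uid[first], chain = atoms$chain[first],
      resno = atoms$resno[first], icode = atoms$icode[first],
      resname = atoms$resname[first],
      asa = as.numeric(sums[match(uid[first], rownames(sums)), 1L]),
      stringsAsFactors = FALSE)
  }
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total = sum(per_atom), probe = probe, n_points = n_points),
            class = "piface_asa")
}

#' Buried (interface) surface area of a chain pair
#'
#' `ASA(a alone) + ASA(b alone) - ASA(a and b together)`: the surface area
#' buried upon forming the two-chain complex, computed with the two chains
#' in isolation from any other chain of the parent structure.
#' Non-negative up to numerical sampling tolerance and exactly symmetric in
#' its arguments.
#'
#' @param chain_a,chain_b atom data frames of the two chains.
#' @inheritParams compute_asa
#' @return buried area in A^2.
#' @export
buried_area <- function(chain_a, chain_b, probe = 1.4, n_points = 960) {
  stopifnot(nrow(chain_a) > 0L, nrow(chain_b) > 0L)
  asa_a <- compute_asa(chain_a, probe, n_points)$total
  asa_b <- compute_asa(chain_b, probe, n_points)$total
  both <- rbind(chain_a[, c("x", "y", "z", "radius")],
                chain_b[, c("x", "y", "z", "radius")])
  asa_ab <- compute_asa(both, probe, n_points)$total
  asa_a + asa_b - asa_ab
}

#' Buried-area prefilter for candidate chain pairs
#'
#' Candidate interfaces whose buried area does not exceed `threshold`
#' (1 A^2) are eliminated before residue-level extraction; the knife-edge
#' equality is excluded (strictly greater passes).
#'
#' @param chain_a,chain_b atom data frames of the two chains.
#' @param threshold buried-area cutoff in A^2.
#' @inheritParams compute_asa
#' @return `TRUE` iff `buried_area(chain_a, chain_b) > threshold`.
#' @export
candidate_prefilter <- function(chain_a, chain_b, threshold = 1,
                                probe = 1.4, n_points = 960) {
  buried_area(chain_a, chain_b, probe, n_points) > threshold
}

#' Relative accessible surface area (RASA)
#'
#' A residue's ASA as a percentage of its reference maximum exposure
#' (extended Ala-X-Ala tripeptide). Values above 100 are possible for
#' extended termini and are not clipped.
#'
#' @param residue_asa absolute residue ASA in A^2 (vectorised).
#' @param aa_type three-letter residue code(s).
#' @param table reference maxima, see [default_max_asa_table()].
#' @return RASA in percent.
#' @export
relative_asa <- function(residue_asa, aa_type, table = default_max_asa_table()) {
  ref <- table[toupper(aa_type)]
  if (anyNA(ref)) {
    stop("no reference ASA for residue type(s): ",
         paste(unique(aa_type[is.na(ref)]), collapse = ", "))
  }
  100 * residue_asa / unname(ref)
}

#' Per-residue ASA and RASA table of one chain in isolation
#'
#' @param s a filtered `piface_structure`.
#' @param chain chain id.
#' @inheritParams compute_asa
#' @param max_asa_table reference maxima for RASA.
#' @return data frame `res_id`, `chain`, `resno`, `icode`, `resname`,
#'   `asa`, `rasa`.
#' @export
chain_rasa_table <- function(s, chain, probe = 1.4, n_points = 960,
                             max_asa_table = default_max_asa_table()) {
  at <- chain_atoms(s, chain)
  if (nrow(at) == 0L) stop("chain ", chain, " absent from structure ", s$pdb_id)
  res <- compute_asa(at, probe, n_points)$per_residue
  res$rasa <- relative_asa(res$asa, res$resname, max_asa_table)
  res
}
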