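#' Size-compatibility gate for interface comparison
#'
#' Comparing a small interface with a much larger one is uninformative, so
#' pairs are aligned only when the larger contact count is at most
#' `contact_factor` (1.25) times the smaller, and the larger total
#' (contact + nearby) count at most `total_factor` (1.50) times the
#' smaller.
#'
#' @param i1,i2 `piface_interface` objects.
#' @param contact_factor,total_factor allowed size ratios.
#' @return `TRUE` iff the pair may be aligned.
#' @export
size_compatible <- function(i1, i2, contact_factor = 1.25, total_factor = 1.50) {
  c1 <- sum(i1$n_contact); c2 <- sum(i2$n_contact)
  t1 <- sum(i1$n_total); t2 <- sum(i2$n_total)
  max(c1, c2) <= contact_factor * min(c1, c2) &&
    max(t1, t2) <= total_factor * min(t1, t2)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' @param P,Q `n x 3` coordinate matrices (P is rotated onto Q).
#' @return list with `rotation` (proper, `det = +1`), `translation`, and
#'   `rmsd` of the superposed points.
#' @keywords internal
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- Pc %*% t(R)
  list(rotation = R, translation = as.numeric(cq) - as.numeric(R %*% cp),
       rmsd = sqrt(mean(rowSums((Pr - Qc)^2))))
}

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2L, t, "+")

# mutual nearest-neighbour matching of transformed points within a cutoff
mutual_nn_match <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2 <- pmax(d2, 0)
  jb <- apply(d2, 1L, which.min)          # best column per row (first on tie)
  ia <- apply(d2, 2L, which.min)
  rows <- which(ia[jb] == seq_len(nrow(A)))
  keep <- rows[d2[cbind(rows, jb[rows])] < cutoff^2]
  cbind(i = keep, j = jb[keep])
}

# local kNN triangles used as alignment seeds: rows (i, j, k, d_ij, d_ik, d_jk)
seed_triangles <- function(X, knn = 5L) {
  n <- nrow(X)
  k <- min(knn, n - 1L)
  if (k < 2L) return(NULL)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  diag(d2) <- Inf
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    prs <- t(combn(nb, 2L))
    out[[i]] <- cbind(i, prs)
  }
  tri <- do.call(rbind, out)
  tri <- tri[!duplicated(t(apply(tri, 1L, sort))), , drop = FALSE]
  d <- function(a, b) sqrt(pmax(rowSums((X[a, , drop = FALSE] - X[b, , drop = FALSE])^2), 0))
  cbind(tri, d12 = d(tri[, 1L], tri[, 2L]), d13 = d(tri[, 1L], tri[, 3L]),
        d23 = d(tri[, 2L], tri[, 3L]))
}

#' Non-sequential structural alignment of two interfaces
#'
#' Deterministic seed-and-extend alignment of the C-alpha point sets of two
#' interfaces, ignoring residue order entirely (interfaces are
#' discontinuous in sequence, so sequential aligners do not apply):
#'
#' 1. candidate seeds are pairs of near-congruent local triangles (each
#'    residue with two of its `knn` nearest neighbours; all six orderings
#'    of the second triangle; side-length deviation below `seed_tol`),
#'    ranked by total side-length deviation and capped at `max_seeds`;
#' 2. each seed's three-point Kabsch transform is extended by mutual
#'    nearest-neighbour matching within `rmsd_threshold` and iteratively
#'    refined (superpose on matches, re-match) to a fixed point;
#' 3. the transform maximising the number of matched residues wins, ties
#'    resolved by lower RMSD, then seed order.
#'
#' @param i1,i2 `piface_interface` objects (or bare C-alpha coordinate
#'   matrices for expert use).
#' @param rmsd_threshold match cutoff in A (3.0).
#' @param knn neighbours per residue for seed triangles.
#' @param seed_tol max per-side length deviation (A) for a seed.
#' @param max_seeds cap on extended seeds (best-first, deterministic).
#' @return `piface_alignment`: list with `matched_pairs` (data frame
#'   `res1`, `res2` of residue uids, or indices for matrix input),
#'   `rotation` (3x3, proper), `translation`, `rmsd` (A, over matches) and
#'   `n_matched`.
#' @export
align_interfaces <- function(i1, i2, rmsd_threshold = 3.0, knn = 5L,
                             seed_tol = 1.0, max_seeds = 400L) {
  X <- interface_ca_coords(i1)
  Y <- interface_ca_coords(i2)
  ids1 <- rownames(X); ids2 <- rownames(Y)
  if (nrow(X) < 3L || nrow(Y) < 3L) {
    stop("alignment needs at least 3 residues with C-alpha on each interface")
  }
  t1 <- seed_triangles(X, knn)
  t2 <- seed_triangles(Y, knn)
  orders <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  # side lengths of an ordered triple (a,b,c): d(ab), d(ac), d(bc)
  tri_sides <- function(tri, ord) {
    a <- tri[, ord[1L]]; b <- tri[, ord[2L]]; c <- tri[, ord[3L]]
    dd <- function(u, v) sqrt(pmax(rowSums((Y[u, , drop = FALSE] - Y[v, , drop = FALSE])^2), 0))
    cbind(dd(a, b), dd(a, c), dd(b, c))
  }
  cand_i <- integer(); cand_j <- integer(); cand_ord <- integer(); cand_dev <- numeric()
  for (oi in seq_len(nrow(orders))) {
    sides2 <- tri_sides(t2[, 1:3, drop = FALSE], orders[oi, ])
    for (s1 in seq_len(nrow(t1))) {
      dev <- abs(sides2[, 1L] - t1[s1, "d12"]) +
        abs(sides2[, 2L] - t1[s1, "d13"]) +
        abs(sides2[, 3L] - t1[s1, "d23"])
      ok <- which(abs(sides2[, 1L] - t1[s1, "d12"]) < seed_tol &
                    abs(sides2[, 2L] - t1[s1, "d13"]) < seed_tol &
                    abs(sides2[, 3L] - t1[s1, "d23"]) < seed_tol)
      if (length(ok) > 0L) {
        cand_i <- c(cand_i, rep(s1, length(ok)))
        cand_j <- c(cand_j, ok)
        cand_ord <- c(cand_ord, rep(oi, length(ok)))
        cand_dev <- c(cand_dev, dev[ok])
      }
    }
  }
  best <- list(n = 0L, rmsd = Inf, match = NULL, R = diag(3), t = c(0, 0, 0))
  if (length(cand_i) > 0L) {
    o <- order(cand_dev, cand_i, cand_j, cand_ord)
    o <- o[seq_len(min(length(o), max_seeds))]
    min_n <- min(nrow(X), nrow(Y))
    for (s in o) {
      p_idx <- as.integer(t1[cand_i[s], 1:3])
      q_idx <- as.integer(t2[cand_j[s], orders[cand_ord[s], ]])
      fit <- kabsch(X[p_idx, , drop = FALSE], Y[q_idx, , drop = FALSE])
      res <- extend_and_refine(X, Y, fit$rotation, fit$translation, rmsd_threshold)
      if (res$n > best$n || (res$n == best$n && res$rmsd < best$rmsd - 1e-12)) {
        best <- res
      }
      if (best$n == min_n && best$rmsd < 0.1) break
    }
  }
  matched <- if (best$n > 0L) {
    data.frame(res1 = ids1[best$match[, 1L]], res2 = ids2[best$match[, 2L]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(res1 = character(), res2 = character(), stringsAsFactors = FALSE)
  }
  structure(list(matched_pairs = matched, rotation = best$R,
                 translation = best$t,
                 rmsd = if (best$n > 0L) best$rmsd else NA_real_,
                 n_matched = best$n),
            class = "piface_alignment")
}

extend_and_refine <- function(X, Y, R, t, cutoff, max_iter = 30L) {
  match <- mutual_nn_match(apply_rigid(X, R, t), Y, cutoff)
  if (nrow(match) < 3L) {
    rmsd <- if (nrow(match) > 0L) {
      sqrt(mean(rowSums((apply_rigid(X, R, t)[match[, 1L], , drop = FALSE] -
                           Y[match[, 2L], , drop = FALSE])^2)))
    } else Inf
    return(list(n = nrow(match), rmsd = rmsd, match = match, R = R, t = t))
  }
  for (it in seq_len(max_iter)) {
    fit <- kabsch(X[match[, 1L], , drop = FALSE], Y[match[, 2L], , drop = FALSE])
    R <- fit$rotation; t <- fit$translation
    new_match <- mutual_nn_match(apply_rigid(X, R, t), Y, cutoff)
    if (nrow(new_match) == nrow(match) &&
        all(new_match == match)) { match <- new_match; break }
    match <- new_match
    if (nrow(match) < 3L) break
  }
  Xr <- apply_rigid(X, R, t)
  rmsd <- if (nrow(match) > 0L) {
    sqrt(mean(rowSums((Xr[match[, 1L], , drop = FALSE] -
                         Y[match[, 2L], , drop = FALSE])^2)))
  } else Inf
  list(n = nrow(match), rmsd = rmsd, match = match, R = R, t = t)
}

# C-alpha coordinates of an interface (contact + nearby, both sides),
# rownames = residue uids; passes matrices through untouched
interface_ca_coords <- function(i) {
  if (is.matrix(i)) {
    if (is.null(rownames(i))) rownames(i) <- as.character(seq_len(nrow(i)))
    return(i)
  }
  stopifnot(inherits(i, "piface_interface"))
  m <- as.matrix(i$ca[, c("x", "y", "z")])
  rownames(m) <- i$ca$res_id
  m
}

#' @export
print.piface_alignment <- function(x, ...) {
  cat("piface_alignment: ", x$n_matched, " matched residues, rmsd ",
      formatC(x$rmsd, digits = 3, format = "f"), " A\n", sep = "")
  invisible(x)
}

#' Interface similarity score
#'
#' The fraction of the smaller interface that is structurally matched:
#' `n_matched / min(size(i1), size(i2))`, capped at 1, where size is the
#' number of interface residues (contact + nearby by default, matching the
#' aligner's input; `residues = "contact"` restricts to contact counts).
#' Alternative denominators (`"mean"`, `"max"`) are provided for
#' sensitivity analyses. Symmetric in its arguments.
#'
#' @param aln a `piface_alignment` produced from `i1`, `i2`.
#' @param i1,i2 the aligned interfaces.
#' @param denom denominator convention: `"min"` (default), `"mean"`, `"max"`.
#' @param residues size convention: `"total"` (default) or `"contact"`.
#' @return `piface_similarity`: list with `value` in `[0, 1]`, `n_matched`,
#'   `denom`.
#' @export
interface_similarity <- function(aln, i1, i2, denom = c("min", "mean", "max"),
                                 residues = c("total", "contact")) {
  denom <- match.arg(denom)
  residues <- match.arg(residues)
  n1 <- n_interface_residues(i1, residues)
  n2 <- n_interface_residues(i2, residues)
  d <- switch(denom, min = min(n1, n2), mean = (n1 + n2) / 2, max = max(n1, n2))
  if (d <= 0) stop("degenerate interface sizes")
  structure(list(value = min(1, aln$n_matched / d),
                 n_matched = aln$n_matched, denom = d),
            class = "piface_similarity")
}

#' Pairwise similarity table over a set of interfaces
#'
#' Applies the size-compatibility gate, aligns the surviving pairs in
#' canonical (sorted-name) order for exact symmetry, and records scores at
#' or above `store_threshold`. The diagonal is implicit (every interface is
#' fully similar to itself).
#'
#' @param interfaces list of `piface_interface` objects (unique names).
#' @param rmsd_threshold aligner cutoff (A).
#' @param store_threshold drop pairs scoring below this (0 keeps all
#'   aligned pairs).
#' @param contact_factor,total_factor size-gate factors.
#' @param denom,residues see [interface_similarity()].
#' @param verbose log progress counts with `message()`.
#' @param ... further arguments to [align_interfaces()].
#' @return `piface_simtable`: data frame `iface1`, `iface2`, `n_matched`,
#'   `rmsd`, `similarity` (iface1 < iface2), with attribute
#'   `interface_names` listing every input interface.
#' @export
pairwise_similarity_matrix <- function(interfaces, rmsd_threshold = 3.0,
                                       store_threshold = 0,
                                       contact_factor = 1.25,
                                       total_factor = 1.50,
                                       denom = "min", residues = "total",
                                       verbose = FALSE, ...) {
  nms <- vapply(interfaces, function(i) i$name, character(1L))
  if (anyDuplicated(nms)) stop("duplicate interface names")
  names(interfaces) <- nms
  ord <- sort(nms)
  rows <- list()
  n_gate <- 0L; n_aligned <- 0L
  if (length(ord) >= 2L) {
    prs <- t(combn(ord, 2L))
    for (r in seq_len(nrow(prs))) {
      i1 <- interfaces[[prs[r, 1L]]]
      i2 <- interfaces[[prs[r, 2L]]]
      if (!size_compatible(i1, i2, contact_factor, total_factor)) {
        n_gate <- n_gate + 1L
        next
      }
      aln <- align_interfaces(i1, i2, rmsd_threshold, ...)
      n_aligned <- n_aligned + 1L
      sim <- interface_similarity(aln, i1, i2, denom, residues)
      if (sim$value >= store_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          iface1 = i1$name, iface2 = i2$name, n_matched = aln$n_matched,
          rmsd = aln$rmsd, similarity = sim$value, stringsAsFactors = FALSE)
      }
    }
  }
  if (verbose) {
    message("pairwise similarity: ", length(ord), " interfaces, ",
            n_aligned, " aligned, ", n_gate, " skipped by size gate")
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iface1 = character(), iface2 = character(),
               n_matched = integer(), rmsd = numeric(),
               similarity = numeric(), stringsAsFactors = FALSE)
  attr(tab, "interface_names") <- ord
  class(tab) <- c("piface_simtable", class(tab))
  tab
}

#' Dense symmetric similarity matrix from a similarity table
#'
#' @param tab a `piface_simtable` (or plain data frame `iface1`, `iface2`,
#'   `similarity`).
#' @param names node names (default: the table's recorded interfaces).
#' @return symmetric numeric matrix, unit diagonal, absent pairs 0.
#' @export
similarity_matrix <- function(tab, names = NULL) {
  if (is.matrix(tab)) return(tab)
  if (is.null(names)) names <- attr(tab, "interface_names")
  if (is.null(names)) names <- sort(unique(c(tab$iface1, tab$iface2)))
  m <- matrix(0, length(names), length(names), dimnames = list(names, names))
  diag(m) <- 1
  if (nrow(tab) > 0L) {
    i <- match(tab$iface1, names); j <- match(tab$iface2, names)
    m[cbind(i, j)] <- tab$similarity
    m[cbind(j, i)] <- tab$similarity
  }
  m
}

#' Read / write similarity tables as TSV
#'
#' The TSV carries `iface1`, `iface2`, `n_matched`, `rmsd`, `similarity`
#' and may be produced externally (e.g. imported MultiProt-style results)
#' to bypass the built-in aligner.
#'
#' @param tab a `piface_simtable`.
#' @param path TSV path.
#' @return `write_similarity_tsv`: `path` invisibly;
#'   `read_similarity_tsv`: a `piface_simtable`.
#' @export
write_similarity_tsv <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("iface1", "iface2", "similarity")
  if (!all(need %in% names(tab))) {
    stop("similarity TSV must contain columns: ", paste(need, collapse = ", "))
  }
  attr(tab, "interface_names") <- sort(unique(c(tab$iface1, tab$iface2)))
  class(tab) <- c("piface_simtable", class(tab))
  tab
}
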