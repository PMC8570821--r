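#' Anisotropic network model parameters
#'
#' The ANM places identical harmonic springs between C-alpha nodes closer
#' than \code{cutoff}; the eigenvectors of the resulting Hessian are
#' directional normal modes, the softest of which describe the most
#' collective deformations.
#'
#' @param cutoff interaction cutoff in Angstrom (> 0).  15 Angstrom is common
#'   ANM practice for C-alpha networks.
#' @param gamma uniform spring constant (arbitrary units, > 0).  Scales all
#'   eigenvalues linearly and leaves eigenvectors untouched.
#' @param n_modes number of softest nonrigid modes to retain
#'   (1 <= n_modes <= 3n - 6).
#' @param zero_mode_tol relative eigenvalue threshold below which a mode is
#'   classified rigid-body (translation/rotation).
#' @return a list of class \code{"AnmParams"}.
#' @export
anm_params <- function(cutoff = 15, gamma = 1, n_modes = 3L,
                       zero_mode_tol = 1e-8) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be > 0", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be > 0", call. = FALSE)
  n_modes <- as.integer(n_modes)
  if (is.na(n_modes) || n_modes < 1L)
    stop("n_modes must be a positive integer", call. = FALSE)
  structure(list(cutoff = cutoff, gamma = gamma, n_modes = n_modes,
                 zero_mode_tol = zero_mode_tol),
            class = "AnmParams")
}

#' Build the ANM Hessian
#'
#' For nodes i != j within \code{cutoff}, the off-diagonal 3x3 superelement is
#' \eqn{-(\gamma / r_{ij}^2)\, d_{ij} d_{ij}^T} with \eqn{d_{ij}} the
#' coordinate difference vector; each diagonal superelement is minus the sum
#' of its row's off-diagonal superelements, so every 3-row block sums to zero
#' across columns (translation invariance) and the matrix is symmetric
#' positive semidefinite.
#'
#' @param coords n x 3 node coordinate matrix (Angstrom), typically the
#'   C-alpha subset of a structure.
#' @param params an \code{AnmParams}.
#' @return a 3n x 3n symmetric numeric matrix (node i occupies rows/columns
#'   \code{3i-2 .. 3i}).
#' @export
build_hessian <- function(coords, params = anm_params()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("ANM needs at least 3 nodes", call. = FALSE)
  if (qr(sweep(coords, 2, colMeans(coords)))$rank < 2L)
    stop("node coordinates are collinear; the elastic network is degenerate",
         call. = FALSE)
  d2 <- as.matrix(stats::dist(coords))^2
  within <- d2 <= params$cutoff^2 & upper.tri(d2)
  pairs <- which(within, arr.ind = TRUE)
  neighbor_count <- integer(n)
  H <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dij <- coords[j, ] - coords[i, ]
    blk <- -(params$gamma / sum(dij^2)) * tcrossprod(dij)
    ri <- (3L * i - 2L):(3L * i); rj <- (3L * j - 2L):(3L * j)
    H[ri, rj] <- blk
    H[rj, ri] <- blk
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
    neighbor_count[i] <- neighbor_count[i] + 1L
    neighbor_count[j] <- neighbor_count[j] + 1L
  }
  isolated <- which(neighbor_count == 0L)
  if (length(isolated))
    stop("node(s) ", paste(isolated, collapse = ", "),
         " have no neighbor within the ", params$cutoff,
         " Angstrom cutoff; the network is disconnected", call. = FALSE)
  H
}

#' Compute ANM normal modes from a Hessian
#'
#' Full dense symmetric eigendecomposition.  Eigenvalues below
#' \code{zero_mode_tol} times the largest eigenvalue are classified as
#' rigid-body modes and discarded; exactly six must be discarded (three
#' translations, three rotations) or the network is degenerate.  The
#' \code{n_modes} smallest remaining eigenpairs are returned in ascending
#' eigenvalue order.
#'
#' @param hessian 3n x 3n matrix from [build_hessian()].
#' @param params an \code{AnmParams}.
#' @return a \code{ModeBasis}: list with \code{eigenvalues} (length m,
#'   ascending, positive), \code{node_vectors} (m x 3n orthonormal rows),
#'   \code{n_nodes}, and \code{atom_vectors}/\code{node_mask} slots filled by
#'   [extend_to_all_atoms()].
#' @export
compute_modes <- function(hessian, params = anm_params()) {
  n3 <- nrow(hessian)
  if (n3 %% 3L != 0L || !isTRUE(all.equal(hessian, t(hessian), tolerance = 1e-8)))
    stop("hessian must be a symmetric 3n x 3n matrix", call. = FALSE)
  eig <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  vals <- rev(eig$values)               # ascending
  vecs <- eig$vectors[, rev(seq_len(n3)), drop = FALSE]
  zero <- vals < params$zero_mode_tol * max(vals)
  n_zero <- sum(zero)
  if (n_zero != 6L)
    stop("expected exactly 6 rigid-body zero modes, found ", n_zero,
         "; the network is degenerate (collinear or disconnected)",
         call. = FALSE)
  avail <- n3 - 6L
  if (params$n_modes > avail)
    stop("n_modes = ", params$n_modes, " exceeds the ", avail,
         " available nonrigid modes", call. = FALSE)
  keep <- (6L + 1L):(6L + params$n_modes)
  structure(list(
    eigenvalues = vals[keep],
    node_vectors = t(vecs[, keep, drop = FALSE]),
    n_nodes = n3 %/% 3L,
    node_mask = NULL,
    atom_vectors = NULL),
    class = "ModeBasis")
}

#' Extend node modes to all atoms of a structure
#'
#' Rigid-residue extension: every atom inherits the 3-vector of its residue's
#' C-alpha node, per mode; C-alpha rows are unchanged.  Node order must
#' follow the structure's C-alpha order.
#'
#' @param mode_basis a \code{ModeBasis} from [compute_modes()].
#' @param structure the \code{Structure} the modes were computed on.
#' @param node_expression selection giving the nodes: a grammar expression
#'   for [select_atoms()], or \code{"auto"} (default) which takes each
#'   residue's \code{CA} atom, falling back to \code{P} then \code{C4'} for
#'   nucleotide residues.
#' @return the \code{ModeBasis} with \code{atom_vectors} (m x 3N) and
#'   \code{node_mask} filled.
#' @export
extend_to_all_atoms <- function(mode_basis, structure,
                                node_expression = "auto") {
  stopifnot(inherits(mode_basis, "ModeBasis"))
  mask <- node_mask(structure, node_expression)
  node_idx <- mask_indices(mask, "node selection")
  if (length(node_idx) != mode_basis$n_nodes)
    stop("structure has ", length(node_idx), " node atoms but the mode basis ",
         "was computed on ", mode_basis$n_nodes, call. = FALSE)
  rk <- residue_key(structure)
  node_of_res <- match(rk, rk[node_idx])   # residue -> node ordinal
  if (anyNA(node_of_res)) {
    bad <- unique(rk[is.na(node_of_res)])
    stop("residue(s) without a node atom: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- length(mode_basis$eigenvalues)
  N <- n_atoms(structure)
  atom_vectors <- matrix(0, m, 3L * N)
  for (k in seq_len(m)) {
    nodev <- matrix(mode_basis$node_vectors[k, ], ncol = 3L, byrow = TRUE)
    atom_vectors[k, ] <- as.vector(t(nodev[node_of_res, , drop = FALSE]))
  }
  mode_basis$atom_vectors <- atom_vectors
  mode_basis$node_mask <- mask
  mode_basis
}

#' Convenience: ANM modes of a structure in one call
#'
#' Builds the Hessian on the node atoms, solves for the softest nonrigid
#' modes, and extends them to all atoms.
#'
#' @inheritParams extend_to_all_atoms
#' @param params an \code{AnmParams}.
#' @return an all-atom-extended \code{ModeBasis}.
#' @export
anm_modes <- function(structure, params = anm_params(),
                      node_expression = "auto") {
  mask <- node_mask(structure, node_expression)
  idx <- mask_indices(mask, "node selection")
  H <- build_hessian(structure$coords[idx, , drop = FALSE], params)
  mb <- compute_modes(H, params)
  extend_to_all_atoms(mb, structure, node_expression)
}

# one node per residue: CA, or for nucleotides P (fallback C4')
node_mask <- function(structure, node_expression = "auto") {
  if (!identical(node_expression, "auto"))
    return(select_atoms(structure, node_expression))
  at <- structure$atoms
  rk <- residue_key(structure)
  mask <- logical(nrow(at))
  for (res in split(seq_len(nrow(at)), factor(rk, levels = unique(rk)))) {
    nm <- at$atom_name[res]
    hit <- res[match(TRUE, nm == "CA")]
    if (is.na(hit)) hit <- res[match(TRUE, nm == "P")]
    if (is.na(hit)) hit <- res[match(TRUE, nm == "C4'")]
    if (!is.na(hit)) mask[hit] <- TRUE
  }
  mask
}

#' @export
print.ModeBasis <- function(x, ...) {
  cat(sprintf("ModeBasis: %d mode(s) on %d nodes%s\n",
              length(x$eigenvalues), x$n_nodes,
              if (is.null(x$atom_vectors)) "" else
                sprintf(", extended to %d atoms", ncol(x$atom_vectors) %/% 3L)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}
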