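#' Sampling parameters
#'
#' @param n_confs conformers generated per parent structure (>= 1).
#' @param target_rmsd deformation size per generation: the unsuperposed
#'   C-alpha RMSD (Angstrom) between each child conformer and its parent.
#'   The random draw fixes only the direction in mode space; the step length
#'   is rescaled to hit \code{target_rmsd} exactly.
#' @param seed integer master seed for the sampling random stream.
#' @return a list of class \code{"SamplingParams"}.
#' @export
sampling_params <- function(n_confs = 50L, target_rmsd = 1.0, seed = 1L) {
  n_confs <- as.integer(n_confs)
  if (is.na(n_confs) || n_confs < 1L)
    stop("n_confs must be >= 1", call. = FALSE)
  if (!is.numeric(target_rmsd) || target_rmsd < 0)
    stop("target_rmsd must be >= 0", call. = FALSE)
  structure(list(n_confs = n_confs, target_rmsd = target_rmsd,
                 seed = as.integer(seed)),
            class = "SamplingParams")
}

#' Ensemble of conformers
#'
#' An ordered set of conformers on one topology, with per-conformer
#' generation index and parent lineage.
#'
#' @param coords M x N x 3 array (or a single N x 3 matrix for M = 1).
#' @param generation length-M integer vector, >= 0 (0 = the input structure).
#' @param parent length-M integer vector indexing the previous generation's
#'   representatives (1-based); -1 marks the input structure as parent.
#' @return a list of class \code{"Ensemble"}.
#' @export
ensemble <- function(coords, generation = NULL, parent = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  M <- dim(coords)[1]
  if (is.null(generation)) generation <- integer(M)
  if (is.null(parent)) parent <- rep(-1L, M)
  stopifnot(length(generation) == M, length(parent) == M)
  if (is.unsorted(generation))
    stop("generation labels must be non-decreasing in storage order",
         call. = FALSE)
  structure(list(coords = coords, generation = as.integer(generation),
                 parent = as.integer(parent)),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Ensemble: %d conformer(s) x %d atoms (generations %d..%d)\n",
              d[1], d[2], min(x$generation), max(x$generation)))
  invisible(x)
}

#' Number of conformers in an Ensemble
#' @param x an \code{Ensemble}.
#' @return integer conformer count.
#' @export
n_conformers <- function(x) {
  stopifnot(inherits(x, "Ensemble"))
  dim(x$coords)[1]
}

#' Concatenate ensembles on a shared topology
#' @param ... \code{Ensemble} objects with identical atom counts.
#' @return a single \code{Ensemble}.
#' @export
bind_ensembles <- function(...) {
  es <- list(...)
  es <- es[!vapply(es, is.null, logical(1))]
  stopifnot(length(es) >= 1L, all(vapply(es, inherits, logical(1), "Ensemble")))
  N <- dim(es[[1]]$coords)[2]
  if (!all(vapply(es, function(e) dim(e$coords)[2], numeric(1)) == N))
    stop("ensembles have differing atom counts", call. = FALSE)
  coords <- do.call(abind3, lapply(es, `[[`, "coords"))
  ensemble(coords,
           generation = unlist(lapply(es, `[[`, "generation")),
           parent = unlist(lapply(es, `[[`, "parent")))
}

# rbind along the first (conformer) dimension of M x N x 3 arrays
abind3 <- function(...) {
  xs <- list(...)
  N <- dim(xs[[1]])[2]
  M <- sum(vapply(xs, function(x) dim(x)[1], numeric(1)))
  out <- array(0, c(M, N, 3L))
  at <- 0L
  for (x in xs) {
    m <- dim(x)[1]
    if (m > 0L) out[at + seq_len(m), , ] <- x
    at <- at + m
  }
  out
}

#' Generate conformers by random deformation along ANM modes
#'
#' For each conformer, mode coefficients are drawn independently and
#' uniformly on \[-1, 1\]; the combined all-atom displacement
#' \eqn{D = \sum_k c_k v_k} is rescaled by
#' \eqn{\alpha = \mathrm{rmsd} \sqrt{n_{C\alpha}} / \lVert D_{C\alpha}\rVert}
#' so that the unsuperposed C-alpha RMSD between child and parent equals
#' \code{target_rmsd} exactly.  Mode displacements are orthogonal to the
#' rigid-body modes by construction, so no superposition is needed.
#'
#' @param parent_coords N x 3 matrix, the parent conformer.
#' @param modes an all-atom-extended \code{ModeBasis}.
#' @param calpha_mask logical mask of the C-alpha (node) atoms used for RMSD
#'   scaling.
#' @param params a \code{SamplingParams}.
#' @param seed integer seed for this call's random stream (defaults to
#'   \code{params$seed}); the pipeline derives one per (generation, parent)
#'   so results are independent of parent processing order.
#' @return an \code{Ensemble} of \code{params$n_confs} children (generation
#'   and parent labels left at defaults; the pipeline assigns lineage).
#' @export
generate_conformers <- function(parent_coords, modes, calpha_mask,
                                params = sampling_params(), seed = NULL) {
  stopifnot(inherits(modes, "ModeBasis"))
  if (is.null(modes$atom_vectors))
    stop("modes must be extended to all atoms first (extend_to_all_atoms)",
         call. = FALSE)
  parent_coords <- as.matrix(parent_coords)
  N <- nrow(parent_coords)
  if (3L * N != ncol(modes$atom_vectors))
    stop("parent has ", N, " atoms but modes are extended to ",
         ncol(modes$atom_vectors) %/% 3L, call. = FALSE)
  ca_idx <- mask_indices(calpha_mask, "C-alpha mask")
  m <- length(modes$eigenvalues)
  if (is.null(seed)) seed <- params$seed
  set.seed(as.integer(seed))
  out <- array(0, c(params$n_confs, N, 3L))
  for (ic in seq_len(params$n_confs)) {
    if (params$target_rmsd == 0) {
      out[ic, , ] <- parent_coords
      next
    }
    disp_norm <- 0
    for (try in seq_len(100L)) {
      coef <- stats::runif(m, -1, 1)
      D <- drop(crossprod(modes$atom_vectors, coef))  # length 3N
      Dm <- matrix(D, ncol = 3L, byrow = TRUE)
      disp_norm <- sqrt(sum(Dm[ca_idx, ]^2))
      if (disp_norm > 0) break
    }
    if (disp_norm == 0)
      stop("zero-norm mode displacement after 100 redraws", call. = FALSE)
    alpha <- params$target_rmsd * sqrt(length(ca_idx)) / disp_norm
    out[ic, , ] <- parent_coords + alpha * Dm
  }
  ensemble(out)
}

# unsuperposed RMSD between two coordinate sets over an index subset
raw_rmsd <- function(a, b, idx = seq_len(nrow(a))) {
  sqrt(sum((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2) / length(idx))
}
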