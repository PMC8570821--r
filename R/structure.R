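#' Biomolecular structure container
#'
#' A \code{Structure} bundles per-atom metadata with Cartesian coordinates in
#' Angstrom.  It is the topology shared by every pipeline stage: mode
#' extension, sampling, clustering, relaxation and analysis all operate on the
#' same atom ordering.
#'
#' @param atoms data frame with columns \code{atom_serial}, \code{atom_name},
#'   \code{element}, \code{residue_index}, \code{residue_name},
#'   \code{chain_id} (one row per atom).
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param coarse_grained logical; \code{TRUE} for reduced models (e.g. a
#'   C-alpha trace with pseudo side-chain atoms) where residues need not carry
#'   full heavy-atom chemistry.
#'
#' @return An object of class \code{"Structure"}: a list with elements
#'   \code{atoms}, \code{coords} and \code{coarse_grained}.
#' @export
Structure <- function(atoms, coords, coarse_grained = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  obj <- structure(
    list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
         coords = coords,
         coarse_grained = isTRUE(coarse_grained)),
    class = "Structure")
  validate_structure(obj)
  obj
}

validate_structure <- function(x) {
  stopifnot(inherits(x, "Structure"))
  at <- x$atoms
  need <- c("atom_serial", "atom_name", "element", "residue_index",
            "residue_name", "chain_id")
  missing_cols <- setdiff(need, names(at))
  if (length(missing_cols))
    stop("Structure atoms table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(at)
  if (n < 3L)
    stop("Structure must contain at least 3 atoms, got ", n, call. = FALSE)
  if (!is.matrix(x$coords) || ncol(x$coords) != 3L || nrow(x$coords) != n)
    stop("coords must be an N x 3 matrix matching the atoms table (N = ",
         n, ")", call. = FALSE)
  if (any(!is.finite(x$coords)))
    stop("coords contain non-finite values", call. = FALSE)
  key <- paste(at$chain_id, at$residue_index, at$atom_name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain_id, residue_index, atom_name) triple: ",
         key[anyDuplicated(key)], call. = FALSE)
  if (!x$coarse_grained) {
    res <- split(at$atom_name, paste(at$chain_id, at$residue_index))
    n_ca <- vapply(res, function(a) sum(a == "CA"), integer(1))
    if (any(n_ca != 1L))
      stop("every residue must contribute exactly one CA atom ",
           "(or flag the structure coarse_grained)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.Structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)%s\n",
              nrow(at),
              length(unique(paste(at$chain_id, at$residue_index))),
              length(unique(at$chain_id)),
              if (x$coarse_grained) " [coarse-grained]" else ""))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param x a \code{Structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "Structure"))
  nrow(x$atoms)
}

#' Replace the coordinates of a Structure
#'
#' Returns a copy of \code{x} whose coordinates are \code{coords}; topology is
#' untouched.  Used by the pipeline to carry relaxed or deformed coordinates
#' on a fixed topology.
#'
#' @param x a \code{Structure}.
#' @param coords numeric N x 3 matrix.
#' @return a \code{Structure}.
#' @export
set_coords <- function(x, coords) {
  stopifnot(inherits(x, "Structure"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(dim(coords) == dim(x$coords)))
    stop("replacement coords must be ", nrow(x$coords), " x 3", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("replacement coords contain non-finite values", call. = FALSE)
  x$coords <- coords
  x
}

# residue key used everywhere a per-residue grouping is needed
residue_key <- function(structure) {
  paste(structure$atoms$chain_id, structure$atoms$residue_index, sep = "|")
}
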