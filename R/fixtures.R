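#' Specification for a synthetic toy structure
#'
#' Toy structures make every pipeline stage testable without external data:
#' a single ideal alpha-helix, or two compact helical domains joined by an
#' extended linker (a minimal hinge system whose softest nonrigid mode is an
#' inter-domain motion).
#'
#' @param n_residues total residue count (>= 4); for \code{two_domain} this
#'   includes the linker residues.
#' @param geometry \code{"helix"} or \code{"two_domain"}.
#' @param linker_length residues in the extended linker (two_domain only,
#'   >= 1).
#' @param seed integer seed for the small (0.005 Angstrom) deterministic
#'   coordinate jitter that breaks exact helical symmetry.
#' @return a list of class \code{"ToySpec"}.
#' @export
toy_spec <- function(n_residues, geometry = c("helix", "two_domain"),
                     linker_length = 4L, seed = 1L) {
  geometry <- match.arg(geometry)
  n_residues <- as.integer(n_residues)
  linker_length <- as.integer(linker_length)
  if (is.na(n_residues) || n_residues < 4L)
    stop("n_residues must be an integer >= 4", call. = FALSE)
  if (is.na(linker_length) || linker_length < 1L)
    stop("linker_length must be an integer >= 1", call. = FALSE)
  if (geometry == "two_domain" && n_residues < linker_length + 6L)
    stop("two_domain geometry needs at least 3 residues per domain beyond ",
         "the linker", call. = FALSE)
  structure(list(n_residues = n_residues, geometry = geometry,
                 linker_length = linker_length, seed = as.integer(seed)),
            class = "ToySpec")
}

# ideal alpha-helical C-alpha curve: rise 1.5 A/residue, radius 2.3 A,
# 100 degree twist per residue; CB pseudo side chain 1.5 A further out
# radially.  Returns list(ca, cb) of n x 3 matrices.
helix_coords <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * i)
  list(ca = sweep(ca, 2, origin, "+"), cb = sweep(cb, 2, origin, "+"))
}

#' Generate a synthetic toy structure
#'
#' Builds a deterministic coarse-grained structure (one \code{CA} plus one
#' \code{CB} pseudo side-chain atom per residue) with known geometry:
#' \describe{
#'   \item{helix}{C-alpha trace on an ideal alpha-helical curve (1.5 Angstrom
#'     rise, 2.3 Angstrom radius, 100 degree twist per residue), consecutive
#'     C-alpha distance about 3.8 Angstrom.}
#'   \item{two_domain}{two compact helical domains joined by an extended
#'     linker, a hinge system for testing inter-domain mode sampling.}
#' }
#' A 0.005-Angstrom uniform jitter (seeded from the spec) breaks exact helical
#' symmetry so normal-mode spectra are non-degenerate; the construction keeps
#' all atom pairs farther apart than 1 Angstrom and the C-alpha set
#' non-collinear (full rank 3), guaranteeing exactly six rigid-body zero
#' modes under the anisotropic network model.
#'
#' @param spec a \code{ToySpec} from [toy_spec()].
#' @return a coarse-grained \code{Structure} with \code{2 * n_residues} atoms.
#' @export
#' @examples
#' s <- make_toy(toy_spec(10))
#' n_atoms(s)  # 20
make_toy <- function(spec) {
  if (!inherits(spec, "ToySpec"))
    stop("spec must be a ToySpec (see toy_spec())", call. = FALSE)
  n <- spec$n_residues
  if (spec$geometry == "helix") {
    h <- helix_coords(n)
    ca <- h$ca; cb <- h$cb
  } else {
    nl <- spec$linker_length
    n1 <- (n - nl) %/% 2L
    n2 <- n - nl - n1
    d1 <- helix_coords(n1)
    z_top <- 1.5 * (n1 - 1L)
    # extended linker along +x, zigzagging in y and z: collinear (or nearly
    # collinear) linker nodes would give the C-alpha network a spurious
    # near-zero twist mode about the linker axis; the wide 3-D zigzag keeps
    # that torsion a regular soft mode
    i <- seq_len(nl)
    xs <- 4.5 + (i - 1L) * 2.0
    ys <- 1.5 * (-1)^i
    zs <- z_top + 0.8 * (-1)^ceiling(i / 2)
    lca <- cbind(xs, ys, zs)
    lcb <- cbind(xs, ys, zs + 1.5)
    d2 <- helix_coords(n2, origin = c(max(xs) + 4.5, 0, z_top))
    ca <- rbind(d1$ca, lca, d2$ca)
    cb <- rbind(d1$cb, lcb, d2$cb)
  }
  # interleave per residue: CA then CB
  coords <- matrix(0, 2L * n, 3L)
  coords[seq(1L, 2L * n, by = 2L), ] <- ca
  coords[seq(2L, 2L * n, by = 2L), ] <- cb
  set.seed(spec$seed)
  coords <- coords + matrix(runif(length(coords), -0.005, 0.005), ncol = 3L)
  atoms <- data.frame(
    atom_serial = seq_len(2L * n),
    atom_name = rep(c("CA", "CB"), n),
    element = "C",
    residue_index = rep(seq_len(n), each = 2L),
    residue_name = "ALA",
    chain_id = "A",
    stringsAsFactors = FALSE)
  Structure(atoms, coords, coarse_grained = TRUE)
}
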