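#' Read a PDB structure file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d's reader) with these
#' policies: first MODEL only; alternate locations other than ' '/'A'
#' dropped; waters (HOH) dropped; residue numbering taken verbatim from the
#' file (author numbering, used by \code{resid} selections); insertion codes
#' kept in the atom uniqueness key but not exposed numerically.  The
#' structure is flagged coarse-grained when some residue lacks a \code{CA}
#' atom (C-alpha traces, nucleic acids) or when residues average fewer than
#' three atoms (reduced models), so trace bonds are restored on relaxation.
#'
#' @param path PDB file path.
#' @return a \code{Structure}.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  check_pdb_coordinates(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     hex = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  if (!nrow(at))
    stop("no accepted ATOM/HETATM records in ", path, call. = FALSE)
  atoms <- data.frame(
    atom_serial = as.integer(at$eleno),
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     substr(trimws(at$elety), 1L, 1L), trimws(at$elesy)),
    residue_index = as.integer(at$resno),
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE)
  coords <- cbind(at$x, at$y, at$z)
  rk <- paste(atoms$chain_id, atoms$residue_index, atoms$insert)
  has_ca <- vapply(split(atoms$atom_name, rk),
                   function(a) sum(a == "CA") == 1L, logical(1))
  cg <- !all(has_ca) || nrow(atoms) / length(has_ca) < 3
  Structure(atoms, coords, coarse_grained = cg)
}

# pre-scan for unparsable coordinate fields so errors can name the line
check_pdb_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  for (ln in which(rec)) {
    fields <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
                substr(lines[ln], 47, 54))
    ok <- !is.na(suppressWarnings(as.numeric(trimws(fields))))
    if (!all(ok))
      stop("unparsable coordinate field on line ", ln, " of ", path,
           call. = FALSE)
  }
  invisible(TRUE)
}

# fixed-column ATOM lines for one coordinate set
format_pdb_atoms <- function(atoms, coords) {
  nm <- atoms$atom_name
  nm <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), nm)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$atom_serial %% 100000L, nm,
          substr(atoms$residue_name, 1L, 3L),
          substr(atoms$chain_id, 1L, 1L),
          atoms$residue_index %% 10000L,
          coords[, 1], coords[, 2], coords[, 3],
          substr(atoms$element, 1L, 2L))
}

#' Write a structure (optionally a whole ensemble) as PDB
#'
#' Single-model PDB when no ensemble is given; otherwise one
#' \code{MODEL}/\code{ENDMDL} block per conformer, order preserved.
#' Coordinates are printed with 3 decimals (the format's precision).
#'
#' @param structure the topology \code{Structure}; its own coordinates are
#'   written when \code{ens} is NULL.
#' @param path output file.
#' @param ens optional \code{Ensemble} on the same topology.
#' @return invisibly, \code{path}.
#' @export
write_pdb <- function(structure, path, ens = NULL) {
  stopifnot(inherits(structure, "Structure"))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(ens)) {
    writeLines(format_pdb_atoms(structure$atoms, structure$coords), con)
  } else {
    stopifnot(inherits(ens, "Ensemble"))
    if (dim(ens$coords)[2] != n_atoms(structure))
      stop("ensemble has ", dim(ens$coords)[2], " atoms but structure has ",
           n_atoms(structure), call. = FALSE)
    for (i in seq_len(n_conformers(ens))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(format_pdb_atoms(structure$atoms,
                                  ens$coords[i, , , drop = TRUE]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB back as a Structure plus Ensemble
#'
#' @param path multi-model PDB file.
#' @return list with \code{structure} (topology + first model's coordinates)
#'   and \code{ensemble} (all models).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE,
                                          verbose = FALSE))
  s <- read_pdb(path)
  xyz <- pdb$xyz
  M <- nrow(xyz)
  N <- ncol(xyz) %/% 3L
  if (N != n_atoms(s))
    stop("model atom counts differ across MODEL blocks in ", path,
         call. = FALSE)
  coords <- array(0, c(M, N, 3L))
  for (i in seq_len(M))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  list(structure = s, ensemble = ensemble(coords))
}

#' Write an ensemble as a CHARMM-style DCD trajectory
#'
#' 32-bit Fortran record markers, \code{CORD} tag, frame count equal to the
#' conformer count, per-frame X/Y/Z coordinate arrays in single precision
#' (Angstrom), frames in ensemble order.
#'
#' @param ens an \code{Ensemble} (M >= 1).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_dcd <- function(ens, path) {
  stopifnot(inherits(ens, "Ensemble"))
  M <- n_conformers(ens)
  if (M < 1L) stop("ensemble has no conformers", call. = FALSE)
  N <- dim(ens$coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header record: 'CORD' + 20-int control block (CHARMM version 24,
  # timestep delta stored as a 32-bit float in slot 10)
  wint(84L)
  writeBin(charToRaw("CORD"), con)
  wint(c(M, 1L, 1L, M, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4L)           # delta as float32
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)
  # title record
  title <- sprintf("%-80s", "Created by enmpipe")
  wint(4L + 80L)
  wint(1L)
  writeBin(charToRaw(title), con)
  wint(4L + 80L)
  # atom-count record
  wint(4L); wint(N); wint(4L)
  for (i in seq_len(M)) {
    fr <- ens$coords[i, , , drop = TRUE]
    for (ax in 1:3) {
      wint(4L * N)
      writeBin(as.numeric(fr[, ax]), con, size = 4L)
      wint(4L * N)
    }
  }
  invisible(path)
}

#' Read a DCD trajectory into an Ensemble
#'
#' Thin wrapper over bio3d's DCD reader.
#'
#' @param path DCD file.
#' @return an \code{Ensemble}.
#' @export
read_dcd_ensemble <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  M <- nrow(xyz); N <- ncol(xyz) %/% 3L
  coords <- array(0, c(M, N, 3L))
  for (i in seq_len(M))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  ensemble(coords)
}
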