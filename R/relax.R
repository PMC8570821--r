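#' Relaxation parameters
#'
#' The built-in backend minimizes a simple geometric energy
#' \deqn{E = \sum_{bonds} k_{bond}(|r_i - r_j| - b_{ij})^2 +
#'       \sum_{nonbonded,\ d < d_0} k_{rep}(d_0 - d)^2}
#' by steepest descent with backtracking: bonds restrain the reference
#' topology, the repulsion term removes steric clashes introduced by mode
#' deformation.  An external molecular-dynamics engine can replace it via
#' [register_relax_adapter()].
#'
#' @param backend \code{"builtin"} or \code{"external"}.
#' @param k_bond bond restraint constant (energy / Angstrom^2).
#' @param k_rep clash repulsion constant (energy / Angstrom^2).
#' @param rep_cutoff repulsion onset distance d0 (Angstrom); heavy-atom
#'   nonbonded pairs closer than this are pushed apart.
#' @param bond_detect_max bond detection distance in the reference structure
#'   (Angstrom).
#' @param step_size displacement (Angstrom) of the highest-force atom per
#'   accepted step.
#' @param max_steps iteration cap.
#' @param force_tol convergence threshold on the maximum per-atom force
#'   magnitude.
#' @param adapter_config opaque list handed to an external adapter.
#' @return a list of class \code{"RelaxParams"}.
#' @export
relax_params <- function(backend = c("builtin", "external"), k_bond = 100,
                         k_rep = 10, rep_cutoff = 2.5, bond_detect_max = 1.9,
                         step_size = 0.01, max_steps = 500L, force_tol = 1e-3,
                         adapter_config = list()) {
  backend <- match.arg(backend)
  nums <- c(k_bond = k_bond, k_rep = k_rep, rep_cutoff = rep_cutoff,
            bond_detect_max = bond_detect_max, step_size = step_size,
            max_steps = max_steps, force_tol = force_tol)
  if (any(!is.finite(nums)) || any(nums <= 0))
    stop("all relaxation parameters must be positive", call. = FALSE)
  structure(list(backend = backend, k_bond = k_bond, k_rep = k_rep,
                 rep_cutoff = rep_cutoff, bond_detect_max = bond_detect_max,
                 step_size = step_size, max_steps = as.integer(max_steps),
                 force_tol = force_tol, adapter_config = adapter_config),
            class = "RelaxParams")
}

# heavy atoms: hydrogens are carried through I/O but excluded from the
# relaxation energy (the repulsion scale d0 is a heavy-atom scale)
heavy_mask <- function(structure) {
  toupper(trimws(structure$atoms$element)) != "H"
}

#' Detect the bond list on the reference structure
#'
#' Heavy-atom pairs within \code{bond_detect_max} Angstrom in the reference
#' coordinates, plus consecutive C-alpha pairs of each chain when the
#' structure is coarse-grained (a C-alpha trace has no sub-1.9 Angstrom
#' contacts).  Equilibrium lengths \code{b_ij} are the reference distances;
#' the list is fixed for a whole pipeline run.
#'
#' @param structure the reference \code{Structure}.
#' @param params a \code{RelaxParams}.
#' @return data frame with columns \code{i}, \code{j}, \code{b} (atom
#'   indices and equilibrium distance in Angstrom).
#' @export
build_bond_list <- function(structure, params = relax_params()) {
  stopifnot(inherits(structure, "Structure"))
  coords <- structure$coords
  heavy <- which(heavy_mask(structure))
  d <- as.matrix(stats::dist(coords[heavy, , drop = FALSE]))
  hit <- which(d <= params$bond_detect_max & upper.tri(d), arr.ind = TRUE)
  bonds <- data.frame(i = heavy[hit[, 1]], j = heavy[hit[, 2]],
                      b = d[hit])
  if (structure$coarse_grained) {
    at <- structure$atoms
    ca <- which(at$atom_name == "CA")
    ca <- ca[order(at$chain_id[ca], at$residue_index[ca])]
    if (length(ca) > 1L) {
      consec <- which(at$chain_id[ca[-length(ca)]] == at$chain_id[ca[-1]] &
                      at$residue_index[ca[-1]] -
                        at$residue_index[ca[-length(ca)]] == 1L)
      if (length(consec)) {
        i <- ca[consec]; j <- ca[consec + 1L]
        b <- sqrt(rowSums((coords[i, , drop = FALSE] -
                           coords[j, , drop = FALSE])^2))
        bonds <- rbind(bonds, data.frame(i = i, j = j, b = b))
      }
    }
  }
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  bonds <- bonds[!duplicated(key), , drop = FALSE]
  rownames(bonds) <- NULL
  bonds
}

# energy and gradient of the geometric relaxation potential
relax_energy_grad <- function(coords, bonds, heavy_idx, params,
                              bond_key_set) {
  grad <- matrix(0, nrow(coords), 3L)
  e_bond <- 0
  if (nrow(bonds)) {
    dv <- coords[bonds$i, , drop = FALSE] - coords[bonds$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    dev <- d - bonds$b
    e_bond <- params$k_bond * sum(dev^2)
    g <- 2 * params$k_bond * dev / pmax(d, 1e-12)
    gv <- dv * g
    for (r in seq_len(nrow(bonds))) {
      grad[bonds$i[r], ] <- grad[bonds$i[r], ] + gv[r, ]
      grad[bonds$j[r], ] <- grad[bonds$j[r], ] - gv[r, ]
    }
  }
  # nonbonded heavy pairs within d0, re-detected at the current coordinates
  e_rep <- 0
  dh <- as.matrix(stats::dist(coords[heavy_idx, , drop = FALSE]))
  close <- which(dh < params$rep_cutoff & upper.tri(dh), arr.ind = TRUE)
  if (nrow(close)) {
    ai <- heavy_idx[close[, 1]]; aj <- heavy_idx[close[, 2]]
    keep <- !(paste(pmin(ai, aj), pmax(ai, aj)) %in% bond_key_set)
    ai <- ai[keep]; aj <- aj[keep]
    if (length(ai)) {
      dv <- coords[ai, , drop = FALSE] - coords[aj, , drop = FALSE]
      d <- sqrt(rowSums(dv^2))
      gap <- params$rep_cutoff - d
      e_rep <- params$k_rep * sum(gap^2)
      g <- -2 * params$k_rep * gap / pmax(d, 1e-12)
      gv <- dv * g
      for (r in seq_along(ai)) {
        grad[ai[r], ] <- grad[ai[r], ] + gv[r, ]
        grad[aj[r], ] <- grad[aj[r], ] - gv[r, ]
      }
    }
  }
  list(energy = e_bond + e_rep, grad = grad)
}

#' Relax a conformer with the built-in geometric minimizer
#'
#' Steepest descent on the bond + repulsion energy, with backtracking: the
#' highest-force atom moves \code{step_size} Angstrom per trial step and the
#' step is halved whenever the energy would increase, so the accepted energy
#' trace is non-increasing by construction.  Convergence is declared when the
#' maximum per-atom force drops below \code{force_tol}.
#'
#' @param conformer_coords N x 3 matrix to relax.
#' @param bonds bond list from [build_bond_list()] on the same topology.
#' @param params a \code{RelaxParams}.
#' @param heavy logical mask of heavy atoms (default: all; the pipeline
#'   passes the structure's hydrogen-free mask).
#' @return a \code{RelaxResult}: list with \code{coords},
#'   \code{energy_trace} (accepted energies, starting with the input's),
#'   \code{converged}, \code{steps_taken}.
#' @export
relax <- function(conformer_coords, bonds, params = relax_params(),
                  heavy = NULL) {
  coords <- as.matrix(conformer_coords)
  if (is.null(heavy)) heavy <- rep(TRUE, nrow(coords))
  heavy_idx <- which(heavy)
  bond_key_set <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  eg <- relax_energy_grad(coords, bonds, heavy_idx, params, bond_key_set)
  trace <- eg$energy
  converged <- FALSE
  steps <- 0L
  for (it in seq_len(params$max_steps)) {
    if (!is.finite(eg$energy) || any(!is.finite(eg$grad)))
      stop("non-finite energy or force at iteration ", it, call. = FALSE)
    force <- -eg$grad
    max_f <- sqrt(max(rowSums(force^2)))
    if (max_f < params$force_tol) { converged <- TRUE; break }
    step <- params$step_size
    accepted <- FALSE
    for (half in seq_len(40L)) {
      trial <- coords + (step / max_f) * force
      eg_trial <- relax_energy_grad(trial, bonds, heavy_idx, params,
                                    bond_key_set)
      if (is.finite(eg_trial$energy) && eg_trial$energy <= eg$energy) {
        coords <- trial; eg <- eg_trial; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break   # no descent direction at this resolution
    steps <- it
    trace <- c(trace, eg$energy)
  }
  structure(list(coords = coords, energy_trace = trace,
                 converged = converged, steps_taken = steps),
            class = "RelaxResult")
}

# adapter registry (package-local environment)
.adapters <- new.env(parent = emptyenv())

#' Register an external relaxation adapter
#'
#' The adapter contract: a function \code{f(coords, structure, config)}
#' returning \code{list(coords = <N x 3 matrix, same atom count and order>,
#' energy = <finite number>)}.  The pipeline treats adapter results exactly
#' like the built-in backend's.  A molecular-dynamics engine (e.g. an
#' implicit-solvent short-MD protocol) plugs in here; the shipped
#' \code{"mock"} adapter returns its input unchanged with energy 0 and is
#' used in pipeline tests.
#'
#' @param name adapter name referenced by
#'   \code{relax_params(backend = "external",
#'   adapter_config = list(name = ...))}.
#' @param fun the adapter function.
#' @return invisibly, \code{name}.
#' @export
register_relax_adapter <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .adapters)
  invisible(name)
}

#' Relax a conformer through a registered external adapter
#'
#' @param conformer_coords N x 3 matrix.
#' @param structure the topology \code{Structure}.
#' @param adapter_config list with at least \code{name}; the rest is passed
#'   to the adapter untouched.
#' @param context optional text (e.g. generation/conformer) used in error
#'   messages.
#' @return a \code{RelaxResult} (energy trace of length 1, converged TRUE).
#' @export
relax_external <- function(conformer_coords, structure, adapter_config,
                           context = NULL) {
  name <- adapter_config$name
  if (is.null(name) || !exists(name, envir = .adapters, inherits = FALSE))
    stop("no relaxation adapter ",
         if (!is.null(name)) paste0("'", name, "' "), "is registered; ",
         "register one with register_relax_adapter(name, fun) and set ",
         "relax_params(backend = 'external', adapter_config = ",
         "list(name = name))", call. = FALSE)
  fun <- get(name, envir = .adapters)
  coords <- as.matrix(conformer_coords)
  res <- tryCatch(fun(coords, structure, adapter_config),
                  error = function(e)
                    stop("relaxation adapter '", name, "' failed",
                         if (!is.null(context)) paste0(" (", context, ")"),
                         ": ", conditionMessage(e), call. = FALSE))
  if (!is.list(res) || is.null(res$coords) || is.null(res$energy))
    stop("adapter '", name, "' must return list(coords, energy)",
         call. = FALSE)
  out <- as.matrix(res$coords)
  if (!all(dim(out) == dim(coords)))
    stop("adapter '", name, "' returned ", nrow(out),
         " atoms; expected ", nrow(coords), call. = FALSE)
  if (!is.finite(res$energy))
    stop("adapter '", name, "' returned a non-finite energy", call. = FALSE)
  structure(list(coords = out, energy_trace = res$energy,
                 converged = TRUE, steps_taken = 0L),
            class = "RelaxResult")
}

# the shipped mock adapter: identity relaxation for pipeline tests
.onLoad <- function(libname, pkgname) {
  register_relax_adapter("mock", function(coords, structure, config)
    list(coords = coords, energy = 0))
}
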