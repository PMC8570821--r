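#' Pipeline configuration
#'
#' Bundles every tunable of the iterative sample / cluster / relax loop.
#'
#' @param n_gens number of generations (>= 1); each generation deforms the
#'   previous one's representatives, so excursions from the input grow with
#'   \code{n_gens}.
#' @param sampling a \code{SamplingParams} (conformers per parent,
#'   deformation RMSD).
#' @param anm an \code{AnmParams} (cutoff, spring constant, mode count).
#' @param cluster a \code{ClusterParams}; with the default
#'   \code{maxclust = 60} a 5-generation run emits 300 conformers.
#' @param relax a \code{RelaxParams} (backend choice and minimizer knobs).
#' @param recompute_modes_each_generation if TRUE (default) the ANM is
#'   rebuilt on every parent so each conformer deforms along its own current
#'   modes; if FALSE the input structure's modes are reused throughout.
#' @param output_dir directory for PDB/DCD output, the run record and
#'   per-generation checkpoints; NULL keeps everything in memory.
#' @param output_formats subset of \code{c("pdb", "dcd")}.
#' @param master_seed integer; all randomness derives from it, so equal
#'   seeds give bit-identical runs.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipeline_config <- function(n_gens = 5L, sampling = sampling_params(),
                            anm = anm_params(), cluster = cluster_params(),
                            relax = relax_params(),
                            recompute_modes_each_generation = TRUE,
                            output_dir = NULL,
                            output_formats = "pdb",
                            master_seed = 1L) {
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 1L) stop("n_gens must be >= 1", call. = FALSE)
  stopifnot(inherits(sampling, "SamplingParams"), inherits(anm, "AnmParams"),
            inherits(cluster, "ClusterParams"), inherits(relax, "RelaxParams"))
  output_formats <- match.arg(output_formats, c("pdb", "dcd"),
                              several.ok = TRUE)
  if (!length(output_formats))
    stop("output_formats must name at least one of 'pdb', 'dcd'",
         call. = FALSE)
  structure(list(n_gens = n_gens, sampling = sampling, anm = anm,
                 cluster = cluster, relax = relax,
                 recompute_modes_each_generation =
                   isTRUE(recompute_modes_each_generation),
                 output_dir = output_dir,
                 output_formats = output_formats,
                 master_seed = as.integer(master_seed)),
            class = "PipelineConfig")
}

# counter-based per-(generation, parent) seed so results are independent of
# parent processing order; all intermediates stay exact in doubles and the
# result stays below 2^31
derive_seed <- function(master_seed, generation, parent_ordinal) {
  ((abs(as.numeric(master_seed)) %% 30269) * 65537 +
     generation * 10007 + parent_ordinal * 101) %% 2147483646 + 1
}

relax_dispatch <- function(coords, structure, bonds, params, heavy, context) {
  if (params$backend == "builtin")
    relax(coords, bonds, params, heavy = heavy)
  else
    relax_external(coords, structure, params$adapter_config, context)
}

# config snapshot used for record files and resume compatibility checks
config_snapshot <- function(config) {
  list(n_gens = config$n_gens,
       sampling = unclass(config$sampling),
       anm = unclass(config$anm),
       cluster = unclass(config$cluster),
       relax = unclass(config$relax[setdiff(names(config$relax),
                                            "adapter_config")]),
       recompute_modes_each_generation =
         config$recompute_modes_each_generation,
       output_formats = config$output_formats,
       master_seed = config$master_seed)
}

#' Run the iterative conformer-generation pipeline
#'
#' Starting from one relaxed input structure, each generation (1) deforms
#' every parent along random combinations of its softest ANM modes to an
#' exact C-alpha RMSD step, (2) pools the generation's conformers, clusters
#' them by pairwise superposed C-alpha RMSD and selects medoid
#' representatives, (3) relaxes the representatives, which become the next
#' generation's parents.  The returned ensemble concatenates all
#' generations' relaxed representatives with full lineage.
#'
#' @param structure input \code{Structure} (all heavy atoms expected for
#'   atomistic systems; coarse-grained traces are supported and flagged).
#' @param config a \code{PipelineConfig}.
#' @param quiet suppress per-stage progress lines.
#' @return list with \code{ensemble} (an \code{Ensemble}) and \code{record}
#'   (a \code{RunRecord} list: per-generation counts, lineage, config
#'   snapshot, seed, timestamps).
#' @export
run_pipeline <- function(structure, config = pipeline_config(),
                         quiet = FALSE) {
  validate_structure(structure)
  stopifnot(inherits(config, "PipelineConfig"))
  state <- pipeline_init(structure, config, quiet)
  pipeline_generations(structure, config, state,
                       from_gen = 1L, quiet = quiet)
}

# generation-0 setup: bond list, node mask, initial relaxation
pipeline_init <- function(structure, config, quiet = FALSE) {
  ca_mask <- node_mask(structure, "auto")
  mask_indices(ca_mask, "node selection")
  bonds <- build_bond_list(structure, config$relax)
  heavy <- heavy_mask(structure)
  t0 <- Sys.time()
  r0 <- relax_dispatch(structure$coords, structure, bonds, config$relax,
                       heavy, "generation 0 (input)")
  if (!quiet)
    message(sprintf("[gen 0] relaxed input: %d steps, final energy %.4g",
                    r0$steps_taken, utils::tail(r0$energy_trace, 1)))
  list(ca_mask = ca_mask, bonds = bonds, heavy = heavy,
       parents = list(r0$coords),
       parent_global = -1L,        # lineage ids of current parents
       ens = NULL,
       gen_rows = list(),
       started = format(t0, "%Y-%m-%d %H:%M:%OS3"),
       base_modes = NULL)
}

pipeline_generations <- function(structure, config, state, from_gen,
                                 quiet = FALSE) {
  N <- n_atoms(structure)
  ca_mask <- state$ca_mask
  for (g in seq(from_gen, config$n_gens)) {
    stage <- function(what) sprintf("generation %d, %s", g, what)
    n_par <- length(state$parents)
    pool <- array(0, c(n_par * config$sampling$n_confs, N, 3L))
    pool_parent <- integer(0)
    tryCatch({
      for (p in seq_len(n_par)) {
        modes <- if (config$recompute_modes_each_generation) {
          anm_modes(set_coords(structure, state$parents[[p]]), config$anm)
        } else {
          if (is.null(state$base_modes))
            state$base_modes <- anm_modes(structure, config$anm)
          state$base_modes
        }
        e <- generate_conformers(state$parents[[p]], modes, ca_mask,
                                 config$sampling,
                                 seed = derive_seed(config$master_seed, g, p))
        rows <- (p - 1L) * config$sampling$n_confs +
          seq_len(config$sampling$n_confs)
        pool[rows, , ] <- e$coords
        pool_parent <- c(pool_parent,
                         rep(p, config$sampling$n_confs))
      }
    }, error = function(e)
      stop(stage("sampling"), ": ", conditionMessage(e), call. = FALSE))
    pool_ens <- ensemble(pool, generation = rep(g, nrow(pool)),
                         parent = pool_parent)
    cr <- tryCatch({
      D <- pairwise_rmsd(pool_ens, ca_mask)
      representatives(D, cluster_conformers(D, config$cluster))
    }, error = function(e)
      stop(stage("clustering"), ": ", conditionMessage(e), call. = FALSE))
    reps <- cr$representatives
    new_parents <- vector("list", length(reps))
    for (k in seq_along(reps)) {
      rr <- tryCatch(
        relax_dispatch(pool[reps[k], , , drop = TRUE], structure,
                       state$bonds, config$relax, state$heavy,
                       stage(sprintf("representative %d", k))),
        error = function(e)
          stop(stage(sprintf("relaxation of representative %d", k)), ": ",
               conditionMessage(e), call. = FALSE))
      new_parents[[k]] <- rr$coords
    }
    rep_coords <- array(0, c(length(reps), N, 3L))
    for (k in seq_along(reps)) rep_coords[k, , ] <- new_parents[[k]]
    # lineage: ordinal of the parent among the previous generation's
    # representatives; -1 marks the input structure (generation 1)
    gen_ens <- ensemble(rep_coords,
                        generation = rep(g, length(reps)),
                        parent = if (g == 1L) rep(-1L, length(reps)) else
                          pool_parent[reps])
    state$ens <- if (is.null(state$ens)) gen_ens else
      bind_ensembles(state$ens, gen_ens)
    state$gen_rows[[g]] <- data.frame(
      generation = g, parents = n_par,
      conformers = nrow(pool), clusters = max(cr$labels),
      representatives = length(reps))
    state$parents <- new_parents
    if (!quiet)
      message(sprintf(
        "[gen %d] %d parent(s) -> %d conformers -> %d representative(s)",
        g, n_par, nrow(pool), length(reps)))
    pipeline_checkpoint(structure, config, state, g)
  }
  record <- pipeline_record(config, state, complete = TRUE)
  pipeline_write_outputs(structure, config, state$ens, record)
  list(ensemble = state$ens, record = record)
}

pipeline_record <- function(config, state, complete) {
  gens <- do.call(rbind, state$gen_rows)
  structure(list(
    config = config_snapshot(config),
    master_seed = config$master_seed,
    started = state$started,
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
    complete = complete,
    generations = gens,
    lineage = data.frame(index = seq_len(n_conformers(state$ens)),
                         generation = state$ens$generation,
                         parent = state$ens$parent)),
    class = "RunRecord")
}

#' @export
print.RunRecord <- function(x, ...) {
  cat(sprintf("RunRecord: %d generation(s), %d conformers, seed %d%s\n",
              nrow(x$generations), nrow(x$lineage), x$master_seed,
              if (x$complete) "" else " [INCOMPLETE]"))
  print(x$generations, row.names = FALSE)
  invisible(x)
}

pipeline_checkpoint <- function(structure, config, state, completed_gen) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(list(snapshot = config_snapshot(config),
               completed_gen = completed_gen,
               state = state[c("ca_mask", "bonds", "heavy", "parents",
                               "ens", "gen_rows", "started")]),
          file.path(dir, "checkpoint.rds"))
  if (completed_gen < config$n_gens)
    writeLines(sprintf("run incomplete: last completed generation %d of %d",
                       completed_gen, config$n_gens),
               file.path(dir, "INCOMPLETE"))
  invisible(NULL)
}

pipeline_write_outputs <- function(structure, config, ens, record) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if ("pdb" %in% config$output_formats)
    write_pdb(structure, file.path(dir, "conformers.pdb"), ens)
  if ("dcd" %in% config$output_formats)
    write_dcd(ens, file.path(dir, "conformers.dcd"))
  rec <- record
  rec$generations <- as.list(as.data.frame(rec$generations))
  rec$lineage <- as.list(rec$lineage)
  jsonlite::write_json(unclass(rec), file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  marker <- file.path(dir, "INCOMPLETE")
  if (record$complete && file.exists(marker)) unlink(marker)
  invisible(NULL)
}

#' Resume an interrupted pipeline run
#'
#' Continues from the last completed generation recorded in the output
#' directory's checkpoint, using the stored configuration and seed
#' derivation, so the final result is identical to an uninterrupted run.
#'
#' @param structure the same input \code{Structure} the run started from.
#' @param output_dir the interrupted run's output directory.
#' @param config optional \code{PipelineConfig}; when given it must match
#'   the stored snapshot (a mismatch is refused with a field-level diff).
#' @param quiet suppress progress lines.
#' @return as [run_pipeline()].
#' @export
resume_pipeline <- function(structure, output_dir, config = NULL,
                            quiet = FALSE) {
  ck_path <- file.path(output_dir, "checkpoint.rds")
  if (!file.exists(ck_path))
    stop("no checkpoint found in ", output_dir, call. = FALSE)
  ck <- readRDS(ck_path)
  if (!is.null(config)) {
    stopifnot(inherits(config, "PipelineConfig"))
    want <- jsonlite::toJSON(config_snapshot(config), auto_unbox = TRUE)
    have <- jsonlite::toJSON(ck$snapshot, auto_unbox = TRUE)
    if (!identical(as.character(want), as.character(have))) {
      diffs <- config_diff(config_snapshot(config), ck$snapshot)
      stop("configuration does not match the stored run snapshot; ",
           "differing field(s): ", paste(diffs, collapse = ", "),
           call. = FALSE)
    }
    cfg <- config
  } else {
    cfg <- snapshot_to_config(ck$snapshot)
  }
  cfg$output_dir <- output_dir
  state <- ck$state
  state$base_modes <- NULL
  state$parent_global <- -1L
  if (ck$completed_gen >= cfg$n_gens) {
    record <- pipeline_record(cfg, state, complete = TRUE)
    return(list(ensemble = state$ens, record = record))
  }
  pipeline_generations(structure, cfg, state,
                       from_gen = ck$completed_gen + 1L, quiet = quiet)
}

config_diff <- function(a, b, prefix = "") {
  out <- character(0)
  for (nm in union(names(a), names(b))) {
    av <- a[[nm]]; bv <- b[[nm]]
    if (is.list(av) && is.list(bv)) {
      out <- c(out, config_diff(av, bv, paste0(prefix, nm, ".")))
    } else if (!identical(av, bv)) {
      out <- c(out, sprintf("%s%s (%s vs %s)", prefix, nm,
                            paste(format(av), collapse = ","),
                            paste(format(bv), collapse = ",")))
    }
  }
  out
}

snapshot_to_config <- function(s) {
  pipeline_config(
    n_gens = s$n_gens,
    sampling = do.call(sampling_params, s$sampling),
    anm = do.call(anm_params, s$anm),
    cluster = do.call(cluster_params, s$cluster),
    relax = do.call(relax_params, s$relax),
    recompute_modes_each_generation = s$recompute_modes_each_generation,
    output_formats = unlist(s$output_formats),
    master_seed = s$master_seed)
}

#' Read a pipeline configuration from a flat key/value YAML file
#'
#' Recognised keys (all optional): \code{n_gens}, \code{n_confs},
#' \code{target_rmsd}, \code{n_modes}, \code{cutoff}, \code{gamma},
#' \code{maxclust}, \code{cluster_mode}, \code{threshold}, \code{linkage},
#' \code{backend}, \code{recompute_modes_each_generation},
#' \code{output_dir}, \code{output_formats} (comma-separated or list),
#' \code{master_seed}.
#'
#' @param path YAML file.
#' @param overrides named list taking precedence over file values (the CLI
#'   passes its flags here).
#' @return a \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  get1 <- function(key, default) if (is.null(vals[[key]])) default else
    vals[[key]]
  fmts <- get1("output_formats", "pdb")
  if (is.character(fmts) && length(fmts) == 1L)
    fmts <- strsplit(fmts, ",")[[1]]
  pipeline_config(
    n_gens = get1("n_gens", 5L),
    sampling = sampling_params(n_confs = get1("n_confs", 50L),
                               target_rmsd = get1("target_rmsd", 1.0)),
    anm = anm_params(cutoff = get1("cutoff", 15),
                     gamma = get1("gamma", 1),
                     n_modes = get1("n_modes", 3L)),
    cluster = cluster_params(mode = get1("cluster_mode", "maxclust"),
                             maxclust = get1("maxclust", 60L),
                             threshold = get1("threshold", NULL),
                             linkage = get1("linkage", "average")),
    relax = relax_params(backend = get1("backend", "builtin")),
    recompute_modes_each_generation =
      get1("recompute_modes_each_generation", TRUE),
    output_dir = get1("output_dir", NULL),
    output_formats = trimws(fmts),
    master_seed = get1("master_seed", 1L))
}
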