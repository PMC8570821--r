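#' Select atoms of a Structure by a small expression grammar
#'
#' Supported forms, combinable with \code{and}:
#' \itemize{
#'   \item \code{"calpha"} -- atoms named \code{CA};
#'   \item \code{"chain A"} -- atoms of one chain;
#'   \item \code{"resid 5-20"} (or a single number \code{"resid 7"}) --
#'     residue index range, inclusive, author numbering;
#'   \item \code{"name CB"} -- atoms with a given name.
#' }
#' \code{"and"} clauses intersect and may appear in any order.
#'
#' @param structure a \code{Structure}.
#' @param expression selection text, e.g. \code{"chain A and resid 1-10"}.
#' @return logical vector of length \code{n_atoms(structure)} (a selection
#'   mask).  May be all-\code{FALSE}; operations consuming a mask reject empty
#'   selections themselves.
#' @export
#' @examples
#' s <- make_toy(toy_spec(n_residues = 8))
#' sum(select_atoms(s, "calpha"))        # 8
#' sum(select_atoms(s, "calpha and resid 1-4"))
select_atoms <- function(structure, expression) {
  stopifnot(inherits(structure, "Structure"))
  if (!is.character(expression) || length(expression) != 1L || is.na(expression))
    stop("selection expression must be a single string", call. = FALSE)
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  clauses <- trimws(clauses)
  clauses <- clauses[nzchar(clauses)]
  if (!length(clauses))
    stop(selection_grammar_msg(expression), call. = FALSE)
  at <- structure$atoms
  mask <- rep(TRUE, nrow(at))
  for (cl in clauses) {
    toks <- strsplit(cl, "\\s+")[[1]]
    kw <- toks[1]
    m <- switch(kw,
      calpha = {
        if (length(toks) != 1L) stop(selection_grammar_msg(cl), call. = FALSE)
        at$atom_name == "CA"
      },
      chain = {
        if (length(toks) != 2L) stop(selection_grammar_msg(cl), call. = FALSE)
        at$chain_id == toks[2]
      },
      name = {
        if (length(toks) != 2L) stop(selection_grammar_msg(cl), call. = FALSE)
        at$atom_name == toks[2]
      },
      resid = {
        if (length(toks) != 2L) stop(selection_grammar_msg(cl), call. = FALSE)
        rng <- parse_resid_range(toks[2], cl)
        at$residue_index >= rng[1] & at$residue_index <= rng[2]
      },
      stop(selection_grammar_msg(cl), call. = FALSE))
    mask <- mask & m
  }
  mask
}

parse_resid_range <- function(tok, clause) {
  if (grepl("^-?[0-9]+--?[0-9]+$", tok)) {
    # split on the dash separating the two bounds (first dash after a digit)
    parts <- regmatches(tok, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tok))[[1]]
    rng <- as.integer(parts[2:3])
  } else if (grepl("^-?[0-9]+$", tok)) {
    rng <- rep(as.integer(tok), 2L)
  } else {
    stop(selection_grammar_msg(clause), call. = FALSE)
  }
  if (rng[1] > rng[2]) rng <- rev(rng)
  rng
}

selection_grammar_msg <- function(bad) {
  paste0("unsupported selection expression: '", bad, "'. Supported grammar: ",
         "'calpha', 'chain <id>', 'resid <a>-<b>', 'name <atomname>', ",
         "joined by 'and'.")
}

# internal: mask -> indices with empty-selection guard, naming the caller's use
mask_indices <- function(mask, what = "selection") {
  idx <- which(mask)
  if (!length(idx))
    stop("empty ", what, ": no atoms selected", call. = FALSE)
  idx
}
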