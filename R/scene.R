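# Selections and scene assembly.

#' Selection expressions
#'
#' Constructors for the three selection kinds: everything, an explicit
#' residue list, or a distance zone around a reference entity. The zone
#' semantics follow common molecular-viewer practice: a polymer residue is
#' selected when any of its heavy atoms lies within `cutoff` Angstrom
#' (inclusive) of any reference atom; the reference residues themselves are
#' excluded.
#'
#' @param keys Character vector of residue keys (see [residue_key()]) or a
#'   list of `residue_record`s.
#' @param reference Reference selector for zones: a residue name (e.g. a
#'   ligand code like `"LIG"`), a `"chain:resi"` string, or an integer
#'   vector of atom serial numbers.
#' @param cutoff Zone radius in Angstrom (> 0).
#' @param frozen For trajectories: evaluate the zone on the first frame only
#'   and reuse that residue list for every frame.
#' @return A `selection_expr`.
#' @export
sel_all <- function() {
  structure(list(kind = "ALL"), class = "selection_expr")
}

#' @rdname sel_all
#' @export
sel_residues <- function(keys) {
  if (is.list(keys))
    keys <- vapply(keys, residue_key, character(1))
  structure(list(kind = "RESIDUE_LIST", residue_keys = keys),
            class = "selection_expr")
}

#' @rdname sel_all
#' @param chain_id Chain identifier.
#' @export
sel_chain <- function(chain_id) {
  structure(list(kind = "CHAIN", chain_id = chain_id),
            class = "selection_expr")
}

#' @rdname sel_all
#' @export
sel_zone <- function(reference, cutoff, frozen = FALSE) {
  stopifnot(is.finite(cutoff), cutoff > 0)
  structure(list(kind = "ZONE", reference = reference, cutoff = cutoff,
                 frozen = isTRUE(frozen)), class = "selection_expr")
}

#' Parse the selection mini-language
#'
#' Grammar: `"all"`; `"chain:A"`; `"resi:A:26+28"` (chain then `+`-separated
#' residue numbers, insertion codes appended to the number); and
#' `"zone:<resname|chain:resi|serial:1+2>:<cutoff>"`.
#'
#' @param text Selection string.
#' @return A `selection_expr`.
#' @export
parse_selection <- function(text) {
  text <- trimws(text)
  if (tolower(text) == "all") return(sel_all())
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  head <- tolower(parts[1])
  if (head == "chain" && length(parts) == 2) return(sel_chain(parts[2]))
  if (head == "resi" && length(parts) == 3) {
    nums <- strsplit(parts[3], "+", fixed = TRUE)[[1]]
    return(structure(list(kind = "RESI", chain_id = parts[2],
                          resi = nums), class = "selection_expr"))
  }
  if (head == "zone" && length(parts) >= 3) {
    cutoff <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (!is.finite(cutoff) || cutoff <= 0)
      stop("bad zone cutoff in selection: ", text)
    ref <- paste(parts[-c(1, length(parts))], collapse = ":")
    if (grepl("^serial:", ref)) {
      serials <- as.integer(strsplit(sub("^serial:", "", ref), "+",
                                     fixed = TRUE)[[1]])
      return(sel_zone(serials, cutoff))
    }
    return(sel_zone(ref, cutoff))
  }
  stop("cannot parse selection expression: ", text)
}

# Resolve a zone reference to its atoms (data.frame) and the keys of the
# residues it covers (excluded from the zone).
resolve_zone_reference <- function(model, reference) {
  pick <- if (is.numeric(reference)) {
    function(r) r$atoms$serial %in% reference
  } else if (grepl(":", reference)) {
    bits <- strsplit(reference, ":", fixed = TRUE)[[1]]
    function(r) if (r$chain_id == bits[1] &
                    paste0(r$seq_number, r$insertion_code) == bits[2])
      rep(TRUE, nrow(r$atoms)) else rep(FALSE, nrow(r$atoms))
  } else {
    function(r) if (r$name3 == toupper(reference))
      rep(TRUE, nrow(r$atoms)) else rep(FALSE, nrow(r$atoms))
  }
  atoms <- list()
  keys <- character()
  for (r in model$residues) {
    sel <- pick(r)
    if (any(sel)) {
      a <- r$atoms[sel, , drop = FALSE]
      a <- a[!is_hydrogen_atom(a$name, a$element), , drop = FALSE]
      if (nrow(a)) atoms[[length(atoms) + 1L]] <- a
      keys <- c(keys, residue_key(r))
    }
  }
  if (!length(atoms))
    stop("zone reference matches no atoms: ",
         paste(reference, collapse = ","))
  list(atoms = do.call(rbind, atoms), keys = keys)
}

#' Residues within a distance zone of reference atoms
#'
#' A polymer residue is selected iff any of its heavy atoms is within
#' `cutoff` (Euclidean, boundary inclusive) of any reference atom.
#'
#' @param model A `molecular_model`.
#' @param reference_atoms Data frame of atoms (columns `x`, `y`, `z`) around
#'   which the zone is taken.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param exclude_keys Residue keys never selected (typically the reference
#'   residues themselves).
#' @return Character vector of residue keys, in model order.
#' @export
zone_selection <- function(model, reference_atoms, cutoff,
                           exclude_keys = character()) {
  stopifnot(is.finite(cutoff), cutoff > 0)
  if (is.null(reference_atoms) || nrow(reference_atoms) == 0)
    stop("zone_selection: empty reference")
  ref <- cbind(reference_atoms$x, reference_atoms$y, reference_atoms$z)
  out <- character()
  for (r in polymer_residues(model)) {
    key <- residue_key(r)
    if (key %in% exclude_keys) next
    a <- heavy_atoms(r)
    if (nrow(a) == 0) next
    pts <- cbind(a$x, a$y, a$z)
    d2 <- outer(rowSums(pts^2), rep(1, nrow(ref))) +
      outer(rep(1, nrow(pts)), rowSums(ref^2)) - 2 * pts %*% t(ref)
    if (min(d2) <= cutoff^2 + 1e-9) out <- c(out, key)
  }
  out
}

selected_residues <- function(model, selection) {
  polys <- polymer_residues(model)
  keys <- vapply(polys, residue_key, character(1))
  keep <- switch(selection$kind,
    ALL = rep(TRUE, length(polys)),
    RESIDUE_LIST = keys %in% selection$residue_keys,
    CHAIN = vapply(polys, function(r)
      r$chain_id == selection$chain_id, logical(1)),
    RESI = vapply(polys, function(r)
      r$chain_id == selection$chain_id &&
        paste0(r$seq_number, r$insertion_code) %in% selection$resi,
      logical(1)),
    ZONE = {
      ref <- resolve_zone_reference(model, selection$reference)
      keys %in% zone_selection(model, ref$atoms, selection$cutoff,
                               exclude_keys = ref$keys)
    },
    stop("unknown selection kind: ", selection$kind))
  polys[keep]
}

selection_label <- function(selection) {
  switch(selection$kind,
         ALL = "all",
         RESIDUE_LIST = sprintf("resi[%d]", length(selection$residue_keys)),
         CHAIN = paste0("chain:", selection$chain_id),
         RESI = paste0("resi:", selection$chain_id, ":",
                       paste(selection$resi, collapse = "+")),
         ZONE = sprintf("zone:%s:%g",
                        paste(selection$reference, collapse = "+"),
                        selection$cutoff))
}

new_glyph_scene <- function(glyphs, source_label, model_index,
                            selection_label, global_alpha = NULL) {
  structure(list(glyphs = glyphs, source_label = source_label,
                 model_index = as.integer(model_index),
                 selection_label = selection_label,
                 global_alpha = global_alpha), class = "glyph_scene")
}

#' @export
print.glyph_scene <- function(x, ...) {
  nd <- sum(vapply(x$glyphs, `[[`, logical(1), "degraded"))
  cat(sprintf("<glyph_scene> %s model %d, selection '%s': %d glyph(s)%s\n",
              x$source_label, x$model_index, x$selection_label,
              length(x$glyphs),
              if (nd) sprintf(" (%d degraded)", nd) else ""))
  invisible(x)
}

#' @export
summary.glyph_scene <- function(object, ...) {
  shapes <- vapply(object$glyphs, function(g) g$spec$shape, character(1))
  list(n_glyphs = length(object$glyphs),
       n_degraded = sum(vapply(object$glyphs, `[[`, logical(1),
                               "degraded")),
       shapes = if (length(shapes)) table(shapes) else table(character()))
}

#' Build a glyph scene from one model
#'
#' Every selected polymer residue is classified, matched against the
#' dictionary (resolving the histidine protonation state on the way) and
#' fitted with its glyph. Residues without a CA atom are skipped with a
#' warning; an empty selection yields an empty scene with a warning.
#'
#' @param model A `molecular_model`.
#' @param selection A `selection_expr` (default all residues).
#' @param options List; honoured elements: `transparency` (global alpha in
#'   `[0, 1]`), `his_overrides` (named list, residue key -> state),
#'   `dictionary`, `sizing`.
#' @return A `glyph_scene`.
#' @export
build_scene <- function(model, selection = sel_all(), options = list()) {
  stopifnot(inherits(model, "molecular_model"))
  dict <- options$dictionary %||% default_dictionary()
  residues <- selected_residues(model, selection)
  if (length(residues) == 0)
    warning("selection '", selection_label(selection),
            "' matches no polymer residues")
  glyphs <- list()
  for (r in residues) {
    his_state <- NULL
    if (toupper(r$name3) %in% HIS_VARIANTS) {
      his_state <- detect_histidine_state(
        r, override = options$his_overrides[[residue_key(r)]])
    }
    spec <- glyph_spec_for(r$name3, his_state, dictionary = dict)
    g <- build_glyph(r, spec, options)
    if (!is.null(g)) glyphs[[length(glyphs) + 1L]] <- g
  }
  new_glyph_scene(glyphs, "", model$model_index,
                  selection_label(selection),
                  global_alpha = options$transparency)
}

#' Build one scene per ensemble model
#'
#' Applies the same selection policy to every model of the ensemble. Zone
#' selections are re-evaluated on each frame by default (neighborhoods are
#' snapshot-specific along a trajectory); with `frozen = TRUE` on the zone
#' the frame-0 residue list is reused for all frames.
#'
#' @param ensemble A `structure_ensemble`.
#' @param selection A `selection_expr`.
#' @param options As for [build_scene()].
#' @return List of `glyph_scene`, one per model.
#' @export
build_trajectory_scenes <- function(ensemble, selection = sel_all(),
                                    options = list()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (identical(selection$kind, "ZONE") && isTRUE(selection$frozen)) {
    frozen_keys <- vapply(
      selected_residues(ensemble$models[[1]], selection),
      residue_key, character(1))
    selection <- sel_residues(frozen_keys)
  }
  lapply(ensemble$models, function(m) {
    sc <- build_scene(m, selection, options)
    sc$source_label <- ensemble$source_label
    sc
  })
}
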