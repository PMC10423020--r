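# PDB parsing into an internal ensemble model. bio3d does the fixed-width
# record parsing; this module owns MODEL-block splitting, altloc resolution,
# polymer flagging and the deterministic residue order.

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

# HETATM residues with these codes are still treated as polymer (modified
# amino acids); they classify as non-standard downstream.
MODIFIED_POLYMER_CODES <- c("MSE", "SEC", "PYL", "MLY", "PTR", "SEP", "TPO",
                            "CSO", "HYP")

new_residue_record <- function(chain_id, seq_number, insertion_code, name3,
                               is_polymer, atoms) {
  structure(list(chain_id = unname(chain_id),
                 seq_number = unname(as.integer(seq_number)),
                 insertion_code = unname(insertion_code),
                 name3 = unname(toupper(name3)),
                 is_polymer = isTRUE(is_polymer), atoms = atoms),
            class = "residue_record")
}

new_molecular_model <- function(residues, model_index = 0L) {
  structure(list(model_index = as.integer(model_index), residues = residues),
            class = "molecular_model")
}

new_structure_ensemble <- function(models, source_label = "") {
  stopifnot(length(models) >= 1)
  structure(list(source_label = source_label, models = models),
            class = "structure_ensemble")
}

#' @export
print.molecular_model <- function(x, ...) {
  np <- sum(vapply(x$residues, `[[`, logical(1), "is_polymer"))
  cat(sprintf("<molecular_model> #%d: %d residues (%d polymer)\n",
              x$model_index, length(x$residues), np))
  invisible(x)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> '%s': %d model(s), %d residues\n",
              x$source_label, length(x$models),
              length(x$models[[1]]$residues)))
  invisible(x)
}

#' Key identifying a residue within a model
#'
#' @param residue A `residue_record`.
#' @return Single string `"<chain>|<seqnum><icode>|<name3>"`.
#' @export
residue_key <- function(residue) {
  paste(residue$chain_id,
        paste0(residue$seq_number, residue$insertion_code),
        residue$name3, sep = "|")
}

model_residue_keys <- function(model) {
  vapply(model$residues, residue_key, character(1))
}

# Sort order: chain, then sequence number, then insertion code (blank first).
residue_order <- function(chain, seqno, icode) {
  order(chain, seqno, icode, method = "radix")
}

atom_positions <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  rownames(m) <- atoms$name
  m
}

#' Read a PDB file into a structure ensemble
#'
#' Parses ATOM/HETATM records into an ordered ensemble of models (one per
#' MODEL block; a single implicit model when none are present). Hydrogens
#' are retained (they drive histidine protonation detection) but are
#' excluded from all geometric fits downstream. Waters and other
#' non-polymer HETATM residues are flagged so glyph building skips them.
#' Alternate locations are resolved by keeping, for each atom name, the
#' location with the highest occupancy (ties go to the alphabetically
#' smallest altloc letter).
#'
#' @param path Path to a PDB file.
#' @param resolve_altlocs Resolve alternate locations (default `TRUE`).
#' @param source_label Label stored on the ensemble; defaults to the file
#'   name.
#' @return A `structure_ensemble`.
#' @export
read_structure <- function(path, resolve_altlocs = TRUE,
                           source_label = basename(path)) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  if (!any(rec %in% c("ATOM  ", "HETATM") | substr(rec, 1, 5) == "MODEL"))
    stop("no ATOM/HETATM records in ", path)

  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  blocks <- if (length(model_starts) == 0) {
    list(lines)
  } else {
    ends <- which(substr(lines, 1, 6) == "ENDMDL")
    lapply(seq_along(model_starts), function(i) {
      from <- model_starts[i] + 1L
      to <- ends[ends > model_starts[i]][1]
      if (is.na(to)) to <- length(lines) + 1L
      lines[seq(from, to - 1L)]
    })
  }

  models <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    models[[i]] <- parse_model_block(blocks[[i]], i - 1L, path,
                                     resolve_altlocs)
  }
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("no parseable coordinates in ", path)

  keys <- lapply(models, model_residue_keys)
  common <- Reduce(intersect, keys)
  if (!all(vapply(keys, function(k) identical(k, keys[[1]]), logical(1)))) {
    warning("models differ in residue content; intersecting to ",
            length(common), " shared residues")
    models <- lapply(models, function(m) {
      m$residues <- m$residues[model_residue_keys(m) %in% common]
      m
    })
  }
  models <- lapply(seq_along(models), function(i) {
    models[[i]]$model_index <- i - 1L
    models[[i]]
  })
  new_structure_ensemble(models, source_label)
}

parse_model_block <- function(block, model_index, path, resolve) {
  keep <- substr(block, 1, 6) %in% c("ATOM  ", "HETATM") |
    substr(block, 1, 3) == "TER"
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(block[keep], "END"), tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, rm.insert = FALSE,
                                     verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(pdb)) return(NULL)
  at <- pdb$atom

  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (all(bad)) stop("all coordinate records malformed in ", path)
  if (any(bad)) {
    warning("skipping ", sum(bad), " atom record(s) with malformed ",
            "coordinates in ", path)
    at <- at[!bad, , drop = FALSE]
  }
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  at$o[is.na(at$o)] <- 1
  if (any(at$o < 0 | at$o > 1)) {
    warning("clamping out-of-range occupancies to [0, 1]")
    at$o <- pmin(pmax(at$o, 0), 1)
  }

  rid <- paste(at$chain, at$resno, at$insert, sep = "\r")
  groups <- split(seq_len(nrow(at)), factor(rid, levels = unique(rid)))
  residues <- lapply(groups, function(idx) {
    a <- at[idx, , drop = FALSE]
    name3 <- toupper(a$resid[1])
    het <- all(a$type == "HETATM")
    polymer <- !het ||
      (name3 %in% c(standard_residues(), HIS_VARIANTS,
                    MODIFIED_POLYMER_CODES) && !name3 %in% WATER_CODES)
    if (name3 %in% WATER_CODES) polymer <- FALSE
    atoms <- data.frame(serial = a$eleno, name = trimws(a$elety),
                        element = trimws(a$elesy), x = a$x, y = a$y, z = a$z,
                        altloc = a$alt, occupancy = a$o,
                        stringsAsFactors = FALSE)
    res <- new_residue_record(a$chain[1], a$resno[1], a$insert[1], name3,
                              polymer, atoms)
    if (resolve) res <- resolve_altlocs(res)
    res
  })
  ord <- residue_order(vapply(residues, `[[`, character(1), "chain_id"),
                       vapply(residues, `[[`, integer(1), "seq_number"),
                       vapply(residues, `[[`, character(1),
                              "insertion_code"))
  new_molecular_model(unname(residues[ord]), model_index)
}

#' Resolve alternate locations within a residue
#'
#' For each atom name, keeps the altloc with the highest occupancy; ties are
#' broken by the lexicographically smallest altloc character. Atom order is
#' preserved (first occurrence of each name). Never increases atom count.
#'
#' @param residue A `residue_record`.
#' @return The residue with one location per atom name.
#' @export
resolve_altlocs <- function(residue) {
  a <- residue$atoms
  if (nrow(a) <= 1 || !anyDuplicated(a$name)) return(residue)
  keep <- vapply(split(seq_len(nrow(a)), factor(a$name, unique(a$name))),
                 function(idx) {
                   sub <- a[idx, , drop = FALSE]
                   best <- order(-sub$occupancy, sub$altloc)[1]
                   idx[best]
                 }, integer(1))
  residue$atoms <- a[sort(keep), , drop = FALSE]
  rownames(residue$atoms) <- NULL
  residue
}

#' Polymer residues of a model, in deterministic order
#'
#' Filters the model's residue list down to polymer residues (amino acids,
#' including modified ones like MSE), excluding waters, ions and ligands.
#'
#' @param model A `molecular_model`.
#' @return List of `residue_record`.
#' @export
polymer_residues <- function(model) {
  Filter(function(r) r$is_polymer, model$residues)
}

#' Find a residue in a model by key components
#'
#' @param model A `molecular_model`.
#' @param chain_id,seq_number,insertion_code Key components.
#' @return The `residue_record`, or `NULL` when absent.
#' @export
find_residue <- function(model, chain_id, seq_number, insertion_code = "") {
  for (r in model$residues) {
    if (r$chain_id == chain_id && r$seq_number == seq_number &&
        r$insertion_code == insertion_code)
      return(r)
  }
  NULL
}
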