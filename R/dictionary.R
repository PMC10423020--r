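# The visual dictionary: residue family, glyph shape, colors and accents.

RESIDUE_CLASSES <- c("HYDROPHOBIC", "NEUTRAL_POLAR", "POSITIVE", "NEGATIVE",
                     "PROLINE", "NONSTANDARD")

SHAPE_KINDS <- c("SPHERE", "ELLIPSOID", "HEXAGONAL_PRISM", "PENTAGONAL_PRISM",
                 "PYRAMID", "TRIANGULAR_PRISM", "CUBOID", "CUBE", "STAR")

ACCENT_PARTS <- c("NONE", "TIP", "END_BAND", "BASE_FACE", "END_FACE",
                  "RING_SEGMENT")

HIS_STATES <- c("NEUTRAL", "PROTONATED", "DEPROTONATED")

#' Standard amino-acid three-letter codes
#'
#' The 20 standard residues, in the conventional alphabetical order of their
#' three-letter codes.
#'
#' @return Character vector of length 20.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Force-field naming variants of histidine; all draw the pentagonal prism.
HIS_VARIANTS <- c("HIS", "HID", "HIE", "HIP", "HSD", "HSE", "HSP")

#' Color palette of the glyph dictionary
#'
#' Fixed RGBA constants behind the color names used throughout the dictionary
#' (green for hydrophobic, dark blue for positive charge, red for negative
#' charge, aquamarine for neutral histidine, gray for neutral-polar bodies
#' and proline, orange for non-standard residues, yellow for sulfur accents).
#' Darker shades keep the hue and reduce the value.
#'
#' @return Named list of length-4 numeric vectors `(r, g, b, a)` in `[0, 1]`.
#' @export
glyph_palette <- function() {
  list(
    green       = c(0.00, 0.80, 0.00, 1.0),
    dark_blue   = c(0.00, 0.00, 0.55, 1.0),
    darker_blue = c(0.00, 0.00, 0.35, 1.0),
    red         = c(0.85, 0.00, 0.00, 1.0),
    darker_red  = c(0.55, 0.00, 0.00, 1.0),
    yellow      = c(1.00, 0.85, 0.00, 1.0),
    aquamarine  = c(0.30, 0.90, 0.75, 1.0),
    gray        = c(0.60, 0.60, 0.60, 1.0),
    orange      = c(1.00, 0.55, 0.00, 1.0)
  )
}

#' Classify a residue into one of the five physicochemical families
#'
#' Amino acids fall into five families: hydrophobic, neutral polar,
#' positively charged, negatively charged, and proline (which gets a family
#' of its own because its cyclic side chain fits none of the others).
#' Any code outside the standard set classifies as `NONSTANDARD`, except the
#' common force-field histidine variants (HID/HIE/HIP/HSD/HSE/HSP), which are
#' histidine and classify as neutral polar.
#'
#' @param name3 Three-letter residue code (case-insensitive, trimmed).
#' @return One of `"HYDROPHOBIC"`, `"NEUTRAL_POLAR"`, `"POSITIVE"`,
#'   `"NEGATIVE"`, `"PROLINE"`, `"NONSTANDARD"`.
#' @export
classify_residue <- function(name3) {
  code <- toupper(trimws(name3))
  vapply(code, function(x) {
    if (x %in% c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP"))
      return("HYDROPHOBIC")
    if (x %in% c("SER", "THR", "CYS", "ASN", "GLN", "TYR") ||
        x %in% HIS_VARIANTS)
      return("NEUTRAL_POLAR")
    if (x %in% c("LYS", "ARG")) return("POSITIVE")
    if (x %in% c("ASP", "GLU")) return("NEGATIVE")
    if (x == "PRO") return("PROLINE")
    "NONSTANDARD"
  }, character(1), USE.NAMES = FALSE)
}

# One dictionary row. accent_color2 holds the second color of a split accent
# (the Asn/Gln base face is red on the oxygen side, dark blue on the
# nitrogen side); NULL elsewhere.
glyph_spec_row <- function(name3, residue_class, shape, base_color,
                           accent_color = NULL, accent_color2 = NULL,
                           accent_part = "NONE", sizing_rule) {
  stopifnot(shape %in% SHAPE_KINDS, accent_part %in% ACCENT_PARTS)
  if (is.null(accent_color) != (accent_part == "NONE"))
    stop("accent_part must be NONE exactly when accent_color is NULL")
  structure(list(name3 = name3, residue_class = residue_class, shape = shape,
                 base_color = base_color, accent_color = accent_color,
                 accent_color2 = accent_color2, accent_part = accent_part,
                 sizing_rule = sizing_rule),
            class = "glyph_spec")
}

#' @export
print.glyph_spec <- function(x, ...) {
  acc <- if (x$accent_part == "NONE") "" else
    sprintf(" + %s accent", x$accent_part)
  cat(sprintf("<glyph_spec> %s: %s %s%s\n", x$name3, x$residue_class,
              x$shape, acc))
  invisible(x)
}

#' The built-in glyph dictionary
#'
#' One entry per standard residue plus the `"*"` fallback row (orange star)
#' used for every non-standard residue. Shapes follow the side-chain
#' geometry: spheres for Gly/Ala, ellipsoids for the branched/linear
#' aliphatics, hexagonal prisms over the aromatic six-rings, a pentagonal
#' prism over the histidine imidazole, pyramids pointing at the hydroxyl or
#' thiol of Ser/Thr/Cys, triangular prisms over the amide and carboxylate
#' groups of Asn/Gln/Asp/Glu, cuboids along the Lys/Arg side chains, and a
#' small gray cube on the proline alpha carbon.
#'
#' @return Named list of `glyph_spec` rows keyed by residue code.
#' @export
default_dictionary <- function() {
  p <- glyph_palette()
  rows <- list(
    glyph_spec_row("GLY", "HYDROPHOBIC", "SPHERE", p$green,
                   sizing_rule = "sphere_gly"),
    glyph_spec_row("ALA", "HYDROPHOBIC", "SPHERE", p$green,
                   sizing_rule = "sphere_ala"),
    glyph_spec_row("VAL", "HYDROPHOBIC", "ELLIPSOID", p$green,
                   sizing_rule = "ellipsoid"),
    glyph_spec_row("LEU", "HYDROPHOBIC", "ELLIPSOID", p$green,
                   sizing_rule = "ellipsoid"),
    glyph_spec_row("ILE", "HYDROPHOBIC", "ELLIPSOID", p$green,
                   sizing_rule = "ellipsoid"),
    glyph_spec_row("MET", "HYDROPHOBIC", "ELLIPSOID", p$green,
                   accent_color = p$yellow, accent_part = "END_BAND",
                   sizing_rule = "ellipsoid"),
    glyph_spec_row("PHE", "HYDROPHOBIC", "HEXAGONAL_PRISM", p$green,
                   sizing_rule = "ring_prism"),
    glyph_spec_row("TRP", "HYDROPHOBIC", "HEXAGONAL_PRISM", p$green,
                   sizing_rule = "ring_prism"),
    glyph_spec_row("SER", "NEUTRAL_POLAR", "PYRAMID", p$gray,
                   accent_color = p$red, accent_part = "TIP",
                   sizing_rule = "pyramid"),
    glyph_spec_row("THR", "NEUTRAL_POLAR", "PYRAMID", p$gray,
                   accent_color = p$red, accent_part = "TIP",
                   sizing_rule = "pyramid"),
    glyph_spec_row("CYS", "NEUTRAL_POLAR", "PYRAMID", p$gray,
                   accent_color = p$yellow, accent_part = "TIP",
                   sizing_rule = "pyramid"),
    glyph_spec_row("ASN", "NEUTRAL_POLAR", "TRIANGULAR_PRISM", p$gray,
                   accent_color = p$red, accent_color2 = p$dark_blue,
                   accent_part = "BASE_FACE", sizing_rule = "tri_prism"),
    glyph_spec_row("GLN", "NEUTRAL_POLAR", "TRIANGULAR_PRISM", p$gray,
                   accent_color = p$red, accent_color2 = p$dark_blue,
                   accent_part = "BASE_FACE", sizing_rule = "tri_prism"),
    glyph_spec_row("TYR", "NEUTRAL_POLAR", "HEXAGONAL_PRISM", p$gray,
                   accent_color = p$red, accent_part = "RING_SEGMENT",
                   sizing_rule = "ring_prism"),
    glyph_spec_row("HIS", "NEUTRAL_POLAR", "PENTAGONAL_PRISM", p$aquamarine,
                   sizing_rule = "ring_prism"),
    glyph_spec_row("LYS", "POSITIVE", "CUBOID", p$dark_blue,
                   accent_color = p$darker_blue, accent_part = "END_FACE",
                   sizing_rule = "cuboid"),
    glyph_spec_row("ARG", "POSITIVE", "CUBOID", p$dark_blue,
                   accent_color = p$darker_blue, accent_part = "END_FACE",
                   sizing_rule = "cuboid"),
    glyph_spec_row("ASP", "NEGATIVE", "TRIANGULAR_PRISM", p$red,
                   accent_color = p$darker_red, accent_part = "BASE_FACE",
                   sizing_rule = "tri_prism"),
    glyph_spec_row("GLU", "NEGATIVE", "TRIANGULAR_PRISM", p$red,
                   accent_color = p$darker_red, accent_part = "BASE_FACE",
                   sizing_rule = "tri_prism"),
    glyph_spec_row("PRO", "PROLINE", "CUBE", p$gray, sizing_rule = "cube"),
    glyph_spec_row("*", "NONSTANDARD", "STAR", p$orange,
                   sizing_rule = "star")
  )
  names(rows) <- vapply(rows, `[[`, character(1), "name3")
  rows
}

#' Look up the glyph specification for a residue
#'
#' Returns the dictionary row for `name3`. Histidine (and its force-field
#' name variants) takes its whole-body color from the protonation state:
#' aquamarine when neutral, dark blue when fully protonated, red when fully
#' deprotonated. Unknown codes return the orange star spec with the code
#' substituted in.
#'
#' @param name3 Three-letter residue code.
#' @param his_state Optional histidine protonation state (`"NEUTRAL"`,
#'   `"PROTONATED"`, `"DEPROTONATED"`); consulted only for histidine.
#' @param dictionary Dictionary table, as from [default_dictionary()].
#' @return A `glyph_spec`.
#' @export
glyph_spec_for <- function(name3, his_state = NULL,
                           dictionary = default_dictionary()) {
  code <- toupper(trimws(name3))
  if (code %in% HIS_VARIANTS) {
    spec <- dictionary[["HIS"]]
    spec$name3 <- code
    if (!is.null(his_state)) {
      stopifnot(his_state %in% HIS_STATES)
      p <- glyph_palette()
      spec$base_color <- switch(his_state,
                                NEUTRAL = spec$base_color,
                                PROTONATED = p$dark_blue,
                                DEPROTONATED = p$red)
    }
    return(spec)
  }
  spec <- dictionary[[code]]
  if (is.null(spec)) {
    spec <- dictionary[["*"]]
    spec$name3 <- code
  }
  spec
}

#' Detect the protonation state of a histidine residue
#'
#' Resolution order: an explicit `override` wins; otherwise force-field name
#' variants decide (HID/HIE/HSD/HSE are neutral tautomers, HIP/HSP is
#' protonated); otherwise explicit hydrogens on the imidazole nitrogens
#' decide (hydrogens on both ND1 and NE2 mean protonated, on exactly one
#' neutral, on neither -- while other hydrogens are present -- deprotonated).
#' A heavy-atom-only histidine defaults to neutral, the dominant state at
#' physiological pH.
#'
#' @param residue A `residue_record` whose name is a histidine variant.
#' @param override Optional `HistidineState` string that short-circuits
#'   detection.
#' @return One of `"NEUTRAL"`, `"PROTONATED"`, `"DEPROTONATED"`.
#' @export
detect_histidine_state <- function(residue, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override %in% HIS_STATES)
    return(override)
  }
  name <- toupper(residue$name3)
  if (!name %in% HIS_VARIANTS)
    stop("detect_histidine_state: residue '", name, "' is not a histidine")
  if (name %in% c("HID", "HIE", "HSD", "HSE")) return("NEUTRAL")
  if (name %in% c("HIP", "HSP")) return("PROTONATED")
  atoms <- residue$atoms
  hyd <- is_hydrogen_atom(atoms$name, atoms$element)
  if (!any(hyd)) return("NEUTRAL")
  hnames <- toupper(atoms$name[hyd])
  # HD1 sits on ND1, HE2 on NE2 (standard PDB v3 naming).
  on_nd1 <- any(hnames == "HD1")
  on_ne2 <- any(hnames == "HE2")
  if (on_nd1 && on_ne2) return("PROTONATED")
  if (on_nd1 || on_ne2) return("NEUTRAL")
  "DEPROTONATED"
}

is_hydrogen_atom <- function(name, element) {
  el <- toupper(trimws(element))
  known <- !is.na(el) & nzchar(el)
  ifelse(known, el %in% c("H", "D"),
         grepl("^[0-9]*[HD]", toupper(trimws(name))))
}

#' Write a dictionary to a human-editable YAML config file
#'
#' @param dictionary Dictionary table, as from [default_dictionary()].
#' @param path Output file path.
#' @export
write_dictionary <- function(dictionary = default_dictionary(), path) {
  recs <- lapply(unname(dictionary), function(s) {
    out <- list(name3 = s$name3, class = s$residue_class, shape = s$shape,
                base_color = as.numeric(s$base_color),
                accent_part = s$accent_part, sizing_rule = s$sizing_rule)
    if (!is.null(s$accent_color))
      out$accent_color <- as.numeric(s$accent_color)
    if (!is.null(s$accent_color2))
      out$accent_color2 <- as.numeric(s$accent_color2)
    out
  })
  yaml::write_yaml(list(glyph_dictionary = recs), path)
  invisible(path)
}

#' Read a dictionary from a YAML config file
#'
#' @param path Path to a file written by [write_dictionary()] (or edited by
#'   hand in the same schema).
#' @return Named list of `glyph_spec` rows.
#' @export
read_dictionary <- function(path) {
  doc <- yaml::read_yaml(path)
  recs <- doc$glyph_dictionary
  if (is.null(recs)) stop("not a glyph dictionary file: ", path)
  rows <- lapply(recs, function(r) {
    glyph_spec_row(r$name3, r$class, r$shape, as.numeric(r$base_color),
                   accent_color = if (!is.null(r$accent_color))
                     as.numeric(r$accent_color),
                   accent_color2 = if (!is.null(r$accent_color2))
                     as.numeric(r$accent_color2),
                   accent_part = r$accent_part,
                   sizing_rule = r$sizing_rule)
  })
  names(rows) <- vapply(rows, `[[`, character(1), "name3")
  rows
}
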