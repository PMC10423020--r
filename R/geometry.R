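# Fitting glyph frames and dimensions to residue heavy-atom coordinates.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic sign fix: flip v so its largest-magnitude component is
# positive (ties go to the lowest index).
sign_fix <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Condition signalled when a shape rule cannot find a required atom; callers
# (build_glyph) catch it and fall back to the degraded sphere.
missing_atom <- function(residue, name) {
  cond <- structure(
    class = c("glyphdict_missing_atom", "error", "condition"),
    list(message = sprintf("residue %s lacks atom %s", residue_key(residue),
                           name),
         call = NULL))
  stop(cond)
}

atom_pos <- function(residue, name, required = TRUE) {
  a <- residue$atoms
  i <- which(toupper(a$name) == toupper(name))[1]
  if (is.na(i)) {
    if (required) missing_atom(residue, name)
    return(NULL)
  }
  c(a$x[i], a$y[i], a$z[i])
}

#' Sizing constants of the glyph grammar
#'
#' All glyph dimensions derive from the residue's own heavy-atom extents
#' plus the padding constants collected here (Angstrom). Override individual
#' entries through the `sizing` element of the options list accepted by
#' [build_glyph()] and [build_scene()].
#'
#' @param ... Named overrides of individual constants.
#' @return Named list of sizing constants.
#' @export
glyph_sizing <- function(...) {
  s <- list(
    ellipsoid_padding   = 0.8,  # added to principal extents
    ellipsoid_min_axis  = 0.8,  # floor for flat/linear side chains
    prism_half_thickness = 0.5, # all ring/triangle prisms
    ring_padding        = 0.6,  # added to ring circumradius
    pyramid_half_width  = 1.0,  # base half-width
    pyramid_extra_height = 0.5, # beyond the polar atom
    cuboid_padding      = 0.7,  # all cuboid half-extents
    cube_half_edge      = 0.9,  # proline
    sphere_radius_gly   = 1.0,
    sphere_radius_ala   = 1.3,
    sphere_radius_degraded = 1.0,
    star_outer_radius   = 1.2,
    star_inner_fraction = 0.45,
    star_half_thickness = 0.3,
    band_fraction       = 0.2,  # Met: outer fraction of the major axis
    tip_fraction        = 0.3,  # pyramid tip accent, fraction of height
    segment_half_angle  = 30    # Tyr rim sector half-width, degrees
  )
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)))
    ov <- ov[[1]]
  for (k in names(ov)) {
    if (!k %in% names(s)) stop("unknown sizing constant: ", k)
    s[[k]] <- ov[[k]]
  }
  s
}

#' Heavy side-chain atoms of a residue
#'
#' Heavy atoms beyond the backbone (N, CA, C, O and the terminal OXT);
#' includes CB. Empty for glycine. Hydrogens never enter geometric fits.
#'
#' @param residue A `residue_record`.
#' @return Data frame of atom rows (possibly zero rows).
#' @export
side_chain_atoms <- function(residue) {
  a <- residue$atoms
  keep <- !toupper(a$name) %in% BACKBONE_NAMES &
    !is_hydrogen_atom(a$name, a$element)
  a[keep, , drop = FALSE]
}

heavy_atoms <- function(residue) {
  a <- residue$atoms
  a[!is_hydrogen_atom(a$name, a$element), , drop = FALSE]
}

#' Principal frame of a point cloud
#'
#' Centroid, principal axes (eigenvectors of the point covariance, by
#' decreasing eigenvalue) and extents (half-range of the point projections
#' on each axis). Sign conventions make the output deterministic: the first
#' axis has non-negative dot product with `direction` (the caller usually
#' passes the Calpha-to-centroid direction; `+z` when absent or degenerate),
#' the second axis has its largest-magnitude component positive, and the
#' third is their cross product, so the frame is right-handed (det +1).
#'
#' @param points Numeric matrix, one 3D point per row.
#' @param direction Optional reference 3-vector fixing the first axis sign.
#' @return List with `centroid` (3-vector), `axes` (3x3, columns = axes),
#'   `extents` (3 half-ranges).
#' @export
principal_frame <- function(points, direction = NULL) {
  points <- rbind(points)
  if (nrow(points) < 1) stop("principal_frame: need at least one point")
  centroid <- colMeans(points)
  if (nrow(points) == 1) {
    return(list(centroid = centroid, axes = diag(3), extents = c(0, 0, 0)))
  }
  centered <- sweep(points, 2, centroid)
  covm <- crossprod(centered) / nrow(points)
  eig <- eigen(covm, symmetric = TRUE)
  axes <- eig$vectors  # columns, decreasing eigenvalue

  ref <- direction
  if (is.null(ref) || vnorm(ref) < 1e-9) ref <- c(0, 0, 1)
  if (sum(axes[, 1] * ref) < 0) axes[, 1] <- -axes[, 1]
  axes[, 2] <- sign_fix(axes[, 2])
  axes[, 3] <- cross3(axes[, 1], axes[, 2])

  proj <- centered %*% axes
  extents <- (apply(proj, 2, max) - apply(proj, 2, min)) / 2
  list(centroid = centroid, axes = axes, extents = as.numeric(extents))
}

#' Plane fit of a ring of atoms
#'
#' Center (ring-atom centroid), least-squares plane normal (direction of the
#' smallest covariance eigenvalue) and circumradius (largest distance of a
#' ring atom from the center). The normal sign points toward positive dot
#' product with global +z, then +y, then +x (first non-zero), making closed
#' prisms deterministic.
#'
#' @param residue A `residue_record`.
#' @param ring_atom_names Atom names of the ring (all must be present).
#' @return List with `center`, `normal` (unit 3-vector), `circumradius`.
#' @export
ring_geometry <- function(residue, ring_atom_names) {
  pts <- t(vapply(ring_atom_names, function(n) atom_pos(residue, n),
                  numeric(3)))
  center <- colMeans(pts)
  centered <- sweep(pts, 2, center)
  eig <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)
  normal <- eig$vectors[, 3]
  for (k in 3:1) {
    if (abs(normal[k]) > 1e-9) {
      if (normal[k] < 0) normal <- -normal
      break
    }
  }
  radius <- max(sqrt(rowSums(centered^2)))
  list(center = center, normal = unitv(normal), circumradius = radius)
}

#' Direction from the alpha carbon to a polar side-chain atom
#'
#' The unit vector that orients pyramids: it points from CA at the polar
#' atom (the hydroxyl oxygen of Ser/Thr, the thiol sulfur of Cys).
#'
#' @param residue A `residue_record` containing CA and the named atom.
#' @param polar_atom_name Atom name of the polar group.
#' @return Unit 3-vector.
#' @export
polar_apex_direction <- function(residue, polar_atom_name) {
  ca <- atom_pos(residue, "CA")
  p <- atom_pos(residue, polar_atom_name)
  unitv(p - ca)
}

new_rigid_frame <- function(origin, axes) {
  list(origin = as.numeric(origin), axes = axes)
}

new_glyph <- function(residue, spec, origin, axes, dims, part_colors,
                      accent_params = list(), degraded = FALSE,
                      transparency = NULL) {
  if (!is.null(transparency)) {
    part_colors <- lapply(part_colors, function(col) {
      col[4] <- transparency
      col
    })
  }
  structure(list(
    residue_key = list(chain_id = residue$chain_id,
                       seq_number = residue$seq_number,
                       insertion_code = residue$insertion_code,
                       name3 = residue$name3),
    spec = spec,
    frame = new_rigid_frame(origin, axes),
    dims = dims,
    part_colors = part_colors,
    accent_params = accent_params,
    degraded = degraded,
    transparency = transparency), class = "glyph")
}

#' @export
print.glyph <- function(x, ...) {
  k <- x$residue_key
  cat(sprintf("<glyph> %s %s%d%s: %s at (%.2f, %.2f, %.2f)%s\n",
              k$name3, k$chain_id, k$seq_number, k$insertion_code,
              x$spec$shape, x$frame$origin[1], x$frame$origin[2],
              x$frame$origin[3], if (x$degraded) " [degraded]" else ""))
  invisible(x)
}

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

PYRAMID_POLAR_ATOM <- c(SER = "OG", THR = "OG1", CYS = "SG")

TRI_PRISM_ATOMS <- list(
  ASN = list(carbonyl = "CG", o = "OD1", n = "ND2"),
  GLN = list(carbonyl = "CD", o = "OE1", n = "NE2"),
  ASP = list(carbonyl = "CG", o = "OD1", n = "OD2"),
  GLU = list(carbonyl = "CD", o = "OE1", n = "OE2")
)

CUBOID_TERMINAL <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))

#' Fit a glyph to a residue
#'
#' Dispatches on the spec's shape kind and applies its placement rule:
#' spheres sit on CA (Gly) or CB (Ala); ellipsoids take the principal frame
#' of the side-chain atoms; hexagonal/pentagonal prisms overlap the aromatic
#' or imidazole ring (hexagons elongate along the first in-plane principal
#' axis until they cover the whole side chain); pyramids sit on CA with the
#' apex at the polar atom; triangular prisms lie flat over the amide or
#' carboxylate plane; cuboids run from CA to the charged terminal group with
#' the darker face at the charged end; the proline cube is centered on CA;
#' the non-standard star sits on CA with its plane normal along CA->CB.
#'
#' When a required atom is missing the glyph degrades to a sphere at CA in
#' the family base color (flagged `degraded`); a residue without CA yields
#' `NULL` with a warning.
#'
#' @param residue A `residue_record`.
#' @param spec A `glyph_spec`, as from [glyph_spec_for()].
#' @param options List; honoured elements are `transparency` (alpha override
#'   in `[0, 1]`) and `sizing` (overrides for [glyph_sizing()]).
#' @return A `glyph`, or `NULL` when the residue has no CA.
#' @export
build_glyph <- function(residue, spec, options = list()) {
  sz <- glyph_sizing(options$sizing %||% list())
  alpha <- options$transparency
  builder <- switch(spec$shape,
                    SPHERE = build_sphere_glyph,
                    ELLIPSOID = build_ellipsoid_glyph,
                    HEXAGONAL_PRISM = build_ring_prism_glyph,
                    PENTAGONAL_PRISM = build_ring_prism_glyph,
                    PYRAMID = build_pyramid_glyph,
                    TRIANGULAR_PRISM = build_tri_prism_glyph,
                    CUBOID = build_cuboid_glyph,
                    CUBE = build_cube_glyph,
                    STAR = build_star_glyph,
                    stop("unknown shape kind: ", spec$shape))
  tryCatch(
    builder(residue, spec, sz, alpha),
    glyphdict_missing_atom = function(cond) {
      ca <- atom_pos(residue, "CA", required = FALSE)
      if (is.null(ca)) {
        warning("skipping residue ", residue_key(residue),
                ": no CA atom (", conditionMessage(cond), ")")
        return(NULL)
      }
      warning("degraded glyph for ", residue_key(residue), ": ",
              conditionMessage(cond))
      new_glyph(residue, spec, ca, diag(3),
                list(radius = sz$sphere_radius_degraded),
                list(BODY = spec$base_color), degraded = TRUE,
                transparency = alpha)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_sphere_glyph <- function(residue, spec, sz, alpha) {
  if (spec$sizing_rule == "sphere_ala") {
    center <- atom_pos(residue, "CB")
    r <- sz$sphere_radius_ala
  } else {
    center <- atom_pos(residue, "CA")
    r <- sz$sphere_radius_gly
  }
  new_glyph(residue, spec, center, diag(3), list(radius = r),
            list(BODY = spec$base_color), transparency = alpha)
}

build_ellipsoid_glyph <- function(residue, spec, sz, alpha) {
  ca <- atom_pos(residue, "CA")
  sc <- side_chain_atoms(residue)
  if (nrow(sc) < 2) missing_atom(residue, "side-chain atoms")
  pts <- atom_positions(sc)
  pf <- principal_frame(pts, colMeans(pts) - ca)
  semi <- pmax(pf$extents + sz$ellipsoid_padding, sz$ellipsoid_min_axis)
  parts <- list(BODY = spec$base_color)
  accent <- list()
  if (identical(spec$accent_part, "END_BAND")) {
    sd <- atom_pos(residue, "SD", required = FALSE) %||%
      atom_pos(residue, "SE", required = FALSE)
    if (is.null(sd)) missing_atom(residue, "SD")
    pole_plus <- pf$centroid + semi[1] * pf$axes[, 1]
    pole_minus <- pf$centroid - semi[1] * pf$axes[, 1]
    pole <- if (vnorm(pole_plus - sd) <= vnorm(pole_minus - sd)) 1 else -1
    accent <- list(band_pole = pole, band_fraction = sz$band_fraction)
    parts$END_BAND <- spec$accent_color
  }
  new_glyph(residue, spec, pf$centroid, pf$axes,
            list(semi_axes = as.numeric(semi)), parts, accent,
            transparency = alpha)
}

# In-plane component of v relative to unit normal z, unit length.
in_plane_unit <- function(v, z) {
  w <- v - sum(v * z) * z
  if (vnorm(w) < 1e-9) return(NULL)
  unitv(w)
}

build_ring_prism_glyph <- function(residue, spec, sz, alpha) {
  ca <- atom_pos(residue, "CA")
  ring_names <- RING_ATOMS[[resolve_ring_key(residue$name3)]]
  if (is.null(ring_names)) missing_atom(residue, "ring template")
  rg <- ring_geometry(residue, ring_names)
  z <- rg$normal
  sc <- side_chain_atoms(residue)
  pts <- atom_positions(sc)

  # First in-plane principal axis of the side chain fixes the elongation
  # direction; sign toward the in-plane CA->ring-center direction.
  flat <- sweep(pts, 2, rg$center)
  flat <- flat - outer(as.numeric(flat %*% z), z)
  ref <- in_plane_unit(rg$center - ca, z)
  x <- NULL
  if (nrow(flat) >= 2 && max(abs(flat)) > 1e-9) {
    pfi <- principal_frame(flat, ref %||% c(0, 0, 1))
    x <- in_plane_unit(pfi$axes[, 1], z)
  }
  if (is.null(x)) x <- ref
  if (is.null(x)) x <- in_plane_unit(c(1, 0, 0), z) %||% in_plane_unit(c(0, 1, 0), z)
  y <- cross3(z, x)
  axes <- cbind(x, y, z, deparse.level = 0)

  radius <- rg$circumradius + sz$ring_padding
  nsides <- if (spec$shape == "PENTAGONAL_PRISM") 5L else 6L
  dims <- list(circumradius = radius,
               half_thickness = sz$prism_half_thickness,
               n_sides = nsides, elongation = 0)
  parts <- list(BODY = spec$base_color)
  accent <- list()
  if (nsides == 6L) {
    span <- as.numeric(flat %*% x)
    elong <- max(0, max(abs(span)) + sz$ring_padding - radius)
    dims$elongation <- elong
    if (identical(spec$accent_part, "RING_SEGMENT")) {
      oh <- atom_pos(residue, "OH")
      d <- in_plane_unit(oh - rg$center, z)
      if (is.null(d)) missing_atom(residue, "OH direction")
      ang <- atan2(sum(d * y), sum(d * x)) * 180 / pi
      accent <- list(segment_center_angle = ang,
                     segment_half_angle = sz$segment_half_angle)
      parts$RING_SEGMENT <- spec$accent_color
    }
  }
  new_glyph(residue, spec, rg$center, axes, dims, parts, accent,
            transparency = alpha)
}

resolve_ring_key <- function(name3) {
  if (name3 %in% HIS_VARIANTS) return("HIS")
  if (name3 %in% names(RING_ATOMS)) return(name3)
  NA_character_
}

build_pyramid_glyph <- function(residue, spec, sz, alpha) {
  ca <- atom_pos(residue, "CA")
  polar_name <- PYRAMID_POLAR_ATOM[[residue$name3]]
  if (is.null(polar_name)) missing_atom(residue, "polar atom template")
  polar <- atom_pos(residue, polar_name)
  if (vnorm(polar - ca) < 1e-9) stop("polar atom coincides with CA")
  z <- polar_apex_direction(residue, polar_name)
  n <- atom_pos(residue, "N", required = FALSE)
  x <- if (!is.null(n)) in_plane_unit(n - ca, z) else NULL
  if (is.null(x)) x <- in_plane_unit(c(1, 0, 0), z) %||% in_plane_unit(c(0, 1, 0), z)
  y <- cross3(z, x)
  height <- vnorm(polar - ca) + sz$pyramid_extra_height
  parts <- list(BODY = spec$base_color, TIP = spec$accent_color)
  new_glyph(residue, spec, ca, cbind(x, y, z, deparse.level = 0),
            list(base_half_width = sz$pyramid_half_width, height = height),
            parts, list(tip_fraction = sz$tip_fraction),
            transparency = alpha)
}

build_tri_prism_glyph <- function(residue, spec, sz, alpha) {
  atom_pos(residue, "CA")  # required even though the prism sits on the group
  tpl <- TRI_PRISM_ATOMS[[residue$name3]]
  if (is.null(tpl)) missing_atom(residue, "amide/carboxylate template")
  pc <- atom_pos(residue, tpl$carbonyl)
  po <- atom_pos(residue, tpl$o)
  pn <- atom_pos(residue, tpl$n)
  center <- (po + pn) / 2  # centroid of the terminal polar atoms
  z <- unitv(cross3(po - pc, pn - pc))
  for (k in 3:1) {
    if (abs(z[k]) > 1e-9) {
      if (z[k] < 0) z <- -z
      break
    }
  }
  x <- in_plane_unit(po - pn, z)  # oxygen side on +x
  if (is.null(x)) missing_atom(residue, "distinct terminal atoms")
  y <- cross3(z, x)
  group <- rbind(pc, po, pn)
  flat <- sweep(group, 2, center)
  flat <- flat - outer(as.numeric(flat %*% z), z)
  radius <- max(sqrt(rowSums(flat^2))) + sz$ring_padding
  split <- identical(spec$residue_class, "NEUTRAL_POLAR")
  parts <- list(BODY = spec$base_color)
  if (split) {
    parts$BASE_FACE_O <- spec$accent_color
    parts$BASE_FACE_N <- spec$accent_color2
  } else {
    parts$BASE_FACE <- spec$accent_color
  }
  new_glyph(residue, spec, center, cbind(x, y, z, deparse.level = 0),
            list(circumradius = radius,
                 half_thickness = sz$prism_half_thickness,
                 split_base = split),
            parts, transparency = alpha)
}

build_cuboid_glyph <- function(residue, spec, sz, alpha) {
  ca <- atom_pos(residue, "CA")
  term_names <- CUBOID_TERMINAL[[residue$name3]]
  if (is.null(term_names)) missing_atom(residue, "terminal group template")
  term <- colMeans(rbind(t(vapply(term_names, function(n)
    atom_pos(residue, n), numeric(3)))))
  if (vnorm(term - ca) < 1e-9) stop("terminal group coincides with CA")
  x <- unitv(term - ca)
  sc <- side_chain_atoms(residue)
  if (nrow(sc) < 1) missing_atom(residue, "side-chain atoms")
  pts <- rbind(atom_positions(sc), CA = ca)
  pf <- principal_frame(pts, term - ca)
  y <- NULL
  for (j in 1:3) {
    cand <- pf$axes[, j] - sum(pf$axes[, j] * x) * x
    if (vnorm(cand) > 1e-6) { y <- sign_fix(unitv(cand)); break }
  }
  if (is.null(y)) y <- sign_fix(in_plane_unit(c(1, 0, 0), x) %||%
                                  in_plane_unit(c(0, 1, 0), x))
  z <- cross3(x, y)
  axes <- cbind(x, y, z, deparse.level = 0)
  proj <- sweep(pts, 2, ca) %*% axes
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  half <- (hi - lo) / 2 + sz$cuboid_padding
  center <- ca + as.numeric(axes %*% ((hi + lo) / 2))
  parts <- list(BODY = spec$base_color, END_FACE = spec$accent_color)
  new_glyph(residue, spec, center, axes,
            list(half_extents = as.numeric(half)), parts,
            list(end_face_sign = 1), transparency = alpha)
}

backbone_frame <- function(residue) {
  ca <- atom_pos(residue, "CA")
  n <- atom_pos(residue, "N", required = FALSE)
  cc <- atom_pos(residue, "C", required = FALSE)
  if (is.null(n) || is.null(cc)) return(list(origin = ca, axes = diag(3)))
  x <- unitv(cc - n)
  w <- ca - (n + cc) / 2
  y <- in_plane_unit(w, x)
  if (is.null(y)) y <- in_plane_unit(c(0, 0, 1), x)
  z <- cross3(x, y)
  list(origin = ca, axes = cbind(x, y, z, deparse.level = 0))
}

build_cube_glyph <- function(residue, spec, sz, alpha) {
  bf <- backbone_frame(residue)
  new_glyph(residue, spec, bf$origin, bf$axes,
            list(half_edge = sz$cube_half_edge),
            list(BODY = spec$base_color), transparency = alpha)
}

build_star_glyph <- function(residue, spec, sz, alpha) {
  ca <- atom_pos(residue, "CA")
  cb <- atom_pos(residue, "CB", required = FALSE)
  z <- if (!is.null(cb) && vnorm(cb - ca) > 1e-9) unitv(cb - ca)
       else c(0, 0, 1)
  n <- atom_pos(residue, "N", required = FALSE)
  x <- if (!is.null(n)) in_plane_unit(n - ca, z) else NULL
  if (is.null(x)) x <- in_plane_unit(c(1, 0, 0), z) %||% in_plane_unit(c(0, 1, 0), z)
  y <- cross3(z, x)
  new_glyph(residue, spec, ca, cbind(x, y, z, deparse.level = 0),
            list(outer_radius = sz$star_outer_radius,
                 inner_radius = sz$star_outer_radius * sz$star_inner_fraction,
                 half_thickness = sz$star_half_thickness,
                 n_points = 5L),
            list(BODY = spec$base_color), transparency = alpha)
}
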