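# Triangulation of glyphs and portable scene export (OBJ/MTL, BILD, JSON).

SCENE_SCHEMA_VERSION <- "1.0"

new_mesh <- function(vertices, faces, face_part, part_colors) {
  structure(list(vertices = vertices, faces = faces, face_part = face_part,
                 part_colors = part_colors), class = "glyph_mesh")
}

#' @export
print.glyph_mesh <- function(x, ...) {
  cat(sprintf("<glyph_mesh> %d vertices, %d faces, parts: %s\n",
              nrow(x$vertices), nrow(x$faces),
              paste(unique(x$face_part), collapse = ", ")))
  invisible(x)
}

#' Signed volume of a triangle mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed mesh with outward-facing winding.
#'
#' @param mesh A `glyph_mesh`.
#' @return Scalar volume (cubic Angstrom).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(det3) / 6
}

#' Is a mesh watertight?
#'
#' Every edge must be shared by exactly two faces, traversed once in each
#' direction (consistent winding).
#'
#' @param mesh A `glyph_mesh`.
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  dir <- paste(edges[, 1], edges[, 2])
  all(table(und) == 2) && !anyDuplicated(dir)
}

mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- unique(paste(pmin(edges[, 1], edges[, 2]),
                      pmax(edges[, 1], edges[, 2])))
  nrow(mesh$vertices) - length(und) + nrow(f)
}

# --- primitive meshes in local coordinates ---------------------------------

# Unit icosphere by midpoint subdivision of an icosahedron.
icosphere <- function(level = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    mid_cache <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); cc <- midpoint(k, i)
      nf[4 * t - 3, ] <- c(i, a, cc)
      nf[4 * t - 2, ] <- c(j, b, a)
      nf[4 * t - 1, ] <- c(k, cc, b)
      nf[4 * t, ] <- c(a, b, cc)
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

# Extrude a 2D polygon (counter-clockwise vertex matrix, star-shaped about
# the origin) into a closed prism from z = -h to z = +h, capping both ends
# with a fan from the polygon center.
extrude_polygon <- function(poly2d, h) {
  n <- nrow(poly2d)
  top <- cbind(poly2d, h)
  bot <- cbind(poly2d, -h)
  v <- rbind(top, bot, c(0, 0, h), c(0, 0, -h))
  ct <- 2L * n + 1L
  cb <- 2L * n + 2L
  nxt <- c(seq_len(n)[-1], 1L)
  faces <- list()
  part_hint <- list()
  for (i in seq_len(n)) {
    j <- nxt[i]
    faces[[length(faces) + 1L]] <- c(ct, i, j)           # top cap
    part_hint[[length(part_hint) + 1L]] <- list(kind = "cap_top", i = i)
    faces[[length(faces) + 1L]] <- c(cb, n + j, n + i)   # bottom cap
    part_hint[[length(part_hint) + 1L]] <- list(kind = "cap_bottom", i = i)
    faces[[length(faces) + 1L]] <- c(i, n + i, n + j)    # side
    part_hint[[length(part_hint) + 1L]] <- list(kind = "side", i = i)
    faces[[length(faces) + 1L]] <- c(i, n + j, j)
    part_hint[[length(part_hint) + 1L]] <- list(kind = "side", i = i)
  }
  list(vertices = v, faces = do.call(rbind, faces), hints = part_hint,
       n = n)
}

regular_polygon_2d <- function(n, radius, elongation = 0) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  p <- cbind(radius * cos(ang), radius * sin(ang))
  if (elongation > 0)
    p[, 1] <- p[, 1] + sign(p[, 1]) * elongation
  p
}

box_mesh <- function(hx, hy, hz) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- cbind(s$x * hx, s$y * hy, s$z * hz)
  # Corner order: (-,-,-),(+,-,-),(-,+,-),(+,+,-),(-,-,+),(+,-,+),(-,+,+),(+,+,+)
  quads <- list(
    xneg = c(1, 3, 7, 5), xpos = c(2, 6, 8, 4),
    yneg = c(1, 5, 6, 2), ypos = c(3, 4, 8, 7),
    zneg = c(1, 2, 4, 3), zpos = c(5, 7, 8, 6))
  faces <- list()
  side <- character()
  for (nm in names(quads)) {
    q <- quads[[nm]]
    faces[[length(faces) + 1L]] <- q[c(1, 2, 3)]
    faces[[length(faces) + 1L]] <- q[c(1, 3, 4)]
    side <- c(side, nm, nm)
  }
  list(vertices = v, faces = do.call(rbind, faces), side = side)
}

to_world <- function(vertices, frame) {
  sweep(vertices %*% t(frame$axes), 2, frame$origin, `+`)
}

angdiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Tessellate a glyph into a triangle mesh
#'
#' Produces a closed, watertight triangle mesh in world coordinates, with
#' accent parts (tip, end band, base/end faces, rim segment) labeled
#' per-face. Spheres and ellipsoids use icosphere subdivision at the given
#' `resolution`; the polyhedral shapes are exact.
#'
#' @param glyph A `glyph`.
#' @param resolution Icosphere subdivision level (>= 1); default 3.
#' @return A `glyph_mesh`.
#' @export
tessellate_glyph <- function(glyph, resolution = 3) {
  stopifnot(resolution >= 1)
  d <- glyph$dims
  shape <- glyph$spec$shape
  if (glyph$degraded) shape <- "SPHERE"

  m <- switch(shape,
    SPHERE = {
      ico <- icosphere(resolution)
      list(vertices = ico$vertices * d$radius, faces = ico$faces,
           part = rep("BODY", nrow(ico$faces)))
    },
    ELLIPSOID = {
      ico <- icosphere(resolution)
      verts <- sweep(ico$vertices, 2, d$semi_axes, `*`)
      part <- rep("BODY", nrow(ico$faces))
      ap <- glyph$accent_params
      if (!is.null(ap$band_pole)) {
        # Band spans the outer band_fraction of the major axis at the pole,
        # measured on the unit sphere's first coordinate.
        t_face <- rowMeans(matrix(ico$vertices[t(ico$faces), 1],
                                  ncol = 3, byrow = TRUE))
        thr <- 1 - 2 * ap$band_fraction
        part[t_face * ap$band_pole >= thr] <- "END_BAND"
      }
      list(vertices = verts, faces = ico$faces, part = part)
    },
    HEXAGONAL_PRISM = ,
    PENTAGONAL_PRISM = {
      poly <- regular_polygon_2d(d$n_sides, d$circumradius,
                                 d$elongation %||% 0)
      ex <- extrude_polygon(poly, d$half_thickness)
      part <- rep("BODY", nrow(ex$faces))
      ap <- glyph$accent_params
      if (!is.null(ap$segment_center_angle)) {
        nxt <- c(seq_len(ex$n)[-1], 1L)
        for (fi in seq_along(ex$hints)) {
          h <- ex$hints[[fi]]
          if (h$kind != "side") next
          mid <- (poly[h$i, ] + poly[nxt[h$i], ]) / 2
          ang <- atan2(mid[2], mid[1]) * 180 / pi
          if (angdiff(ang, ap$segment_center_angle) <=
              ap$segment_half_angle)
            part[fi] <- "RING_SEGMENT"
        }
      }
      list(vertices = ex$vertices, faces = ex$faces, part = part)
    },
    TRIANGULAR_PRISM = {
      poly <- regular_polygon_2d(3L, d$circumradius)
      ex <- extrude_polygon(poly, d$half_thickness)
      part <- rep("BODY", nrow(ex$faces))
      for (fi in seq_along(ex$hints)) {
        h <- ex$hints[[fi]]
        if (!h$kind %in% c("cap_top", "cap_bottom")) next
        if (isTRUE(d$split_base)) {
          tri <- ex$vertices[ex$faces[fi, ], 1]
          part[fi] <- if (mean(tri) >= 0) "BASE_FACE_O" else "BASE_FACE_N"
        } else {
          part[fi] <- "BASE_FACE"
        }
      }
      list(vertices = ex$vertices, faces = ex$faces, part = part)
    },
    CUBOID = {
      bm <- box_mesh(d$half_extents[1], d$half_extents[2],
                     d$half_extents[3])
      part <- ifelse(bm$side == "xpos", "END_FACE", "BODY")
      list(vertices = bm$vertices, faces = bm$faces, part = part)
    },
    CUBE = {
      bm <- box_mesh(d$half_edge, d$half_edge, d$half_edge)
      list(vertices = bm$vertices, faces = bm$faces,
           part = rep("BODY", nrow(bm$faces)))
    },
    PYRAMID = {
      pyramid_mesh(d$base_half_width, d$height,
                   glyph$accent_params$tip_fraction %||% 0.3,
                   has_tip = "TIP" %in% names(glyph$part_colors))
    },
    STAR = {
      k <- seq_len(2L * d$n_points)
      rad <- ifelse(k %% 2 == 1, d$outer_radius, d$inner_radius)
      ang <- 2 * pi * (k - 1) / (2 * d$n_points)
      poly <- cbind(rad * cos(ang), rad * sin(ang))
      ex <- extrude_polygon(poly, d$half_thickness)
      list(vertices = ex$vertices, faces = ex$faces,
           part = rep("BODY", nrow(ex$faces)))
    },
    stop("unknown shape kind: ", shape))

  verts <- to_world(m$vertices, glyph$frame)
  mesh <- new_mesh(verts, m$faces, m$part, glyph$part_colors)
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# Square pyramid: base at z = 0, apex at z = height; the tip accent is the
# top tip_fraction of the height, separated by a frustum ring.
pyramid_mesh <- function(w, height, tip_fraction, has_tip = TRUE) {
  base <- rbind(c(w, w, 0), c(-w, w, 0), c(-w, -w, 0), c(w, -w, 0))
  zc <- height * (1 - tip_fraction)
  wc <- w * tip_fraction
  ring <- rbind(c(wc, wc, zc), c(-wc, wc, zc), c(-wc, -wc, zc),
                c(wc, -wc, zc))
  apex <- c(0, 0, height)
  v <- rbind(base, ring, apex)
  faces <- list(); part <- character()
  nxt <- c(2, 3, 4, 1)
  for (i in 1:4) {
    j <- nxt[i]
    faces[[length(faces) + 1L]] <- c(i, j, 4 + j); part <- c(part, "BODY")
    faces[[length(faces) + 1L]] <- c(i, 4 + j, 4 + i); part <- c(part, "BODY")
    faces[[length(faces) + 1L]] <- c(4 + i, 4 + j, 9L)
    part <- c(part, if (has_tip) "TIP" else "BODY")
  }
  faces[[length(faces) + 1L]] <- c(1, 3, 2); part <- c(part, "BODY")
  faces[[length(faces) + 1L]] <- c(1, 4, 3); part <- c(part, "BODY")
  list(vertices = v, faces = do.call(rbind, faces), part = part)
}

# --- exporters -------------------------------------------------------------

glyph_group_name <- function(glyph) {
  k <- glyph$residue_key
  sprintf("%s_%s%s_%s", k$chain_id, k$seq_number, k$insertion_code,
          k$name3)
}

material_name <- function(col) {
  sprintf("c_%03d_%03d_%03d_%03d", round(col[1] * 255), round(col[2] * 255),
          round(col[3] * 255), round(col[4] * 255))
}

fmt <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

#' Write a scene as Wavefront OBJ + MTL
#'
#' One named object group per glyph (`<chain>_<resi>_<name3>`), faces split
#' by part, one MTL material per distinct RGBA color (OBJ has no per-face
#' color standard). Output is deterministic: re-running on the same scene
#' produces byte-identical files.
#'
#' @param scene A `glyph_scene`.
#' @param path Output `.obj` path; the `.mtl` sidecar is written next to it.
#' @param resolution Tessellation level, see [tessellate_glyph()].
#' @export
write_obj <- function(scene, path, resolution = 3) {
  mtl_path <- sub("\\.obj$", ".mtl", path)
  if (identical(mtl_path, path)) mtl_path <- paste0(path, ".mtl")
  meshes <- lapply(scene$glyphs, tessellate_glyph, resolution = resolution)

  mats <- list()
  for (m in meshes) {
    for (part in unique(m$face_part)) {
      col <- m$part_colors[[part]] %||% m$part_colors$BODY
      nm <- material_name(col)
      if (is.null(mats[[nm]])) mats[[nm]] <- col
    }
  }
  mtl <- c("# glyphdict materials")
  for (nm in names(mats)) {
    col <- mats[[nm]]
    mtl <- c(mtl, paste("newmtl", nm),
             paste("Kd", fmt(col[1]), fmt(col[2]), fmt(col[3])),
             paste("d", fmt(col[4])), "")
  }
  writeLines(mtl, mtl_path)

  out <- c("# glyphdict scene export",
           paste("mtllib", basename(mtl_path)))
  offset <- 0L
  for (gi in seq_along(scene$glyphs)) {
    g <- scene$glyphs[[gi]]
    m <- meshes[[gi]]
    out <- c(out, paste("o", glyph_group_name(g)))
    vt <- m$vertices
    out <- c(out, paste("v", fmt(vt[, 1]), fmt(vt[, 2]), fmt(vt[, 3])))
    for (part in unique(m$face_part)) {
      col <- m$part_colors[[part]] %||% m$part_colors$BODY
      out <- c(out, paste("usemtl", material_name(col)))
      ff <- m$faces[m$face_part == part, , drop = FALSE] + offset
      out <- c(out, paste("f", ff[, 1], ff[, 2], ff[, 3]))
    }
    offset <- offset + nrow(vt)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a scene as Chimera BILD geometry commands
#'
#' Spheres become `.sphere`, frame-aligned boxes `.box`, everything else
#' `.polygon` triangles from the tessellation. `.color` / `.transparency`
#' commands precede each part's geometry; all numbers use a fixed 3-decimal
#' format so re-runs are byte-identical.
#'
#' @param scene A `glyph_scene`.
#' @param path Output `.bild` path.
#' @param resolution Tessellation level for the polygonal shapes.
#' @export
write_bild <- function(scene, path, resolution = 3) {
  out <- character()
  emit_color <- function(col) {
    out <<- c(out,
              paste(".color", fmt(col[1], 3), fmt(col[2], 3),
                    fmt(col[3], 3)),
              paste(".transparency", fmt(1 - col[4], 3)))
  }
  for (g in scene$glyphs) {
    out <- c(out, paste("# glyph", glyph_group_name(g)))
    shape <- if (g$degraded) "SPHERE" else g$spec$shape
    if (shape == "SPHERE") {
      emit_color(g$part_colors$BODY)
      o <- g$frame$origin
      out <- c(out, paste(".sphere", fmt(o[1], 3), fmt(o[2], 3),
                          fmt(o[3], 3), fmt(g$dims$radius, 3)))
      next
    }
    aligned <- shape %in% c("CUBE", "CUBOID") &&
      max(abs(g$frame$axes - diag(3))) < 1e-9
    if (aligned) {
      emit_color(g$part_colors$BODY)
      half <- if (shape == "CUBE") rep(g$dims$half_edge, 3) else
        g$dims$half_extents
      lo <- g$frame$origin - half
      hi <- g$frame$origin + half
      out <- c(out, paste(".box", fmt(lo[1], 3), fmt(lo[2], 3),
                          fmt(lo[3], 3), fmt(hi[1], 3), fmt(hi[2], 3),
                          fmt(hi[3], 3)))
      next
    }
    m <- tessellate_glyph(g, resolution = resolution)
    for (part in unique(m$face_part)) {
      emit_color(m$part_colors[[part]] %||% m$part_colors$BODY)
      ff <- m$faces[m$face_part == part, , drop = FALSE]
      for (fi in seq_len(nrow(ff))) {
        tri <- m$vertices[ff[fi, ], , drop = FALSE]
        out <- c(out, paste(".polygon",
                            paste(fmt(t(tri), 3), collapse = " ")))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a scene as a JSON document
#'
#' Schema-versioned dump of every glyph's parameters (frames, dimensions,
#' colors, accents) without meshes; [read_scene_json()] reconstructs an
#' equal scene.
#'
#' @param scene A `glyph_scene`.
#' @param path Output `.json` path.
#' @export
write_scene_json <- function(scene, path) {
  doc <- list(
    schema_version = SCENE_SCHEMA_VERSION,
    source_label = scene$source_label,
    model_index = scene$model_index,
    selection_label = scene$selection_label,
    global_alpha = scene$global_alpha,
    glyphs = lapply(scene$glyphs, function(g) {
      list(residue_key = g$residue_key,
           spec = list(name3 = g$spec$name3,
                       residue_class = g$spec$residue_class,
                       shape = g$spec$shape,
                       base_color = g$spec$base_color,
                       accent_color = g$spec$accent_color,
                       accent_color2 = g$spec$accent_color2,
                       accent_part = g$spec$accent_part,
                       sizing_rule = g$spec$sizing_rule),
           origin = g$frame$origin,
           axes = as.numeric(g$frame$axes),
           dims = g$dims,
           part_colors = g$part_colors,
           accent_params = g$accent_params,
           degraded = g$degraded,
           transparency = g$transparency)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a scene written by [write_scene_json()]
#'
#' @param path Path to the JSON scene file.
#' @return A `glyph_scene`.
#' @export
read_scene_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    stop("not a glyph scene file: ", path)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  glyphs <- lapply(doc$glyphs, function(gj) {
    sj <- gj$spec
    spec <- glyph_spec_row(sj$name3, sj$residue_class, sj$shape,
                           num(sj$base_color),
                           accent_color = num(sj$accent_color),
                           accent_color2 = num(sj$accent_color2),
                           accent_part = sj$accent_part,
                           sizing_rule = sj$sizing_rule)
    dims <- lapply(gj$dims, function(x) {
      v <- unlist(x)
      if (is.logical(v)) v else as.numeric(v)
    })
    # restore integer-valued counters
    for (nm in c("n_sides", "n_points"))
      if (!is.null(dims[[nm]])) dims[[nm]] <- as.integer(dims[[nm]])
    structure(list(
      residue_key = list(chain_id = gj$residue_key$chain_id,
                         seq_number = as.integer(gj$residue_key$seq_number),
                         insertion_code = gj$residue_key$insertion_code,
                         name3 = gj$residue_key$name3),
      spec = spec,
      frame = new_rigid_frame(num(gj$origin),
                              matrix(num(gj$axes), 3, 3)),
      dims = dims,
      part_colors = lapply(gj$part_colors, function(x) num(x)),
      accent_params = lapply(gj$accent_params, function(x)
        as.numeric(unlist(x))),
      degraded = isTRUE(gj$degraded),
      transparency = if (is.null(gj$transparency)) NULL else
        as.numeric(gj$transparency)), class = "glyph")
  })
  new_glyph_scene(glyphs, doc$source_label, as.integer(doc$model_index),
                  doc$selection_label,
                  global_alpha = if (is.null(doc$global_alpha)) NULL else
                    as.numeric(doc$global_alpha))
}
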