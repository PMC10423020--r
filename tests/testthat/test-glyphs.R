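# Glyph placement contracts, fallbacks, equivariance, determinism.

build_for <- function(code, ...) {
  res <- ideal_residue(code)
  build_glyph(res, glyph_spec_for(code), list(...))
}

test_that("spheres sit on CA for Gly and on CB for Ala", {
  gly <- build_for("GLY")
  expect_equal(gly$frame$origin, glyphdict:::atom_pos(ideal_residue("GLY"), "CA"))
  expect_equal(gly$dims$radius, 1.0)
  ala <- build_for("ALA")
  expect_equal(ala$frame$origin, glyphdict:::atom_pos(ideal_residue("ALA"), "CB"))
  expect_equal(ala$dims$radius, 1.3)
})

test_that("the proline cube is centered on CA", {
  pro <- build_for("PRO")
  expect_equal(pro$spec$shape, "CUBE")
  expect_equal(pro$frame$origin,
               glyphdict:::atom_pos(ideal_residue("PRO"), "CA"),
               tolerance = 1e-9)
  expect_equal(pro$dims$half_edge, 0.9)
})

test_that("pyramids point from CA at the polar atom", {
  for (code in c("SER", "THR", "CYS")) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    ca <- glyphdict:::atom_pos(res, "CA")
    polar <- glyphdict:::atom_pos(
      res, c(SER = "OG", THR = "OG1", CYS = "SG")[[code]])
    dir <- (polar - ca) / sqrt(sum((polar - ca)^2))
    expect_equal(g$frame$origin, ca)
    expect_equal(g$frame$axes[, 3], dir, tolerance = 1e-9)
    apex <- g$frame$origin + g$dims$height * g$frame$axes[, 3]
    expect_gt(sum((apex - g$frame$origin) * dir), 0)
    # apex reaches past the polar atom by the configured padding
    expect_equal(sqrt(sum((apex - ca)^2)),
                 sqrt(sum((polar - ca)^2)) + 0.5, tolerance = 1e-9)
    expect_equal(g$part_colors$TIP, g$spec$accent_color)
  }
})

test_that("ring prisms are centered on the ring centroid", {
  for (code in c("PHE", "TYR", "TRP", "HIS")) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    ring <- glyphdict:::RING_ATOMS[[glyphdict:::resolve_ring_key(code)]]
    pts <- t(vapply(ring, function(n) glyphdict:::atom_pos(res, n),
                    numeric(3)))
    expect_equal(g$frame$origin, colMeans(pts), tolerance = 1e-6)
    expect_equal(g$dims$n_sides, if (code == "HIS") 5L else 6L)
    # prism plane contains the ring: all ring atoms near z = 0 locally
    local_z <- sweep(pts, 2, g$frame$origin) %*% g$frame$axes[, 3]
    expect_lt(max(abs(local_z)), 0.1)
  }
})

test_that("hexagon elongation covers the whole side chain in-plane", {
  for (code in c("PHE", "TRP", "TYR")) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    sc <- glyphdict:::atom_positions(side_chain_atoms(res))
    local <- sweep(sc, 2, g$frame$origin) %*% g$frame$axes
    half_x <- g$dims$circumradius + g$dims$elongation
    expect_true(all(abs(local[, 1]) <= half_x + 1e-6))
  }
  # Trp spans two rings, so its hexagon must elongate
  trp <- build_for("TRP")
  expect_gt(trp$dims$elongation, 0)
})

test_that("the Tyr rim segment faces the hydroxyl", {
  res <- ideal_residue("TYR")
  g <- build_glyph(res, glyph_spec_for("TYR"))
  expect_true("RING_SEGMENT" %in% names(g$part_colors))
  oh <- glyphdict:::atom_pos(res, "OH")
  local <- as.numeric((oh - g$frame$origin) %*% g$frame$axes)
  ang <- atan2(local[2], local[1]) * 180 / pi
  expect_lt(min(abs(ang - g$accent_params$segment_center_angle),
                360 - abs(ang - g$accent_params$segment_center_angle)),
            1e-6)
})

test_that("the Met end band sits at the pole nearest the sulfur", {
  res <- ideal_residue("MET")
  g <- build_glyph(res, glyph_spec_for("MET"))
  sd <- glyphdict:::atom_pos(res, "SD")
  a <- g$dims$semi_axes[1]
  poles <- list(g$frame$origin + a * g$frame$axes[, 1],
                g$frame$origin - a * g$frame$axes[, 1])
  d <- vapply(poles, function(p) sqrt(sum((p - sd)^2)), numeric(1))
  chosen <- if (g$accent_params$band_pole > 0) 1 else 2
  expect_equal(chosen, which.min(d))
  expect_true("END_BAND" %in% names(g$part_colors))

  # same for selenomethionine via the SE atom on a MET-shaped spec
  mse <- ideal_residue("MSE")
  g2 <- build_glyph(mse, glyph_spec_for("MET"))
  expect_true("END_BAND" %in% names(g2$part_colors))
})

test_that("triangular prisms lie flat over the amide/carboxylate group", {
  tpl <- list(ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2"),
              ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"))
  for (code in names(tpl)) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    at <- tpl[[code]]
    term <- (glyphdict:::atom_pos(res, at[2]) +
               glyphdict:::atom_pos(res, at[3])) / 2
    expect_equal(g$frame$origin, term, tolerance = 1e-9)
    # prism axis is the group plane normal
    p1 <- glyphdict:::atom_pos(res, at[1])
    p2 <- glyphdict:::atom_pos(res, at[2])
    p3 <- glyphdict:::atom_pos(res, at[3])
    n <- glyphdict:::cross3(p2 - p1, p3 - p1)
    n <- n / sqrt(sum(n^2))
    expect_gt(abs(sum(g$frame$axes[, 3] * n)), 1 - 1e-9)
    # oxygen side carries the red half on amides; acids one darker face
    if (code %in% c("ASN", "GLN")) {
      expect_true(all(c("BASE_FACE_O", "BASE_FACE_N") %in%
                        names(g$part_colors)))
      local_o <- as.numeric((p2 - g$frame$origin) %*% g$frame$axes)
      expect_gt(local_o[1], 0)
    } else {
      expect_true("BASE_FACE" %in% names(g$part_colors))
    }
  }
})

test_that("cuboids run from CA to the charged end, darker face at the end", {
  for (code in c("LYS", "ARG")) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    ca <- glyphdict:::atom_pos(res, "CA")
    term <- if (code == "LYS") glyphdict:::atom_pos(res, "NZ") else
      colMeans(rbind(glyphdict:::atom_pos(res, "NH1"),
                     glyphdict:::atom_pos(res, "NH2"),
                     glyphdict:::atom_pos(res, "NE")))
    dir <- (term - ca) / sqrt(sum((term - ca)^2))
    expect_gt(sum(g$frame$axes[, 1] * dir), 1 - 1e-9)
    # END_FACE (+x face) center is nearer the terminal group than the -x one
    fpos <- g$frame$origin + g$dims$half_extents[1] * g$frame$axes[, 1]
    fneg <- g$frame$origin - g$dims$half_extents[1] * g$frame$axes[, 1]
    expect_lt(sum((fpos - term)^2), sum((fneg - term)^2))
    expect_true("END_FACE" %in% names(g$part_colors))
  }
})

test_that("ellipsoids and cuboids contain every side-chain heavy atom", {
  for (code in c("VAL", "LEU", "ILE", "MET", "LYS", "ARG")) {
    res <- ideal_residue(code)
    g <- build_glyph(res, glyph_spec_for(code))
    pts <- glyphdict:::atom_positions(side_chain_atoms(res))
    local <- sweep(pts, 2, g$frame$origin) %*% g$frame$axes
    if (g$spec$shape == "ELLIPSOID") {
      q <- rowSums(sweep(local, 2, g$dims$semi_axes, `/`)^2)
      expect_true(all(q <= 1 + 1e-6))
    } else {
      inside <- sweep(abs(local), 2, g$dims$half_extents + 1e-6, `<=`)
      expect_true(all(inside))
    }
  }
})

test_that("the non-standard star sits on CA with its normal along CA->CB", {
  res <- ideal_residue("MSE")
  g <- build_glyph(res, glyph_spec_for("MSE"))
  expect_equal(g$spec$shape, "STAR")
  ca <- glyphdict:::atom_pos(res, "CA")
  cb <- glyphdict:::atom_pos(res, "CB")
  expect_equal(g$frame$origin, ca)
  dir <- (cb - ca) / sqrt(sum((cb - ca)^2))
  expect_gt(sum(g$frame$axes[, 3] * dir), 1 - 1e-9)
  expect_equal(g$dims$inner_radius, 0.45 * g$dims$outer_radius)
})

test_that("every glyph frame is orthonormal with determinant +1", {
  sc <- build_scene(synthetic_peptide(ALL20_SEQ))
  for (g in sc$glyphs) expect_orthonormal(g$frame$axes)
})

test_that("missing atoms degrade to a sphere at CA; missing CA skips", {
  leu <- ideal_residue("LEU")
  leu$atoms <- leu$atoms[leu$atoms$name %in% c("N", "CA", "C", "O", "CB"), ]
  expect_warning(g <- build_glyph(leu, glyph_spec_for("LEU")), "degraded")
  expect_true(g$degraded)
  expect_equal(g$frame$origin, glyphdict:::atom_pos(leu, "CA"))
  expect_equal(g$part_colors$BODY, glyph_spec_for("LEU")$base_color)

  noca <- ideal_residue("PHE")
  noca$atoms <- noca$atoms[noca$atoms$name != "CA", ]
  expect_warning(g2 <- build_glyph(noca, glyph_spec_for("PHE")),
                 "no CA")
  expect_null(g2)
})

test_that("glyphs are equivariant under rigid motions", {
  set.seed(41)
  for (trial in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 20)
    for (code in template_residues()) {
      res <- ideal_residue(code)
      g0 <- build_glyph(res, glyph_spec_for(code))
      g1 <- build_glyph(transform_residue(res, rot, shift),
                        glyph_spec_for(code))
      expect_equal(g1$frame$origin,
                   as.numeric(rot %*% g0$frame$origin + shift),
                   tolerance = 1e-6)
      expect_equal(g1$dims[names(g1$dims) != "split_base"],
                   g0$dims[names(g0$dims) != "split_base"],
                   tolerance = 1e-6)
      if (g0$spec$shape %in% c("SPHERE")) next  # rotation-free shape
      expected_axes <- rot %*% g0$frame$axes
      for (j in 1:3) {
        dot <- abs(sum(g1$frame$axes[, j] * expected_axes[, j]))
        expect_gt(dot, 1 - 1e-6)
      }
    }
  }
})

test_that("glyph building is deterministic", {
  for (code in c("MET", "TRP", "ARG", "HIS")) {
    expect_identical(build_for(code), build_for(code))
  }
})

test_that("transparency overrides the alpha of every part color", {
  g <- build_for("MET", transparency = 0.4)
  for (col in g$part_colors) expect_equal(col[4], 0.4)
  expect_equal(g$transparency, 0.4)
})
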