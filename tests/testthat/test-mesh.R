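# Tessellation integrity and the OBJ/BILD/JSON exporters.

# minimal structural OBJ validation: grammar, index ranges, material refs
check_obj_file <- function(obj_path) {
  lines <- readLines(obj_path)
  mtl_file <- sub("^mtllib ", "", grep("^mtllib ", lines, value = TRUE))
  expect_length(mtl_file, 1)
  mtl_lines <- readLines(file.path(dirname(obj_path), mtl_file))
  materials <- sub("^newmtl ", "", grep("^newmtl ", mtl_lines,
                                        value = TRUE))
  nv <- 0L
  for (ln in lines) {
    if (grepl("^v ", ln)) {
      coords <- suppressWarnings(as.numeric(strsplit(ln, " +")[[1]][-1]))
      expect_length(coords, 3)
      expect_false(anyNA(coords))
      nv <- nv + 1L
    } else if (grepl("^f ", ln)) {
      idx <- suppressWarnings(as.integer(strsplit(ln, " +")[[1]][-1]))
      expect_length(idx, 3)
      expect_true(all(idx >= 1 & idx <= nv))
    } else if (grepl("^usemtl ", ln)) {
      expect_true(sub("^usemtl ", "", ln) %in% materials)
    } else {
      expect_match(ln, "^(#|o |mtllib |$)")
    }
  }
  invisible(nv)
}

test_that("the cube tessellates to the analytic 8-vertex, 12-face mesh", {
  g <- build_glyph(ideal_residue("PRO"), glyph_spec_for("PRO"))
  m <- tessellate_glyph(g)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_equal(mesh_volume(m), (2 * 0.9)^3, tolerance = 1e-9)
  expect_true(mesh_is_watertight(m))
})

test_that("icosphere meshes are topological spheres at every resolution", {
  g <- build_glyph(ideal_residue("GLY"), glyph_spec_for("GLY"))
  for (lev in 1:3) {
    m <- tessellate_glyph(g, resolution = lev)
    expect_equal(glyphdict:::mesh_euler_characteristic(m), 2)
    expect_true(mesh_is_watertight(m))
  }
})

test_that("ellipsoid mesh volume approaches (4/3)*pi*abc", {
  g <- build_glyph(ideal_residue("LEU"), glyph_spec_for("LEU"))
  exact <- 4 / 3 * pi * prod(g$dims$semi_axes)
  vdef <- mesh_volume(tessellate_glyph(g))
  expect_lt(abs(vdef - exact) / exact, 0.02)
  # refinement converges toward the closed form
  v2 <- mesh_volume(tessellate_glyph(g, 2))
  expect_lt(abs(vdef - exact) / exact, abs(v2 - exact) / exact)
})

test_that("all glyph meshes are watertight with positive signed volume", {
  sc <- build_scene(synthetic_peptide(paste0(ALL20_SEQ, "X")))
  expect_length(sc$glyphs, 21)
  for (g in sc$glyphs) {
    m <- tessellate_glyph(g)
    expect_true(mesh_is_watertight(m), label = g$residue_key$name3)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("accent parts appear on the faces that carry them", {
  met <- tessellate_glyph(build_glyph(ideal_residue("MET"),
                                      glyph_spec_for("MET")))
  expect_true("END_BAND" %in% met$face_part)
  tyr <- tessellate_glyph(build_glyph(ideal_residue("TYR"),
                                      glyph_spec_for("TYR")))
  expect_true("RING_SEGMENT" %in% tyr$face_part)
  ser <- tessellate_glyph(build_glyph(ideal_residue("SER"),
                                      glyph_spec_for("SER")))
  expect_true("TIP" %in% ser$face_part)
  asn <- tessellate_glyph(build_glyph(ideal_residue("ASN"),
                                      glyph_spec_for("ASN")))
  expect_true(all(c("BASE_FACE_O", "BASE_FACE_N") %in% asn$face_part))
  lys <- tessellate_glyph(build_glyph(ideal_residue("LYS"),
                                      glyph_spec_for("LYS")))
  expect_equal(sum(lys$face_part == "END_FACE"), 2)
})

test_that("unknown shapes are rejected", {
  g <- build_glyph(ideal_residue("PRO"), glyph_spec_for("PRO"))
  g$spec$shape <- "DODECAHEDRON"
  expect_error(tessellate_glyph(g), "unknown shape")
  expect_error(tessellate_glyph(build_glyph(ideal_residue("PRO"),
                                            glyph_spec_for("PRO")),
                                resolution = 0))
})

test_that("OBJ export writes valid, deterministic files", {
  sc <- build_scene(synthetic_peptide("ACDEF"))
  p1 <- tempfile(fileext = ".obj")
  write_obj(sc, p1)
  first <- readLines(p1)
  write_obj(sc, p1)  # re-run onto the same path
  expect_identical(readLines(p1), first)
  check_obj_file(p1)
  lines <- readLines(p1)
  expect_equal(sum(grepl("^o ", lines)), 5)
  expect_true("o A_1_ALA" %in% lines)

  # a one-cube scene has exactly 8 vertex lines
  cube_sc <- build_scene(synthetic_peptide("P"))
  pc <- tempfile(fileext = ".obj")
  write_obj(cube_sc, pc)
  expect_equal(sum(grepl("^v ", readLines(pc))), 8)

  # empty scene stays valid with zero object groups
  empty <- suppressWarnings(
    build_scene(glyphdict:::new_molecular_model(list(), 0L)))
  pe <- tempfile(fileext = ".obj")
  write_obj(empty, pe)
  expect_equal(sum(grepl("^o ", readLines(pe))), 0)
})

test_that("BILD export emits spheres, boxes and polygons with fixed format", {
  gly <- ideal_residue("GLY")
  gly$atoms[gly$atoms$name == "CA", c("x", "y", "z")] <- c(1, 2, 3)
  sc <- glyphdict:::new_glyph_scene(
    list(build_glyph(gly, glyph_spec_for("GLY"))), "t", 0L, "all")
  p <- tempfile(fileext = ".bild")
  write_bild(sc, p)
  lines <- readLines(p)
  expect_true(".sphere 1.000 2.000 3.000 1.000" %in% lines)

  # frame-aligned cube -> .box with min/max corners
  aligned <- make_residue("PRO", atoms_df(
    c("N", "CA", "C"), rbind(c(-1, 0, 0), c(0, 1, 0), c(1, 0, 0))))
  g <- build_glyph(aligned, glyph_spec_for("PRO"))
  expect_lt(max(abs(g$frame$axes - diag(3))), 1e-9)
  scb <- glyphdict:::new_glyph_scene(list(g), "t", 0L, "all")
  pb <- tempfile(fileext = ".bild")
  write_bild(scb, pb)
  expect_true(any(grepl("^\\.box -0\\.900 0\\.100 -0\\.900 0\\.900 1\\.900 0\\.900$",
                        readLines(pb))))

  # rotated cube falls back to 12 polygons
  g2 <- build_glyph(ideal_residue("PRO"), glyph_spec_for("PRO"))
  sc2 <- glyphdict:::new_glyph_scene(list(g2), "t", 0L, "all")
  p2 <- tempfile(fileext = ".bild")
  write_bild(sc2, p2)
  expect_equal(sum(grepl("^\\.polygon ", readLines(p2))), 12)

  # transparency precedes geometry
  sct <- glyphdict:::new_glyph_scene(
    list(build_glyph(gly, glyph_spec_for("GLY"),
                     list(transparency = 0.5))), "t", 0L, "all")
  pt <- tempfile(fileext = ".bild")
  write_bild(sct, pt)
  tl <- readLines(pt)
  itr <- grep("^\\.transparency 0\\.5", tl)
  isp <- grep("^\\.sphere", tl)
  expect_length(itr, 1)
  expect_lt(itr, isp)

  # determinism
  pt2 <- tempfile(fileext = ".bild")
  write_bild(sct, pt2)
  expect_identical(readLines(pt), readLines(pt2))
})

test_that("JSON scenes round-trip to equal objects", {
  sc <- build_scene(synthetic_peptide(paste0(ALL20_SEQ, "X")),
                    options = list(transparency = 0.7))
  p <- tempfile(fileext = ".json")
  write_scene_json(sc, p)
  back <- read_scene_json(p)
  expect_equal(back, sc)

  doc <- jsonlite::read_json(p)
  expect_equal(doc$schema_version, glyphdict:::SCENE_SCHEMA_VERSION)

  empty <- suppressWarnings(
    build_scene(glyphdict:::new_molecular_model(list(), 0L)))
  pe <- tempfile(fileext = ".json")
  write_scene_json(empty, pe)
  expect_length(read_scene_json(pe)$glyphs, 0)

  p2 <- tempfile(fileext = ".json")
  write_scene_json(sc, p2)
  expect_identical(readLines(p), readLines(p2))
})
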