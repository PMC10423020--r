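# Shared helpers: hand-written PDB text, bare residue records, rigid motions.

ALL20_SEQ <- "ACDEFGHIKLMNPQRSTVWY"

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, altloc = " ", icode = " ",
                          element = substr(name, 1, 1), het = FALSE) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resno, icode, x, y, z, occ, 0, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

ala_lines <- function(resno = 1, chain = "A", z0 = 0) {
  c(pdb_atom_line(1, "N", "ALA", chain, resno, 0, 0, z0),
    pdb_atom_line(2, "CA", "ALA", chain, resno, 1.458, 0, z0),
    pdb_atom_line(3, "C", "ALA", chain, resno, 2.004, 1.424, z0),
    pdb_atom_line(4, "O", "ALA", chain, resno, 1.251, 2.390, z0),
    pdb_atom_line(5, "CB", "ALA", chain, resno, 2.01, -0.77, z0 + 1.21))
}

# Residue record straight from a coordinate table (bypasses parsing).
make_residue <- function(name3, atoms_df, chain = "A", resno = 1L,
                         icode = "", polymer = TRUE) {
  atoms_df$serial <- seq_len(nrow(atoms_df))
  if (is.null(atoms_df$altloc)) atoms_df$altloc <- ""
  if (is.null(atoms_df$occupancy)) atoms_df$occupancy <- 1
  glyphdict:::new_residue_record(chain, resno, icode, name3, polymer,
                                 atoms_df)
}

atoms_df <- function(names, xyz, elements = substr(names, 1, 1)) {
  xyz <- rbind(xyz)
  data.frame(serial = seq_along(names), name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], altloc = "",
             occupancy = 1, stringsAsFactors = FALSE)
}

# Uniform random rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_residue <- function(residue, rot, shift) {
  xyz <- as.matrix(residue$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rot)
  residue$atoms$x <- xyz[, 1] + shift[1]
  residue$atoms$y <- xyz[, 2] + shift[2]
  residue$atoms$z <- xyz[, 3] + shift[3]
  residue
}

transform_model <- function(model, rot, shift) {
  model$residues <- lapply(model$residues, transform_residue, rot = rot,
                           shift = shift)
  model
}

expect_orthonormal <- function(axes, tol = 1e-6) {
  expect_lt(max(abs(crossprod(axes) - diag(3))), tol)
  expect_lt(abs(det(axes) - 1), tol)
}

scene_shapes <- function(scene)
  vapply(scene$glyphs, function(g) g$spec$shape, character(1))
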