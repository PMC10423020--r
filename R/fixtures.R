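# Synthetic structures: ideal residues, straight-axis peptides, ensembles
# and toy ligand complexes, so the whole pipeline is testable offline.
#
# Templates are generated by internal-coordinate (NeRF) construction from a
# compact Z-matrix per residue. Rings use equal bond lengths and planar
# dihedrals so closure is exact; chemical accuracy beyond bond lengths and
# planarity is irrelevant to glyph fitting and not pursued.

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D
# angle and the A-B-C-D dihedral (degrees).
nerf_place <- function(a, b, cpos, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- unitv(cpos - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.numeric(cpos + cbind(bc, m, n) %*% d2)
}

# Z-matrix rows: name, element, three reference atoms, bond, angle, dihedral.
zrow <- function(name, el, a, b, c, bond, angle, dihedral) {
  list(name = name, el = el, a = a, b = b, c = c, bond = bond,
       angle = angle, dihedral = dihedral)
}

side_chain_zmatrix <- function() {
  cb <- function() zrow("CB", "C", "N", "C", "CA", 1.521, 110.1, -122.6)
  list(
    GLY = list(),
    ALA = list(cb()),
    VAL = list(cb(),
               zrow("CG1", "C", "N", "CA", "CB", 1.52, 110.5, 180),
               zrow("CG2", "C", "N", "CA", "CB", 1.52, 110.5, -60)),
    LEU = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.53, 116.3, 180),
               zrow("CD1", "C", "CA", "CB", "CG", 1.52, 110.7, 180),
               zrow("CD2", "C", "CA", "CB", "CG", 1.52, 110.7, 60)),
    ILE = list(cb(),
               zrow("CG1", "C", "N", "CA", "CB", 1.53, 110.4, 180),
               zrow("CG2", "C", "N", "CA", "CB", 1.53, 110.5, -60),
               zrow("CD1", "C", "CA", "CB", "CG1", 1.51, 113.8, 180)),
    MET = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("SD", "S", "CA", "CB", "CG", 1.80, 112.7, 180),
               zrow("CE", "C", "CB", "CG", "SD", 1.79, 100.9, 180)),
    MSE = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("SE", "SE", "CA", "CB", "CG", 1.95, 112.7, 180),
               zrow("CE", "C", "CB", "CG", "SE", 1.95, 98.0, 180)),
    PHE = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180),
               zrow("CD1", "C", "CA", "CB", "CG", 1.39, 120, 90),
               zrow("CE1", "C", "CB", "CG", "CD1", 1.39, 120, 180),
               zrow("CZ", "C", "CG", "CD1", "CE1", 1.39, 120, 0),
               zrow("CE2", "C", "CD1", "CE1", "CZ", 1.39, 120, 0),
               zrow("CD2", "C", "CE1", "CZ", "CE2", 1.39, 120, 0)),
    TYR = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180),
               zrow("CD1", "C", "CA", "CB", "CG", 1.39, 120, 90),
               zrow("CE1", "C", "CB", "CG", "CD1", 1.39, 120, 180),
               zrow("CZ", "C", "CG", "CD1", "CE1", 1.39, 120, 0),
               zrow("CE2", "C", "CD1", "CE1", "CZ", 1.39, 120, 0),
               zrow("CD2", "C", "CE1", "CZ", "CE2", 1.39, 120, 0),
               zrow("OH", "O", "CD1", "CE1", "CZ", 1.38, 120, 180)),
    TRP = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180),
               zrow("CD1", "C", "CA", "CB", "CG", 1.40, 122, 90),
               zrow("NE1", "N", "CB", "CG", "CD1", 1.40, 108, 180),
               zrow("CE2", "C", "CG", "CD1", "NE1", 1.40, 108, 0),
               zrow("CD2", "C", "CD1", "NE1", "CE2", 1.40, 108, 0),
               zrow("CE3", "C", "NE1", "CE2", "CD2", 1.40, 120, 180),
               zrow("CZ3", "C", "CE2", "CD2", "CE3", 1.40, 120, 0),
               zrow("CH2", "C", "CD2", "CE3", "CZ3", 1.40, 120, 0),
               zrow("CZ2", "C", "CE3", "CZ3", "CH2", 1.40, 120, 0)),
    SER = list(cb(),
               zrow("OG", "O", "N", "CA", "CB", 1.42, 110.8, 180)),
    THR = list(cb(),
               zrow("OG1", "O", "N", "CA", "CB", 1.43, 109.6, 180),
               zrow("CG2", "C", "N", "CA", "CB", 1.52, 110.3, -60)),
    CYS = list(cb(),
               zrow("SG", "S", "N", "CA", "CB", 1.81, 114.0, 180)),
    ASN = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 112.6, 180),
               zrow("OD1", "O", "CA", "CB", "CG", 1.23, 120.8, 0),
               zrow("ND2", "N", "CA", "CB", "CG", 1.33, 116.4, 180)),
    GLN = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("CD", "C", "CA", "CB", "CG", 1.52, 112.6, 180),
               zrow("OE1", "O", "CB", "CG", "CD", 1.23, 120.8, 0),
               zrow("NE2", "N", "CB", "CG", "CD", 1.33, 116.4, 180)),
    ASP = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 112.6, 180),
               zrow("OD1", "O", "CA", "CB", "CG", 1.25, 118.4, 0),
               zrow("OD2", "O", "CA", "CB", "CG", 1.25, 118.4, 180)),
    GLU = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("CD", "C", "CA", "CB", "CG", 1.52, 112.6, 180),
               zrow("OE1", "O", "CB", "CG", "CD", 1.25, 118.4, 0),
               zrow("OE2", "O", "CB", "CG", "CD", 1.25, 118.4, 180)),
    HIS = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180),
               zrow("ND1", "N", "CA", "CB", "CG", 1.37, 122.7, 90),
               zrow("CE1", "C", "CB", "CG", "ND1", 1.37, 108, 180),
               zrow("NE2", "N", "CG", "ND1", "CE1", 1.37, 108, 0),
               zrow("CD2", "C", "ND1", "CE1", "NE2", 1.37, 108, 0)),
    LYS = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("CD", "C", "CA", "CB", "CG", 1.52, 111.3, 180),
               zrow("CE", "C", "CB", "CG", "CD", 1.52, 111.9, 180),
               zrow("NZ", "N", "CG", "CD", "CE", 1.49, 111.7, 180)),
    ARG = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180),
               zrow("CD", "C", "CA", "CB", "CG", 1.52, 111.3, 180),
               zrow("NE", "N", "CB", "CG", "CD", 1.46, 112.0, 180),
               zrow("CZ", "C", "CG", "CD", "NE", 1.33, 124.2, 180),
               zrow("NH1", "N", "CD", "NE", "CZ", 1.33, 120, 0),
               zrow("NH2", "N", "CD", "NE", "CZ", 1.33, 120, 180)),
    PRO = list(cb(),
               zrow("CG", "C", "N", "CA", "CB", 1.50, 104.5, 30),
               zrow("CD", "C", "CA", "CB", "CG", 1.50, 106.0, -35))
  )
}

#' Supported fixture residue codes
#'
#' @return The 20 standard codes plus `"MSE"` (the non-standard path).
#' @export
template_residues <- function() names(side_chain_zmatrix())

#' Build a residue with ideal coordinates in a canonical local frame
#'
#' Backbone N/CA/C/O plus the residue's heavy side-chain atoms, generated
#' from internal coordinates (canonical bond lengths, tetrahedral/trigonal
#' angles, trans dihedrals, planar rings).
#'
#' @param name3 Residue code in [template_residues()].
#' @param chain_id,seq_number,insertion_code Residue key (defaults `A`, 1,
#'   blank).
#' @return A `residue_record`.
#' @export
ideal_residue <- function(name3, chain_id = "A", seq_number = 1L,
                          insertion_code = "") {
  name3 <- toupper(name3)
  zm <- side_chain_zmatrix()[[name3]]
  if (is.null(zm)) stop("no ideal-coordinate template for: ", name3)
  pos <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0),
    C = c(1.458, 0, 0) + 1.525 * c(cos(69 * pi / 180),
                                   sin(69 * pi / 180), 0))
  pos$O <- nerf_place(pos$N, pos$CA, pos$C, 1.231, 120.5, 180)
  el <- c(N = "N", CA = "C", C = "C", O = "O")
  for (row in zm) {
    pos[[row$name]] <- nerf_place(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                                  row$bond, row$angle, row$dihedral)
    el[row$name] <- row$el
  }
  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  atoms <- data.frame(serial = seq_along(nm), name = nm,
                      element = unname(el[nm]), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], altloc = "", occupancy = 1,
                      stringsAsFactors = FALSE)
  new_residue_record(chain_id, seq_number, insertion_code, name3,
                     is_polymer = TRUE, atoms = atoms)
}

ONE_TO_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
                  X = "MSE")

#' Coordinate jitter specification for fixtures
#'
#' @param seed RNG seed (integer).
#' @param sigma Isotropic per-coordinate Gaussian jitter, Angstrom (>= 0).
#' @return A `perturb_spec`.
#' @export
perturb_spec <- function(seed, sigma) {
  stopifnot(is.finite(sigma), sigma >= 0)
  structure(list(seed = as.integer(seed), sigma = sigma),
            class = "perturb_spec")
}

#' Generate a synthetic straight-axis peptide
#'
#' Residues are placed with their alpha carbons on a straight line at the
#' given spacing. No peptide bonding is attempted: fixtures exercise glyph
#' geometry, not chemistry, and the straight layout keeps zone constructions
#' solvable in closed form. The one-letter alphabet is the standard 20 plus
#' `X`/`x` for selenomethionine (MSE), the non-standard path.
#'
#' @param sequence One-letter sequence string.
#' @param spacing CA-CA spacing along the axis, Angstrom.
#' @param perturb Optional [perturb_spec()] adding seeded isotropic jitter.
#' @param chain_id Chain identifier for all residues.
#' @return A `molecular_model`.
#' @export
synthetic_peptide <- function(sequence, spacing = 5.0, perturb = NULL,
                              chain_id = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0) stop("empty sequence")
  codes <- ONE_TO_THREE[letters1]
  if (anyNA(codes))
    stop("unknown sequence letter(s): ",
         paste(unique(letters1[is.na(codes)]), collapse = ", "))
  residues <- vector("list", length(codes))
  serial <- 0L
  for (i in seq_along(codes)) {
    r <- ideal_residue(codes[i], chain_id = chain_id, seq_number = i)
    shift <- c((i - 1) * spacing - 1.458, 0, 0)  # CA onto the axis
    r$atoms$x <- r$atoms$x + shift[1]
    r$atoms$y <- r$atoms$y + shift[2]
    r$atoms$z <- r$atoms$z + shift[3]
    r$atoms$serial <- serial + seq_len(nrow(r$atoms))
    serial <- serial + nrow(r$atoms)
    residues[[i]] <- r
  }
  if (!is.null(perturb) && perturb$sigma > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(perturb$seed)
    for (i in seq_along(residues)) {
      n <- nrow(residues[[i]]$atoms)
      jit <- matrix(stats::rnorm(3 * n, 0, perturb$sigma), ncol = 3)
      residues[[i]]$atoms$x <- residues[[i]]$atoms$x + jit[, 1]
      residues[[i]]$atoms$y <- residues[[i]]$atoms$y + jit[, 2]
      residues[[i]]$atoms$z <- residues[[i]]$atoms$z + jit[, 3]
    }
  }
  new_molecular_model(residues, 0L)
}

#' Generate a peptide-plus-ligand toy complex
#'
#' Appends a single-atom HETATM ligand (`LIG`, chain `L`) to a synthetic
#' peptide, placed so that exactly the residues at `contact_indices` have a
#' heavy atom within `cutoff` Angstrom of it. The position is solved by a
#' deterministic grid search over the peptide plane; an explicit
#' `ligand_position` is verified instead of searched.
#'
#' @param sequence One-letter peptide sequence.
#' @param contact_indices Integer residue indices (1-based) that must be the
#'   exact zone-selection result, possibly empty.
#' @param ligand_position Optional explicit 3-vector for the ligand.
#' @param cutoff Zone cutoff used for the construction, Angstrom.
#' @param spacing CA-CA spacing of the peptide.
#' @return A `molecular_model` (peptide residues plus the ligand).
#' @export
synthetic_complex <- function(sequence, contact_indices = integer(),
                              ligand_position = NULL, cutoff = 8,
                              spacing = 5.0) {
  pep <- synthetic_peptide(sequence, spacing = spacing)
  n <- length(pep$residues)
  contact_indices <- sort(unique(as.integer(contact_indices)))
  if (length(contact_indices) && (min(contact_indices) < 1 ||
                                  max(contact_indices) > n))
    stop("contact indices out of range")
  target <- vapply(pep$residues[contact_indices], residue_key, character(1))

  coords <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- heavy_atoms(pep$residues[[i]])
    cbind(a$x, a$y, a$z, i)
  }))
  zone_at <- function(p) {
    d2 <- (coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2 +
      (coords[, 3] - p[3])^2
    sort(unique(coords[d2 <= cutoff^2 + 1e-9, 4]))
  }
  if (is.null(ligand_position)) {
    if (length(contact_indices) == 0) {
      ligand_position <- c(0, 1000, 0)
      if (length(zone_at(ligand_position)))
        stop("infeasible ligand placement")
    } else {
      cas <- spacing * (contact_indices - 1)
      found <- FALSE
      for (y in as.vector(rbind(seq(0.5, 30, 0.25), -seq(0.5, 30, 0.25)))) {
        for (x in seq(min(cas) - 5, max(cas) + 5, 0.25)) {
          if (identical(zone_at(c(x, y, 0)), as.numeric(contact_indices))) {
            ligand_position <- c(x, y, 0)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found)
        stop("infeasible ligand placement for contacts {",
             paste(contact_indices, collapse = ","), "}")
    }
  } else if (!identical(zone_at(ligand_position),
                        as.numeric(contact_indices))) {
    stop("ligand_position does not realize the requested contact set")
  }

  max_serial <- max(vapply(pep$residues, function(r) max(r$atoms$serial),
                           numeric(1)))
  lig <- new_residue_record("L", 1L, "", "LIG", is_polymer = FALSE,
    atoms = data.frame(serial = max_serial + 1, name = "C1", element = "C",
                       x = ligand_position[1], y = ligand_position[2],
                       z = ligand_position[3], altloc = "", occupancy = 1,
                       stringsAsFactors = FALSE))
  new_molecular_model(c(pep$residues, list(lig)), 0L)
}

#' Write a model or ensemble as a fixed-width PDB file
#'
#' Ensembles emit one MODEL/ENDMDL block per frame. Reading the file back
#' with [read_structure()] reproduces residue keys, atom names and
#' coordinates to the PDB 8.3 coordinate precision.
#'
#' @param x A `molecular_model` or `structure_ensemble`.
#' @param path Output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "molecular_model")) {
    writeLines(c(pdb_block_lines(x), "END"), path)
  } else if (inherits(x, "structure_ensemble")) {
    out <- character()
    for (i in seq_along(x$models)) {
      out <- c(out, sprintf("MODEL     %4d", i),
               pdb_block_lines(x$models[[i]]), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    stop("write_pdb expects a molecular_model or structure_ensemble")
  }
  invisible(path)
}

pdb_block_lines <- function(model) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  rows <- do.call(rbind, lapply(model$residues, function(r) {
    a <- r$atoms
    data.frame(type = if (r$is_polymer) "ATOM" else "HETATM",
               eleno = a$serial, elety = a$name, alt = a$altloc,
               resid = r$name3, chain = r$chain_id, resno = r$seq_number,
               insert = r$insertion_code, x = a$x, y = a$y, z = a$z,
               o = a$occupancy, elesy = a$element,
               stringsAsFactors = FALSE)
  }))
  rows$alt[rows$alt == ""] <- NA
  rows$insert[rows$insert == ""] <- NA
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = tmp, xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
    type = rows$type, eleno = rows$eleno, elety = rows$elety,
    alt = rows$alt, resid = rows$resid, chain = rows$chain,
    resno = rows$resno, insert = rows$insert, o = rows$o,
    b = rep(0, nrow(rows)), elesy = rows$elesy, end = FALSE))
  readLines(tmp, warn = FALSE)
}
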