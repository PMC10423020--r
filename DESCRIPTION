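Package: glyphdict
Title: A Visual Dictionary of Residue Glyphs for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Renders protein structures as a coarse visual grammar: every
    amino-acid residue is classified into one of five physicochemical
    families (hydrophobic, neutral polar, positively charged, negatively
    charged, and proline) and replaced by a colored geometric glyph --
    sphere, ellipsoid, hexagonal or pentagonal prism, pyramid, triangular
    prism, cuboid, cube, or star -- fitted to the residue's heavy-atom
    coordinates. Reads single- and multi-MODEL PDB files, supports
    residue-list and distance-zone selections, histidine protonation
    states, and exports portable 3D scenes as Wavefront OBJ/MTL, Chimera
    BILD, or JSON for display in any molecular or generic 3D viewer.
    Includes a synthetic-structure generator (ideal residues, peptides,
    ensembles, toy ligand complexes) so the whole pipeline is testable
    offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
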