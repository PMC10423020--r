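---
title: "Residue glyphs: model, placement rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue glyphs: model, placement rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyphdict)
```

## The representation

glyphdict implements a coarse visual grammar for proteins: one colored
geometric primitive per residue, fitted to that residue's heavy-atom
coordinates. The premise is that a side chain's *family* (hydrophobic,
neutral polar, positively charged, negatively charged, or proline) and its
*rough geometry* (globular, elongated, planar-aromatic, directional-polar)
carry most of the information a structural biologist scans for, and that a
dictionary of shapes and colors communicates both faster than sticks or
surfaces. The package is renderer-agnostic: it fits glyphs and exports
portable scenes (OBJ/MTL, Chimera BILD, JSON), to be overlaid on a ribbon
or stick representation in whatever viewer the user prefers.

The pipeline is `read_structure()` (PDB, multi-MODEL) →
`build_scene()`/`build_trajectory_scenes()` over a selection →
`write_obj()`/`write_bild()`/`write_scene_json()`. Everything is
deterministic: identical inputs give bitwise-identical glyph parameters and
byte-identical export files.

## Classification and colors

`classify_residue()` is a total function: the 20 standard codes partition
into families of sizes 8 (Gly, Ala, Val, Leu, Ile, Met, Phe, Trp),
7 (Ser, Thr, Cys, Asn, Gln, Tyr, His), 2 (Lys, Arg), 2 (Asp, Glu) and
1 (Pro); anything else is non-standard and draws the orange star. Two
borderline placements deserve a note. Glycine has no side chain but sits
with the small aliphatics and gets a sphere on its Cα. Tyrosine is
physicochemically a neutral polar residue, yet geometrically an aromatic:
it keeps the hexagonal ring prism and signals its polarity through the red
rim segment at the hydroxyl. Histidine's pentagon recolors as a whole with
protonation state rather than carrying an accent, because the state changes
the residue's charge globally.

The palette fixes RGBA constants for color *names* that are conventional in
biochemistry (green hydrophobic, dark blue positive, red negative, yellow
sulfur, aquamarine neutral histidine, orange non-standard); darker accent
shades keep the hue and lower the value so base and accent read as one
object. Bodies of the neutral-polar pyramids and amide prisms are gray — a
deliberately quiet color, since their information lives in the accent
(tip or base face). The whole table, constants included, is editable: it
ships as a YAML config (`write_dictionary()` / `read_dictionary()`,
default in `inst/extdata/dictionary.yaml`), and only that table defines
the residue → glyph mapping.

Histidine protonation resolves in a fixed order: an explicit user override;
else force-field name variants (HID/HIE/HSD/HSE neutral tautomers, HIP/HSP
protonated); else explicit hydrogens on the imidazole nitrogens (both ND1
and NE2 → protonated, exactly one → neutral, none while other hydrogens
exist → deprotonated). A heavy-atom-only HIS defaults to neutral, the
dominant state at physiological pH; a deprotonated histidine is therefore
reachable only through explicit hydrogens or an override, since standard
PDB naming cannot express it.

## Geometric fits

All fits use heavy atoms only. Hydrogens are parsed and retained (they
drive protonation detection) but never enter a frame, extent or distance.

- **Principal frames** (`principal_frame()`): eigenvectors of the point
  covariance ordered by decreasing eigenvalue; extents are half-ranges of
  the point projections, so ellipsoids and cuboids contain every atom by
  construction once padding is added. Sign conventions make output unique:
  the leading axis points along the caller's Cα→centroid direction, the
  second axis has its largest component positive, the third completes a
  right-handed frame. The sign choices are cosmetic for closed shapes but
  guarantee reproducible files.
- **Ring planes** (`ring_geometry()`): centroid, least-squares normal
  (smallest-eigenvalue direction) and circumradius of the named ring atoms;
  the normal's global sign is fixed toward +z, then +y, then +x.
- **Placement**: spheres sit on Cα (Gly) or Cβ (Ala); pyramids sit on Cα
  with the local z axis through the polar atom and height reaching past it;
  ring prisms overlap the ring plane, hexagons elongating along the first
  in-plane principal axis until the whole side chain is covered (this is
  how one prism spans tryptophan's indole); amide/carboxylate prisms lie
  flat over the sp² group with the base face on the two terminal polar
  atoms, the oxygen side defining +x so the red/blue split is oriented;
  cuboids run from Cα to the terminal charged group with the darker end
  face there; the proline cube rides a backbone (N, Cα, C) frame so it
  rotates rigidly with the structure; the star's plane normal follows
  Cα→Cβ (falling back to +z when no Cβ exists — the orientation of a star
  on Cα is not otherwise defined by the grammar).

## Sizing constants

The grammar states that elongation follows "the dimensions of the side
chain" without quantifying it, so all paddings are package constants,
collected in `glyph_sizing()` (Å): ellipsoid padding 0.8 with a 0.8
minimum semi-axis, ring padding 0.6, prism half-thickness 0.5, pyramid
base half-width 1.0 and 0.5 beyond the polar atom, cuboid padding 0.7,
cube half-edge 0.9, Gly/Ala sphere radii 1.0/1.3, star outer radius 1.2
(inner 0.45×, half-thickness 0.3), Met band over the outer 20% of the
major axis, pyramid tip accent 30% of the height, Tyr rim segment ±30°.
They were chosen once, by eye against the ideal fixtures, to cover the
side chain snugly without swallowing neighbors at typical packing
distances; every one is overridable through the `sizing` option.

## Selections and trajectories

Zone selection follows common viewer semantics: a polymer residue is
selected iff *any* of its heavy atoms lies within the cutoff (inclusive) of
*any* reference atom, references themselves excluded — atom-wise rather
than residue-center-wise, which is the stricter and more common reading.
On ensembles the zone re-evaluates per frame by default, since
neighborhoods along a trajectory are snapshot-specific; `frozen = TRUE`
pins the frame-0 residue list for comparisons across frames.

## Structure input

Parsing is delegated to bio3d behind the package's interface; the package
owns MODEL-block splitting (so ragged ensembles warn and intersect to the
shared residues), deterministic ordering (chain, sequence number,
insertion code), polymer flagging (HETATMs keep polymer status only for
standard or known modified codes such as MSE; waters never) and altloc
resolution (highest occupancy wins, ties to the alphabetically smallest
altloc — a common convention the source format leaves open). Coordinates
stay in the file's Å frame; nothing is recentered. mmCIF is out of scope
for this version; the reader sits behind one function so a second dialect
can be added.

When a shape rule cannot find its atoms, the glyph *degrades* to a sphere
at Cα in the family base color and is flagged, so partial side chains stay
visible rather than silently vanishing; a residue without Cα is skipped
with a warning. Degraded glyphs are counted in the CLI summary.

## Meshes and export

Spheres and ellipsoids tessellate as subdivided icosahedra; prisms,
pyramids, cuboids and stars are exact polyhedra. Every mesh is closed and
consistently wound (positive signed volume), which the tests verify
edge-by-edge. The default subdivision level is 3: the inscribed level-2
icosphere under-estimates an ellipsoid's volume by about 3%, level 3 is
within 1% of (4/3)πabc, and at a few hundred triangles per residue the
files stay small. OBJ colors go through one MTL material per distinct RGBA
(OBJ has no per-face color standard); BILD numbers are fixed at three
decimals, and its `.transparency` value is 1 − alpha per that format's
convention. The JSON export is a schema-versioned dump of glyph parameters
(no meshes) and round-trips to an equal scene.

## Synthetic fixtures

`ideal_residue()` builds every standard residue (plus MSE) from internal
coordinates — canonical bond lengths, tetrahedral/trigonal angles, trans
dihedrals, rings with equal bonds and planar dihedrals so closure is
exact. `synthetic_peptide()` places residues with Cα on a straight axis
at 5 Å spacing: no peptide bonds are attempted, because the fixtures
exercise glyph geometry and zone arithmetic, not chemistry, and the
straight layout makes contact constructions solvable. `synthetic_complex()`
adds a one-atom ligand positioned by grid search so that *exactly* a
requested set of residues falls inside the 8 Å zone. What passing tests on
these fixtures show is that the classification, fitting, selection and
export machinery is correct; what they do not show is robustness to real
crystallographic pathologies (missing density, clashing altloc networks,
chain breaks) beyond the degraded-glyph fallback, nor aesthetic quality on
dense real packings.

## Numerical choices and limitations

Problem sizes in the test suite and acceptance script (20–21-residue
peptides, 100 random point sets, 3 random rigid motions over the 21
templates) were chosen as the smallest sizes that exercise every code path;
all checks are at 1e-6 or tighter except where a format's printed precision
(PDB 8.3) caps round-trips at 1e-3 Å.

Known limitations: no glyphs for ligands, solvents or ions (the grammar
does not define them yet — zones make them visible through their
neighborhood instead); no secondary-structure ribbons (overlay in a
viewer); no mmCIF; degenerate inputs (a side chain collapsed onto Cα, a
zero-area ring) degrade or error loudly rather than guessing.
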