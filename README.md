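# glyphdict

**glyphdict** renders protein structures as a *visual dictionary* of residue
glyphs: every amino-acid side chain is replaced by a single colored geometric
primitive that keeps the residue's rough shape and announces its
physicochemical family at a glance. Hydrophobic patches, charged rings and
polar contacts that drown in a full-atom view become immediately legible,
while a ribbon or stick overlay in any viewer restores the atomic detail.
It is aimed at structural biologists and modelers inspecting binding sites,
interfaces and molecular-dynamics snapshots.

## The grammar

Residues are partitioned into five families, each with its own color code,
and mapped onto shapes fitted to the residue's own heavy-atom coordinates:

| family (count)      | residues                              | glyph |
|---------------------|----------------------------------------|-------|
| hydrophobic (8)     | Gly, Ala                               | green sphere on Cα (Gly) / Cβ (Ala) |
|                     | Val, Leu, Ile, Met                     | green ellipsoid along the side chain's principal axes (Met: yellow band at the sulfur pole) |
|                     | Phe, Trp                               | green hexagonal prism over the aromatic ring, elongated to cover the side chain |
| neutral polar (7)   | Ser, Thr, Cys                          | pyramid centered on Cα, vertex at the polar atom (red hydroxyl / yellow thiol tip) |
|                     | Asn, Gln                               | triangular prism flat over the amide plane, base face split red (O) / dark blue (N) |
|                     | Tyr                                    | hexagonal prism over the ring, red rim segment at the hydroxyl |
|                     | His                                    | pentagonal prism over the imidazole: aquamarine neutral, dark blue protonated, red deprotonated |
| positive (2)        | Lys, Arg                               | dark-blue cuboid from Cα to the amino/guanidinium group, darker face at the charged end |
| negative (2)        | Asp, Glu                               | red triangular prism over the carboxylate, darker-red base face |
| proline (1)         | Pro                                    | small gray cube centered on Cα |
| non-standard        | MSE, ...                               | orange star on Cα |

The geometric fits are classical: principal-axis frames come from the
eigendecomposition of the side-chain covariance (extents are projection
half-ranges), ring planes from a least-squares (smallest-eigenvalue) fit,
and all dimensions are the residue's own extents plus fixed paddings
(`glyph_sizing()`). All fits use heavy atoms only and are deterministic and
rigid-motion equivariant.

## Worked example

```r
library(glyphdict)

# a 20-residue synthetic peptide covering every family
pep <- synthetic_peptide("ACDEFGHIKLMNPQRSTVWY")
scene <- build_scene(pep)
scene
#> <glyph_scene>  model 0, selection 'all': 20 glyph(s)
summary(scene)$shapes
#> shapes
#>             CUBE           CUBOID        ELLIPSOID  HEXAGONAL_PRISM
#>                1                2                4                3
#> PENTAGONAL_PRISM          PYRAMID           SPHERE TRIANGULAR_PRISM
#>                1                3                2                4

# residues within 8 Å of a bound ligand, written for any OBJ viewer
cmplx <- synthetic_complex("ACDEFGHIKL", contact_indices = c(3, 4))
write_pdb(cmplx, "complex.pdb")
render_structure("complex.pdb", select = "zone:LIG:8.0",
                 out = "site.obj")
```

The scene summary says the 20 standard residues produced one glyph each —
two spheres (Gly, Ala), four ellipsoids (Val/Leu/Ile/Met), three hexagonal
prisms (Phe/Trp/Tyr), one pentagonal prism (His), three pyramids
(Ser/Thr/Cys), four triangular prisms (Asn/Gln/Asp/Glu), two cuboids
(Lys/Arg) and the proline cube — with zero degraded fallbacks. The zone
render keeps exactly residues 3 and 4, the contacts the toy complex was
constructed to have.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/glyphs.R render complex.pdb --select zone:LIG:8.0 \
    --out site.bild --summary
# model=0 rendered=2 degraded=0 skipped=0
```

Multi-MODEL files (e.g. MD snapshots) yield one scene per frame; zone
selections re-evaluate each frame by default or can be frozen to frame 0.

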