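glyph_dictionary:
- name3: GLY
  class: HYDROPHOBIC
  shape: SPHERE
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: sphere_gly
- name3: ALA
  class: HYDROPHOBIC
  shape: SPHERE
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: sphere_ala
- name3: VAL
  class: HYDROPHOBIC
  shape: ELLIPSOID
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: ellipsoid
- name3: LEU
  class: HYDROPHOBIC
  shape: ELLIPSOID
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: ellipsoid
- name3: ILE
  class: HYDROPHOBIC
  shape: ELLIPSOID
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: ellipsoid
- name3: MET
  class: HYDROPHOBIC
  shape: ELLIPSOID
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: END_BAND
  sizing_rule: ellipsoid
  accent_color:
  - 1.0
  - 0.85
  - 0.0
  - 1.0
- name3: PHE
  class: HYDROPHOBIC
  shape: HEXAGONAL_PRISM
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: ring_prism
- name3: TRP
  class: HYDROPHOBIC
  shape: HEXAGONAL_PRISM
  base_color:
  - 0.0
  - 0.8
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: ring_prism
- name3: SER
  class: NEUTRAL_POLAR
  shape: PYRAMID
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: TIP
  sizing_rule: pyramid
  accent_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
- name3: THR
  class: NEUTRAL_POLAR
  shape: PYRAMID
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: TIP
  sizing_rule: pyramid
  accent_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
- name3: CYS
  class: NEUTRAL_POLAR
  shape: PYRAMID
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: TIP
  sizing_rule: pyramid
  accent_color:
  - 1.0
  - 0.85
  - 0.0
  - 1.0
- name3: ASN
  class: NEUTRAL_POLAR
  shape: TRIANGULAR_PRISM
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: BASE_FACE
  sizing_rule: tri_prism
  accent_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
  accent_color2:
  - 0.0
  - 0.0
  - 0.55
  - 1.0
- name3: GLN
  class: NEUTRAL_POLAR
  shape: TRIANGULAR_PRISM
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: BASE_FACE
  sizing_rule: tri_prism
  accent_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
  accent_color2:
  - 0.0
  - 0.0
  - 0.55
  - 1.0
- name3: TYR
  class: NEUTRAL_POLAR
  shape: HEXAGONAL_PRISM
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: RING_SEGMENT
  sizing_rule: ring_prism
  accent_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
- name3: HIS
  class: NEUTRAL_POLAR
  shape: PENTAGONAL_PRISM
  base_color:
  - 0.3
  - 0.9
  - 0.75
  - 1.0
  accent_part: NONE
  sizing_rule: ring_prism
- name3: LYS
  class: POSITIVE
  shape: CUBOID
  base_color:
  - 0.0
  - 0.0
  - 0.55
  - 1.0
  accent_part: END_FACE
  sizing_rule: cuboid
  accent_color:
  - 0.0
  - 0.0
  - 0.35
  - 1.0
- name3: ARG
  class: POSITIVE
  shape: CUBOID
  base_color:
  - 0.0
  - 0.0
  - 0.55
  - 1.0
  accent_part: END_FACE
  sizing_rule: cuboid
  accent_color:
  - 0.0
  - 0.0
  - 0.35
  - 1.0
- name3: ASP
  class: NEGATIVE
  shape: TRIANGULAR_PRISM
  base_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
  accent_part: BASE_FACE
  sizing_rule: tri_prism
  accent_color:
  - 0.55
  - 0.0
  - 0.0
  - 1.0
- name3: GLU
  class: NEGATIVE
  shape: TRIANGULAR_PRISM
  base_color:
  - 0.85
  - 0.0
  - 0.0
  - 1.0
  accent_part: BASE_FACE
  sizing_rule: tri_prism
  accent_color:
  - 0.55
  - 0.0
  - 0.0
  - 1.0
- name3: PRO
  class: PROLINE
  shape: CUBE
  base_color:
  - 0.6
  - 0.6
  - 0.6
  - 1.0
  accent_part: NONE
  sizing_rule: cube
- name3: '*'
  class: NONSTANDARD
  shape: STAR
  base_color:
  - 1.0
  - 0.55
  - 0.0
  - 1.0
  accent_part: NONE
  sizing_rule: star
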