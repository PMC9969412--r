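selection:
  peptide:
    resnames:
    - LEU
    - ALA
    - PRO
    - PHE
    - GLY
    - VAL
    - ILE
    backbone:
    - CA
    - 'N'
    - HN
    - H
    - O
    - C
    ellipse: ^CA$
    donor: ^N$
    donor_h: ^(HN|H)$
    acceptor: ^O$
    sidechain: ^C[BGDEZ]
  lipid:
    resnames:
    - PLIP
    - POPC
    - POPE
    - DOPC
    headgroup_n: ^(NC3|N4|N)$
    phosphate: ^(P|P8|PO4)$
    ester: ^(EST[12]|C1A|C1B|C2[12]|C3[12])$
    tail: ^(T[0-9]|C[2-9][0-9]*|C1[0-9])$
  solvent:
    resnames:
    - SOL
    - HOH
    - WAT
    - W
    - TIP3
residues:
  polarity:
  - apolar
  - apolar
  - apolar
  - polar
  - polar
  - apolar
  - apolar
  anchors:
  - 1
  - 3
  - 4
  - 5
  - 6
  - 8
  - 9
  - 10
  reporters:
  - 4
  - 9
  turns:
  - 5
  - 10
thresholds:
  rmsd_closed: 0.2
  hb_dist: 0.35
  hb_angle: 150.0
  contact_cutoff: 0.45
  parallel_max_theta: 30.0
  gap_access_area: 0.23
  leaflet_hysteresis: 0.2
dwell_ns:
  anchoring: 1.0
  insertion: 2.0
  conformation: 1.0
  rotation: 1.0
  crossing_persist: 5.0
gapscan:
  cell: 0.1
  radii:
  - 0.35
  - 0.3
  - 0.3
  - 0.35
  depth_pad: 0.5
hbond_pattern:
  canonical:
  - - 1
    - 8
  - - 8
    - 1
  - - 3
    - 6
  - - 6
    - 3
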