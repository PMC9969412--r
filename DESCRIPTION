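Package: permeatrace
Title: Trajectory Analysis of Cyclic Peptide Membrane Permeation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometric descriptors, event detectors and statistics for
    molecular-dynamics trajectories of cyclic peptides permeating lipid
    bilayers. Computes per-frame membrane reference surfaces, peptide
    depth, backbone-ellipse orientation angles, conformational state
    (closed/half-closed/open via RMSD and intramolecular hydrogen bonds),
    phenylalanine lock state and orientation A/B labels; detects the four
    permeation steps (anchoring, insertion, in-membrane closing, leaflet
    crossing with flip) as typed events; scans leaflet surfaces for
    transient headgroup gaps (lipid packing defects) on a periodic grid;
    and aggregates anchor-probability statistics over pulling-run
    ensembles. Includes a seeded synthetic trajectory generator with
    scripted ground-truth events so every pipeline stage is testable
    without molecular-dynamics engines or external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'config.R'
    'gro.R'
    'trajio.R'
    'membrane.R'
    'geometry.R'
    'conformation.R'
    'orientation.R'
    'gapscan.R'
    'events.R'
    'pulling.R'
    'synthetic.R'
    'descriptors.R'
    'cli.R'
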