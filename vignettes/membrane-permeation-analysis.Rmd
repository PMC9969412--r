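---
title: "Analyzing cyclic-peptide membrane permeation trajectories"
author: "permeatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing cyclic-peptide membrane permeation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeatrace)
```

## The problem

Flexible cyclic decapeptides (CDPs) can passively cross lipid bilayers
despite exposing several hydrogen-bond donors and acceptors. Molecular
dynamics studies of such systems resolve the permeation pathway into four
steps: (1) *anchoring* — an apolar side chain engages lipid tails exposed
by a transient gap between headgroups; (2) *insertion and orientation* —
the peptide passes the headgroup region in an upright pose and then lies
down parallel to the membrane plane at the polar/apolar interface, in one
of two poses (orientation A or B, related by a roughly 180° roll about the
peptide's major axis); (3) *in-membrane closing* — a peptide that entered
in an open conformation forms its intramolecular hydrogen-bond network,
shielding its polar groups; (4) *leaflet crossing* — the closed peptide
anchors into the opposite leaflet and flips by ~180° about its major axis
while passing the bilayer center, so it adopts the favorable orientation
in the destination leaflet.

`permeatrace` turns this qualitative picture into reproducible,
quantitative trajectory analysis: per-frame geometric descriptors, typed
event records with frame intervals, surface gap maps, and ensemble
statistics. Because production MD trajectories of such systems are
microsecond-scale and rarely deposited, the package ships a synthetic
trajectory generator that scripts the same kinematics with known ground
truth, so every stage of the pipeline is testable end to end without an
MD engine.

## Descriptors

**Membrane frame.** The bilayer is assumed planar with its normal fixed
to the z axis (the same approximation made when the orientation angle is
defined against the z axis; center-of-mass motion removal in typical MD
setups keeps the membrane in place). Per frame we compute the upper and
lower headgroup surfaces as the per-leaflet mean z of the choline
nitrogens, the tail-start surfaces as the per-leaflet mean z of the
carbons succeeding the ester groups, and the bilayer center as the
midpoint of the two tail-start surfaces. The center definition is a
package choice: it is symmetric and robust against leaflet-asymmetric
jitter. Leaflets are assigned by the sign of each lipid's headgroup z
relative to the midplane, with a ±0.2 nm hysteresis band within which the
previous frame's assignment is carried, to avoid flicker in crossing
analyses.

**Peptide position and orientation.** Depth is the mass-weighted peptide
center of mass z minus the bilayer center. The peptide normal is the
normalized cross product of the major and minor axes of the backbone
"ellipse"; the axes are extracted by a centered second-moment (PCA-style)
decomposition of the backbone beads, chosen over least-squares ellipse
fitting because it is unique, fast and rotation-equivariant. The
orientation angle θ is the arccos of the dot product with the membrane
normal (argument clamped to [−1, 1]); it is reported raw in [0°, 180°]
and folded to [0°, 90°]. A ring lying in the membrane plane has θ = 0°;
the upright anchored pose has θ ≈ 90°.

Axis *signs* matter: orientation A and B differ by a 180° roll about the
major axis, which is invisible to unsigned axes. Both axes therefore take
the sign that gives the first backbone bead a positive projection, which
makes the normal track rolls reproducibly.

**Conformation.** The closed reference state carries four cross-ring
backbone hydrogen bonds. A frame is *closed* when its backbone RMSD to
the closed reference (after optimal rigid superposition, Kabsch) is at
most 0.2 nm, the conventional open/closed boundary for this scaffold.
Above the threshold, a frame with a partial canonical bond pattern (1–3
of the 4 bonds, correct register) is *half-closed*; anything else is
*open*. The hydrogen-bond criterion is geometric — donor–acceptor
heavy-atom distance ≤ 0.35 nm and donor–H–acceptor angle ≥ 150°, standard
MD practice — and falls back to the distance criterion with a warning when
hydrogen positions are absent. A *register shift* is flagged when the
observed donor→acceptor pattern equals the canonical one displaced by one
ring position (either direction, since no direction is inherent).

**Lock.** Bulky β-turn residues (phenylalanine at positions 5 and 10 in
this scaffold class) can sterically prevent ring closure when they point
toward the membrane center. The lock descriptor projects each turn
side-chain centroid's *out-of-plane* displacement (its component along
the ring normal) onto the membrane-pointing direction: *locked* if any
configured residue points toward the center, *unlocked* if all point
toward the aqueous phase. Two deliberate choices: the out-of-plane
component is used instead of the raw z offset because, for a tilted ring,
in-plane backbone geometry would otherwise leak into the projection; and
the state is `n/a` not only when no turn residue is configured but also
when the ring is not parallel to the membrane (folded θ above the
parallel gate), because the membrane-pointing component of the ring
normal is then noise-dominated and per-frame labels would be arbitrary.

**Orientation A/B.** Frames are labelled only when the peptide is inside
the membrane (COM below the upper headgroup surface) *and* parallel to
the membrane plane. "Parallel" means the folded θ is at most 30° — i.e.
the ring plane within 30° of the membrane plane — configurable as
`parallel_max_theta`. The A/B decision is the sign of the reporter
(proline-class) side chains' mean projection onto the aqueous direction:
toward the membrane center is A, toward the aqueous phase is B; in the
lower leaflet the aqueous direction flips sign. The boundary sits exactly
at zero projection.

## Event detection

Detectors are threshold-plus-dwell state machines over the descriptor
series; the dwell times (defaults: anchoring 1 ns, insertion 2 ns,
conformational events 1 ns, crossing persistence 5 ns) are specified in
ns and converted by the frame stride, because the underlying narrative is
about events, not per-frame flicker.

- **Anchoring**: peptide COM still above the upper headgroup surface
  while ≥ 1 apolar side-chain heavy atom sits within 0.45 nm of lipid
  tail atoms, persisting through the dwell. Contacting residues are
  ranked by contact frames; concurrent backbone–lipid hydrogen bonds
  (phosphate or ester oxygens, tagged by moiety) are recorded as
  stabilizing interactions.
- **Insertion**: first persistent interval with the COM below the upper
  headgroup surface; attributes record the perpendicular-to-parallel θ
  change and whether the final position lies in the headgroup/tail
  interface slab.
- **Closing / half-closing / opening / lock release**: persistent
  transitions of the dwell-filtered conformation and lock label series.
  Each closing-type event records the orientation label at onset —
  so the data-level finding that closing starts from orientation B is
  *checkable*, never hard-coded: a scripted closing in orientation A is
  still reported, with `orientation_at_onset = "A"`.
- **Leaflet crossing**: sign changes of the COM depth. An excursion that
  persists beyond the crossing-persistence threshold (or to the end of
  the trajectory) is *permanent*; one that returns earlier is
  *transient*. Returns shorter than a small rejoin window (3 frames) are
  absorbed into the excursion, so descriptor noise at the midplane does
  not fragment one crossing into many. The flip analysis accumulates the
  signed rotation of the peptide normal about the instantaneous major
  axis over the frames near the membrane center (|depth| < 1 nm); a flip
  requires a net roll of 180° ± 45° *and* orientation B in the
  destination leaflet.
- **Rotation (A↔B)**: persistent label changes on the A/B subsequence.
  Frames labelled `none` are skipped, because the rotation itself passes
  through non-parallel angles; this makes the detector consistent with a
  run-length-encoding oracle of the labelled frames.

## Headgroup-gap scanning

The gap scanner is a from-scratch grid implementation of packing-defect
detection (in the spirit of published Packmem-style analyses): each
leaflet surface is rasterized at 0.1 nm (cell size adjusted to divide the
box evenly), and for each cell the first atom encountered from the
solvent side within the interfacial depth window (head surface + 0.5 nm
down to tail surface − 0.5 nm) decides the class — covered-polar
(headgroup/phosphate/ester), exposed-apolar (tail), or empty. Atom
footprints are circles with per-role radii. Connected exposed-apolar
cells under 4-connectivity with x/y periodicity form gaps; gap area is
cell count × cell area (the cell-count convention is documented rather
than an alpha-shape area). Gap tracks link components sharing at least
one cell in consecutive frames; a gap's lifetime is its frame span times
the stride. The accessibility threshold defaults to 0.23 nm², the
approximate minimum gap area for a leucine side chain, configurable per
residue class.

## The synthetic generator

`generateScenario()` builds a planar two-leaflet pseudo-bilayer
(headgroup surfaces at ±2.0 nm, tail starts at ±1.5 nm, default 64
lipids per leaflet at 0.65 nm² per lipid — POPC-like dimensions so
descriptor magnitudes fall in realistic plotted ranges) and a 10-residue
ring peptide with one side-chain bead per residue, then drives the
peptide through scripted phases (`diffuse`, `approach`, `anchor`,
`insert`, `orient`, `lock`/`unlock`, `half_close`/`close`/`open`,
`cross`, `retreat`, `stay`). Key construction choices:

- The closed conformer realizes exactly the four canonical cross-ring
  hydrogen bonds at 0.29 nm / 180°. Open and half-closed conformers
  deform the ring *tangentially in-plane* (amplitudes chosen to give
  backbone RMSDs of ≈ 0.35 and ≈ 0.23 nm to the closed reference,
  cleanly straddling the 0.2 nm threshold). An out-of-plane saddle large
  enough for an RMSD of 0.35 nm would flip the ring's second principal
  moment into z and corrupt the ellipse normal, which is why the
  deformation is in-plane. A register-shifted conformer rotates the bead
  indices by one position on the (elliptical, hence asymmetric) ring.
- Orientation changes and the crossing flip are rolls about the ring's
  own major axis, composed before the spin that places the scripted
  anchor residue at the ring bottom; the flip roll is concentrated in
  the middle of the crossing, while the peptide passes the center.
- Peptide noise is a rigid-body Gaussian displacement (s.d. `noise`,
  default 0.02 nm) plus a 5× smaller independent per-atom term. Thermal
  motion of covalently bonded atoms is strongly correlated; fully
  independent per-atom noise at comparable amplitude would unphysically
  destroy hydrogen-bond geometry.
- Headgroup "removal" (the gap schedule, and the gap under a scripted
  anchor) buries the polar beads of a lipid below the interfacial
  window, which keeps the atom count constant across frames.
- A `stiffness` parameter divides jitter and gap frequency, emulating
  the direction of the cholesterol effect (fewer gaps in stiffer
  membranes) without modelling cholesterol chemistry.

The generator's per-frame truth labels keep a 5° safety margin inside
the classifier's parallel gate, so scripted truth never sits on a
decision boundary. Scripted event intervals record phase onsets; a
detector's *end* frame may legitimately differ (anchoring persists until
insertion; a permanent crossing runs to the end of the trajectory), so
recovery is judged by type, residue and onset within the dwell window.

What the generator does **not** emulate: forces, thermostats, membrane
undulations and curvature, lipid flip-flop, realistic kinetics or event
rates, or solvent. Passing tests therefore demonstrate that the
*analysis* is correct against known geometry and kinematics — not that
any specific biological system behaves this way.

## Statistical modules

`generatePullingEnsemble()` scripts per-run anchoring success as a
Bernoulli draw with a known per-residue probability; successful runs
anchor and stay anchored to the run end, failures make only a sub-dwell
contact and retreat. `analyzePullingRuns()` then *detects* the outcome
with the anchoring detector (success = an anchoring event persisting to
the run end, the configurable operational definition), and
`anchorProbability()` pools successes per pulled residue position across
peptides, split by start conformation. `orientationFractions()` reports
the percentage of A- and B-labelled frames after an equilibration cut
(by default the end of the insertion event), excluding unlabelled
frames; the two percentages sum to 100 exactly.

## Numerical choices and degenerate inputs

arccos arguments are clamped to [−1, 1]; collinear backbones raise a
degenerate-geometry error; a lipid exactly on the midplane is assigned
from the previous frame and errors on the first; zero-length label series
after the equilibration cut raise an error rather than returning NaN; an
all-one-class polarity map yields a zero hydrophobic moment with a
warning; exact threshold values are inclusive (`RMSD = 0.2 nm` is closed,
`area = 0.23 nm²` is accessible, zero lock projection is aqueous/unlocked).
Coordinates are held in nm and times in ps regardless of input dialect;
frames are 0-based; event logs carry both frame indices and times.

## Problem sizes used in the tests

The shipped test-suite and acceptance studies use 36–64 lipids per
leaflet, 80–175-frame scenarios at 100 ps stride, 20 scripted plus 10
null event-recovery scenarios, 10⁴-frame label series, 120–200-run
pulling ensembles and ≈ 150 gap-scan frames. These sizes were chosen so
that the statistical checks have discriminating power (binomial and
multinomial error bounds well below the tested tolerances) while the
whole suite runs in minutes on one CPU.

## Known limitations

The membrane normal is fixed to z; undulating or curved membranes are
out of scope. The gap scanner's cell-count area slightly underestimates
areas of very ragged gaps relative to alpha-shape definitions. Lock and
orientation descriptors are undefined (reported `n/a` / `none`) while
the ring is tilted, which is a definition choice, not a detection
failure. DCD trajectories without box information inherit the structure
file's box. The pipeline analyzes one peptide per system.
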