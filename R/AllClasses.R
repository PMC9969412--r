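#' @import methods
NULL

#' Atom role map for a peptide/bilayer system
#'
#' Partition of the atom indices of a system into the functional roles the
#' permeation analysis needs: peptide backbone (with the backbone amide
#' donor/acceptor machinery singled out per residue), peptide side chains
#' keyed by residue label, lipid headgroup nitrogens (choline N), phosphate
#' atoms, ester carbons (the carbon succeeding each ester group, marking the
#' start of the tail region), lipid tail atoms, and solvent.
#'
#' All index slots refer to rows of the trajectory atom table. Role sets are
#' disjoint except that the per-residue donor/acceptor/ellipse slots are
#' subsets of \code{backbone}.
#'
#' @slot backbone integer indices of all peptide backbone atoms.
#' @slot ellipse integer indices of the backbone atoms used for the
#'   backbone-ellipse fit (by default the C-alpha equivalents).
#' @slot bbN,bbH,bbO named integer vectors (one per residue label) of the
#'   backbone amide nitrogen, its hydrogen, and the carbonyl oxygen.
#' @slot sidechains named list of integer vectors, residue label to
#'   side-chain atom indices.
#' @slot headN integer indices of lipid headgroup (choline) nitrogens.
#' @slot phosphate integer indices of lipid phosphate atoms.
#' @slot ester integer indices of the ester-succeeding carbons, one per tail.
#' @slot tail integer indices of lipid tail atoms.
#' @slot solvent integer indices of solvent atoms (may be empty).
#' @slot lipidId integer vector, one per atom: id of the lipid molecule the
#'   atom belongs to, \code{NA} for non-lipid atoms.
#' @slot residueLabels character vector of peptide residue labels in
#'   sequence order (e.g. \code{"LEU1"}).
#' @exportClass AtomRoles
setClass("AtomRoles", representation(
  backbone = "integer",
  ellipse = "integer",
  bbN = "integer",
  bbH = "integer",
  bbO = "integer",
  sidechains = "list",
  headN = "integer",
  phosphate = "integer",
  ester = "integer",
  tail = "integer",
  solvent = "integer",
  lipidId = "integer",
  residueLabels = "character"
))

setValidity("AtomRoles", function(object) {
  msg <- character()
  sets <- list(
    peptide = c(object@backbone, unlist(object@sidechains, use.names = FALSE)),
    headN = object@headN, phosphate = object@phosphate,
    ester = object@ester, tail = object@tail, solvent = object@solvent
  )
  all_idx <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_idx))
    msg <- c(msg, "role sets are not disjoint")
  if (anyDuplicated(object@residueLabels))
    msg <- c(msg, "peptide residue labels are not unique")
  n_lipid_atoms <- sum(!is.na(object@lipidId))
  if (n_lipid_atoms > 0L && length(object@ester) == 0L)
    msg <- c(msg, "ester_carbons empty although lipids are present")
  for (s in c("bbN", "bbH", "bbO")) {
    v <- slot(object, s)
    if (length(v) && !setequal(names(v), object@residueLabels))
      msg <- c(msg, sprintf("names of %s do not match residue labels", s))
  }
  if (length(msg)) msg else TRUE
})

#' Molecular trajectory with role-tagged atom selections
#'
#' Neutral internal representation of a structure + coordinate trajectory:
#' an ordered stack of frames (coordinates in nm, orthorhombic box lengths
#' in nm, times in ps) over a fixed atom table, plus an \linkS4class{AtomRoles}
#' selection map. Coordinates are stored in nm and times in ps regardless of
#' the input file dialect.
#'
#' @slot coords numeric array \code{[n_atoms, 3, n_frames]}, nm.
#' @slot box numeric matrix \code{[n_frames, 3]} of box edge lengths, nm.
#' @slot times numeric vector of frame times, ps, strictly increasing.
#' @slot atoms data.frame with columns \code{name}, \code{resid},
#'   \code{resname}, \code{segment}, \code{mass}.
#' @slot roles an \linkS4class{AtomRoles} object.
#' @exportClass Trajectory
setClass("Trajectory", representation(
  coords = "array",
  box = "matrix",
  times = "numeric",
  atoms = "data.frame",
  roles = "AtomRoles"
))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an [n_atoms, 3, n_frames] array")
  else {
    if (nrow(object@atoms) != d[1])
      msg <- c(msg, "atom table row count does not match coords")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
      msg <- c(msg, "box must be an [n_frames, 3] matrix")
    if (length(object@times) != d[3])
      msg <- c(msg, "times length does not match frame count")
  }
  if (any(object@box <= 0))
    msg <- c(msg, "box lengths must be positive")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "frame times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-frame membrane reference geometry
#'
#' Holds, for every frame, the upper/lower headgroup surface z, the
#' upper/lower tail-start surface z (ester-succeeding carbons), the bilayer
#' center (midpoint of the two tail-start surfaces), the area per lipid, and
#' a per-frame leaflet assignment for every lipid. The membrane normal is
#' fixed to the z axis.
#'
#' @slot table data.frame with one row per frame: \code{frame},
#'   \code{time_ps}, \code{z_head_upper}, \code{z_head_lower},
#'   \code{z_tail_upper}, \code{z_tail_lower}, \code{z_center},
#'   \code{area_per_lipid}.
#' @slot leaflets character matrix \code{[n_lipids, n_frames]} with entries
#'   \code{"upper"}/\code{"lower"}.
#' @slot lipidIds integer vector of lipid ids (rows of \code{leaflets}).
#' @exportClass MembraneRef
setClass("MembraneRef", representation(
  table = "data.frame",
  leaflets = "matrix",
  lipidIds = "integer"
))

setValidity("MembraneRef", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("frame", "z_head_upper", "z_head_lower", "z_tail_upper",
            "z_tail_lower", "z_center")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "reference table missing required columns")
  else if (nrow(tb)) {
    ok <- tb$z_head_upper > tb$z_tail_upper & tb$z_tail_upper > tb$z_center &
      tb$z_center > tb$z_tail_lower & tb$z_tail_lower > tb$z_head_lower
    if (!all(ok)) msg <- c(msg, "surface ordering violated on some frame")
  }
  if (length(msg)) msg else TRUE
})

#' Per-frame leaflet-surface gap map
#'
#' Grid classification of one leaflet surface viewed from the solvent side:
#' each cell is covered-polar (a headgroup/phosphate/ester atom is the first
#' atom encountered), exposed-apolar (a tail atom is first: a headgroup gap,
#' i.e. lipid packing defect), or empty. Connected exposed-apolar cells
#' (4-connectivity, periodic in x/y) form gaps with areas in nm^2.
#'
#' @slot leaflet \code{"upper"} or \code{"lower"}.
#' @slot frame frame index (0-based).
#' @slot cell grid cell edge length, nm.
#' @slot grid integer matrix: 0 empty, 1 covered-polar, 2 exposed-apolar.
#' @slot labels integer matrix of gap component ids (0 for non-gap cells).
#' @slot gaps data.frame: \code{gap_id}, \code{n_cells}, \code{area_nm2}.
#' @exportClass GapMap
setClass("GapMap", representation(
  leaflet = "character",
  frame = "integer",
  cell = "numeric",
  grid = "matrix",
  labels = "matrix",
  gaps = "data.frame"
))

setValidity("GapMap", function(object) {
  msg <- character()
  if (!object@leaflet %in% c("upper", "lower"))
    msg <- c(msg, "leaflet must be 'upper' or 'lower'")
  if (object@cell <= 0) msg <- c(msg, "cell size must be positive")
  if (nrow(object@gaps) &&
      !isTRUE(all.equal(object@gaps$area_nm2,
                        object@gaps$n_cells * object@cell^2)))
    msg <- c(msg, "gap areas inconsistent with cell counts")
  if (length(msg)) msg else TRUE
})

## ---- generics -------------------------------------------------------------

#' @rdname Trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("frameBox", function(x, frame) standardGeneric("frameBox"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("atomRoles", function(x) standardGeneric("atomRoles"))
#' @rdname Trajectory-accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname MembraneRef-accessors
#' @export
setGeneric("refTable", function(x) standardGeneric("refTable"))
#' @rdname MembraneRef-accessors
#' @export
setGeneric("leafletOf", function(x, frame) standardGeneric("leafletOf"))
#' @rdname GapMap-accessors
#' @export
setGeneric("gapTable", function(x) standardGeneric("gapTable"))

#' Accessors for Trajectory objects
#'
#' @param x a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @return \code{nFrames}/\code{nAtoms}: integer. \code{frameCoords}: an
#'   \code{[n_atoms, 3]} matrix in nm. \code{frameBox}: length-3 numeric.
#'   \code{frameTimes}: numeric vector in ps. \code{atomRoles}: the
#'   \linkS4class{AtomRoles}. \code{atomData}: the atom table.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname Trajectory-accessors
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname Trajectory-accessors
setMethod("frameCoords", "Trajectory", function(x, frame) {
  stopifnot(frame >= 0, frame < nFrames(x))
  x@coords[, , frame + 1L, drop = TRUE]
})
#' @rdname Trajectory-accessors
setMethod("frameBox", "Trajectory", function(x, frame) {
  stopifnot(frame >= 0, frame < nFrames(x))
  x@box[frame + 1L, ]
})
#' @rdname Trajectory-accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname Trajectory-accessors
setMethod("atomRoles", "Trajectory", function(x) x@roles)
#' @rdname Trajectory-accessors
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' Accessors for MembraneRef objects
#'
#' @param x a \linkS4class{MembraneRef}.
#' @param frame 0-based frame index.
#' @return \code{refTable}: the per-frame reference data.frame.
#'   \code{leafletOf}: named character vector lipid id -> leaflet at
#'   \code{frame}.
#' @name MembraneRef-accessors
NULL

#' @rdname MembraneRef-accessors
setMethod("refTable", "MembraneRef", function(x) x@table)
#' @rdname MembraneRef-accessors
setMethod("leafletOf", "MembraneRef", function(x, frame) {
  stopifnot(frame >= 0, frame < ncol(x@leaflets))
  stats::setNames(x@leaflets[, frame + 1L], x@lipidIds)
})

#' Accessors for GapMap objects
#'
#' @param x a \linkS4class{GapMap}.
#' @return \code{gapTable}: data.frame of gap components with areas.
#' @name GapMap-accessors
NULL

#' @rdname GapMap-accessors
setMethod("gapTable", "GapMap", function(x) x@gaps)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms, %d frames (%.1f-%.1f ps)\n",
              nAtoms(object), nFrames(object),
              object@times[1], object@times[length(object@times)]))
  r <- object@roles
  cat(sprintf("  peptide: %d residues, %d backbone atoms; lipids: %d; solvent atoms: %d\n",
              length(r@residueLabels), length(r@backbone),
              length(unique(stats::na.omit(r@lipidId))), length(r@solvent)))
  invisible(object)
})

setMethod("show", "MembraneRef", function(object) {
  tb <- object@table
  cat(sprintf("MembraneRef: %d frames, %d lipids\n", nrow(tb), length(object@lipidIds)))
  if (nrow(tb))
    cat(sprintf("  mean surfaces [nm]: head %+0.2f/%+0.2f, tail %+0.2f/%+0.2f, center %+0.2f\n",
                mean(tb$z_head_upper), mean(tb$z_head_lower),
                mean(tb$z_tail_upper), mean(tb$z_tail_lower), mean(tb$z_center)))
  invisible(object)
})

setMethod("show", "GapMap", function(object) {
  cat(sprintf("GapMap: %s leaflet, frame %d, %dx%d grid (cell %.2f nm), %d gap(s)\n",
              object@leaflet, object@frame, nrow(object@grid), ncol(object@grid),
              object@cell, nrow(object@gaps)))
  invisible(object)
})
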