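# Per-frame peptide descriptors: center-of-mass depth, backbone-ellipse
# axes, orientation angle between the peptide normal and the membrane
# normal, hydrophobic moment, and the periodic-boundary entry-side
# normalization.

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

clampAcosDeg <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi

#' Peptide center-of-mass depth
#'
#' Mass-weighted z of the peptide center of mass minus the bilayer center;
#' positive above the center.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param z_center bilayer center z (absolute, nm), e.g. from
#'   \code{\link{referenceSurfaces}}.
#' @return signed depth in nm.
#' @export
peptideComZ <- function(traj, frame, z_center = 0) {
  roles <- atomRoles(traj)
  idx <- c(roles@backbone, unlist(roles@sidechains, use.names = FALSE))
  if (!length(idx)) stop("empty peptide selection")
  xyz <- frameCoords(traj, frame)
  m <- atomData(traj)$mass[idx]
  sum(xyz[idx, 3] * m) / sum(m) - z_center
}

# signed principal axes of a point cloud with a reproducible sign convention
principalAxes <- function(pts) {
  if (nrow(pts) < 3L) stop("need at least 3 backbone atoms")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (ev$values[2] < 1e-10)
    stop("degenerate geometry: backbone atoms are collinear")
  major <- ev$vectors[, 1]
  minor <- ev$vectors[, 2]
  # sign convention: the first backbone atom (falling back to the second)
  # projects positively on both axes, so the peptide normal a = major x minor
  # carries a reproducible, conformation-tracking sign
  fixSign <- function(ax) {
    for (i in seq_len(nrow(X))) {
      p <- sum(X[i, ] * ax)
      if (abs(p) > 1e-9) return(if (p < 0) -ax else ax)
    }
    ax
  }
  major <- fixSign(major)
  minor <- fixSign(minor)
  list(major = major, minor = minor, center = ctr)
}

#' Backbone-ellipse axes
#'
#' Principal axes of the peptide backbone atom cloud (centered second-moment
#' decomposition): the major axis is the largest-spread direction, the minor
#' the second. Axis signs follow a fixed convention (positive projection of
#' residue 1's backbone bead) so that the peptide normal
#' \code{major x minor} can track 180-degree rolls about the major axis.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @return list with unit vectors \code{major}, \code{minor} and the
#'   backbone centroid \code{center}.
#' @export
backboneEllipseAxes <- function(traj, frame) {
  roles <- atomRoles(traj)
  xyz <- frameCoords(traj, frame)
  principalAxes(xyz[roles@ellipse, , drop = FALSE])
}

#' Orientation angle between the peptide and membrane normals
#'
#' The peptide normal is the normalized cross product of the major and
#' minor backbone-ellipse axes; the membrane normal is the z axis. The
#' angle is \code{arccos} of their dot product (argument clamped to
#' [-1, 1]), reported both raw in [0, 180] and folded to [0, 90] for
#' parallel-versus-perpendicular plots.
#'
#' @param major,minor unit vectors of the backbone ellipse.
#' @param b membrane normal unit vector (default z axis).
#' @return list: \code{normal} (peptide normal a), \code{theta} raw degrees,
#'   \code{theta_folded} degrees in [0, 90].
#' @export
orientationAngle <- function(major, minor, b = c(0, 0, 1)) {
  a <- c(major[2] * minor[3] - major[3] * minor[2],
         major[3] * minor[1] - major[1] * minor[3],
         major[1] * minor[2] - major[2] * minor[1])
  if (sqrt(sum(a^2)) < 1e-12) stop("major and minor axes are parallel")
  a <- unitv(a)
  b <- unitv(b)
  th <- clampAcosDeg(sum(a * b))
  list(normal = a, theta = th, theta_folded = min(th, 180 - th))
}

#' Hydrophobic moment of the peptide
#'
#' Vector from the center of mass of the polar-residue atoms to the center
#' of mass of the apolar-residue atoms.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param polarity named character vector mapping residue name (e.g.
#'   \code{"LEU"}) to \code{"polar"}/\code{"apolar"}; must cover every
#'   peptide residue.
#' @return length-3 numeric vector in nm (zero vector, with a warning, if
#'   all residues fall in one class).
#' @export
hydrophobicMoment <- function(traj, frame,
                              polarity = defaultConfig()$residues$polarity) {
  roles <- atomRoles(traj)
  atoms <- atomData(traj)
  xyz <- frameCoords(traj, frame)
  labs <- roles@residueLabels
  resnames <- sub("[0-9]+$", "", labs)
  if (!all(resnames %in% names(polarity)))
    stop("polarity map does not cover residues: ",
         paste(setdiff(resnames, names(polarity)), collapse = ", "))
  comOf <- function(which_labs) {
    idx <- integer()
    for (l in which_labs)
      idx <- c(idx, roles@sidechains[[l]],
               roles@bbN[l], roles@bbO[l],
               roles@backbone[atoms$resid[roles@backbone] ==
                                as.integer(sub("^[A-Za-z]+", "", l))])
    idx <- unique(idx[!is.na(idx)])
    m <- atoms$mass[idx]
    colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
  }
  pol <- labs[polarity[resnames] == "polar"]
  apo <- labs[polarity[resnames] == "apolar"]
  if (!length(pol) || !length(apo)) {
    warning("all residues in one polarity class; hydrophobic moment is zero")
    return(c(0, 0, 0))
  }
  comOf(apo) - comOf(pol)
}

#' Rotate the simulation box 180 degrees about the x axis
#'
#' Maps every coordinate (x, y, z) to (x, box_y - y, box_z - z), i.e. a
#' 180-degree rotation about the box-center line parallel to x. Applying it
#' twice is the identity.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return the transformed \linkS4class{Trajectory}.
#' @export
rotateBoxX180 <- function(traj) {
  arr <- traj@coords
  for (i in seq_len(nFrames(traj))) {
    arr[, 2, i] <- traj@box[i, 2] - arr[, 2, i]
    arr[, 3, i] <- traj@box[i, 3] - arr[, 3, i]
  }
  methods::initialize(traj, coords = arr)
}

# first frame with any peptide atom within `cutoff` nm of any lipid atom,
# or NA if no contact
firstContactFrame <- function(traj, cutoff = 0.45) {
  roles <- atomRoles(traj)
  pep <- c(roles@backbone, unlist(roles@sidechains, use.names = FALSE))
  lip <- which(!is.na(roles@lipidId))
  for (i in seq_len(nFrames(traj))) {
    xyz <- traj@coords[, , i]
    d2 <- minCrossDist2(xyz[pep, , drop = FALSE], xyz[lip, , drop = FALSE])
    if (d2 <= cutoff^2) return(i - 1L)
  }
  NA_integer_
}

# squared minimum distance between two coordinate sets
minCrossDist2 <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  best
}

#' Normalize the membrane entry side
#'
#' If the peptide's first membrane contact happens at the lower leaflet, the
#' whole trajectory is rotated 180 degrees about the box x axis
#' (\code{\link{rotateBoxX180}}) so that the contact is at the upper
#' leaflet; otherwise the trajectory is returned unchanged. Trajectories
#' with no membrane contact are returned unchanged.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param cutoff contact cutoff in nm for the first-contact search.
#' @return a \linkS4class{Trajectory} with upper-leaflet entry.
#' @export
normalizeEntrySide <- function(traj, cutoff = 0.45) {
  fc <- firstContactFrame(traj, cutoff)
  if (is.na(fc)) return(traj)
  zc <- referenceSurfaces(traj, fc)$z_center
  if (peptideComZ(traj, fc, zc) >= 0) return(traj)
  rotateBoxX180(traj)
}
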