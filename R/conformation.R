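# Conformational classification: RMSD to the closed reference after optimal
# rigid superposition, intramolecular hydrogen bonds, closed/half-closed/
# open labels, register-shift detection, and the bulky-turn-residue lock
# descriptor.

#' Optimal-superposition backbone RMSD (Kabsch)
#'
#' Minimum root-mean-square deviation between two coordinate sets of
#' corresponding atoms after removing the optimal rigid rotation and
#' translation (Kabsch algorithm via SVD, with the determinant correction
#' that excludes reflections).
#'
#' @param X,Y numeric \code{[n, 3]} matrices of corresponding atoms, nm.
#' @return RMSD in nm.
#' @export
kabschRmsd <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Yc - Xc %*% t(R))^2)))
}

#' RMSD of a frame's backbone to the closed reference
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param reference \code{[n_backbone, 3]} matrix of the closed-conformation
#'   backbone coordinates, in the order of the trajectory's backbone atoms.
#' @return RMSD in nm.
#' @export
rmsdToClosed <- function(traj, frame, reference) {
  roles <- atomRoles(traj)
  xyz <- frameCoords(traj, frame)[roles@backbone, , drop = FALSE]
  if (nrow(xyz) != nrow(reference))
    stop(sprintf("backbone atom mismatch: frame has %d, reference has %d",
                 nrow(xyz), nrow(reference)))
  kabschRmsd(xyz, reference)
}

# residue index from a label like "LEU5"
residueIndex <- function(labels) as.integer(sub("^[A-Za-z]+", "", labels))

circularSeparation <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

#' Intramolecular backbone hydrogen bonds
#'
#' Geometric criterion: donor-acceptor heavy-atom (N...O) distance at most
#' \code{dist} nm and donor-H-acceptor angle at least \code{angle} degrees.
#' Pairs i->i and i->(i+-1) (circular) are excluded. If a donor has no
#' hydrogen position, that donor falls back to the distance criterion alone,
#' with a warning.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param dist donor-acceptor cutoff, nm.
#' @param angle minimum donor-H-acceptor angle, degrees.
#' @return data.frame with columns \code{donor}, \code{acceptor} (residue
#'   labels), \code{donor_pos}, \code{acceptor_pos} (1-based ring
#'   positions), \code{dist_nm}, \code{angle_deg}.
#' @export
intraHbonds <- function(traj, frame, dist = 0.35, angle = 150) {
  roles <- atomRoles(traj)
  xyz <- frameCoords(traj, frame)
  labs <- roles@residueLabels
  n <- length(labs)
  pos <- seq_len(n)
  out <- list()
  warned <- FALSE
  for (di in pos) for (ai in pos) {
    if (circularSeparation(di, ai, n) < 2L) next
    iN <- roles@bbN[labs[di]]; iO <- roles@bbO[labs[ai]]
    if (is.na(iN) || is.na(iO)) next
    d <- sqrt(sum((xyz[iN, ] - xyz[iO, ])^2))
    if (d > dist) next
    iH <- roles@bbH[labs[di]]
    if (is.na(iH)) {
      if (!warned) {
        warning("missing donor hydrogen; using heavy-atom distance only")
        warned <- TRUE
      }
      ang <- NA_real_
    } else {
      v1 <- xyz[iN, ] - xyz[iH, ]
      v2 <- xyz[iO, ] - xyz[iH, ]
      ang <- clampAcosDeg(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      if (ang < angle) next
    }
    out[[length(out) + 1L]] <- data.frame(
      donor = labs[di], acceptor = labs[ai], donor_pos = di,
      acceptor_pos = ai, dist_nm = d, angle_deg = ang,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donor = character(), acceptor = character(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      dist_nm = numeric(), angle_deg = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# pattern as a canonical string set for comparison, from (donor, acceptor)
# position pairs
patternKey <- function(donor_pos, acceptor_pos) {
  sort(paste(donor_pos, acceptor_pos, sep = ">"))
}

shiftPattern <- function(pairs, shift, n = 10L) {
  lapply(pairs, function(p) ((p - 1L + shift) %% n) + 1L)
}

#' Detect a register shift in the hydrogen-bond pattern
#'
#' True iff the observed donor-to-acceptor pairs equal the canonical
#' closed-state pattern with every residue position displaced by one (the
#' shift is checked in both ring directions).
#'
#' @param observed data.frame with \code{donor_pos}, \code{acceptor_pos}
#'   (e.g. from \code{\link{intraHbonds}}).
#' @param canonical list of length-2 integer vectors (donor, acceptor) ring
#'   positions of the closed-state bonds.
#' @param n_residues ring size.
#' @return logical.
#' @export
detectRegisterShift <- function(observed,
                                canonical = defaultConfig()$hbond_pattern$canonical,
                                n_residues = 10L) {
  if (!nrow(observed)) return(FALSE)
  obs <- patternKey(observed$donor_pos, observed$acceptor_pos)
  for (s in c(1L, -1L)) {
    sh <- shiftPattern(canonical, s, n_residues)
    key <- patternKey(vapply(sh, `[`, integer(1), 1),
                      vapply(sh, `[`, integer(1), 2))
    if (identical(obs, key)) return(TRUE)
  }
  FALSE
}

# TRUE iff every observed bond is part of the canonical pattern
patternSubset <- function(observed, canonical) {
  if (!nrow(observed)) return(TRUE)
  can <- patternKey(vapply(canonical, `[`, integer(1), 1),
                    vapply(canonical, `[`, integer(1), 2))
  all(paste(observed$donor_pos, observed$acceptor_pos, sep = ">") %in% can)
}

#' Classify the peptide conformation
#'
#' \code{closed} if the RMSD to the closed reference is at most
#' \code{rmsd_threshold}; \code{half_closed} if the RMSD is above the
#' threshold but a partial canonical hydrogen-bond pattern (at least one and
#' fewer than the full set, with resolved register) is present; otherwise
#' \code{open}.
#'
#' @param rmsd_closed RMSD to the closed reference, nm.
#' @param hbonds data.frame of observed intramolecular bonds
#'   (\code{\link{intraHbonds}}).
#' @param canonical canonical closed-state (donor, acceptor) position pairs.
#' @param rmsd_threshold open/closed boundary, nm.
#' @return list: \code{label} in \code{c("closed", "half_closed", "open")},
#'   \code{register_shift} logical, \code{n_hbonds} integer.
#' @export
classifyConformation <- function(rmsd_closed, hbonds,
                                 canonical = defaultConfig()$hbond_pattern$canonical,
                                 rmsd_threshold = 0.2) {
  stopifnot(is.finite(rmsd_closed))
  shift <- detectRegisterShift(hbonds, canonical)
  nhb <- nrow(hbonds)
  nfull <- length(canonical)
  label <- if (rmsd_closed <= rmsd_threshold) "closed"
  else if (nhb >= 1L && nhb < nfull && !shift &&
           patternSubset(hbonds, canonical)) "half_closed"
  else "open"
  list(label = label, register_shift = shift, n_hbonds = nhb)
}

#' Lock state of the bulky turn residues
#'
#' For each configured turn residue (phenylalanine class), the side-chain
#' centroid's displacement out of the ring plane (its component along the
#' backbone-ellipse normal) is resolved into the membrane-pointing
#' direction: the direction of decreasing |z| toward the bilayer center for
#' the peptide's current side. The state is \code{unlocked} iff all
#' configured residues project toward the aqueous side, \code{locked} iff
#' at least one projects toward the membrane center (projection exactly
#' zero counts as aqueous), and \code{n/a} if no turn residue is
#' configured or if the ring is not parallel to the membrane plane (folded
#' orientation angle above \code{parallel_max_theta}), where the
#' membrane-pointing direction of the ring normal is not defined.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param turn_positions integer ring positions of the bulky turn residues.
#' @param z_center bilayer center z (absolute, nm).
#' @return list: \code{state} in \code{c("locked", "unlocked", "n/a")},
#'   \code{projections} named numeric (positive = toward membrane center).
#' @export
lockState <- function(traj, frame,
                      turn_positions = defaultConfig()$residues$turns,
                      z_center = 0, parallel_max_theta = 30) {
  roles <- atomRoles(traj)
  labs <- roles@residueLabels
  keep <- labs[residueIndex(labs) %in% turn_positions &
                 vapply(labs, function(l) length(roles@sidechains[[l]]) > 0,
                        logical(1))]
  if (!length(keep)) return(list(state = "n/a", projections = numeric()))
  xyz <- frameCoords(traj, frame)
  ax <- backboneEllipseAxes(traj, frame)
  ori <- orientationAngle(ax$major, ax$minor)
  if (ori$theta_folded > parallel_max_theta)
    return(list(state = "n/a", projections = numeric()))
  aqueous <- if (peptideComZ(traj, frame, z_center) >= 0) c(0, 0, 1)
             else c(0, 0, -1)
  a_aq <- sum(ori$normal * aqueous)
  proj <- vapply(keep, function(l) {
    sc <- colMeans(xyz[roles@sidechains[[l]], , drop = FALSE])
    s_a <- sum((sc - ax$center) * ori$normal)  # out-of-plane displacement
    -s_a * a_aq                                # positive = toward center
  }, numeric(1))
  state <- if (any(proj > 0)) "locked" else "unlocked"
  list(state = state, projections = proj)
}
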