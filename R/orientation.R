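# Orientation A/B classification of in-membrane frames, rotation and flip
# detection, occupancy statistics.

#' Classify the in-membrane orientation (A or B)
#'
#' A frame is labelled only when the peptide is inside the membrane (COM
#' below the upper headgroup surface) and lies parallel to the membrane
#' plane (folded orientation angle at most \code{parallel_max_theta}
#' degrees, i.e. the ring normal within that angle of the membrane normal).
#' The label is then decided by the reporter side chains (proline-class turn
#' residues): orientation A when they point toward the membrane center,
#' orientation B when they point toward the aqueous phase. For a peptide in
#' the lower leaflet the aqueous direction flips sign.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param refrow one-row reference data.frame for the frame
#'   (\code{\link{referenceSurfaces}}).
#' @param reporter_positions integer ring positions of the reporter
#'   residues.
#' @param parallel_max_theta folded-theta gate, degrees.
#' @return list: \code{label} in \code{c("A", "B", "none")},
#'   \code{reporter_projection} (signed, positive toward the aqueous phase),
#'   \code{in_membrane} logical, \code{theta_folded}.
#' @export
classifyOrientation <- function(traj, frame, refrow,
                                reporter_positions = defaultConfig()$residues$reporters,
                                parallel_max_theta = 30) {
  roles <- atomRoles(traj)
  labs <- roles@residueLabels
  rep_labs <- labs[residueIndex(labs) %in% reporter_positions &
                     vapply(labs, function(l)
                       length(roles@sidechains[[l]]) > 0, logical(1))]
  if (!length(rep_labs))
    stop("reporter residues absent from the peptide")
  zc <- refrow$z_center
  z <- peptideComZ(traj, frame, zc)
  ax <- backboneEllipseAxes(traj, frame)
  ori <- orientationAngle(ax$major, ax$minor)
  in_mem <- z < (refrow$z_head_upper - zc) && z > (refrow$z_head_lower - zc)
  xyz <- frameCoords(traj, frame)
  aqueous <- if (z >= 0) c(0, 0, 1) else c(0, 0, -1)
  proj <- mean(vapply(rep_labs, function(l) {
    sc <- colMeans(xyz[roles@sidechains[[l]], , drop = FALSE])
    sum((sc - ax$center) * aqueous)
  }, numeric(1)))
  label <- if (!in_mem || ori$theta_folded > parallel_max_theta) "none"
  else if (proj > 0) "B" else "A"
  list(label = label, reporter_projection = proj, in_membrane = in_mem,
       theta_folded = ori$theta_folded)
}

# run-length encoding with a dwell filter: runs shorter than `dwell` frames
# are relabelled to the previous persistent label
dwellFilterLabels <- function(labels, dwell) {
  r <- rle(labels)
  keep <- r$lengths >= dwell
  if (!any(keep)) return(labels)
  vals <- r$values
  last <- NA_character_
  for (i in seq_along(vals)) {
    if (keep[i]) last <- vals[i]
    else if (!is.na(last)) vals[i] <- last
  }
  # leading short runs inherit the first persistent label backwards
  firstKeep <- which(keep)[1]
  if (firstKeep > 1) vals[seq_len(firstKeep - 1)] <- vals[firstKeep]
  inverse.rle(list(lengths = r$lengths, values = vals))
}

#' Detect persistent orientation rotation events (A<->B)
#'
#' Emits one event per persistent label change on the A/B subsequence:
#' frames labelled \code{"none"} (outside the membrane or not parallel, as
#' during the rotation itself) are skipped, so a rotation that passes
#' through intermediate angles still registers as a single A-to-B change.
#' Both the leaving and the entering label must persist for at least
#' \code{dwell} labelled frames; shorter-lived flickers are suppressed.
#'
#' @param labels per-frame character vector of orientation labels
#'   (\code{"A"}, \code{"B"}, \code{"none"}).
#' @param times frame times, ps.
#' @param dwell minimum persistence, labelled frames.
#' @return event data.frame with types \code{"rotation_AB"} /
#'   \code{"rotation_BA"}; the interval marks the first dwell-confirmed
#'   frames of the new label.
#' @export
detectRotationEvents <- function(labels, times, dwell = 5L) {
  keep <- which(labels %in% c("A", "B"))
  ev <- emptyEvents()
  if (!length(keep)) return(ev)
  filt <- dwellFilterLabels(labels[keep], dwell)
  r <- rle(filt)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  for (i in seq_along(r$values)[-1]) {
    from <- r$values[i - 1]; to <- r$values[i]
    if (from %in% c("A", "B") && to %in% c("A", "B") && from != to) {
      ev <- rbind(ev, eventRecord(
        paste0("rotation_", from, to), keep[starts[i]] - 1L,
        keep[min(starts[i] + dwell - 1L, ends[i])] - 1L, times,
        attributes = list(from = from, to = to)))
    }
  }
  ev
}

#' Cumulative roll about the major axis and flip call for a crossing
#'
#' Tracks the peptide normal between consecutive frames of a
#' leaflet-crossing interval, accumulating the signed rotation about the
#' instantaneous major axis. The crossing counts as a flip when the net
#' rotation is within \code{tol} degrees of 180 and the post-crossing
#' orientation label is B in the destination leaflet.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frames integer vector of 0-based frame indices spanning the
#'   crossing interval (ordered).
#' @param ref a \linkS4class{MembraneRef} (for the post-crossing label).
#' @param reporter_positions reporter residue positions for the label.
#' @param tol flip tolerance around 180 degrees.
#' @return list: \code{flip} logical, \code{net_rotation_deg},
#'   \code{rotation_series} cumulative degrees per frame,
#'   \code{post_label}.
#' @export
detectFlip <- function(traj, frames, ref,
                       reporter_positions = defaultConfig()$residues$reporters,
                       tol = 45) {
  stopifnot(length(frames) >= 2L)
  cum <- numeric(length(frames))
  prev <- NULL
  for (k in seq_along(frames)) {
    ax <- backboneEllipseAxes(traj, frames[k])
    ori <- orientationAngle(ax$major, ax$minor)
    cur <- list(major = ax$major, normal = ori$normal)
    if (!is.null(prev)) {
      m <- prev$major
      # project both normals into the plane orthogonal to the major axis
      p1 <- prev$normal - sum(prev$normal * m) * m
      p2 <- cur$normal - sum(cur$normal * m) * m
      n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2))
      dth <- 0
      if (n1 > 1e-9 && n2 > 1e-9) {
        cosd <- sum(p1 * p2) / (n1 * n2)
        crossp <- c(p1[2] * p2[3] - p1[3] * p2[2],
                    p1[3] * p2[1] - p1[1] * p2[3],
                    p1[1] * p2[2] - p1[2] * p2[1])
        dth <- clampAcosDeg(cosd) * sign(sum(crossp * m) + 1e-300)
      }
      cum[k] <- cum[k - 1] + dth
    }
    prev <- cur
  }
  lastf <- frames[length(frames)]
  refrow <- refTable(ref)[lastf + 1L, ]
  post <- classifyOrientation(traj, lastf, refrow, reporter_positions)
  net <- abs(cum[length(cum)])
  list(flip = (abs(net - 180) <= tol) && identical(post$label, "B"),
       net_rotation_deg = cum[length(cum)],
       rotation_series = cum, post_label = post$label)
}

#' Fractions of time spent in orientation A and B
#'
#' Percentages over the frames labelled A or B (frames labelled
#' \code{"none"} are excluded), after discarding everything up to the
#' equilibration cut. The two percentages sum to 100.
#'
#' @param labels per-frame orientation labels.
#' @param equilibration_cut 0-based frame index; frames before it are
#'   discarded (default 0 = use all).
#' @return named numeric \code{c(A = , B = )} in percent.
#' @export
orientationFractions <- function(labels, equilibration_cut = 0L) {
  lab <- labels[(equilibration_cut + 1L):length(labels)]
  lab <- lab[lab %in% c("A", "B")]
  if (!length(lab)) stop("no labelled frames after the equilibration cut")
  c(A = 100 * mean(lab == "A"), B = 100 * mean(lab == "B"))
}

#' Occupancy histogram over depth and orientation angle
#'
#' 2-D histogram of (distance to bilayer center, orientation angle) over
#' frames. Densities are counts (optionally normalized); they are not
#' converted to free energies.
#'
#' @param z per-frame signed depth, nm.
#' @param theta per-frame orientation angle, degrees.
#' @param z_breaks,theta_breaks histogram bin edges.
#' @param normalize divide counts by the total.
#' @return list: \code{counts} matrix (rows = z bins, cols = theta bins),
#'   \code{z_breaks}, \code{theta_breaks}.
#' @export
occupancyHeatmap <- function(z, theta,
                             z_breaks = seq(-4, 6, by = 0.25),
                             theta_breaks = seq(0, 180, by = 5),
                             normalize = FALSE) {
  stopifnot(length(z) == length(theta))
  zi <- cut(z, z_breaks, include.lowest = TRUE, labels = FALSE)
  ti <- cut(theta, theta_breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(zi) & !is.na(ti)
  counts <- matrix(0, length(z_breaks) - 1, length(theta_breaks) - 1)
  for (k in which(ok)) counts[zi[k], ti[k]] <- counts[zi[k], ti[k]] + 1
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  list(counts = counts, z_breaks = z_breaks, theta_breaks = theta_breaks)
}
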