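# Event detectors for the four permeation steps: anchoring, insertion,
# in-membrane conformational events (closing / half-closing / opening and
# lock release), leaflet crossing (permanent/transient, with flip), plus
# the merged timeline.

# runs of TRUE in a logical vector: data.frame(start, end) (1-based)
trueRuns <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# per-frame, per-residue minimum distance between apolar side-chain atoms
# and lipid tail atoms; optionally restricted to one leaflet's lipids.
# Returns a [n_frames, n_residues] matrix (Inf where residue has no side
# chain).
sidechainTailDistances <- function(traj, residues = NULL, leaflet = NULL,
                                   ref = NULL) {
  roles <- atomRoles(traj)
  labs <- if (is.null(residues)) roles@residueLabels else residues
  nfr <- nFrames(traj)
  out <- matrix(Inf, nfr, length(labs), dimnames = list(NULL, labs))
  tail_idx <- roles@tail
  for (i in seq_len(nfr)) {
    tidx <- tail_idx
    if (!is.null(leaflet)) {
      leafs <- leafletOf(ref, i - 1L)
      tidx <- tail_idx[leafs[as.character(roles@lipidId[tail_idx])] == leaflet]
    }
    if (!length(tidx)) next
    xyz <- traj@coords[, , i]
    for (l in labs) {
      sc <- roles@sidechains[[l]]
      if (!length(sc)) next
      out[i, l] <- sqrt(minCrossDist2(xyz[sc, , drop = FALSE],
                                      xyz[tidx, , drop = FALSE]))
    }
  }
  out
}

apolarResidues <- function(roles, polarity) {
  labs <- roles@residueLabels
  labs[polarity[sub("[0-9]+$", "", labs)] == "apolar" &
         vapply(labs, function(l) length(roles@sidechains[[l]]) > 0,
                logical(1))]
}

#' Track peptide-lipid hydrogen bonds
#'
#' Geometric hydrogen bonds between the peptide backbone amide donors and
#' the lipid phosphate or ester oxygens, with the lipid moiety tagged.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frames 0-based frame indices (default all).
#' @param dist donor-acceptor heavy-atom cutoff, nm.
#' @param angle minimum donor-H-acceptor angle, degrees.
#' @return data.frame: \code{frame}, \code{residue} (peptide donor),
#'   \code{lipid_atom} (index), \code{lipid_id}, \code{moiety}
#'   (\code{"phosphate"}/\code{"ester"}), \code{dist_nm}, \code{angle_deg}.
#' @export
trackPeptideLipidHbonds <- function(traj, frames = seq_len(nFrames(traj)) - 1L,
                                    dist = 0.35, angle = 150) {
  roles <- atomRoles(traj)
  acc <- c(roles@phosphate, roles@ester)
  moiety <- c(rep("phosphate", length(roles@phosphate)),
              rep("ester", length(roles@ester)))
  labs <- roles@residueLabels
  rows <- list()
  for (f in frames) {
    xyz <- frameCoords(traj, f)
    for (l in labs) {
      iN <- roles@bbN[l]; iH <- roles@bbH[l]
      if (is.na(iN)) next
      d <- sqrt((xyz[acc, 1] - xyz[iN, 1])^2 + (xyz[acc, 2] - xyz[iN, 2])^2 +
                  (xyz[acc, 3] - xyz[iN, 3])^2)
      cand <- which(d <= dist)
      for (k in cand) {
        ang <- NA_real_
        if (!is.na(iH)) {
          v1 <- xyz[iN, ] - xyz[iH, ]
          v2 <- xyz[acc[k], ] - xyz[iH, ]
          ang <- clampAcosDeg(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
          if (ang < angle) next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, residue = l, lipid_atom = acc[k],
          lipid_id = roles@lipidId[acc[k]], moiety = moiety[k],
          dist_nm = d[k], angle_deg = ang, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(), residue = character(),
                      lipid_atom = integer(), lipid_id = integer(),
                      moiety = character(), dist_nm = numeric(),
                      angle_deg = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Detect anchoring events
#'
#' An anchoring event is a persistent interval in which the peptide center
#' of mass is still above the upper headgroup surface (not yet inserted)
#' while at least one apolar side-chain heavy atom is within the contact
#' cutoff of the lipid tail atoms. Participating residues are ranked by
#' their number of contact frames; the attributes record the conformation at
#' first contact and any concurrent peptide-backbone-to-lipid hydrogen
#' bonds.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ref a \linkS4class{MembraneRef}.
#' @param desc descriptor table from \code{\link{computeDescriptors}}.
#' @param config configuration list.
#' @return event data.frame (type \code{"anchoring"}).
#' @export
detectAnchoring <- function(traj, ref, desc, config = defaultConfig()) {
  th <- config$thresholds
  dwell <- dwellFrames(config$dwell_ns$anchoring, frameStride(traj))
  roles <- atomRoles(traj)
  apo <- apolarResidues(roles, config$residues$polarity)
  dists <- sidechainTailDistances(traj, residues = apo)
  contact <- dists <= th$contact_cutoff
  tb <- refTable(ref)
  above <- desc$z_com > (tb$z_head_upper - tb$z_center)
  cond <- above & rowSums(contact) > 0
  runs <- trueRuns(cond)
  runs <- runs[runs$end - runs$start + 1L >= dwell, , drop = FALSE]
  ev <- emptyEvents()
  times <- frameTimes(traj)
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    counts <- colSums(contact[s:e, , drop = FALSE])
    res <- names(sort(counts[counts > 0], decreasing = TRUE))
    hb <- trackPeptideLipidHbonds(traj, frames = (s - 1L),
                                  dist = th$hb_dist, angle = th$hb_angle)
    ev <- rbind(ev, eventRecord(
      "anchoring", s - 1L, e - 1L, times, residues = res,
      attributes = list(
        conformation_at_contact = desc$conf_label[s],
        stabilizing_hbonds = if (nrow(hb))
          paste(hb$residue, hb$moiety, sep = ":") else character())))
  }
  ev
}

#' Detect the insertion event
#'
#' Insertion is the first interval in which the peptide center of mass
#' drops below the upper headgroup surface and stays below for at least the
#' insertion dwell. Attributes record the orientation angle at onset and at
#' the end (perpendicular-to-parallel rotation) and whether the final
#' position lies in the headgroup/tail interface slab.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ref a \linkS4class{MembraneRef}.
#' @param desc descriptor table.
#' @param config configuration list.
#' @return event data.frame with zero or one row (type \code{"insertion"}).
#' @export
detectInsertion <- function(traj, ref, desc, config = defaultConfig()) {
  dwell <- dwellFrames(config$dwell_ns$insertion, frameStride(traj))
  tb <- refTable(ref)
  below <- desc$z_com < (tb$z_head_upper - tb$z_center)
  runs <- trueRuns(below)
  runs <- runs[runs$end - runs$start + 1L >= dwell, , drop = FALSE]
  if (!nrow(runs)) return(emptyEvents())
  s <- runs$start[1]; e <- runs$end[1]
  z_end <- desc$z_com[e]
  interface <- z_end < (tb$z_head_upper[e] - tb$z_center[e]) &&
    z_end > (tb$z_tail_upper[e] - tb$z_center[e])
  eventRecord("insertion", s - 1L, e - 1L, frameTimes(traj),
              attributes = list(
                theta_onset = desc$theta_folded[s],
                theta_end = desc$theta_folded[e],
                final_interface = interface))
}

#' Detect conformational and lock events
#'
#' Applies a dwell filter to the per-frame conformation labels and emits an
#' event per persistent transition: any transition into \code{closed} is a
#' \code{closing}, \code{open} to \code{half_closed} is a
#' \code{half_closing}, transitions out of \code{closed} or from
#' \code{half_closed} back to \code{open} are \code{opening}. Persistent
#' locked-to-unlocked transitions of the lock series are emitted as
#' \code{lock_release}. Each closing/half-closing event records the
#' orientation label at onset and the lock state just before onset.
#'
#' @param desc descriptor table (needs \code{conf_label}, \code{lock_state},
#'   \code{orientation}, \code{time_ps}).
#' @param dwell minimum persistence, frames.
#' @return event data.frame.
#' @export
detectConformationEvents <- function(desc, dwell = 5L) {
  times <- desc$time_ps
  lab <- dwellFilterLabels(desc$conf_label, dwell)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ev <- emptyEvents()
  evType <- function(from, to) {
    if (to == "closed") "closing"
    else if (from == "open" && to == "half_closed") "half_closing"
    else "opening"
  }
  for (i in seq_along(r$values)[-1]) {
    from <- r$values[i - 1]; to <- r$values[i]
    if (from == to) next
    s <- starts[i]
    ev <- rbind(ev, eventRecord(
      evType(from, to), s - 1L, min(s - 1L + dwell - 1L, ends[i] - 1L),
      times, attributes = list(
        from = from, to = to,
        orientation_at_onset = desc$orientation[s],
        lock_before_onset = desc$lock_state[max(1L, s - 1L)])))
  }
  lock <- dwellFilterLabels(desc$lock_state, dwell)
  rl <- rle(lock)
  lends <- cumsum(rl$lengths)
  lstarts <- c(1L, utils::head(lends, -1) + 1L)
  for (i in seq_along(rl$values)[-1]) {
    if (rl$values[i - 1] == "locked" && rl$values[i] == "unlocked") {
      s <- lstarts[i]
      ev <- rbind(ev, eventRecord(
        "lock_release", s - 1L, min(s - 1L + dwell - 1L, lends[i] - 1L),
        times, attributes = list(orientation_at_onset = desc$orientation[s])))
    }
  }
  if (nrow(ev)) ev <- ev[order(ev$start_frame), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect leaflet-crossing events
#'
#' A crossing interval starts when the peptide center of mass changes sign
#' across the bilayer center. The crossing is permanent when the residence
#' in the new leaflet exceeds the persistence threshold or lasts until the
#' end of the trajectory, transient when the peptide returns within the
#' threshold. Attributes record the leaflets, the destination-leaflet
#' anchor residue (apolar side chain in contact with destination-leaflet
#' tail atoms around the crossing onset), and the flip analysis of
#' \code{\link{detectFlip}} over the interval.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ref a \linkS4class{MembraneRef}.
#' @param desc descriptor table.
#' @param config configuration list.
#' @return event data.frame (types \code{"crossing_permanent"} /
#'   \code{"crossing_transient"}).
#' @export
detectLeafletCrossing <- function(traj, ref, desc, config = defaultConfig(),
                                  rejoin = 3L, flip_halfwidth = 1.0) {
  persist <- dwellFrames(config$dwell_ns$crossing_persist, frameStride(traj))
  z <- desc$z_com
  nfr <- length(z)
  sgn <- ifelse(z >= 0, 1L, -1L)
  ev <- emptyEvents()
  times <- desc$time_ps
  roles <- atomRoles(traj)
  apo <- apolarResidues(roles, config$residues$polarity)
  dist_cache <- list()
  tailDist <- function(leaf) {
    if (is.null(dist_cache[[leaf]]))
      dist_cache[[leaf]] <<- sidechainTailDistances(traj, residues = apo,
                                                    leaflet = leaf, ref = ref)
    dist_cache[[leaf]]
  }
  home <- sgn[1]
  pos <- 2L
  while (pos <= nfr) {
    if (sgn[pos] == home) { pos <- pos + 1L; next }
    # excursion into the other leaflet; brief returns (< rejoin frames)
    # are absorbed
    s <- pos
    last_new <- s
    ret <- 0L
    j <- s
    while (j <= nfr) {
      if (sgn[j] != home) { last_new <- j; ret <- 0L }
      else { ret <- ret + 1L; if (ret >= rejoin) break }
      j <- j + 1L
    }
    permanent <- (last_new == nfr) || (last_new - s + 1L >= persist)
    to_leaf <- if (home > 0) "lower" else "upper"
    from_leaf <- if (to_leaf == "lower") "upper" else "lower"
    # flip window: contiguous frames around the crossing with the peptide
    # near the membrane center
    lo <- s; while (lo > 1L && abs(z[lo - 1L]) < flip_halfwidth) lo <- lo - 1L
    hi <- s
    hi_max <- min(nfr, if (permanent) nfr else last_new + rejoin)
    while (hi < hi_max && abs(z[hi + 1L]) < flip_halfwidth) hi <- hi + 1L
    flip <- if (hi - lo >= 1L)
      detectFlip(traj, (lo:hi) - 1L, ref, config$residues$reporters)
    else list(flip = FALSE, net_rotation_deg = 0)
    # destination-leaflet anchor contact preceding the crossing
    pre <- max(1L, s - 10L):max(1L, s - 1L)
    dd <- tailDist(to_leaf)
    pre_min <- apply(dd[pre, , drop = FALSE], 2, min)
    anchor <- names(pre_min)[which.min(pre_min)]
    anchored <- min(pre_min) <= config$thresholds$contact_cutoff
    ev <- rbind(ev, eventRecord(
      if (permanent) "crossing_permanent" else "crossing_transient",
      s - 1L, last_new - 1L, times,
      residues = if (anchored) anchor else character(),
      attributes = list(leaflet_from = from_leaf, leaflet_to = to_leaf,
                        flip = flip$flip,
                        net_rotation_deg = flip$net_rotation_deg)))
    if (permanent) { home <- -home; pos <- last_new + 1L }
    else pos <- if (j > last_new) j + 1L else last_new + 1L
  }
  ev
}

#' Merge detector outputs into one timeline
#'
#' Chronologically merges all event tables, flags inconsistent orderings
#' (an in-membrane event before any insertion), and tabulates counts by
#' type and by the trajectory's start conformation.
#'
#' @param ... event data.frames from the detectors.
#' @param start_conformation conformation label of the trajectory's first
#'   frame (\code{"open"}/\code{"closed"}/\code{"half_closed"}).
#' @return list: \code{timeline} (events sorted by start frame, with a
#'   \code{consistent} flag), \code{counts} (table by type),
#'   \code{start_conformation}.
#' @export
assembleTimeline <- function(..., start_conformation = NA_character_) {
  evs <- list(...)
  evs <- evs[vapply(evs, function(e) !is.null(e) && nrow(e) > 0, logical(1))]
  if (!length(evs)) {
    tl <- emptyEvents()
    tl$consistent <- logical()
    return(list(timeline = tl, counts = table(character()),
                start_conformation = start_conformation))
  }
  tl <- do.call(rbind, evs)
  tl <- tl[order(tl$start_frame, tl$type), , drop = FALSE]
  rownames(tl) <- NULL
  ins_start <- if (any(tl$type == "insertion"))
    min(tl$start_frame[tl$type == "insertion"]) else NA_integer_
  in_mem_types <- c("closing", "half_closing", "opening",
                    "crossing_permanent", "crossing_transient", "flip",
                    "lock_release")
  tl$consistent <- TRUE
  bad <- tl$type %in% in_mem_types &
    (is.na(ins_start) | tl$start_frame < ins_start)
  tl$consistent[bad] <- FALSE
  list(timeline = tl, counts = table(tl$type),
       start_conformation = start_conformation)
}
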