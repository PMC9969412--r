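# The per-frame descriptor pipeline and the end-to-end analysis driver.

#' Compute the per-frame descriptor table
#'
#' Runs the geometric and conformational descriptors over all frames:
#' center-of-mass depth relative to the bilayer center, orientation angle
#' (raw and folded), RMSD to the closed reference, intramolecular
#' hydrogen-bond count, register shift, conformation label, lock state, and
#' the orientation A/B label with its reporter projection.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ref a \linkS4class{MembraneRef}; computed if \code{NULL}.
#' @param reference_backbone closed-reference backbone coordinates; default
#'   is the canonical closed template for the peptide's sequence.
#' @param config configuration list.
#' @return data.frame with one row per frame: \code{frame}, \code{time_ps},
#'   \code{z_com}, \code{theta}, \code{theta_folded}, \code{rmsd_closed},
#'   \code{n_intra_hbonds}, \code{register_shift}, \code{conf_label},
#'   \code{lock_state}, \code{orientation}, \code{reporter_projection},
#'   \code{in_membrane}.
#' @export
computeDescriptors <- function(traj, ref = NULL, reference_backbone = NULL,
                               config = defaultConfig()) {
  if (is.null(ref)) ref <- membraneReference(
    traj, hysteresis = config$thresholds$leaflet_hysteresis)
  roles <- atomRoles(traj)
  if (is.null(reference_backbone)) {
    sequence <- sub("[0-9]+$", "", roles@residueLabels)
    reference_backbone <- closedReferenceBackbone(sequence)
  }
  th <- config$thresholds
  tb <- refTable(ref)
  nfr <- nFrames(traj)
  out <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    f <- i - 1L
    refrow <- tb[i, ]
    zc <- refrow$z_center
    z <- peptideComZ(traj, f, zc)
    ax <- backboneEllipseAxes(traj, f)
    ori <- orientationAngle(ax$major, ax$minor)
    rmsd <- rmsdToClosed(traj, f, reference_backbone)
    hb <- intraHbonds(traj, f, dist = th$hb_dist, angle = th$hb_angle)
    cls <- classifyConformation(rmsd, hb,
                                canonical = config$hbond_pattern$canonical,
                                rmsd_threshold = th$rmsd_closed)
    lock <- lockState(traj, f, config$residues$turns, zc,
                      parallel_max_theta = th$parallel_max_theta)
    ol <- classifyOrientation(traj, f, refrow, config$residues$reporters,
                              th$parallel_max_theta)
    out[[i]] <- data.frame(
      frame = f, time_ps = frameTimes(traj)[i], z_com = z,
      theta = ori$theta, theta_folded = ori$theta_folded,
      rmsd_closed = rmsd, n_intra_hbonds = cls$n_hbonds,
      register_shift = cls$register_shift, conf_label = cls$label,
      lock_state = lock$state, orientation = ol$label,
      reporter_projection = ol$reporter_projection,
      in_membrane = ol$in_membrane, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' End-to-end permeation analysis of one trajectory
#'
#' Normalizes the entry side, computes the membrane reference and the
#' descriptor table, runs all event detectors, assembles the timeline, and
#' computes orientation fractions (with the equilibration cut after the
#' insertion event, when one is detected) plus the depth/orientation
#' occupancy histogram. Optionally writes descriptors.csv, events.csv/.json,
#' fractions.csv, heatmap.tsv and heatmap.png to \code{out_dir}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param config configuration list.
#' @param out_dir optional output directory.
#' @return list: \code{descriptors}, \code{reference}, \code{events}
#'   (merged timeline data.frame), \code{counts}, \code{fractions},
#'   \code{heatmap}, \code{start_conformation}.
#' @export
analyzeTrajectory <- function(traj, config = defaultConfig(),
                              out_dir = NULL) {
  traj <- normalizeEntrySide(traj, config$thresholds$contact_cutoff)
  ref <- membraneReference(traj, config$thresholds$leaflet_hysteresis)
  desc <- computeDescriptors(traj, ref = ref, config = config)
  dwell_conf <- dwellFrames(config$dwell_ns$conformation, frameStride(traj))
  dwell_rot <- dwellFrames(config$dwell_ns$rotation, frameStride(traj))
  anchoring <- detectAnchoring(traj, ref, desc, config)
  insertion <- detectInsertion(traj, ref, desc, config)
  conf_ev <- detectConformationEvents(desc, dwell_conf)
  rot_ev <- detectRotationEvents(desc$orientation, desc$time_ps, dwell_rot)
  cross_ev <- detectLeafletCrossing(traj, ref, desc, config)
  start_conf <- desc$conf_label[1]
  tl <- assembleTimeline(anchoring, insertion, conf_ev, rot_ev, cross_ev,
                         start_conformation = start_conf)
  cut <- if (nrow(insertion)) insertion$end_frame[1] else 0L
  fractions <- tryCatch(orientationFractions(desc$orientation, cut),
                        error = function(e) c(A = NA_real_, B = NA_real_))
  hm <- occupancyHeatmap(desc$z_com, desc$theta)
  res <- list(descriptors = desc, reference = ref, events = tl$timeline,
              counts = tl$counts, fractions = fractions, heatmap = hm,
              start_conformation = start_conf)
  if (!is.null(out_dir)) writeAnalysis(res, out_dir)
  res
}

#' Write the analysis outputs of \code{\link{analyzeTrajectory}}
#'
#' @param res result list from \code{\link{analyzeTrajectory}}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, \code{out_dir}.
#' @export
writeAnalysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$descriptors, file.path(out_dir, "descriptors.csv"),
                   row.names = FALSE)
  ev <- res$events
  ev$consistent <- NULL
  writeEventLog(ev, file.path(out_dir, "events.csv"))
  utils::write.csv(data.frame(orientation = names(res$fractions),
                              percent = unname(res$fractions)),
                   file.path(out_dir, "fractions.csv"), row.names = FALSE)
  utils::write.table(res$heatmap$counts, file.path(out_dir, "heatmap.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  grDevices::png(file.path(out_dir, "heatmap.png"), width = 600,
                 height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(x = res$heatmap$theta_breaks, y = res$heatmap$z_breaks,
                  z = t(res$heatmap$counts),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  xlab = "orientation angle [deg]",
                  ylab = "distance to bilayer center [nm]",
                  main = "occupancy")
  invisible(out_dir)
}
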