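# Per-frame membrane reference geometry: headgroup and tail-start surfaces,
# bilayer center, leaflet assignment, area per lipid. The membrane normal is
# fixed to the z axis throughout.

lipidHeadZ <- function(traj, frame) {
  roles <- atomRoles(traj)
  xyz <- frameCoords(traj, frame)
  idx <- roles@headN
  stats::setNames(xyz[idx, 3], roles@lipidId[idx])
}

#' Assign lipids to leaflets for one frame
#'
#' A lipid is assigned by the sign of its headgroup nitrogen z relative to
#' the bilayer midplane (mean headgroup z). Within a hysteresis band of
#' \code{hysteresis} nm around the midplane the previous frame's assignment
#' is carried over to avoid flicker; a lipid exactly on the midplane with no
#' previous assignment is an error.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param previous optional named character vector of the previous frame's
#'   assignment (lipid id -> \code{"upper"}/\code{"lower"}).
#' @param hysteresis half-width of the carry-over band, nm.
#' @return named character vector lipid id -> leaflet.
#' @export
assignLeaflets <- function(traj, frame, previous = NULL, hysteresis = 0.2) {
  hz <- lipidHeadZ(traj, frame)
  if (!length(hz)) stop("no lipid headgroups present")
  mid <- mean(hz)
  leaf <- ifelse(hz > mid, "upper", ifelse(hz < mid, "lower", NA))
  near <- abs(hz - mid) < hysteresis
  if (!is.null(previous)) {
    carry <- near & names(hz) %in% names(previous)
    leaf[carry] <- previous[names(hz)[carry]]
  }
  if (anyNA(leaf)) {
    if (is.null(previous))
      stop("lipid exactly on the midplane in the first frame")
    leaf[is.na(leaf)] <- previous[names(hz)[is.na(leaf)]]
  }
  if (!any(leaf == "upper") || !any(leaf == "lower"))
    stop("degenerate membrane: a leaflet has zero lipids")
  stats::setNames(leaf, names(hz))
}

#' Membrane reference surfaces for one frame
#'
#' Computes the per-leaflet mean z of the headgroup nitrogens (headgroup
#' surfaces), the per-leaflet mean z of the ester-succeeding carbons
#' (tail-start surfaces), and the bilayer center as the midpoint of the two
#' tail-start surfaces.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param leaflets optional precomputed leaflet assignment
#'   (\code{\link{assignLeaflets}}).
#' @return one-row data.frame: \code{frame}, \code{time_ps},
#'   \code{z_head_upper}, \code{z_head_lower}, \code{z_tail_upper},
#'   \code{z_tail_lower}, \code{z_center}, \code{area_per_lipid}.
#' @export
referenceSurfaces <- function(traj, frame, leaflets = NULL) {
  roles <- atomRoles(traj)
  if (!length(roles@headN) || !length(roles@ester))
    stop("lipid role sets are empty")
  if (is.null(leaflets)) leaflets <- assignLeaflets(traj, frame)
  xyz <- frameCoords(traj, frame)
  hz <- lipidHeadZ(traj, frame)
  ez <- xyz[roles@ester, 3]
  elip <- as.character(roles@lipidId[roles@ester])
  eleaf <- leaflets[elip]
  zhu <- mean(hz[leaflets[names(hz)] == "upper"])
  zhl <- mean(hz[leaflets[names(hz)] == "lower"])
  ztu <- mean(ez[eleaf == "upper"])
  ztl <- mean(ez[eleaf == "lower"])
  data.frame(frame = as.integer(frame), time_ps = frameTimes(traj)[frame + 1L],
             z_head_upper = zhu, z_head_lower = zhl,
             z_tail_upper = ztu, z_tail_lower = ztl,
             z_center = (ztu + ztl) / 2,
             area_per_lipid = areaPerLipid(traj, frame, leaflets))
}

#' Area per lipid for one frame
#'
#' \code{box_x * box_y / (lipids per leaflet)}, with the per-leaflet count
#' taken as the mean of the two leaflets.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param leaflets optional precomputed leaflet assignment.
#' @return area per lipid, nm^2.
#' @export
areaPerLipid <- function(traj, frame, leaflets = NULL) {
  if (is.null(leaflets)) leaflets <- assignLeaflets(traj, frame)
  n <- length(leaflets) / 2
  if (n == 0) stop("zero lipids")
  box <- frameBox(traj, frame)
  box[1] * box[2] / n
}

#' Membrane reference geometry for a whole trajectory
#'
#' Runs \code{\link{assignLeaflets}} (with hysteresis carry-over between
#' frames) and \code{\link{referenceSurfaces}} over all frames.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param hysteresis leaflet hysteresis half-width, nm.
#' @return a \linkS4class{MembraneRef}.
#' @export
membraneReference <- function(traj, hysteresis = 0.2) {
  nfr <- nFrames(traj)
  prev <- NULL
  rows <- vector("list", nfr)
  leafmat <- NULL
  for (i in seq_len(nfr)) {
    leaf <- assignLeaflets(traj, i - 1L, previous = prev,
                           hysteresis = hysteresis)
    if (is.null(leafmat))
      leafmat <- matrix(NA_character_, length(leaf), nfr,
                        dimnames = list(names(leaf), NULL))
    leafmat[names(leaf), i] <- leaf
    rows[[i]] <- referenceSurfaces(traj, i - 1L, leaf)
    prev <- leaf
  }
  new("MembraneRef", table = do.call(rbind, rows), leaflets = leafmat,
      lipidIds = as.integer(rownames(leafmat)))
}

#' Export the per-frame reference table as CSV
#'
#' @param ref a \linkS4class{MembraneRef}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeReferenceTable <- function(ref, path) {
  utils::write.csv(refTable(ref), path, row.names = FALSE)
  invisible(path)
}
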