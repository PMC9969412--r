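# Trajectory loading with declarative role resolution, plus event-log and
# descriptor-table I/O.

guessMass <- function(name) {
  el <- toupper(substr(sub("^[0-9]+", "", name), 1, 1))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
         S = 32.06, T = 12.011, W = 15.999, E = 12.011)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}

matchAny <- function(x, patterns) {
  hit <- rep(FALSE, length(x))
  for (p in patterns) hit <- hit | grepl(p, x)
  hit
}

#' Resolve role-tagged atom selections
#'
#' Applies the declarative residue-name/atom-name rules of a configuration
#' (see \code{\link{defaultConfig}}) to an atom table and returns an
#' \linkS4class{AtomRoles} map. A role that is required for the analysis but
#' matches zero atoms raises an error naming the role.
#'
#' @param atoms data.frame with columns \code{name}, \code{resid},
#'   \code{resname}.
#' @param config configuration list.
#' @return an \linkS4class{AtomRoles} object.
#' @export
resolveRoles <- function(atoms, config = defaultConfig()) {
  sel <- config$selection
  seg <- rep("other", nrow(atoms))
  seg[atoms$resname %in% sel$peptide$resnames] <- "peptide"
  seg[atoms$resname %in% sel$lipid$resnames] <- "lipid"
  seg[atoms$resname %in% sel$solvent$resnames] <- "solvent"

  pep <- which(seg == "peptide")
  lip <- which(seg == "lipid")
  is_bb <- atoms$name %in% sel$peptide$backbone
  backbone <- pep[is_bb[pep]]
  ellipse <- pep[grepl(sel$peptide$ellipse, atoms$name[pep]) & is_bb[pep]]
  if (length(pep) && !length(backbone))
    stop("role resolution failed: 'peptide_backbone' matches zero atoms")
  if (length(pep) && !length(ellipse))
    stop("role resolution failed: 'ellipse' matches zero atoms")

  presid <- sort(unique(atoms$resid[pep]))
  labels <- vapply(presid, function(r) {
    paste0(atoms$resname[pep][match(r, atoms$resid[pep])], r)
  }, character(1))
  pickPer <- function(pattern) {
    v <- vapply(presid, function(r) {
      idx <- pep[atoms$resid[pep] == r & grepl(pattern, atoms$name[pep])]
      if (length(idx)) idx[1] else NA_integer_
    }, integer(1))
    stats::setNames(v, labels)
  }
  bbN <- pickPer(sel$peptide$donor)
  bbH <- pickPer(sel$peptide$donor_h)
  bbO <- pickPer(sel$peptide$acceptor)
  sidechains <- lapply(presid, function(r)
    pep[atoms$resid[pep] == r & grepl(sel$peptide$sidechain, atoms$name[pep])])
  names(sidechains) <- labels

  pickLip <- function(pattern, role) {
    idx <- lip[grepl(pattern, atoms$name[lip])]
    if (length(lip) && !length(idx))
      stop(sprintf("role resolution failed: '%s' matches zero atoms", role))
    idx
  }
  headN <- pickLip(sel$lipid$headgroup_n, "headgroup_nitrogens")
  phosphate <- pickLip(sel$lipid$phosphate, "phosphate_atoms")
  ester <- pickLip(sel$lipid$ester, "ester_carbons")
  tail <- pickLip(sel$lipid$tail, "tail_atoms")
  claimed <- c(headN, phosphate, ester)
  tail <- setdiff(tail, claimed)

  lipidId <- rep(NA_integer_, nrow(atoms))
  lipidId[lip] <- atoms$resid[lip]

  new("AtomRoles", backbone = as.integer(backbone),
      ellipse = as.integer(ellipse),
      bbN = bbN, bbH = bbH, bbO = bbO, sidechains = sidechains,
      headN = as.integer(headN), phosphate = as.integer(phosphate),
      ester = as.integer(ester), tail = as.integer(tail),
      solvent = as.integer(which(seg == "solvent")),
      lipidId = lipidId, residueLabels = labels)
}

#' Load a structure + trajectory into a Trajectory object
#'
#' Reads a structure file (GRO or PDB) and optionally a coordinate
#' trajectory (multi-frame GRO text, or DCD binary), resolves the atom
#' roles from the configuration's selection rules, and returns a
#' \linkS4class{Trajectory}. Coordinates are stored in nm and times in ps
#' regardless of input dialect; frames are indexed 0-based.
#'
#' @param structure_path path to a \code{.gro} or \code{.pdb} file.
#' @param trajectory_path optional path to a multi-frame \code{.gro} or a
#'   \code{.dcd} file; if \code{NULL} the structure's frame(s) are used.
#' @param config configuration list (see \code{\link{loadConfig}}).
#' @return a \linkS4class{Trajectory}.
#' @export
loadTrajectory <- function(structure_path, trajectory_path = NULL,
                           config = defaultConfig()) {
  if (!file.exists(structure_path)) stop("structure file not found: ",
                                         structure_path)
  ext <- tolower(tools::file_ext(structure_path))
  st <- switch(ext,
               gro = readGro(structure_path),
               pdb = readPdbStructure(structure_path),
               stop("unsupported structure format: .", ext))
  atoms <- st$atoms
  atoms$mass <- guessMass(atoms$name)

  if (is.null(trajectory_path)) {
    tr <- st
  } else {
    if (!file.exists(trajectory_path)) stop("trajectory file not found: ",
                                            trajectory_path)
    text <- tolower(tools::file_ext(trajectory_path))
    tr <- switch(text,
                 gro = readGro(trajectory_path),
                 dcd = readDcdTrajectory(trajectory_path, st$box[1, ]),
                 stop("unsupported trajectory format: .", text))
    n_tr <- nrow(if (!is.null(tr$atoms)) tr$atoms else tr$coords[[1]])
    if (!is.null(tr$atoms)) n_tr <- nrow(tr$atoms) else
      n_tr <- nrow(tr$coords[[1]])
    if (n_tr != nrow(atoms))
      stop(sprintf("atom-count mismatch: structure has %d, trajectory has %d",
                   nrow(atoms), n_tr))
  }
  roles <- resolveRoles(atoms, config)
  nfr <- length(tr$coords)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  for (i in seq_len(nfr)) arr[, , i] <- tr$coords[[i]]
  times <- tr$times
  if (length(unique(times)) != nfr) times <- seq_len(nfr) - 1
  seg <- rep("other", nrow(atoms))
  seg[c(roles@backbone, unlist(roles@sidechains, use.names = FALSE))] <- "peptide"
  seg[!is.na(roles@lipidId)] <- "lipid"
  seg[roles@solvent] <- "solvent"
  atoms$segment <- seg
  new("Trajectory", coords = arr, box = tr$box, times = as.numeric(times),
      atoms = atoms, roles = roles)
}

#' Write a Trajectory back to GRO files
#'
#' Writes the first frame as a GRO structure and, optionally, all frames as
#' a multi-frame GRO trajectory (the plain-text trajectory dialect).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param structure_path output path for the single-frame structure.
#' @param trajectory_path optional output path for the multi-frame file.
#' @return invisibly, \code{structure_path}.
#' @export
writeTrajectory <- function(traj, structure_path, trajectory_path = NULL) {
  atoms <- atomData(traj)
  con <- file(structure_path, "w")
  writeGroFrame(con, atoms, frameCoords(traj, 0), frameBox(traj, 0),
                frameTimes(traj)[1])
  close(con)
  if (!is.null(trajectory_path)) {
    con <- file(trajectory_path, "w")
    for (i in seq_len(nFrames(traj))) {
      writeGroFrame(con, atoms, traj@coords[, , i], traj@box[i, ],
                    traj@times[i])
    }
    close(con)
  }
  invisible(structure_path)
}

## ---- event logs -----------------------------------------------------------

EVENT_COLUMNS <- c("type", "start_frame", "end_frame", "start_time_ps",
                   "end_time_ps", "residues", "attributes")

#' Empty event table
#'
#' @return a zero-row data.frame with the event-log schema: \code{type},
#'   \code{start_frame}, \code{end_frame}, \code{start_time_ps},
#'   \code{end_time_ps}, \code{residues} (';'-joined labels) and
#'   \code{attributes} (JSON-encoded key/value map).
#' @export
emptyEvents <- function() {
  data.frame(type = character(), start_frame = integer(),
             end_frame = integer(), start_time_ps = numeric(),
             end_time_ps = numeric(), residues = character(),
             attributes = character(), stringsAsFactors = FALSE)
}

#' Construct a single event record
#'
#' @param type event type string (e.g. \code{"anchoring"},
#'   \code{"crossing_permanent"}).
#' @param start_frame,end_frame 0-based frame interval, start <= end.
#' @param times numeric vector of frame times (ps) for conversion.
#' @param residues character vector of participating residue labels.
#' @param attributes named list of extra attributes (JSON-encoded).
#' @return one-row event data.frame.
#' @export
eventRecord <- function(type, start_frame, end_frame, times,
                        residues = character(), attributes = list()) {
  stopifnot(start_frame <= end_frame)
  data.frame(type = type, start_frame = as.integer(start_frame),
             end_frame = as.integer(end_frame),
             start_time_ps = times[start_frame + 1L],
             end_time_ps = times[end_frame + 1L],
             residues = paste(residues, collapse = ";"),
             attributes = as.character(
               jsonlite::toJSON(attributes, auto_unbox = TRUE)),
             stringsAsFactors = FALSE)
}

#' Write an event log as CSV and JSON
#'
#' Writes one row (CSV) and one object (JSON) per event. Events must be
#' sorted by start frame.
#'
#' @param events event data.frame (see \code{\link{emptyEvents}}).
#' @param csv_path output CSV path.
#' @param json_path output JSON path; default replaces the extension.
#' @return invisibly, \code{csv_path}.
#' @export
writeEventLog <- function(events, csv_path,
                          json_path = sub("\\.[^.]*$", ".json", csv_path)) {
  stopifnot(all(EVENT_COLUMNS %in% names(events)))
  if (nrow(events) > 1L && is.unsorted(events$start_frame))
    stop("events must be sorted by start_frame")
  utils::write.csv(events[, EVENT_COLUMNS], csv_path, row.names = FALSE)
  objs <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    list(type = ev$type, start_frame = ev$start_frame,
         end_frame = ev$end_frame, start_time_ps = ev$start_time_ps,
         end_time_ps = ev$end_time_ps,
         residues = if (nzchar(ev$residues))
           strsplit(ev$residues, ";")[[1]] else character(),
         attributes = jsonlite::fromJSON(ev$attributes))
  })
  jsonlite::write_json(objs, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' Read an event log written by \code{\link{writeEventLog}}
#'
#' @param csv_path path to the CSV event log.
#' @return event data.frame with the standard schema.
#' @export
readEventLog <- function(csv_path) {
  ev <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = c(type = "character",
                                       residues = "character",
                                       attributes = "character"))
  if (!nrow(ev)) return(emptyEvents())
  ev$residues[is.na(ev$residues)] <- ""
  ev[, EVENT_COLUMNS]
}
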