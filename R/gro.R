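# Readers/writers for the text coordinate dialects used by the pipeline.
# GRO (GROMACS fixed-width, nm) is parsed directly; multi-frame GRO files
# double as the plain-text trajectory fallback. PDB structures and DCD
# binary trajectories are read through bio3d and converted from Angstrom
# to nm on the way in.

GRO_FMT <- "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"

# parse one GRO frame starting at line `at`; returns list(atoms, coords,
# box, time, next_at) or NULL at EOF
parseGroFrame <- function(lines, at) {
  if (at > length(lines) || !nzchar(trimws(lines[at]))) return(NULL)
  title <- lines[at]
  n <- as.integer(trimws(lines[at + 1L]))
  if (is.na(n)) stop("malformed GRO: bad atom count at line ", at + 1L)
  rows <- lines[(at + 2L):(at + 1L + n)]
  resid <- as.integer(substr(rows, 1, 5))
  resname <- trimws(substr(rows, 6, 10))
  name <- trimws(substr(rows, 11, 15))
  x <- as.numeric(substr(rows, 21, 28))
  y <- as.numeric(substr(rows, 29, 36))
  z <- as.numeric(substr(rows, 37, 44))
  boxline <- as.numeric(strsplit(trimws(lines[at + 2L + n]), "\\s+")[[1]])
  tm <- 0
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m))
  list(atoms = data.frame(name = name, resid = resid, resname = resname,
                          stringsAsFactors = FALSE),
       coords = cbind(x, y, z), box = boxline[1:3], time = tm,
       next_at = at + 3L + n)
}

readGro <- function(path) {
  lines <- readLines(path)
  frames <- list(); at <- 1L; atoms <- NULL
  repeat {
    fr <- parseGroFrame(lines, at)
    if (is.null(fr)) break
    if (is.null(atoms)) atoms <- fr$atoms
    else if (nrow(fr$atoms) != nrow(atoms))
      stop("atom count changes between GRO frames in ", path)
    frames[[length(frames) + 1L]] <- fr
    at <- fr$next_at
    if (at > length(lines)) break
  }
  if (!length(frames)) stop("no frames found in GRO file ", path)
  list(atoms = atoms,
       coords = lapply(frames, `[[`, "coords"),
       box = do.call(rbind, lapply(frames, `[[`, "box")),
       times = vapply(frames, `[[`, numeric(1), "time"))
}

writeGroFrame <- function(con, atoms, coords, box, time) {
  writeLines(sprintf("generated by permeatrace, t= %.3f", time), con)
  writeLines(sprintf("%5d", nrow(atoms)), con)
  writeLines(sprintf(GRO_FMT, atoms$resid %% 100000L, atoms$resname,
                     atoms$name, seq_len(nrow(atoms)) %% 100000L,
                     coords[, 1], coords[, 2], coords[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
}

readPdbStructure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom
  box <- c(10, 10, 10)
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cl))
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33))) / 10
  list(atoms = data.frame(name = trimws(sel$elety),
                          resid = as.integer(sel$resno),
                          resname = trimws(sel$resid),
                          stringsAsFactors = FALSE),
       coords = list(cbind(sel$x, sel$y, sel$z) / 10),
       box = matrix(box, 1, 3), times = 0)
}

readDcdTrajectory <- function(path, fallback_box) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nfr <- nrow(xyz)
  coords <- lapply(seq_len(nfr), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10)
  list(coords = coords,
       box = matrix(rep(fallback_box, each = nfr), nfr, 3),
       times = seq_len(nfr) - 1)
}
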