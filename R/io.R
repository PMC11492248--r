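# File-format boundary: everything internal is Angstrom / ps; GRO and
# TRR files are nm (converted on read/write), PDB is Angstrom.
#
# On reading coordinate files, molecules are identified with residues
# (the CG convention: one residue per lipid molecule), so molid = resid
# and the residue name is the species label.

.nm <- 10   # Angstrom per nm

#' Read a GRO coordinate (or concatenated multi-frame GRO) file
#'
#' @param path file path.
#' @return a [bead_frame()] (single frame) or [bead_trajectory()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list(); i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1)
      stop("unparsable GRO atom count at line ", i + 1L, ": '",
           lines[i + 1L], "'")
    if (i + 1L + n + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i)
    at <- lines[(i + 2L):(i + 1L + n)]
    resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
    if (anyNA(resid))
      stop("unparsable GRO atom record at line ",
           i + 1L + which(is.na(resid))[1], ": '",
           at[which(is.na(resid))[1]], "'")
    species <- trimws(substr(at, 6, 10))
    name <- trimws(substr(at, 11, 15))
    xyz <- matrix(suppressWarnings(as.numeric(c(
      substr(at, 21, 28), substr(at, 29, 36), substr(at, 37, 44)))), ncol = 3)
    if (anyNA(xyz))
      stop("unparsable GRO coordinates at line ",
           i + 1L + which(is.na(rowSums(xyz)))[1])
    boxv <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + n]), "\\s+")[[1]]))
    if (length(boxv) < 3 || anyNA(boxv[1:3]))
      stop("unparsable GRO box line at line ", i + 2L + n)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    fi <- fi + 1L
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else fi - 1
    frames[[fi]] <- bead_frame(
      data.frame(name = name, resid = resid, molid = resid,
                 species = species,
                 x = xyz[, 1] * .nm, y = xyz[, 2] * .nm, z = xyz[, 3] * .nm),
      box = boxv[1:3] * .nm, time = time, frame = fi)
    i <- i + n + 3L
  }
  if (!length(frames)) stop("no frames found in ", path)
  if (length(frames) == 1L) frames[[1]] else bead_trajectory(frames)
}

#' Write frames to a GRO file (multi-frame GRO for trajectories)
#'
#' Coordinates are written in nm at the GRO precision of 0.001 nm
#' (0.01 Angstrom).
#'
#' @param x a [bead_frame()] or [bead_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path) {
  frames <- if (inherits(x, "bead_frame")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    b <- fr$beads
    writeLines(sprintf("membrane scene, t= %.3f", fr$time), con)
    writeLines(sprintf("%5d", nrow(b)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$resid %% 100000L, substr(b$species, 1, 5),
                       substr(b$name, 1, 5),
                       seq_len(nrow(b)) %% 100000L,
                       b$x / .nm, b$y / .nm, b$z / .nm), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1] / .nm,
                       fr$box[2] / .nm, fr$box[3] / .nm), con)
  }
  invisible(path)
}

#' Read a PDB file (single or multi-MODEL) into bead frames
#'
#' Parsing is delegated to \pkg{bio3d}.  PDB files carry no frame
#' times; model indices are used as ps.  The box is taken from the
#' CRYST1 record when present, otherwise from the coordinate extent.
#'
#' @param path file path.
#' @return a [bead_frame()] or [bead_trajectory()].
#' @export
read_pdb_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
  if (length(cr)) {
    abc <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    if (!anyNA(abc) && all(abc > 0)) box <- abc
  }
  nmod <- nrow(pdb$xyz)
  mk <- function(xyz, i) {
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    bead_frame(data.frame(name = a$elety, resid = a$resno, molid = a$resno,
                          species = a$resid, x = m[, 1], y = m[, 2],
                          z = m[, 3]),
               box = box %||% (apply(m, 2, function(v) diff(range(v))) + 20),
               time = i - 1, frame = i)
  }
  frames <- lapply(seq_len(nmod), function(i) mk(pdb$xyz[i, ], i))
  if (nmod == 1L) frames[[1]] else bead_trajectory(frames)
}

## ---- TRR (GROMACS binary trajectory, big-endian XDR) ----------------

.trr_read_string <- function(con) {
  slen <- readBin(con, "integer", 1, endian = "big")
  len <- readBin(con, "integer", 1, endian = "big")
  raw <- readBin(con, "raw", 4 * ceiling(len / 4))
  rawToChar(raw[seq_len(len - 1)])
}

#' Read a GROMACS TRR trajectory
#'
#' A self-contained reader for the uncompressed TRR format (big-endian
#' XDR; single or double precision).  Only positions, box and times are
#' used; velocities and forces are skipped.  Bead labels come from the
#' accompanying topology frame.
#'
#' @param path TRR file path.
#' @param topology a [bead_frame()] providing names/residues/species.
#' @return a [bead_trajectory()] (Angstrom / ps).
#' @export
read_trr <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list(); fi <- 0L
  repeat {
    magic <- readBin(con, "integer", 1, endian = "big")
    if (!length(magic)) break
    if (magic != 1993)
      stop("bad TRR magic number (", magic, ") in ", path)
    .trr_read_string(con)
    h <- readBin(con, "integer", 13, endian = "big")
    names(h) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                  "x", "v", "f", "natoms", "step", "nre")
    if (h["natoms"] != nbeads(topology))
      stop("TRR frame has ", h["natoms"], " beads but topology has ",
           nbeads(topology))
    fsize <- if (h["box"] > 0) h[["box"]] / 9 else h[["x"]] / (3 * h[["natoms"]])
    if (!fsize %in% c(4, 8)) stop("cannot determine TRR precision")
    rfloat <- function(n) readBin(con, "double", n, size = fsize,
                                  endian = "big")
    t_lambda <- rfloat(2)
    skip <- function(sz) if (sz > 0) readBin(con, "raw", sz)
    box <- if (h["box"] > 0) rfloat(9) else rep(0, 9)
    skip(h[["vir"]]); skip(h[["pres"]])
    if (h["x"] <= 0) stop("TRR frame ", fi + 1L, " carries no coordinates")
    xyz <- matrix(rfloat(3 * h[["natoms"]]), ncol = 3, byrow = TRUE)
    skip(h[["v"]]); skip(h[["f"]])
    fi <- fi + 1L
    b <- topology$beads
    b$x <- xyz[, 1] * .nm; b$y <- xyz[, 2] * .nm; b$z <- xyz[, 3] * .nm
    frames[[fi]] <- bead_frame(b, box = box[c(1, 5, 9)] * .nm,
                               time = t_lambda[1], frame = fi)
  }
  if (!length(frames)) stop("no frames found in ", path)
  bead_trajectory(frames)
}

#' Write a trajectory as single-precision TRR
#'
#' @param x a [bead_frame()] or [bead_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trr <- function(x, path) {
  frames <- if (inherits(x, "bead_frame")) list(x) else x
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(v) writeBin(as.integer(v), con, endian = "big")
  wfloat <- function(v) writeBin(as.numeric(v), con, size = 4,
                                 endian = "big")
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    n <- nbeads(fr)
    wint(1993)
    wint(13); wint(13)
    writeBin(c(charToRaw("GMX_trn_file"), as.raw(c(0, 0, 0, 0))), con)
    wint(c(0, 0, 36, 0, 0, 0, 0, 3 * 4 * n, 0, 0, n, i - 1L, 0))
    wfloat(c(fr$time, 0))                     # t (ps), lambda
    box <- diag(fr$box / .nm)
    wfloat(as.numeric(t(box)))
    m <- coords(fr) / .nm
    wfloat(as.numeric(t(m)))
  }
  invisible(path)
}

## ---- dispatching reader ---------------------------------------------

.guess_format <- function(path, hint = NULL) {
  if (!is.null(hint)) return(tolower(hint))
  tolower(tools::file_ext(path))
}

#' Read coordinate + trajectory files into bead frames
#'
#' Accepts a GRO or PDB topology, optionally paired with a trajectory
#' (TRR, multi-frame GRO, or multi-MODEL PDB).  Units are normalised to
#' Angstrom and ps.  Single-coordinate files yield one frame.
#'
#' @param topology_path coordinate file (GRO or PDB).
#' @param trajectory_path optional trajectory file.
#' @param format_hint optional format override (`"gro"`, `"pdb"`,
#'   `"trr"`) for the trajectory file.
#' @return a [bead_frame()] or [bead_trajectory()].
#' @export
read_frames <- function(topology_path, trajectory_path = NULL,
                        format_hint = NULL) {
  tfmt <- .guess_format(topology_path)
  top <- switch(tfmt,
                gro = read_gro(topology_path),
                pdb = read_pdb_frames(topology_path),
                stop("unsupported topology format '", tfmt, "'"))
  top1 <- if (inherits(top, "bead_trajectory")) top[[1]] else top
  if (is.null(trajectory_path)) return(top)
  ffmt <- .guess_format(trajectory_path, format_hint)
  tr <- switch(ffmt,
               trr = read_trr(trajectory_path, top1),
               gro = read_gro(trajectory_path),
               pdb = read_pdb_frames(trajectory_path),
               stop("unsupported trajectory format '", ffmt, "'"))
  tr <- as_trajectory(tr)
  if (nbeads(tr[[1]]) != nbeads(top1))
    stop("topology has ", nbeads(top1), " beads but trajectory frames have ",
         nbeads(tr[[1]]))
  # trajectory coordinates + topology labels
  relabel <- function(fr) {
    b <- top1$beads
    b$x <- fr$beads$x; b$y <- fr$beads$y; b$z <- fr$beads$z
    bead_frame(b, fr$box, fr$time, fr$frame)
  }
  bead_trajectory(lapply(tr, relabel))
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Every atom of a residue carries that residue's score, formatted to
#' two decimals per the fixed-width PDB standard; residues without a
#' score get 0.00.  Scores outside the printable range [-99.99, 999.99]
#' are clamped with a warning.  The usual vehicle for visualising
#' contact frequencies on a structure.
#'
#' @param frame a [bead_frame()].
#' @param scores named numeric vector, residue id -> score.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_score_structure <- function(frame, scores = NULL, path) {
  b <- frame$beads
  bf <- rep(0, nrow(b))
  if (!is.null(scores)) {
    if (any(!is.finite(scores))) stop("scores must be finite")
    hit <- match(as.character(b$resid), names(scores))
    bf[!is.na(hit)] <- scores[hit[!is.na(hit)]]
    if (any(bf > 999.99 | bf < -99.99)) {
      warning("score magnitude overflows the 6-character B-factor field; ",
              "clamping")
      bf <- clamp(bf, -99.99, 999.99)
    }
  }
  # fixed-width ATOM records written directly: 4-character CG residue
  # names occupy columns 18-21, which trips general-purpose writers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1], frame$box[2], frame$box[3]), con)
  nm <- ifelse(nchar(b$name) < 4, paste0(" ", b$name), b$name)
  writeLines(sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(nrow(b)) %% 100000L, substr(nm, 1, 4),
                     substr(b$species, 1, 4), b$resid %% 10000L,
                     b$x, b$y, b$z, 1, bf), con)
  writeLines("END", con)
  invisible(path)
}
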