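#' Read a molecular structure (PDB or GRO)
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files (fixed-width GROMACS
#' format, coordinates in nm) are parsed directly and converted to Angstrom.
#' All coordinates returned by this package are in Angstrom.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param substrate_resname Optional residue name; if given, the topology is
#'   partitioned into protein and substrate copies with
#'   [topology_by_residue()], otherwise all atoms are protein.
#' @return A list with elements `topology` ([topology()]), `coords`
#'   (`n_atoms x 3` matrix, Angstrom) and `box` ([sim_box()] or `NULL` when
#'   the file carries no box).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           substrate_resname = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gro = "gro", pdb = "pdb", ent = "pdb",
                     abort(paste0("cannot guess structure format of ", path)))
  }
  parsed <- if (format == "gro") .read_gro(path) else .read_pdb_single(path)
  atoms <- parsed$atoms
  if (nrow(atoms) == 0L) abort(paste0("no atoms in ", path))
  top <- if (is.null(substrate_resname)) {
    topology(atoms, protein = seq_len(nrow(atoms)))
  } else {
    topology_by_residue(atoms, substrate_resname)
  }
  list(topology = top, coords = parsed$coords, box = parsed$box)
}

.read_pdb_single <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("failed to parse PDB ", path, ": ",
                                 conditionMessage(e)))
                  })
  a <- pdb$atom
  atoms <- tibble(
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain), "", a$chain),
    element = {
      el <- if (!is.null(a$elesy)) trimws(a$elesy) else ""
      ifelse(is.na(el) | el == "", .guess_element(trimws(a$elety)), el)
    }
  )
  coords <- cbind(a$x, a$y, a$z)
  box <- NULL
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst)) {
    v <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                       substr(cryst[1], 16, 24),
                                       substr(cryst[1], 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cryst[1], 34, 40),
                                         substr(cryst[1], 41, 47),
                                         substr(cryst[1], 48, 54))))
    if (all(is.finite(v)) && all(v > 0)) {
      if (all(is.finite(ang)) && any(abs(ang - 90) > 1e-3)) {
        abort("triclinic boxes are not supported (CRYST1 angles != 90)")
      }
      box <- sim_box(v, periodic = TRUE)
    }
  }
  list(atoms = atoms, coords = coords, box = box)
}

.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) abort(paste0("no atoms in ", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(paste0("malformed GRO atom count (line 2) in ", path))
  if (n == 0L) abort(paste0("no atoms in ", path))
  if (length(lines) < 2L + n + 1L) {
    abort(sprintf("GRO file %s truncated: %d atoms declared, %d atom lines",
                  path, n, max(0L, length(lines) - 3L)))
  }
  al <- lines[3:(2 + n)]
  num <- function(from, to) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (anyNA(v)) {
      abort(sprintf("malformed GRO record at line %d of %s",
                    2L + which(is.na(v))[1], path))
    }
    v
  }
  atoms <- tibble(
    atom_name = trimws(substr(al, 11, 15)),
    residue_name = trimws(substr(al, 6, 10)),
    residue_number = as.integer(num(1, 5)),
    chain_id = ""
  )
  coords <- cbind(num(21, 28), num(29, 36), num(37, 44)) * 10  # nm -> A
  bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                             "\\s+")[[1]]))
  box <- NULL
  if (length(bv) >= 3 && all(is.finite(bv[1:3])) && all(bv[1:3] > 0)) {
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9)) {
      abort("triclinic boxes are not supported (GRO off-diagonal box vectors)")
    }
    box <- sim_box(bv[1:3] * 10, periodic = TRUE)
  }
  list(atoms = atoms, coords = coords, box = box)
}

.pdb_atom_line <- function(i, name, resname, chain, resno, xyz, element) {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    i %% 100000, nm, substr(resname, 1, 3),
    substr(ifelse(nchar(chain), chain, " "), 1, 1),
    resno %% 10000, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' One `MODEL`/`ENDMDL` block per frame; a periodic box is recorded as a
#' `CRYST1` record. Coordinates are written at the PDB precision of 1e-3 A.
#'
#' @param x A `trajectory`, or a [topology()] (then `coords` is required).
#' @param path Output file path.
#' @param coords `n_atoms x 3` matrix when `x` is a topology.
#' @param box Optional [sim_box()] when `x` is a topology.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, coords = NULL, box = NULL) {
  if (inherits(x, "trajectory")) {
    top <- x$topology
    arr <- x$coords
    box <- x$box[[1]]
  } else {
    top <- x
    if (is.null(coords)) abort("coords required when writing a topology")
    arr <- array(coords, c(dim(coords), 1L))
  }
  a <- top$atoms
  nf <- dim(arr)[3]
  out <- character(0)
  if (!is.null(box) && box$periodic) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box$lengths[1], box$lengths[2], box$lengths[3], 90, 90, 90)
  }
  for (f in seq_len(nf)) {
    if (nf > 1L) out <- c(out, sprintf("MODEL     %4d", f))
    lines <- vapply(seq_len(nrow(a)), function(i) {
      .pdb_atom_line(i, a$atom_name[i], a$residue_name[i], a$chain_id[i],
                     a$residue_number[i], arr[i, , f], a$element[i])
    }, character(1))
    out <- c(out, lines, if (nf > 1L) "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a coordinate trajectory (DCD or multi-model PDB)
#'
#' DCD files are read with [bio3d::read.dcd()]; multi-model PDB with
#' [bio3d::read.pdb()]. XTC is not supported: convert to DCD or PDB first
#' (e.g. `mdconvert` or `gmx trjconv`).
#'
#' @param path Trajectory file path.
#' @param topology The [topology()] the frames belong to; atom counts must
#'   match.
#' @param format `"auto"`, `"dcd"` or `"pdb"`.
#' @param frame_interval Time between stored frames (ps).
#' @param box Optional [sim_box()] applied to every frame; when `NULL`, the
#'   box is taken from the file when present (PDB `CRYST1`) and otherwise
#'   non-periodic.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "dcd", "pdb", "xtc"),
                            frame_interval = 1, box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcd = "dcd", pdb = "pdb", xtc = "xtc",
                     abort(paste0("cannot guess trajectory format of ", path)))
  }
  if (format == "xtc") {
    abort("XTC reading is not supported; convert to DCD or multi-model PDB")
  }
  n <- n_atoms(topology)
  if (format == "dcd") {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) {
                      abort(paste0("failed to read DCD ", path, ": ",
                                   conditionMessage(e)))
                    })
    xyz <- unclass(xyz)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    file_box <- NULL
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) {
                      abort(paste0("failed to read PDB ", path, ": ",
                                   conditionMessage(e)))
                    })
    xyz <- unclass(pdb$xyz)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    file_box <- .read_pdb_single(path)$box
  }
  if (ncol(xyz) != 3L * n) {
    abort(sprintf("trajectory %s has %d atoms but topology has %d",
                  path, ncol(xyz) %/% 3L, n))
  }
  nf <- nrow(xyz)
  arr <- aperm(array(t(xyz), c(3L, n, nf)), c(2L, 1L, 3L))
  trajectory(topology, arr,
             box = box %||% file_box %||% sim_box(periodic = FALSE),
             frame_interval = frame_interval)
}

#' Write a trajectory to DCD
#'
#' Writes the CHARMM/NAMD DCD binary layout (single-precision coordinates,
#' no unit-cell records); files round-trip through [bio3d::read.dcd()].
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  marker <- function(len) writeBin(as.integer(len), con, size = 4L)
  # header record: "CORD" + 20 control ints (delta occupies slot 10 as float)
  marker(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(as.integer(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L)), con, size = 4L)
  writeBin(as.numeric(traj$frame_interval), con, size = 4L)
  writeBin(as.integer(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L)),
           con, size = 4L)
  marker(84L)
  title <- formatC("Written by subaccess", width = -80L)
  marker(84L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  marker(84L)
  marker(4L)
  writeBin(as.integer(na), con, size = 4L)
  marker(4L)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      marker(4L * na)
      writeBin(as.numeric(traj$coords[, d, f]), con, size = 4L)
      marker(4L * na)
    }
  }
  invisible(path)
}

#' Write a trajectory
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), dcd = "dcd", pdb = "pdb",
                     abort(paste0("cannot guess trajectory format of ", path)))
  }
  if (format == "dcd") write_dcd(traj, path) else write_pdb(traj, path)
}

#' Write a tabular result as CSV with a unit-comment header
#'
#' All tabular outputs of the package use plain CSV preceded by `#` comment
#' lines naming the units of each column.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comment Character vector of comment lines (without the leading
#'   `"# "`).
#' @return `path`, invisibly.
#' @export
write_csv_units <- function(x, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_units()]
#' @param path File path.
#' @return A tibble (comment lines skipped).
#' @export
read_csv_units <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}
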