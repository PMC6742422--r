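#' Static structure container
#'
#' A light container for one model of a macromolecular structure: an atom
#' table plus an n x 3 coordinate matrix in Angstrom. Constructed directly
#' or via [read_structure()].
#'
#' @param atoms data.frame with columns `eleno` (atom id), `elety` (atom
#'   name), `elesy` (element symbol), `resno`, `resid`, `chain`, `insert`
#'   (insertion code, "" if none), `occ`.
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param model optional model index.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, model = 1L) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3, nrow(xyz) == nrow(atoms))
  if (nrow(atoms) == 0) stop("empty model: structure has no atoms")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  if (anyDuplicated(atoms$eleno)) stop("atom ids not unique within model")
  need <- c("eleno", "elety", "elesy", "resno", "resid", "chain", "insert", "occ")
  for (f in setdiff(need, names(atoms))) {
    atoms[[f]] <- switch(f, elesy = guess_element(atoms$elety),
                         insert = "", occ = 1, stop("missing atom field: ", f))
  }
  structure(list(atoms = atoms[, need], xyz = xyz, model = model),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# element symbol from a PDB atom name ("CA" -> C, "MG" -> MG, "O4'" -> O)
guess_element <- function(elety) {
  two <- c("MG", "FE", "ZN", "MN", "NA", "CL", "CA")  # CA only as ion resname context
  vapply(elety, function(nm) {
    nm <- toupper(gsub("[^A-Za-z]", "", nm))
    if (nm %in% c("MG", "ZN", "FE", "MN")) return(nm)
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# standard atomic masses (Da) by element symbol
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, MG = 24.305, ZN = 65.38,
                     FE = 55.845, MN = 54.938, X = 12.0)

#' Atomic masses of a structure's atoms
#' @param structure a `structure_model`.
#' @return numeric vector of masses in Daltons (unknown elements fall back
#'   to 12 Da).
#' @export
atom_masses <- function(structure) {
  el <- toupper(structure$atoms$elesy)
  m <- .element_masses[el]
  m[is.na(m)] <- .element_masses[["X"]]
  unname(m)
}

#' Read a structure file (PDB or mmCIF)
#'
#' Parses the file with bio3d and returns one model as a
#' [structure_model()]. Alternate locations are resolved deterministically
#' to the first altloc id; insertion codes are retained in the atom table.
#'
#' @param path file path.
#' @param format "pdb" or "cif"; default guessed from the extension.
#' @param model model index to extract (multi-model files), default 1.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = NULL, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input: zero-byte structure file")
  if (is.null(format))
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  format <- match.arg(format, c("pdb", "cif"))
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("unparseable ", format, " file: ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model: no ATOM/HETATM records")
  # first altloc id per atom slot
  if (!is.null(at$alt)) {
    alt <- at$alt
    alt[is.na(alt)] <- ""
    keep_alt <- alt == "" | !duplicated(paste(at$chain, at$resno, at$insert, at$elety))
    at <- at[alt == "" | alt == sort(unique(alt[alt != ""]))[1] | keep_alt, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno,
                               ifelse(is.na(at$insert), "", at$insert), at$elety)), ,
             drop = FALSE]
  }
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod) stop("model index ", model, " exceeds ", nmod, " models")
  xyz_row <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz_row, ncol = 3, byrow = TRUE)[as.integer(rownames(at)), , drop = FALSE]
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety,
    elesy = if (!is.null(at$elesy) && !all(is.na(at$elesy)) && !all(at$elesy == ""))
      at$elesy else guess_element(at$elety),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(is.na(at$insert), "", at$insert),
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, xyz, model = model)
}

#' Write a structure to a PDB file
#' @param structure a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   eleno = a$eleno, elety = a$elety, o = a$occ,
                   elesy = a$elesy)
  invisible(path)
}

#' Trajectory container
#'
#' Ordered frames of coordinates sharing one atom topology.
#'
#' @param topology a `structure_model` giving the shared atom table.
#' @param frames numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   x1,y1,z1,x2,... order; or a list of n x 3 matrices.
#' @param times frame times in ns, strictly increasing; default `0, 1, ...`
#'   at a 1 ns stride.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.list(frames) && !is.matrix(frames))
    frames <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  frames <- as.matrix(frames)
  n_atoms <- nrow(topology$atoms)
  if (ncol(frames) != 3 * n_atoms)
    stop("topology mismatch: frames have ", ncol(frames) / 3,
         " atoms, topology has ", n_atoms)
  if (is.null(times)) times <- seq_len(nrow(frames)) - 1
  if (length(times) != nrow(frames)) stop("times length != number of frames")
  if (nrow(frames) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms, t = [%g, %g] ns\n",
              nrow(x$frames), ncol(x$frames) / 3,
              if (nrow(x$frames)) min(x$times) else NA,
              if (nrow(x$frames)) max(x$times) else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trj a `trajectory_ensemble`.
#' @export
n_frames <- function(trj) nrow(trj$frames)

#' Extract one frame as an n x 3 coordinate matrix
#' @param trj a `trajectory_ensemble`.
#' @param i frame index.
#' @export
frame_coords <- function(trj, i) {
  matrix(trj$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Read coordinate trajectories
#'
#' Reads one or more trajectory files (multi-model PDB or DCD) and
#' concatenates their frames in the order given. Frame times are synthesized
#' at a fixed stride; XTC is not supported.
#'
#' @param topology a `structure_model` the frames must match.
#' @param paths character vector of trajectory files.
#' @param dt_ns time stride between frames, ns (default 1, one frame per
#'   nanosecond).
#' @return a `trajectory_ensemble`.
#' @export
read_trajectory <- function(topology, paths, dt_ns = 1) {
  stopifnot(inherits(topology, "structure_model"))
  n_atoms <- nrow(topology$atoms)
  blocks <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    ext <- tolower(tools::file_ext(p))
    if (ext == "xtc")
      stop("unsupported trajectory format 'xtc'; supply DCD or multi-model PDB")
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
    }
    if (ncol(xyz) != 3 * n_atoms)
      stop("topology mismatch in ", p, ": ", ncol(xyz) / 3,
           " atoms vs ", n_atoms, " in topology")
    xyz
  })
  frames <- do.call(rbind, blocks)
  trajectory_ensemble(topology, frames, times = (seq_len(nrow(frames)) - 1) * dt_ns)
}

#' Write a trajectory as a multi-model PDB
#' @param trj a `trajectory_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trj, path) {
  a <- trj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(trj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- frame_coords(trj, i)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     a$eleno %% 100000, substr(a$elety, 1, 4), substr(a$resid, 1, 3),
                     substr(a$chain, 1, 1), a$resno %% 10000,
                     xyz[, 1], xyz[, 2], xyz[, 3], a$occ, 0, substr(a$elesy, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
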