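## PDB fixed-column reader/writer and atom selections.
##
## The trajectory interchange dialect is multi-model PDB: MODEL/ENDMDL blocks
## sharing one atom list. Only ATOM/HETATM records are interpreted; the first
## MODEL of a reference file is read; altloc other than blank/'A' is dropped;
## insertion codes are rejected. Coordinates in Angstrom.

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns serial, atom_name, residue_name,
#'   residue_number, chain_id.
#' @param coords numeric n x 3 matrix (Angstrom).
#' @param label character label.
#' @return a \linkS4class{StructureModel}
#' @export
structureModel <- function(atoms, coords, label = "structure") {
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$chain_id <- as.character(atoms$chain_id)
  rownames(atoms) <- NULL
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  new("StructureModel", atoms = atoms, coords = coords, label = label)
}

#' Construct a Trajectory
#'
#' @param topology a \linkS4class{StructureModel}.
#' @param frames n_frames x n_atoms x 3 array, or a list of n_atoms x 3
#'   matrices (Angstrom).
#' @param frameInterval time between frames, ps.
#' @param label character label.
#' @return a \linkS4class{Trajectory}
#' @export
trajectory <- function(topology, frames, frameInterval, label = "trajectory") {
  if (is.list(frames)) {
    n <- length(frames)
    arr <- array(NA_real_, c(n, nrow(topology@atoms), 3))
    for (k in seq_len(n)) arr[k, , ] <- frames[[k]]
    frames <- arr
  }
  new("Trajectory", topology = topology, frames = frames,
      frameInterval = as.numeric(frameInterval), label = label)
}

#' @describeIn trajectory frame times t_k = (k-1) * frameInterval (ps)
#' @param x a Trajectory
#' @export
frameTimes <- function(x) {
  (seq_len(dim(x@frames)[1]) - 1) * x@frameInterval
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@frames)[1])

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' @rdname atomData
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' @rdname coords
#' @export
setMethod("coords", "StructureModel", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x) x@frames)

#' @rdname structureLabel
#' @export
setMethod("structureLabel", "StructureModel", function(x) x@label)

#' @rdname structureLabel
#' @export
setMethod("structureLabel", "Trajectory", function(x) x@label)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s': %d atoms, residues %d-%d\n",
              object@label, nrow(a), min(a$residue_number),
              max(a$residue_number)))
})

setMethod("show", "Trajectory", function(object) {
  n <- nFrames(object)
  cat(sprintf(
    "Trajectory '%s': %d frames x %d atoms, interval %g ps (duration %g ps)\n",
    object@label, n, nrow(object@topology@atoms), object@frameInterval,
    (n - 1) * object@frameInterval))
})

## ---- parsing ----------------------------------------------------------

.parseAtomLines <- function(lines, lineno) {
  field <- function(from, to) substr(lines, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v))
    if (length(bad))
      .stopf("malformed PDB %s field at line %d: '%s'", what,
             lineno[bad[1]], lines[bad[1]])
    v
  }
  icode <- trimws(field(27, 27))
  if (any(icode != ""))
    .stopf("insertion codes are not supported (line %d)",
           lineno[which(icode != "")[1]])
  altloc <- field(17, 17)
  keep <- altloc %in% c(" ", "", "A")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(NULL)
  field <- function(from, to) substr(lines, from, to)
  list(
    atoms = data.frame(
      serial = as.integer(num(field(7, 11), "serial")),
      atom_name = trimws(field(13, 16)),
      residue_name = trimws(field(18, 20)),
      residue_number = as.integer(num(field(23, 26), "residue number")),
      chain_id = field(22, 22),
      stringsAsFactors = FALSE),
    coords = cbind(x = num(field(31, 38), "x"),
                   y = num(field(39, 46), "y"),
                   z = num(field(47, 54), "z")))
}

.splitModels <- function(txt) {
  ## Returns a list of integer index vectors: ATOM/HETATM line numbers per model.
  isAtom <- grepl("^(ATOM  |HETATM)", txt)
  isModel <- grepl("^MODEL", txt)
  isEnd <- grepl("^ENDMDL", txt)
  if (!any(isModel)) {
    idx <- which(isAtom)
    if (!length(idx)) return(list())
    return(list(idx))
  }
  starts <- which(isModel)
  ends <- which(isEnd)
  models <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    to <- if (k <= length(ends)) ends[k] else length(txt) + 1L
    rng <- seq(starts[k] + 1L, length.out = max(0L, to - starts[k] - 1L))
    models[[k]] <- rng[isAtom[rng]]
  }
  models[lengths(models) > 0L]
}

#' Read a reference structure from PDB text
#'
#' Reads one AtomRecord per ATOM/HETATM line of the first model. Fixed-column
#' parsing; altloc other than blank/'A' dropped; insertion codes rejected with
#' an error.
#'
#' @param source path to a PDB file, or a connection/character vector of lines.
#' @param label label for the structure (defaults to the file name).
#' @return a \linkS4class{StructureModel}
#' @export
readPDB <- function(source, label = NULL) {
  txt <- if (is.character(source) && length(source) == 1L && file.exists(source))
    readLines(source) else if (inherits(source, "connection"))
    readLines(source) else as.character(source)
  if (is.null(label))
    label <- if (is.character(source) && length(source) == 1L &&
                 file.exists(source)) basename(source) else "structure"
  models <- .splitModels(txt)
  if (!length(models)) .stopf("no ATOM records found: empty structure")
  idx <- models[[1]]
  p <- .parseAtomLines(txt[idx], idx)
  if (is.null(p)) .stopf("no ATOM records found after altloc filtering")
  structureModel(p$atoms, p$coords, label)
}

#' Read a trajectory from multi-model PDB text
#'
#' One frame per MODEL block; the topology is taken from the first model; all
#' models must share an identical atom list (names, residues, order).
#'
#' @param source path / connection / character lines of a multi-model PDB.
#' @param frameInterval time between successive models, ps.
#' @param label trajectory label.
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(source, frameInterval, label = NULL) {
  txt <- if (is.character(source) && length(source) == 1L && file.exists(source))
    readLines(source) else if (inherits(source, "connection"))
    readLines(source) else as.character(source)
  if (is.null(label))
    label <- if (is.character(source) && length(source) == 1L &&
                 file.exists(source)) basename(source) else "trajectory"
  models <- .splitModels(txt)
  if (!length(models)) .stopf("no ATOM records found: empty trajectory")
  first <- .parseAtomLines(txt[models[[1]]], models[[1]])
  topo <- structureModel(first$atoms, first$coords, label)
  na <- nrow(topo@atoms)
  key0 <- with(topo@atoms, paste(atom_name, residue_name, residue_number, chain_id))
  frames <- array(NA_real_, c(length(models), na, 3))
  frames[1, , ] <- first$coords
  for (k in seq_along(models)[-1]) {
    p <- .parseAtomLines(txt[models[[k]]], models[[k]])
    keyk <- with(p$atoms, paste(atom_name, residue_name, residue_number, chain_id))
    if (length(keyk) != na || any(keyk != key0)) {
      d <- if (length(keyk) != na) min(length(keyk), na) + 1L
           else which(keyk != key0)[1]
      .stopf("atom list of model %d differs from model 1 at atom %d (%s)",
             k, d, if (d <= length(keyk)) keyk[d] else "<missing>")
    }
    frames[k, , ] <- p$coords
  }
  trajectory(topo, frames, frameInterval, label)
}

## ---- writing ----------------------------------------------------------

.formatAtomLines <- function(atoms, xyz) {
  if (any(nchar(atoms$atom_name) > 4L))
    .stopf("atom name too long for PDB column (max 4): '%s'",
           atoms$atom_name[which(nchar(atoms$atom_name) > 4L)[1]])
  if (any(nchar(atoms$residue_name) > 3L))
    .stopf("residue name too long for PDB column (max 3): '%s'",
           atoms$residue_name[which(nchar(atoms$residue_name) > 3L)[1]])
  if (any(abs(xyz) >= 10000))
    .stopf("coordinate does not fit the 8.3 PDB column (|x| >= 10000)")
  ## names shorter than 4 chars start in column 14 (PDB convention)
  nm <- ifelse(nchar(atoms$atom_name) >= 4L, atoms$atom_name,
               sprintf(" %-3s", atoms$atom_name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          atoms$serial %% 100000L, nm, atoms$residue_name, atoms$chain_id,
          atoms$residue_number, xyz[, 1], xyz[, 2], xyz[, 3])
}

#' Write a structure as PDB text
#'
#' Fixed-column output; \code{readPDB} inverts it exactly for names/numbers
#' and to 3 decimals for coordinates.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param sink file path or connection.
#' @return invisibly, the path/connection
#' @export
writePDB <- function(model, sink) {
  lines <- c(.formatAtomLines(model@atoms, model@coords), "END")
  writeLines(lines, sink)
  invisible(sink)
}

#' Write a trajectory as multi-model PDB text
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param sink file path or connection.
#' @return invisibly, the path/connection
#' @export
writeTrajectory <- function(traj, sink) {
  atoms <- traj@topology@atoms
  n <- nFrames(traj)
  blocks <- vector("list", n)
  for (k in seq_len(n)) {
    blocks[[k]] <- c(sprintf("MODEL %8d", k),
                     .formatAtomLines(atoms, traj@frames[k, , , drop = TRUE]),
                     "ENDMDL")
  }
  writeLines(c(unlist(blocks), "END"), sink)
  invisible(sink)
}

## ---- selections -------------------------------------------------------

#' Resolve a named atom/residue selection
#'
#' Matches atoms on any combination of atom name, residue number (scalar or
#' range) and residue name; all matching atoms are returned in topology order.
#' The three canonical queries are: a named atom of a numbered residue
#' (\code{atomName="NZ", residueNumber=745}), C-alpha of a residue range
#' (\code{atomName="CA", residueNumber=c(752, 767)}), and C-alpha of the whole
#' chain (\code{atomName="CA"}).
#'
#' @param model a \linkS4class{StructureModel} or \linkS4class{Trajectory}
#'   (selection is resolved on its topology).
#' @param atomName character or NULL.
#' @param residueNumber integer scalar or length-2 range (inclusive), or NULL.
#' @param residueName character or NULL.
#' @return an \linkS4class{AtomSelection}; matching zero atoms is an error.
#' @export
selectAtoms <- function(model, atomName = NULL, residueNumber = NULL,
                        residueName = NULL) {
  if (is(model, "Trajectory")) model <- model@topology
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  desc <- character()
  if (!is.null(atomName)) {
    keep <- keep & a$atom_name %in% atomName
    desc <- c(desc, paste0("name=", paste(atomName, collapse = ",")))
  }
  if (!is.null(residueNumber)) {
    if (length(residueNumber) == 1L) {
      keep <- keep & a$residue_number == residueNumber
      desc <- c(desc, paste0("resno=", residueNumber))
    } else if (length(residueNumber) == 2L) {
      keep <- keep & a$residue_number >= residueNumber[1] &
        a$residue_number <= residueNumber[2]
      desc <- c(desc, paste0("resno=", residueNumber[1], "-", residueNumber[2]))
    } else .stopf("residueNumber must be a scalar or a length-2 range")
  }
  if (!is.null(residueName)) {
    keep <- keep & a$residue_name %in% residueName
    desc <- c(desc, paste0("resname=", paste(residueName, collapse = ",")))
  }
  idx <- which(keep)
  descriptor <- if (length(desc)) paste(desc, collapse = " & ") else "all"
  if (!length(idx))
    .stopf("selection '%s' matches no atoms", descriptor)
  new("AtomSelection", indices = as.integer(idx), descriptor = descriptor)
}

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection [%s]: %d atoms\n", object@descriptor,
              length(object@indices)))
})

## Resolve a selection argument: AtomSelection, integer indices, or NULL.
.resolveSelection <- function(sel, n, what = "selection") {
  if (is.null(sel)) return(NULL)
  idx <- if (is(sel, "AtomSelection")) sel@indices else as.integer(sel)
  if (any(idx < 1L | idx > n)) .stopf("%s index out of bounds", what)
  idx
}

.selectionDescriptor <- function(sel) {
  if (is(sel, "AtomSelection")) sel@descriptor else "indices"
}
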