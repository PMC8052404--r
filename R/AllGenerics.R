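#' Number of frames in a trajectory
#' @param x a Trajectory
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame interval (ps)
#' @param x a Trajectory
#' @return numeric, ps
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Per-atom identity table
#' @param x a StructureModel or Trajectory
#' @return data.frame with one row per atom
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Coordinates
#'
#' For a StructureModel the n_atoms x 3 matrix; for a Trajectory the
#' n_frames x n_atoms x 3 array (Angstrom).
#' @param x object
#' @return numeric matrix or array
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Object label
#' @param x object
#' @return character
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))
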