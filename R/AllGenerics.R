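#' Number of frames
#' @param x a [Trajectory-class] or [Dynophore-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a [Topology-class] or [Trajectory-class]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom table accessor
#' @param x a [Topology-class] or [Trajectory-class]
#' @return data.frame of atom records
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Bond list accessor
#' @param x a [Topology-class] or [Trajectory-class]
#' @return two-column integer matrix of bonded serials
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' Topology accessor
#' @param x a [Trajectory-class]
#' @return the underlying [Topology-class]
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Frame coordinates
#' @param x a [Trajectory-class]
#' @param frame 0-based frame index
#' @return numeric matrix `n_atoms x 3` (Angstrom)
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' Superfeature list accessor
#' @param x a [Dynophore-class]
#' @return named list of [Superfeature-class] objects
#' @export
setGeneric("superfeatures", function(x) standardGeneric("superfeatures"))

# ---- methods ---------------------------------------------------------------

#' @describeIn nFrames frames in a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @describeIn nFrames frames analyzed by a dynophore
#' @export
setMethod("nFrames", "Dynophore", function(x) x@nFrames)

#' @describeIn nAtoms atoms in a topology
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @describeIn nAtoms atoms in a trajectory's topology
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @describeIn atoms atom table of a topology
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @describeIn atoms atom table of a trajectory
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @describeIn bonds bonds of a topology
#' @export
setMethod("bonds", "Topology", function(x) x@bonds)

#' @describeIn bonds bonds of a trajectory
#' @export
setMethod("bonds", "Trajectory", function(x) x@topology@bonds)

#' @describeIn topology topology of a trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn frameCoords coordinates of one frame (0-based index)
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame) {
  nf <- dim(x@coords)[3]
  if (frame < 0 || frame >= nf)
    stop("frame index ", frame, " out of range [0, ", nf - 1, "]")
  m <- x@coords[, , frame + 1, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

#' @describeIn superfeatures superfeatures of a dynophore
#' @export
setMethod("superfeatures", "Dynophore", function(x) x@superfeatures)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms,", nrow(object@bonds), "bonds,",
      length(unique(paste(a$resname, a$resnum, a$chain))), "residues\n")
  cat("  elements:", paste(sort(unique(a$element)), collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object), "atoms\n")
  if (all(is.na(object@times))) cat("  times: not available\n")
  else cat("  times:", object@times[1], "-", object@times[length(object@times)], "ps\n")
})

setMethod("show", "InteractionCriteria", function(object) {
  cat("InteractionCriteria (Angstrom / degrees):\n")
  cat(sprintf("  hbond_dist_min   = %.2f\n", object@hbondDistMin))
  cat(sprintf("  hbond_dist_max   = %.2f\n", object@hbondDistMax))
  cat(sprintf("  hbond_angle_min  = %.1f\n", object@hbondAngleMin))
  cat(sprintf("  ionic_dist_max   = %.2f\n", object@ionicDistMax))
  cat(sprintf("  hydrophob_dist_max = %.2f\n", object@hydrophobDistMax))
  cat(sprintf("  metal_coord_max  = %.2f\n", object@metalCoordMax))
})

setMethod("show", "FeatureTemplate", function(object) {
  cat(sprintf("FeatureTemplate %s: atoms [%s]%s\n", object@label,
              paste(object@atoms, collapse = ","),
              if (length(object@hydrogens))
                paste0(" H [", paste(object@hydrogens, collapse = ","), "]")
              else ""))
})

setMethod("show", "Superfeature", function(object) {
  cat(sprintf("Superfeature %s: %d/%d frames (%.1f%%), %d events, %d partner(s)\n",
              object@label, length(object@frames), object@nFrames,
              100 * length(object@frames) / max(1L, object@nFrames),
              nrow(object@events),
              length(unique(object@events$partner))))
})

setMethod("show", "Dynophore", function(object) {
  cat("Dynophore:", length(object@superfeatures), "superfeatures over",
      object@nFrames, "frames\n")
  for (s in object@superfeatures) {
    cat(sprintf("  %-14s %6.1f%%  partners: %s\n", s@label,
                100 * length(s@frames) / max(1L, s@nFrames),
                paste(unique(s@events$partner), collapse = ", ")))
  }
})
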