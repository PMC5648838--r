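#' @import methods
NULL

#' Molecular topology
#'
#' Ordered atom table plus covalent bond list for one molecular system.
#' Atom order is fixed for the lifetime of any trajectory built on top of
#' the topology; residue numbers are kept verbatim from the input file.
#'
#' @slot atoms data.frame with one row per atom and columns `serial`
#'   (unique positive integer), `name`, `element`, `resname`, `resnum`,
#'   `chain`, `charge` (formal, integer), `het` (logical, HETATM record),
#'   `vdw` (van der Waals radius, Angstrom).
#' @slot bonds two-column integer matrix of bonded atom serials
#'   (unordered pairs, stored with smaller serial first).
#'
#' @seealso [readTopology()], [resolveSelection()]
#' @export
setClass("Topology", representation(atoms = "data.frame", bonds = "matrix"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resnum", "chain",
            "charge", "het", "vdw")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("topology has zero atoms")
  if (anyDuplicated(a$serial)) return("duplicate atom serials")
  if (any(a$serial <= 0)) return("atom serials must be positive")
  if (any(!nzchar(a$element))) return("empty element symbol")
  if (any(a$vdw <= 0)) return("vdw radii must be positive")
  b <- object@bonds
  if (length(b)) {
    if (ncol(b) != 2) return("bonds must be a 2-column matrix")
    if (!all(b %in% a$serial)) return("bond endpoint not in atom table")
    if (any(b[, 1] == b[, 2])) return("self-bond")
  }
  TRUE
})

#' Coordinate trajectory over a fixed topology
#'
#' @slot topology a [Topology-class] object.
#' @slot coords numeric array `c(n_atoms, 3, n_frames)`, Angstrom, atom
#'   order identical to the topology.
#' @slot times numeric vector of frame times in ps (`NA` when the source
#'   format carries no times).
#'
#' Frames are indexed 0-based in all user-facing functions, matching the
#' dominant trajectory-analysis convention.
#'
#' @seealso [readTrajectory()], [alignTrajectory()]
#' @export
setClass("Trajectory",
         representation(topology = "Topology", coords = "array",
                        times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3) return("coords must be a 3-d array (atoms x 3 x frames)")
  if (d[2] != 3) return("second coords dimension must be 3")
  if (d[1] != nrow(object@topology@atoms))
    return("coordinate count does not match topology atom count")
  if (d[3] < 1) return("trajectory needs at least one frame")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  if (length(object@times) != d[3]) return("times length must equal frame count")
  TRUE
})

#' Geometric interaction criteria
#'
#' Distance and angle windows that decide whether a ligand feature and an
#' environment partner interact in a frame. All distances in Angstrom,
#' angles in degrees. Perception thresholds of commercial pharmacophore
#' tools are unpublished, so the defaults are standard literature
#' geometric criteria and every value is user-configurable.
#'
#' @slot hbondDistMin,hbondDistMax donor-acceptor heavy-atom distance window.
#' @slot hbondAngleMin minimum D-H...A angle at the explicit hydrogen.
#' @slot ionicDistMax maximum charged-group centroid-centroid distance.
#' @slot hydrophobDistMax maximum apolar heavy-atom pair distance.
#' @slot metalCoordMax maximum distance for metal coordination, counted as
#'   an ionic contact of a negative ionizable feature with a metal partner.
#'
#' @seealso [defaultCriteria()], [readCriteria()]
#' @export
setClass("InteractionCriteria",
         representation(hbondDistMin = "numeric", hbondDistMax = "numeric",
                        hbondAngleMin = "numeric", ionicDistMax = "numeric",
                        hydrophobDistMax = "numeric", metalCoordMax = "numeric"))

setValidity("InteractionCriteria", function(object) {
  v <- c(object@hbondDistMin, object@hbondDistMax, object@hbondAngleMin,
         object@ionicDistMax, object@hydrophobDistMax, object@metalCoordMax)
  if (any(!is.finite(v)) || any(v <= 0)) return("criteria must be positive finite")
  if (object@hbondDistMin >= object@hbondDistMax)
    return("hbondDistMin must be < hbondDistMax")
  TRUE
})

#' Ligand pharmacophore feature template
#'
#' A typed set of ligand atoms that can instantiate interactions: e.g. one
#' hydroxyl donor, one acceptor oxygen, a charged group, or a hydrophobic
#' carbon fragment.
#'
#' @slot type one of `"HBD"`, `"HBA"`, `"PI"`, `"NI"`, `"H"`.
#' @slot atoms integer serials of the heavy atoms defining the feature.
#' @slot hydrogens integer serials of attached hydrogens (HBD only).
#' @slot label human-readable label, e.g. `"HBD[OG]"`.
#' @export
setClass("FeatureTemplate",
         representation(type = "character", atoms = "integer",
                        hydrogens = "integer", label = "character"))

setValidity("FeatureTemplate", function(object) {
  if (!object@type %in% c("HBD", "HBA", "PI", "NI", "H"))
    return("unknown feature type")
  if (length(object@atoms) == 0) return("feature template needs atoms")
  TRUE
})

#' Superfeature: one feature type on one ligand atom set, over time
#'
#' All per-frame interaction events that share the same interaction type
#' and the same ligand atoms, treated as one time-resolved entity.
#'
#' @slot type,atoms,hydrogens,label as in [FeatureTemplate-class].
#' @slot events data.frame with one row per (frame, partner) event:
#'   `frame` (0-based), `partner` (identity key `"RES/num/chain"`),
#'   `resname`, `resnum`, `chain`, `pclass` (partner class), `distance`
#'   (Angstrom), `x`,`y`,`z` (feature centroid, aligned coordinates).
#' @slot frames sorted 0-based indices of frames with at least one event.
#' @slot nFrames total frame count of the parent trajectory.
#' @export
setClass("Superfeature",
         representation(type = "character", atoms = "integer",
                        hydrogens = "integer", label = "character",
                        events = "data.frame", nFrames = "integer",
                        frames = "integer"))

setValidity("Superfeature", function(object) {
  if (nrow(object@events)) {
    if (!setequal(unique(object@events$frame), object@frames))
      return("frames slot must equal distinct event frames")
  }
  if (length(object@frames) > object@nFrames)
    return("occurrence count exceeds frame count")
  TRUE
})

#' Dynophore: the full superfeature collection of one trajectory
#'
#' @slot superfeatures named list of [Superfeature-class] objects
#'   (unique labels).
#' @slot nFrames total number of analyzed frames.
#' @slot criteria the [InteractionCriteria-class] used for detection.
#' @slot ligand the ligand selection expression.
#' @slot meta list of provenance fields (source paths, alignment
#'   reference, water handling).
#' @seealso [buildDynophore()], [exportReport()]
#' @export
setClass("Dynophore",
         representation(superfeatures = "list", nFrames = "integer",
                        criteria = "InteractionCriteria", ligand = "character",
                        meta = "list"))

setValidity("Dynophore", function(object) {
  labs <- vapply(object@superfeatures, function(s) s@label, character(1))
  if (anyDuplicated(labs)) return("duplicate superfeature labels")
  for (s in object@superfeatures)
    if (s@nFrames != object@nFrames)
      return("superfeature frame count inconsistent with dynophore")
  TRUE
})
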