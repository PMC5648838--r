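#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation that minimize the RMSD of
#' `mobile` onto `reference` in the least-squares sense, via SVD of the
#' cross-covariance matrix with a determinant sign correction so the
#' result is always a rotation (never a reflection).
#'
#' @param mobile,reference numeric matrices `n x 3`, equal `n >= 3`,
#'   not all collinear.
#' @return a list of class `"RigidTransform"` with elements `rotation`
#'   (3x3 orthonormal, det +1), `translation` (length 3) and `rmsd`
#'   (post-fit RMSD in Angstrom). Apply as `x %*% t(rotation) +
#'   translation` (see [applyTransform()]).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(18), ncol = 3)
#' tr <- kabschSuperpose(x, x)
#' tr$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("geometry error: point counts differ")
  if (nrow(mobile) < 3)
    stop("geometry error: need at least 3 points for superposition")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  if (svd(X)$d[2] < 1e-9)
    stop("geometry error: degenerate (collinear or coincident) point set")
  H <- crossprod(X, Y)                 # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)          # maps centered mobile -> centered ref
  t <- cr - as.vector(R %*% cm)
  fitted <- mobile %*% t(R) + matrix(t, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param coords numeric matrix `n x 3`
#' @param transform a `RigidTransform` from [kabschSuperpose()]
#' @return transformed `n x 3` matrix
#' @export
applyTransform <- function(coords, transform) {
  coords <- as.matrix(coords)
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' Superpose every trajectory frame onto a reference frame
#'
#' Each frame is rigid-body fitted (Kabsch) on the `fit_selection` atoms
#' onto the same atoms of the reference frame; the frame's transform
#' moves *all* atoms, ligand included. This is the alpha-carbon alignment
#' step that removes global tumbling before interaction centroids are
#' pooled across frames.
#'
#' @param traj a [Trajectory-class]
#' @param fit_selection selection expression or serial vector (>= 3
#'   atoms); default `"calpha"`.
#' @param reference_frame 0-based index of the reference frame (default 0).
#' @return an aligned [Trajectory-class]
#' @export
alignTrajectory <- function(traj, fit_selection = "calpha",
                            reference_frame = 0) {
  sel <- .resolveSel(topology(traj), fit_selection)
  if (length(sel) < 3)
    stop("alignment requires >= 3 fit atoms, got ", length(sel))
  idx <- .serialIndex(topology(traj), sel)
  nf <- nFrames(traj)
  ref <- frameCoords(traj, reference_frame)[idx, , drop = FALSE]
  out <- traj@coords
  for (f in seq_len(nf)) {
    mob <- out[idx, , f]
    tr <- tryCatch(kabschSuperpose(mob, ref), error = function(e)
      stop("alignment failed at frame ", f - 1, ": ", conditionMessage(e)))
    out[, , f] <- applyTransform(out[, , f], tr)
  }
  new("Trajectory", topology = traj@topology, coords = out,
      times = traj@times)
}

#' Per-frame RMSD over a selection
#'
#' Root-mean-square deviation of the selected atoms from the reference
#' frame, optionally after a Kabsch pre-fit of each frame on the
#' `prefit_selection` atoms (alpha carbons by default, matching the usual
#' least-squares-fit-then-measure convention).
#'
#' @param traj a [Trajectory-class]
#' @param selection atoms measured (expression or serials)
#' @param reference_frame 0-based reference index (default 0)
#' @param prefit logical; superpose each frame before measuring
#' @param prefit_selection fit atoms used when `prefit = TRUE`
#' @return numeric vector, one Angstrom value per frame
#' @export
computeRmsd <- function(traj, selection, reference_frame = 0, prefit = TRUE,
                        prefit_selection = "calpha") {
  sel <- .resolveSel(topology(traj), selection)
  if (length(sel) == 0) stop("empty selection for RMSD")
  if (prefit) traj <- alignTrajectory(traj, prefit_selection, reference_frame)
  idx <- .serialIndex(topology(traj), sel)
  ref <- frameCoords(traj, reference_frame)[idx, , drop = FALSE]
  vapply(seq_len(nFrames(traj)), function(f) {
    x <- traj@coords[idx, , f, drop = FALSE]
    dim(x) <- c(length(idx), 3)
    sqrt(mean(rowSums((x - ref)^2)))
  }, numeric(1))
}

#' Per-atom RMSF over a selection
#'
#' Root-mean-square fluctuation of each selected atom about its own
#' time-average position, computed on the (optionally pre-aligned)
#' trajectory. With `by_residue = TRUE` the per-atom values are averaged
#' over each residue's selected atoms.
#'
#' @param traj a [Trajectory-class] with >= 2 frames
#' @param selection atoms measured (expression or serials)
#' @param prefit superpose frames on `prefit_selection` first
#' @param prefit_selection fit atoms used when `prefit = TRUE`
#' @param by_residue reduce to one value per residue
#' @return data.frame with `serial`, `resname`, `resnum`, `chain`, `rmsf`
#'   (or the per-residue reduction of it)
#' @export
computeRmsf <- function(traj, selection = "calpha", prefit = TRUE,
                        prefit_selection = "calpha", by_residue = FALSE) {
  if (nFrames(traj) < 2)
    stop("RMSF undefined for a single frame")
  sel <- .resolveSel(topology(traj), selection)
  if (length(sel) == 0) stop("empty selection for RMSF")
  if (prefit) traj <- alignTrajectory(traj, prefit_selection, 0)
  idx <- .serialIndex(topology(traj), sel)
  sub <- traj@coords[idx, , , drop = FALSE]
  avg <- apply(sub, c(1, 2), mean)
  dev2 <- sweep(sub, c(1, 2), avg)^2
  rmsf <- sqrt(apply(dev2, 1, sum) / dim(sub)[3])
  a <- atoms(traj)[idx, ]
  out <- data.frame(serial = a$serial, resname = a$resname, resnum = a$resnum,
                    chain = a$chain, rmsf = rmsf, stringsAsFactors = FALSE)
  if (by_residue) {
    key <- paste(out$resname, out$resnum, out$chain)
    agg <- tapply(out$rmsf, key, mean)
    first <- !duplicated(key)
    out <- data.frame(resname = out$resname[first], resnum = out$resnum[first],
                      chain = out$chain[first],
                      rmsf = as.numeric(agg[key[first]]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chain, out$resnum), ]
    rownames(out) <- NULL
  }
  out
}

#' Sphere-bounded grid pocket volume
#'
#' Unoccluded volume of an inclusion sphere around a chosen center atom:
#' a cubic grid of the given spacing is laid over the sphere and the
#' volume is `spacing^3` times the number of grid points that fall inside
#' the sphere and outside every occluding atom's `vdw + probe` sphere.
#' Protein and ion atoms occlude; ligand and water atoms are excluded
#' from the occluders by default (the cavity they occupy is the quantity
#' of interest). Hard-sphere occlusion, no contiguity filtering.
#'
#' @param traj a [Trajectory-class]
#' @param center_serial serial of the atom defining the sphere center
#'   (e.g. the ligand boron of a boronic-acid inhibitor)
#' @param frame 0-based frame index (default 0)
#' @param radius inclusion sphere radius, Angstrom (default 10)
#' @param spacing grid spacing, Angstrom (default 0.5; must be <=
#'   radius/5)
#' @param probe added to each occluder's van der Waals radius (default 0)
#' @param exclude selection of atoms that never occlude (default: the
#'   ligand plus all water)
#' @return volume in cubic Angstrom
#' @export
pocketVolume <- function(traj, center_serial, frame = 0, radius = 10.0,
                         spacing = 0.5, probe = 0.0, exclude = NULL) {
  top <- topology(traj)
  a <- atoms(top)
  if (!center_serial %in% a$serial)
    stop("selection error: center atom serial ", center_serial, " not found")
  if (spacing > radius / 5)
    stop("spacing must be <= radius/5")
  xyz <- frameCoords(traj, frame)
  center <- xyz[.serialIndex(top, center_serial), ]
  if (is.null(exclude)) {
    lig <- suppressWarnings(resolveSelection(top, "ligand"))
    wat <- suppressWarnings(resolveSelection(top, "water"))
    exclude <- c(lig, wat)
  } else {
    exclude <- .resolveSel(top, exclude)
  }
  occ <- !(a$serial %in% exclude) & a$serial != center_serial &
    a$element != "H"
  occ_xyz <- xyz[occ, , drop = FALSE]
  occ_r <- a$vdw[occ] + probe
  # cubic grid covering the sphere, indexed so per-atom bounding boxes
  # can be addressed directly
  g1 <- seq(-radius, radius, by = spacing)
  ng <- length(g1)
  inside_sphere <- function(px, py, pz) px^2 + py^2 + pz^2 <= radius^2
  free <- array(TRUE, dim = c(ng, ng, ng))
  # occlusion pass: subcube per occluder
  if (nrow(occ_xyz) > 0) {
    rel <- sweep(occ_xyz, 2, center)
    near <- rowSums(rel^2) <= (radius + max(occ_r))^2
    rel <- rel[near, , drop = FALSE]
    rr <- occ_r[near]
    for (k in seq_len(nrow(rel))) {
      r <- rr[k]
      lo <- pmax(1L, ceiling((rel[k, ] - r + radius) / spacing) + 1L)
      hi <- pmin(ng, floor((rel[k, ] + r + radius) / spacing) + 1L)
      if (any(lo > hi)) next
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      dx2 <- (g1[ii] - rel[k, 1])^2
      dy2 <- (g1[jj] - rel[k, 2])^2
      dz2 <- (g1[kk] - rel[k, 3])^2
      sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
      # both sides flatten in the same column-major subcube order
      free[ii, jj, kk] <- free[ii, jj, kk] & !c(sub)
    }
  }
  # restrict to the inclusion sphere
  gx <- array(g1, dim = c(ng, ng, ng))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  n_free <- sum(free & inside_sphere(gx, gy, gz))
  n_free * spacing^3
}

#' Per-frame pocket volume series
#'
#' @inheritParams pocketVolume
#' @param frames 0-based frame indices (default: all)
#' @return data.frame with columns `frame` and `volume` (cubic Angstrom)
#' @export
pocketVolumeSeries <- function(traj, center_serial, frames = NULL,
                               radius = 10.0, spacing = 0.5, probe = 0.0,
                               exclude = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj)) - 1L
  vol <- vapply(frames, function(f)
    pocketVolume(traj, center_serial, f, radius, spacing, probe, exclude),
    numeric(1))
  data.frame(frame = as.integer(frames), volume = vol)
}
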