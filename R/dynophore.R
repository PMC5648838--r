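#' Build a dynophore from a trajectory
#'
#' The full pipeline: align the trajectory on the fit selection (Kabsch,
#' reference frame 0 by default), perceive ligand feature templates,
#' classify environment partners, detect interactions in every frame, and
#' group events by (interaction type, ligand atom set) into superfeatures.
#' Superfeatures with zero events are omitted. A superfeature "occurs" in
#' a frame when it has at least one detected environment interaction
#' there, so reported frequencies are interaction times.
#'
#' @param traj a [Trajectory-class]
#' @param ligand_selection ligand atoms (expression or serials)
#' @param criteria an [InteractionCriteria-class]
#' @param fit_selection alignment atoms (default `"calpha"`)
#' @param align superpose frames before detection (default TRUE; disable
#'   only for pre-aligned input)
#' @param include_water count water partners (default FALSE)
#' @param reference_frame 0-based alignment reference
#' @param method pair search, `"cell"` or `"brute"` (identical results)
#' @return a [Dynophore-class]
#' @examples
#' spec <- toySpec(n_frames = 10, schedules = list(
#'   schedule("HBD", "hydroxyl", "bbO", frames = 0:4)))
#' toy <- generateToyTrajectory(spec)
#' dyn <- buildDynophore(toy$trajectory)
#' dyn
#' @export
buildDynophore <- function(traj, ligand_selection = "ligand",
                           criteria = defaultCriteria(),
                           fit_selection = "calpha", align = TRUE,
                           include_water = FALSE, reference_frame = 0,
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- topology(traj)
  lig <- .resolveSel(top, ligand_selection)
  if (length(lig) == 0) stop("ligand selection is empty")
  if (align) traj <- alignTrajectory(traj, fit_selection, reference_frame)
  templates <- perceiveFeatures(top, lig)
  partners <- classifyEnvironment(top, lig)
  sites <- .environmentSites(top, partners)
  nf <- nFrames(traj)
  events <- vector("list", nf)
  for (f in seq_len(nf) - 1L) {
    events[[f + 1L]] <- withCallingHandlers(
      detectFrameInteractions(traj, f, templates, partners, criteria,
                              include_water, method, sites),
      warning = function(w) {
        if (f > 0) invokeRestart("muffleWarning")  # warn once, first frame
      })
  }
  ev <- do.call(rbind, events)
  sfs <- list()
  if (!is.null(ev) && nrow(ev) > 0) {
    for (tmpl in templates) {
      sub <- ev[ev$label == tmpl@label, , drop = FALSE]
      if (nrow(sub) == 0) next
      rownames(sub) <- NULL
      sfs[[tmpl@label]] <- new("Superfeature", type = tmpl@type,
                               atoms = tmpl@atoms, hydrogens = tmpl@hydrogens,
                               label = tmpl@label, events = sub,
                               nFrames = as.integer(nf),
                               frames = sort(unique(sub$frame)))
    }
  } else {
    warning("no interactions detected; dynophore has zero superfeatures")
  }
  new("Dynophore", superfeatures = sfs, nFrames = as.integer(nf),
      criteria = criteria,
      ligand = if (is.character(ligand_selection)) ligand_selection
               else paste("serial", paste(range(lig), collapse = "-")),
      meta = list(aligned = align,
                  fit_selection = if (is.character(fit_selection))
                    fit_selection else "custom serials",
                  reference_frame = reference_frame,
                  include_water = include_water,
                  n_templates = length(templates)))
}

#' Superfeature occurrence frequency
#'
#' Percent of all considered frames in which the superfeature is
#' detected: `100 * n_occurrence_frames / n_frames`.
#'
#' @param sf a [Superfeature-class]
#' @param n_frames total frames (defaults to the superfeature's own
#'   trajectory frame count)
#' @return percent in `[0, 100]`
#' @export
superfeatureFrequency <- function(sf, n_frames = sf@nFrames) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  100 * length(sf@frames) / n_frames
}

#' Partner interaction frequency
#'
#' Percent of the superfeature's occurrence frames in which a given
#' environment partner interacts. Several partners can interact in the
#' same frame, so partner frequencies may sum to more than 100.
#'
#' @param sf a [Superfeature-class]
#' @param partner_key partner identity `"RESNAME/resnum/chain"`; `NULL`
#'   returns the named vector over all of the superfeature's partners
#' @return percent (or named vector); `NaN` with a warning when the
#'   superfeature never occurs
#' @export
partnerFrequency <- function(sf, partner_key = NULL) {
  n_occ <- length(sf@frames)
  if (n_occ == 0) {
    warning("superfeature has zero occurrences; partner frequency undefined")
    return(NaN)
  }
  keys <- unique(sf@events$partner)
  freq <- vapply(keys, function(k)
    100 * length(unique(sf@events$frame[sf@events$partner == k])) / n_occ,
    numeric(1))
  names(freq) <- keys
  if (is.null(partner_key)) return(freq)
  if (!partner_key %in% keys) return(0)
  unname(freq[partner_key])
}

.typeCutoff <- function(type, criteria) {
  switch(type,
         HBD = criteria@hbondDistMax, HBA = criteria@hbondDistMax,
         PI = criteria@ionicDistMax, NI = criteria@ionicDistMax,
         H = criteria@hydrophobDistMax)
}

#' Interaction distance histogram
#'
#' Histogram of event distances for a superfeature (optionally restricted
#' to one partner). Bins of `bin_width` span from the minimum observed
#' distance rounded down to one decimal up to the feature type's maximum
#' cutoff; bins are half-open `[lo, hi)` with the last bin closed, so
#' counts always sum to the number of binned distances.
#'
#' @param sf a [Superfeature-class]
#' @param partner_key optional partner restriction
#' @param bin_width bin width in Angstrom (default 0.1)
#' @param criteria criteria used for detection (sets the upper bin edge)
#' @return an object of class `"histogram"` (see [graphics::hist()])
#' @export
distanceHistogram <- function(sf, partner_key = NULL, bin_width = 0.1,
                              criteria = defaultCriteria()) {
  d <- sf@events$distance
  if (!is.null(partner_key)) d <- d[sf@events$partner == partner_key]
  if (length(d) == 0) stop("no events to bin for ", sf@label)
  lo <- floor(min(d) * 10) / 10
  hi <- .typeCutoff(sf@type, criteria)
  edges <- seq(lo, hi, by = bin_width)
  if (max(edges) < hi) edges <- c(edges, max(edges) + bin_width)
  h <- graphics::hist(d, breaks = edges, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  h$xname <- paste0(sf@label,
                    if (!is.null(partner_key)) paste0(" / ", partner_key))
  h
}

#' Occurrence bar code
#'
#' Boolean presence/absence per frame for a superfeature (or for one of
#' its partner interactions). The number of `TRUE` values equals the
#' corresponding occurrence count.
#'
#' @param sf a [Superfeature-class]
#' @param partner_key optional partner restriction
#' @return logical vector of length `n_frames` (element `f + 1` is frame
#'   `f`, 0-based)
#' @export
occurrenceBarcode <- function(sf, partner_key = NULL) {
  frames <- if (is.null(partner_key)) sf@frames
            else unique(sf@events$frame[sf@events$partner == partner_key])
  out <- rep(FALSE, sf@nFrames)
  out[frames + 1L] <- TRUE
  out
}

#' Superfeature point cloud
#'
#' One point per occurrence frame: the template heavy-atom centroid in
#' the aligned coordinates of that frame. Export with
#' [writePseudoatomPdb()].
#'
#' @param sf a [Superfeature-class]
#' @param partner_key optional partner restriction
#' @return data.frame with `frame`, `x`, `y`, `z`
#' @export
pointCloud <- function(sf, partner_key = NULL) {
  ev <- sf@events
  if (!is.null(partner_key)) ev <- ev[ev$partner == partner_key, , drop = FALSE]
  ev <- ev[!duplicated(ev$frame), c("frame", "x", "y", "z")]
  ev <- ev[order(ev$frame), ]
  rownames(ev) <- NULL
  ev
}

#' Concatenate trajectories over the same topology
#'
#' Frame-additive statistics over simulation repeats are obtained by
#' concatenating the repeats before the dynophore analysis.
#'
#' @param ... two or more [Trajectory-class] objects sharing one topology
#' @return a [Trajectory-class]
#' @export
concatTrajectories <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && is.list(ts[[1]])) ts <- ts[[1]]
  nat <- unique(vapply(ts, nAtoms, integer(1)))
  if (length(nat) != 1)
    stop("trajectories have different atom counts")
  coords <- array(0, dim = c(nat, 3, sum(vapply(ts, nFrames, integer(1)))))
  at <- 0L
  for (t in ts) {
    nf <- nFrames(t)
    coords[, , at + seq_len(nf)] <- t@coords
    at <- at + nf
  }
  new("Trajectory", topology = ts[[1]]@topology, coords = coords,
      times = unlist(lapply(ts, function(t) t@times)))
}

# ---- export / import --------------------------------------------------------

.safeName <- function(x) gsub("[^A-Za-z0-9.-]+", "_", x)

.dynophoreToList <- function(dyn) {
  sfs <- lapply(dyn@superfeatures, function(s) {
    partners <- lapply(unique(s@events$partner), function(k) {
      sub <- s@events[s@events$partner == k, , drop = FALSE]
      list(key = k, resname = sub$resname[1], resnum = sub$resnum[1],
           chain = sub$chain[1], pclass = sub$pclass[1],
           count = nrow(sub), frames = sort(unique(sub$frame)),
           frequency = partnerFrequency(s, k),
           distances = sub$distance[order(sub$frame)])
    })
    list(label = s@label, type = s@type, atoms = s@atoms,
         hydrogens = s@hydrogens,
         occurrence_count = length(s@frames),
         frequency = superfeatureFrequency(s),
         frames = s@frames, partners = partners)
  })
  names(sfs) <- NULL
  list(schema_version = "1.0", n_frames = dyn@nFrames, ligand = dyn@ligand,
       criteria = .criteriaList(dyn@criteria), meta = dyn@meta,
       superfeatures = sfs)
}

#' Export a dynophore report
#'
#' Writes into `out_dir`:
#' \itemize{
#'   \item `dynophore.json`: full statistics at full precision, including
#'     criteria and run provenance (versioned schema).
#'   \item `superfeatures.csv`: one summary row per superfeature-partner
#'     pair (frequencies rounded to one decimal, the conventional
#'     reporting precision).
#'   \item `barcodes.csv`: frame-by-frame occurrence bar codes, one
#'     column per superfeature and per (superfeature, partner) pair.
#'   \item one `cloud_<label>.pdb` pseudo-atom point cloud per
#'     superfeature.
#'   \item with `plots = TRUE`, PNG bar-code and distance-histogram
#'     plots per superfeature.
#' }
#'
#' @param dyn a [Dynophore-class]
#' @param out_dir output directory (created if needed)
#' @param plots write PNG plots
#' @return `out_dir`, invisibly
#' @export
exportReport <- function(dyn, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.dynophoreToList(dyn),
                       file.path(out_dir, "dynophore.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rows <- list()
  bc <- list(frame = seq_len(dyn@nFrames) - 1L)
  for (s in dyn@superfeatures) {
    bc[[s@label]] <- as.integer(occurrenceBarcode(s))
    for (k in unique(s@events$partner)) {
      rows[[length(rows) + 1]] <- data.frame(
        superfeature = s@label, type = s@type,
        superfeature_pct = round(superfeatureFrequency(s), 1),
        partner = k, partner_class = s@events$pclass[s@events$partner == k][1],
        partner_pct = round(partnerFrequency(s, k), 1),
        n_events = sum(s@events$partner == k),
        mean_distance = round(mean(
          s@events$distance[s@events$partner == k]), 3),
        stringsAsFactors = FALSE)
      bc[[paste(s@label, k, sep = "|")]] <-
        as.integer(occurrenceBarcode(s, k))
    }
    cloud <- pointCloud(s)
    writePseudoatomPdb(as.matrix(cloud[, c("x", "y", "z")]),
                       labels = s@type,
                       path = file.path(out_dir,
                                        paste0("cloud_", .safeName(s@label),
                                               ".pdb")),
                       frames = cloud$frame)
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(superfeature = character(0), type = character(0),
               superfeature_pct = numeric(0), partner = character(0),
               partner_class = character(0), partner_pct = numeric(0),
               n_events = integer(0), mean_distance = numeric(0))
  utils::write.csv(summary_df, file.path(out_dir, "superfeatures.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bc, check.names = FALSE),
                   file.path(out_dir, "barcodes.csv"), row.names = FALSE)
  if (plots) {
    for (s in dyn@superfeatures) {
      grDevices::png(file.path(out_dir,
                               paste0("barcode_", .safeName(s@label), ".png")),
                     width = 900, height = 300)
      plotBarcode(s)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir,
                               paste0("hist_", .safeName(s@label), ".png")),
                     width = 600, height = 400)
      graphics::plot(distanceHistogram(s, criteria = dyn@criteria),
                     col = "grey70", main = s@label,
                     xlab = "distance [Angstrom]")
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}

#' Read a dynophore JSON report back
#'
#' @param path a `dynophore.json` written by [exportReport()]
#' @return the report as a nested list (schema `"1.0"`)
#' @export
readReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(rep$schema_version))
    stop("not a dynophore report: ", path)
  rep
}

#' Bar-code plot of a superfeature
#'
#' One row per partner interaction sequence, the superfeature occurrence
#' sequence on top; filled cells mark frames with a detected interaction.
#'
#' @param sf a [Superfeature-class]
#' @param col fill color
#' @return invisibly, the matrix of plotted bar codes
#' @export
plotBarcode <- function(sf, col = "steelblue4") {
  partners <- unique(sf@events$partner)
  rows <- c(list(occurrenceBarcode(sf)),
            lapply(partners, function(k) occurrenceBarcode(sf, k)))
  labels <- c(sf@label, partners)
  m <- do.call(rbind, rows)
  nr <- nrow(m)
  graphics::plot(NA, xlim = c(0, sf@nFrames), ylim = c(0, nr),
                 xlab = "frame", ylab = "", yaxt = "n",
                 main = paste("occurrence bar codes:", sf@label))
  graphics::axis(2, at = seq_len(nr) - 0.5, labels = rev(labels), las = 2,
                 cex.axis = 0.7)
  for (r in seq_len(nr)) {
    on <- which(m[r, ])
    if (length(on))
      graphics::rect(on - 1, nr - r, on, nr - r + 0.8, col = col,
                     border = NA)
  }
  invisible(m)
}
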