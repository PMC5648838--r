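# Synthetic receptor-ligand systems with scripted per-frame interaction
# geometry. The receptor is a ring of pseudo-residues, each presenting
# one interaction site (backbone acceptor, serine-like donor/acceptor,
# aspartate-like carboxylate, arginine-like guanidinium, threonine-like
# methyl, two metal cations, a hydroxide). The ligand is a small probe
# whose functional groups are translated frame-by-frame onto or away
# from their scheduled partner sites, so which interactions fire in
# which frame is known by construction. Internal ligand geometry is
# idealized and allowed to distort: detection depends only on
# interatomic geometry, and bonds are carried by CONECT records.

.RING_RADIUS <- 10
.CA_RADIUS <- 13
.BBO2_OFFSET <- 3.4  # z-offset of the second backbone acceptor

.slotDir <- function(k, n_slots = 7) {
  th <- 2 * pi * k / n_slots
  c(cos(th), sin(th), 0)
}

# Receptor recipe: atoms, bonds, and declared interaction sites per
# partner label. Positions chosen so sites sit exactly on the ring
# radius and approach axes are the inward radials.
.toyReceptor <- function(include_metals = TRUE) {
  atoms <- list(); bonds <- list(); partners <- list()
  serial <- 0L
  add_atom <- function(name, element, resname, resnum, pos, charge = 0L,
                       het = FALSE) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resnum = resnum, chain = "A", charge = as.integer(charge), het = het,
      vdw = vdwRadius(element), x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
    serial
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)

  ez <- c(0, 0, 1)
  for (variant in 1:2) {  # two backbone acceptors: bbO and bbO2
    u <- .slotDir(0)
    off <- if (variant == 2) .BBO2_OFFSET * ez else c(0, 0, 0)
    ca <- add_atom("CA", "C", "GLY", variant, .CA_RADIUS * u + off)
    cc <- add_atom("C", "C", "GLY", variant, 11.2 * u + off)
    oo <- add_atom("O", "O", "GLY", variant, .RING_RADIUS * u + off)
    add_bond(ca, cc); add_bond(cc, oo)
    partners[[if (variant == 1) "bbO" else "bbO2"]] <- list(
      resname = "GLY", resnum = variant, class = "protein",
      site = .RING_RADIUS * u + off, axis = -u,
      acceptors = oo, donors = list(), pos = list(), neg = list(),
      hydro = ca)
  }
  u <- .slotDir(1)
  ca <- add_atom("CA", "C", "SER", 3, .CA_RADIUS * u)
  cb <- add_atom("CB", "C", "SER", 3, 11.4 * u)
  og <- add_atom("OG", "O", "SER", 3, .RING_RADIUS * u)
  hg <- add_atom("HG", "H", "SER", 3, 9 * u)
  add_bond(ca, cb); add_bond(cb, og); add_bond(og, hg)
  partners[["serOG"]] <- list(
    resname = "SER", resnum = 3, class = "protein",
    site = .RING_RADIUS * u, axis = -u,
    acceptors = og, donors = list(list(d = og, h = hg)), pos = list(),
    neg = list(), hydro = ca)

  u <- .slotDir(2)
  ca <- add_atom("CA", "C", "ASP", 4, 13.6 * u)
  cb <- add_atom("CB", "C", "ASP", 4, 12.1 * u)
  cg <- add_atom("CG", "C", "ASP", 4, 10.6 * u)
  od1 <- add_atom("OD1", "O", "ASP", 4, .RING_RADIUS * u + 1.1 * ez, -1L)
  od2 <- add_atom("OD2", "O", "ASP", 4, .RING_RADIUS * u - 1.1 * ez)
  add_bond(ca, cb); add_bond(cb, cg); add_bond(cg, od1); add_bond(cg, od2)
  partners[["aspCOO"]] <- list(
    resname = "ASP", resnum = 4, class = "protein",
    site = .RING_RADIUS * u, axis = -u,
    acceptors = c(od1, od2), donors = list(),
    pos = list(), neg = list(list(serials = c(od1, od2), metal = FALSE)),
    hydro = c(ca, cb))

  u <- .slotDir(3)
  w <- c(-u[2], u[1], 0)  # horizontal perpendicular
  cz <- add_atom("CZ", "C", "ARG", 5, .RING_RADIUS * u)
  # guanidinium plane perpendicular to the approach axis, centroid = CZ
  ne <- add_atom("NE", "N", "ARG", 5, .RING_RADIUS * u + 1.33 * ez)
  nh1 <- add_atom("NH1", "N", "ARG", 5,
                  .RING_RADIUS * u + 1.33 * (-0.5 * ez + 0.866 * w))
  nh2 <- add_atom("NH2", "N", "ARG", 5,
                  .RING_RADIUS * u + 1.33 * (-0.5 * ez - 0.866 * w), 1L)
  hh1 <- add_atom("HH1", "H", "ARG", 5,
                  .RING_RADIUS * u + 1.33 * (-0.5 * ez + 0.866 * w) - u)
  hh2 <- add_atom("HH2", "H", "ARG", 5,
                  .RING_RADIUS * u + 1.33 * (-0.5 * ez - 0.866 * w) - u)
  cd <- add_atom("CD", "C", "ARG", 5, .RING_RADIUS * u + 2.83 * ez)
  ca <- add_atom("CA", "C", "ARG", 5, .CA_RADIUS * u + 2.83 * ez)
  add_bond(cz, ne); add_bond(cz, nh1); add_bond(cz, nh2)
  add_bond(nh1, hh1); add_bond(nh2, hh2); add_bond(ne, cd); add_bond(cd, ca)
  partners[["argGua"]] <- list(
    resname = "ARG", resnum = 5, class = "protein",
    site = .RING_RADIUS * u, axis = -u,
    acceptors = integer(0),
    donors = list(list(d = nh1, h = hh1), list(d = nh2, h = hh2)),
    pos = list(list(serials = c(cz, ne, nh1, nh2), metal = FALSE)),
    neg = list(), hydro = ca)

  u <- .slotDir(4)
  ca <- add_atom("CA", "C", "THR", 6, .CA_RADIUS * u)
  cb <- add_atom("CB", "C", "THR", 6, 11.5 * u)
  cg2 <- add_atom("CG2", "C", "THR", 6, .RING_RADIUS * u)
  add_bond(ca, cb); add_bond(cb, cg2)
  partners[["thrMe"]] <- list(
    resname = "THR", resnum = 6, class = "protein",
    site = .RING_RADIUS * u, axis = -u,
    acceptors = integer(0), donors = list(), pos = list(), neg = list(),
    hydro = c(ca, cb, cg2))

  if (include_metals) {
    u <- .slotDir(5)
    mn1 <- add_atom("MN", "MN", "MN", 301, .RING_RADIUS * u, 2L, het = TRUE)
    mn2 <- add_atom("MN", "MN", "MN", 302, .RING_RADIUS * u + 2.8 * ez, 2L,
                    het = TRUE)
    partners[["MN1"]] <- list(resname = "MN", resnum = 301, class = "metal",
                              site = .RING_RADIUS * u, axis = -u,
                              acceptors = integer(0), donors = list(),
                              pos = list(list(serials = mn1, metal = TRUE)),
                              neg = list(), hydro = integer(0))
    partners[["MN2"]] <- list(resname = "MN", resnum = 302, class = "metal",
                              site = .RING_RADIUS * u + 2.8 * ez, axis = -u,
                              acceptors = integer(0), donors = list(),
                              pos = list(list(serials = mn2, metal = TRUE)),
                              neg = list(), hydro = integer(0))
    u <- .slotDir(6)
    oh <- add_atom("O", "O", "OH", 303, .RING_RADIUS * u, -1L, het = TRUE)
    hoh <- add_atom("H1", "H", "OH", 303, .RING_RADIUS * u + 1.0 * ez)
    bonds[[length(bonds) + 1]] <- c(oh, hoh)
    partners[["OH"]] <- list(resname = "OH", resnum = 303, class = "hydroxide",
                             site = .RING_RADIUS * u, axis = -u,
                             acceptors = oh,
                             donors = list(list(d = oh, h = hoh)),
                             pos = list(),
                             neg = list(list(serials = oh, metal = FALSE)),
                             hydro = integer(0))
  }
  list(atoms = do.call(rbind, atoms),
       bonds = do.call(rbind, bonds),
       partners = partners)
}

# Ligand recipes. Each functional group declares the feature templates
# it instantiates (type + defining atom names), the atoms that move with
# it, its anchor (defining point) and its donor hydrogens.
.toyLigand <- function(recipe = c("amino", "boronate"), serial0) {
  recipe <- match.arg(recipe)
  atoms <- list(); bonds <- list(); serial <- serial0
  add_atom <- function(name, element, pos, charge = 0L) {
    serial <<- serial + 1L
    atoms[[length(atoms) + 1]] <<- data.frame(
      serial = serial, name = name, element = element,
      resname = if (recipe == "amino") "LIG" else "LIB",
      resnum = 900L, chain = "A", charge = as.integer(charge), het = TRUE,
      vdw = vdwRadius(element), x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
    serial
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)
  groups <- list()
  if (recipe == "amino") {
    n <- add_atom("N", "N", c(1.3, 0, 0), 1L)
    h1 <- add_atom("H1", "H", c(1.8, 0.8, 0.4))
    h2 <- add_atom("H2", "H", c(1.8, -0.8, 0.4))
    h3 <- add_atom("H3", "H", c(1.3, 0, -1.0))
    ca <- add_atom("CA", "C", c(0, 0, 0))
    cc <- add_atom("C", "C", c(-1.0, 1.0, 0))
    o1 <- add_atom("O1", "O", c(-1.0, 2.2, 0.4))
    o2 <- add_atom("O2", "O", c(-2.0, 0.6, -0.6), -1L)
    og <- add_atom("OG", "O", c(0.0, -1.4, 0.0))
    ho <- add_atom("HO", "H", c(0.0, -1.9, 0.8))
    cb <- add_atom("CB", "C", c(1.0, 0.5, 1.2))
    cg <- add_atom("CG", "C", c(1.5, 1.2, 2.4))
    cd <- add_atom("CD", "C", c(2.2, 0.6, 3.5))
    for (b in list(c(n, h1), c(n, h2), c(n, h3), c(n, ca), c(ca, cc),
                   c(cc, o1), c(cc, o2), c(ca, og), c(og, ho), c(ca, cb),
                   c(cb, cg), c(cg, cd)))
      add_bond(b[1], b[2])
    groups <- list(
      hydroxyl = list(types = c("HBD", "HBA"), feature_atoms = og,
                      hydrogens = ho, movable = c(og, ho), anchor = og),
      amine = list(types = c("HBD", "PI"), feature_atoms = n,
                   hydrogens = c(h1, h2, h3), movable = c(n, h1, h2, h3),
                   anchor = n),
      carboxylate = list(types = "NI", feature_atoms = c(o1, o2),
                         hydrogens = integer(0), movable = c(cc, o1, o2),
                         anchor = NA),  # centroid of feature atoms
      tail = list(types = "H", feature_atoms = c(cb, cg, cd),
                  hydrogens = integer(0), movable = c(cb, cg, cd),
                  anchor = cg)
    )
  } else {
    b <- add_atom("B", "B", c(0, 0, 0), -1L)
    o1 <- add_atom("O1", "O", 1.4 * c(0.94, 0.33, 0))
    o2 <- add_atom("O2", "O", 1.4 * c(-0.47, 0.33, 0.82))
    o3 <- add_atom("O3", "O", 1.4 * c(-0.47, 0.33, -0.82))
    h1 <- add_atom("HO1", "H", 1.4 * c(0.94, 0.33, 0) + c(0.6, 0.7, 0))
    h2 <- add_atom("HO2", "H", 1.4 * c(-0.47, 0.33, 0.82) + c(-0.4, 0.7, 0.5))
    h3 <- add_atom("HO3", "H", 1.4 * c(-0.47, 0.33, -0.82) + c(-0.4, 0.7, -0.5))
    c1 <- add_atom("C1", "C", c(0, -1.6, 0))
    c2 <- add_atom("C2", "C", c(0.5, -2.8, -0.8))
    for (bb in list(c(b, o1), c(b, o2), c(b, o3), c(o1, h1), c(o2, h2),
                    c(o3, h3), c(b, c1), c(c1, c2)))
      add_bond(bb[1], bb[2])
    groups <- list(
      boronate = list(types = "NI", feature_atoms = c(b, o1, o2, o3),
                      hydrogens = integer(0),
                      movable = c(b, o1, o2, o3, h1, h2, h3), anchor = NA),
      boron = list(types = "HBA", feature_atoms = b, hydrogens = integer(0),
                   movable = c(b, o1, o2, o3, h1, h2, h3), anchor = b),
      bOH1 = list(types = "HBD", feature_atoms = o1, hydrogens = h1,
                  movable = c(o1, h1), anchor = o1),
      bOH2 = list(types = "HBD", feature_atoms = o2, hydrogens = h2,
                  movable = c(o2, h2), anchor = o2),
      bOH3 = list(types = "HBD", feature_atoms = o3, hydrogens = h3,
                  movable = c(o3, h3), anchor = o3)
    )
  }
  list(atoms = do.call(rbind, atoms), bonds = do.call(rbind, bonds),
       groups = groups)
}

.DEFAULT_ON <- function(type, metal) {
  if (type %in% c("HBD", "HBA")) 2.9
  else if (type == "H") 3.5
  else if (metal) 2.2 else 4.5
}
.DEFAULT_OFF <- function(type, metal) {
  if (type %in% c("HBD", "HBA")) 5.3
  else if (type == "H") 6.5
  else if (metal) 4.5 else 7.5
}

#' Declare one scheduled interaction
#'
#' @param type feature type (`"HBD"`, `"HBA"`, `"PI"`, `"NI"`, `"H"`)
#' @param group ligand group label (amino probe: `hydroxyl`, `amine`,
#'   `carboxylate`, `tail`; boronate probe: `boronate`, `boron`,
#'   `bOH1..3`)
#' @param partner receptor partner label (`bbO`, `bbO2`, `serOG`,
#'   `aspCOO`, `argGua`, `thrMe`, `MN1`, `MN2`, `OH`)
#' @param frames 0-based frame indices in which the interaction is active
#' @param on,off scheduled distance when active / inactive (Angstrom);
#'   defaults are placed mid-window and 1.5 Angstrom outside it
#' @return a schedule list for [toySpec()]
#' @export
schedule <- function(type, group, partner, frames, on = NULL, off = NULL) {
  stopifnot(type %in% c("HBD", "HBA", "PI", "NI", "H"))
  metal <- partner %in% c("MN1", "MN2")
  list(type = type, group = group, partner = partner,
       frames = sort(unique(as.integer(frames))),
       on = if (is.null(on)) .DEFAULT_ON(type, metal) else on,
       off = if (is.null(off)) .DEFAULT_OFF(type, metal) else off)
}

.typeWindow <- function(type, metal, criteria) {
  if (type %in% c("HBD", "HBA"))
    c(criteria@hbondDistMin, criteria@hbondDistMax)
  else if (type == "H") c(0, criteria@hydrophobDistMax)
  else if (metal) c(0, criteria@metalCoordMax)
  else c(0, criteria@ionicDistMax)
}

#' Specify a synthetic scheduled receptor-ligand system
#'
#' Validates the schedule against the interaction criteria: every `on`
#' distance must sit inside its type's window with margin at least three
#' jitter sigmas, every `off` distance outside by at least 0.5 Angstrom
#' plus three sigmas, so the scheduled truth survives jitter (which is
#' additionally clipped, see [generateToyTrajectory()]).
#'
#' @param n_frames number of frames (>= 1)
#' @param ligand `"amino"` (carboxylate + protonated amine + hydroxyl +
#'   3-carbon tail) or `"boronate"` (tetrahedral borate + ethyl)
#' @param schedules list of [schedule()] entries
#' @param jitter_sigma Gaussian jitter s.d. on scheduled distances
#'   (Angstrom)
#' @param seed RNG seed; output is fully determined by the spec
#' @param rigid_tumble apply a random rigid rotation + translation to the
#'   whole system in every frame (removable by alignment)
#' @param include_metals include the Mn pair and hydroxide
#' @param criteria the [InteractionCriteria-class] the schedule is
#'   validated against (defaults)
#' @return a validated spec list for [generateToyTrajectory()]
#' @export
toySpec <- function(n_frames, ligand = c("amino", "boronate"),
                    schedules = list(), jitter_sigma = 0, seed = 1L,
                    rigid_tumble = FALSE, include_metals = TRUE,
                    criteria = defaultCriteria()) {
  ligand <- match.arg(ligand)
  stopifnot(n_frames >= 1, jitter_sigma >= 0)
  keys <- vapply(schedules, function(s)
    paste(s$type, s$group, s$partner), character(1))
  if (anyDuplicated(keys))
    stop("duplicate schedule key: ", keys[duplicated(keys)][1])
  for (s in schedules) {
    if (length(s$frames) && (min(s$frames) < 0 || max(s$frames) >= n_frames))
      stop("schedule ", paste(s$type, s$group, s$partner),
           ": active frames outside [0, ", n_frames - 1, "]")
    metal <- s$partner %in% c("MN1", "MN2")
    win <- .typeWindow(s$type, metal, criteria)
    on_margin <- min(s$on - win[1], win[2] - s$on)
    if (on_margin <= 0)
      stop("on_distance ", s$on, " outside the ", s$type, " window [",
           win[1], ", ", win[2], "]")
    off_margin <- min(abs(s$off - win)) * (s$off < win[1] || s$off > win[2])
    if (off_margin < 0.5)
      stop("off_distance ", s$off, " must clear the ", s$type,
           " window by >= 0.5 Angstrom")
    if (3 * jitter_sigma > min(on_margin, off_margin))
      stop("jitter_sigma ", jitter_sigma, " too large for schedule ",
           paste(s$type, s$group, s$partner), " (3*sigma exceeds margin ",
           round(min(on_margin, off_margin), 3), ")")
  }
  list(n_frames = as.integer(n_frames), ligand = ligand,
       schedules = schedules, jitter_sigma = jitter_sigma,
       seed = as.integer(seed), rigid_tumble = rigid_tumble,
       include_metals = include_metals, criteria = criteria)
}

# Clipped Gaussian jitter: truncation at 3 sigma and never past the
# validated margin, so scheduled distances stay on their side of the
# window by construction.
.jitter <- function(n, sigma, clip) {
  if (sigma == 0) return(rep(0, n))
  pmax(-clip, pmin(clip, pmax(-3 * sigma, pmin(3 * sigma,
                                               stats::rnorm(n, 0, sigma)))))
}

.unit <- function(v) v / sqrt(sum(v^2))

# Direction for a donor hydrogen serving two acceptors at once: search
# the plane spanned by the two donor->acceptor directions for the unit
# vector that maximizes the smaller of the two D-H...A angles (H is
# placed 1 Angstrom from D along it).
.bestDonorDir <- function(D, A1, A2) {
  e1 <- .unit(A1 - D)
  u2 <- A2 - D
  u2 <- u2 - sum(u2 * e1) * e1
  e2 <- if (sum(u2^2) < 1e-10) .perp(e1) else .unit(u2)
  best <- e1; best_v <- -Inf
  for (th in seq(0, 2 * pi, length.out = 361)[-361]) {
    u <- cos(th) * e1 + sin(th) * e2
    H <- D + u
    v <- min(.angleDeg(D, H, A1), .angleDeg(D, H, A2))
    if (v > best_v) { best_v <- v; best <- u }
  }
  best
}

# A unit vector perpendicular to v: cross(v, ez), or cross(v, ex) when
# v is (anti)parallel to ez.
.perp <- function(v) {
  p <- c(v[2], -v[1], 0)
  if (sum(p^2) < 1e-8) p <- c(0, v[3], -v[2])
  .unit(p)
}

# Solve |P-A1| = d1, |P-A2| = d2, picking the intersection-circle point
# closest to the origin (deterministic).
.twoSphere <- function(A1, A2, d1, d2, frame) {
  L <- .dist3(A1, A2)
  if (L > d1 + d2 || L < abs(d1 - d2) - 1e-9)
    stop("infeasible schedule at frame ", frame,
         ": partners ", round(L, 2), " Angstrom apart cannot both be at ",
         d1, " and ", d2)
  e <- .unit(A2 - A1)
  t <- (d1^2 - d2^2 + L^2) / (2 * L)
  r2 <- d1^2 - t^2
  r <- sqrt(max(0, r2))
  foot <- A1 + t * e
  radial <- -foot - sum(-foot * e) * e   # toward the origin, perp to e
  p <- if (sum(radial^2) < 1e-10) .perp(e) else .unit(radial)
  foot + r * p
}

#' Generate a scheduled toy receptor-ligand trajectory
#'
#' Builds per-frame coordinates in which each scheduled interaction is
#' geometrically satisfied exactly in its active frames (distance =
#' `on` +/- clipped jitter, H-bond angles near 180 degrees) and violated
#' otherwise (distance = `off` +/- jitter, outside the window). Every
#' frame is then brute-force verified: the realized geometry must fire
#' exactly the scheduled (feature, partner) pairs under the criteria, or
#' generation aborts naming the frame. An optional random rigid tumble
#' per frame tests alignment; it is removable by a Calpha fit on the
#' receptor.
#'
#' @param spec a validated [toySpec()]
#' @param out_dir if non-NULL, write `topology.pdb` (1 model + CONECT),
#'   `trajectory.pdb` (multi-model) and `truth.json` there
#' @param verify run the per-frame geometric self-check (default TRUE)
#' @return list with `topology` ([Topology-class]), `trajectory`
#'   (untumbled or tumbled [Trajectory-class] per spec), `truth` (ground
#'   truth list: expected superfeatures, occurrence and partner
#'   frequencies), and `files` (paths, when written)
#' @export
generateToyTrajectory <- function(spec, out_dir = NULL, verify = TRUE) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  rec <- .toyReceptor(spec$include_metals)
  lig <- .toyLigand(spec$ligand, serial0 = max(rec$atoms$serial))
  atoms_df <- rbind(rec$atoms, lig$atoms)
  bonds <- rbind(rec$bonds, lig$bonds)
  storage.mode(bonds) <- "integer"
  top <- new("Topology",
             atoms = atoms_df[, c("serial", "name", "element", "resname",
                                  "resnum", "chain", "charge", "het", "vdw")],
             bonds = bonds)
  base <- as.matrix(atoms_df[, c("x", "y", "z")])
  rownames(base) <- NULL
  row_of <- function(serials) match(serials, atoms_df$serial)

  partners <- rec$partners
  groups <- lig$groups
  for (s in spec$schedules) {
    if (!s$group %in% names(groups))
      stop("unknown ligand group '", s$group, "' for the ", spec$ligand,
           " probe")
    if (!s$partner %in% names(partners))
      stop("unknown partner label '", s$partner, "'")
    if (!s$type %in% groups[[s$group]]$types)
      stop("group '", s$group, "' does not carry feature type ", s$type)
  }

  anchor_of <- function(g, coords) {
    grp <- groups[[g]]
    if (is.na(grp$anchor[1]))
      colMeans(coords[row_of(grp$feature_atoms), , drop = FALSE])
    else coords[row_of(grp$anchor), ]
  }
  site_of <- function(p) partners[[p]]$site

  # schedules indexed by group
  by_group <- split(seq_along(spec$schedules),
                    vapply(spec$schedules, `[[`, "", "group"))

  crit <- spec$criteria
  nf <- spec$n_frames
  coords <- array(0, dim = c(nrow(atoms_df), 3, nf))
  # per-schedule jitter streams, margin-clipped (validated in toySpec)
  jit_on <- list(); jit_off <- list()
  for (si in seq_along(spec$schedules)) {
    s <- spec$schedules[[si]]
    metal <- s$partner %in% c("MN1", "MN2")
    win <- .typeWindow(s$type, metal, crit)
    on_m <- min(s$on - win[1], win[2] - s$on)
    off_m <- min(abs(s$off - win))
    jit_on[[si]] <- .jitter(nf, spec$jitter_sigma, 0.95 * on_m)
    jit_off[[si]] <- .jitter(nf, spec$jitter_sigma, 0.95 * off_m)
  }

  for (f in seq_len(nf) - 1L) {
    xyz <- base
    for (g in names(by_group)) {
      sis <- by_group[[g]]
      act <- sis[vapply(sis, function(si)
        f %in% spec$schedules[[si]]$frames, logical(1))]
      grp <- groups[[g]]
      if (length(act) > 2)
        stop("infeasible schedule at frame ", f, ": group '", g,
             "' has ", length(act), " simultaneous placements")
      if (length(act) == 0) {
        si <- sis[1]
        s <- spec$schedules[[si]]
        d <- s$off + jit_off[[si]][f + 1]
        target <- site_of(s$partner) + d * partners[[s$partner]]$axis
        toward <- NULL
      } else if (length(act) == 1) {
        s <- spec$schedules[[act]]
        d <- s$on + jit_on[[act]][f + 1]
        target <- site_of(s$partner) + d * partners[[s$partner]]$axis
        toward <- if (s$type == "HBD") site_of(s$partner)
      } else {
        s1 <- spec$schedules[[act[1]]]; s2 <- spec$schedules[[act[2]]]
        d1 <- s1$on + jit_on[[act[1]]][f + 1]
        d2 <- s2$on + jit_on[[act[2]]][f + 1]
        target <- .twoSphere(site_of(s1$partner), site_of(s2$partner),
                             d1, d2, f)
        toward <- if (s1$type == "HBD" || s2$type == "HBD")
          (site_of(s1$partner) + site_of(s2$partner)) / 2
      }
      shift <- target - anchor_of(g, base)
      mi <- row_of(grp$movable)
      xyz[mi, ] <- base[mi, , drop = FALSE] +
        matrix(shift, length(mi), 3, byrow = TRUE)
      # donor hydrogen placement: first H on the donor->partner axis,
      # the rest pointing back; all H away from partners when inactive
      if (length(grp$hydrogens) > 0 && "HBD" %in% grp$types) {
        Dpos <- xyz[row_of(grp$feature_atoms[1]), ]
        v <- if (is.null(toward)) {
          .unit(Dpos - site_of(spec$schedules[[sis[1]]]$partner))
        } else if (length(act) == 2) {
          # point the hydrogen to maximize the smaller of the two
          # D-H...A angles (grid search over the acceptor plane)
          .bestDonorDir(Dpos, site_of(spec$schedules[[act[1]]]$partner),
                        site_of(spec$schedules[[act[2]]]$partner))
        } else {
          .unit(toward - Dpos)
        }
        q <- .perp(v)
        hs <- row_of(grp$hydrogens)
        xyz[hs[1], ] <- Dpos + v
        if (length(hs) > 1)
          xyz[hs[2], ] <- Dpos - 0.5 * v + 0.866 * q
        if (length(hs) > 2)
          xyz[hs[3], ] <- Dpos - 0.5 * v - 0.866 * q
      }
    }
    if (verify) .verifyFrame(f, xyz, row_of, groups, partners, spec, crit)
    coords[, , f + 1] <- xyz
  }

  if (spec$rigid_tumble) {
    for (f in seq_len(nf)) {
      R <- .randomRotation()
      shift <- stats::runif(3, -5, 5)
      coords[, , f] <- coords[, , f] %*% t(R) +
        matrix(shift, nrow(atoms_df), 3, byrow = TRUE)
    }
  }

  traj <- new("Trajectory", topology = top, coords = coords,
              times = rep(NA_real_, nf))
  truth <- .scheduleTruth(spec, groups, partners, atoms_df)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    top_path <- file.path(out_dir, "topology.pdb")
    trj_path <- file.path(out_dir, "trajectory.pdb")
    tru_path <- file.path(out_dir, "truth.json")
    writeTrajectoryPdb(makeTrajectory(top, coords[, , 1]), top_path)
    writeTrajectoryPdb(traj, trj_path, conect = FALSE)
    jsonlite::write_json(truth, tru_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- list(topology = top_path, trajectory = trj_path,
                  truth = tru_path)
  }
  list(topology = top, trajectory = traj, truth = truth, files = files)
}

# Uniform random rotation via quaternion.
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Defining distance (and H-bond angle pass) of one ligand feature group
# against one partner, from raw coordinates. Used only for generator
# self-checks; deliberately a direct transcription of the criteria.
.wouldFire <- function(type, grp, pp, xyz, row_of, crit) {
  win <- NULL
  if (type == "HBD") {
    if (length(pp$acceptors) == 0) return(FALSE)
    D <- xyz[row_of(grp$feature_atoms[1]), ]
    for (a in pp$acceptors) {
      A <- xyz[row_of(a), ]
      d <- .dist3(D, A)
      if (d < crit@hbondDistMin || d > crit@hbondDistMax) next
      if (length(grp$hydrogens) == 0) return(TRUE)
      for (h in grp$hydrogens)
        if (.angleDeg(D, xyz[row_of(h), ], A) >= crit@hbondAngleMin)
          return(TRUE)
    }
    return(FALSE)
  }
  if (type == "HBA") {
    if (length(pp$donors) == 0) return(FALSE)
    A <- xyz[row_of(grp$feature_atoms[1]), ]
    for (dn in pp$donors) {
      D <- xyz[row_of(dn$d), ]
      d <- .dist3(D, A)
      if (d < crit@hbondDistMin || d > crit@hbondDistMax) next
      for (h in dn$h)
        if (.angleDeg(D, xyz[row_of(h), ], A) >= crit@hbondAngleMin)
          return(TRUE)
    }
    return(FALSE)
  }
  if (type %in% c("PI", "NI")) {
    gs <- if (type == "PI") pp$neg else pp$pos
    if (length(gs) == 0) return(FALSE)
    cl <- colMeans(xyz[row_of(grp$feature_atoms), , drop = FALSE])
    for (g in gs) {
      cp <- colMeans(xyz[row_of(g$serials), , drop = FALSE])
      cutoff <- if (isTRUE(g$metal)) crit@metalCoordMax else crit@ionicDistMax
      if (.dist3(cl, cp) <= cutoff) return(TRUE)
    }
    return(FALSE)
  }
  if (type == "H") {
    if (length(pp$hydro) == 0) return(FALSE)
    L <- xyz[row_of(grp$feature_atoms), , drop = FALSE]
    P <- xyz[row_of(pp$hydro), , drop = FALSE]
    return(min(.crossDist2(L, P)) <= crit@hydrophobDistMax^2)
  }
  FALSE
}

.verifyFrame <- function(f, xyz, row_of, groups, partners, spec, crit) {
  sched_on <- vapply(spec$schedules, function(s)
    if (f %in% s$frames) paste(s$type, s$group, s$partner) else "",
    character(1))
  for (g in names(groups)) {
    grp <- groups[[g]]
    for (type in grp$types) {
      for (p in names(partners)) {
        fire <- .wouldFire(type, grp, partners[[p]], xyz, row_of, crit)
        want <- paste(type, g, p) %in% sched_on
        if (fire != want)
          stop("infeasible schedule at frame ", f, ": ", type, " ", g,
               " vs ", p, if (want) " fails to fire" else
                 " fires although not scheduled")
      }
    }
  }
  invisible(TRUE)
}

# Ground truth from schedule arithmetic: occurrence = union of active
# frames per (type, group); partner frequency relative to that union.
.scheduleTruth <- function(spec, groups, partners, atoms_df) {
  name_of <- stats::setNames(atoms_df$name, as.character(atoms_df$serial))
  keys <- vapply(spec$schedules, function(s) paste(s$type, s$group),
                 character(1))
  sfs <- list()
  for (k in unique(keys)) {
    sch <- spec$schedules[keys == k]
    type <- sch[[1]]$type; g <- sch[[1]]$group
    occ <- sort(unique(unlist(lapply(sch, `[[`, "frames"))))
    if (length(occ) == 0) next
    parts <- lapply(sch, function(s) {
      pp <- partners[[s$partner]]
      list(label = s$partner,
           key = paste(pp$resname, pp$resnum, "A", sep = "/"),
           count = length(s$frames),
           frames = s$frames,
           frequency = 100 * length(s$frames) / length(occ))
    })
    sfs[[length(sfs) + 1]] <- list(
      type = type, group = g,
      atom_names = unname(name_of[as.character(
        sort(groups[[g]]$feature_atoms))]),
      occurrence_count = length(occ),
      frames = occ,
      frequency = 100 * length(occ) / spec$n_frames,
      partners = parts)
  }
  list(n_frames = spec$n_frames, ligand = spec$ligand, seed = spec$seed,
       jitter_sigma = spec$jitter_sigma, rigid_tumble = spec$rigid_tumble,
       superfeatures = sfs)
}

#' Write a volume phantom: a marker atom plus explicit occluders
#'
#' A single-model PDB with a HETATM boron marker at the origin (the
#' sphere center for [pocketVolume()]; HETATM, so it never occludes) and
#' one carbon ATOM record per occluder position (ATOM records of a
#' non-water residue, so they do occlude).
#'
#' @param path output PDB path
#' @param occluders numeric matrix / data.frame of occluder positions
#'   (columns x, y, z); `NULL` for an empty sphere
#' @param element occluder element symbol (sets the vdW radius;
#'   default `"C"`, 1.7 Angstrom)
#' @return the path, invisibly
#' @export
generateVolumePhantom <- function(path, occluders = NULL, element = "C") {
  n <- if (is.null(occluders)) 0L else nrow(occluders)
  atoms <- data.frame(
    serial = seq_len(n + 1L),
    name = c("B", rep(element, n)),
    element = c("B", rep(element, n)),
    resname = c("CEN", rep("OCC", n)),
    resnum = c(1L, rep(2L, n)),
    chain = "A",
    charge = 0L,
    het = c(TRUE, rep(FALSE, n)),
    vdw = vdwRadius(c("B", rep(element, n))),
    stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0),
                  if (n) as.matrix(occluders[, 1:3]) else NULL)
  top <- new("Topology", atoms = atoms, bonds = matrix(integer(0), ncol = 2))
  writeTrajectoryPdb(makeTrajectory(top, coords), path, conect = FALSE)
  invisible(path)
}

#' Occluder grids for volume phantoms
#'
#' `slabOccluders` fills the half-space `z <= z_top` (within reach of the
#' inclusion sphere) with a cubic carbon grid whose effective surface
#' plane averages to `z = 0`; `ballOccluders` fills the whole sphere, and
#' `NULL` occluders give the empty phantom.
#'
#' @param radius inclusion sphere radius the phantom will be probed with
#' @param spacing occluder grid spacing (Angstrom)
#' @param z_top z of the top occluder layer; the default places the mean
#'   hard-sphere surface of a 1.7 Angstrom carbon grid at z = 0
#' @return data.frame of x, y, z occluder centers
#' @export
slabOccluders <- function(radius = 10, spacing = 1.0, z_top = -1.623) {
  g <- seq(-radius - 2, radius + 2, by = spacing)
  zs <- seq(z_top, -radius - 2, by = -spacing)
  pts <- expand.grid(x = g, y = g, z = zs)
  pts[pts$x^2 + pts$y^2 + pts$z^2 <= (radius + 2.5)^2, ]
}

#' @rdname slabOccluders
#' @export
ballOccluders <- function(radius = 10, spacing = 1.5) {
  g <- seq(-radius - 1.5, radius + 1.5, by = spacing)
  pts <- expand.grid(x = g, y = g, z = g)
  pts[pts$x^2 + pts$y^2 + pts$z^2 <= (radius + 1.5)^2, ]
}
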