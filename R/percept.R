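#' Pharmacophore feature taxonomy
#'
#' The closed feature enumeration used throughout the package, with the
#' canonical display colors: hydrogen-bond donor (green), hydrogen-bond
#' acceptor (red), positive ionizable (blue), negative ionizable
#' (orange), hydrophobic contact (yellow).
#'
#' @return data.frame with columns `type`, `description`, `color`
#' @export
featureTypes <- function() {
  data.frame(
    type = c("HBD", "HBA", "PI", "NI", "H"),
    description = c("H-bond donor", "H-bond acceptor",
                    "positive ionizable", "negative ionizable",
                    "hydrophobic contact"),
    color = c("green", "red", "blue", "orange", "yellow"),
    stringsAsFactors = FALSE
  )
}

#' Default geometric interaction criteria
#'
#' Standard literature criteria: hydrogen bond 2.5-3.8 Angstrom
#' donor-acceptor heavy-atom distance with D-H...A angle >= 130 degrees;
#' ionic contact <= 5.5 Angstrom between charged-group centroids;
#' hydrophobic contact <= 4.5 Angstrom between apolar heavy atoms; metal
#' coordination <= 3.0 Angstrom, counted as the ionic event class for
#' negative ionizable features with metal partners.
#'
#' @return an [InteractionCriteria-class]
#' @export
defaultCriteria <- function() {
  new("InteractionCriteria",
      hbondDistMin = 2.5, hbondDistMax = 3.8, hbondAngleMin = 130,
      ionicDistMax = 5.5, hydrophobDistMax = 4.5, metalCoordMax = 3.0)
}

.CRITERIA_KEYS <- c(
  hbond_dist_min = "hbondDistMin", hbond_dist_max = "hbondDistMax",
  hbond_angle_min = "hbondAngleMin", ionic_dist_max = "ionicDistMax",
  hydrophobic_dist_max = "hydrophobDistMax", metal_coord_max = "metalCoordMax"
)

#' Read interaction criteria from a flat key=value file
#'
#' Recognised keys: `hbond_dist_min`, `hbond_dist_max`,
#' `hbond_angle_min`, `ionic_dist_max`, `hydrophobic_dist_max`,
#' `metal_coord_max`. Missing keys keep their defaults; unknown keys are
#' rejected. Lines starting with `#` are comments.
#'
#' @param path config file
#' @return an [InteractionCriteria-class]
#' @export
readCriteria <- function(path) {
  if (!file.exists(path)) stop("criteria file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  crit <- defaultCriteria()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("criteria parse error: expected key=value, got '", ln, "'")
    key <- trimws(kv[1])
    if (!key %in% names(.CRITERIA_KEYS))
      stop("criteria parse error: unknown key '", key, "'")
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("criteria parse error: non-numeric value in '", ln, "'")
    slot(crit, .CRITERIA_KEYS[[key]]) <- val
  }
  validObject(crit)
  crit
}

#' Write interaction criteria as a flat key=value file
#' @param criteria an [InteractionCriteria-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeCriteria <- function(criteria, path) {
  lines <- vapply(names(.CRITERIA_KEYS), function(k)
    sprintf("%s = %g", k, slot(criteria, .CRITERIA_KEYS[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

.criteriaList <- function(criteria) {
  out <- lapply(names(.CRITERIA_KEYS), function(k)
    slot(criteria, .CRITERIA_KEYS[[k]]))
  names(out) <- names(.CRITERIA_KEYS)
  out
}

# ---- structural perception --------------------------------------------------

# Adjacency list (serial -> neighbor serials) from the bond matrix.
.adjacency <- function(topology) {
  b <- bonds(topology)
  if (nrow(b) == 0) return(list())
  split(c(b[, 2], b[, 1]), factor(c(b[, 1], b[, 2])))
}

# Rule-based site perception over one covalent unit (a ligand or one
# environment residue). Returns donor/acceptor atoms, charged groups and
# hydrophobic atoms, by serial.
.perceiveSites <- function(topology, serials, adj = .adjacency(topology),
                           warn_unknown = TRUE) {
  a <- atoms(topology)
  idx <- .serialIndex(topology, serials)
  sub <- a[idx, ]
  elem_of <- stats::setNames(a$element, as.character(a$serial))
  chg_of <- stats::setNames(a$charge, as.character(a$serial))
  nbrs <- function(s) {
    n <- adj[[as.character(s)]]
    if (is.null(n)) integer(0) else n
  }
  nbr_elem <- function(s) elem_of[as.character(nbrs(s))]

  known <- c("H", "C", "N", "O", "S", "P", "B", "F", "CL", "BR", "I",
             .METAL_ELEMENTS)
  unk <- !(sub$element %in% known)
  if (any(unk) && warn_unknown)
    warning("unknown element(s) skipped in typing: ",
            paste(unique(sub$element[unk]), collapse = ", "))
  sub <- sub[!unk, ]

  donors <- list(); acceptors <- integer(0)
  pos <- list(); neg <- list(); hydro <- integer(0)
  in_pos <- integer(0); borate_o <- integer(0); grouped_neg <- integer(0)

  # group patterns first (they veto per-atom typing)
  for (i in seq_len(nrow(sub))) {
    s <- sub$serial[i]; el <- sub$element[i]
    ne <- nbr_elem(s); nn <- nbrs(s)
    if (el == "B" && sum(ne == "O") >= 3) {
      o_nb <- nn[ne == "O"]
      neg[[length(neg) + 1]] <- list(serials = c(s, o_nb), metal = FALSE,
                                     kind = "borate")
      grouped_neg <- c(grouped_neg, s, o_nb)
      borate_o <- c(borate_o, o_nb)
      acceptors <- c(acceptors, s)  # group acceptor carried by the boron
    } else if (el %in% c("C", "S", "P")) {
      o_nb <- nn[ne == "O"]
      terminal_o <- o_nb[vapply(o_nb, function(o) {
        on <- nbr_elem(o)
        length(on[on != "H"]) == 1 && !any(on == "H")
      }, logical(1))]
      min_o <- c(C = 2L, S = 3L, P = 2L)[[el]]
      if (length(terminal_o) >= min_o) {
        grp <- if (el == "C") terminal_o else terminal_o
        neg[[length(neg) + 1]] <- list(serials = sort(grp), metal = FALSE,
                                       kind = c(C = "carboxylate",
                                                S = "sulfonate",
                                                P = "phosphate")[[el]])
        grouped_neg <- c(grouped_neg, grp)
      }
      if (el == "C" && sum(ne == "N") == 3) {
        n_nb <- nn[ne == "N"]
        pos[[length(pos) + 1]] <- list(serials = sort(c(s, n_nb)),
                                       metal = FALSE, kind = "guanidinium")
        in_pos <- c(in_pos, s, n_nb)
      }
    } else if (el %in% .METAL_ELEMENTS) {
      pos[[length(pos) + 1]] <- list(serials = s, metal = TRUE, kind = "metal")
      in_pos <- c(in_pos, s)
    }
  }

  # hydroxide-like: charged O bonded to H only
  for (i in seq_len(nrow(sub))) {
    s <- sub$serial[i]
    if (sub$element[i] == "O" && chg_of[as.character(s)] < 0 &&
        !(s %in% grouped_neg)) {
      ne <- nbr_elem(s)
      if (all(ne == "H")) {
        neg[[length(neg) + 1]] <- list(serials = s, metal = FALSE,
                                       kind = "hydroxide")
        grouped_neg <- c(grouped_neg, s)
      }
    }
  }

  for (i in seq_len(nrow(sub))) {
    s <- sub$serial[i]; el <- sub$element[i]
    nn <- nbrs(s); ne <- nbr_elem(s)
    chg <- chg_of[as.character(s)]
    if (el %in% c("O", "N")) {
      hyd <- nn[ne == "H"]
      if (length(hyd) > 0)
        donors[[length(donors) + 1]] <- list(serial = s, hydrogens = sort(hyd))
      # protonated amine: formal + charge or 4 connections
      if (el == "N" && !(s %in% in_pos) && (chg > 0 || length(nn) >= 4)) {
        pos[[length(pos) + 1]] <- list(serials = s, metal = FALSE,
                                       kind = "ammonium")
        in_pos <- c(in_pos, s)
      }
      is_pos <- s %in% in_pos || chg > 0
      if (el == "O" && !is_pos && !(s %in% borate_o))
        acceptors <- c(acceptors, s)
      if (el == "N" && !is_pos && length(nn) <= 3)
        acceptors <- c(acceptors, s)
    } else if (el %in% c("C", "S")) {
      if (length(ne) > 0 && all(ne %in% c("C", "H", "S")))
        hydro <- c(hydro, s)
    }
    # residual formal charges not covered by a group pattern
    if (chg > 0 && !(s %in% in_pos) && !(el %in% c("O", "N"))) {
      pos[[length(pos) + 1]] <- list(serials = s, metal = FALSE, kind = "cation")
      in_pos <- c(in_pos, s)
    }
    if (chg < 0 && !(s %in% grouped_neg) && !(el == "O" && s %in% borate_o)) {
      neg[[length(neg) + 1]] <- list(serials = s, metal = FALSE, kind = "anion")
      grouped_neg <- c(grouped_neg, s)
    }
  }

  # connected components of hydrophobic carbons (C-C bonds only)
  comp <- list()
  if (length(hydro) > 0) {
    carbons <- hydro[a$element[.serialIndex(topology, hydro)] == "C"]
    remaining <- carbons
    while (length(remaining) > 0) {
      seed <- remaining[1]
      grp <- seed
      frontier <- seed
      while (length(frontier) > 0) {
        nxt <- unique(unlist(lapply(frontier, nbrs)))
        nxt <- nxt[nxt %in% remaining & !(nxt %in% grp)]
        grp <- c(grp, nxt)
        frontier <- nxt
      }
      comp[[length(comp) + 1]] <- sort(grp)
      remaining <- setdiff(remaining, grp)
    }
  }

  list(donors = donors, acceptors = sort(unique(acceptors)), pos = pos,
       neg = neg, hydro = sort(unique(hydro)), carbon_components = comp)
}

#' Perceive ligand pharmacophore feature templates
#'
#' Rule-based typing over the ligand atoms:
#' \itemize{
#'   \item HBD: every O/N carrying at least one explicit hydrogen (one
#'     template per O/N-H group, all of the group's hydrogens attached).
#'   \item HBA: every O/N bearing a lone pair and not positively charged.
#'     A tetrahedral borate contributes a single group acceptor on the
#'     boron; its hydroxyl oxygens act as donors only.
#'   \item PI: protonated amines (formal positive charge or four
#'     connections) and guanidinium/amidine carbon groups.
#'   \item NI: carboxylates (both oxygens in one template), tetrahedral
#'     borates/boronates, sulfonates, phosphates, and residual formally
#'     negative atoms.
#'   \item H: maximal connected sets of carbons bonded only to C/H/S, of
#'     at least three carbons.
#' }
#'
#' @param topology a [Topology-class] with bonds, elements and formal
#'   charges
#' @param ligand_selection selection expression or serial vector
#' @return list of [FeatureTemplate-class], ordered by type then atoms
#' @export
perceiveFeatures <- function(topology, ligand_selection = "ligand") {
  lig <- .resolveSel(topology, ligand_selection)
  if (length(lig) == 0) stop("ligand selection is empty")
  sites <- .perceiveSites(topology, lig)
  nm <- stats::setNames(atoms(topology)$name,
                        as.character(atoms(topology)$serial))
  lab <- function(type, serials) {
    s <- sort(serials)
    if (length(s) > 4)
      sprintf("%s[%s..%s]", type, nm[as.character(s[1])],
              nm[as.character(s[length(s)])])
    else sprintf("%s[%s]", type, paste(nm[as.character(s)], collapse = ","))
  }
  tmpl <- list()
  add <- function(type, atoms_, hyd = integer(0)) {
    tmpl[[length(tmpl) + 1]] <<- new("FeatureTemplate", type = type,
                                     atoms = as.integer(sort(atoms_)),
                                     hydrogens = as.integer(sort(hyd)),
                                     label = lab(type, atoms_))
  }
  for (d in sites$donors) add("HBD", d$serial, d$hydrogens)
  for (s in sites$acceptors) add("HBA", s)
  for (g in sites$pos) if (!g$metal) add("PI", g$serials)
  for (g in sites$neg) add("NI", g$serials)
  for (cc in sites$carbon_components) if (length(cc) >= 3) add("H", cc)
  # unique on (type, atoms)
  key <- vapply(tmpl, function(t)
    paste(t@type, paste(t@atoms, collapse = ",")), character(1))
  tmpl <- tmpl[!duplicated(key)]
  ord <- order(match(vapply(tmpl, function(t) t@type, character(1)),
                     c("HBD", "HBA", "PI", "NI", "H")),
               vapply(tmpl, function(t) t@atoms[1], integer(1)))
  tmpl[ord]
}

#' Classify environment residues into interaction partners
#'
#' Every residue outside the ligand selection becomes one partner,
#' identified by `(resname, resnum, chain)` and classed as `protein`,
#' `metal` (Mn, Zn, Mg, Ca, Fe, Na, K ions), `hydroxide`, `water`, or
#' `other-het`.
#'
#' @param topology a [Topology-class]
#' @param ligand_selection the ligand (excluded from partners)
#' @return data.frame with columns `key`, `resname`, `resnum`, `chain`,
#'   `pclass` and a list-column `serials`
#' @export
classifyEnvironment <- function(topology, ligand_selection = "ligand") {
  a <- atoms(topology)
  lig <- .resolveSel(topology, ligand_selection)
  env <- a[!(a$serial %in% lig), ]
  if (nrow(env) == 0)
    return(data.frame(key = character(0), resname = character(0),
                      resnum = integer(0), chain = character(0),
                      pclass = character(0)))
  key <- paste(env$resname, env$resnum, env$chain, sep = "/")
  keys <- unique(key)
  rows <- lapply(keys, function(k) {
    sub <- env[key == k, ]
    pclass <- if (all(sub$element %in% .METAL_ELEMENTS)) "metal"
      else if (sub$resname[1] %in% .HYDROXIDE_RESNAMES) "hydroxide"
      else if (sub$resname[1] %in% .WATER_RESNAMES) "water"
      else if (sub$resname[1] %in% .STANDARD_AA) "protein"
      else "other-het"
    data.frame(key = k, resname = sub$resname[1], resnum = sub$resnum[1],
               chain = sub$chain[1], pclass = pclass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$serials <- I(lapply(keys, function(k) env$serial[key == k]))
  rownames(out) <- NULL
  out
}

# Flattened environment interaction sites across all partners, computed
# once per system (coordinates-independent).
.environmentSites <- function(topology, partners) {
  adj <- .adjacency(topology)
  don_serial <- integer(0); don_partner <- integer(0); don_h <- list()
  acc_serial <- integer(0); acc_partner <- integer(0)
  grp <- list()
  hyd_serial <- integer(0); hyd_partner <- integer(0)
  for (p in seq_len(nrow(partners))) {
    sites <- .perceiveSites(topology, partners$serials[[p]], adj,
                            warn_unknown = FALSE)
    for (d in sites$donors) {
      don_serial <- c(don_serial, d$serial)
      don_partner <- c(don_partner, p)
      don_h[[length(don_h) + 1]] <- d$hydrogens
    }
    acc_serial <- c(acc_serial, sites$acceptors)
    acc_partner <- c(acc_partner, rep(p, length(sites$acceptors)))
    for (g in sites$pos)
      grp[[length(grp) + 1]] <- list(serials = g$serials, partner = p,
                                     sign = 1L, metal = g$metal)
    for (g in sites$neg)
      grp[[length(grp) + 1]] <- list(serials = g$serials, partner = p,
                                     sign = -1L, metal = FALSE)
    hyd_serial <- c(hyd_serial, sites$hydro)
    hyd_partner <- c(hyd_partner, rep(p, length(sites$hydro)))
  }
  list(donors = list(serial = don_serial, partner = don_partner, h = don_h),
       acceptors = list(serial = acc_serial, partner = acc_partner),
       groups = grp,
       hydro = list(serial = hyd_serial, partner = hyd_partner))
}

# Candidate pair pruning by cell binning: returns candidate (i, j) index
# pairs between coordinate sets A and B with pair distance possibly
# <= cutoff. Exact distances are re-checked downstream, so the list may
# contain false positives but never misses a true pair.
.cellPairs <- function(A, B, cutoff) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(cbind(i = integer(0), j = integer(0)))
  cell_of <- function(M) floor(sweep(M, 2, c(0, 0, 0)) / cutoff)
  ca <- cell_of(A); cb <- cell_of(B)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_len(nrow(B)), keyb)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(nrow(A))) {
    neigh <- sweep(offs, 2, ca[i, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    js <- unlist(bmap[keys], use.names = FALSE)
    if (length(js)) {
      out_i <- c(out_i, rep(i, length(js)))
      out_j <- c(out_j, js)
    }
  }
  cbind(i = out_i, j = out_j)
}

.allPairs <- function(A, B, cutoff = NULL) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(cbind(i = integer(0), j = integer(0)))
  as.matrix(expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B))))
}

#' Detect ligand-environment interactions in one frame
#'
#' Applies the geometric criteria to every (feature template, partner)
#' combination:
#' \itemize{
#'   \item HBD: ligand donor heavy atom within the H-bond distance window
#'     of a partner acceptor heavy atom, and the best D-H...A angle over
#'     the donor's explicit hydrogens at least `hbond_angle_min`. A donor
#'     without explicit hydrogens is evaluated on heavy-atom distance
#'     alone (with a one-time warning).
#'   \item HBA: symmetric, with partner donors.
#'   \item PI/NI: opposite-sign charged-group centroids within
#'     `ionic_dist_max`; metals count as positive partners within
#'     `metal_coord_max` (same event class).
#'   \item H: any template carbon within `hydrophobic_dist_max` of a
#'     partner hydrophobic heavy atom.
#' }
#' At most one event per (template, partner) per frame is kept, with the
#' minimal qualifying distance. Water partners are skipped unless
#' `include_water = TRUE`.
#'
#' @param traj an (aligned) [Trajectory-class]
#' @param frame 0-based frame index
#' @param templates list of [FeatureTemplate-class] from
#'   [perceiveFeatures()]
#' @param partners data.frame from [classifyEnvironment()]
#' @param criteria an [InteractionCriteria-class]
#' @param include_water include water partners
#' @param method `"cell"` (neighbor-list accelerated) or `"brute"`
#'   (all-pairs); both return the identical event set
#' @param sites optional precomputed result of the internal environment
#'   site perception (used by [buildDynophore()] to avoid re-perception
#'   per frame)
#' @return data.frame of events: `frame`, `label`, `type`, `partner`,
#'   `resname`, `resnum`, `chain`, `pclass`, `distance`, `x`, `y`, `z`
#'   (feature centroid)
#' @export
detectFrameInteractions <- function(traj, frame, templates, partners,
                                    criteria = defaultCriteria(),
                                    include_water = FALSE,
                                    method = c("cell", "brute"),
                                    sites = NULL) {
  method <- match.arg(method)
  top <- topology(traj)
  xyz <- frameCoords(traj, frame)
  if (is.null(sites)) sites <- .environmentSites(top, partners)
  keep_p <- if (include_water) rep(TRUE, nrow(partners))
            else partners$pclass != "water"
  pos_of <- function(serials) {
    i <- .serialIndex(top, serials)
    if (length(i) == 1) xyz[i, , drop = FALSE]
    else matrix(colMeans(xyz[i, , drop = FALSE]), 1, 3)
  }
  atom_xyz <- function(serials) xyz[.serialIndex(top, serials), , drop = FALSE]
  pairfun <- if (method == "cell") .cellPairs else .allPairs

  ev <- list()
  push <- function(tmpl, p, dist, centroid) {
    ev[[length(ev) + 1]] <<- data.frame(
      frame = as.integer(frame), label = tmpl@label, type = tmpl@type,
      partner = partners$key[p], resname = partners$resname[p],
      resnum = partners$resnum[p], chain = partners$chain[p],
      pclass = partners$pclass[p], distance = dist,
      x = centroid[1], y = centroid[2], z = centroid[3],
      stringsAsFactors = FALSE)
  }
  warned_noh <- FALSE

  hb_lo <- criteria@hbondDistMin; hb_hi <- criteria@hbondDistMax
  ang_min <- criteria@hbondAngleMin

  for (tmpl in templates) {
    centroid <- colMeans(atom_xyz(tmpl@atoms))
    if (tmpl@type == "HBD") {
      acc <- sites$acceptors
      ok_p <- keep_p[acc$partner]
      A <- atom_xyz(acc$serial[ok_p])
      pidx <- acc$partner[ok_p]
      D <- atom_xyz(tmpl@atoms[1])
      cand <- pairfun(D, A, hb_hi)
      if (nrow(cand)) {
        H <- atom_xyz(tmpl@hydrogens)
        if (nrow(H) == 0 && !warned_noh) {
          warning("donor ", tmpl@label, " has no explicit hydrogens; ",
                  "evaluated on heavy-atom distance only")
          warned_noh <- TRUE
        }
        best <- list()
        for (r in seq_len(nrow(cand))) {
          j <- cand[r, 2]
          d <- .dist3(D[1, ], A[j, ])
          if (d < hb_lo || d > hb_hi) next
          if (nrow(H) > 0) {
            angs <- vapply(seq_len(nrow(H)), function(h)
              .angleDeg(D[1, ], H[h, ], A[j, ]), numeric(1))
            if (max(angs) < ang_min) next
          }
          p <- pidx[j]
          if (is.null(best[[as.character(p)]]) ||
              d < best[[as.character(p)]])
            best[[as.character(p)]] <- d
        }
        for (pk in names(best))
          push(tmpl, as.integer(pk), best[[pk]], centroid)
      }
    } else if (tmpl@type == "HBA") {
      don <- sites$donors
      ok <- which(keep_p[don$partner])
      if (length(ok)) {
        Dp <- atom_xyz(don$serial[ok])
        # acceptor position: the acceptor heavy atom (the boron itself
        # for borate group acceptors)
        Al <- atom_xyz(tmpl@atoms[1])
        cand <- pairfun(Al, Dp, hb_hi)
        best <- list()
        for (r in seq_len(nrow(cand))) {
          j <- cand[r, 2]
          d <- .dist3(Al[1, ], Dp[j, ])
          if (d < hb_lo || d > hb_hi) next
          hyd <- don$h[[ok[j]]]
          if (length(hyd) > 0) {
            Hp <- atom_xyz(hyd)
            angs <- vapply(seq_len(nrow(Hp)), function(h)
              .angleDeg(Dp[j, ], Hp[h, ], Al[1, ]), numeric(1))
            if (max(angs) < ang_min) next
          }
          p <- don$partner[ok[j]]
          if (is.null(best[[as.character(p)]]) || d < best[[as.character(p)]])
            best[[as.character(p)]] <- d
        }
        for (pk in names(best))
          push(tmpl, as.integer(pk), best[[pk]], centroid)
      }
    } else if (tmpl@type %in% c("PI", "NI")) {
      want_sign <- if (tmpl@type == "PI") -1L else 1L
      best <- list()
      for (g in sites$groups) {
        if (g$sign != want_sign || !keep_p[g$partner]) next
        cutoff <- if (g$metal) criteria@metalCoordMax else criteria@ionicDistMax
        d <- .dist3(as.vector(pos_of(tmpl@atoms)), as.vector(pos_of(g$serials)))
        if (d > cutoff) next
        p <- g$partner
        if (is.null(best[[as.character(p)]]) || d < best[[as.character(p)]])
          best[[as.character(p)]] <- d
      }
      for (pk in names(best))
        push(tmpl, as.integer(pk), best[[pk]], centroid)
    } else if (tmpl@type == "H") {
      hyd <- sites$hydro
      ok <- which(keep_p[hyd$partner])
      if (length(ok)) {
        Lc <- atom_xyz(tmpl@atoms)
        Pc <- atom_xyz(hyd$serial[ok])
        cand <- pairfun(Lc, Pc, criteria@hydrophobDistMax)
        best <- list()
        for (r in seq_len(nrow(cand))) {
          d <- .dist3(Lc[cand[r, 1], ], Pc[cand[r, 2], ])
          if (d > criteria@hydrophobDistMax) next
          p <- hyd$partner[ok[cand[r, 2]]]
          if (is.null(best[[as.character(p)]]) || d < best[[as.character(p)]])
            best[[as.character(p)]] <- d
        }
        for (pk in names(best))
          push(tmpl, as.integer(pk), best[[pk]], centroid)
      }
    }
  }
  if (length(ev) == 0)
    return(data.frame(frame = integer(0), label = character(0),
                      type = character(0), partner = character(0),
                      resname = character(0), resnum = integer(0),
                      chain = character(0), pclass = character(0),
                      distance = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  out[order(out$label, out$partner), ]
}
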