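# Independent reference implementations used as oracles. These are kept
# deliberately naive (nested loops, dense grids) and separate from the
# package's computation paths.

# Direct per-frame RMSD formula (no prefit).
oracle_rmsd <- function(traj, serials, reference_frame = 0) {
  idx <- match(serials, atoms(traj)$serial)
  ref <- frameCoords(traj, reference_frame)[idx, , drop = FALSE]
  sapply(seq_len(nFrames(traj)) - 1L, function(f) {
    x <- frameCoords(traj, f)[idx, , drop = FALSE]
    s <- 0
    for (i in seq_len(nrow(x))) s <- s + sum((x[i, ] - ref[i, ])^2)
    sqrt(s / nrow(x))
  })
}

# Direct per-atom RMSF formula (no prefit).
oracle_rmsf <- function(traj, serials) {
  idx <- match(serials, atoms(traj)$serial)
  nf <- nFrames(traj)
  sapply(idx, function(i) {
    xs <- t(sapply(seq_len(nf) - 1L, function(f) frameCoords(traj, f)[i, ]))
    mu <- colMeans(xs)
    sqrt(mean(rowSums(sweep(xs, 2, mu)^2)))
  })
}

# Hierarchically refined dense rotation-grid search for the minimal
# RMSD of mobile onto reference (proper rotations; optimal translation
# via centroids at every grid point).
oracle_grid_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  rot_zyz <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_r <- function(a, b, c) {
    R <- rot_zyz(a, b, c)
    sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
  }
  best <- c(0, 0, 0); best_v <- Inf
  sweep_grid <- function(as, bs, cs) {
    for (a in as) for (b in bs) for (c in cs) {
      v <- eval_r(a, b, c)
      if (v < best_v) { best_v <<- v; best <<- c(a, b, c) }
    }
  }
  d2r <- pi / 180
  sweep_grid(seq(0, 350, 10) * d2r, seq(0, 180, 10) * d2r,
             seq(0, 350, 10) * d2r)
  for (step in c(2, 0.4, 0.08, 0.016)) {
    ctr <- best
    sweep_grid(ctr[1] + seq(-5, 5) * step * d2r,
               ctr[2] + seq(-5, 5) * step * d2r,
               ctr[3] + seq(-5, 5) * step * d2r)
  }
  best_v
}

# All-pairs brute-force interaction scan, written directly from the
# geometric criteria (independent of the package's detection code).
# Returns a sorted "type|label|partner|distance" event multiset string.
oracle_events <- function(top, xyz, templates, partners, crit,
                          include_water = FALSE) {
  a <- atoms(top)
  row_of <- function(s) match(s, a$serial)
  pos <- function(s) {
    m <- xyz[row_of(s), , drop = FALSE]
    if (nrow(m) == 1) m[1, ] else colMeans(m)
  }
  dist3 <- function(p, q) sqrt(sum((p - q)^2))
  ang <- function(p, v, q) {
    v1 <- p - v; v2 <- q - v
    acos(max(-1, min(1, sum(v1 * v2) /
                       sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  adj <- local({
    b <- bonds(top)
    if (nrow(b) == 0) list() else
      split(c(b[, 2], b[, 1]), factor(c(b[, 1], b[, 2])))
  })
  nbrs <- function(s) { n <- adj[[as.character(s)]]; if (is.null(n)) integer(0) else n }
  el <- function(s) a$element[row_of(s)]
  chg <- function(s) a$charge[row_of(s)]

  # per-residue environment sites, re-derived with simple loops
  res_sites <- lapply(seq_len(nrow(partners)), function(p) {
    ss <- partners$serials[[p]]
    don <- list(); acc <- integer(0); posg <- list(); negg <- list()
    hyd <- integer(0)
    in_pos <- integer(0); in_neg <- integer(0); bor_o <- integer(0)
    for (s in ss) {
      e <- el(s); nn <- nbrs(s)
      ne <- vapply(nn, el, character(1))
      if (e == "B" && sum(ne == "O") >= 3) {
        os <- nn[ne == "O"]
        negg[[length(negg) + 1]] <- list(s = c(s, os), metal = FALSE)
        in_neg <- c(in_neg, s, os); bor_o <- c(bor_o, os)
        acc <- c(acc, s)
      }
      if (e == "C" && length(nn[ne == "N"]) == 3) {
        posg[[length(posg) + 1]] <- list(s = c(s, nn[ne == "N"]),
                                         metal = FALSE)
        in_pos <- c(in_pos, s, nn[ne == "N"])
      }
      if (e %in% c("C", "S", "P")) {
        to <- nn[ne == "O"]
        to <- to[vapply(to, function(o) {
          on <- vapply(nbrs(o), el, character(1))
          sum(on != "H") == 1 && !any(on == "H")
        }, logical(1))]
        need <- c(C = 2, S = 3, P = 2)[[e]]
        if (length(to) >= need) {
          negg[[length(negg) + 1]] <- list(s = sort(to), metal = FALSE)
          in_neg <- c(in_neg, to)
        }
      }
      if (e %in% c("MN", "ZN", "MG", "CA", "FE", "NA", "K")) {
        posg[[length(posg) + 1]] <- list(s = s, metal = TRUE)
        in_pos <- c(in_pos, s)
      }
    }
    for (s in ss) {
      e <- el(s); nn <- nbrs(s)
      ne <- vapply(nn, el, character(1))
      if (e == "O" && chg(s) < 0 && length(ne) && all(ne == "H") &&
          !(s %in% in_neg)) {
        negg[[length(negg) + 1]] <- list(s = s, metal = FALSE)
        in_neg <- c(in_neg, s)
      }
    }
    for (s in ss) {
      e <- el(s); nn <- nbrs(s)
      ne <- vapply(nn, el, character(1))
      if (e %in% c("O", "N")) {
        hs <- nn[ne == "H"]
        if (length(hs)) don[[length(don) + 1]] <- list(d = s, h = hs)
        if (e == "N" && !(s %in% in_pos) &&
            (chg(s) > 0 || length(nn) >= 4)) {
          posg[[length(posg) + 1]] <- list(s = s, metal = FALSE)
          in_pos <- c(in_pos, s)
        }
        okpos <- (s %in% in_pos) || chg(s) > 0
        if (e == "O" && !okpos && !(s %in% bor_o)) acc <- c(acc, s)
        if (e == "N" && !okpos && length(nn) <= 3) acc <- c(acc, s)
      }
      if (e %in% c("C", "S") && length(ne) && all(ne %in% c("C", "H", "S")))
        hyd <- c(hyd, s)
    }
    list(don = don, acc = acc, posg = posg, negg = negg, hyd = hyd)
  })

  out <- character(0)
  for (ti in seq_along(templates)) {
    t <- templates[[ti]]
    for (p in seq_len(nrow(partners))) {
      if (!include_water && partners$pclass[p] == "water") next
      st <- res_sites[[p]]
      best <- Inf
      if (t@type == "HBD") {
        D <- pos(t@atoms[1])
        for (acp in st$acc) {
          d <- dist3(D, pos(acp))
          if (d < crit@hbondDistMin || d > crit@hbondDistMax) next
          okang <- length(t@hydrogens) == 0
          for (h in t@hydrogens)
            if (ang(D, pos(h), pos(acp)) >= crit@hbondAngleMin) okang <- TRUE
          if (okang) best <- min(best, d)
        }
      } else if (t@type == "HBA") {
        A <- pos(t@atoms[1])
        for (dn in st$don) {
          d <- dist3(pos(dn$d), A)
          if (d < crit@hbondDistMin || d > crit@hbondDistMax) next
          okang <- FALSE
          for (h in dn$h)
            if (ang(pos(dn$d), pos(h), A) >= crit@hbondAngleMin) okang <- TRUE
          if (okang) best <- min(best, d)
        }
      } else if (t@type %in% c("PI", "NI")) {
        gs <- if (t@type == "PI") st$negg else st$posg
        ctr <- pos(t@atoms)
        for (g in gs) {
          cutoff <- if (isTRUE(g$metal)) crit@metalCoordMax
                    else crit@ionicDistMax
          d <- dist3(ctr, pos(g$s))
          if (d <= cutoff) best <- min(best, d)
        }
      } else if (t@type == "H") {
        for (cl in t@atoms) for (cp in st$hyd) {
          d <- dist3(pos(cl), pos(cp))
          if (d <= crit@hydrophobDistMax) best <- min(best, d)
        }
      }
      if (is.finite(best))
        out <- c(out, sprintf("%s|%s|%s|%.9f", t@type, t@label,
                              partners$key[p], best))
    }
  }
  sort(out)
}

# Package events -> comparable multiset string.
event_multiset <- function(ev) {
  if (nrow(ev) == 0) return(character(0))
  sort(sprintf("%s|%s|%s|%.9f", ev$type, ev$label, ev$partner, ev$distance))
}

# Dense fine-grid pocket volume (naive full enumeration).
oracle_volume <- function(center, radius, spacing, occ_xyz, occ_r) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- rowSums(pts^2) <= radius^2
  pts <- pts[keep, , drop = FALSE]
  free <- rep(TRUE, nrow(pts))
  if (length(occ_r)) {
    for (k in seq_along(occ_r)) {
      rel <- sweep(pts, 2, occ_xyz[k, ] - center)
      free <- free & rowSums(rel^2) > occ_r[k]^2
    }
  }
  sum(free) * spacing^3
}

# Naive loop binning for histogram checks.
oracle_bins <- function(x, edges) {
  counts <- integer(length(edges) - 1)
  for (v in x) {
    for (b in seq_len(length(counts))) {
      lo <- edges[b]; hi <- edges[b + 1]
      last <- b == length(counts)
      if (v >= lo && (v < hi || (last && v <= hi))) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# A random-coordinate trajectory over the toy topology (seeded).
random_frames_traj <- function(n_frames, seed = 1, ligand = "amino",
                               box = 16) {
  spec <- toySpec(1, ligand = ligand,
                  schedules = list(), seed = 1L)
  toy <- generateToyTrajectory(spec, verify = FALSE)
  top <- toy$topology
  set.seed(seed)
  nat <- nAtoms(top)
  coords <- array(stats::runif(nat * 3 * n_frames, -box / 2, box / 2),
                  dim = c(nat, 3, n_frames))
  makeTrajectory(top, coords)
}
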