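#' Read a molecular topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), CONECT records, and PDB formal
#' charge columns into a [Topology-class]. When the file carries no CONECT
#' records, bonds are inferred from the first model by an element-pair
#' distance rule: two atoms are bonded when their distance is below
#' `bond_factor` times the sum of their covalent radii. Bonds involving
#' metal atoms are never inferred (metal coordination is treated as a
#' non-covalent interaction downstream); explicit CONECT records always
#' win over inference.
#'
#' Missing element symbols are derived from atom-name first letters per
#' PDB v3 rules. Residue numbers are kept verbatim from the input.
#'
#' @param path path to a PDB file with explicit hydrogens.
#' @param format input format; only `"pdb"` is supported.
#' @param bond_factor multiplier on the covalent-radius sum used by bond
#'   inference (default 1.6).
#' @return a [Topology-class]
#' @examples
#' pdb <- generateVolumePhantom(file.path(tempdir(), "phantom.pdb"))
#' top <- readTopology(pdb)
#' nAtoms(top)
#' @export
readTopology <- function(path, format = "pdb", bond_factor = 1.6) {
  format <- match.arg(tolower(format), "pdb")
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .checkPdbRecords(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                                          hex = TRUE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atoms in PDB file: ", path)
  if (anyDuplicated(a$eleno))
    stop("parse error: duplicate atom serial ", a$eleno[duplicated(a$eleno)][1],
         " in ", path)
  element <- trimws(ifelse(is.na(a$elesy) | a$elesy == "", NA, a$elesy))
  miss <- is.na(element) | !nzchar(element)
  if (any(miss)) element[miss] <- .elementFromName(a$elety[miss])
  element <- toupper(element)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = element,
    resname = trimws(a$resid),
    resnum = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    charge = .parseCharge(a$charge),
    het = a$type == "HETATM",
    vdw = vdwRadius(element),
    stringsAsFactors = FALSE
  )
  bonds <- .parseConect(lines, atoms$serial)
  if (is.null(bonds)) {
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
    bonds <- .inferBonds(atoms, xyz, bond_factor)
  }
  new("Topology", atoms = atoms, bonds = bonds)
}

# Reject structurally broken ATOM/HETATM records early, naming the line.
.checkPdbRecords <- function(lines, path) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error at line ", i, " of ", path, ": record too short")
    co <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                        substr(ln, 47, 54))))
    if (any(is.na(co)))
      stop("parse error at line ", i, " of ", path,
           ": unreadable coordinates")
  }
  invisible(TRUE)
}

# CONECT records -> 2-column bond matrix (or NULL when absent).
.parseConect <- function(lines, serials) {
  con <- grep("^CONECT", lines, value = TRUE)
  if (length(con) == 0) return(NULL)
  pairs <- list()
  for (ln in con) {
    body <- substring(ln, 7)
    starts <- seq(1, nchar(body), by = 5)
    fields <- trimws(substring(body, starts, pmin(starts + 4, nchar(body))))
    nums <- suppressWarnings(as.integer(fields[nzchar(fields)]))
    nums <- nums[!is.na(nums)]
    if (length(nums) >= 2) {
      from <- nums[1]
      for (to in nums[-1]) {
        if (from != to)
          pairs[[length(pairs) + 1]] <- c(min(from, to), max(from, to))
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  b <- unique(do.call(rbind, pairs))
  b <- b[b[, 1] %in% serials & b[, 2] %in% serials, , drop = FALSE]
  storage.mode(b) <- "integer"
  b
}

# Distance-rule bond inference on one coordinate set. Chunked O(n^2).
.inferBonds <- function(atoms, xyz, bond_factor) {
  n <- nrow(atoms)
  rc <- covalentRadius(atoms$element)
  rc[is.na(rc)] <- 0.77
  metal <- atoms$element %in% .METAL_ELEMENTS
  out <- list()
  chunk <- 2000L
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- .crossDist2(xyz[lo:hi, , drop = FALSE], xyz)
    cut <- outer(rc[lo:hi], rc, "+") * bond_factor
    hit <- which(d2 < cut^2 & d2 > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- hit[, 1] + lo - 1L
      j <- hit[, 2]
      keep <- i < j & !metal[i] & !metal[j]
      if (any(keep))
        out[[length(out) + 1]] <- cbind(atoms$serial[i[keep]],
                                        atoms$serial[j[keep]])
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  b <- unique(do.call(rbind, out))
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  storage.mode(b) <- "integer"
  b
}

#' Read a coordinate trajectory over an existing topology
#'
#' Supports multi-model PDB (each MODEL block one frame; a file without
#' MODEL records yields a one-frame trajectory) and binary DCD (via
#' bio3d). Every frame must carry exactly one coordinate triple per
#' topology atom; a mismatch raises an error naming the offending
#' (0-based) frame.
#'
#' @param topology a [Topology-class]
#' @param path trajectory file
#' @param format `"pdb"` or `"dcd"`
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(topology, path, format = c("pdb", "dcd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  nat <- nAtoms(topology)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    counts <- .modelAtomCounts(lines)
    bad <- which(counts != nat)
    if (length(bad))
      stop("shape error: frame ", bad[1] - 1, " has ", counts[bad[1]],
           " atoms, topology has ", nat)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                                            hex = TRUE))
    xyz <- pdb$xyz
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    if (ncol(xyz) != 3 * nat)
      stop("shape error: DCD frame has ", ncol(xyz) / 3,
           " atoms, topology has ", nat)
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nat, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new("Trajectory", topology = topology, coords = coords,
      times = rep(NA_real_, nf))
}

.modelAtomCounts <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_at <- grep("^MODEL", lines)
  if (length(model_at) == 0) return(sum(is_atom))
  endml <- grep("^ENDMDL", lines)
  if (length(endml) < length(model_at)) endml <- c(endml, length(lines))
  vapply(seq_along(model_at), function(k) {
    sum(is_atom[model_at[k]:endml[k]])
  }, integer(1))
}

#' Build a trajectory from in-memory coordinates
#'
#' @param topology a [Topology-class]
#' @param coords array `n_atoms x 3 x n_frames` or a single `n_atoms x 3`
#'   matrix (one frame)
#' @param times optional per-frame times (ps)
#' @return a [Trajectory-class]
#' @export
makeTrajectory <- function(topology, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  nf <- dim(coords)[3]
  if (is.null(times)) times <- rep(NA_real_, nf)
  new("Trajectory", topology = topology, coords = coords, times = times)
}

#' Resolve an atom selection expression against a topology
#'
#' A deterministic mini-language; clauses joined by `and` intersect:
#' \describe{
#'   \item{`all`}{every atom}
#'   \item{`calpha`}{atoms named CA in standard amino-acid residues}
#'   \item{`protein`}{standard amino-acid residues}
#'   \item{`ligand`}{HETATM residues that are not water, metal ions or
#'     hydroxide}
#'   \item{`water`}{water residues (HOH/WAT/...)}
#'   \item{`resname X [Y ...]`}{by residue name}
#'   \item{`resnum A-B` / `resnum A B ...`}{residue number (inclusive
#'     1-based range, verbatim PDB numbering)}
#'   \item{`name N [...]`}{by atom name}
#'   \item{`element E [...]`}{by element symbol}
#'   \item{`chain C`}{by chain identifier}
#'   \item{`serial A-B` / list}{by atom serial}
#' }
#'
#' @param topology a [Topology-class]
#' @param expression selection string, e.g. `"resname ABH"`,
#'   `"calpha and chain A"`, `"resnum 130-139"`.
#' @return integer vector of atom serials in topology order, with the
#'   expression attached as attribute `"expression"`. An empty result
#'   warns but is not an error.
#' @export
resolveSelection <- function(topology, expression) {
  a <- atoms(topology)
  expr <- trimws(expression)
  if (!nzchar(expr)) stop("selection parse error: empty expression")
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(a))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- tolower(toks[1])
    args <- toks[-1]
    m <- switch(key,
      all = rep(TRUE, nrow(a)),
      calpha = a$name == "CA" & a$resname %in% .STANDARD_AA,
      protein = a$resname %in% .STANDARD_AA,
      ligand = a$het & !(a$resname %in% .WATER_RESNAMES) &
        !(a$resname %in% .HYDROXIDE_RESNAMES) &
        !(a$element %in% .METAL_ELEMENTS),
      water = a$resname %in% .WATER_RESNAMES,
      resname = a$resname %in% toupper(args),
      name = a$name %in% args,
      element = a$element %in% toupper(args),
      chain = a$chain %in% args,
      resnum = a$resnum %in% .expandRange(args, cl),
      serial = a$serial %in% .expandRange(args, cl),
      stop("selection parse error: unknown keyword '", key, "' in '", cl, "'")
    )
    if (key %in% c("resname", "name", "element", "chain", "resnum", "serial") &&
        length(args) == 0)
      stop("selection parse error: '", key, "' needs arguments")
    keep <- keep & m
  }
  out <- a$serial[keep]
  if (length(out) == 0)
    warning("selection '", expression, "' matched no atoms")
  attr(out, "expression") <- expression
  out
}

.expandRange <- function(args, clause) {
  out <- integer(0)
  for (tok in args) {
    if (grepl("^-?[0-9]+--?[0-9]+$", tok)) {
      parts <- regmatches(tok, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tok))[[1]]
      out <- c(out, seq(as.integer(parts[2]), as.integer(parts[3])))
    } else if (grepl("^-?[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else {
      stop("selection parse error: bad number/range '", tok, "' in '",
           clause, "'")
    }
  }
  out
}

# Map a selection argument (expression string, serial vector, or NULL)
# to serials.
.resolveSel <- function(topology, sel) {
  if (is.character(sel)) resolveSelection(topology, sel)
  else as.integer(sel)
}

# Row indices into the atom table for a serial vector.
.serialIndex <- function(topology, serials) {
  match(serials, atoms(topology)$serial)
}

#' Write a point cloud as a pseudo-atom PDB
#'
#' One HETATM per point. The residue name encodes the feature type
#' (`HBD`, `HBA`, `PI`, `NI`, `HYD`) and the B-factor column carries the
#' frame index modulo 1000 (the widest value the fixed-width column
#' holds). Serial and residue numbers wrap per PDB fixed-width
#' convention, so arbitrarily large clouds remain parseable.
#'
#' @param points numeric matrix `n x 3` (Angstrom)
#' @param labels feature-type label recycled over points (one of the
#'   feature types, or any string; the first 3 characters are used)
#' @param path output file
#' @param frames optional 0-based frame index per point (default 0)
#' @return the path, invisibly
#' @export
writePseudoatomPdb <- function(points, labels = "HBD", path, frames = NULL) {
  points <- as.matrix(points)
  n <- if (length(points)) nrow(points) else 0L
  if (is.null(frames)) frames <- rep(0L, n)
  resmap <- c(HBD = "HBD", HBA = "HBA", PI = "PI", NI = "NI", H = "HYD")
  labels <- rep_len(as.character(labels), max(n, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   dynophore pseudo-atom point cloud", con)
  if (n > 0) {
    res <- ifelse(labels %in% names(resmap), resmap[labels],
                  substr(labels, 1, 3))
    for (i in seq_len(n)) {
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        (i - 1L) %% 99999L + 1L, "PSD", res[i], "P", (i - 1L) %% 9999L + 1L,
        points[i, 1], points[i, 2], points[i, 3], 1.00,
        frames[i] %% 1000L, "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory (or topology) as a PDB file
#'
#' Multi-model output with CONECT records, re-readable by
#' [readTopology()] / [readTrajectory()]. Formal charges are written in
#' the PDB charge columns (`1-` style). Output is byte-deterministic for
#' identical input.
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @param conect write CONECT records (default TRUE)
#' @return the path, invisibly
#' @export
writeTrajectoryPdb <- function(traj, path, conect = TRUE) {
  a <- atoms(traj)
  nf <- nFrames(traj)
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  chg <- ifelse(a$charge == 0, "  ",
                paste0(abs(a$charge), ifelse(a$charge > 0, "+", "-")))
  name4 <- ifelse(nchar(a$element) >= 2 | nchar(a$name) >= 4,
                  sprintf("%-4s", a$name), sprintf(" %-3s", a$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , f, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    writeLines(sprintf(
      "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%s",
      rec, a$serial %% 99999L, name4, a$resname, a$chain, a$resnum %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00,
      sprintf("%2s", a$element), chg), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  if (conect && nrow(bonds(traj)) > 0) {
    b <- bonds(traj)
    for (s in sort(unique(b[, 1]))) {
      to <- sort(b[b[, 1] == s, 2])
      for (lo in seq(1, length(to), by = 4)) {
        grp <- to[lo:min(lo + 3, length(to))]
        writeLines(paste0("CONECT",
                          paste0(sprintf("%5d", c(s, grp)), collapse = "")),
                   con)
      }
    }
  }
  writeLines("END", con)
  invisible(path)
}
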