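# Element property tables used for bond inference, occlusion radii and
# atom typing. Covalent radii after Cordero et al.; van der Waals radii
# after Bondi/Mantina. Values in Angstrom.

.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA_ = 1.66, MG = 1.41, P = 1.07, S = 1.05, CL = 1.02,
  K = 2.03, CA = 1.76, MN = 1.39, FE = 1.32, ZN = 1.22, BR = 1.20, I = 1.39
)

.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  NA_ = 2.27, MG = 1.73, P = 1.80, S = 1.80, CL = 1.75,
  K = 2.75, CA = 2.31, MN = 2.05, FE = 2.04, ZN = 2.10, BR = 1.85, I = 1.98
)

.METAL_ELEMENTS <- c("MN", "ZN", "MG", "CA", "FE", "NA", "K")

.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

.WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "T3P")
.HYDROXIDE_RESNAMES <- c("OH", "HO", "OXH")

.elementKey <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  key
}

#' Look up covalent radii by element symbol
#' @param element character vector of element symbols
#' @return numeric vector in Angstrom; `NA` for unknown elements
#' @keywords internal
covalentRadius <- function(element) {
  unname(.COVALENT_RADII[.elementKey(element)])
}

#' Look up van der Waals radii by element symbol
#' @param element character vector of element symbols
#' @return numeric vector in Angstrom; 1.7 (carbon-like) for unknown elements
#' @keywords internal
vdwRadius <- function(element) {
  r <- unname(.VDW_RADII[.elementKey(element)])
  r[is.na(r)] <- 1.70
  r
}

# Derive an element symbol from a PDB v3 atom name when the element
# column is absent: first alphabetic character, except recognised
# two-letter element names occupying columns 13-14.
.elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- character(length(nm))
  known2 <- c("MN", "ZN", "MG", "FE", "CL", "BR", "NA", "CA")
  for (i in seq_along(nm)) {
    if (two[i] %in% known2 && !grepl("^C[ABGDEZ0-9]", nm[i]) &&
        !grepl("^N[ABGDEZH0-9]", nm[i])) {
      out[i] <- two[i]
    } else {
      out[i] <- sub("^[0-9]*", "", nm[i])
      out[i] <- substr(out[i], 1, 1)
    }
  }
  out
}

# Parse PDB charge strings: "1-", "-1", "2+", "+2", "" -> integer.
.parseCharge <- function(charge) {
  ch <- trimws(as.character(charge))
  ch[is.na(ch) | ch == ""] <- "0"
  sign <- ifelse(grepl("-", ch), -1L, 1L)
  mag <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
  mag[is.na(mag)] <- 0L
  sign * mag
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Pairwise squared distances between two coordinate matrices (n x 3, m x 3).
.crossDist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Angle at vertex `b` of the triangle a-b-c, in degrees.
.angleDeg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}
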