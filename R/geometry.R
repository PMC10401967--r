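# Geometric primitives: distances, torsions, Ramachandran-region and chi1
# binning, Kabsch superposition, RMSD. All angles are degrees wrapped to
# (-180, 180]; all distances are angstroms.

#' Euclidean distance between two points
#' @param a,b Numeric 3-vectors.
#' @return Distance in angstroms.
#' @export
vec_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

# wrap degrees to (-180, 180]
.wrap180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  # x %% 360 gives [0, 360); map 180 stays 180, -180 -> 180
  y
}

#' Signed torsion angle of four points
#'
#' Standard IUPAC convention: cis = 0, trans = +/-180, right-handed rotation
#' positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-9) stop("degenerate torsion: p2 == p3")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("degenerate torsion: collinear bonded triple")
  }
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  .wrap180(ang)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default Ramachandran-region and chi1-bin boundaries
#'
#' Rectangular partition of the (phi, psi) torus into the beta (`B`),
#' alpha (`A`), left-handed (`L`) regions and a catch-all `E` region, plus
#' the chi1 rotamer bin edges. All intervals are half-open `[lo, hi)` so
#' every grid point receives exactly one label. The rectangles capture the
#' standard basins; users replicating a specific published labelling scheme
#' should substitute that scheme's boundaries via `region_config`.
#'
#' @return List with elements `B`, `A`, `L` (each a list of `phi` and `psi`
#'   interval specs) and `chi1_edges`.
#' @export
default_region_config <- function() {
  list(
    # B: phi in [-180, 0) and (psi >= 50 or psi < -120)
    B = list(phi = c(-180, 0), psi_hi = 50, psi_lo = -120),
    # A: phi in [-180, 0) and psi in [-120, 50)
    A = list(phi = c(-180, 0), psi = c(-120, 50)),
    # L: phi in [0, 180] and psi in [-50, 100)
    L = list(phi = c(0, 180), psi = c(-50, 100)),
    chi1_edges = c(-120, 0, 120)
  )
}

#' Load region/rotamer boundaries from a JSON config file
#' @param path JSON file mirroring [default_region_config()].
#' @return Config list.
#' @export
read_region_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_region_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Ramachandran region of a (phi, psi) point
#'
#' Total function: every finite (phi, psi) pair receives exactly one of
#' `"B"`, `"A"`, `"L"`, `"E"`.
#'
#' @param phi,psi Backbone dihedrals in degrees.
#' @param config Region boundaries, see [default_region_config()].
#' @return Single character label.
#' @export
rama_region <- function(phi, psi, config = default_region_config()) {
  stopifnot(is.finite(phi), is.finite(psi))
  phi <- .wrap180(phi)
  psi <- .wrap180(psi)
  if (phi >= config$B$phi[1] && phi < config$B$phi[2] &&
      (psi >= config$B$psi_hi || psi < config$B$psi_lo)) {
    return("B")
  }
  if (phi >= config$A$phi[1] && phi < config$A$phi[2] &&
      psi >= config$A$psi[1] && psi < config$A$psi[2]) {
    return("A")
  }
  if (phi >= config$L$phi[1] && phi <= config$L$phi[2] &&
      psi >= config$L$psi[1] && psi < config$L$psi[2]) {
    return("L")
  }
  "E"
}

#' chi1 rotamer bin
#'
#' Gauche-minus (`"minus"`, the ~-60 degree well), gauche-plus (`"plus"`,
#' ~+60) and `"trans"` (~180), with standard staggered-well edges at
#' -120/0/120 degrees (half-open intervals).
#'
#' @param chi1 Side-chain chi1 dihedral, degrees.
#' @param edges Bin edges `c(minus_lo, minus_hi, plus_hi)`.
#' @return `"minus"`, `"plus"` or `"trans"`.
#' @export
chi1_rotamer <- function(chi1, edges = default_region_config()$chi1_edges) {
  stopifnot(is.finite(chi1))
  x <- .wrap180(chi1)
  if (x >= edges[1] && x < edges[2]) return("minus")
  if (x >= edges[2] && x < edges[3]) return("plus")
  "trans"
}

# gamma atom used as the fourth chi1 atom, per residue type
.chi1_gamma_atom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", GLN = "CG", GLU = "CG", HIS = "CG",
  LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG", PRO = "CG", TRP = "CG",
  TYR = "CG", ILE = "CG1", VAL = "CG1", THR = "OG1", SER = "OG", CYS = "SG"
)

#' chi1 dihedral of a residue
#'
#' Computed over N-CA-CB-G where G is the residue type's standard gamma
#' atom (CG; CG1 for Ile/Val; OG1 Thr; OG Ser; SG Cys). Returns `NA` when
#' any of the four atoms is absent (e.g. Gly/Ala).
#'
#' @param chain A `kin_chain`.
#' @param ordinal 0-based residue ordinal.
#' @return chi1 in degrees, or `NA_real_`.
#' @export
residue_chi1 <- function(chain, ordinal) {
  aa3 <- chain$residues$aa3[match(ordinal, chain$residues$ordinal)]
  gamma <- unname(.chi1_gamma_atom[aa3])
  if (is.na(gamma)) return(NA_real_)
  ats <- lapply(c("N", "CA", "CB", gamma), function(nm)
    get_atom(chain, ordinal, nm))
  if (any(vapply(ats, is.null, logical(1)))) return(NA_real_)
  dihedral_angle(ats[[1]]$xyz, ats[[2]]$xyz, ats[[3]]$xyz, ats[[4]]$xyz)
}

#' Backbone phi/psi dihedrals of a residue
#'
#' phi uses C of the preceding residue (by ordinal), psi the N of the
#' following residue; either is `NA` when the neighbour or any backbone
#' atom is missing.
#'
#' @param chain A `kin_chain`.
#' @param ordinal 0-based residue ordinal.
#' @return Named numeric vector `c(phi=, psi=)` (degrees, possibly `NA`).
#' @export
residue_phi_psi <- function(chain, ordinal) {
  g <- function(o, nm) {
    a <- get_atom(chain, o, nm)
    if (is.null(a)) NULL else a$xyz
  }
  n <- g(ordinal, "N"); ca <- g(ordinal, "CA"); cc <- g(ordinal, "C")
  cp <- g(ordinal - 1L, "C"); nn <- g(ordinal + 1L, "N")
  phi <- if (!is.null(cp) && !is.null(n) && !is.null(ca) && !is.null(cc))
    dihedral_angle(cp, n, ca, cc) else NA_real_
  psi <- if (!is.null(n) && !is.null(ca) && !is.null(cc) && !is.null(nn))
    dihedral_angle(n, ca, cc, nn) else NA_real_
  c(phi = phi, psi = psi)
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation minimising the RMSD of `mobile`
#' onto `reference`, via SVD with determinant correction so reflections are
#' excluded.
#'
#' @param mobile,reference Numeric n-by-3 matrices (n >= 3, non-collinear).
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% t(rotation) + translation`), and `rmsd` over the
#'   fitted points.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("Kabsch superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (max(svd(A)$d) < 1e-9 || svd(A)$d[2] < 1e-12) {
    stop("degenerate (collinear) point configuration")
  }
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords n-by-3 matrix.
#' @param transform List with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return Transformed n-by-3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' RMSD without refitting
#' @param a,b Numeric n-by-3 matrices in a common frame.
#' @return Root-mean-square per-point distance.
#' @export
rmsd_no_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3) {
    stop("rmsd_no_fit: coordinate sets must be equal-size n-by-3 matrices")
  }
  if (nrow(a) < 1) stop("rmsd_no_fit: need at least one point")
  sqrt(mean(rowSums((a - b)^2)))
}
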