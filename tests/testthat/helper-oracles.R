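# Independent oracles and small text fixtures used across the test files.

# Quaternion (Theobald characteristic-polynomial style) minimum RMSD:
# independent of the SVD-based Kabsch implementation under test.
quaternion_min_rmsd <- function(mobile, reference) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(reference), 2, colMeans(reference))
  n <- nrow(A)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# random proper rotation + translation
random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, 0, 20))
}

# apply a rigid transform to every atom of a kin_structure
transform_structure <- function(struct, tr) {
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(tr$rotation), 2, tr$translation, `+`)
  struct$atoms$x <- xyz[, 1]
  struct$atoms$y <- xyz[, 2]
  struct$atoms$z <- xyz[, 3]
  struct
}

# Independent two-stage fit-then-measure using bio3d::fit.xyz: superpose
# model CTD CA onto reference CTD CA, then plain RMSD over loop backbone.
bio3d_two_stage_rmsd <- function(model_chain, ref_chain, map) {
  get_xyz <- function(chain, ords, atoms) {
    out <- c()
    for (o in ords) for (nm in atoms) {
      a <- get_atom(chain, o, nm)
      out <- c(out, a$xyz)
    }
    out
  }
  m_ctd <- get_xyz(model_chain, map$ctd$model_ord, "CA")
  r_ctd <- get_xyz(ref_chain, map$ctd$ref_ord, "CA")
  m_loop <- get_xyz(model_chain, map$loop$model_ord, c("N", "CA", "C", "O"))
  r_loop <- get_xyz(ref_chain, map$loop$ref_ord, c("N", "CA", "C", "O"))
  m_all <- c(m_ctd, m_loop)
  fitted <- bio3d::fit.xyz(fixed = c(r_ctd, r_loop), mobile = m_all,
                           fixed.inds = seq_along(r_ctd),
                           mobile.inds = seq_along(m_ctd))
  loop_fit <- matrix(fitted[(length(m_ctd) + 1):length(m_all)],
                     ncol = 3, byrow = TRUE)
  loop_ref <- matrix(r_loop, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((loop_fit - loop_ref)^2)))
}

# ---- small text fixtures -------------------------------------------------

mini_pdb_lines <- function() {
  c(
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 21.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.167  -4.943  1.00 22.00           C",
    "ATOM      4  O   ALA A   1      13.600   7.300  -5.760  1.00 23.00           O",
    "ATOM      5  CA  LYS A   2      14.000   7.000  -4.000  1.00 26.00           C",
    "ATOM      6  CB ALYS A   2      10.547   6.200  -4.098  0.60 24.00           C",
    "ATOM      7  CB BLYS A   2      10.647   6.300  -4.198  0.40 25.00           C",
    "ATOM      8  NZ  LYS A   2      14.500   7.500  -3.500  1.00 26.00           N",
    "ATOM      9  CA  GLY A   3      15.000   8.000  -3.000  1.00 27.00           C",
    "END"
  )
}

mini_cif_lines <- function() {
  c(
    "data_mini",
    "#",
    "_refine.ls_d_res_high 1.80",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 20.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 21.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 12.685 7.167 -4.943 1.00 22.00 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 13.600 7.300 -5.760 1.00 23.00 1 ALA A O 1",
    "ATOM 5 C CA . LYS A 1 2 ? 14.000 7.000 -4.000 1.00 26.00 2 LYS A CA 1",
    "ATOM 6 C CB A LYS A 1 2 ? 10.547 6.200 -4.098 0.60 24.00 2 LYS A CB 1",
    "ATOM 7 C CB B LYS A 1 2 ? 10.647 6.300 -4.198 0.40 25.00 2 LYS A CB 1",
    "ATOM 8 N NZ . LYS A 1 2 ? 14.500 7.500 -3.500 1.00 26.00 2 LYS A NZ 1",
    "ATOM 9 C CA . GLY A 1 3 ? 15.000 8.000 -3.000 1.00 27.00 3 GLY A CA 1",
    "#"
  )
}

write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(mini_pdb_lines(), path)
  path
}

write_mini_cif <- function(path = tempfile(fileext = ".cif")) {
  writeLines(mini_cif_lines(), path)
  path
}

# fixture spec variants spanning the in/out regimes of every criterion;
# intent is recorded alongside so tests can check each criterion state
random_regime_spec <- function() {
  regime <- function(p_in = 0.5) stats::runif(1) < p_in
  sb_in <- regime(); nt_in <- regime(); ct_in <- regime()
  spat <- sample(c("DFGin", "DFGout", "DFGinter"), 1)
  chi <- sample(c("minus", "plus", "trans"), 1)
  dl <- if (regime(0.6)) c(-120, 130, 60, 45, -60, -45)  # B, L, A
        else c(-60, -45, -120, 130, 60, 45)              # A, B, L
  anchors <- switch(spat,
    DFGin = c(stats::runif(1, 11.5, 16), stats::runif(1, 6, 10.5)),
    DFGout = c(stats::runif(1, 6, 10.5), stats::runif(1, 11.5, 16)),
    DFGinter = c(stats::runif(1, 6, 10.5), stats::runif(1, 6, 10.5))
  )
  spec <- default_fixture_spec(
    d_saltbridge = if (sb_in) stats::runif(1, 2.6, 3.5)
                   else stats::runif(1, 3.7, 12),
    d_actloop_nt = if (nt_in) stats::runif(1, 2.6, 3.5)
                   else stats::runif(1, 3.7, 12),
    d_actloop_ct = if (ct_in) stats::runif(1, 3.0, 5.9)
                   else stats::runif(1, 6.1, 14),
    d_phe_lys = anchors[1], d_phe_glu4 = anchors[2],
    xdfg_phi_psi = rbind(x = dl[1:2], d = dl[3:4], f = dl[5:6]),
    phe_chi1 = switch(chi, minus = -60, plus = 60, trans = 180),
    spine = stats::runif(3, 3.5, 4.8)
  )
  list(
    spec = spec,
    expect = list(
      saltbridge = if (sb_in) "in" else "out",
      actloop_nt = if (nt_in) "in" else "out",
      actloop_ct = if (ct_in) "in" else "out",
      spatial = spat,
      dihedral = paste0(if (identical(dl[1], -120)) "BLA" else "ABL", chi),
      active = (sb_in && nt_in && ct_in && spat == "DFGin" &&
                  identical(dl[1], -120) && chi == "minus")
    )
  )
}
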