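# Active-state classification of one annotated kinase chain.
#
# Five criteria make the Active verdict: DFGin spatial state, BLAminus
# dihedral state, salt bridge in, ActLoopNT in, ActLoopCT in (the last two
# place the activation loop for substrate binding). The regulatory spine is
# measured and reported but never gates the verdict. Missing atoms make a
# criterion "unevaluable", never "out": disorder is not evidence of an
# inactive state.

#' Default distance cutoffs for the active-state criteria
#'
#' All in angstroms: the 11 A DFG-Phe anchor rule, 3.6 A for the
#' Lys-Nz/Glu-Oe salt bridge, 3.6 A for the DFG6/XHRD backbone hydrogen
#' bond, 6 A (non-TYR) / 8 A (TYR) for the APE9-Ca/HRD-Arg-O contact, and
#' 5 A for an intact regulatory spine.
#'
#' @return List of cutoffs.
#' @export
default_cutoffs <- function() {
  list(
    dfg_anchor_cutoff = 11.0,
    saltbridge_cutoff = 3.6,
    actloop_nt_cutoff = 3.6,
    actloop_ct_cutoff_nontyr = 6.0,
    actloop_ct_cutoff_tyr = 8.0,
    spine_cutoff = 5.0
  )
}

#' Load cutoffs from a JSON file
#' @param path JSON object with any subset of the [default_cutoffs()] names.
#' @return Cutoff list (unnamed fields fall back to the defaults).
#' @export
read_cutoffs <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- default_cutoffs()
  for (nm in names(cfg)) out[[nm]] <- as.numeric(cfg[[nm]])
  stopifnot(all(unlist(out) > 0),
            out$actloop_ct_cutoff_tyr >= out$actloop_ct_cutoff_nontyr)
  out
}

# Surrogate for the DFG-Phe ring Cz when the DFG+1 residue is not Phe/Tyr:
# the heavy side-chain atom with the greatest bond-path distance from Cb,
# ties broken by atom-name order. Expressed as a priority list per residue
# type; unknown types fall back to a generic remoteness ranking.
.cz_surrogate <- list(
  PHE = c("CZ"), TYR = c("CZ"), TRP = c("CH2"), MET = c("CE"),
  LEU = c("CD1"), ILE = c("CD1"), VAL = c("CG1"), HIS = c("NE2"),
  GLN = c("NE2"), GLU = c("OE1"), LYS = c("NZ"), ARG = c("NH1"),
  ASN = c("ND2"), ASP = c("OD1"), THR = c("OG1"), SER = c("OG"),
  CYS = c("SG")
)
.generic_remoteness <- c("CB", "CG", "CG1", "CG2", "OG", "OG1", "SG",
                         "CD", "CD1", "CD2", "SD", "OD1", "OD2", "ND1",
                         "ND2", "CE", "CE1", "CE2", "CE3", "NE", "NE1",
                         "NE2", "OE1", "OE2", "CZ", "CZ2", "CZ3", "NZ",
                         "CH2", "NH1", "NH2", "OH")

.phe_tip_atom <- function(chain, ordinal) {
  a <- get_atom(chain, ordinal, "CZ")
  if (!is.null(a)) return(a)
  aa3 <- chain$residues$aa3[match(ordinal, chain$residues$ordinal)]
  cands <- .cz_surrogate[[aa3]]
  if (!is.null(cands)) {
    for (nm in cands) {
      a <- get_atom(chain, ordinal, nm)
      if (!is.null(a)) return(a)
    }
  }
  sc <- .side_chain_atoms(chain, ordinal)
  if (is.null(sc)) return(NULL)
  ranked <- intersect(rev(.generic_remoteness), rownames(sc))
  if (length(ranked) == 0) ranked <- sort(rownames(sc), decreasing = TRUE)
  get_atom(chain, ordinal, ranked[1])
}

# minimum heavy side-chain atom-pair distance between two residues; NA when
# either side chain is absent (e.g. Gly)
.min_sidechain_dist <- function(chain, o1, o2) {
  a <- .side_chain_atoms(chain, o1)
  b <- .side_chain_atoms(chain, o2)
  if (is.null(a) || is.null(b)) return(NA_real_)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Measure all active-state observables of an annotated chain
#'
#' Computes, from heavy atoms only, every distance and dihedral the
#' classification reads: the two DFG-Phe Cz anchor distances, the minimum
#' Lys-Nz/Glu-Oe salt-bridge distance, the minimum DFG6/XHRD backbone N-O
#' or O-N distance, the APE9-Ca to HRD-Arg carbonyl-O distance, the three
#' regulatory-spine distances, the XDFG backbone dihedrals and the DFG-Phe
#' chi1. Any missing atom or residue yields `NA` for that observable only.
#'
#' @param chain A `kin_chain`.
#' @param annotation A `kin_annotation` resolved against `chain`.
#' @param region_config Ramachandran/rotamer boundaries.
#' @return A `kin_geometry` list of observables.
#' @export
measure_geometry <- function(chain, annotation,
                             region_config = default_region_config()) {
  stopifnot(inherits(chain, "kin_chain"),
            inherits(annotation, "kin_annotation"))
  if (!is.null(annotation$dfg_d) &&
      !(annotation$dfg_d %in% chain$residues$ordinal)) {
    stop("annotation/chain mismatch: DFG ordinal absent from chain")
  }
  gx <- function(ordinal, name) {
    if (is.null(ordinal)) return(NULL)
    a <- get_atom(chain, ordinal, name)
    if (is.null(a)) NULL else a$xyz
  }
  dist_or_na <- function(p, q) {
    if (is.null(p) || is.null(q)) NA_real_ else vec_distance(p, q)
  }
  phe_tip <- if (!is.null(annotation$dfg_f))
    .phe_tip_atom(chain, annotation$dfg_f) else NULL
  phe_tip_xyz <- if (is.null(phe_tip)) NULL else phe_tip$xyz
  lys_ca <- gx(annotation$beta3_lys, "CA")
  glu4_ca <- gx(annotation$glu4, "CA")

  lys_nz <- gx(annotation$beta3_lys, "NZ")
  oe1 <- gx(annotation$chelix_glu, "OE1")
  oe2 <- gx(annotation$chelix_glu, "OE2")
  d_sb <- suppressWarnings(min(dist_or_na(lys_nz, oe1),
                               dist_or_na(lys_nz, oe2), na.rm = TRUE))
  if (!is.finite(d_sb)) d_sb <- NA_real_

  n6 <- gx(annotation$dfg6, "N"); o6 <- gx(annotation$dfg6, "O")
  nx <- gx(annotation$xhrd, "N"); ox <- gx(annotation$xhrd, "O")
  d_nt <- suppressWarnings(min(dist_or_na(n6, ox), dist_or_na(o6, nx),
                               na.rm = TRUE))
  if (!is.finite(d_nt)) d_nt <- NA_real_

  d_ct <- dist_or_na(gx(annotation$ape9, "CA"), gx(annotation$hrd_r, "O"))

  spine <- c(
    .min_sidechain_dist_or_na(chain, annotation$hrd_h, annotation$dfg_f),
    .min_sidechain_dist_or_na(chain, annotation$dfg_f, annotation$glu4),
    .min_sidechain_dist_or_na(chain, annotation$glu4, annotation$hpn7)
  )

  dihed <- lapply(c(x = annotation$xdfg, d = annotation$dfg_d,
                    f = annotation$dfg_f),
                  function(o) if (is.null(o)) c(phi = NA_real_, psi = NA_real_)
                              else residue_phi_psi(chain, o))
  chi1 <- if (is.null(annotation$dfg_f)) NA_real_ else
    residue_chi1(chain, annotation$dfg_f)

  structure(list(
    d_phe_lys = dist_or_na(phe_tip_xyz, lys_ca),
    d_phe_glu4 = dist_or_na(phe_tip_xyz, glu4_ca),
    d_saltbridge = d_sb,
    d_actloop_nt = d_nt,
    d_actloop_ct = d_ct,
    spine1 = spine[1], spine2 = spine[2], spine3 = spine[3],
    xdfg_dihedrals = dihed,
    phe_chi1 = chi1,
    phe_tip_atom = if (is.null(phe_tip)) NA_character_ else phe_tip$name
  ), class = "kin_geometry")
}

.min_sidechain_dist_or_na <- function(chain, o1, o2) {
  if (is.null(o1) || is.null(o2)) return(NA_real_)
  .min_sidechain_dist(chain, o1, o2)
}

#' Spatial (DFGin/DFGout/DFGinter) label from the two anchor distances
#'
#' DFGin: the DFG-Phe ring tip is near the C-helix Glu4 Ca (<= 11 A) and
#' far from the beta3 Lys Ca (>= 11 A). DFGout is the reverse; anything
#' else (including the doubly-degenerate 11/11 point) is DFGinter.
#'
#' @param d_phe_lys,d_phe_glu4 Distances in angstroms (`NA` allowed).
#' @param cutoffs See [default_cutoffs()].
#' @return `"DFGin"`, `"DFGout"`, `"DFGinter"` or `"unevaluable"`.
#' @export
spatial_label <- function(d_phe_lys, d_phe_glu4, cutoffs = default_cutoffs()) {
  if (is.na(d_phe_lys) || is.na(d_phe_glu4)) return("unevaluable")
  cz <- cutoffs$dfg_anchor_cutoff
  in_c <- d_phe_glu4 <= cz && d_phe_lys >= cz
  out_c <- d_phe_glu4 >= cz && d_phe_lys <= cz
  if (in_c && out_c) return("DFGinter")
  if (in_c) return("DFGin")
  if (out_c) return("DFGout")
  "DFGinter"
}

#' Dihedral label of the XDFG motif
#'
#' Concatenates the Ramachandran region letters of the X, D and F residues
#' with the DFG-Phe chi1 rotamer bin, e.g. `"BLAminus"` (the active state)
#' or `"ABAminus"` (the peptide-flipped state).
#'
#' @param x_region,d_region,f_region Region letters (`"B"`, `"A"`, `"L"`,
#'   `"E"`) or `NA`.
#' @param f_chi1_bin `"minus"`, `"plus"`, `"trans"` or `NA` (e.g. a Gly-like
#'   DFG-Phe position with no chi1).
#' @return Label string, or `"unevaluable"` when any component is missing.
#' @export
dihedral_label <- function(x_region, d_region, f_region, f_chi1_bin) {
  parts <- c(x_region, d_region, f_region, f_chi1_bin)
  if (any(is.na(parts)) || any(!nzchar(parts))) return("unevaluable")
  paste0(x_region, d_region, f_region, f_chi1_bin)
}

#' Per-criterion in/out states from measured observables
#'
#' All "in" decisions are strict (`<` the cutoff). The ActLoopCT cutoff is
#' family dependent (8 A for TYR kinases, 6 A otherwise). Exception-flagged
#' annotations return `"skipped"` for the corresponding criterion; `NA`
#' observables return `"unevaluable"`.
#'
#' @param report A `kin_geometry` from [measure_geometry()].
#' @param annotation A `kin_annotation` (for family and skip flags).
#' @param cutoffs See [default_cutoffs()].
#' @return Named list: `saltbridge`, `actloop_nt`, `actloop_ct`,
#'   `spine_intact`, `max_spine`.
#' @export
criterion_states <- function(report, annotation, cutoffs = default_cutoffs()) {
  sb <- if (isTRUE(annotation$skip_saltbridge)) "skipped"
        else if (is.na(report$d_saltbridge)) "unevaluable"
        else if (report$d_saltbridge < cutoffs$saltbridge_cutoff) "in" else "out"
  nt <- if (is.na(report$d_actloop_nt)) "unevaluable"
        else if (report$d_actloop_nt < cutoffs$actloop_nt_cutoff) "in" else "out"
  ct_cut <- if (identical(annotation$family, "TYR"))
    cutoffs$actloop_ct_cutoff_tyr else cutoffs$actloop_ct_cutoff_nontyr
  ct <- if (isTRUE(annotation$skip_actloopct)) "skipped"
        else if (is.na(report$d_actloop_ct)) "unevaluable"
        else if (report$d_actloop_ct < ct_cut) "in" else "out"
  spines <- c(report$spine1, report$spine2, report$spine3)
  spine <- if (any(is.na(spines))) "unevaluable"
           else if (max(spines) < cutoffs$spine_cutoff) "true" else "false"
  list(saltbridge = sb, actloop_nt = nt, actloop_ct = ct,
       spine_intact = spine,
       max_spine = if (any(is.na(spines))) NA_real_ else max(spines))
}

#' Classify the conformational and activity state of a kinase chain
#'
#' Composes [measure_geometry()], [spatial_label()], [dihedral_label()] and
#' [criterion_states()] into the five-criterion Active verdict:
#' `active = "true"` iff spatial is DFGin, the dihedral label is BLAminus,
#' the salt bridge is in (or skipped for exception genes), ActLoopNT is in
#' and ActLoopCT is in (or skipped). Any unevaluable required criterion
#' makes the verdict `"unevaluable"`. The regulatory spine is reported but
#' never affects the verdict.
#'
#' @param chain A `kin_chain`.
#' @param annotation A `kin_annotation`.
#' @param cutoffs See [default_cutoffs()].
#' @param region_config Ramachandran/rotamer boundaries.
#' @return A `kin_conformation`: list with `spatial`, `dihedral`,
#'   `saltbridge`, `actloop_nt`, `actloop_ct`, `spine_intact`, `active`,
#'   `report` (the `kin_geometry`), `max_spine` and `reasons` (one line per
#'   criterion with the measured value and cutoff).
#' @export
classify <- function(chain, annotation, cutoffs = default_cutoffs(),
                     region_config = default_region_config()) {
  report <- measure_geometry(chain, annotation, region_config)
  spatial <- spatial_label(report$d_phe_lys, report$d_phe_glu4, cutoffs)
  regions <- vapply(report$xdfg_dihedrals, function(pp) {
    if (any(is.na(pp))) NA_character_
    else rama_region(pp[["phi"]], pp[["psi"]], region_config)
  }, character(1))
  chi_bin <- if (is.na(report$phe_chi1)) NA_character_
             else chi1_rotamer(report$phe_chi1, region_config$chi1_edges)
  dihed <- dihedral_label(regions[["x"]], regions[["d"]], regions[["f"]],
                          chi_bin)
  st <- criterion_states(report, annotation, cutoffs)

  crit <- c(
    spatial = if (spatial == "unevaluable") NA else spatial == "DFGin",
    dihedral = if (dihed == "unevaluable") NA else dihed == "BLAminus",
    saltbridge = if (st$saltbridge == "unevaluable") NA
                 else st$saltbridge %in% c("in", "skipped"),
    actloop_nt = if (st$actloop_nt == "unevaluable") NA
                 else st$actloop_nt == "in",
    actloop_ct = if (st$actloop_ct == "unevaluable") NA
                 else st$actloop_ct %in% c("in", "skipped")
  )
  active <- if (any(is.na(crit))) "unevaluable"
            else if (all(crit)) "true" else "false"

  fmt <- function(x, digits = 2) {
    if (is.na(x)) "NA" else formatC(x, format = "f", digits = digits)
  }
  ct_cut <- if (identical(annotation$family, "TYR"))
    cutoffs$actloop_ct_cutoff_tyr else cutoffs$actloop_ct_cutoff_nontyr
  reasons <- c(
    paste0("spatial=", spatial, " (PheTip-LysCA ", fmt(report$d_phe_lys),
           " A, PheTip-Glu4CA ", fmt(report$d_phe_glu4), " A, cutoff ",
           cutoffs$dfg_anchor_cutoff, " A)"),
    paste0("dihedral=", dihed),
    paste0("saltbridge=", st$saltbridge, " (", fmt(report$d_saltbridge),
           " A, cutoff ", cutoffs$saltbridge_cutoff, " A)"),
    paste0("actloop_nt=", st$actloop_nt, " (", fmt(report$d_actloop_nt),
           " A, cutoff ", cutoffs$actloop_nt_cutoff, " A)"),
    paste0("actloop_ct=", st$actloop_ct, " (", fmt(report$d_actloop_ct),
           " A, cutoff ", ct_cut, " A)"),
    paste0("spine_intact=", st$spine_intact, " (max spine ",
           fmt(st$max_spine), " A, cutoff ", cutoffs$spine_cutoff,
           " A; reported only, not a verdict criterion)")
  )
  structure(list(
    entry_id = chain$entry_id, chain_id = chain$chain_id,
    spatial = spatial, dihedral = dihed,
    saltbridge = st$saltbridge, actloop_nt = st$actloop_nt,
    actloop_ct = st$actloop_ct, spine_intact = st$spine_intact,
    max_spine = st$max_spine, active = active,
    report = report, reasons = reasons
  ), class = "kin_conformation")
}

#' @export
print.kin_conformation <- function(x, ...) {
  cat("<kin_conformation> ", x$entry_id, " chain ", x$chain_id, "\n",
      sep = "")
  cat("  active: ", x$active, "\n  ", sep = "")
  cat(paste(x$reasons, collapse = "\n  "), "\n")
  invisible(x)
}

#' One-row data frame summary of a classification
#' @param x A `kin_conformation`.
#' @param ... Unused.
#' @return data.frame with the TSV-report columns.
#' @method as.data.frame kin_conformation
#' @export
as.data.frame.kin_conformation <- function(x, ...) {
  r <- x$report
  data.frame(
    entry = x$entry_id, chain = x$chain_id, spatial = x$spatial,
    dihedral = x$dihedral,
    saltbr_dist = r$d_saltbridge, saltbr = x$saltbridge,
    nt_dist = r$d_actloop_nt, nt = x$actloop_nt,
    ct_dist = r$d_actloop_ct, ct = x$actloop_ct,
    spine1 = r$spine1, spine2 = r$spine2, spine3 = r$spine3,
    spine_intact = x$spine_intact, active = x$active,
    reasons = paste(x$reasons, collapse = "; "),
    stringsAsFactors = FALSE
  )
}
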