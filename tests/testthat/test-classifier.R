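test_that("the spatial label follows the 11 A two-anchor rule", {
  expect_equal(spatial_label(12.0, 9.0), "DFGin")
  expect_equal(spatial_label(9.0, 14.0), "DFGout")
  expect_equal(spatial_label(9.0, 9.0), "DFGinter")
  expect_equal(spatial_label(14.0, 14.0), "DFGinter")
  # boundary semantics: the anchor tests are inclusive, the doubly
  # degenerate point is DFGinter, and missing distances are unevaluable
  expect_equal(spatial_label(11.0, 9.0), "DFGin")
  expect_equal(spatial_label(12.0, 11.0), "DFGin")
  expect_equal(spatial_label(11.0, 11.0), "DFGinter")
  expect_equal(spatial_label(NA, 9.0), "unevaluable")
})

test_that("the dihedral label is the region/rotamer concatenation", {
  expect_equal(dihedral_label("B", "L", "A", "minus"), "BLAminus")
  expect_equal(dihedral_label("A", "B", "A", "minus"), "ABAminus")
  expect_equal(dihedral_label("B", "L", "A", "plus"), "BLAplus")
  expect_equal(dihedral_label("B", "L", NA, "minus"), "unevaluable")
  expect_equal(dihedral_label("B", "L", "A", NA), "unevaluable")
})

test_that("criterion states use strict cutoffs and the TYR-specific contact", {
  mkrep <- function(...) {
    r <- list(d_saltbridge = NA, d_actloop_nt = NA, d_actloop_ct = NA,
              spine1 = NA, spine2 = NA, spine3 = NA)
    r[names(list(...))] <- list(...)
    structure(r, class = "kin_geometry")
  }
  ann <- structure(list(family = "AGC", skip_saltbridge = FALSE,
                        skip_actloopct = FALSE), class = "kin_annotation")
  st <- criterion_states(mkrep(d_saltbridge = 3.0), ann)
  expect_equal(st$saltbridge, "in")
  # exactly at the cutoff is out (strict inequality)
  expect_equal(criterion_states(mkrep(d_saltbridge = 3.6), ann)$saltbridge,
               "out")
  expect_equal(criterion_states(mkrep(d_actloop_nt = 3.59), ann)$actloop_nt,
               "in")
  # 7.3 A APE9 contact: in for TYR kinases, out otherwise
  ann_tyr <- ann; ann_tyr$family <- "TYR"
  expect_equal(criterion_states(mkrep(d_actloop_ct = 7.3),
                                ann_tyr)$actloop_ct, "in")
  expect_equal(criterion_states(mkrep(d_actloop_ct = 7.3), ann)$actloop_ct,
               "out")
  # skip flags and unevaluable observables
  ann_skip <- ann; ann_skip$skip_saltbridge <- TRUE
  expect_equal(criterion_states(mkrep(), ann_skip)$saltbridge, "skipped")
  expect_equal(criterion_states(mkrep(), ann)$saltbridge, "unevaluable")
  sp <- criterion_states(mkrep(spine1 = 3.9, spine2 = 4.2, spine3 = 4.9),
                         ann)
  expect_equal(sp$spine_intact, "true")
  expect_equal(sp$max_spine, 4.9)
  expect_equal(criterion_states(mkrep(spine1 = 3.9, spine2 = 5.6,
                                      spine3 = 4.0), ann)$spine_intact,
               "false")
})

test_that("measured observables use the minimum-pair rules", {
  fx <- make_kinase_fixture()
  g <- measure_geometry(fx$chain, fx$annotation)
  # salt bridge takes the shorter of the two carboxylate oxygens
  nz <- get_atom(fx$chain, fx$annotation$beta3_lys, "NZ")$xyz
  oe1 <- get_atom(fx$chain, fx$annotation$chelix_glu, "OE1")$xyz
  oe2 <- get_atom(fx$chain, fx$annotation$chelix_glu, "OE2")$xyz
  expect_equal(g$d_saltbridge,
               min(vec_distance(nz, oe1), vec_distance(nz, oe2)))
  # ActLoopNT takes the minimum of the N-O and O-N backbone pairings
  n6 <- get_atom(fx$chain, fx$annotation$dfg6, "N")$xyz
  o6 <- get_atom(fx$chain, fx$annotation$dfg6, "O")$xyz
  nx <- get_atom(fx$chain, fx$annotation$xhrd, "N")$xyz
  ox <- get_atom(fx$chain, fx$annotation$xhrd, "O")$xyz
  expect_equal(g$d_actloop_nt,
               min(vec_distance(n6, ox), vec_distance(o6, nx)))
  expect_equal(g$phe_tip_atom, "CZ")
})

test_that("a fixture built to the active geometry classifies as active", {
  fx <- make_kinase_fixture()
  cl <- classify(fx$chain, fx$annotation)
  expect_equal(cl$spatial, "DFGin")
  expect_equal(cl$dihedral, "BLAminus")
  expect_equal(cl$saltbridge, "in")
  expect_equal(cl$actloop_nt, "in")
  expect_equal(cl$actloop_ct, "in")
  expect_equal(cl$active, "true")
})

test_that("breaking one criterion flips the verdict and names the criterion", {
  fx <- make_kinase_fixture(default_fixture_spec(d_saltbridge = 8))
  cl <- classify(fx$chain, fx$annotation)
  expect_equal(cl$active, "false")
  expect_equal(cl$saltbridge, "out")
  expect_match(cl$reasons[grepl("saltbridge", cl$reasons)], "out")
  fx2 <- make_kinase_fixture(default_fixture_spec(d_actloop_ct = 10.5))
  expect_equal(classify(fx2$chain, fx2$annotation)$active, "false")
  fx3 <- make_kinase_fixture(default_fixture_spec(d_phe_lys = 9,
                                                  d_phe_glu4 = 14))
  expect_equal(classify(fx3$chain, fx3$annotation)$spatial, "DFGout")
})

test_that("exception genes skip their criterion and can still be active", {
  fx <- make_kinase_fixture(default_fixture_spec(
    gene_label = "OTHER_WNK1", family = "OTHER", d_saltbridge = 8))
  cl <- classify(fx$chain, fx$annotation)
  expect_equal(cl$saltbridge, "skipped")
  expect_equal(cl$active, "true")
})

test_that("missing coordinates give unevaluable, never out or false", {
  fx <- make_kinase_fixture()
  # delete the DFG6 residue entirely (disordered in the crystal); the
  # numbering gap makes the derived position unresolvable on re-annotation
  dfg6_resno <- fx$chain$residues$resno[
    fx$chain$residues$ordinal == fx$annotation$dfg6]
  s2 <- fx$structure
  s2$atoms <- s2$atoms[s2$atoms$resno != dfg6_resno, ]
  ch2 <- select_chain(s2, "A")
  ann2 <- annotate_from_config(ch2, list(
    family = fx$spec$family, gene_label = fx$spec$gene_label,
    anchors = fx$spec$anchors))
  expect_null(ann2$dfg6)
  cl <- classify(ch2, ann2)
  expect_equal(cl$actloop_nt, "unevaluable")
  expect_equal(cl$active, "unevaluable")
  # a Gly-like DFG-Phe with no chi1 makes the dihedral label unevaluable
  s3 <- fx$structure
  phe_resno <- fx$chain$residues$resno[
    fx$chain$residues$ordinal == fx$annotation$dfg_f]
  s3$atoms <- s3$atoms[!(s3$atoms$resno == phe_resno &
                           s3$atoms$elety %in% c("CB", "CG")), ]
  cl3 <- classify(select_chain(s3, "A"), fx$annotation)
  expect_equal(cl3$dihedral, "unevaluable")
  expect_equal(cl3$active, "unevaluable")
})

test_that("a broken spine does not affect the active verdict", {
  fx <- make_kinase_fixture(default_fixture_spec(spine = c(6.5, 6.5, 6.5)))
  cl <- classify(fx$chain, fx$annotation)
  expect_equal(cl$spine_intact, "false")
  expect_equal(cl$active, "true")
})

test_that("criterion states are monotone: shrinking a distance never flips in to out", {
  ann <- structure(list(family = "CAMK", skip_saltbridge = FALSE,
                        skip_actloopct = FALSE), class = "kin_annotation")
  mkrep <- function(d) structure(
    list(d_saltbridge = d, d_actloop_nt = d, d_actloop_ct = d,
         spine1 = NA, spine2 = NA, spine3 = NA), class = "kin_geometry")
  lvl <- c(out = 0, `in` = 1)
  prev <- c(-Inf, -Inf, -Inf)
  for (d in seq(12, 0.5, by = -0.5)) {
    st <- criterion_states(mkrep(d), ann)
    cur <- lvl[c(st$saltbridge, st$actloop_nt, st$actloop_ct)]
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("an active verdict always implies the BLAminus dihedral label", {
  set.seed(42)
  holds <- logical(0)
  for (i in 1:25) {
    rs <- random_regime_spec()
    fx <- make_kinase_fixture(rs$spec)
    cl <- classify(fx$chain, fx$annotation)
    holds <- c(holds, cl$active != "true" || cl$dihedral == "BLAminus")
  }
  expect_true(all(holds))
  # and a guaranteed-active case exercises the implication non-vacuously
  fx_act <- make_kinase_fixture()
  cl_act <- classify(fx_act$chain, fx_act$annotation)
  expect_equal(cl_act$active, "true")
  expect_equal(cl_act$dihedral, "BLAminus")
})

test_that("classification is invariant under rigid transforms of the chain", {
  fx <- make_kinase_fixture()
  cl0 <- classify(fx$chain, fx$annotation)
  set.seed(99)
  for (i in 1:10) {
    s2 <- transform_structure(fx$structure, random_rigid_transform())
    cl <- classify(select_chain(s2, "A"), fx$annotation)
    expect_equal(cl$active, cl0$active)
    expect_equal(cl$dihedral, cl0$dihedral)
    expect_equal(cl$spatial, cl0$spatial)
    expect_equal(cl$report$d_saltbridge, cl0$report$d_saltbridge,
                 tolerance = 1e-9)
  }
})

test_that("classification reports flatten to the documented table row", {
  fx <- make_kinase_fixture()
  df <- as.data.frame(classify(fx$chain, fx$annotation))
  expect_equal(df$active, "true")
  expect_named(df, c("entry", "chain", "spatial", "dihedral", "saltbr_dist",
                     "saltbr", "nt_dist", "nt", "ct_dist", "ct", "spine1",
                     "spine2", "spine3", "spine_intact", "active",
                     "reasons"))
})

test_that("cutoff configs load from JSON with defaults for absent fields", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(saltbridge_cutoff = 4.0), f, auto_unbox = TRUE)
  cut <- read_cutoffs(f)
  expect_equal(cut$saltbridge_cutoff, 4.0)
  expect_equal(cut$dfg_anchor_cutoff, 11.0)
  expect_equal(cut$actloop_ct_cutoff_tyr, 8.0)
  # the packaged config files mirror the in-code defaults exactly
  expect_equal(read_cutoffs(system.file("extdata", "default_cutoffs.json",
                                        package = "kinactive")),
               default_cutoffs())
  rc <- read_region_config(system.file("extdata", "region_config.json",
                                       package = "kinactive"))
  expect_equal(rc$chi1_edges, default_region_config()$chi1_edges)
  expect_equal(rc$B$psi_hi, default_region_config()$B$psi_hi)
})
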